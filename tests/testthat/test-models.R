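# MLP and shallow neural decision forest

test_that("an all-zero MLP scores every row at 0.5 and maps rows independently", {
  cfg <- mlp_config(input_dim = 7, n_hidden = 4)
  m <- model_init(cfg, seed = 1)
  m <- unflatten_params(m, rep(0, length(m$params)))
  X <- rand_X(6, 7, seed = 2)
  expect_equal(predict(m, X), rep(0.5, 6))
  # row-order invariance of a trained model
  m2 <- model_init(cfg, seed = 3)
  s <- predict(m2, X)
  expect_equal(predict(m2, X[6:1, ]), s[6:1])
  expect_error(predict(m2, X[, 1:5]), "dimension mismatch")
})

test_that("sNDF with zero split activations routes uniformly", {
  cfg <- sndf_config(input_dim = 4, n_trees = 1, depth = 1, feature_rate = 1)
  m <- model_init(cfg, seed = 5)
  m$params[] <- 0
  # leaves pinned to (1,0) and (0,1) through extreme logits
  m <- unflatten_params(m, replace(m$params,
                                   fedvariant:::layout_idx(m$layout, "leaf_logits"),
                                   c(30, -30, -30, 30)))
  out <- sndf_forward(m, rand_X(3, 4, seed = 6))
  expect_equal(out, matrix(0.5, 3, 2), tolerance = 1e-9)
})

test_that("leaf reach probabilities always sum to one per tree", {
  for (seed in 1:5) {
    cfg <- sndf_config(input_dim = 6, n_trees = 3, depth = 4, feature_rate = 0.7)
    m <- model_init(cfg, seed = seed)
    fw <- fedvariant:::sndf_forward_full(m, rand_X(8, 6, seed = seed + 50))
    for (t in 1:3) {
      expect_lt(max(abs(rowSums(fw$caches[[t]]$leaf_reach) - 1)), 1e-9)
    }
    # outputs are probability vectors
    expect_equal(rowSums(fw$probs), rep(1, 8), tolerance = 1e-12)
    expect_true(all(fw$probs >= 0))
  }
})

test_that("a depth-2 tree equals the brute-force sum over its four root-leaf paths", {
  cfg <- sndf_config(input_dim = 3, n_trees = 1, depth = 2, feature_rate = 1)
  m <- model_init(cfg, seed = 9)
  X <- rand_X(5, 3, seed = 10)
  W <- matrix(fedvariant:::seg_get(m, "W"), 3, 3)
  b <- fedvariant:::seg_get(m, "b")
  pi_t <- fedvariant:::sndf_leaf_dists(m)[[1]]
  f <- sweep(X %*% W, 2, b, "+")
  d <- 1 / (1 + exp(-f))  # routing at nodes 1..3 (root, left, right)
  brute <- matrix(0, 5, 2)
  for (i in 1:5) {
    reach <- c(d[i, 1] * d[i, 2],            # leaf 1: left, left
               d[i, 1] * (1 - d[i, 2]),      # leaf 2: left, right
               (1 - d[i, 1]) * d[i, 3],      # leaf 3: right, left
               (1 - d[i, 1]) * (1 - d[i, 3]))# leaf 4: right, right
    brute[i, ] <- colSums(reach * pi_t)
  }
  expect_equal(sndf_forward(m, X), brute, tolerance = 1e-12)
})

test_that("a forest of identical trees equals its single tree", {
  cfg1 <- sndf_config(input_dim = 5, n_trees = 1, depth = 3, feature_rate = 1)
  cfg3 <- sndf_config(input_dim = 5, n_trees = 3, depth = 3, feature_rate = 1)
  m1 <- model_init(cfg1, seed = 12)
  m3 <- model_init(cfg3, seed = 12)
  S <- cfg1$n_splits; L <- cfg1$n_leaves
  W1 <- matrix(fedvariant:::seg_get(m1, "W"), 5, S)
  m3 <- fedvariant:::seg_set(m3, "W", cbind(W1, W1, W1))
  m3 <- fedvariant:::seg_set(m3, "b", rep(fedvariant:::seg_get(m1, "b"), 3))
  m3 <- fedvariant:::seg_set(m3, "leaf_logits",
                             rep(fedvariant:::seg_get(m1, "leaf_logits"), 3))
  m3$masks <- m1$masks[, c(1, 1, 1)]
  X <- rand_X(7, 5, seed = 13)
  expect_equal(sndf_forward(m3, X), sndf_forward(m1, X), tolerance = 1e-12)
})

test_that("analytic gradients match central finite differences", {
  fd_check <- function(model, X, y, loss_grad, active) {
    lg <- loss_grad(model, X, y)
    h <- 1e-5
    worst <- 0
    for (i in active) {
      mp <- model; mp$params[i] <- mp$params[i] + h
      mm <- model; mm$params[i] <- mm$params[i] - h
      fd <- (loss_grad(mp, X, y)$loss - loss_grad(mm, X, y)$loss) / (2 * h)
      worst <- max(worst, abs(fd - lg$grad[i]) / max(abs(fd), 1e-6))
    }
    worst
  }
  # MLP, with and without batch normalisation
  for (bn in c(FALSE, TRUE)) {
    cfg <- mlp_config(6, 4, use_batch_norm = bn)
    m <- model_init(cfg, seed = 21)
    X <- rand_X(5, 6, seed = 22); y <- c(1, 0, 1, 1, 0)
    act <- which(fedvariant:::trainable_mask(m$layout))
    expect_lt(fd_check(m, X, y, function(mo, X, y)
      fedvariant:::mlp_loss_grad(mo, X, y, training = TRUE), act), 1e-4)
  }
  # sNDF on a 3-sample batch; mask-frozen weights are structurally excluded
  cfg <- sndf_config(6, n_trees = 2, depth = 2, feature_rate = 0.8)
  m <- model_init(cfg, seed = 23)
  X <- rand_X(3, 6, seed = 24); y <- c(1, 0, 1)
  mask_w <- as.vector(vapply(seq_len(cfg$n_trees), function(t)
    matrix(m$masks[, t], cfg$input_dim, cfg$n_splits),
    matrix(TRUE, cfg$input_dim, cfg$n_splits)))
  active <- c(fedvariant:::layout_idx(m$layout, "W")[mask_w],
              fedvariant:::layout_idx(m$layout, "b"),
              fedvariant:::layout_idx(m$layout, "leaf_logits"))
  expect_lt(fd_check(m, X, y, function(mo, X, y)
    fedvariant:::sndf_loss_grad(mo, X, y), active), 1e-4)
})

test_that("flat parameter vectors round-trip and reject layout mismatches", {
  cfg <- sndf_config(5, n_trees = 2, depth = 2, feature_rate = 0.9)
  m <- model_init(cfg, seed = 31)
  v <- flatten_params(m)
  expect_identical(unflatten_params(m, v)$params, m$params)
  set.seed(32)
  v2 <- rnorm(length(v))
  expect_equal(flatten_params(unflatten_params(m, v2)), v2,
               ignore_attr = TRUE)
  expect_error(unflatten_params(m, v[-1]), "layout mismatch")
})

test_that("local training is deterministic and leaves its input untouched", {
  fx <- make_snv_fixture(silo_sizes = c(a = 30, b = 30), seed = 41, test1_n = 4)
  cfg <- mlp_config(60, 4)
  m0 <- model_init(cfg, seed = 42)
  before <- m0$params
  lc <- local_train_config(0.05, "sgd", batch_size = 8, epochs = 3)
  t1 <- local_train(m0, fx$Xs, fx$fm$y, lc, seed = 43)
  t2 <- local_train(m0, fx$Xs, fx$fm$y, lc, seed = 43)
  expect_identical(t1$params, t2$params)
  expect_identical(m0$params, before)
  expect_false(identical(t1$params, before))
  expect_error(local_train(m0, fx$Xs[0, , drop = FALSE], integer(0), lc, 1),
               "empty")
  # leaf distributions remain valid probability vectors after training
  ms <- model_init(sndf_config(60, 2, 2, 0.8), seed = 44)
  ts <- local_train(ms, fx$Xs, fx$fm$y, local_train_config(0.1, "adam", 8, 2),
                    seed = 45)
  for (pi_t in fedvariant:::sndf_leaf_dists(ts)) {
    expect_equal(rowSums(pi_t), rep(1, nrow(pi_t)), tolerance = 1e-12)
    expect_true(all(pi_t >= 0))
  }
})

test_that("the proximal term pulls parameters toward the anchor as mu grows", {
  fx <- make_snv_fixture(silo_sizes = c(a = 30, b = 30), seed = 51, test1_n = 4)
  cfg <- mlp_config(60, 4)
  m0 <- model_init(cfg, seed = 52)
  anchor <- m0$params
  # sweep mu over decades inside the SGD stability region (lr * mu << 1;
  # beyond it the proximal force itself makes fixed-step SGD diverge)
  lc0 <- local_train_config(0.001, "sgd", batch_size = 8, epochs = 2)
  gaps <- vapply(c(0, 1, 10, 100), function(mu) {
    lc <- lc0; lc$proximal_mu <- mu
    tr <- local_train(m0, fx$Xs, fx$fm$y, lc, seed = 53, anchor = anchor)
    max(abs(tr$params - anchor))
  }, numeric(1))
  expect_true(all(diff(gaps) < 0))            # monotone shrinkage over decades
  expect_lt(gaps[4], 0.15 * gaps[1])          # strong mu: pulled to the anchor
  # mu = 0 must coincide exactly with plain local training
  lc0 <- local_train_config(0.05, "sgd", batch_size = 8, epochs = 2)
  tr0 <- local_train(m0, fx$Xs, fx$fm$y, lc0, seed = 53)
  lcp <- lc0; lcp$proximal_mu <- 0
  trp <- local_train(m0, fx$Xs, fx$fm$y, lcp, seed = 53, anchor = anchor)
  expect_identical(tr0$params, trp$params)
  expect_error(local_train(m0, fx$Xs, fx$fm$y,
                           local_train_config(0.05, proximal_mu = 1), seed = 1),
               "anchor")
})

test_that("a trained MLP separates the separable synthetic cohort", {
  fx <- make_snv_fixture(silo_sizes = c(a = 150, b = 150), class_sep = 3,
                         seed = 61, test1_n = 100)
  m <- model_init(mlp_config(60, 6), seed = 62)
  tr <- local_train(m, fx$Xs, fx$fm$y, local_train_config(0.05, "sgd", 32, 10),
                    seed = 63)
  expect_gt(auc_roc(predict(tr, fx$test1$X), fx$test1$y), 0.95)
})
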