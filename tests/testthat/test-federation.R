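# Federated aggregation and the training loop

test_that("client sampling respects the rate with round-half-up and a floor of 1", {
  ids8 <- paste0("c", 1:8)
  expect_setequal(sample_clients(ids8, 1.0, seed = 1), ids8)
  expect_length(sample_clients(ids8, 0.5, seed = 2), 4)
  expect_length(sample_clients(paste0("c", 1:7), 0.5, seed = 3), 4)  # 3.5 -> 4
  expect_length(sample_clients(ids8, 0.01, seed = 4), 1)
  expect_identical(sample_clients(ids8, 0.5, seed = 5),
                   sample_clients(ids8, 0.5, seed = 5))
  expect_error(sample_clients(character(0), 0.5, seed = 1), "empty")
})

test_that("weighted-mean aggregation matches its definition", {
  u <- function(p, n, id) list(params = p, n_samples = n, client_id = id)
  expect_equal(aggregate_weighted_mean(list(u(1.0, 1, "a"), u(3.0, 3, "b"))), 2.5)
  # fixed point on identical updates
  v <- c(0.2, -1, 4)
  expect_equal(aggregate_weighted_mean(list(u(v, 5, "a"), u(v, 9, "b"))), v)
  # independent elementwise recomputation with explicit loops
  set.seed(6)
  ups <- lapply(1:3, function(i) u(rnorm(7), sample(1:20, 1), paste0("c", i)))
  manual <- numeric(7)
  tot <- sum(vapply(ups, `[[`, numeric(1), "n_samples"))
  for (up in ups) for (j in 1:7)
    manual[j] <- manual[j] + up$n_samples / tot * up$params[j]
  expect_equal(aggregate_weighted_mean(ups), manual)
  expect_error(aggregate_weighted_mean(list(u(1:3, 2, "a"), u(1:2, 2, "b"))),
               "layout mismatch")
})

test_that("adaptive server recursions match hand-unrolled scalar oracles", {
  deltas <- c(0.3, -0.2, 0.5)
  eta <- 0.1; tau <- 0.01; b1 <- 0.9; b2 <- 0.999
  for (alg in c("fedadagrad", "fedadam", "fedyogi")) {
    cfg <- aggregator_config(alg, server_lr = eta, tau = tau, n_rounds = 3)
    state <- server_state_init(1, tau)
    w <- 0
    # package path: feed client updates whose delta is the scripted sequence
    for (d in deltas) {
      up <- server_update_adaptive(w, state, list(list(params = w + d,
                                                       n_samples = 1,
                                                       client_id = "c")), cfg)
      w <- up$global_params; state <- up$state
    }
    # oracle: plain arithmetic unroll of the published recursions
    m <- 0; v <- tau^2; wo <- 0
    for (d in deltas) {
      if (alg == "fedadagrad") { m <- d; v <- v + d^2 }
      else if (alg == "fedadam") { m <- b1 * m + (1 - b1) * d; v <- b2 * v + (1 - b2) * d^2 }
      else { m <- b1 * m + (1 - b1) * d; v <- v - (1 - b2) * d^2 * sign(v - d^2) }
      wo <- wo + eta * m / (sqrt(v) + tau)
    }
    expect_equal(w, wo, tolerance = 1e-12, label = alg)
  }
})

test_that("a zero aggregated delta leaves the global model unchanged", {
  for (alg in c("fedadagrad", "fedadam", "fedyogi")) {
    cfg <- aggregator_config(alg, server_lr = 0.5, tau = 0.01)
    state <- server_state_init(3, 0.01)
    w <- c(1, -2, 0.5)
    up <- server_update_adaptive(w, state,
                                 list(list(params = w, n_samples = 4,
                                           client_id = "c")), cfg)
    expect_equal(up$global_params, w)
  }
})

test_that("Yogi and Adam nearly coincide on the first step when v0 < delta^2", {
  # algebraically: adam v1 = v0 + (1-b2)(d^2 - v0), yogi v1 = v0 + (1-b2) d^2;
  # they differ by (1-b2) v0 = (1-b2) tau^2, negligible for small tau
  tau <- 1e-4; d <- 0.5
  out <- lapply(c("fedadam", "fedyogi"), function(alg) {
    cfg <- aggregator_config(alg, server_lr = 0.1, tau = tau)
    server_update_adaptive(0, server_state_init(1, tau),
                           list(list(params = d, n_samples = 1,
                                     client_id = "c")), cfg)$global_params
  })
  expect_equal(out[[1]], out[[2]], tolerance = 1e-6)
})

test_that("FedProx with mu = 0 under SGD reproduces the FedAvg trajectory", {
  fx <- make_snv_fixture(silo_sizes = c(a = 40, b = 30), seed = 71, test1_n = 10)
  mc <- mlp_config(60, 3)
  lc <- local_train_config(0.05, "sgd", batch_size = 16, epochs = 2)
  favg <- run_federated_training(fx$clients, mc, lc,
                                 aggregator_config("fedavg", n_rounds = 3),
                                 seed = 72)
  fprox <- run_federated_training(fx$clients, mc, lc,
                                  aggregator_config("fedprox", proximal_mu = 0,
                                                    n_rounds = 3),
                                  seed = 72)
  expect_identical(favg$model$params, fprox$model$params)
  # and a positive mu departs from it
  fprox2 <- run_federated_training(fx$clients, mc, lc,
                                   aggregator_config("fedprox", proximal_mu = 0.5,
                                                     n_rounds = 3),
                                   seed = 72)
  expect_false(identical(favg$model$params, fprox2$model$params))
})

test_that("single-client full-participation FedAvg equals centralized training", {
  fx <- make_snv_fixture(silo_sizes = c(a = 40, b = 30), seed = 81, test1_n = 10)
  pooled <- list(X = do.call(rbind, lapply(fx$clients, `[[`, "X")),
                 y = unlist(lapply(fx$clients, `[[`, "y"), use.names = FALSE))
  mc <- mlp_config(60, 3)
  lc <- local_train_config(0.05, "sgd", batch_size = 16, epochs = 2)
  fed <- run_federated_training(list(pooled), mc, lc,
                                aggregator_config("fedavg", client_rate = 1,
                                                  n_rounds = 4),
                                seed = 82)
  cds <- run_centralized_training(pooled$X, pooled$y, mc, lc, seed = 82,
                                  n_rounds = 4)
  expect_identical(fed$model$params, cds$model$params)
})

test_that("federated runs are deterministic and log one row per round", {
  fx <- make_snv_fixture(silo_sizes = c(a = 30, b = 30, c = 30), seed = 91,
                         test1_n = 10)
  mc <- mlp_config(60, 3)
  lc <- local_train_config(0.05, "sgd", batch_size = 16, epochs = 1)
  ag <- aggregator_config("fedadam", client_rate = 0.5, n_rounds = 6)
  r1 <- run_federated_training(fx$clients, mc, lc, ag, seed = 92)
  r2 <- run_federated_training(fx$clients, mc, lc, ag, seed = 92)
  expect_identical(r1$model$params, r2$model$params)
  expect_identical(r1$history, r2$history)
  expect_equal(nrow(r1$history), 6)
  expect_true(all(r1$history$n_selected == 2))  # round_half_up(0.5 * 3)
  # without early stopping the loop runs to its configured horizon
  ag200 <- aggregator_config("fedavg", n_rounds = 200)
  tiny <- list(s = list(X = rand_X(4, 2, seed = 93), y = c(0, 1, 0, 1)))
  run <- run_federated_training(tiny, mlp_config(2, 2),
                                local_train_config(0.01, "sgd", 4, epochs = 1),
                                ag200, seed = 94)
  expect_equal(nrow(run$history), 200)
})

test_that("early stopping returns the best-round model within patience", {
  fx <- make_snv_fixture(silo_sizes = c(a = 40, b = 40), seed = 101, test1_n = 60)
  mc <- mlp_config(60, 4)
  lc <- local_train_config(0.05, "sgd", batch_size = 16, epochs = 2)
  ag <- aggregator_config("fedavg", n_rounds = 50)
  eval_fn <- function(model) auc_roc(predict(model, fx$test1$X), fx$test1$y)
  run <- run_federated_training(fx$clients, mc, lc, ag, seed = 102,
                                eval_fn = eval_fn, patience = 3)
  expect_lt(nrow(run$history), 50)            # stopped before the horizon
  expect_equal(nrow(run$history), run$best_round + 3)
  # the returned model is the best round's snapshot
  expect_equal(eval_fn(run$model), max(run$history$metric))
})

test_that("keep-local batch-norm policy excludes BN state from exchange", {
  fx <- make_snv_fixture(silo_sizes = c(a = 40, b = 30), seed = 111, test1_n = 10)
  mc <- mlp_config(60, 4, use_batch_norm = TRUE)
  lc <- local_train_config(0.05, "sgd", batch_size = 16, epochs = 1)
  keep <- run_federated_training(fx$clients, mc, lc,
                                 aggregator_config("fedavg", n_rounds = 2,
                                                   bn_policy = "keep_local"),
                                 seed = 112)
  agg <- run_federated_training(fx$clients, mc, lc,
                                aggregator_config("fedavg", n_rounds = 2,
                                                  bn_policy = "aggregate"),
                                seed = 112)
  init <- model_init(mc, derive_seed(112, 0L))
  bn_stats <- c(fedvariant:::layout_idx(init$layout, "bn_mean"),
                fedvariant:::layout_idx(init$layout, "bn_var"))
  # with keep_local the global BN statistics never move off initialisation;
  # with aggregation they absorb the clients' batch moments
  expect_identical(keep$model$params[bn_stats], init$params[bn_stats])
  expect_false(identical(agg$model$params[bn_stats], init$params[bn_stats]))
})

test_that("client failures propagate with client attribution", {
  clients <- list(good = list(X = rand_X(8, 3, seed = 121), y = rep(0:1, 4)),
                  broken = list(X = rand_X(0, 3, seed = 122), y = integer(0)))
  expect_error(
    run_federated_training(clients, mlp_config(3, 2),
                           local_train_config(0.01, "sgd", 4, epochs = 1),
                           aggregator_config("fedavg", n_rounds = 1), seed = 123),
    "broken")
})
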