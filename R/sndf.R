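# Shallow Neural Decision Forest ----------------------------------------------
#
# Each tree is a full binary tree of depth `depth`: 2^depth - 1 split nodes and
# 2^depth leaves. A fully connected layer maps the input x to one activation
# f_n per split node; the routing probability at node n is d_n(x) = sigmoid(f_n(x))
# (probability of taking the left child). A sample's probability of reaching
# leaf l is the product of routing probabilities along the root-to-leaf path,
# and the tree's prediction is the reach-probability-weighted mixture of the
# leaf class distributions pi_l. The forest prediction is the average over
# trees. Leaf distributions are parameterised as unconstrained logits mapped
# through a row-wise softmax, so every gradient step keeps each pi_l a valid
# probability vector and all trainable state lives in one flat vector, as
# federated exchange requires. Per-tree feature subsetting (rate
# `feature_rate`) is realised as a fixed random mask drawn at initialisation:
# masked weights are zero and their gradients are zeroed, so they stay zero
# through training and aggregation.
#
# Nodes are indexed heap-style: node 1 is the root, node i has children 2i
# (left) and 2i+1 (right); leaves are nodes 2^depth .. 2^(depth+1) - 1.

#' Shallow neural decision forest configuration
#'
#' @param input_dim number of input features.
#' @param n_trees number of trees; the study grid uses {3, 5, 10, 15}.
#' @param depth tree depth; the study grid uses {3, 6, 9}.
#' @param feature_rate probability that an input feature is available to a
#'   given tree; the study grid uses {0.5, ..., 0.9}.
#' @return an object of class `sndf_config`.
#' @export
sndf_config <- function(input_dim, n_trees = 5L, depth = 3L, feature_rate = 0.7) {
  assert_that(input_dim >= 1, "input_dim must be >= 1")
  assert_that(depth >= 1, "depth must be >= 1")
  assert_that(n_trees >= 1, "n_trees must be >= 1")
  assert_that(feature_rate > 0 && feature_rate <= 1, "feature_rate must be in (0, 1]")
  structure(
    list(model = "sndf", input_dim = as.integer(input_dim),
         n_trees = as.integer(n_trees), depth = as.integer(depth),
         feature_rate = feature_rate,
         n_splits = 2L^as.integer(depth) - 1L,
         n_leaves = 2L^as.integer(depth)),
    class = c("sndf_config", "fedvar_config")
  )
}

sndf_layout <- function(config) {
  d <- config$input_dim; Tt <- config$n_trees
  S <- config$n_splits; L <- config$n_leaves
  param_layout(list(
    W          = list(n = d * Tt * S, trainable = TRUE, bn = FALSE),
    b          = list(n = Tt * S,     trainable = TRUE, bn = FALSE),
    leaf_logits = list(n = Tt * L * 2L, trainable = TRUE, bn = FALSE)
  ))
}

sndf_init <- function(config, seed) {
  layout <- sndf_layout(config)
  model <- structure(
    list(config = config, layout = layout,
         params = numeric(layout$end[nrow(layout)])),
    class = c("fedvar_sndf", "fedvar_model")
  )
  d <- config$input_dim; Tt <- config$n_trees; S <- config$n_splits; L <- config$n_leaves
  with_seed(seed, {
    # per-tree feature masks: Bernoulli(feature_rate) per feature, redrawn for
    # a tree until it keeps at least one feature
    masks <- matrix(FALSE, d, Tt)
    for (t in seq_len(Tt)) {
      repeat {
        m <- stats::runif(d) < config$feature_rate
        if (any(m)) break
      }
      masks[, t] <- m
    }
    W <- matrix(0, d, Tt * S)
    for (t in seq_len(Tt)) {
      idx <- ((t - 1L) * S + 1L):(t * S)
      d_eff <- sum(masks[, t])
      W[masks[, t], idx] <- stats::rnorm(d_eff * S, sd = sqrt(2 / d_eff))
    }
    model <- seg_set(model, "W", W)
    model <- seg_set(model, "leaf_logits", stats::rnorm(Tt * L * 2L, sd = 0.1))
    model$masks <- masks
  })
  model
}

# leaf distributions as a list of (n_leaves x 2) probability matrices
sndf_leaf_dists <- function(model) {
  cfg <- model$config
  logits <- array(seg_get(model, "leaf_logits"), dim = c(cfg$n_leaves, 2L, cfg$n_trees))
  lapply(seq_len(cfg$n_trees), function(t) softmax_rows(logits[, , t, drop = TRUE]))
}

# reach probabilities over all heap nodes for one tree's routing matrix d
# (n x n_splits); returns n x (2 * n_leaves - 1 + ... ) full node matrix
sndf_reach <- function(d_mat, depth) {
  n <- nrow(d_mat)
  S <- 2L^depth - 1L
  n_nodes <- 2L^(depth + 1L) - 1L
  R <- matrix(0, n, n_nodes)
  R[, 1L] <- 1
  for (i in seq_len(S)) {
    R[, 2L * i]      <- R[, i] * d_mat[, i]
    R[, 2L * i + 1L] <- R[, i] * (1 - d_mat[, i])
  }
  R
}

#' Forward pass of the shallow neural decision forest
#'
#' @param model an initialised `fedvar_sndf` model.
#' @param X numeric matrix of feature rows.
#' @return an `n x 2` matrix of class probabilities (benign, pathogenic).
#' @export
sndf_forward <- function(model, X) {
  sndf_forward_full(model, X)$probs
}

sndf_forward_full <- function(model, X) {
  cfg <- model$config
  if (ncol(X) != cfg$input_dim)
    stop_fv("dimension mismatch: model expects %d features, got %d",
            cfg$input_dim, ncol(X))
  n <- nrow(X); Tt <- cfg$n_trees; S <- cfg$n_splits; L <- cfg$n_leaves
  W <- seg_mat(model, "W", cfg$input_dim, Tt * S)
  f <- X %*% W
  f <- sweep(f, 2L, seg_get(model, "b"), "+")
  pis <- sndf_leaf_dists(model)
  probs <- matrix(0, n, 2L)
  caches <- vector("list", Tt)
  for (t in seq_len(Tt)) {
    idx <- ((t - 1L) * S + 1L):(t * S)
    d_mat <- sigmoid(f[, idx, drop = FALSE])
    R <- sndf_reach(d_mat, cfg$depth)
    leaf_reach <- R[, (S + 1L):(S + L), drop = FALSE]
    tree_prob <- leaf_reach %*% pis[[t]]
    probs <- probs + tree_prob
    caches[[t]] <- list(d = d_mat, R = R, leaf_reach = leaf_reach,
                        pi = pis[[t]], tree_prob = tree_prob)
  }
  probs <- probs / Tt
  list(probs = probs, caches = caches)
}

# negative log-likelihood of the forest class probabilities and flat gradient
sndf_loss_grad <- function(model, X, y, training = TRUE) {
  cfg <- model$config
  n <- nrow(X); Tt <- cfg$n_trees; S <- cfg$n_splits; L <- cfg$n_leaves
  fw <- sndf_forward_full(model, X)
  p_true <- ifelse(y == 1, fw$probs[, 2L], fw$probs[, 1L])
  p_true <- pmax(p_true, 1e-12)
  loss <- -mean(log(p_true))
  coef <- -1 / (n * p_true * Tt)        # d loss / d (tree prob of true class)
  grad <- numeric(length(model$params))
  gW <- matrix(0, cfg$input_dim, Tt * S)
  gb <- numeric(Tt * S)
  g_logits <- array(0, dim = c(L, 2L, Tt))
  n_nodes <- 2L * L - 1L
  for (t in seq_len(Tt)) {
    caches_t <- fw$caches[[t]]
    # V[, i]: expected true-class probability of the subtree rooted at node i;
    # leaf values are pi_l(y_i) for each sample i and leaf l
    V <- matrix(0, n, n_nodes)
    pi_t <- caches_t$pi
    V[, (S + 1L):(S + L)] <- matrix(pi_t[, 1L], n, L, byrow = TRUE) * (y == 0) +
      matrix(pi_t[, 2L], n, L, byrow = TRUE) * (y == 1)
    for (i in S:1L) {
      V[, i] <- caches_t$d[, i] * V[, 2L * i] + (1 - caches_t$d[, i]) * V[, 2L * i + 1L]
    }
    # split gradients: dP/d f_i = R_i (V_left - V_right) d_i (1 - d_i)
    gf <- matrix(0, n, S)
    for (i in seq_len(S)) {
      gf[, i] <- coef * caches_t$R[, i] * (V[, 2L * i] - V[, 2L * i + 1L]) *
        caches_t$d[, i] * (1 - caches_t$d[, i])
    }
    idx <- ((t - 1L) * S + 1L):(t * S)
    gW[, idx] <- crossprod(X, gf)
    # zero gradients for features masked out of this tree
    gW[!model$masks[, t], idx] <- 0
    gb[idx] <- colSums(gf)
    # leaf logit gradients through the row-wise softmax:
    # A[i, l] = coef_i * reach_{il} * pi_l(y_i)
    A <- coef * caches_t$leaf_reach *
      (matrix(pi_t[, 1L], n, L, byrow = TRUE) * (y == 0) +
       matrix(pi_t[, 2L], n, L, byrow = TRUE) * (y == 1))
    s0 <- colSums(A[y == 0, , drop = FALSE])
    s1 <- colSums(A[y == 1, , drop = FALSE])
    tot <- s0 + s1
    g_logits[, 1L, t] <- s0 - tot * pi_t[, 1L]
    g_logits[, 2L, t] <- s1 - tot * pi_t[, 2L]
  }
  grad[layout_idx(model$layout, "W")] <- as.numeric(gW)
  grad[layout_idx(model$layout, "b")] <- gb
  grad[layout_idx(model$layout, "leaf_logits")] <- as.numeric(g_logits)
  list(loss = loss, grad = grad)
}
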