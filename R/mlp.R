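# Three-layer MLP -------------------------------------------------------------
#
# The MLP counts its input and output layers: input (d features) -> one hidden
# layer of `n_hidden` rectified units (optionally batch-normalised) -> a single
# sigmoid output giving the pathogenicity score in [0, 1]. Training is
# mini-batch gradient descent on binary cross-entropy (see local_train), with
# gradients computed by the closed-form backward pass below.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

#' MLP configuration
#'
#' @param input_dim number of input features (60 for the SNV encoding, 38 for
#'   the CNV encoding).
#' @param n_hidden hidden-layer width; tuned over 3..9 in the study grid.
#' @param use_batch_norm add a batch-normalisation layer on the hidden
#'   pre-activations. Running mean/variance become part of the model state;
#'   how they are shared across clients is a federation policy (`bn_policy`).
#' @return an object of class `mlp_config`.
#' @export
mlp_config <- function(input_dim, n_hidden = 6L, use_batch_norm = FALSE) {
  assert_that(input_dim >= 1, "input_dim must be >= 1")
  assert_that(n_hidden >= 1, "n_hidden must be >= 1")
  structure(
    list(model = "mlp", input_dim = as.integer(input_dim),
         n_hidden = as.integer(n_hidden),
         use_batch_norm = isTRUE(use_batch_norm)),
    class = c("mlp_config", "fedvar_config")
  )
}

mlp_layout <- function(config) {
  d <- config$input_dim; h <- config$n_hidden
  segs <- list(
    W1 = list(n = d * h, trainable = TRUE,  bn = FALSE),
    b1 = list(n = h,     trainable = TRUE,  bn = FALSE)
  )
  if (config$use_batch_norm) {
    segs$bn_gamma <- list(n = h, trainable = TRUE,  bn = TRUE)
    segs$bn_beta  <- list(n = h, trainable = TRUE,  bn = TRUE)
    segs$bn_mean  <- list(n = h, trainable = FALSE, bn = TRUE)
    segs$bn_var   <- list(n = h, trainable = FALSE, bn = TRUE)
  }
  segs$W2 <- list(n = h, trainable = TRUE, bn = FALSE)
  segs$b2 <- list(n = 1, trainable = TRUE, bn = FALSE)
  param_layout(segs)
}

mlp_init <- function(config, seed) {
  layout <- mlp_layout(config)
  n_par <- layout$end[nrow(layout)]
  model <- structure(
    list(config = config, layout = layout, params = numeric(n_par)),
    class = c("fedvar_mlp", "fedvar_model")
  )
  d <- config$input_dim; h <- config$n_hidden
  with_seed(seed, {
    model <- seg_set(model, "W1", stats::rnorm(d * h, sd = sqrt(2 / d)))
    model <- seg_set(model, "W2", stats::rnorm(h, sd = sqrt(2 / h)))
  })
  if (config$use_batch_norm) {
    model <- seg_set(model, "bn_gamma", rep(1, h))
    model <- seg_set(model, "bn_var", rep(1, h))
  }
  model
}

# forward pass returning intermediates needed by the backward pass.
# training = TRUE uses batch statistics for BN (and reports them);
# training = FALSE uses running statistics, making inference deterministic.
mlp_forward_full <- function(model, X, training = FALSE) {
  cfg <- model$config
  if (ncol(X) != cfg$input_dim)
    stop_fv("dimension mismatch: model expects %d features, got %d",
            cfg$input_dim, ncol(X))
  d <- cfg$input_dim; h <- cfg$n_hidden
  W1 <- seg_mat(model, "W1", d, h)
  b1 <- seg_get(model, "b1")
  z <- X %*% W1
  z <- sweep(z, 2L, b1, "+")
  cache <- list(z = z)
  if (cfg$use_batch_norm) {
    if (training) {
      mu <- colMeans(z)
      va <- colMeans(sweep(z, 2L, mu)^2)  # biased batch variance
    } else {
      mu <- seg_get(model, "bn_mean")
      va <- seg_get(model, "bn_var")
    }
    zc <- sweep(z, 2L, mu)
    inv_sd <- 1 / sqrt(va + BN_EPS)
    zn <- sweep(zc, 2L, inv_sd, "*")
    zb <- sweep(sweep(zn, 2L, seg_get(model, "bn_gamma"), "*"),
                2L, seg_get(model, "bn_beta"), "+")
    cache <- c(cache, list(mu = mu, va = va, zc = zc, inv_sd = inv_sd, zn = zn, zb = zb))
  } else {
    zb <- z
  }
  a <- relu(zb)
  W2 <- seg_get(model, "W2")
  logit <- drop(a %*% W2) + seg_get(model, "b2")
  cache$a <- a
  cache$zb <- zb
  list(scores = sigmoid(logit), cache = cache)
}

# mean binary cross-entropy loss and flat gradient; returns batch statistics
# so the caller can update BN running moments during training
mlp_loss_grad <- function(model, X, y, training = TRUE) {
  cfg <- model$config
  n <- nrow(X); h <- cfg$n_hidden; d <- cfg$input_dim
  fw <- mlp_forward_full(model, X, training = training)
  s <- pmin(pmax(fw$scores, 1e-12), 1 - 1e-12)
  loss <- -mean(y * log(s) + (1 - y) * log(1 - s))
  g_out <- (fw$scores - y) / n                      # d loss / d output logit
  a <- fw$cache$a
  W2 <- seg_get(model, "W2")
  grad <- numeric(length(model$params))
  grad[layout_idx(model$layout, "W2")] <- drop(crossprod(a, g_out))
  grad[layout_idx(model$layout, "b2")] <- sum(g_out)
  ga <- outer(g_out, W2)                            # n x h
  gzb <- ga * (fw$cache$zb > 0)
  if (cfg$use_batch_norm) {
    zn <- fw$cache$zn; zc <- fw$cache$zc; inv_sd <- fw$cache$inv_sd
    gamma <- seg_get(model, "bn_gamma")
    grad[layout_idx(model$layout, "bn_gamma")] <- colSums(gzb * zn)
    grad[layout_idx(model$layout, "bn_beta")]  <- colSums(gzb)
    gn <- sweep(gzb, 2L, gamma, "*")
    if (training) {
      gvar <- colSums(gn * zc) * (-0.5) * inv_sd^3
      gmu <- -colSums(gn) * inv_sd
      gz <- sweep(gn, 2L, inv_sd, "*") +
        sweep(zc, 2L, 2 * gvar / n, "*") +
        matrix(gmu / n, n, h, byrow = TRUE)
    } else {
      gz <- sweep(gn, 2L, inv_sd, "*")
    }
  } else {
    gz <- gzb
  }
  grad[layout_idx(model$layout, "W1")] <- as.numeric(crossprod(X, gz))
  grad[layout_idx(model$layout, "b1")] <- colSums(gz)
  out <- list(loss = loss, grad = grad)
  if (cfg$use_batch_norm && training) out$batch_stats <- list(mu = fw$cache$mu, va = fw$cache$va)
  out
}

# fold a batch's statistics into the running BN moments
mlp_update_running <- function(model, batch_stats) {
  if (is.null(batch_stats)) return(model)
  rm_ <- seg_get(model, "bn_mean"); rv <- seg_get(model, "bn_var")
  model <- seg_set(model, "bn_mean", (1 - BN_MOMENTUM) * rm_ + BN_MOMENTUM * batch_stats$mu)
  seg_set(model, "bn_var", (1 - BN_MOMENTUM) * rv + BN_MOMENTUM * batch_stats$va)
}
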