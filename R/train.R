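# Model-generic interface and local (client-side) training --------------------

#' Initialise a model from its configuration
#'
#' @param config an `mlp_config` or `sndf_config`.
#' @param seed integer seed controlling weight initialisation (and, for the
#'   forest, the per-tree feature masks).
#' @return a `fedvar_model` with a flat parameter vector and layout.
#' @export
model_init <- function(config, seed) {
  switch(config$model,
         mlp  = mlp_init(config, seed),
         sndf = sndf_init(config, seed),
         stop_fv("unknown model type '%s'", config$model))
}

#' Pathogenicity scores of a model on feature rows
#'
#' Inference is deterministic: the MLP's batch-norm layer (when present) uses
#' its running statistics. For the forest the score is the pathogenic-class
#' probability of the averaged tree mixture.
#'
#' @param object a `fedvar_model`.
#' @param newdata numeric matrix of feature rows.
#' @param ... unused.
#' @return numeric vector of scores in \[0, 1\].
#' @export
predict.fedvar_model <- function(object, newdata, ...) {
  if (inherits(object, "fedvar_mlp")) {
    mlp_forward_full(object, newdata, training = FALSE)$scores
  } else {
    sndf_forward(object, newdata)[, 2L]
  }
}

# loss and flat gradient dispatch (loss only; penalties are added by the
# optimiser step so the proximal anchor never leaks into the model code)
model_loss_grad <- function(model, X, y, training = TRUE) {
  if (inherits(model, "fedvar_mlp")) mlp_loss_grad(model, X, y, training = training)
  else sndf_loss_grad(model, X, y, training = training)
}

#' Local training configuration
#'
#' Mirrors the study's client-side settings: SGD with momentum 0.9 or Adam
#' (beta1 = 0.9, beta2 = 0.999), learning rate in {0.1, 0.01, 0.001, 0.0001},
#' batch size in {4, 8, 16, 32}, 10 local epochs, weight decay 1e-4. A
#' positive `proximal_mu` adds the FedProx penalty (mu/2) * ||w - anchor||^2
#' to the local loss and requires an anchor (the round's global parameters).
#'
#' @param learning_rate local step size.
#' @param optimizer `"sgd"` (momentum 0.9) or `"adam"`.
#' @param batch_size mini-batch size.
#' @param epochs local epochs per call (the study fixes 10 per round).
#' @param weight_decay L2 penalty coefficient on trainable parameters.
#' @param proximal_mu FedProx proximal coefficient (0 disables the term).
#' @param momentum SGD momentum.
#' @return an object of class `local_train_config`.
#' @export
local_train_config <- function(learning_rate = 0.01, optimizer = c("sgd", "adam"),
                               batch_size = 32L, epochs = 10L,
                               weight_decay = 1e-4, proximal_mu = 0,
                               momentum = 0.9) {
  optimizer <- match.arg(optimizer)
  assert_that(proximal_mu >= 0, "proximal_mu must be >= 0")
  structure(
    list(learning_rate = learning_rate, optimizer = optimizer,
         batch_size = as.integer(batch_size), epochs = as.integer(epochs),
         weight_decay = weight_decay, proximal_mu = proximal_mu,
         momentum = momentum, beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8),
    class = "local_train_config"
  )
}

opt_state_init <- function(n_par) {
  list(v = numeric(n_par), m = numeric(n_par), t = 0L)
}

# one optimiser step on the trainable coordinates; returns params + state
opt_step <- function(params, grad, cfg, state, tmask) {
  g <- grad[tmask]
  if (cfg$optimizer == "sgd") {
    v <- cfg$momentum * state$v[tmask] + g
    params[tmask] <- params[tmask] - cfg$learning_rate * v
    state$v[tmask] <- v
  } else {
    state$t <- state$t + 1L
    m <- cfg$beta1 * state$m[tmask] + (1 - cfg$beta1) * g
    v <- cfg$beta2 * state$v[tmask] + (1 - cfg$beta2) * g^2
    mhat <- m / (1 - cfg$beta1^state$t)
    vhat <- v / (1 - cfg$beta2^state$t)
    params[tmask] <- params[tmask] - cfg$learning_rate * mhat / (sqrt(vhat) + cfg$adam_eps)
    state$m[tmask] <- m
    state$v[tmask] <- v
  }
  list(params = params, state = state)
}

#' Train a model locally by mini-batch gradient descent
#'
#' Runs `cfg$epochs` passes of shuffled mini-batch optimisation of the
#' cross-entropy loss (negative log-likelihood for the forest). Weight decay
#' is added to the gradient of every trainable coordinate; when
#' `cfg$proximal_mu > 0` the FedProx term mu * (w - anchor) is added as well.
#' The batch schedule is a deterministic function of `seed`, so two calls with
#' identical inputs are bit-identical. The input model is left untouched.
#'
#' @param model a `fedvar_model` (typically the round's global model).
#' @param X,y training features and 0/1 labels.
#' @param cfg a [local_train_config()].
#' @param seed integer seed controlling batch shuffling.
#' @param anchor optional flat parameter vector for the proximal term;
#'   required when `cfg$proximal_mu > 0`.
#' @param opt_state optional optimiser state to continue from (used by the
#'   centralized trainer to chain segments); fresh state if NULL.
#' @return the trained model, with the final optimiser state attached as
#'   attribute `opt_state`.
#' @export
local_train <- function(model, X, y, cfg, seed, anchor = NULL, opt_state = NULL) {
  if (is.null(dim(X)) || nrow(X) == 0L) stop_fv("empty training data")
  assert_that(length(y) == nrow(X), "X and y size mismatch")
  if (cfg$proximal_mu > 0 && is.null(anchor))
    stop_fv("proximal_mu > 0 requires an anchor parameter vector")
  n <- nrow(X)
  tmask <- trainable_mask(model$layout)
  state <- opt_state %||% opt_state_init(length(model$params))
  for (epoch in seq_len(cfg$epochs)) {
    ord <- with_seed(derive_seed(seed, epoch), sample.int(n))
    starts <- seq.int(1L, n, by = cfg$batch_size)
    for (s in starts) {
      idx <- ord[s:min(s + cfg$batch_size - 1L, n)]
      lg <- model_loss_grad(model, X[idx, , drop = FALSE], y[idx], training = TRUE)
      grad <- lg$grad
      grad[tmask] <- grad[tmask] + cfg$weight_decay * model$params[tmask]
      if (cfg$proximal_mu > 0)
        grad[tmask] <- grad[tmask] + cfg$proximal_mu * (model$params[tmask] - anchor[tmask])
      if (any(!is.finite(grad)))
        stop_fv("non-finite gradient encountered during local training")
      step <- opt_step(model$params, grad, cfg, state, tmask)
      model$params <- step$params
      state <- step$state
      if (!is.null(lg$batch_stats)) model <- mlp_update_running(model, lg$batch_stats)
    }
  }
  attr(model, "opt_state") <- state
  model
}
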