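# Cross-silo federated training loop ------------------------------------------
#
# One round: (i) the server holds a global model; (ii) it selects a random
# subset of clients (client_rate) and broadcasts the global parameters;
# (iii) each selected client optimises the model on its local data for a fixed
# number of epochs; (iv) clients return their updated parameter vectors;
# (v) the server aggregates them into the next global model. FedAvg/FedProx
# aggregate by dataset-size-weighted averaging (FedProx additionally imposes
# the proximal penalty during local training; with mu = 0 and SGD it reduces
# exactly to FedAvg). The adaptive family (FedAdagrad/FedAdam/FedYogi) treats
# the weighted-average client delta as a pseudo-gradient and applies a
# server-side adaptive step eta * m / (sqrt(v) + tau).

#' Aggregation algorithm configuration
#'
#' @param algorithm one of "fedavg", "fedprox", "fedadagrad", "fedadam",
#'   "fedyogi".
#' @param proximal_mu FedProx proximal coefficient (study grid:
#'   {0.5, 0.1, 0.01, 0.001, 0.0001, 0}).
#' @param server_lr server learning rate eta for the adaptive family (grid:
#'   {1, 0.1, 0.01, 0.001}).
#' @param tau adaptivity parameter of the adaptive family (grid:
#'   {0.0001, 0.01, 0.1}); the second moment is initialised to tau^2.
#' @param beta1,beta2 server moment coefficients (FedAdam/FedYogi).
#' @param client_rate fraction of clients selected each round ({0.5, 1}).
#' @param n_rounds maximum number of federated rounds (200 in the study).
#' @param bn_policy "aggregate" exchanges batch-norm parameters and running
#'   statistics like any other coordinate; "keep_local" excludes them from
#'   exchange so they persist per client.
#' @return an object of class `aggregator_config`.
#' @export
aggregator_config <- function(algorithm = c("fedavg", "fedprox", "fedadagrad",
                                            "fedadam", "fedyogi"),
                              proximal_mu = 0, server_lr = 0.1, tau = 0.01,
                              beta1 = 0.9, beta2 = 0.999,
                              client_rate = 1, n_rounds = 200L,
                              bn_policy = c("aggregate", "keep_local")) {
  algorithm <- match.arg(algorithm)
  bn_policy <- match.arg(bn_policy)
  assert_that(client_rate > 0 && client_rate <= 1, "client_rate must be in (0, 1]")
  if (algorithm != "fedprox" && proximal_mu != 0)
    stop_fv("proximal_mu applies to fedprox only")
  structure(
    list(algorithm = algorithm, proximal_mu = proximal_mu,
         server_lr = server_lr, tau = tau, beta1 = beta1, beta2 = beta2,
         client_rate = client_rate, n_rounds = as.integer(n_rounds),
         bn_policy = bn_policy),
    class = "aggregator_config"
  )
}

#' Sample the clients participating in a round
#'
#' Subset size is `max(1, round_half_up(client_rate * n_clients))`, drawn
#' uniformly without replacement; deterministic under the given seed.
#'
#' @param client_ids character vector of registered clients.
#' @param client_rate fraction in (0, 1].
#' @param seed integer seed.
#' @return character vector of selected clients.
#' @export
sample_clients <- function(client_ids, client_rate, seed) {
  if (length(client_ids) == 0L) stop_fv("empty client registry")
  assert_that(client_rate > 0 && client_rate <= 1, "client_rate must be in (0, 1]")
  k <- max(1L, round_half_up(client_rate * length(client_ids)))
  with_seed(seed, sort(sample(client_ids, k)))
}

#' Dataset-size-weighted average of client parameter vectors
#'
#' Weights are n_i / sum(n) over the participating clients of the round
#' (renormalised over the sampled subset).
#'
#' @param updates list of `list(params =, n_samples =, client_id =)`.
#' @return numeric parameter vector.
#' @export
aggregate_weighted_mean <- function(updates) {
  if (length(updates) == 0L) stop_fv("no client updates to aggregate")
  len <- length(updates[[1L]]$params)
  ns <- vapply(updates, function(u) as.numeric(u$n_samples), numeric(1))
  assert_that(all(ns > 0), "client sample sizes must be positive")
  w <- ns / sum(ns)
  out <- numeric(len)
  for (i in seq_along(updates)) {
    if (length(updates[[i]]$params) != len)
      stop_fv("parameter layout mismatch in update from client '%s'",
              updates[[i]]$client_id %||% i)
    out <- out + w[i] * updates[[i]]$params
  }
  out
}

#' Server state for the adaptive aggregation family
#'
#' @param n_par number of model parameters.
#' @param tau adaptivity parameter; second moment starts at tau^2.
#' @return list with global_params placeholder, m, v, round_index.
#' @export
server_state_init <- function(n_par, tau) {
  list(m = numeric(n_par), v = rep(tau^2, n_par), round_index = 0L)
}

#' One adaptive server step (FedAdagrad / FedAdam / FedYogi)
#'
#' The pseudo-gradient is Delta = weighted_mean(updates) - global. Moments:
#' FedAdagrad m = Delta, v <- v + Delta^2; FedAdam m <- b1 m + (1-b1) Delta,
#' v <- b2 v + (1-b2) Delta^2; FedYogi m as Adam,
#' v <- v - (1-b2) Delta^2 * sign(v - Delta^2). Step:
#' global <- global + eta * m / (sqrt(v) + tau), elementwise.
#'
#' @param global_params current global parameter vector.
#' @param state server moment state from [server_state_init()].
#' @param updates list of client updates (see [aggregate_weighted_mean()]).
#' @param cfg an [aggregator_config()] with an adaptive `algorithm`.
#' @return list(global_params, state).
#' @export
server_update_adaptive <- function(global_params, state, updates, cfg) {
  delta <- aggregate_weighted_mean(updates) - global_params
  if (any(!is.finite(delta)))
    stop_fv("non-finite aggregated delta at round %d", state$round_index + 1L)
  if (cfg$algorithm == "fedadagrad") {
    m <- delta
    v <- state$v + delta^2
  } else if (cfg$algorithm == "fedadam") {
    m <- cfg$beta1 * state$m + (1 - cfg$beta1) * delta
    v <- cfg$beta2 * state$v + (1 - cfg$beta2) * delta^2
  } else if (cfg$algorithm == "fedyogi") {
    m <- cfg$beta1 * state$m + (1 - cfg$beta1) * delta
    v <- state$v - (1 - cfg$beta2) * delta^2 * sign(state$v - delta^2)
  } else {
    stop_fv("'%s' is not an adaptive algorithm", cfg$algorithm)
  }
  global_params <- global_params + cfg$server_lr * m / (sqrt(v) + cfg$tau)
  list(global_params = global_params,
       state = list(m = m, v = v, round_index = state$round_index + 1L))
}

#' Run the federated training loop
#'
#' Simulates the full cross-silo protocol in-process. The server object never
#' receives client data: clients contribute only parameter vectors and sample
#' counts. Early stopping, when an `eval_fn` is supplied, follows the study
#' rule: stop when the validation metric has not strictly improved for
#' `patience` consecutive rounds, and return the best round's parameters.
#'
#' @param clients named list; each element is `list(X =, y =)` for one silo.
#' @param model_config an `mlp_config` or `sndf_config`.
#' @param local_cfg a [local_train_config()] (its `proximal_mu` is overridden
#'   by the aggregator's for fedprox).
#' @param agg an [aggregator_config()].
#' @param seed root seed: controls initialisation, client sampling, and every
#'   client's batch schedule.
#' @param eval_fn optional `function(model) -> metric` (higher is better),
#'   evaluated once per round on e.g. the collaborative validation set.
#' @param patience early-stopping patience in rounds (study: 20).
#' @return list with elements `model` (final or best-round model), `history`
#'   (one row per executed round: round, n_selected, selected, delta_norm,
#'   metric), and `best_round`.
#' @export
run_federated_training <- function(clients, model_config, local_cfg, agg, seed,
                                   eval_fn = NULL, patience = 20L) {
  if (length(clients) == 0L) stop_fv("at least one client required")
  ids <- names(clients) %||% as.character(seq_along(clients))
  if (is.null(names(clients))) names(clients) <- ids
  global <- model_init(model_config, derive_seed(seed, 0L))
  n_par <- length(global$params)
  bn_keep <- agg$bn_policy == "keep_local"
  bnm <- if (bn_keep) bn_mask(global$layout) else rep(FALSE, n_par)
  client_bn <- lapply(clients, function(cl) global$params[bnm])
  state <- server_state_init(n_par, agg$tau)
  adaptive <- agg$algorithm %in% c("fedadagrad", "fedadam", "fedyogi")
  local_cfg$proximal_mu <- if (agg$algorithm == "fedprox") agg$proximal_mu else 0
  history <- vector("list", agg$n_rounds)
  metrics <- numeric(0)
  best_params <- global$params
  best_round <- NA_integer_
  for (r in seq_len(agg$n_rounds)) {
    selected <- sample_clients(ids, agg$client_rate, derive_seed(seed, r, 999983L))
    anchor <- global$params
    updates <- lapply(selected, function(cid) {
      cl <- clients[[cid]]
      local_model <- global
      if (bn_keep) local_model$params[bnm] <- client_bn[[cid]]
      trained <- tryCatch(
        local_train(local_model, cl$X, cl$y, local_cfg,
                    seed = derive_seed(seed, r, match(cid, ids)),
                    anchor = anchor),
        error = function(e) stop_fv("client '%s' failed at round %d: %s",
                                    cid, r, conditionMessage(e))
      )
      if (bn_keep) {
        client_bn[[cid]] <<- trained$params[bnm]
        # excluded from exchange: report the global values back unchanged
        trained$params[bnm] <- anchor[bnm]
      }
      list(params = trained$params, n_samples = nrow(cl$X), client_id = cid)
    })
    if (adaptive) {
      up <- server_update_adaptive(global$params, state, updates, agg)
      new_params <- up$global_params
      state <- up$state
    } else {
      new_params <- aggregate_weighted_mean(updates)
    }
    delta_norm <- sqrt(sum((new_params - global$params)^2))
    global <- unflatten_params(global, new_params)
    metric <- if (!is.null(eval_fn)) eval_fn(global) else NA_real_
    history[[r]] <- data.frame(round = r, n_selected = length(selected),
                               selected = paste(selected, collapse = ","),
                               delta_norm = delta_norm, metric = metric)
    if (!is.null(eval_fn)) {
      metrics <- c(metrics, metric)
      es <- early_stopping(metrics, patience = patience)
      if (es$best == length(metrics)) best_params <- global$params
      best_round <- es$best
      if (es$stop) break
    }
  }
  history <- do.call(rbind, history[!vapply(history, is.null, logical(1))])
  if (!is.null(eval_fn)) global <- unflatten_params(global, best_params)
  list(model = global, history = history, best_round = best_round)
}

#' Centralized (CDS) baseline training
#'
#' Trains one model on the pooled data with the same schedule as a federated
#' client: segments of `local_cfg$epochs` epochs with a fresh optimiser state
#' per segment, one early-stopping evaluation per segment. CDS and FL
#' therefore differ only in data locality and aggregation, and a single-client
#' full-participation FedAvg run is exactly equivalent to this loop under a
#' shared seed.
#'
#' @param X,y pooled training data.
#' @param model_config model configuration.
#' @param local_cfg a [local_train_config()].
#' @param seed root seed (same derivation as a federated run's client 1).
#' @param n_rounds number of epoch segments (matches the FL round budget).
#' @param eval_fn optional metric function for early stopping.
#' @param patience early-stopping patience in segments.
#' @return list(model, history, best_round) as in [run_federated_training()].
#' @export
run_centralized_training <- function(X, y, model_config, local_cfg, seed,
                                     n_rounds = 200L, eval_fn = NULL,
                                     patience = 20L) {
  model <- model_init(model_config, derive_seed(seed, 0L))
  metrics <- numeric(0)
  best_params <- model$params
  best_round <- NA_integer_
  history <- vector("list", n_rounds)
  for (r in seq_len(n_rounds)) {
    model <- local_train(model, X, y, local_cfg, seed = derive_seed(seed, r, 1L))
    metric <- if (!is.null(eval_fn)) eval_fn(model) else NA_real_
    history[[r]] <- data.frame(round = r, n_selected = 1L, selected = "pooled",
                               delta_norm = NA_real_, metric = metric)
    if (!is.null(eval_fn)) {
      metrics <- c(metrics, metric)
      es <- early_stopping(metrics, patience = patience)
      if (es$best == length(metrics)) best_params <- model$params
      best_round <- es$best
      if (es$stop) break
    }
  }
  history <- do.call(rbind, history[!vapply(history, is.null, logical(1))])
  if (!is.null(eval_fn)) model <- unflatten_params(model, best_params)
  list(model = model, history = history, best_round = best_round)
}

#' Single-silo (local baseline) training
#'
#' The individual-institution baseline: identical to
#' [run_centralized_training()] restricted to one silo's data.
#'
#' @inheritParams run_centralized_training
#' @export
run_local_training <- function(X, y, model_config, local_cfg, seed,
                               n_rounds = 200L, eval_fn = NULL, patience = 20L) {
  run_centralized_training(X, y, model_config, local_cfg, seed,
                           n_rounds = n_rounds, eval_fn = eval_fn,
                           patience = patience)
}
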