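# Evaluation battery -----------------------------------------------------------

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney U) form: the probability that a random pathogenic
#' variant outranks a random benign one, with ties contributing 1/2.
#'
#' @param scores numeric scores (higher = more pathogenic).
#' @param labels 0/1 labels; both classes must be present.
#' @return AUC in \[0, 1\].
#' @export
auc_roc <- function(scores, labels) {
  assert_that(length(scores) == length(labels), "scores/labels length mismatch")
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0L || n_neg == 0L)
    stop_fv("AUC undefined: both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Spearman rank similarity of two score vectors
#'
#' Average ranks for ties; two-sided p-value from the t approximation (exact
#' p-values are unavailable under ties, so the approximation is used
#' throughout for consistency).
#'
#' @param scores_a,scores_b equal-length numeric vectors (n >= 3).
#' @return list(rho, p_value).
#' @export
score_similarity <- function(scores_a, scores_b) {
  assert_that(length(scores_a) == length(scores_b) && length(scores_a) >= 3,
              "need two equal-length score vectors of length >= 3")
  ct <- suppressWarnings(
    stats::cor.test(scores_a, scores_b, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Early-stopping controller
#'
#' Stop once the metric has not strictly improved on its best value for
#' `patience` consecutive evaluations; the best index is the first occurrence
#' of the maximum.
#'
#' @param metric_history numeric vector, higher is better.
#' @param patience consecutive non-improving evaluations tolerated.
#' @return list(stop = logical, best = index of best evaluation).
#' @export
early_stopping <- function(metric_history, patience = 20L) {
  assert_that(length(metric_history) >= 1, "empty metric history")
  best <- which.max(metric_history)
  list(stop = (length(metric_history) - best) >= patience, best = best)
}

#' Leave-one-chromosome-out fold plan
#'
#' One fold per chromosome symbol (1-22, X): a bundle of 23 classifiers in
#' which variants on a chromosome are scored by the model trained on the
#' remaining chromosomes, preventing positional leakage. Folds with no
#' held-out records are retained and flagged; folds with an empty training
#' set are flagged as degenerate.
#'
#' @param fm a `feature_matrix` (its `chromosome` vector is used).
#' @return data.frame with columns held_out, n_heldout, n_train, degenerate.
#' @export
plan_loco <- function(fm) {
  chrom <- fm$chromosome
  bad <- setdiff(unique(chrom), CHROMOSOMES)
  if (length(bad)) stop_fv("unknown chromosome symbol '%s'", bad[1])
  counts <- table(factor(chrom, levels = CHROMOSOMES))
  data.frame(
    held_out = CHROMOSOMES,
    n_heldout = as.integer(counts),
    n_train = length(chrom) - as.integer(counts),
    degenerate = (length(chrom) - as.integer(counts)) == 0L,
    stringsAsFactors = FALSE
  )
}

#' Score every record under the leave-one-chromosome-out scheme
#'
#' @param fm a `feature_matrix`.
#' @param train_fun `function(X, y, held_out) -> fedvar_model`, called once
#'   per non-empty fold on the rows outside the held-out chromosome.
#' @return numeric score vector aligned with `fm` rows.
#' @export
run_loco <- function(fm, train_fun) {
  plan <- plan_loco(fm)
  scores <- rep(NA_real_, length(fm$y))
  for (i in seq_len(nrow(plan))) {
    held <- plan$held_out[i]
    idx <- which(fm$chromosome == held)
    if (length(idx) == 0L) next
    if (plan$degenerate[i])
      stop_fv("fold '%s' has an empty training set", held)
    model <- train_fun(fm$X[-idx, , drop = FALSE], fm$y[-idx], held)
    scores[idx] <- predict(model, fm$X[idx, , drop = FALSE])
  }
  scores
}

#' Collaborative cross-validation plan
#'
#' Each silo splits its own records into k near-equal folds; global fold f is
#' the union of the silos' folds f, so the validation set aggregates every
#' institution's local validation split.
#'
#' @param silo_sizes named integer vector of per-silo record counts.
#' @param k number of folds (study default 10).
#' @param seed integer seed.
#' @return object of class `ccv_plan`: list(k, assignments, seed), where
#'   assignments is a named list of per-silo fold-id vectors.
#' @export
ccv_plan <- function(silo_sizes, k = 10L, seed = 1L) {
  small <- names(silo_sizes)[silo_sizes < k]
  if (length(small))
    stop_fv("silo '%s' has fewer records (%d) than k = %d",
            small[1], silo_sizes[[small[1]]], k)
  assignments <- with_seed(seed, {
    lapply(silo_sizes, function(n) sample(rep_len(seq_len(k), n)))
  })
  structure(list(k = as.integer(k), assignments = assignments, seed = seed),
            class = "ccv_plan")
}

# internal: train one model in the requested mode and return it
train_one <- function(clients, model_config, local_cfg, agg, seed, mode,
                      n_rounds, eval_fn = NULL, patience = 20L) {
  if (mode == "federated") {
    agg$n_rounds <- as.integer(n_rounds)
    run_federated_training(clients, model_config, local_cfg, agg, seed,
                           eval_fn = eval_fn, patience = patience)$model
  } else {
    X <- do.call(rbind, lapply(clients, `[[`, "X"))
    y <- unlist(lapply(clients, `[[`, "y"), use.names = FALSE)
    run_centralized_training(X, y, model_config, local_cfg, seed,
                             n_rounds = n_rounds, eval_fn = eval_fn,
                             patience = patience)$model
  }
}

#' Run collaborative cross-validation
#'
#' For every fold and seed, trains on all silos' training portions and scores
#' the aggregated validation fold. The same plan object must be reused when
#' comparing federated and centralized modes, so both consume identical
#' splits.
#'
#' @param clients named list of `list(X =, y =)` per silo.
#' @param model_config,local_cfg,agg model and training configurations.
#' @param plan a [ccv_plan()] built from these silos' sizes.
#' @param seeds integer vector of model-initialisation seeds.
#' @param mode "federated" or "centralized".
#' @param n_rounds training rounds per fit.
#' @return data.frame with one row per (fold, seed): mode, fold, seed, auc,
#'   n_val.
#' @export
run_ccv <- function(clients, model_config, local_cfg, agg, plan, seeds,
                    mode = c("federated", "centralized"), n_rounds = 20L) {
  mode <- match.arg(mode)
  assert_that(setequal(names(clients), names(plan$assignments)),
              "plan silos do not match clients")
  out <- list()
  for (f in seq_len(plan$k)) {
    tr_clients <- lapply(names(clients), function(id) {
      keep <- plan$assignments[[id]] != f
      list(X = clients[[id]]$X[keep, , drop = FALSE], y = clients[[id]]$y[keep])
    })
    names(tr_clients) <- names(clients)
    val_X <- do.call(rbind, lapply(names(clients), function(id) {
      clients[[id]]$X[plan$assignments[[id]] == f, , drop = FALSE]
    }))
    val_y <- unlist(lapply(names(clients), function(id) {
      clients[[id]]$y[plan$assignments[[id]] == f]
    }), use.names = FALSE)
    for (s in seeds) {
      model <- train_one(tr_clients, model_config, local_cfg, agg, s, mode, n_rounds)
      out[[length(out) + 1L]] <- data.frame(
        mode = mode, fold = f, seed = s,
        auc = auc_roc(predict(model, val_X), val_y), n_val = length(val_y))
    }
  }
  do.call(rbind, out)
}

#' Client-dropout robustness study
#'
#' Runs the full train/evaluate cycle once with all clients and once per
#' excluded client (K clients => K + 1 conditions), in both federated and
#' centralized modes, over a seed list. The all-clients condition uses
#' exactly the same seeds as a standalone run, so its results are
#' reproducible independently of the study loop.
#'
#' @param clients named list of `list(X =, y =)` per silo (>= 2).
#' @param model_config,local_cfg,agg configurations.
#' @param seeds integer seed vector.
#' @param test `list(X =, y =)` evaluation pool.
#' @param n_rounds training rounds per fit.
#' @param modes which training modes to run.
#' @return data.frame: mode, dropout_client ("none" for all-clients), seed, auc.
#' @export
dropout_study <- function(clients, model_config, local_cfg, agg, seeds, test,
                          n_rounds = 20L, modes = c("federated", "centralized")) {
  assert_that(length(clients) >= 2, "dropout study needs at least 2 clients")
  conditions <- c("none", names(clients))
  out <- list()
  for (mode in modes) {
    for (drop_id in conditions) {
      cl <- if (drop_id == "none") clients else clients[names(clients) != drop_id]
      for (s in seeds) {
        model <- train_one(cl, model_config, local_cfg, agg, s, mode, n_rounds)
        out[[length(out) + 1L]] <- data.frame(
          mode = mode, dropout_client = drop_id, seed = s,
          auc = auc_roc(predict(model, test$X), test$y))
      }
    }
  }
  do.call(rbind, out)
}

#' IID-partition null experiment
#'
#' Asks whether the real silo assignment carries non-IID signal: the training
#' records are randomly redistributed across the same silo ids (sizes
#' preserved) `n_partitions` times; federated models are trained on each
#' partition over the seed list, and the original partition's median test AUC
#' is placed against the null distribution of partition medians via a
#' z-score. Quartiles and 1.5 IQR bounds are reported alongside.
#'
#' @param train training record data.frame (silo_id column defines the
#'   original partition).
#' @param tests named list of `list(X =, y =)` evaluation pools (already
#'   encoded and scaled consistently with the training features — use the
#'   same scaler).
#' @param model_config,local_cfg,agg configurations (federated training).
#' @param n_partitions number of null partitions (study default 100).
#' @param seeds model-initialisation seeds per partition (study default 30).
#' @param seed partitioning seed.
#' @param n_rounds training rounds per fit.
#' @param scaler optional scaler applied to the encoded training features.
#' @return named list (one element per test set): list(original_median,
#'   null_medians, z, q1, q3, lower, upper).
#' @export
iid_null_experiment <- function(train, tests, model_config, local_cfg, agg,
                                n_partitions = 100L, seeds = 1:30, seed = 1L,
                                n_rounds = 10L, scaler = NULL) {
  assert_that(length(unique(train$silo_id)) >= 2, "need at least 2 silos")
  fm <- build_feature_matrix(train)
  X <- if (is.null(scaler)) fm$X else apply_scaler(fm$X, scaler)
  clients_of <- function(silo_vec) {
    idx <- split(seq_len(nrow(X)), silo_vec)
    lapply(idx, function(i) list(X = X[i, , drop = FALSE], y = fm$y[i]))
  }
  median_aucs <- function(silo_vec) {
    cl <- clients_of(silo_vec)
    per_seed <- vapply(seeds, function(s) {
      model <- train_one(cl, model_config, local_cfg, agg, s, "federated", n_rounds)
      vapply(tests, function(te) auc_roc(predict(model, te$X), te$y), numeric(1))
    }, numeric(length(tests)))
    per_seed <- matrix(per_seed, nrow = length(tests))
    apply(per_seed, 1L, stats::median)
  }
  original <- median_aucs(train$silo_id)
  partitions <- partition_random_iid(train, n_partitions, seed)
  null_mat <- vapply(partitions, function(p) median_aucs(p$silo_id),
                     numeric(length(tests)))
  null_mat <- matrix(null_mat, nrow = length(tests))
  out <- lapply(seq_along(tests), function(i) {
    nm <- null_mat[i, ]
    sdn <- stats::sd(nm)
    z <- if (is.na(sdn) || sdn == 0) {
      warning("degenerate null (s.d. = 0): z undefined")
      NA_real_
    } else (original[i] - mean(nm)) / sdn
    q <- stats::quantile(nm, c(0.25, 0.75), names = FALSE)
    list(original_median = original[i], null_medians = nm, z = z,
         q1 = q[1], q3 = q[2],
         lower = q[1] - 1.5 * (q[2] - q[1]),
         upper = q[2] + 1.5 * (q[2] - q[1]))
  })
  stats::setNames(out, names(tests))
}

#' Enumerate the federated hyperparameter grid
#'
#' Cartesian product per aggregation family — FedProx: local learning rate x
#' local optimizer x client rate x proximal mu; adaptive family (FedAdagrad,
#' FedAdam, FedYogi): local learning rate x local optimizer x client rate x
#' server learning rate x tau — crossed with the model families. With the
#' study's axis values this yields 96 FedProx and 3 x 192 adaptive settings
#' per model: 672 per model, 1344 in total.
#'
#' @param models model families to cross.
#' @param local_lr,local_optimizer,client_rate general axes.
#' @param proximal_mu FedProx axis.
#' @param server_lr,tau adaptive-family axes.
#' @return data.frame, one row per setting.
#' @export
enumerate_grid <- function(models = c("mlp", "sndf"),
                           local_lr = c(0.1, 0.01, 0.001, 0.0001),
                           local_optimizer = c("sgd", "adam"),
                           client_rate = c(0.5, 1),
                           proximal_mu = c(0.5, 0.1, 0.01, 0.001, 0.0001, 0),
                           server_lr = c(1, 0.1, 0.01, 0.001),
                           tau = c(0.0001, 0.01, 0.1)) {
  axes <- list(models = models, local_lr = local_lr,
               local_optimizer = local_optimizer, client_rate = client_rate,
               proximal_mu = proximal_mu, server_lr = server_lr, tau = tau)
  empty <- names(axes)[vapply(axes, length, integer(1)) == 0L]
  if (length(empty)) stop_fv("empty grid axis '%s'", empty[1])
  prox <- expand.grid(model = models, algorithm = "fedprox",
                      local_lr = local_lr, local_optimizer = local_optimizer,
                      client_rate = client_rate, proximal_mu = proximal_mu,
                      server_lr = NA_real_, tau = NA_real_,
                      stringsAsFactors = FALSE)
  adap <- expand.grid(model = models,
                      algorithm = c("fedadagrad", "fedadam", "fedyogi"),
                      local_lr = local_lr, local_optimizer = local_optimizer,
                      client_rate = client_rate, proximal_mu = NA_real_,
                      server_lr = server_lr, tau = tau,
                      stringsAsFactors = FALSE)
  out <- rbind(prox, adap)
  rownames(out) <- NULL
  out
}

#' Two-sided Wilcoxon rank-sum comparison of per-seed AUC distributions
#'
#' @param auc_a,auc_b numeric AUC vectors from two settings.
#' @return list(p_value, median_a, median_b).
#' @export
compare_auc_wilcoxon <- function(auc_a, auc_b) {
  wt <- suppressWarnings(stats::wilcox.test(auc_a, auc_b, exact = FALSE))
  list(p_value = wt$p.value,
       median_a = stats::median(auc_a), median_b = stats::median(auc_b))
}
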