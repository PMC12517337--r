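# Experiment configuration, manifests, checkpoints -----------------------------
#
# Every analysis script is driven by a YAML document whose sections mirror the
# package's configuration objects (cohort, model, local training, aggregator,
# seeds). A manifest (config + seeds + package version) is hashed into a
# stable identifier carried by every output file, so any result table can be
# traced to the exact configuration that produced it and re-run
# bit-identically.

#' Build an experiment manifest
#'
#' @param cohort a [cohort_config()] (or NULL).
#' @param model an `mlp_config`/`sndf_config` (or NULL).
#' @param local a [local_train_config()] (or NULL).
#' @param aggregator an [aggregator_config()] (or NULL).
#' @param seeds integer seed vector.
#' @param extra optional named list of additional scalars.
#' @return list of class `experiment_manifest` with a `hash` field.
#' @export
experiment_manifest <- function(cohort = NULL, model = NULL, local = NULL,
                                aggregator = NULL, seeds = integer(0),
                                extra = list()) {
  m <- list(cohort = unclass(cohort), model = unclass(model),
            local = unclass(local), aggregator = unclass(aggregator),
            seeds = as.integer(seeds), extra = extra,
            package_version = as.character(utils::packageVersion("fedvariant")))
  m$hash <- manifest_hash(m)
  structure(m, class = "experiment_manifest")
}

# canonicalise (sort names recursively) so the hash is stable under field
# reordering
canonicalise <- function(x) {
  if (is.list(x)) {
    if (!is.null(names(x))) x <- x[order(names(x))]
    lapply(x, canonicalise)
  } else x
}

#' Stable hash of a manifest or configuration list
#' @param m list to hash (the `hash` field itself is ignored).
#' @return sha1 string.
#' @export
manifest_hash <- function(m) {
  m$hash <- NULL
  digest::digest(canonicalise(unclass(m)), algo = "sha1")
}

#' Load an experiment configuration from YAML
#'
#' Recognised sections: `cohort` (silos as a list of
#' id/n_variants/feature_shift/class_balance entries plus the cohort
#' scalars), `model` (`type: mlp|sndf` plus its fields), `local`
#' (local_train_config fields) and `aggregator` (aggregator_config fields);
#' unknown field names raise a schema error naming the field.
#'
#' @param path YAML file path.
#' @return list(cohort, model, local, aggregator, seeds) of built config
#'   objects (absent sections are NULL).
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  take <- function(x, allowed, section) {
    bad <- setdiff(names(x), allowed)
    if (length(bad)) stop_fv("unknown field '%s' in config section '%s'", bad[1], section)
    x
  }
  out <- list(cohort = NULL, model = NULL, local = NULL, aggregator = NULL,
              seeds = as.integer(raw$seeds %||% 1L))
  if (!is.null(raw$cohort)) {
    co <- take(raw$cohort, c("variant_type", "silos", "split_date", "test1_n",
                             "test2_n", "class_sep", "seed", "chrom_weights",
                             "shift_mode"),
               "cohort")
    silos <- lapply(co$silos, function(s) {
      s <- take(s, c("silo_id", "n_variants", "feature_shift", "class_balance"), "silos")
      silo_spec(s$silo_id, s$n_variants, s$feature_shift %||% 0,
                s$class_balance %||% 0.5)
    })
    out$cohort <- cohort_config(co$variant_type, silos,
                                split_date = as.Date(co$split_date %||% "2020-01-01"),
                                test1_n = co$test1_n %||% 500L,
                                test2_n = co$test2_n %||% 500L,
                                class_sep = co$class_sep %||% 3,
                                seed = co$seed %||% 1L,
                                shift_mode = co$shift_mode %||% "both")
  }
  if (!is.null(raw$model)) {
    mo <- raw$model
    if (is.null(mo$type) || !mo$type %in% c("mlp", "sndf"))
      stop_fv("config field 'model.type' must be 'mlp' or 'sndf'")
    out$model <- if (mo$type == "mlp") {
      mo <- take(mo, c("type", "input_dim", "n_hidden", "use_batch_norm"), "model")
      mlp_config(mo$input_dim, mo$n_hidden %||% 6L,
                 isTRUE(mo$use_batch_norm))
    } else {
      mo <- take(mo, c("type", "input_dim", "n_trees", "depth", "feature_rate"), "model")
      sndf_config(mo$input_dim, mo$n_trees %||% 5L, mo$depth %||% 3L,
                  mo$feature_rate %||% 0.7)
    }
  }
  if (!is.null(raw$local)) {
    lo <- take(raw$local, c("learning_rate", "optimizer", "batch_size",
                            "epochs", "weight_decay", "proximal_mu", "momentum"),
               "local")
    out$local <- local_train_config(lo$learning_rate %||% 0.01,
                                    lo$optimizer %||% "sgd",
                                    lo$batch_size %||% 32L,
                                    lo$epochs %||% 10L,
                                    lo$weight_decay %||% 1e-4,
                                    lo$proximal_mu %||% 0,
                                    lo$momentum %||% 0.9)
  }
  if (!is.null(raw$aggregator)) {
    ag <- take(raw$aggregator, c("algorithm", "proximal_mu", "server_lr", "tau",
                                 "beta1", "beta2", "client_rate", "n_rounds",
                                 "bn_policy"), "aggregator")
    if (!is.null(ag$algorithm) &&
        !ag$algorithm %in% c("fedavg", "fedprox", "fedadagrad", "fedadam", "fedyogi"))
      stop_fv("config field 'aggregator.algorithm': unknown algorithm '%s'",
              ag$algorithm)
    out$aggregator <- aggregator_config(ag$algorithm %||% "fedavg",
                                        ag$proximal_mu %||% 0,
                                        ag$server_lr %||% 0.1,
                                        ag$tau %||% 0.01,
                                        ag$beta1 %||% 0.9,
                                        ag$beta2 %||% 0.999,
                                        ag$client_rate %||% 1,
                                        ag$n_rounds %||% 200L,
                                        ag$bn_policy %||% "aggregate")
  }
  out
}

#' Save a model checkpoint as text
#'
#' JSON header (configuration, layout, manifest hash) plus the flat
#' parameter array at full precision.
#'
#' @param model a `fedvar_model`.
#' @param path output path.
#' @param hash optional manifest hash to embed.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path, hash = NULL) {
  payload <- list(
    config = unclass(model$config),
    layout = model$layout,
    masks = if (!is.null(model$masks)) as.logical(model$masks) else NULL,
    manifest_hash = hash,
    params = model$params
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load a model checkpoint written by [save_checkpoint()]
#' @param path checkpoint path.
#' @return a `fedvar_model`.
#' @export
load_checkpoint <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- payload$config
  config <- if (cfg$model == "mlp") {
    mlp_config(cfg$input_dim, cfg$n_hidden, isTRUE(cfg$use_batch_norm))
  } else {
    sndf_config(cfg$input_dim, cfg$n_trees, cfg$depth, cfg$feature_rate)
  }
  model <- model_init(config, seed = 0L)
  model <- unflatten_params(model, payload$params)
  if (!is.null(payload$masks) && config$model == "sndf")
    model$masks <- matrix(payload$masks, config$input_dim, config$n_trees)
  model
}
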