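# Synthetic multi-silo cohorts -------------------------------------------------
#
# The generator emulates submitter-attributed variant collections: a small
# number of institutional silos with heavily skewed sizes, a temporal split
# into a training window and a later independent test window, a second
# independent test pool drawn from silos that did not participate in
# training, and 1:1 pathogenic/benign balance obtained by downsampling.
# Feature payloads come from a two-class generative model: class-conditional
# multivariate Gaussians with shared unit diagonal covariance, where
# `class_sep` is the per-informative-dimension mean separation (in s.d.
# units), plus an additive per-silo mean shift (zero => IID silos). The shift
# can apply to the whole silo ("both") or to the pathogenic class only
# ("pathogenic"), the latter emulating collections whose pathogenic variants
# cluster by client of origin — the structure behind CNV-like non-IID silos.
#
# A cohort is a plain data.frame with one row per variant: variant_id,
# chromosome (1-22, X), silo_id, report_date, label (1 pathogenic / 0 benign),
# variant_type, length_bp (CNVs), then payload columns (window sequence and
# conservation tracks for SNVs; region features and an overlapping-gene table
# for CNVs).

SNV_TRACKS <- c("phyloP100", "phyloP470", "phyloP3", "phyloP4", "phyloP7",
                "phyloP17", "phyloP20")

CNV_REGION_COLS <- c("cov_open_chromatin", "cov_tfbs", "cov_promoter",
                     "cov_promoter_flank", "cov_ctcf", "cov_enhancer",
                     "max_recomb", "max_cadd", "max_gerp", "max_gene_density",
                     "overlap_har", "overlap_lad", "overlap_ucne",
                     "overlap_sv_hotspot", "dist_centromere_mb",
                     "dist_telomere_mb")

CNV_GENE_COLS <- c("pli", "loeuf", "pnull", "ccr", "eds", "hi_pred", "ts_pred",
                   "ohnolog", "tf", "crispr", "complex_member", "expr_mean",
                   "expr_min", "phastcons", "promoter_cpg", "degree",
                   "pagerank", "betweenness", "closeness", "sp_hi", "sp_ts")

snv_payload_cols <- function() {
  c("window_seq", as.vector(t(outer(SNV_TRACKS, paste0("_p", 1:5), paste0))))
}

#' Specification of one institutional silo
#'
#' @param silo_id unique silo identifier.
#' @param n_variants raw silo size before class balancing (>= 2).
#' @param feature_shift per-silo additive mean offset on the continuous
#'   payload dimensions: a scalar (recycled) or a full-length vector. Zero
#'   for every silo yields IID silos.
#' @param class_balance fraction of pathogenic variants in the raw pool,
#'   in (0, 1).
#' @return an object of class `silo_spec`.
#' @export
silo_spec <- function(silo_id, n_variants, feature_shift = 0, class_balance = 0.5) {
  assert_that(n_variants >= 2, "silo '%s': n_variants must be >= 2", silo_id)
  assert_that(class_balance > 0 && class_balance < 1,
              "silo '%s': class_balance must be in (0, 1)", silo_id)
  structure(list(silo_id = as.character(silo_id),
                 n_variants = as.integer(n_variants),
                 feature_shift = feature_shift,
                 class_balance = class_balance),
            class = "silo_spec")
}

#' Cohort configuration
#'
#' @param variant_type "coding_snv", "noncoding_snv" or "deletion_cnv".
#' @param silos list of [silo_spec()] (>= 2, unique ids).
#' @param split_date calendar date separating the training window from the
#'   later independent test window.
#' @param test1_n size of the independent test pool contributed by silos that
#'   did not participate in training (dated before `split_date`).
#' @param test2_n size of the temporally independent test pool (dated after
#'   `split_date`).
#' @param class_sep class-conditional mean separation per informative
#'   dimension, in units of the shared s.d. At the default 3 the two classes
#'   are cleanly separable (Bayes AUC ~ 1), matching the separable synthetic
#'   condition used for recovery experiments.
#' @param seed integer seed; identical config + seed reproduce the cohort
#'   byte-identically.
#' @param chrom_weights optional length-23 weight vector over chromosomes
#'   1-22, X; uniform when NULL.
#' @param shift_mode "both" applies each silo's `feature_shift` to all of its
#'   records; "pathogenic" shifts only the pathogenic class, emulating
#'   per-client clustering of pathogenic variants (class-conditional
#'   non-IID).
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(variant_type = c("coding_snv", "noncoding_snv", "deletion_cnv"),
                          silos, split_date = as.Date("2020-01-01"),
                          test1_n = 500L, test2_n = 500L, class_sep = 3,
                          seed = 1L, chrom_weights = NULL,
                          shift_mode = c("both", "pathogenic")) {
  variant_type <- match.arg(variant_type)
  shift_mode <- match.arg(shift_mode)
  assert_that(length(silos) >= 2, "at least 2 silos required")
  ids <- vapply(silos, function(s) s$silo_id, character(1))
  if (anyDuplicated(ids)) stop_fv("duplicate silo_id: %s", ids[duplicated(ids)][1])
  if (!is.null(chrom_weights))
    assert_that(length(chrom_weights) == 23L, "chrom_weights must have length 23")
  structure(list(variant_type = variant_type, silos = silos,
                 split_date = as.Date(split_date),
                 test1_n = as.integer(test1_n), test2_n = as.integer(test2_n),
                 class_sep = class_sep, seed = as.integer(seed),
                 chrom_weights = chrom_weights, shift_mode = shift_mode),
            class = "cohort_config")
}

# chromosome assignment: uniform (or weighted) draw, but guaranteeing that all
# 23 symbols appear when n >= 23 by seeding with one permutation of the set
draw_chromosomes <- function(n, weights = NULL) {
  w <- weights %||% rep(1, 23)
  out <- sample(CHROMOSOMES, n, replace = TRUE, prob = w)
  if (n >= 23L) out[sample.int(n, 23L)] <- sample(CHROMOSOMES)
  out
}

# class-conditional conservation payload for SNVs: benign mean 0, pathogenic
# mean +class_sep on the centre position of each track, shared unit s.d.
snv_payload <- function(n, labels, class_sep, shift, shift_on = rep(TRUE, n)) {
  ncols <- 35L
  shift <- rep_len(shift, ncols)
  mu <- matrix(rep(shift, each = n), n, ncols)
  mu[!shift_on, ] <- 0
  informative <- which(rep(1:5, times = 7) == 3L)   # centre position per track
  mu[labels == 1, informative] <- mu[labels == 1, informative] + class_sep
  cons <- mu + matrix(stats::rnorm(n * ncols), n, ncols)
  window <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T", "N"), 5, replace = TRUE,
                 prob = c(rep(0.2475, 4), 0.01)), collapse = ""),
    character(1))
  df <- as.data.frame(cons)
  names(df) <- snv_payload_cols()[-1]
  cbind(data.frame(window_seq = window, stringsAsFactors = FALSE), df)
}

# one synthetic overlapping-gene table; pathogenic CNVs hit more constrained,
# more connected genes with shorter network paths to dosage-sensitive genes
cnv_gene_table <- function(n_genes, pathogenic, class_sep) {
  if (n_genes == 0L) {
    return(stats::setNames(as.data.frame(matrix(numeric(0), 0, length(CNV_GENE_COLS))),
                           CNV_GENE_COLS))
  }
  s <- class_sep / 3           # scale the separation to unit-range scores
  bump <- if (pathogenic) s else 0
  data.frame(
    pli = stats::plogis(stats::rnorm(n_genes, -1 + 2 * bump)),
    loeuf = stats::plogis(stats::rnorm(n_genes, 0 + bump)),
    pnull = stats::plogis(stats::rnorm(n_genes, 0 - bump)),
    ccr = pmax(0, stats::rnorm(n_genes, 50 + 20 * bump, 15)),
    eds = stats::plogis(stats::rnorm(n_genes, -0.5 + bump)),
    hi_pred = stats::plogis(stats::rnorm(n_genes, -1 + 2 * bump)),
    ts_pred = stats::plogis(stats::rnorm(n_genes, -1.5 + bump)),
    ohnolog = stats::rbinom(n_genes, 1, 0.2 + 0.2 * min(bump, 1)),
    tf = stats::rbinom(n_genes, 1, 0.1 + 0.1 * min(bump, 1)),
    crispr = stats::rnorm(n_genes, -0.5 - bump, 1),
    complex_member = stats::rbinom(n_genes, 1, 0.3 + 0.2 * min(bump, 1)),
    expr_mean = pmax(0, stats::rnorm(n_genes, 20 + 10 * bump, 8)),
    expr_min = pmax(0, stats::rnorm(n_genes, 2 + bump, 1.5)),
    phastcons = stats::plogis(stats::rnorm(n_genes, -0.5 + bump)),
    promoter_cpg = stats::plogis(stats::rnorm(n_genes, 0 + bump)),
    degree = stats::rpois(n_genes, 10 + 10 * bump) + 1,
    pagerank = stats::rexp(n_genes, rate = 1 / (1e-4 * (1 + bump))),
    betweenness = stats::rexp(n_genes, rate = 1 / (100 * (1 + bump))),
    closeness = stats::plogis(stats::rnorm(n_genes, -1 + bump)),
    sp_hi = pmax(1, stats::rpois(n_genes, max(0.5, 4 - 2 * bump))),
    sp_ts = pmax(1, stats::rpois(n_genes, max(0.5, 5 - 2 * bump)))
  )
}

cnv_payload <- function(n, labels, class_sep, shift, shift_on = rep(TRUE, n)) {
  s <- class_sep / 3
  bump <- ifelse(labels == 1, s, 0)
  shift <- rep_len(shift, length(CNV_REGION_COLS))
  cont <- c("cov_open_chromatin", "cov_tfbs", "cov_promoter", "cov_promoter_flank",
            "cov_ctcf", "cov_enhancer", "max_recomb", "max_cadd", "max_gerp",
            "max_gene_density", "dist_centromere_mb", "dist_telomere_mb")
  df <- data.frame(
    cov_open_chromatin = pmin(1, pmax(0, stats::rnorm(n, 0.1 + 0.1 * bump, 0.08))),
    cov_tfbs = pmin(1, pmax(0, stats::rnorm(n, 0.08 + 0.08 * bump, 0.06))),
    cov_promoter = pmin(1, pmax(0, stats::rnorm(n, 0.05 + 0.05 * bump, 0.05))),
    cov_promoter_flank = pmin(1, pmax(0, stats::rnorm(n, 0.05 + 0.05 * bump, 0.05))),
    cov_ctcf = pmin(1, pmax(0, stats::rnorm(n, 0.04 + 0.04 * bump, 0.04))),
    cov_enhancer = pmin(1, pmax(0, stats::rnorm(n, 0.06 + 0.06 * bump, 0.05))),
    max_recomb = pmax(0, stats::rnorm(n, 2, 1)),
    max_cadd = pmax(0, stats::rnorm(n, 15 + 5 * bump, 4)),
    max_gerp = stats::rnorm(n, 2 + 2 * bump, 1.5),
    max_gene_density = pmax(0, stats::rnorm(n, 10 + 5 * bump, 4)),
    overlap_har = stats::rbinom(n, 1, 0.05 + 0.1 * pmin(bump, 1)),
    overlap_lad = stats::rbinom(n, 1, 0.3),
    overlap_ucne = stats::rbinom(n, 1, 0.05 + 0.15 * pmin(bump, 1)),
    overlap_sv_hotspot = stats::rbinom(n, 1, 0.15),
    dist_centromere_mb = stats::rexp(n, 1 / 30),
    dist_telomere_mb = stats::rexp(n, 1 / 20)
  )
  shift_named <- stats::setNames(shift, CNV_REGION_COLS)
  for (col in cont) df[[col]] <- df[[col]] + shift_named[[col]] * shift_on
  for (col in grep("^cov_", names(df), value = TRUE)) df[[col]] <- pmin(1, pmax(0, df[[col]]))
  for (col in c("dist_centromere_mb", "dist_telomere_mb")) df[[col]] <- pmax(0, df[[col]])
  genes <- lapply(seq_len(n), function(i) {
    ng <- stats::rpois(1, if (labels[i] == 1) 2.5 else 1.5)
    cnv_gene_table(ng, labels[i] == 1, class_sep)
  })
  df$genes <- I(genes)
  df
}

make_records <- function(config, n, silo_id, labels, date_lo, date_hi, shift,
                         id_prefix) {
  dates <- date_lo + floor(stats::runif(n) * (as.numeric(date_hi - date_lo) + 1))
  base <- data.frame(
    variant_id = sprintf("%s_%06d", id_prefix, seq_len(n)),
    chromosome = draw_chromosomes(n, config$chrom_weights),
    silo_id = silo_id,
    report_date = dates,
    label = labels,
    variant_type = config$variant_type,
    stringsAsFactors = FALSE
  )
  shift_on <- if ((config$shift_mode %||% "both") == "pathogenic") labels == 1
              else rep(TRUE, n)
  if (config$variant_type == "deletion_cnv") {
    base$length_bp <- round(stats::rlnorm(n, meanlog = ifelse(labels == 1, 11.5, 10.8),
                                          sdlog = 1.1)) + 1
    cbind(base, cnv_payload(n, labels, config$class_sep, shift, shift_on))
  } else {
    base$length_bp <- NA_integer_
    cbind(base, snv_payload(n, labels, config$class_sep, shift, shift_on))
  }
}

#' Generate a synthetic multi-silo cohort
#'
#' Returns training records grouped by silo (one data.frame with a `silo_id`
#' column), plus two independent test pools: `test1` from silos that did not
#' participate in training (dated inside the training window) and `test2`
#' dated after the split date. Test pools are balanced and unshifted, so they
#' probe generalisation rather than silo idiosyncrasies.
#'
#' @param config a [cohort_config()].
#' @return list(train, test1, test2) of record data.frames.
#' @export
generate_cohort <- function(config) {
  assert_that(inherits(config, "cohort_config"), "config must be a cohort_config")
  with_seed(config$seed, {
    train <- do.call(rbind, lapply(config$silos, function(sp) {
      n_path <- round_half_up(sp$n_variants * sp$class_balance)
      n_path <- min(max(n_path, 1L), sp$n_variants - 1L)  # keep both classes
      labels <- sample(rep(c(1L, 0L), c(n_path, sp$n_variants - n_path)))
      make_records(config, sp$n_variants, sp$silo_id, labels,
                   config$split_date - 365L, config$split_date - 1L,
                   sp$feature_shift, paste0(config$variant_type, "_", sp$silo_id))
    }))
    balanced_half <- function(n) sample(rep(c(1L, 0L), c(ceiling(n / 2), floor(n / 2))))
    test1 <- do.call(rbind, lapply(1:2, function(k) {
      n_k <- if (k == 1) ceiling(config$test1_n / 2) else floor(config$test1_n / 2)
      if (n_k == 0L) return(NULL)
      make_records(config, n_k, paste0("external_", k), balanced_half(n_k),
                   config$split_date - 365L, config$split_date - 1L, 0,
                   paste0(config$variant_type, "_ext", k))
    }))
    test2 <- make_records(config, config$test2_n, "post_split",
                          balanced_half(config$test2_n),
                          config$split_date, config$split_date + 364L, 0,
                          paste0(config$variant_type, "_t2"))
    rownames(train) <- rownames(test1) <- rownames(test2) <- NULL
    list(train = train, test1 = test1, test2 = test2)
  })
}

#' Downsample each silo to a 1:1 pathogenic/benign balance
#'
#' The majority class of every silo is randomly downsampled to the minority
#' count; the result is a subset of the input and deterministic under `seed`.
#'
#' @param records record data.frame with `silo_id` and `label` columns.
#' @param seed integer seed.
#' @return the balanced subset, original row order preserved.
#' @export
balance_classes <- function(records, seed) {
  keep <- with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(records)), records$silo_id), function(idx) {
      labs <- records$label[idx]
      n1 <- sum(labs == 1); n0 <- sum(labs == 0)
      if (n1 == 0L || n0 == 0L)
        stop_fv("silo '%s' has only one label present", records$silo_id[idx[1]])
      n_keep <- min(n1, n0)
      c(sample(idx[labs == 1], n_keep), sample(idx[labs == 0], n_keep))
    }))
  })
  records[sort(keep), , drop = FALSE]
}

#' Pair pathogenic CNVs with length-matched benign CNVs
#'
#' Greedy nearest-neighbour matching on log genomic length, processing
#' pathogenic CNVs in descending length order; each benign CNV is used at most
#' once. The paired benign record inherits the pathogenic record's report
#' date (emulating same-submission-date matched pairs).
#'
#' @param pathogenic data.frame of pathogenic deletion CNV records.
#' @param benign_pool data.frame of candidate benign records, at least as
#'   large as `pathogenic`.
#' @return data.frame of the selected benign records (dates copied), with a
#'   `matched_to` column naming the paired pathogenic variant_id, ordered as
#'   `pathogenic` rows.
#' @export
match_benign_by_length <- function(pathogenic, benign_pool) {
  assert_that(all(pathogenic$variant_type == "deletion_cnv") &&
                all(benign_pool$variant_type == "deletion_cnv"),
              "length matching applies to deletion CNVs only")
  if (nrow(benign_pool) < nrow(pathogenic))
    stop_fv("benign pool (%d) smaller than pathogenic set (%d)",
            nrow(benign_pool), nrow(pathogenic))
  ord <- order(pathogenic$length_bp, decreasing = TRUE)
  available <- rep(TRUE, nrow(benign_pool))
  pick <- integer(nrow(pathogenic))
  for (i in ord) {
    if (!any(available)) stop_fv("benign pool exhausted")
    cand <- which(available)
    d <- abs(log(benign_pool$length_bp[cand]) - log(pathogenic$length_bp[i]))
    j <- cand[which.min(d)]
    pick[i] <- j
    available[j] <- FALSE
  }
  out <- benign_pool[pick, , drop = FALSE]
  out$report_date <- pathogenic$report_date
  out$matched_to <- pathogenic$variant_id
  rownames(out) <- NULL
  out
}

#' Random IID re-partitions of the training records
#'
#' Each partition reassigns all training records to the same silo ids with
#' the original per-silo counts preserved exactly — the null construction
#' used to ask whether the real silo assignment carries non-IID signal.
#'
#' @param train training record data.frame (with `silo_id`).
#' @param n_partitions number of independent partitions.
#' @param seed integer seed; partition k is a deterministic function of
#'   (seed, k).
#' @return list of `n_partitions` data.frames.
#' @export
partition_random_iid <- function(train, n_partitions, seed) {
  if (nrow(train) == 0L) stop_fv("empty training set")
  counts <- table(train$silo_id)
  ids <- rep(names(counts), as.integer(counts))
  lapply(seq_len(n_partitions), function(k) {
    perm <- with_seed(derive_seed(seed, k), sample.int(nrow(train)))
    out <- train
    out$silo_id[perm] <- ids
    out
  })
}

# TSV round-trip ---------------------------------------------------------------

#' Write a cohort to TSV files
#'
#' One file per split (train/test1/test2), ISO-8601 dates; the CNV
#' overlapping-gene tables are serialised as compact JSON in a `genes`
#' column so the files stay plain text.
#'
#' @param cohort list(train, test1, test2) from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (split in names(cohort)) {
    df <- cohort[[split]]
    if (!is.null(df$genes)) {
      df$genes <- vapply(df$genes, function(g)
        as.character(jsonlite::toJSON(g, digits = NA)), character(1))
    }
    df$report_date <- format(df$report_date, "%Y-%m-%d")
    utils::write.table(df, file.path(dir, paste0(split, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory holding train.tsv / test1.tsv / test2.tsv.
#' @return list of record data.frames.
#' @export
read_cohort <- function(dir) {
  splits <- c("train", "test1", "test2")
  out <- lapply(splits, function(split) {
    f <- file.path(dir, paste0(split, ".tsv"))
    if (!file.exists(f)) return(NULL)
    df <- utils::read.delim(f, stringsAsFactors = FALSE, quote = "",
                            colClasses = c(chromosome = "character"))
    df$report_date <- as.Date(df$report_date)
    if (!is.null(df$genes)) {
      df$genes <- I(lapply(df$genes, function(s) {
        g <- jsonlite::fromJSON(s)
        if (length(g) == 0L || nrow(as.data.frame(g)) == 0L)
          cnv_gene_table(0L, FALSE, 0)
        else as.data.frame(g)[, CNV_GENE_COLS]
      }))
    }
    df
  })
  stats::setNames(out, splits)
}
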