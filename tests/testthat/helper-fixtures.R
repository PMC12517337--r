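# Shared fixtures: everything is generated in code at test time.

# small SNV cohort with encoded, scaled features and silo-wise clients
make_snv_fixture <- function(silo_sizes = c(a = 120, b = 80), class_sep = 3,
                             seed = 7, test1_n = 100, shifts = NULL,
                             shift_mode = "both") {
  silos <- lapply(seq_along(silo_sizes), function(i) {
    silo_spec(names(silo_sizes)[i], silo_sizes[i],
              feature_shift = if (is.null(shifts)) 0 else shifts[[i]])
  })
  cfg <- cohort_config("coding_snv", silos, test1_n = test1_n, test2_n = 50,
                       class_sep = class_sep, seed = seed,
                       shift_mode = shift_mode)
  coh <- generate_cohort(cfg)
  fm <- build_feature_matrix(coh$train)
  scaler <- fit_scaler(fm$X)
  Xs <- apply_scaler(fm$X, scaler)
  clients <- lapply(split(seq_len(nrow(Xs)), fm$silo_id),
                    function(i) list(X = Xs[i, , drop = FALSE], y = fm$y[i]))
  fmt <- build_feature_matrix(coh$test1)
  list(config = cfg, cohort = coh, fm = fm, scaler = scaler, Xs = Xs,
       clients = clients,
       test1 = list(X = apply_scaler(fmt$X, scaler), y = fmt$y))
}

# closed-form linear oracle under the generator's shared-diagonal-covariance
# model: score along the difference of class means
fisher_scores <- function(X, y, X_new = X) {
  w <- colMeans(X[y == 1, , drop = FALSE]) - colMeans(X[y == 0, , drop = FALSE])
  drop(X_new %*% w)
}

# brute-force AUC oracle: pairwise concordance count with half-credit ties
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# minimal per-gene table for CNV encoding tests
gene_row <- function(...) {
  defaults <- list(pli = 0.5, loeuf = 0.5, pnull = 0.5, ccr = 50, eds = 0.5,
                   hi_pred = 0.5, ts_pred = 0.5, ohnolog = 0, tf = 0,
                   crispr = 0, complex_member = 0, expr_mean = 10,
                   expr_min = 2, phastcons = 0.5, promoter_cpg = 0.5,
                   degree = 5, pagerank = 1e-4, betweenness = 10,
                   closeness = 0.3, sp_hi = 3, sp_ts = 4)
  args <- list(...)
  defaults[names(args)] <- args
  as.data.frame(defaults)
}

region_defaults <- function(...) {
  d <- list(cov_open_chromatin = 0.1, cov_tfbs = 0.1, cov_promoter = 0.05,
            cov_promoter_flank = 0.05, cov_ctcf = 0.04, cov_enhancer = 0.06,
            max_recomb = 2, max_cadd = 15, max_gerp = 2, max_gene_density = 10,
            overlap_har = 0, overlap_lad = 1, overlap_ucne = 0,
            overlap_sv_hotspot = 0, dist_centromere_mb = 30, dist_telomere_mb = 20)
  args <- list(...)
  d[names(args)] <- args
  d
}

# tiny random model + data for gradient and round-trip checks
rand_X <- function(n, d, seed) {
  set.seed(seed)
  matrix(stats::rnorm(n * d), n, d)
}
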