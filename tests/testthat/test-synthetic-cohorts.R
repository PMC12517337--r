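# Synthetic multi-silo cohort generator

test_that("silo sizes follow the configured skewed proportions", {
  # skew profile of the coding-SNV collaboration: 64.8% down to 3%
  props <- c(64.8, 13, 9, 6, 4.2, 3) / 100
  n_total <- 2000
  silos <- lapply(seq_along(props), function(i)
    silo_spec(paste0("inst", i), round(props[i] * n_total)))
  cfg <- cohort_config("coding_snv", silos, test1_n = 50, test2_n = 50, seed = 3)
  coh <- generate_cohort(cfg)
  counts <- table(coh$train$silo_id)[paste0("inst", seq_along(props))]
  expect_equal(as.integer(counts), vapply(silos, function(s) s$n_variants, integer(1)))
  expect_equal(as.numeric(counts / sum(counts)), props, tolerance = 1e-3)
})

test_that("cohorts are reproducible under a fixed seed and vary across seeds", {
  silos <- list(silo_spec("a", 40), silo_spec("b", 30))
  c1 <- generate_cohort(cohort_config("coding_snv", silos, seed = 5,
                                      test1_n = 20, test2_n = 20))
  c2 <- generate_cohort(cohort_config("coding_snv", silos, seed = 5,
                                      test1_n = 20, test2_n = 20))
  c3 <- generate_cohort(cohort_config("coding_snv", silos, seed = 6,
                                      test1_n = 20, test2_n = 20))
  expect_identical(c1, c2)
  expect_false(identical(c1$train, c3$train))
})

test_that("temporal and silo disjointness of the test pools holds", {
  fx <- make_snv_fixture(seed = 11)
  coh <- fx$cohort
  expect_true(all(coh$train$report_date < fx$config$split_date))
  expect_true(all(coh$test2$report_date >= fx$config$split_date))
  expect_true(all(coh$test1$report_date < fx$config$split_date))
  expect_length(intersect(unique(coh$train$silo_id), unique(coh$test1$silo_id)), 0)
})

test_that("all 23 chromosome symbols are covered when n >= 23", {
  fx <- make_snv_fixture(seed = 12)
  expect_setequal(unique(fx$cohort$train$chromosome), c(as.character(1:22), "X"))
})

test_that("zero feature shift yields statistically indistinguishable silo means", {
  # property: at alpha = 0.01 a two-sample test of per-silo feature means
  # should fail to reject in at least 95% of IID cohorts
  n_rep <- 40
  rejections <- 0L
  for (r in seq_len(n_rep)) {
    silos <- list(silo_spec("a", 40), silo_spec("b", 40))
    coh <- generate_cohort(cohort_config("coding_snv", silos, seed = 100 + r,
                                         test1_n = 4, test2_n = 4))
    x <- coh$train$phyloP100_p1
    p <- stats::t.test(x[coh$train$silo_id == "a"], x[coh$train$silo_id == "b"])$p.value
    if (p < 0.01) rejections <- rejections + 1L
  }
  expect_lte(rejections / n_rep, 0.05)
})

test_that("a separable cohort is linearly separable by the closed-form direction", {
  # class-conditional means separated by 3 s.d. per informative dimension
  fx <- make_snv_fixture(silo_sizes = c(a = 1000, b = 1000), class_sep = 3,
                         seed = 21, test1_n = 10)
  auc <- auc_roc(fisher_scores(fx$Xs, fx$fm$y), fx$fm$y)
  expect_gt(auc, 0.99)
})

test_that("invalid cohort configurations are rejected", {
  expect_error(silo_spec("a", 1), "n_variants")
  expect_error(cohort_config("coding_snv",
                             list(silo_spec("a", 10), silo_spec("a", 10))),
               "duplicate silo_id")
  expect_error(cohort_config("coding_snv", list(silo_spec("a", 10))),
               "at least 2 silos")
})

test_that("class balancing downsamples the majority class per silo", {
  rec <- data.frame(
    variant_id = sprintf("v%02d", 1:95),
    silo_id = rep(c("a", "b"), c(40, 55)),
    label = c(rep(1, 30), rep(0, 10), rep(1, 5), rep(0, 50))
  )
  bal <- balance_classes(rec, seed = 4)
  tab <- table(bal$silo_id, bal$label)
  expect_equal(unname(tab["a", ]), c(10, 10))
  expect_equal(unname(tab["b", ]), c(5, 5))
  # subset of the input, deterministic
  expect_true(all(bal$variant_id %in% rec$variant_id))
  expect_identical(bal, balance_classes(rec, seed = 4))
  # already balanced silo passes through intact
  rec2 <- rec[rec$silo_id == "a", ][c(1:10, 31:40), ]
  expect_setequal(balance_classes(rec2, seed = 1)$variant_id, rec2$variant_id)
})

test_that("balancing fails loudly on a single-label silo", {
  rec <- data.frame(variant_id = c("x1", "x2"), silo_id = "solo", label = c(1, 1))
  expect_error(balance_classes(rec, seed = 1), "solo")
})

test_that("benign CNVs are matched to pathogenic by log-length, optimally", {
  mk <- function(id, len, lab) data.frame(
    variant_id = id, chromosome = "1", silo_id = "s",
    report_date = as.Date("2020-06-01") + seq_along(id), label = lab,
    variant_type = "deletion_cnv", length_bp = len
  )
  path <- mk(c("p1", "p2"), c(1000, 5000), 1)
  pool <- mk(c("b1", "b2", "b3"), c(990, 5100, 200), 0)
  matched <- match_benign_by_length(path, pool)
  expect_equal(matched$matched_to, c("p1", "p2"))
  expect_equal(matched$variant_id, c("b1", "b2"))
  # oracle: exhaustive search over all one-to-one assignments
  best <- Inf; best_pick <- NULL
  for (perm in list(c(1, 2), c(1, 3), c(2, 1), c(2, 3), c(3, 1), c(3, 2))) {
    cost <- sum(abs(log(pool$length_bp[perm]) - log(path$length_bp)))
    if (cost < best) { best <- cost; best_pick <- perm }
  }
  expect_equal(matched$variant_id, pool$variant_id[best_pick])
  # matched benign records carry the pathogenic submission dates
  expect_equal(matched$report_date, path$report_date)
  # identical pools match perfectly with zero total log-ratio
  pool_eq <- mk(c("c1", "c2"), c(1000, 5000), 0)
  m2 <- match_benign_by_length(path, pool_eq)
  expect_equal(sum(abs(log(m2$length_bp) - log(path$length_bp))), 0)
  # exhausted pool errors
  expect_error(match_benign_by_length(path, pool[1, ]), "pool")
})

test_that("random IID partitions preserve silo sizes and records exactly", {
  fx <- make_snv_fixture(silo_sizes = c(a = 5, b = 3), seed = 31, test1_n = 4)
  parts <- partition_random_iid(fx$cohort$train, n_partitions = 100, seed = 9)
  expect_length(parts, 100)
  orig_sizes <- table(fx$cohort$train$silo_id)
  for (p in parts[c(1, 50, 100)]) {
    expect_equal(table(p$silo_id), orig_sizes)
    expect_setequal(p$variant_id, fx$cohort$train$variant_id)
  }
  # deterministic, but partitions differ from each other
  parts2 <- partition_random_iid(fx$cohort$train, n_partitions = 2, seed = 9)
  expect_identical(parts[[1]], parts2[[1]])
  expect_false(identical(parts[[1]]$silo_id, parts[[2]]$silo_id))
})

test_that("cohort TSV round-trip preserves records", {
  dir <- withr::local_tempdir()
  fx <- make_snv_fixture(silo_sizes = c(a = 10, b = 8), seed = 41, test1_n = 6)
  write_cohort(fx$cohort, dir)
  back <- read_cohort(dir)
  expect_equal(back$train$variant_id, fx$cohort$train$variant_id)
  expect_equal(back$train$report_date, fx$cohort$train$report_date)
  expect_equal(back$train$phyloP20_p5, fx$cohort$train$phyloP20_p5)
  # CNV cohorts round-trip their gene tables through JSON
  silos <- list(silo_spec("a", 6), silo_spec("b", 6))
  coh <- generate_cohort(cohort_config("deletion_cnv", silos, test1_n = 4,
                                       test2_n = 4, seed = 42))
  write_cohort(coh, dir)
  back2 <- read_cohort(dir)
  m1 <- build_feature_matrix(coh$train)
  m2 <- build_feature_matrix(back2$train)
  expect_equal(m2$X, m1$X)
})
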