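#!/usr/bin/env Rscript
# Simulate the three multi-silo study scenarios and write them as TSV cohorts.
#
# Scenario shapes mirror the real collaborations the generator emulates:
#   - coding SNVs: 6 silos, heavily skewed (64.8% down to 3%)
#   - non-coding SNVs: 8 silos, skew 45.5% down to 2%
#   - deletion CNVs: 8 silos, one holding ~90% of the data
# Every silo is downsampled to a 1:1 pathogenic/benign balance, as in the
# study. Sizes here are desk-scale (a few thousand variants in total), and
# the class separation is moderate (class_sep = 1.5, Bayes AUC ~ 0.99) so
# that the local/centralized/federated comparison downstream has headroom to
# differ — a fully separable cohort saturates every mode at AUC 1.

suppressPackageStartupMessages(library(fedvariant))

out_dir <- "results/cohorts"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

scenarios <- list(
  coding_snv = list(
    type = "coding_snv", total = 3000,
    props = c(0.648, 0.13, 0.09, 0.06, 0.042, 0.03)),
  noncoding_snv = list(
    type = "noncoding_snv", total = 2000,
    props = c(0.455, 0.18, 0.12, 0.08, 0.06, 0.045, 0.04, 0.02)),
  deletion_cnv = list(
    type = "deletion_cnv", total = 1500,
    props = c(0.90, 0.022, 0.018, 0.015, 0.013, 0.012, 0.012, 0.008))
)

for (name in names(scenarios)) {
  sc <- scenarios[[name]]
  silos <- lapply(seq_along(sc$props), function(i)
    silo_spec(sprintf("inst_%02d", i), max(4, round(sc$props[i] * sc$total)),
              class_balance = 0.5))
  cfg <- cohort_config(sc$type, silos, test1_n = 300, test2_n = 200,
                       class_sep = 1.5, seed = 20260100 + match(name, names(scenarios)))
  coh <- generate_cohort(cfg)
  coh$train <- balance_classes(coh$train, seed = cfg$seed + 1)
  write_cohort(coh, file.path(out_dir, name))
  sizes <- sort(table(coh$train$silo_id), decreasing = TRUE)
  cat(sprintf("\n%s: %d training variants across %d silos (train window before %s)\n",
              name, nrow(coh$train), length(sizes), cfg$split_date))
  print(round(100 * sizes / sum(sizes), 1))
  cat(sprintf("  test1 (non-participating silos): %d; test2 (post-split): %d\n",
              nrow(coh$test1), nrow(coh$test2)))
}

cat("\ncohort TSVs written under", out_dir, "\n")
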