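# Variant feature encoding ----------------------------------------------------
#
# SNVs: 60 features = 25 one-hot values for the five-nucleotide window centred
# on the mutated position (position-major, alphabet A, C, G, T, N), then the
# phyloP100 and phyloP470 conservation tracks over positions 1..5 (10 values),
# then the phyloP3, phyloP4, phyloP7, phyloP17 and phyloP20 tracks over
# positions 1..5 (25 values).
#
# CNVs: 38 features = a 22-column gene block summarising the overlapping-gene
# table (quantitative features aggregated by the maximum across genes, except
# minimum expression and the shortest network paths to haploinsufficient /
# triplosensitive genes, which take the minimum; categorical features encoded
# as presence of at least one gene with the attribute; plus the gene count)
# followed by the 16 region features copied/clipped from the annotation input.
# The flat ordering is frozen in cnv_feature_names() and written as a JSON
# manifest next to every encoded matrix.

SNV_ALPHABET <- c("A", "C", "G", "T", "N")

# sentinel for shortest-path features when no gene overlaps the CNV: an
# effectively infinite network distance, capped at a documented finite value
SP_EMPTY_SENTINEL <- 100

#' Frozen SNV feature names (length 60)
#' @return character vector of 60 names in encoding order.
#' @export
snv_feature_names <- function() {
  onehot <- as.vector(t(outer(paste0("pos", 1:5, "_"), SNV_ALPHABET, paste0)))
  cons <- as.vector(t(outer(SNV_TRACKS, paste0("_p", 1:5), paste0)))
  c(onehot, cons)
}

#' Frozen CNV feature names (length 38)
#' @return character vector of 38 names in encoding order.
#' @export
cnv_feature_names <- function() {
  gene_block <- c("n_genes", "pli_max", "loeuf_max", "pnull_max", "ccr_max",
                  "eds_max", "hi_pred_max", "ts_pred_max", "ohnolog_any",
                  "tf_any", "crispr_max", "complex_any", "expr_mean_max",
                  "expr_min_min", "phastcons_max", "promoter_cpg_max",
                  "degree_max", "pagerank_max", "betweenness_max",
                  "closeness_max", "sp_hi_min", "sp_ts_min")
  c(gene_block, CNV_REGION_COLS)
}

#' Encode one SNV annotation input as a 60-vector
#'
#' @param window_seq 5-symbol string over A, C, G, T, N centred on the
#'   mutated position.
#' @param conservation named list of the 7 phyloP tracks, each a 5-vector
#'   aligned to the window positions; or a single 35-vector in track-major
#'   order.
#' @return named numeric vector of length 60.
#' @export
encode_snv <- function(window_seq, conservation) {
  chars <- strsplit(window_seq, "")[[1]]
  if (length(chars) != 5L)
    stop_fv("window sequence must have exactly 5 symbols, got %d", length(chars))
  slot <- match(chars, SNV_ALPHABET)
  if (anyNA(slot))
    stop_fv("unknown symbol '%s' in window sequence", chars[is.na(slot)][1])
  onehot <- numeric(25L)
  onehot[(seq_len(5L) - 1L) * 5L + slot] <- 1
  if (is.list(conservation)) {
    missing <- setdiff(SNV_TRACKS, names(conservation))
    if (length(missing)) stop_fv("missing conservation track '%s'", missing[1])
    cons <- unlist(lapply(SNV_TRACKS, function(tr) {
      v <- conservation[[tr]]
      if (length(v) != 5L) stop_fv("track '%s' must have 5 values", tr)
      as.numeric(v)
    }))
  } else {
    if (length(conservation) != 35L)
      stop_fv("conservation vector must have 35 values, got %d", length(conservation))
    cons <- as.numeric(conservation)
  }
  if (anyNA(cons)) stop_fv("missing values in conservation tracks")
  stats::setNames(c(onehot, cons), snv_feature_names())
}

#' Encode one CNV annotation input as a 38-vector
#'
#' @param genes data.frame of per-gene annotation values (possibly 0 rows)
#'   with the columns of the package's gene schema.
#' @param region named list or one-row data.frame of the 16 region features.
#' @param length_bp unused by the encoding itself; retained for interface
#'   symmetry (genomic length enters matching, not the feature vector).
#' @return named numeric vector of length 38.
#' @export
encode_cnv <- function(genes, region, length_bp = NULL) {
  missing_g <- setdiff(CNV_GENE_COLS, names(genes))
  if (length(missing_g)) stop_fv("gene table lacks column '%s'", missing_g[1])
  agg_max <- function(col) if (nrow(genes) == 0L) 0 else max(as.numeric(genes[[col]]))
  agg_min <- function(col, empty) if (nrow(genes) == 0L) empty else min(as.numeric(genes[[col]]))
  agg_any <- function(col) if (nrow(genes) == 0L) 0 else as.numeric(any(genes[[col]] > 0))
  gene_vals <- c(
    n_genes = nrow(genes),
    pli_max = agg_max("pli"), loeuf_max = agg_max("loeuf"),
    pnull_max = agg_max("pnull"), ccr_max = agg_max("ccr"),
    eds_max = agg_max("eds"), hi_pred_max = agg_max("hi_pred"),
    ts_pred_max = agg_max("ts_pred"), ohnolog_any = agg_any("ohnolog"),
    tf_any = agg_any("tf"), crispr_max = agg_max("crispr"),
    complex_any = agg_any("complex_member"),
    expr_mean_max = agg_max("expr_mean"),
    expr_min_min = agg_min("expr_min", 0),
    phastcons_max = agg_max("phastcons"),
    promoter_cpg_max = agg_max("promoter_cpg"),
    degree_max = agg_max("degree"), pagerank_max = agg_max("pagerank"),
    betweenness_max = agg_max("betweenness"), closeness_max = agg_max("closeness"),
    sp_hi_min = agg_min("sp_hi", SP_EMPTY_SENTINEL),
    sp_ts_min = agg_min("sp_ts", SP_EMPTY_SENTINEL)
  )
  missing_r <- setdiff(CNV_REGION_COLS, names(region))
  if (length(missing_r)) stop_fv("region input lacks column '%s'", missing_r[1])
  region_vals <- vapply(CNV_REGION_COLS, function(col) {
    v <- as.numeric(region[[col]])[1]
    if (is.na(v)) stop_fv("missing value in region column '%s'", col)
    v
  }, numeric(1))
  for (col in grep("^cov_", CNV_REGION_COLS, value = TRUE))
    region_vals[[col]] <- min(1, max(0, region_vals[[col]]))
  for (col in grep("^overlap_", CNV_REGION_COLS, value = TRUE))
    region_vals[[col]] <- as.numeric(region_vals[[col]] > 0)
  for (col in grep("^dist_", CNV_REGION_COLS, value = TRUE))
    region_vals[[col]] <- max(0, region_vals[[col]])
  out <- c(gene_vals, region_vals)
  names(out) <- cnv_feature_names()
  out
}

#' Build an aligned feature matrix from variant records
#'
#' Row order preserves the input record order; labels, chromosomes and silo
#' ids stay aligned with the rows of X.
#'
#' @param records record data.frame of one homogeneous `variant_type`.
#' @return an object of class `feature_matrix`: list(X, y, chromosome,
#'   silo_id, feature_names, variant_id).
#' @export
build_feature_matrix <- function(records) {
  types <- unique(records$variant_type)
  if (length(types) > 1L)
    stop_fv("mixed variant types in one matrix: %s", paste(types, collapse = ", "))
  is_cnv <- length(types) == 1L && types == "deletion_cnv"
  fn <- if (is_cnv) cnv_feature_names() else snv_feature_names()
  n <- nrow(records)
  X <- matrix(0, n, length(fn), dimnames = list(NULL, fn))
  if (n > 0L) {
    if (is_cnv) {
      for (i in seq_len(n))
        X[i, ] <- encode_cnv(records$genes[[i]], records[i, CNV_REGION_COLS])
    } else {
      cons_cols <- snv_payload_cols()[-1]
      cons <- as.matrix(records[, cons_cols])
      for (i in seq_len(n))
        X[i, ] <- encode_snv(records$window_seq[i], cons[i, ])
    }
  }
  structure(
    list(X = X, y = as.integer(records$label),
         chromosome = as.character(records$chromosome),
         silo_id = as.character(records$silo_id),
         variant_id = as.character(records$variant_id),
         feature_names = fn),
    class = "feature_matrix"
  )
}

#' Fit a feature scaler on training rows only
#'
#' Z-scoring fit on the training silos and applied everywhere is the
#' pipeline's default for gradient-trained models (mixed-scale features make
#' raw gradient descent ill-conditioned). Constant features get s.d. 1 so
#' they map to zero rather than NaN.
#'
#' @param X numeric training matrix.
#' @return list(center, scale) usable with [apply_scaler()].
#' @export
fit_scaler <- function(X) {
  center <- colMeans(X)
  scale <- apply(X, 2L, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  list(center = center, scale = scale)
}

#' Apply a fitted scaler
#' @param X numeric matrix.
#' @param scaler list from [fit_scaler()].
#' @return scaled matrix.
#' @export
apply_scaler <- function(X, scaler) {
  sweep(sweep(X, 2L, scaler$center), 2L, scaler$scale, "/")
}

#' Write a feature-name manifest next to an encoded matrix
#' @param fm a `feature_matrix`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_feature_manifest <- function(fm, path) {
  jsonlite::write_json(
    list(n_features = length(fm$feature_names),
         feature_names = fm$feature_names,
         sha1 = digest::digest(fm$feature_names, algo = "sha1")),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
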