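#' @keywords internal
"_PACKAGE"

# Chromosome symbols used throughout: autosomes 1-22 plus X (no Y), i.e. the
# 23 symbols matched by one leave-one-chromosome-out classifier each.
CHROMOSOMES <- c(as.character(1:22), "X")

#' Derive a reproducible child seed from a root seed
#'
#' All randomness in the package flows from a single root seed; nested
#' components (rounds, clients, epochs, partitions) draw their own seeds with
#' this mixing function so that sub-streams are decorrelated but fully
#' determined by the root. Results stay below 2^31 so they are valid R
#' integer seeds.
#'
#' @param seed integer root seed.
#' @param ... integer indices identifying the sub-stream (small integers).
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  ks <- c(...)
  h <- as.numeric(seed) %% 2147483647
  for (k in ks) {
    # all intermediates stay < 2^53, so double arithmetic is exact
    h <- (h * 69069 + (as.numeric(k) %% 1e7) * 7919 + 12345) %% 2147483647
  }
  as.integer(h)
}

# round-half-up (R's round() is banker's rounding); used for client sampling
round_half_up <- function(x) floor(x + 0.5)

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) pmax(x, 0)

# row-wise softmax of a matrix of logits, numerically stabilised
softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fv <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(ok, fmt, ...) if (!isTRUE(ok)) stop_fv(fmt, ...)

# run an expression under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards so library code never disturbs user RNG
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
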