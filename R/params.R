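# Flat parameter vectors ------------------------------------------------------
#
# The unit of client/server exchange in the federated loop is a flat, ordered
# numeric vector of every model parameter, together with a layout table that
# maps named model components (weight matrices, biases, batch-norm statistics,
# leaf distributions) to index ranges. Clients and server share one layout per
# model configuration, so elementwise aggregation is well defined.

#' Build a parameter layout table
#'
#' @param segments named list; each element is `list(n =, trainable =, bn =)`.
#' @return data.frame with columns segment, start, end, n, trainable, bn.
#' @keywords internal
param_layout <- function(segments) {
  n <- vapply(segments, function(s) as.integer(s$n), integer(1))
  end <- cumsum(n)
  data.frame(
    segment   = names(segments),
    start     = end - n + 1L,
    end       = end,
    n         = n,
    trainable = vapply(segments, function(s) isTRUE(s$trainable), logical(1)),
    bn        = vapply(segments, function(s) isTRUE(s$bn), logical(1)),
    stringsAsFactors = FALSE
  )
}

layout_idx <- function(layout, segment) {
  row <- layout[layout$segment == segment, , drop = FALSE]
  if (nrow(row) != 1L) stop_fv("unknown parameter segment '%s'", segment)
  seq.int(row$start, row$end)
}

# logical index of trainable coordinates
trainable_mask <- function(layout) {
  m <- logical(layout$end[nrow(layout)])
  for (i in seq_len(nrow(layout))) if (layout$trainable[i]) m[layout$start[i]:layout$end[i]] <- TRUE
  m
}

# logical index of batch-norm coordinates (parameters and running statistics)
bn_mask <- function(layout) {
  m <- logical(layout$end[nrow(layout)])
  for (i in seq_len(nrow(layout))) if (layout$bn[i]) m[layout$start[i]:layout$end[i]] <- TRUE
  m
}

#' Extract the flat parameter vector of a model
#'
#' @param model a `fedvar_model`.
#' @return numeric vector carrying the model's layout as attribute `layout`.
#' @export
flatten_params <- function(model) {
  v <- model$params
  attr(v, "layout") <- model$layout
  v
}

#' Replace a model's parameters from a flat vector
#'
#' The vector must match the model's layout length exactly; the layout itself
#' (segment order and sizes) is fixed by the model configuration, mirroring a
#' federation in which every client runs the same architecture.
#'
#' @param model a `fedvar_model`.
#' @param values numeric vector of length `sum(layout$n)`.
#' @return the model with `params` replaced.
#' @export
unflatten_params <- function(model, values) {
  if (length(values) != length(model$params))
    stop_fv("parameter layout mismatch: expected %d values, got %d",
            length(model$params), length(values))
  model$params <- as.numeric(values)
  model
}

# convenience accessors used by the forward/backward passes
seg_get <- function(model, segment) model$params[layout_idx(model$layout, segment)]
seg_set <- function(model, segment, value) {
  model$params[layout_idx(model$layout, segment)] <- as.numeric(value)
  model
}
seg_mat <- function(model, segment, nrow, ncol) {
  matrix(seg_get(model, segment), nrow = nrow, ncol = ncol)
}
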