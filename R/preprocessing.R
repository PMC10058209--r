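#' Background-correct linear-scale intensities
#'
#' Subtracts an optional per-spot background matrix, floors the result at
#' zero, and adds a positive offset so every intensity is strictly positive
#' before log transformation. Operates on linear-scale intensities.
#'
#' @param raw Numeric matrix of non-negative linear-scale foreground
#'   intensities (probes x samples).
#' @param background Optional numeric matrix of the same shape with per-spot
#'   background estimates.
#' @param offset Non-negative value added after background subtraction;
#'   default 50.
#' @return A matrix of the same shape, every value `>= offset`.
#' @export
background_correct <- function(raw, background = NULL, offset = 50) {
  if (!is.matrix(raw) || !is.numeric(raw)) {
    stop("'raw' must be a numeric matrix", call. = FALSE)
  }
  if (any(raw < 0, na.rm = TRUE)) {
    stop("'raw' must contain non-negative linear-scale intensities",
         call. = FALSE)
  }
  if (length(offset) != 1L || is.na(offset) || offset < 0) {
    stop("'offset' must be a single non-negative value", call. = FALSE)
  }
  out <- raw
  if (!is.null(background)) {
    if (!identical(dim(background), dim(raw))) {
      stop("'background' must have the same dimensions as 'raw'",
           call. = FALSE)
    }
    out <- pmax(raw - background, 0)
  }
  out + offset
}

#' Quantile normalization between arrays
#'
#' Forces every column (array) to share the common distribution of averaged
#' order statistics; within-column ranks are preserved. Ties within a column
#' receive the mean of the normalized values at their tied ranks, which makes
#' the operation idempotent. Thin wrapper over
#' [limma::normalizeQuantiles()].
#'
#' @param m Numeric matrix (probes x samples, log2 scale) with no missing
#'   values and at least one column.
#' @return The normalized matrix with dimnames preserved.
#' @export
quantile_normalize <- function(m) {
  if (!is.matrix(m) || !is.numeric(m) || ncol(m) < 1L || nrow(m) < 1L) {
    stop("'m' must be a non-empty numeric matrix", call. = FALSE)
  }
  if (anyNA(m)) stop("'m' must not contain missing values", call. = FALSE)
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Percentile-shift normalization
#'
#' Shifts each column additively so that its chosen percentile (default the
#' 75th) equals zero, leaving all within-column differences unchanged. This
#' is the shift-to-75th-percentile method applied to log2 intensities, as in
#' GeneSpring-style preprocessing. Percentiles use linear interpolation
#' between closest order statistics ([stats::quantile()] type 7).
#'
#' @param m Numeric matrix (probes x samples, log2 scale).
#' @param percentile Percentile to anchor at zero, in (0, 100); default 75.
#' @return The shifted matrix with dimnames preserved.
#' @export
percentile_shift_normalize <- function(m, percentile = 75) {
  if (!is.matrix(m) || !is.numeric(m) || ncol(m) < 1L || nrow(m) < 1L) {
    stop("'m' must be a non-empty numeric matrix", call. = FALSE)
  }
  if (length(percentile) != 1L || is.na(percentile) ||
      percentile <= 0 || percentile >= 100) {
    stop("'percentile' must lie strictly between 0 and 100", call. = FALSE)
  }
  anchors <- apply(m, 2, stats::quantile, probs = percentile / 100,
                   names = FALSE, type = 7)
  sweep(m, 2, anchors, "-")
}
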