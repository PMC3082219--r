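#' Collective quantile normalization
#'
#' Forces every sample (column) of the merged matrix onto the common empirical
#' distribution given by the row-wise means of the column-sorted matrix, while
#' preserving within-column ranks. Ties within a column receive the mean of
#' the reference values at the tied ranks. Delegates the numerics to
#' [limma::normalizeQuantiles()].
#'
#' @param m A [merged_matrix()] (or plain numeric matrix).
#' @return Object of the same type with normalised values; idempotent.
#' @export
quantile_normalize <- function(m) {
  if (inherits(m, "merged_matrix")) {
    m$values <- quantile_normalize(m$values)
    return(m)
  }
  x <- as.matrix(m)
  if (anyNA(x)) stop("missing values are not allowed")
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}
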