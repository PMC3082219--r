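#' @importFrom rlang .data %||%
#' @importFrom dplyr %>%
NULL

#' Leave-one-out 1-nearest-neighbour accuracy
#'
#' A deliberately simple diagnostic: each sample is assigned the label of its
#' nearest other sample (Euclidean distance). Used to quantify how strongly a
#' merged dataset clusters by study (batch signal) versus by class
#' (biological signal), before and after integration.
#'
#' @param x Numeric matrix, samples x features.
#' @param labels Vector of labels, one per row.
#' @return Fraction of samples whose nearest neighbour shares their label.
#' @export
nn1_accuracy <- function(x, labels) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(labels), nrow(x) >= 2)
  d <- as.matrix(stats::dist(x))
  diag(d) <- Inf
  nn <- apply(d, 1, which.min)
  mean(as.character(labels)[nn] == as.character(labels))
}

# deterministic writer for small provenance/report JSON
.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
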