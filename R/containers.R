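#' Expression containers
#'
#' Light S3 containers for per-study and merged expression data. Expression
#' values are kept as plain numeric matrices (features x samples) because every
#' downstream step (quantile normalization, DWD, centroid classification) is
#' matrix arithmetic; all derived results are returned as tibbles.
#'
#' @name containers
NULL

#' Construct a per-study expression matrix
#'
#' Bundles one study's log2 expression values with per-sample class labels and
#' per-probe RefSeq annotation sets.
#'
#' @param study_id Character scalar naming the study.
#' @param values Numeric matrix, probes x samples, with unique rownames (probe
#'   ids) and colnames (sample ids). No missing values.
#' @param annotations Named list mapping each probe id to a character vector of
#'   RefSeq-like identifiers (possibly empty for unannotated probes).
#' @param labels Character or factor vector of per-sample class labels, one per
#'   column of `values` (e.g. `"PTC"` / `"benign"`).
#' @return An object of class `study_matrix`.
#' @export
study_matrix <- function(study_id, values, annotations, labels) {
  stopifnot(is.character(study_id), length(study_id) == 1L)
  values <- as.matrix(values)
  if (anyNA(values)) stop("study '", study_id, "': missing values are not allowed")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("study '", study_id, "': probe ids (rownames) must be present and unique")
  if (length(labels) != ncol(values))
    stop("study '", study_id, "': one label per sample required")
  labels <- as.character(labels)
  missing_ann <- setdiff(rownames(values), names(annotations))
  if (length(missing_ann))
    stop("study '", study_id, "': probes without annotation entry: ",
         paste(utils::head(missing_ann, 5), collapse = ", "))
  structure(
    list(study_id = study_id, values = values,
         annotations = annotations[rownames(values)], labels = labels),
    class = "study_matrix"
  )
}

#' @export
print.study_matrix <- function(x, ...) {
  cat("<study_matrix> ", x$study_id, ": ", nrow(x$values), " probes x ",
      ncol(x$values), " samples (",
      paste(sprintf("%s=%d", names(table(x$labels)), table(x$labels)), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Construct a mapped (feature-keyed) study
#'
#' @param study_id Character scalar.
#' @param values Numeric matrix, feature keys x samples; rownames are canonical
#'   [feature_key()] strings.
#' @param labels Per-sample class labels.
#' @return An object of class `mapped_study`.
#' @export
mapped_study <- function(study_id, values, labels) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("mapped study needs unique feature keys as rownames")
  stopifnot(length(labels) == ncol(values))
  structure(list(study_id = study_id, values = values, labels = as.character(labels)),
            class = "mapped_study")
}

#' @export
print.mapped_study <- function(x, ...) {
  cat("<mapped_study> ", x$study_id, ": ", nrow(x$values), " features x ",
      ncol(x$values), " samples\n", sep = "")
  invisible(x)
}

#' Construct a merged multi-study matrix
#'
#' @param values Numeric matrix, features x all samples.
#' @param sample_study Character vector mapping each column to its study of
#'   origin.
#' @param labels Per-sample class labels.
#' @return An object of class `merged_matrix`.
#' @export
merged_matrix <- function(values, sample_study, labels) {
  values <- as.matrix(values)
  stopifnot(length(sample_study) == ncol(values), length(labels) == ncol(values))
  structure(list(values = values, sample_study = as.character(sample_study),
                 labels = as.character(labels)),
            class = "merged_matrix")
}

#' @export
print.merged_matrix <- function(x, ...) {
  cat("<merged_matrix> ", nrow(x$values), " features x ", ncol(x$values),
      " samples from ", length(unique(x$sample_study)), " studies\n", sep = "")
  invisible(x)
}

#' Split a merged matrix back into per-study parts
#'
#' @param m A [merged_matrix()].
#' @return Named list of `mapped_study` objects, one per study, in first-seen
#'   column order.
#' @export
split_merged <- function(m) {
  stopifnot(inherits(m, "merged_matrix"))
  ids <- unique(m$sample_study)
  out <- lapply(ids, function(s) {
    keep <- m$sample_study == s
    mapped_study(s, m$values[, keep, drop = FALSE], m$labels[keep])
  })
  stats::setNames(out, ids)
}
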