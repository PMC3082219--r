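#' Canonical feature key for a set of RefSeq identifiers
#'
#' Two probes are treated as measuring the same feature only when their full
#' annotation sets are identical (set equality, not overlap): a probe specific
#' to one splice variant must not be merged with a probe covering a different
#' variant set. The key is the sorted, de-duplicated, `"|"`-joined identifier
#' set, so it is order-independent.
#'
#' @param ids Character vector of RefSeq-like identifiers.
#' @return Character scalar key, or `NA_character_` for an empty set.
#' @export
feature_key <- function(ids) {
  ids <- unique(ids[!is.na(ids) & nzchar(ids)])
  if (!length(ids)) return(NA_character_)
  paste(sort(ids), collapse = "|")
}

#' Collapse probes to annotation-set features
#'
#' Merges all probes of a study that annotate to the same RefSeq identifier
#' set into one feature row, using the per-sample median over the probes.
#' Probes with an empty annotation set are dropped (the count is reported via
#' a message and the `n_dropped` attribute).
#'
#' @param study A [study_matrix()].
#' @return A [mapped_study()] keyed by [feature_key()], rows in sorted key
#'   order, with attributes `n_dropped` (unannotated probes removed) and
#'   `n_probes_in`.
#' @export
collapse_probes <- function(study) {
  stopifnot(inherits(study, "study_matrix"))
  keys <- vapply(study$annotations, feature_key, "")
  keys[!nzchar(keys)] <- NA_character_
  drop <- is.na(keys)
  if (all(drop)) stop("study '", study$study_id, "': all probes are unannotated")
  if (any(drop))
    message("study '", study$study_id, "': dropped ", sum(drop),
            " unannotated probe(s)")
  vals <- study$values[!drop, , drop = FALSE]
  keys <- keys[!drop]
  uk <- sort(unique(keys))
  idx <- split(seq_along(keys), keys)
  out <- matrix(NA_real_, nrow = length(uk), ncol = ncol(vals),
                dimnames = list(uk, colnames(vals)))
  for (k in uk) {
    rows <- idx[[k]]
    out[k, ] <- if (length(rows) == 1L) vals[rows, ]
                else apply(vals[rows, , drop = FALSE], 2, stats::median)
  }
  res <- mapped_study(study$study_id, out, study$labels)
  attr(res, "n_dropped") <- sum(drop)
  attr(res, "n_probes_in") <- length(drop)
  res
}

#' Restrict studies to their shared features
#'
#' Keeps only the feature keys present in every study and returns all studies
#' with rows in one shared sorted order, ready for column-wise merging.
#'
#' @param studies List of [mapped_study()] objects (at least 2).
#' @return List of restricted `mapped_study` objects, identically ordered,
#'   with attribute `shared_features`.
#' @export
intersect_features <- function(studies) {
  stopifnot(length(studies) >= 2)
  stopifnot(all(vapply(studies, inherits, TRUE, "mapped_study")))
  shared <- Reduce(intersect, lapply(studies, function(s) rownames(s$values)))
  if (!length(shared)) {
    ids <- vapply(studies, `[[`, "", "study_id")
    stop("empty feature intersection across studies: ",
         paste(ids, collapse = ", "))
  }
  shared <- sort(shared)
  out <- lapply(studies, function(s)
    mapped_study(s$study_id, s$values[shared, , drop = FALSE], s$labels))
  attr(out, "shared_features") <- shared
  out
}

#' Merge feature-intersected studies column-wise
#'
#' @param studies List of [mapped_study()] objects sharing an identical row
#'   (feature) order, as produced by [intersect_features()].
#' @return A [merged_matrix()].
#' @export
merge_studies <- function(studies) {
  if (inherits(studies, "mapped_study")) studies <- list(studies)
  feats <- rownames(studies[[1]]$values)
  ok <- vapply(studies, function(s) identical(rownames(s$values), feats), TRUE)
  if (!all(ok)) stop("studies must share an identical feature order; run intersect_features() first")
  merged_matrix(
    do.call(cbind, lapply(studies, `[[`, "values")),
    rep(vapply(studies, `[[`, "", "study_id"),
        vapply(studies, function(s) ncol(s$values), 1L)),
    unlist(lapply(studies, `[[`, "labels"), use.names = FALSE)
  )
}
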