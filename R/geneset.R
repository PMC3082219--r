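#' Read gene sets from a GMT file
#'
#' @param path Path to a GMT file (set id, description, then member ids,
#'   tab-separated).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(!is.null(names(sets)))
  lines <- vapply(names(sets), function(id)
    paste(c(id, "na", sets[[id]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Competitive accumulated-t gene-set test
#'
#' Tests whether a set's genes carry higher (or lower, or more extreme)
#' t-statistics than random gene sets of the same size drawn from the tested
#' universe. The observed statistic is the mean t over the set's members
#' (mean |t| for direction `"mixed"`); the null is `B` draws without
#' replacement from the universe, and
#' `p = (1 + #\{null >= observed\}) / (B + 1)` for `"up"` (mirrored for
#' `"down"`, on |t| for `"mixed"`). Adjusted q-values are BH over all tested
#' sets.
#'
#' @param t_stats Named numeric vector of per-gene t-statistics (the tested
#'   universe).
#' @param sets Named list of character vectors of member genes, or a single
#'   character vector. Members outside the universe are dropped; sets left
#'   with fewer than 2 members are skipped with a warning.
#' @param direction `"up"`, `"down"` or `"mixed"`; recycled over sets. A
#'   per-set `direction` attribute on `sets` (as from [planted_gene_sets()])
#'   is used when `direction` is `NULL`.
#' @param B Number of permutation draws (>= 99; default 10000).
#' @param seed Integer seed (mandatory: the null is Monte-Carlo).
#' @return Tibble with `set_id`, `size`, `direction`, `statistic`, `p_value`,
#'   `q_value`.
#' @export
set_test <- function(t_stats, sets, direction = NULL, B = 10000, seed) {
  stopifnot(!is.null(names(t_stats)), B >= 99, !missing(seed))
  if (!is.list(sets)) sets <- list(set = sets)
  if (is.null(direction))
    direction <- attr(sets, "direction") %||% "up"
  direction <- rep_len(direction, length(sets))
  stopifnot(all(direction %in% c("up", "down", "mixed")))
  universe <- names(t_stats)

  kept <- lapply(sets, function(s) intersect(unique(s), universe))
  sizes <- lengths(kept)
  if (any(sizes > length(universe)))
    stop("a set is larger than the tested universe")
  if (any(sizes < 2)) {
    warning(sum(sizes < 2), " set(s) with fewer than 2 mapped members dropped")
  }
  ok <- sizes >= 2
  res <- withr::with_seed(as.integer(seed), {
    purrr::map_dfr(which(ok), function(j) {
      members <- kept[[j]]
      dir <- direction[j]
      stat_fun <- if (dir == "mixed") function(v) mean(abs(v)) else mean
      obs <- stat_fun(t_stats[members])
      null <- vapply(seq_len(B), function(b)
        stat_fun(t_stats[sample.int(length(universe), length(members))]),
        0)
      p <- switch(dir,
        up = (1 + sum(null >= obs)) / (B + 1),
        down = (1 + sum(null <= obs)) / (B + 1),
        mixed = (1 + sum(null >= obs)) / (B + 1))
      tibble::tibble(set_id = names(kept)[j], size = length(members),
                     direction = dir, statistic = obs, p_value = p)
    })
  })
  if (!nrow(res)) stop("no testable sets after intersection with the universe")
  res$q_value <- bh_adjust(res$p_value)
  res
}

#' Per-study gene-set testing with cross-study concordance
#'
#' Runs the differential-expression t-statistics and the competitive set test
#' within each study separately, then summarises how concordant the per-set
#' calls are across studies (sign agreement among studies where the set is
#' significant).
#'
#' @param studies List of [mapped_study()] objects (two classes each).
#' @param sets Named list of gene sets (feature keys).
#' @param positive Case class label.
#' @param direction As in [set_test()].
#' @param B Permutation draws per study.
#' @param seed Integer seed; the same seed is used for every study's null so
#'   that identical studies yield identical tables.
#' @param q_cutoff Significance cutoff for the concordance summary.
#' @return Tibble of per-study set results (`study_id` column added), with a
#'   `concordance` attribute: per set, the number of studies tested,
#'   significant, and whether all significant calls agree in sign.
#' @export
per_study_set_test <- function(studies, sets, positive = "PTC",
                               direction = NULL, B = 2000, seed,
                               q_cutoff = 0.05) {
  stopifnot(!missing(seed))
  res <- purrr::map_dfr(studies, function(s) {
    if (min(table(s$labels)) < 2) {
      warning("study '", s$study_id, "' too small for t-statistics; skipped")
      return(tibble::tibble())
    }
    de <- moderated_t_table(s$values, s$labels, positive,
                            filter_prop = 0, sens_spec = FALSE)
    tt <- stats::setNames(de$t, de$feature)
    dplyr::mutate(
      set_test(tt, sets, direction = direction, B = B, seed = as.integer(seed)),
      study_id = s$study_id, .before = 1)
  })
  conc <- res %>%
    dplyr::group_by(.data$set_id) %>%
    dplyr::summarise(
      n_studies = dplyr::n(),
      n_significant = sum(.data$q_value < q_cutoff),
      sign_concordant = {
        sig <- .data$statistic[.data$q_value < q_cutoff &
                               .data$direction != "mixed"]
        length(sig) < 2 || all(sign(sig) == sign(sig[1]))
      },
      .groups = "drop")
  attr(res, "concordance") <- conc
  res
}
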