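#' Estimate the empirical-Bayes variance prior
#'
#' Moment-matching on the log sample variances: the prior degrees of freedom
#' `d0` solve `trigamma(d0/2) = var(log s_g^2) - trigamma(d/2)` and the prior
#' variance `s0^2` follows from the mean of `log s_g^2` with the digamma
#' correction. When the empirical spread of the log variances does not exceed
#' what sampling alone explains, the prior is degenerate (`d0 = Inf`) and all
#' gene variances shrink fully to `s0^2`. The numerics are delegated to
#' [limma::fitFDist()], the reference implementation of this moment matching.
#'
#' @param variances Per-gene sample variances `s_g^2` (>= 10 positive values).
#' @param df Residual degrees of freedom `d` of each variance.
#' @return An `eb_prior` list with elements `d0` and `s0_sq`.
#' @export
estimate_prior <- function(variances, df) {
  variances <- as.numeric(variances)
  stopifnot(length(df) == 1L, df > 0)
  if (sum(variances > 0) < 10)
    stop("need at least 10 genes with positive variance")
  if (length(unique(variances)) == 1L) {
    return(structure(list(d0 = Inf, s0_sq = variances[1]), class = "eb_prior"))
  }
  fit <- limma::fitFDist(variances, df1 = df)
  structure(list(d0 = unname(fit$df2), s0_sq = unname(fit$scale)),
            class = "eb_prior")
}

#' @export
print.eb_prior <- function(x, ...) {
  cat("<eb_prior> d0 = ", format(x$d0), ", s0^2 = ", format(x$s0_sq), "\n", sep = "")
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment,
#' `adj_i = min_{j >= rank(i)} (m * p_(j) / j)` capped at 1, via
#' [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Single-gene sensitivity and specificity
#'
#' Treats one gene's expression as a univariate classifier: the decision
#' direction (case-high vs case-low) comes from the sign of the class-mean
#' difference (or is supplied), and the cut-point is the ROC-optimal
#' threshold (Youden's J maximiser over all midpoints between consecutive
#' sorted unique values; ties resolved toward higher sensitivity). For a gene
#' identical in both classes the convention is (sens, spec) = (1, 0): the
#' degenerate threshold calls everything positive.
#'
#' @param values Numeric vector, one gene across all samples.
#' @param labels Class labels.
#' @param positive Label of the positive (case) class.
#' @param direction `+1` (cases high), `-1` (cases low) or `NULL` to take the
#'   sign of the class-mean difference.
#' @return Tibble with `sens`, `spec`, `threshold`, `direction`.
#' @export
per_gene_sens_spec <- function(values, labels, positive, direction = NULL) {
  labels <- as.character(labels)
  stopifnot(length(values) == length(labels), positive %in% labels,
            any(labels != positive))
  is_pos <- labels == positive
  if (is.null(direction)) {
    direction <- sign(mean(values[is_pos]) - mean(values[!is_pos]))
    if (direction == 0) direction <- 1
  }
  v <- direction * values      # after flipping, cases are high by convention
  su <- sort(unique(v))
  if (length(su) == 1L) {
    return(tibble::tibble(sens = 1, spec = 0, threshold = -Inf,
                          direction = direction))
  }
  cuts <- c(su[1] - 1, (su[-1] + su[-length(su)]) / 2)
  res <- purrr::map_dfr(cuts, function(th) {
    pred <- v > th
    tibble::tibble(threshold = th,
                   sens = mean(pred[is_pos]),
                   spec = mean(!pred[!is_pos]))
  })
  j <- res$sens + res$spec - 1
  cand <- res[j >= max(j) - 1e-9, ]         # J ties within numerical noise
  best <- cand[order(-cand$sens, cand$threshold), ][1, ]
  tibble::tibble(sens = best$sens, spec = best$spec,
                 threshold = best$threshold * direction, direction = direction)
}

#' Moderated-t differential expression table
#'
#' Two-class comparison with empirical-Bayes moderated variances: the
#' posterior variance `s~_g^2 = (d0 s0^2 + d s_g^2) / (d0 + d)` replaces the
#' pooled variance in the two-sample t-statistic, which then has `d0 + d`
#' degrees of freedom. P-values are two-sided and BH-adjusted over all tested
#' genes; each gene also gets its single-feature sensitivity and specificity.
#'
#' @param x Numeric matrix, genes x samples (log2 scale).
#' @param labels Two-class labels, each class with >= 2 samples.
#' @param positive Label of the case class; `logfc` is case minus control.
#' @param prior An [estimate_prior()] result, or `NULL` to estimate from the
#'   (filtered) data. Pass `eb_prior` with `d0 = 0` for ordinary t-statistics
#'   or `d0 = Inf` for a common-variance z-like statistic.
#' @param filter_prop Non-specific variance filter: drop this fraction of
#'   lowest-variance genes before testing (default 0.2; set 0 to disable).
#'   The number filtered is reported via the `n_filtered` attribute.
#' @param sens_spec Compute per-gene sensitivity/specificity columns
#'   (default `TRUE`).
#' @return Tibble sorted by adjusted p with columns `feature`, `logfc`,
#'   `t`, `p_value`, `adj_p`, and (optionally) `sens`, `spec`; attributes
#'   `prior` and `n_filtered`.
#' @export
moderated_t_table <- function(x, labels, positive, prior = NULL,
                              filter_prop = 0.2, sens_spec = TRUE) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  stopifnot(ncol(x) == length(labels), positive %in% labels)
  classes <- unique(labels)
  if (length(classes) != 2L) stop("exactly two classes required")
  other <- setdiff(classes, positive)
  n1 <- sum(labels == positive); n2 <- sum(labels == other)
  if (n1 < 2L || n2 < 2L) stop("each class needs >= 2 samples")

  # non-specific filtering: drop the flattest genes before any testing
  n_filtered <- 0L
  if (filter_prop > 0) {
    rv <- apply(x, 1, stats::var)
    keep <- rv > stats::quantile(rv, filter_prop)
    n_filtered <- sum(!keep)
    x <- x[keep, , drop = FALSE]
  }

  m1 <- rowMeans(x[, labels == positive, drop = FALSE])
  m2 <- rowMeans(x[, labels == other, drop = FALSE])
  logfc <- m1 - m2
  d <- n1 + n2 - 2
  ss1 <- rowSums((x[, labels == positive, drop = FALSE] - m1)^2)
  ss2 <- rowSums((x[, labels == other, drop = FALSE] - m2)^2)
  s2 <- (ss1 + ss2) / d
  if (is.null(prior)) prior <- estimate_prior(s2, d)
  stopifnot(inherits(prior, "eb_prior"))
  s2_post <- if (is.infinite(prior$d0)) rep(prior$s0_sq, length(s2))
             else (prior$d0 * prior$s0_sq + d * s2) / (prior$d0 + d)
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  tt <- logfc / se
  df_total <- prior$d0 + d
  p <- if (is.infinite(df_total)) 2 * stats::pnorm(-abs(tt))
       else 2 * stats::pt(-abs(tt), df = df_total)

  out <- tibble::tibble(
    feature = rownames(x) %||% as.character(seq_len(nrow(x))),
    logfc = unname(logfc), t = unname(tt),
    p_value = unname(p), adj_p = bh_adjust(p)
  )
  if (sens_spec) {
    ssr <- purrr::map_dfr(seq_len(nrow(x)), function(i)
      per_gene_sens_spec(x[i, ], labels, positive,
                         direction = if (logfc[i] >= 0) 1 else -1)[, c("sens", "spec")])
    out <- dplyr::bind_cols(out, ssr)
  }
  out <- dplyr::arrange(out, .data$adj_p, .data$p_value, .data$feature)
  attr(out, "prior") <- prior
  attr(out, "n_filtered") <- n_filtered
  out
}
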