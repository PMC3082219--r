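#' Read a qPCR Ct table from CSV
#'
#' Expected columns: `sample_id`, `entity`, `assay`, `replicate`, `ct`.
#'
#' @param path CSV path.
#' @return Tibble with the five columns, types coerced.
#' @export
read_ct_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "entity", "assay", "replicate", "ct")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("Ct table is missing column(s): ", paste(missing_cols, collapse = ", "))
  tibble::as_tibble(df[need]) %>%
    dplyr::mutate(replicate = as.integer(.data$replicate),
                  ct = as.numeric(.data$ct))
}

#' Write a qPCR Ct table to CSV
#' @param ct Tibble as produced by [simulate_qpcr()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(ct, path) {
  utils::write.csv(ct, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# replicate-averaged Ct per sample x assay (averaging on the Ct scale)
.mean_ct <- function(ct) {
  ct %>%
    dplyr::group_by(.data$sample_id, .data$entity, .data$assay) %>%
    dplyr::summarise(ct = mean(.data$ct), .groups = "drop")
}

#' geNorm reference-gene stability ranking
#'
#' For every assay pair (j, k) the pairwise variation
#' `V_jk = SD over samples of log2(q_j / q_k)` is computed on linear-scale
#' relative quantities; the stability measure `M_j` is the mean of `V_jk`
#' over all partners k. Lower M means more stable: a transcript whose ratio
#' to every other candidate is constant across samples. The most stable assay
#' (minimal M, ties broken lexicographically) is the recommended
#' normalisation reference.
#'
#' @param quantities Numeric matrix, samples x assays, strictly positive
#'   linear-scale relative quantities with assay colnames.
#' @param stepwise Also compute the classical stepwise exclusion ranking
#'   (repeatedly dropping the least stable assay and recomputing M)?
#' @return A `stability_ranking`: tibble with `assay`, `m_value`, `rank`,
#'   attributes `chosen` (best assay) and `pairwise_v` (the V matrix), and,
#'   if requested, attribute `stepwise_exclusion_order`.
#' @export
genorm_stability <- function(quantities, stepwise = FALSE) {
  q <- as.matrix(quantities)
  if (is.null(colnames(q))) colnames(q) <- paste0("assay", seq_len(ncol(q)))
  if (ncol(q) < 3) stop("geNorm needs at least 3 candidate assays")
  bad <- which(q <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("non-positive quantity for sample row ", bad[1, 1],
         ", assay '", colnames(q)[bad[1, 2]], "'")
  lg <- log2(q)
  v_pair <- outer(colnames(q), colnames(q), Vectorize(function(j, k)
    if (j == k) 0 else stats::sd(lg[, j] - lg[, k])))
  dimnames(v_pair) <- list(colnames(q), colnames(q))
  m_of <- function(cols) {
    vapply(cols, function(j) {
      partners <- setdiff(cols, j)
      mean(vapply(partners, function(k) stats::sd(lg[, j] - lg[, k]), 0))
    }, 0)
  }
  m <- m_of(colnames(q))
  out <- tibble::tibble(assay = colnames(q), m_value = unname(m)) %>%
    dplyr::arrange(.data$m_value, .data$assay) %>%
    dplyr::mutate(rank = dplyr::row_number())
  attr(out, "chosen") <- out$assay[1]
  attr(out, "pairwise_v") <- v_pair
  if (stepwise) {
    remaining <- colnames(q)
    dropped <- character()
    while (length(remaining) > 2) {
      m_r <- m_of(remaining)
      worst <- remaining[order(-m_r, remaining)][1]
      dropped <- c(dropped, worst)
      remaining <- setdiff(remaining, worst)
    }
    attr(out, "stepwise_exclusion_order") <- c(dropped, sort(remaining))
  }
  class(out) <- c("stability_ranking", class(out))
  out
}

#' Relative quantification against a reference assay
#'
#' Replicate Cts are averaged per sample and assay on the Ct scale, then the
#' normalised expression is `2^-(Ct_target - Ct_reference)` (PCR efficiency
#' fixed at 2). Samples missing either assay are dropped with a warning.
#'
#' @param ct Ct table (`sample_id`, `entity`, `assay`, `replicate`, `ct`).
#' @param target Target assay name.
#' @param reference Reference assay name.
#' @param efficiency Amplification efficiency (default 2).
#' @return Tibble with `sample_id`, `entity`, `quantity`.
#' @export
relative_quantity <- function(ct, target, reference, efficiency = 2) {
  stopifnot(target %in% ct$assay, reference %in% ct$assay, efficiency > 1)
  wide <- .mean_ct(ct) %>%
    dplyr::filter(.data$assay %in% c(target, reference)) %>%
    tidyr::pivot_wider(names_from = "assay", values_from = "ct")
  miss <- !stats::complete.cases(wide[, c(target, reference)])
  if (any(miss)) {
    warning(sum(miss), " sample(s) dropped: missing target or reference assay")
    wide <- wide[!miss, ]
  }
  tibble::tibble(
    sample_id = wide$sample_id, entity = wide$entity,
    quantity = efficiency^-(wide[[target]] - wide[[reference]])
  )
}

#' ROC analysis and decision-threshold selection
#'
#' Builds the full ROC over all midpoints between consecutive sorted unique
#' score values (a sample is called positive when its score exceeds the
#' threshold) and picks the operating point by policy. `"max-sens"` keeps
#' sensitivity at 1 and maximises specificity — the choice that tolerates
#' false positives rather than false negatives, appropriate when a missed
#' carcinoma is the costly error. `"youden"` maximises sens + spec - 1. Ties
#' resolve to the lower threshold.
#'
#' @param values Numeric score vector (higher = more positive).
#' @param labels Class labels.
#' @param positive Positive class label.
#' @param policy `"max-sens"` or `"youden"`.
#' @return A `roc_result`: list with `threshold` (NA when the scores are
#'   constant), `policy`, `roc` (tibble: `threshold`, `sens`, `spec`) and
#'   `auc` (trapezoidal).
#' @export
roc_threshold <- function(values, labels, positive,
                          policy = c("max-sens", "youden")) {
  policy <- match.arg(policy)
  labels <- as.character(labels)
  stopifnot(length(values) == length(labels), positive %in% labels,
            any(labels != positive))
  is_pos <- labels == positive
  su <- sort(unique(values))
  if (length(su) == 1L) {
    roc <- tibble::tibble(threshold = NA_real_, sens = 1, spec = 0)
    return(structure(list(threshold = NA_real_, policy = policy,
                          roc = roc, auc = NA_real_),
                     class = "roc_result"))
  }
  cuts <- c(su[1] - 1, (su[-1] + su[-length(su)]) / 2, su[length(su)] + 1)
  roc <- purrr::map_dfr(cuts, function(th) {
    pred <- values > th
    tibble::tibble(threshold = th, sens = mean(pred[is_pos]),
                   spec = mean(!pred[!is_pos]))
  })
  # maximise the policy criterion; ties (within numerical noise) resolve to
  # the lower threshold
  crit <- if (policy == "max-sens") ifelse(roc$sens == 1, roc$spec, -Inf)
          else roc$sens + roc$spec - 1
  cand <- roc[crit >= max(crit) - 1e-9, ]
  chosen <- min(cand$threshold)
  fpr <- 1 - roc$spec
  ord <- order(fpr, roc$sens)
  auc <- sum(diff(fpr[ord]) * (roc$sens[ord][-1] + roc$sens[ord][-nrow(roc)]) / 2)
  structure(list(threshold = chosen, policy = policy, roc = roc, auc = auc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  at <- x$roc[which.min(abs(x$roc$threshold - x$threshold)), ]
  cat("<roc_result> policy ", x$policy, ": threshold ", format(x$threshold),
      " (sens ", format(at$sens), ", spec ", format(at$spec),
      "), AUC ", format(x$auc), "\n", sep = "")
  invisible(x)
}

#' Plot an ROC curve with its chosen operating point
#' @param object A `roc_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.roc_result <- function(object, ...) {
  at <- object$roc[which.min(abs(object$roc$threshold - object$threshold)), ]
  ggplot2::ggplot(object$roc,
                  ggplot2::aes(x = 1 - .data$spec, y = .data$sens)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::geom_point(data = at, shape = 4, size = 4, colour = "red") +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity") +
    ggplot2::theme_minimal()
}

#' Confusion-matrix counts and derived metrics
#'
#' Counts true/false positives/negatives of a binary prediction against the
#' truth (multi-entity truth is binarised as `positive` vs everything else)
#' and derives sensitivity, specificity, PPV, NPV and accuracy. Ratios with a
#' zero denominator are `NA`, never 0. No internal rounding.
#'
#' @param predicted Logical vector, or vector of predicted labels.
#' @param truth Truth labels.
#' @param positive Positive class label.
#' @return One-row tibble: `tp`, `fp`, `tn`, `fn`, `sens`, `spec`, `ppv`,
#'   `npv`, `accuracy`.
#' @export
confusion_metrics <- function(predicted, truth, positive) {
  if (length(predicted) != length(truth)) stop("length mismatch")
  stopifnot(positive %in% truth)
  pred_pos <- if (is.logical(predicted)) predicted
              else as.character(predicted) == positive
  true_pos <- as.character(truth) == positive
  tp <- sum(pred_pos & true_pos); fp <- sum(pred_pos & !true_pos)
  tn <- sum(!pred_pos & !true_pos); fn <- sum(!pred_pos & true_pos)
  ratio <- function(a, b) if (b == 0) NA_real_ else a / b
  tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sens = ratio(tp, tp + fn), spec = ratio(tn, tn + fp),
    ppv = ratio(tp, tp + fp), npv = ratio(tn, tn + fn),
    accuracy = (tp + tn) / length(predicted)
  )
}
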