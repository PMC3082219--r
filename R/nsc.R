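#' Fit a nearest-shrunken-centroid classifier family
#'
#' Computes, per gene i and class k, the standardized centroid contrast
#' `d_ik = (xbar_ik - xbar_i) / (m_k * (s_i + s0))` with
#' `m_k = sqrt(1/n_k - 1/n)`, pooled within-class SD `s_i` (df `n - K`) and
#' fudge `s0 = median(s_i)`. Soft-thresholding the contrasts at each value of
#' a shrinkage grid `Delta` gives a family of classifiers with embedded gene
#' selection: genes whose contrasts shrink to zero in every class drop out of
#' the classifier.
#'
#' @param x Numeric matrix, genes x samples.
#' @param labels Class label per sample; every class needs >= 2 samples.
#' @param delta_grid Numeric vector of shrinkage thresholds; default
#'   `n_delta` equispaced values from 0 to `max |d_ik|`.
#' @param n_delta Grid size when `delta_grid` is `NULL` (default 30).
#' @return An `nsc_model` holding the shared statistics, the contrast matrix
#'   and the threshold grid. Use [nsc_predict()] to score new samples at a
#'   chosen threshold.
#' @export
nsc_fit <- function(x, labels, delta_grid = NULL, n_delta = 30) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  stopifnot(ncol(x) == length(labels))
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("need at least 2 classes")
  n_k <- vapply(classes, function(k) sum(labels == k), 0L)
  if (any(n_k < 2L)) stop("every class needs at least 2 samples")
  n <- ncol(x); K <- length(classes)

  xbar <- rowMeans(x)
  cent <- matrix(vapply(classes, function(k)
    rowMeans(x[, labels == k, drop = FALSE]), numeric(nrow(x))),
    nrow = nrow(x), dimnames = list(rownames(x), classes))
  ss <- matrix(vapply(classes, function(k) {
    xc <- x[, labels == k, drop = FALSE] - cent[, k]
    rowSums(xc * xc)
  }, numeric(nrow(x))), nrow = nrow(x))
  s <- sqrt(rowSums(ss) / (n - K))
  if (all(s == 0)) stop("all genes are constant within classes; nothing to fit")
  s0 <- stats::median(s)
  m_k <- sqrt(1 / n_k - 1 / n)
  denom <- outer(s + s0, m_k)
  d <- (cent - xbar) / denom
  d[denom == 0] <- 0
  if (is.null(delta_grid))
    delta_grid <- seq(0, max(abs(d)), length.out = n_delta)
  stopifnot(all(delta_grid >= 0))
  structure(
    list(classes = classes, n_k = n_k, priors = n_k / n, n = n,
         centroid_overall = xbar, centroids = cent,
         s = s, s0 = s0, m_k = m_k, d = d,
         delta_grid = sort(unique(delta_grid)),
         features = rownames(x) %||% as.character(seq_len(nrow(x)))),
    class = "nsc_model"
  )
}

#' @export
print.nsc_model <- function(x, ...) {
  cat("<nsc_model> ", length(x$features), " genes, classes ",
      paste(sprintf("%s (n=%d)", x$classes, x$n_k), collapse = ", "),
      "; grid of ", length(x$delta_grid), " thresholds\n", sep = "")
  invisible(x)
}

# soft-thresholded contrasts at one Delta
.nsc_shrink <- function(model, delta) {
  sign(model$d) * pmax(abs(model$d) - delta, 0)
}

# discriminant scores without tibble overhead (used by the CV loops)
.nsc_scores <- function(model, newx, delta) {
  ds <- .nsc_shrink(model, delta)
  sc <- model$s + model$s0
  keep <- sc > 0
  shrunk_cent <- model$centroid_overall +
    sweep(ds, 1, sc, `*`) %*% diag(model$m_k, length(model$m_k))
  vapply(seq_along(model$classes), function(k) {
    z <- (newx[keep, , drop = FALSE] - shrunk_cent[keep, k]) / sc[keep]
    colSums(z * z) - 2 * log(model$priors[k])
  }, numeric(ncol(newx)))
}

.nsc_label <- function(model, scores) {
  apply(matrix(scores, ncol = length(model$classes)), 1, function(row) {
    best <- which(row <= min(row) + 1e-12)
    if (length(best) > 1L)
      best <- best[order(-model$priors[best], model$classes[best])][1]
    model$classes[best]
  })
}

#' Active genes of an NSC model at a threshold
#'
#' @param model An `nsc_model`.
#' @param delta Shrinkage threshold.
#' @return Character vector of genes whose shrunken contrast is non-zero in at
#'   least one class.
#' @export
nsc_active_genes <- function(model, delta) {
  ds <- .nsc_shrink(model, delta)
  model$features[rowSums(ds != 0) > 0]
}

#' Predict classes from an NSC model
#'
#' Scores a sample by the shrunken-centroid discriminant
#' `delta_k(x*) = sum_i (x*_i - xbar'_ik)^2 / (s_i + s0)^2 - 2 log pi_k`
#' with `xbar'_ik = xbar_i + m_k (s_i + s0) d'_ik`, and assigns the class with
#' the smallest score. Exact ties go to the class with the larger prior, then
#' lexicographically.
#'
#' @param model An `nsc_model`.
#' @param newx Numeric matrix, genes x samples, on the model's feature space.
#' @param delta Shrinkage threshold (default 0 = plain nearest centroid with
#'   prior term).
#' @return Tibble with `sample`, `predicted`, and one score column per class.
#' @export
nsc_predict <- function(model, newx, delta = 0) {
  stopifnot(inherits(model, "nsc_model"))
  newx <- as.matrix(newx)
  if (nrow(newx) != length(model$features))
    stop("feature dimension does not match the model")
  scores <- matrix(.nsc_scores(model, newx, delta),
                   ncol = length(model$classes),
                   dimnames = list(colnames(newx), model$classes))
  pred <- .nsc_label(model, scores)
  tibble::tibble(
    sample = colnames(newx) %||% as.character(seq_len(ncol(newx))),
    predicted = unname(pred)
  ) %>%
    dplyr::bind_cols(tibble::as_tibble(scores))
}

#' Leave-one-out cross-validation with threshold selection
#'
#' Each sample is held out in turn and the classifier (centroids, pooled SDs,
#' fudge factor) refitted on the remainder, then scored across the whole
#' threshold grid. The chosen threshold attains the minimal CV error; among
#' minimisers the largest threshold (fewest genes) wins.
#'
#' @param x Numeric matrix, genes x samples (n >= 3).
#' @param labels Class labels.
#' @param delta_grid Threshold grid; default computed from the full-data fit
#'   so per-threshold error counts aggregate over folds.
#' @param n_delta Grid size when `delta_grid` is `NULL`.
#' @return An `nsc_cv` object: `grid` (tibble: `delta`, `errors`, `accuracy`,
#'   `n_active` from the full-data fit), `chosen_delta`, `accuracy` at the
#'   chosen threshold, `predictions` (tibble: `sample`, `truth`, `predicted`
#'   at the chosen threshold) and the full-data `model`.
#' @export
nsc_loocv <- function(x, labels, delta_grid = NULL, n_delta = 30) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  n <- ncol(x)
  if (n < 3L) stop("leave-one-out needs n >= 3")
  # boundary inputs (e.g. a singleton class) cannot support a full-data fit;
  # the loop still runs, with failing folds counted as errors
  full <- tryCatch(nsc_fit(x, labels, delta_grid, n_delta),
                   error = function(e) NULL)
  grid <- if (!is.null(full)) full$delta_grid else sort(unique(delta_grid %||% 0))
  pred_mat <- matrix(NA_character_, nrow = n, ncol = length(grid))
  for (i in seq_len(n)) {
    fit_i <- tryCatch(nsc_fit(x[, -i, drop = FALSE], labels[-i], grid),
                      error = function(e) NULL)
    if (is.null(fit_i)) {
      warning("fold ", i, " skipped (class vanished); counted as error")
      next
    }
    xi <- x[, i, drop = FALSE]
    for (g in seq_along(grid)) {
      pred_mat[i, g] <- .nsc_label(fit_i, .nsc_scores(fit_i, xi, grid[g]))
    }
  }
  errors <- colSums(pred_mat != labels | is.na(pred_mat))
  n_active <- if (is.null(full)) rep(NA_integer_, length(grid))
              else vapply(grid, function(dl) length(nsc_active_genes(full, dl)), 0L)
  best <- which(errors == min(errors))
  chosen <- grid[max(best)]   # largest threshold among minimisers
  structure(
    list(grid = tibble::tibble(delta = grid, errors = as.integer(errors),
                               accuracy = 1 - errors / n, n_active = n_active),
         chosen_delta = chosen,
         accuracy = 1 - min(errors) / n,
         predictions = tibble::tibble(
           sample = colnames(x) %||% as.character(seq_len(n)),
           truth = labels,
           predicted = pred_mat[, max(best)]),
         model = full),
    class = "nsc_cv"
  )
}

#' @export
print.nsc_cv <- function(x, ...) {
  cat("<nsc_cv> chosen Delta = ", format(x$chosen_delta), ", accuracy = ",
      format(x$accuracy), ", ", sum(x$grid$n_active[x$grid$delta == x$chosen_delta]),
      " active gene(s)\n", sep = "")
  invisible(x)
}

#' Cross-study classification matrix
#'
#' For every ordered (train, test) study pair, fits the classifier on the
#' training study at its own internally cross-validated threshold and reports
#' accuracy on the test study; the diagonal holds within-study leave-one-out
#' accuracy. Run on pre- and post-integration data, the contrast between the
#' two matrices measures how much dataset bias blocks classifier transfer.
#'
#' @param studies List of [mapped_study()] objects on one shared feature
#'   space (identical row order).
#' @param delta_grid Optional shared threshold grid (default: per-train-study
#'   grid).
#' @param n_delta Grid size when `delta_grid` is `NULL`.
#' @return Tibble with columns `train`, `test`, `accuracy`, `chosen_delta`,
#'   `n_active`.
#' @export
cross_study_matrix <- function(studies, delta_grid = NULL, n_delta = 30) {
  if (inherits(studies, "mapped_study")) studies <- list(studies)
  ids <- vapply(studies, `[[`, "", "study_id")
  feats <- rownames(studies[[1]]$values)
  stopifnot(all(vapply(studies, function(s) identical(rownames(s$values), feats), TRUE)))
  purrr::map_dfr(seq_along(studies), function(a) {
    tr <- studies[[a]]
    cv <- nsc_loocv(tr$values, tr$labels, delta_grid, n_delta)
    model <- cv$model
    purrr::map_dfr(seq_along(studies), function(b) {
      acc <- if (a == b) cv$accuracy else {
        te <- studies[[b]]
        mean(nsc_predict(model, te$values, cv$chosen_delta)$predicted == te$labels)
      }
      tibble::tibble(train = ids[a], test = ids[b], accuracy = acc,
                     chosen_delta = cv$chosen_delta,
                     n_active = length(nsc_active_genes(model, cv$chosen_delta)))
    })
  })
}

#' Iterative marker-removal signatures
#'
#' Repeatedly cross-validates, records the chosen signature and its accuracy,
#' removes the signature's genes from the matrix and repeats — revealing
#' whether discriminative power rests on one gene or on a redundant reservoir
#' of alternative signatures.
#'
#' @param x Numeric matrix, genes x samples.
#' @param labels Class labels.
#' @param delta_grid Optional threshold grid (recomputed per round when
#'   `NULL`, since the gene universe shrinks).
#' @param max_rounds Maximum number of rounds (>= 1).
#' @param accuracy_floor Stop once a round's accuracy falls below this.
#' @param n_delta Grid size when `delta_grid` is `NULL`.
#' @return Tibble with columns `round`, `signature` (list column of gene
#'   ids), `n_genes`, `accuracy`, `chosen_delta`; attribute `truncated` is
#'   `TRUE` when the matrix was exhausted before `max_rounds`.
#' @export
iterative_marker_removal <- function(x, labels, delta_grid = NULL,
                                     max_rounds = 4, accuracy_floor = 0.9,
                                     n_delta = 30) {
  stopifnot(max_rounds >= 1)
  x <- as.matrix(x)
  rounds <- list()
  truncated <- FALSE
  for (r in seq_len(max_rounds)) {
    if (nrow(x) == 0L) { truncated <- TRUE; break }
    cv <- nsc_loocv(x, labels, delta_grid, n_delta)
    sig <- nsc_active_genes(cv$model, cv$chosen_delta)
    if (!length(sig)) {
      # fully shrunk classifier: nothing left to remove
      rounds[[r]] <- tibble::tibble(round = r, signature = list(character()),
                                    n_genes = 0L, accuracy = cv$accuracy,
                                    chosen_delta = cv$chosen_delta)
      truncated <- TRUE
      break
    }
    rounds[[r]] <- tibble::tibble(round = r, signature = list(sig),
                                  n_genes = length(sig), accuracy = cv$accuracy,
                                  chosen_delta = cv$chosen_delta)
    if (cv$accuracy < accuracy_floor) break
    x <- x[setdiff(rownames(x), sig), , drop = FALSE]
  }
  out <- dplyr::bind_rows(rounds)
  attr(out, "truncated") <- truncated
  out
}

#' Tidy NSC contrasts at a threshold
#' @param x An `nsc_model`.
#' @param delta Shrinkage threshold (default 0).
#' @param ... Unused.
#' @return Tibble with `feature`, `class`, `centroid`, `contrast`,
#'   `shrunken_contrast`, `active`.
#' @export
tidy.nsc_model <- function(x, delta = 0, ...) {
  ds <- .nsc_shrink(x, delta)
  tidyr::expand_grid(feature = x$features, class = x$classes) %>%
    dplyr::mutate(
      centroid = as.vector(t(x$centroids)),
      contrast = as.vector(t(x$d)),
      shrunken_contrast = as.vector(t(ds)),
      active = .data$shrunken_contrast != 0
    )
}

#' One-row summary of an NSC model
#' @param x An `nsc_model`.
#' @param ... Unused.
#' @return Tibble with class count, sample count, gene count and `s0`.
#' @export
glance.nsc_model <- function(x, ...) {
  tibble::tibble(n_classes = length(x$classes), n_samples = x$n,
                 n_genes = length(x$features), s0 = x$s0,
                 max_contrast = max(abs(x$d)))
}

#' Tidy per-threshold cross-validation results
#' @param x An `nsc_cv`.
#' @param ... Unused.
#' @return The per-threshold grid tibble.
#' @export
tidy.nsc_cv <- function(x, ...) x$grid

#' One-row summary of a cross-validation run
#' @param x An `nsc_cv`.
#' @param ... Unused.
#' @return Tibble with the chosen threshold, accuracy and active-gene count.
#' @export
glance.nsc_cv <- function(x, ...) {
  tibble::tibble(chosen_delta = x$chosen_delta, accuracy = x$accuracy,
                 n_active = length(nsc_active_genes(x$model, x$chosen_delta)))
}

#' Plot the cross-validation profile of an NSC run
#'
#' Accuracy against shrinkage threshold, annotated with the number of active
#' genes and the chosen threshold.
#'
#' @param object An `nsc_cv` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nsc_cv <- function(object, ...) {
  ggplot2::ggplot(object$grid, ggplot2::aes(x = .data$delta, y = .data$accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_active), alpha = 0.6) +
    ggplot2::geom_vline(xintercept = object$chosen_delta, linetype = 2) +
    ggplot2::labs(x = "shrinkage threshold Δ", y = "LOOCV accuracy",
                  size = "active genes") +
    ggplot2::theme_minimal()
}

#' Plot a cross-study accuracy matrix
#'
#' @param cm Tibble from [cross_study_matrix()] (optionally with an extra
#'   `stage` column to facet pre/post integration).
#' @return A ggplot tile map, trains on rows and tests on columns.
#' @export
plot_cross_study <- function(cm) {
  p <- ggplot2::ggplot(cm, ggplot2::aes(x = .data$test, y = .data$train,
                                        fill = .data$accuracy)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$accuracy))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::theme_minimal()
  if ("stage" %in% names(cm)) p <- p + ggplot2::facet_wrap(~stage)
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
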