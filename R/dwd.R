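#' Fit Distance Weighted Discrimination between two batches
#'
#' DWD finds the hyperplane direction `w` (unit norm) and offset `beta`
#' minimising the sum of reciprocal residuals plus a slack penalty,
#'
#'   minimise  sum_i 1/r_i + C sum_i xi_i
#'   subject to r_i = y_i (w . x_i + beta) + xi_i,  r_i > 0,  xi_i >= 0,
#'              ||w|| <= 1.
#'
#' Unlike an SVM it lets every sample pull on the direction, which makes it
#' well suited to finding (and then removing) a batch-separating direction in
#' high-dimensional expression data. Internally the slack variables are
#' eliminated analytically, giving the equivalent smooth convex loss
#' `V(m) = 1/m` for `m >= 1/sqrt(C)` and `V(m) = 2*sqrt(C) - C*m` otherwise,
#' which is minimised over the unit sphere (the norm constraint is always
#' active) after an SVD reduction to the span of the samples.
#'
#' @param x Numeric matrix, samples x features.
#' @param batch_labels Vector of two distinct batch labels (or +1/-1), one per
#'   sample.
#' @param C Positive penalty; default `dwd_default_C(x)`, the standard
#'   `100 / median^2` pairwise-distance heuristic.
#' @return A `dwd_model` with elements `w` (unit direction over features),
#'   `beta`, `C`, `objective`, `batch_levels`, `batch_mean_projections`
#'   (per-batch mean of `w . x`), and bookkeeping tying the model to the data
#'   it was fitted on.
#' @export
solve_dwd <- function(x, batch_labels, C = NULL) {
  x <- as.matrix(x)
  y <- .dwd_pm1(batch_labels)
  lev <- attr(y, "levels")
  if (length(unique(y)) != 2L) stop("both batches must be non-empty")
  if (is.null(C)) C <- dwd_default_C(x)
  stopifnot(C > 0)
  n <- nrow(x)

  # reduce to the sample span: any w-component orthogonal to it only wastes norm
  sv <- svd(x, nu = n, nv = min(n, ncol(x)))
  r <- sum(sv$d > max(sv$d[1], 1) * 1e-12)
  if (r == 0L) stop("all-zero data matrix")
  Z <- sv$u[, seq_len(r), drop = FALSE] %*% diag(sv$d[seq_len(r)], r, r)
  V <- sv$v[, seq_len(r), drop = FALSE]

  th <- 1 / sqrt(C)
  loss <- function(m) ifelse(m >= th, 1 / m, 2 * sqrt(C) - C * m)
  dloss <- function(m) ifelse(m >= th, -1 / m^2, -C)

  fn <- function(par) {
    u <- par[seq_len(r)]; s <- sqrt(sum(u^2))
    if (s < 1e-12) return(.Machine$double.xmax)
    a <- u / s
    m <- y * (drop(Z %*% a) + par[r + 1])
    sum(loss(m))
  }
  gr <- function(par) {
    u <- par[seq_len(r)]; s <- sqrt(sum(u^2)); a <- u / s
    m <- y * (drop(Z %*% a) + par[r + 1])
    d <- dloss(m) * y
    ga <- drop(crossprod(Z, d))
    c((ga - sum(ga * a) * a) / s, sum(d))
  }

  # init: mean-difference direction, offset at the midpoint of projections
  d0 <- colMeans(Z[y > 0, , drop = FALSE]) - colMeans(Z[y < 0, , drop = FALSE])
  if (sum(d0^2) < 1e-12) d0 <- c(1, rep(0, r - 1))
  a0 <- d0 / sqrt(sum(d0^2))
  p0 <- drop(Z %*% a0)
  b0 <- -(mean(p0[y > 0]) + mean(p0[y < 0])) / 2
  par <- c(a0, b0)

  obj <- Inf
  for (round in 1:5) {
    fit <- stats::optim(par, fn, gr, method = "BFGS",
                        control = list(maxit = 2000, reltol = 1e-14))
    par <- fit$par
    if (abs(obj - fit$value) < 1e-10 * (1 + abs(fit$value))) { obj <- fit$value; break }
    obj <- fit$value
  }
  if (fit$convergence != 0 && round == 5)
    stop("DWD solver did not converge (optim status ", fit$convergence, ")")

  u <- par[seq_len(r)]; a <- u / sqrt(sum(u^2))
  w <- drop(V %*% a)
  names(w) <- colnames(x)
  proj <- drop(x %*% w)
  bmp <- vapply(lev, function(l) mean(proj[batch_labels == l]), 0)
  structure(
    list(w = w, beta = par[r + 1], C = C, objective = obj,
         batch_levels = lev, batch_mean_projections = bmp,
         n_samples = n,
         data_checksum = .dwd_checksum(x)),
    class = "dwd_model"
  )
}

#' @export
print.dwd_model <- function(x, ...) {
  cat("<dwd_model> ", length(x$w), " features, batches ",
      paste(x$batch_levels, collapse = " vs "),
      "; mean-projection gap ", format(diff(x$batch_mean_projections)),
      "; objective ", format(x$objective), "\n", sep = "")
  invisible(x)
}

#' Default DWD penalty
#'
#' The common heuristic `C = 100 / median(d)^2` with `d` the pairwise
#' inter-point Euclidean distances.
#' @param x Numeric matrix, samples x features.
#' @return Positive scalar.
#' @export
dwd_default_C <- function(x) {
  md <- stats::median(stats::dist(as.matrix(x)))
  if (!is.finite(md) || md <= 0) md <- 1
  100 / md^2
}

#' Remove per-batch mean shifts along the DWD direction
#'
#' Projects every sample onto the fitted direction `w` and subtracts its
#' batch's mean projection: `x_i' = x_i - m_b(i) * w`. After adjustment every
#' batch mean projects to zero on `w`; components orthogonal to `w` are
#' untouched. A model is valid only for the exact sample set it was fitted on
#' (adding a sample changes the whole merged dataset), so the call refuses
#' data that does not match the fit.
#'
#' @param x Numeric matrix, samples x features, as passed to [solve_dwd()].
#' @param batch_labels Batch labels as passed to [solve_dwd()].
#' @param model A `dwd_model` fitted on `x`.
#' @return Adjusted matrix of the same shape.
#' @export
adjust_batches <- function(x, batch_labels, model) {
  stopifnot(inherits(model, "dwd_model"))
  x <- as.matrix(x)
  if (ncol(x) != length(model$w)) stop("feature dimension does not match the model")
  if (!isTRUE(all.equal(.dwd_checksum(x), model$data_checksum)))
    stop("model was fitted on a different sample set; refit before adjusting")
  m <- model$batch_mean_projections[as.character(batch_labels)]
  if (anyNA(m)) stop("batch label absent from the fitted model")
  x - outer(unname(m), model$w)
}

.dwd_pm1 <- function(labels) {
  lev <- unique(as.character(labels))
  if (length(lev) != 2L) stop("exactly two batch labels required")
  out <- ifelse(as.character(labels) == lev[1], 1, -1)
  attr(out, "levels") <- lev
  out
}

.dwd_checksum <- function(x) {
  c(nrow(x), ncol(x), sum(x), sum(x * x))
}

#' Integrate two batches in one step
#'
#' Convenience wrapper: fit DWD on the batch labels and subtract the per-batch
#' mean projections.
#'
#' @inheritParams solve_dwd
#' @return List with `adjusted` (matrix) and `model` (`dwd_model`).
#' @export
dwd_integrate <- function(x, batch_labels, C = NULL) {
  model <- solve_dwd(x, batch_labels, C)
  list(adjusted = adjust_batches(x, batch_labels, model), model = model)
}

#' Sequentially DWD-integrate more than two studies
#'
#' DWD is a two-class construction, so K datasets are merged pairwise and
#' sequentially: the accumulated set is integrated with the next dataset in
#' plan order. The default plan merges larger datasets first.
#'
#' @param m A [merged_matrix()] (features x samples) carrying the per-sample
#'   study assignment.
#' @param plan Character vector of study ids defining the merge order; each
#'   study exactly once. Default: descending sample count (ties broken by
#'   name).
#' @param C DWD penalty; `NULL` for the per-step default heuristic.
#' @return A [merged_matrix()] with adjusted values (columns in plan order),
#'   with attributes `provenance` (tibble: one row per step, the direction
#'   norm and removed batch mean gap) and `models` (list of `dwd_model`).
#' @export
sequential_merge <- function(m, plan = NULL, C = NULL) {
  stopifnot(inherits(m, "merged_matrix"))
  sizes <- table(m$sample_study)
  if (is.null(plan))
    plan <- names(sizes)[order(-as.vector(sizes), names(sizes))]
  if (!setequal(plan, names(sizes)) || anyDuplicated(plan))
    stop("plan must list every study exactly once")
  if (length(plan) < 2L) stop("need at least 2 studies to integrate")

  ord <- order(match(m$sample_study, plan))
  vals <- m$values[, ord, drop = FALSE]
  stu <- m$sample_study[ord]
  labs <- m$labels[ord]

  acc <- which(stu == plan[1])
  models <- list()
  prov <- vector("list", length(plan) - 1L)
  for (k in 2:length(plan)) {
    nxt <- which(stu == plan[k])
    idx <- c(acc, nxt)
    xt <- t(vals[, idx, drop = FALSE])
    batch <- c(rep("accumulated", length(acc)), rep(plan[k], length(nxt)))
    res <- dwd_integrate(xt, batch, C)
    vals[, idx] <- t(res$adjusted)
    models[[k - 1L]] <- res$model
    prov[[k - 1L]] <- tibble::tibble(
      step = k - 1L,
      merged_in = plan[k],
      n_accumulated = length(acc),
      n_new = length(nxt),
      direction_norm = sqrt(sum(res$model$w^2)),
      gap_removed = abs(diff(res$model$batch_mean_projections))
    )
    acc <- idx
  }
  out <- merged_matrix(vals, stu, labs)
  attr(out, "provenance") <- dplyr::bind_rows(prov)
  attr(out, "models") <- models
  attr(out, "plan") <- plan
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a DWD model into per-feature weights
#' @param x A `dwd_model`.
#' @param ... Unused.
#' @return Tibble with columns `feature`, `weight`.
#' @export
tidy.dwd_model <- function(x, ...) {
  tibble::tibble(
    feature = names(x$w) %||% as.character(seq_along(x$w)),
    weight = unname(x$w)
  )
}

#' One-row summary of a DWD fit
#' @param x A `dwd_model`.
#' @param ... Unused.
#' @return Tibble with the objective, offset, penalty, sample count and the
#'   between-batch mean-projection gap.
#' @export
glance.dwd_model <- function(x, ...) {
  tibble::tibble(
    objective = x$objective, beta = x$beta, C = x$C,
    n_samples = x$n_samples,
    mean_projection_gap = abs(diff(x$batch_mean_projections))
  )
}
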