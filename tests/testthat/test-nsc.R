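# independent re-evaluation of the shrunken-centroid statistics with plain loops
nsc_oracle_stats <- function(x, labels) {
  classes <- sort(unique(labels))
  n <- ncol(x); K <- length(classes)
  xbar <- apply(x, 1, mean)
  cent <- sapply(classes, function(k) apply(x[, labels == k, drop = FALSE], 1, mean))
  s2 <- numeric(nrow(x))
  for (i in seq_len(nrow(x))) {
    acc <- 0
    for (k in classes)
      acc <- acc + sum((x[i, labels == k] - cent[i, k])^2)
    s2[i] <- acc / (n - K)
  }
  s <- sqrt(s2); s0 <- median(s)
  mk <- sapply(classes, function(k) sqrt(1 / sum(labels == k) - 1 / n))
  d <- matrix(0, nrow(x), K, dimnames = list(rownames(x), classes))
  for (i in seq_len(nrow(x))) for (j in seq_len(K))
    d[i, j] <- (cent[i, j] - xbar[i]) / (mk[j] * (s[i] + s0))
  list(xbar = xbar, cent = cent, s = s, s0 = s0, mk = mk, d = d)
}

nsc_oracle_score <- function(or, xstar, delta, priors) {
  classes <- colnames(or$d)
  sapply(seq_along(classes), function(j) {
    dprime <- sign(or$d[, j]) * pmax(abs(or$d[, j]) - delta, 0)
    centp <- or$xbar + or$mk[j] * (or$s + or$s0) * dprime
    sum((xstar - centp)^2 / (or$s + or$s0)^2) - 2 * log(priors[j])
  })
}

test_that("contrasts and shrinkage match a hand-coded evaluation of the formulas", {
  rl <- random_labelled_matrix(5, 4, shift_gene = "g001", shift = 2, seed = 31)
  fit <- nsc_fit(rl$x, rl$labels)
  or <- nsc_oracle_stats(rl$x, rl$labels)
  expect_equal(fit$s0, or$s0)
  expect_equal(unname(fit$d), unname(or$d), tolerance = 1e-12)
  for (delta in c(0, 0.4, 1.5)) {
    ds <- sign(or$d) * pmax(abs(or$d) - delta, 0)
    td <- tidy(fit, delta = delta)
    expect_equal(td$shrunken_contrast,
                 as.vector(t(ds)), tolerance = 1e-12)
  }
  # discriminant scores agree with the loop oracle for a new sample
  xstar <- rnorm(5)
  pr <- nsc_predict(fit, matrix(xstar, ncol = 1), delta = 0.4)
  expect_equal(unname(unlist(pr[1, fit$classes])),
               unname(nsc_oracle_score(or, xstar, 0.4, fit$priors)),
               tolerance = 1e-10)
})

test_that("zero shrinkage reproduces plain nearest-centroid with the prior term", {
  rl <- random_labelled_matrix(8, 5, shift_gene = "g002", shift = 1.5, seed = 32)
  fit <- nsc_fit(rl$x, rl$labels)
  xnew <- matrix(rnorm(8 * 6), nrow = 8)
  colnames(xnew) <- paste0("n", 1:6)
  got <- nsc_predict(fit, xnew, delta = 0)$predicted
  or <- nsc_oracle_stats(rl$x, rl$labels)
  want <- apply(xnew, 2, function(xs) {
    sc <- sapply(seq_along(fit$classes), function(j)
      sum((xs - or$cent[, j])^2 / (or$s + or$s0)^2) - 2 * log(fit$priors[j]))
    fit$classes[which.min(sc)]
  })
  expect_equal(got, unname(want))
})

test_that("full shrinkage scores every sample by priors alone", {
  rl <- random_labelled_matrix(6, 3, seed = 33)
  labels <- c(rep("PTC", 4), rep("benign", 2))   # unbalanced priors
  x <- rl$x[, 1:6]
  fit <- nsc_fit(x, labels)
  big <- max(abs(fit$d)) + 1
  expect_length(nsc_active_genes(fit, big), 0)
  pred <- nsc_predict(fit, matrix(rnorm(60), nrow = 6), delta = big)
  expect_true(all(pred$predicted == "PTC"))   # majority class wins always
})

test_that("exact ties break toward the larger prior", {
  # two identical class distributions -> centroids equal, scores tie
  x <- rbind(g1 = c(1, 2, 1, 2, 1, 2, 1, 2, 1, 2))
  labels <- c("a", "a", "a", "a", "b", "b", "b", "b", "b", "b")
  x[1, labels == "a"] <- c(1, 2, 1, 2)
  x[1, labels == "b"] <- c(1, 2, 1, 2, 1.5, 1.5)
  fit <- nsc_fit(x, labels)
  big <- max(abs(fit$d)) + 1   # prior term only: b has the larger prior
  expect_equal(nsc_predict(fit, matrix(5), delta = big)$predicted, "b")
})

test_that("the active-gene count is non-increasing in the threshold", {
  rl <- random_labelled_matrix(40, 6, shift_gene = "g010", shift = 2, seed = 34)
  fit <- nsc_fit(rl$x, rl$labels)
  counts <- vapply(fit$delta_grid, function(d) length(nsc_active_genes(fit, d)), 0L)
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[1], 40L)   # delta = 0 keeps everything
})

test_that("loocv recovers a planted one-gene signature with the fewest-genes rule", {
  rl <- random_labelled_matrix(50, 15, shift_gene = "g025", shift = 4,
                               sd = 0.5, seed = 35)
  cv <- nsc_loocv(rl$x, rl$labels)
  expect_equal(cv$accuracy, 1.0)
  expect_equal(nsc_active_genes(cv$model, cv$chosen_delta), "g025")
  # chosen threshold is the largest among error minimisers
  minims <- cv$grid$delta[cv$grid$errors == min(cv$grid$errors)]
  expect_equal(cv$chosen_delta, max(minims))
  expect_equal(nrow(cv$predictions), 30L)
})

test_that("loocv error at zero shrinkage equals plain nearest-centroid CV error", {
  rl <- random_labelled_matrix(10, 6, shift_gene = "g003", shift = 1, seed = 36)
  cv <- nsc_loocv(rl$x, rl$labels, delta_grid = 0)
  # loop oracle
  errs <- 0
  for (i in seq_len(ncol(rl$x))) {
    or <- nsc_oracle_stats(rl$x[, -i, drop = FALSE], rl$labels[-i])
    priors <- table(rl$labels[-i])[sort(unique(rl$labels[-i]))] / (ncol(rl$x) - 1)
    sc <- nsc_oracle_score(or, rl$x[, i], 0, as.numeric(priors))
    if (sort(unique(rl$labels))[which.min(sc)] != rl$labels[i]) errs <- errs + 1
  }
  expect_equal(cv$grid$errors[cv$grid$delta == 0], errs)
})

test_that("label permutation drives loocv accuracy to the chance level", {
  rl <- random_labelled_matrix(30, 15, shift_gene = "g001", shift = 3, seed = 37)
  perm <- withr::with_seed(38, sample(rl$labels))
  cv <- nsc_loocv(rl$x, perm)
  # majority rate 0.5; allow 3 binomial SDs around it
  expect_lt(abs(cv$accuracy - 0.5), 0.5 * 3 * sqrt(1 / 30) + 1e-9)
})

test_that("the minimal n = 3 boundary case still reports three predictions", {
  x <- matrix(c(1, 2, 10), nrow = 1, dimnames = list("g1", paste0("s", 1:3)))
  suppressWarnings(cv <- nsc_loocv(x, c("a", "a", "b"), delta_grid = 0))
  expect_equal(nrow(cv$predictions), 3L)
})

test_that("identical studies give a flat cross-study matrix; one study gives loocv", {
  rl <- random_labelled_matrix(20, 8, shift_gene = "g005", shift = 3, seed = 39)
  s1 <- mapped_study("s1", rl$x, rl$labels)
  s2 <- mapped_study("s2", rl$x, rl$labels)
  cm <- cross_study_matrix(list(s1, s2))
  wide <- tidyr::pivot_wider(cm[, 1:3], names_from = "test",
                             values_from = "accuracy")
  expect_equal(wide$s1, wide$s2)

  cm1 <- cross_study_matrix(list(s1))
  cv <- nsc_loocv(rl$x, rl$labels)
  expect_equal(nrow(cm1), 1L)
  expect_equal(cm1$accuracy, cv$accuracy)
})

test_that("marker removal uncovers the redundant signature reservoir", {
  withr::with_seed(40, {
    n <- 20
    labels <- rep(c("PTC", "benign"), each = n)
    x <- matrix(rnorm(30 * 2 * n, sd = 0.4), nrow = 30,
                dimnames = list(sprintf("g%03d", 1:30), NULL))
    x["g001", labels == "PTC"] <- x["g001", labels == "PTC"] + 5   # dominant marker
    for (g in c("g010", "g011", "g012"))                            # redundant block
      x[g, labels == "PTC"] <- x[g, labels == "PTC"] + 2.5
  })
  rounds <- iterative_marker_removal(x, labels, max_rounds = 2,
                                     accuracy_floor = 0.5)
  expect_equal(rounds$signature[[1]], "g001")
  expect_true(all(rounds$signature[[2]] %in% c("g010", "g011", "g012")))
  expect_gte(rounds$accuracy[2], 0.9)

  one <- iterative_marker_removal(x, labels, max_rounds = 1)
  cv <- nsc_loocv(x, labels)
  expect_equal(one$accuracy, cv$accuracy)
  expect_equal(one$signature[[1]], nsc_active_genes(cv$model, cv$chosen_delta))
})

test_that("marker removal terminates cleanly when the matrix is exhausted", {
  rl <- random_labelled_matrix(2, 6, shift_gene = "g001", shift = 4, seed = 41)
  rounds <- iterative_marker_removal(rl$x, rl$labels, max_rounds = 10,
                                     accuracy_floor = 0)
  expect_true(isTRUE(attr(rounds, "truncated")) || nrow(rounds) < 10)
})

test_that("degenerate inputs are rejected with clear errors", {
  x <- matrix(1, nrow = 3, ncol = 4, dimnames = list(paste0("g", 1:3), NULL))
  expect_error(nsc_fit(x, c("a", "a", "b", "b")), "constant")
  expect_error(nsc_fit(x, c("a", "a", "a", "a")), "2 classes")
  expect_error(nsc_fit(matrix(rnorm(12), 3), c("a", "b", "b", "b")), "2 samples")
})
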