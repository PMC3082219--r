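test_that("exactly proportional assays have zero pairwise variation", {
  withr::with_seed(61, base <- 2^rnorm(8, 0, 1))
  q <- cbind(a1 = base, a2 = 3 * base, a3 = 2^rnorm(8, 0, 0.5))
  rk <- genorm_stability(q)
  v <- attr(rk, "pairwise_v")
  expect_equal(v["a1", "a2"], 0, tolerance = 1e-12)
  expect_gt(v["a1", "a3"], 0)
  # the proportional pair is the most stable
  expect_setequal(rk$assay[1:2], c("a1", "a2"))
})

test_that("M values match a hand-computed 3 x 4 evaluation", {
  q <- rbind(c(1, 2, 4), c(2, 2, 8), c(4, 8, 8), c(1, 4, 2))
  colnames(q) <- c("a", "b", "c")
  lg <- log2(q)
  v <- function(j, k) sd(lg[, j] - lg[, k])
  want <- c(a = mean(c(v(1, 2), v(1, 3))),
            b = mean(c(v(2, 1), v(2, 3))),
            c = mean(c(v(3, 1), v(3, 2))))
  rk <- genorm_stability(q)
  expect_equal(rk$m_value, unname(sort(want)), tolerance = 1e-12)
  expect_equal(attr(rk, "chosen"), names(which.min(want)))
})

test_that("geNorm M is invariant to per-sample rescaling and rejects bad input", {
  withr::with_seed(62, q <- matrix(2^rnorm(24), 8, 3,
                                   dimnames = list(NULL, c("a", "b", "c"))))
  scaled <- q * 2^rnorm(8)     # one loading factor per sample row
  expect_equal(genorm_stability(q)$m_value, genorm_stability(scaled)$m_value,
               tolerance = 1e-10)
  qbad <- q; qbad[3, 2] <- 0
  expect_error(genorm_stability(qbad), "non-positive")
  expect_error(genorm_stability(q[, 1:2]), "at least 3")
})

test_that("relative quantities follow the delta-Ct rule", {
  ct <- tibble::tibble(
    sample_id = rep(c("s1", "s2"), each = 4),
    entity = "PTC",
    assay = rep(c("tgt", "tgt", "ref", "ref"), 2),
    replicate = rep(1:2, 4),
    ct = c(19, 21, 25, 25,   24, 24, 24, 24)
  )
  q <- relative_quantity(ct, "tgt", "ref")
  expect_equal(q$quantity[q$sample_id == "s1"], 32)   # mean Ct 20 vs 25 -> 2^5
  expect_equal(q$quantity[q$sample_id == "s2"], 1)

  ct_miss <- dplyr::filter(ct, !(sample_id == "s2" & assay == "ref"))
  expect_warning(q2 <- relative_quantity(ct_miss, "tgt", "ref"), "dropped")
  expect_equal(q2$sample_id, "s1")
})

test_that("the ROC equals brute-force threshold enumeration on a toy vector", {
  v <- c(0.2, 0.8, 1.0, 1.0, 1.3, 2.0, 2.5, 3.1)
  labels <- c("NG", "NG", "NG", "PTC", "NG", "PTC", "PTC", "PTC")
  res <- roc_threshold(v, labels, "PTC", policy = "youden")
  pos <- labels == "PTC"
  brute <- t(vapply(res$roc$threshold, function(th) {
    pred <- v > th
    c(mean(pred[pos]), mean(!pred[!pos]))
  }, c(0, 0)))
  expect_equal(res$roc$sens, brute[, 1])
  expect_equal(res$roc$spec, brute[, 2])
  # every achievable (sens, spec) pair appears in the curve
  all_cuts <- sort(unique(c(v - 1e-9, v + 1e-9)))
  pairs <- unique(t(vapply(all_cuts, function(th) {
    pred <- v > th
    c(mean(pred[pos]), mean(!pred[!pos]))
  }, c(0, 0))))
  curve <- unique(cbind(res$roc$sens, res$roc$spec))
  expect_equal(nrow(curve), nrow(pairs))
  # youden threshold matches the exhaustive maximiser
  j_best <- max(brute[, 1] + brute[, 2] - 1)
  at <- res$roc[res$roc$threshold == res$threshold, ]
  expect_equal(at$sens + at$spec - 1, j_best)
})

test_that("threshold policies behave at the extremes", {
  sepd <- roc_threshold(c(1, 2, 3, 10, 11, 12),
                        rep(c("benign", "PTC"), each = 3), "PTC", "max-sens")
  at <- sepd$roc[sepd$roc$threshold == sepd$threshold, ]
  expect_equal(c(at$sens, at$spec), c(1, 1))
  expect_equal(sepd$auc, 1)

  const <- roc_threshold(rep(1, 6), rep(c("benign", "PTC"), each = 3), "PTC")
  expect_true(is.na(const$threshold))

  # max-sens tolerates false positives, never false negatives
  v <- c(0.5, 0.9, 1.2, 1.5, 2.0, 3.0)
  lab <- c("NG", "NG", "NG", "PTC", "PTC", "PTC")
  ms <- roc_threshold(v, lab, "PTC", "max-sens")
  expect_true(all(v[lab == "PTC"] > ms$threshold))
})

test_that("a fixed published-style decision value splits samples by 'above threshold'", {
  v <- c(0.20, 0.95, 1.07, 1.08, 1.09, 2.40, 36.0)
  expect_equal(v > 1.08, c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
})

test_that("sens and spec are invariant under monotone score transformation", {
  withr::with_seed(63, {
    v <- rlnorm(40)
    lab <- rep(c("PTC", "NG"), 20)
    v[lab == "PTC"] <- v[lab == "PTC"] * 4
  })
  r1 <- roc_threshold(v, lab, "PTC", "youden")
  r2 <- roc_threshold(log2(v), lab, "PTC", "youden")
  a1 <- r1$roc[r1$roc$threshold == r1$threshold, ]
  a2 <- r2$roc[r2$roc$threshold == r2$threshold, ]
  expect_equal(c(a1$sens, a1$spec), c(a2$sens, a2$spec))
  expect_equal(r1$auc, r2$auc, tolerance = 1e-12)
})

test_that("confusion metrics equal brute-force counting on all short binary vectors", {
  for (n in c(4, 6)) {
    grid <- expand.grid(rep(list(c(FALSE, TRUE)), n))
    for (i in seq_len(min(nrow(grid), 64))) {
      truth_bits <- as.logical(grid[i, ])
      if (!any(truth_bits)) next
      truth <- ifelse(truth_bits, "PTC", "other")
      pred_bits <- as.logical(grid[(i * 7) %% nrow(grid) + 1, ])
      cm <- confusion_metrics(pred_bits, truth, "PTC")
      tp <- sum(pred_bits & truth_bits); fp <- sum(pred_bits & !truth_bits)
      tn <- sum(!pred_bits & !truth_bits); fn <- sum(!pred_bits & truth_bits)
      expect_equal(unlist(cm[, c("tp", "fp", "tn", "fn")]),
                   c(tp = tp, fp = fp, tn = tn, fn = fn))
      expect_equal(cm$tp + cm$fp + cm$tn + cm$fn, n)
      if (tp + fp == 0) expect_true(is.na(cm$ppv))
      else expect_equal(cm$ppv, tp / (tp + fp))
      if (tn + fn == 0) expect_true(is.na(cm$npv))
      else expect_equal(cm$npv, tn / (tn + fn))
      expect_equal(cm$accuracy, (tp + tn) / n)
    }
  }
  perfect <- confusion_metrics(c(TRUE, FALSE), c("PTC", "NG"), "PTC")
  expect_equal(unlist(perfect[, c("sens", "spec", "ppv", "npv", "accuracy")]),
               c(sens = 1, spec = 1, ppv = 1, npv = 1, accuracy = 1))
  expect_error(confusion_metrics(TRUE, c("PTC", "NG"), "PTC"), "length")
})

test_that("Ct tables round-trip through CSV and reject malformed files", {
  ct <- simulate_qpcr(qpcr_config(seed = 64))
  path <- withr::local_tempfile(fileext = ".csv")
  write_ct_table(ct, path)
  back <- read_ct_table(path)
  expect_equal(as.data.frame(back), as.data.frame(ct), tolerance = 1e-12)

  bad <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(sample_id = "s1", ct = 20), bad, row.names = FALSE)
  expect_error(read_ct_table(bad), "missing column")
})
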