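# independent moment-matching oracle: bisection on the trigamma equation
prior_oracle <- function(s2, d) {
  z <- log(s2)
  ev <- var(z)
  excess <- ev - trigamma(d / 2)
  if (excess <= 0)
    return(list(d0 = Inf, s0_sq = exp(mean(z) - digamma(d / 2) + log(d / 2))))
  f <- function(h) trigamma(h / 2) - excess   # decreasing in h
  lo <- 1e-6; hi <- 1e6
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  d0 <- (lo + hi) / 2
  # E log s^2 = log s0^2 + digamma(d/2) - log(d/2) - digamma(d0/2) + log(d0/2)
  s0_sq <- exp(mean(z) - digamma(d / 2) + log(d / 2) +
                 digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq)
}

test_that("identical variances give the degenerate prior and full shrinkage", {
  pr <- estimate_prior(rep(2.5, 50), df = 6)
  expect_identical(pr$d0, Inf)
  expect_equal(pr$s0_sq, 2.5)
  rl <- random_labelled_matrix(20, 4, seed = 51)
  de <- moderated_t_table(rl$x, rl$labels, "PTC", prior = pr,
                          filter_prop = 0, sens_spec = FALSE)
  # with d0 = Inf the statistic uses the common s0 and normal tails
  expect_equal(de$p_value, 2 * pnorm(-abs(de$t)), tolerance = 1e-12)
})

test_that("the prior is recovered from scaled-inverse-chi-squared variances", {
  withr::with_seed(52, {
    G <- 5000; d0 <- 4; s0sq <- 1; d <- 8
    sigma2 <- s0sq * d0 / rchisq(G, d0)
    s2 <- sigma2 * rchisq(G, d) / d
  })
  pr <- estimate_prior(s2, d)
  expect_lt(abs(pr$d0 - d0) / d0, 0.25)
  expect_lt(abs(pr$s0_sq - s0sq) / s0sq, 0.10)
  # and it agrees with an independent bisection solver of the same equations
  or <- prior_oracle(s2, d)
  expect_equal(pr$d0, or$d0, tolerance = 0.02)
  expect_equal(pr$s0_sq, or$s0_sq, tolerance = 0.02)
})

test_that("with the prior weight off, the statistic is the ordinary pooled t", {
  rl <- random_labelled_matrix(30, 5, shift_gene = "g001", shift = 1, seed = 53)
  pr <- structure(list(d0 = 0, s0_sq = 1), class = "eb_prior")
  de <- moderated_t_table(rl$x, rl$labels, "PTC", prior = pr,
                          filter_prop = 0, sens_spec = FALSE)
  for (g in c("g001", "g007", "g023")) {
    tt <- t.test(rl$x[g, rl$labels == "PTC"], rl$x[g, rl$labels == "benign"],
                 var.equal = TRUE)
    row <- de[de$feature == g, ]
    expect_equal(abs(row$t), abs(unname(tt$statistic)), tolerance = 1e-10)
    expect_equal(row$p_value, tt$p.value, tolerance = 1e-10)
    expect_equal(row$logfc, unname(diff(rev(tt$estimate))), tolerance = 1e-10)
  }
})

test_that("the moderated pipeline agrees with the reference linear-model route", {
  rl <- random_labelled_matrix(200, 6, shift_gene = "g050", shift = 2, seed = 54)
  de <- moderated_t_table(rl$x, rl$labels, "PTC", filter_prop = 0,
                          sens_spec = FALSE)
  design <- cbind(1, rl$labels == "PTC")
  lf <- limma::eBayes(limma::lmFit(rl$x, design))
  ref <- data.frame(feature = rownames(rl$x), t = lf$t[, 2],
                    p = lf$p.value[, 2])
  mg <- merge(de, ref, by = "feature")
  expect_equal(mg$t.x, mg$t.y, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(mg$p_value, mg$p, tolerance = 1e-6)
  pr <- attr(de, "prior")
  expect_equal(pr$d0, lf$df.prior, tolerance = 1e-6)
  expect_equal(pr$s0_sq, lf$s2.prior, tolerance = 1e-6)
})

test_that("permuted labels give approximately uniform p-values", {
  rl <- random_labelled_matrix(400, 10, shift_gene = "g001", shift = 3, seed = 55)
  perm <- withr::with_seed(56, sample(rl$labels))
  de <- moderated_t_table(rl$x, perm, "PTC", filter_prop = 0, sens_spec = FALSE)
  expect_lt(mean(de$adj_p < 0.05), 0.05)
  expect_gt(mean(de$p_value), 0.40)
  expect_lt(mean(de$p_value), 0.60)
})

test_that("the planted marker ranks first by adjusted p on simulated studies", {
  cfg <- small_sim(seed = 57)
  merged <- prep_merged(cfg)
  integrated <- sequential_merge(merged)
  de <- moderated_t_table(integrated$values, integrated$labels, "PTC")
  expect_equal(de$feature[1], sim_gene_key(cfg, "g0001"))
  expect_equal(de$logfc[1], 3.3, tolerance = 0.2)
  # variance filter is applied before testing and its count is logged
  expect_gt(attr(de, "n_filtered"), 0)
})

test_that("BH adjustment equals the brute-force step-up on short vectors", {
  # straight transliteration of the step-up definition, loops only
  bh_brute <- function(p) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    adj_sorted <- numeric(m)
    for (j in seq_len(m)) adj_sorted[j] <- min(1, min(m * ps[j:m] / (j:m)))
    adj <- numeric(m); adj[o] <- adj_sorted
    adj
  }
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  withr::with_seed(58, {
    for (len in 1:8) {
      for (rep in 1:20) {
        p <- round(runif(len), 3)
        expect_equal(bh_adjust(p), bh_brute(p), tolerance = 1e-12)
      }
    }
    p <- runif(8)
    perm <- sample(8)
    expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  })
})

test_that("single-gene sensitivity/specificity matches exhaustive threshold search", {
  sens_spec_brute <- function(v, labels, positive, dir) {
    vv <- dir * v
    pos <- labels == positive
    cand <- c(min(vv) - 1, sort(unique(vv)), max(vv) + 1)
    best <- c(-Inf, NA, NA)
    for (th in cand) {
      pred <- vv > th
      se <- mean(pred[pos]); sp <- mean(!pred[!pos])
      j <- se + sp - 1
      if (j > best[1] + 1e-12 ||
          (abs(j - best[1]) <= 1e-12 && se > best[2] + 1e-12))
        best <- c(j, se, sp)
    }
    best[2:3]
  }
  withr::with_seed(59, {
    for (rep in 1:25) {
      v <- round(rnorm(10), 1)   # rounded to force ties
      labels <- sample(rep(c("PTC", "benign"), 5))
      for (dir in c(1, -1)) {
        got <- per_gene_sens_spec(v, labels, "PTC", direction = dir)
        want <- sens_spec_brute(v, labels, "PTC", dir)
        expect_equal(c(got$sens, got$spec), want)
      }
    }
  })
  # perfectly separated and constant genes
  sep <- per_gene_sens_spec(c(5, 6, 7, 1, 2, 3),
                            rep(c("PTC", "benign"), each = 3), "PTC")
  expect_equal(c(sep$sens, sep$spec), c(1, 1))
  cst <- per_gene_sens_spec(rep(2, 6), rep(c("PTC", "benign"), each = 3), "PTC")
  expect_equal(c(cst$sens, cst$spec), c(1, 0))
})
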