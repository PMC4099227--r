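test_that("descriptive statistics follow the summary-table conventions", {
  d <- descriptiveStats(c(1, 2, 3))
  expect_equal(d$mean, 2)
  expect_equal(d$st_dev, 1)
  expect_equal(d$min, 1)
  expect_equal(d$max, 3)

  one <- descriptiveStats(5)
  expect_equal(one$st_dev, 0)  # convention for n = 1
  expect_equal(descriptiveStats(rep(7, 10))$st_dev, 0)
  expect_error(descriptiveStats(numeric(0)), class = "lg_empty_input_error")
})

test_that("two-sample t-test matches hand computation and is antisymmetric", {
  r <- twoSampleT(c(1, 2, 3), c(3, 4, 5), pooled = TRUE)
  expect_equal(r$t_stat, -sqrt(6), tolerance = 1e-12)  # -2.449
  expect_equal(r$df, 4)
  expect_equal(r$p_value, 2 * pt(-sqrt(6), 4), tolerance = 1e-12)
  expect_equal(r$p_value, 0.0705, tolerance = 1e-3)

  same <- twoSampleT(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t_stat, 0)
  expect_equal(same$p_value, 1)

  a <- rnorm(10); b <- rnorm(12, 1)
  for (pooled in c(TRUE, FALSE)) {
    f <- twoSampleT(a, b, pooled); g <- twoSampleT(b, a, pooled)
    expect_equal(f$t_stat, -g$t_stat)
    expect_equal(f$p_value, g$p_value)
  }
  # Welch df differs from pooled df under unequal variances/sizes
  set.seed(8)
  a <- rnorm(8, sd = 4); b <- rnorm(20, sd = 0.5)
  expect_equal(twoSampleT(a, b, pooled = TRUE)$df, 26)
  expect_lt(twoSampleT(a, b, pooled = FALSE)$df, 26)
  expect_error(twoSampleT(1, c(1, 2)), class = "lg_empty_input_error")
})

test_that("empirical AUC equals brute-force pair enumeration (ties half)", {
  r <- empiricalAUC(pos = c(2, 3, 4), neg = c(1, 2, 3))
  expect_equal(r$auc, 7 / 9)
  expect_equal(empiricalAUC(5, 5)$auc, 0.5)
  expect_equal(empiricalAUC(c(10, 11), c(1, 2, 3))$auc, 1)

  set.seed(13)
  for (i in 1:200) {
    np <- sample(1:8, 1); nn <- sample(1:8, 1)
    # integer scores force frequent ties
    pos <- sample(0:5, np, replace = TRUE)
    neg <- sample(0:5, nn, replace = TRUE)
    expect_equal(empiricalAUC(pos, neg)$auc, bruteForceAUC(pos, neg))
  }
})

test_that("AUC complement and monotone-transform invariance hold", {
  set.seed(14)
  for (i in 1:25) {
    pos <- sample(0:20, sample(2:10, 1), replace = TRUE)
    neg <- sample(0:20, sample(2:10, 1), replace = TRUE)
    a <- empiricalAUC(pos, neg)$auc
    expect_equal(a + empiricalAUC(neg, pos)$auc, 1, tolerance = 1e-15)
    tr <- function(x) exp(0.3 * x) + x^3  # strictly increasing
    expect_equal(empiricalAUC(tr(pos), tr(neg))$auc, a)
  }
})

test_that("empirical AUC agrees with the rank-sum statistic oracle", {
  set.seed(15)
  pos <- rnorm(25, 1); neg <- rnorm(30)
  w <- suppressWarnings(wilcox.test(pos, neg))  # W = U statistic
  expect_equal(empiricalAUC(pos, neg)$auc,
               unname(w$statistic) / (25 * 30))
})

test_that("Hanley-McNeil SE and null p-value behave as documented", {
  pos <- c(2, 3, 4, 6, 7); neg <- c(1, 2, 3, 3, 5)
  r <- empiricalAUC(pos, neg)
  A <- r$auc; np <- 5; nn <- 5
  q1 <- A / (2 - A); q2 <- 2 * A^2 / (1 + A)
  seHM <- sqrt((A * (1 - A) + (np - 1) * (q1 - A^2) +
                  (nn - 1) * (q2 - A^2)) / (np * nn))
  expect_equal(r$se, seHM)
  var0 <- (0.25 + (np + nn - 2) * (1 / 3 - 0.25)) / (np * nn)
  expect_equal(r$p_value, 2 * pnorm(-abs((A - 0.5) / sqrt(var0))))

  # a perfectly uninformative split is never significant
  expect_equal(empiricalAUC(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # DeLong option: same AUC, finite SE
  d <- empiricalAUC(pos, neg, method = "delong")
  expect_equal(d$auc, r$auc)
  expect_gt(d$se, 0)
})

test_that("ROC curve points are monotone and integrate to the AUC", {
  p1 <- rocCurvePoints(pos = 2, neg = 1)
  expect_equal(p1$fpr, c(0, 0, 1))
  expect_equal(p1$tpr, c(0, 1, 1))
  expect_equal(trapezoidalAUC(p1), 1)
  expect_equal(trapezoidalAUC(rocCurvePoints(pos = 1, neg = 2)), 0)

  set.seed(16)
  for (i in 1:50) {
    pos <- sample(0:10, sample(2:12, 1), replace = TRUE)
    neg <- sample(0:10, sample(2:12, 1), replace = TRUE)
    pts <- rocCurvePoints(pos, neg)
    expect_true(all(diff(pts$fpr) >= 0))
    expect_true(all(diff(pts$tpr) >= 0))
    expect_equal(pts$fpr[1], 0); expect_equal(pts$tpr[1], 0)
    expect_equal(pts$fpr[nrow(pts)], 1)
    expect_equal(pts$tpr[nrow(pts)], 1)
    expect_equal(trapezoidalAUC(pts), empiricalAUC(pos, neg)$auc,
                 tolerance = 1e-12)
  }
})

test_that("binormal AUC evaluates its closed form and edge cases", {
  expect_equal(binormalAUC(0, 1, 0, 1), 0.5)
  expect_equal(binormalAUC(1, 1 / sqrt(2), 0, 1 / sqrt(2)), pnorm(1))
  expect_equal(pnorm(1), 0.8413, tolerance = 1e-4)
  # flat-bone SDGL parameters: closed form about 0.878
  expect_equal(binormalAUC(270.66, 16.80, 248.12, 9.51),
               pnorm(22.54 / sqrt(16.80^2 + 9.51^2)))
  expect_equal(binormalAUC(270.66, 16.80, 248.12, 9.51), 0.878,
               tolerance = 1e-3)
  expect_identical(binormalAUC(2, 0, 1, 0), 1)
  expect_error(binormalAUC(1, 0, 1, 0), class = "lg_degenerate_error")
  expect_error(binormalAUC(1, -1, 0, 1), class = "lg_param_error")
})

test_that("mean empirical AUC converges to the binormal value", {
  set.seed(17)
  muP <- 1; muN <- 0; sdP <- 1.2; sdN <- 0.8
  target <- binormalAUC(muP, sdP, muN, sdN)
  aucs <- replicate(400, empiricalAUC(rnorm(20, muP, sdP),
                                      rnorm(25, muN, sdN))$auc)
  mcse <- sd(aucs) / sqrt(length(aucs))
  expect_lt(abs(mean(aucs) - target), 3 * mcse)
})
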