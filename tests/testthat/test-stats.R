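test_that("signed-rank test handles degenerate, textbook and enumerated cases", {
  expect_identical(wilcoxon_signed_rank(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_true(wilcoxon_signed_rank(c(1, 2, 3), c(1, 2, 3))$degenerate)
  # all-positive differences {1..5}: one extreme tail of 32 sign patterns
  r <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5))
  expect_identical(r$p_value, 2 / 32)
  expect_true(r$exact)
  # exact path equals the brute-force enumeration oracle
  set.seed(11)
  for (i in 1:25) {
    d <- stats::rnorm(8)
    expect_equal(wilcoxon_signed_rank(d)$p_value, enum_signed_rank_p(d),
                 tolerance = 1e-12)
  }
  # ties force the corrected normal approximation
  rt <- wilcoxon_signed_rank(c(1, 1, 2, -2, 3, 4))
  expect_false(rt$exact)
  expect_true(rt$p_value >= 0 && rt$p_value <= 1)
})

test_that("paired t matches hand arithmetic and rejects zero variance", {
  y <- c(10, 20, 30)
  r <- paired_t(y + c(1, 2, 3), y)
  expect_equal(r$t, 2 / (1 / sqrt(3)), tolerance = 1e-6)
  expect_identical(r$df, 2)
  expect_equal(r$p_value, 2 * stats::pt(-r$t, 2))
  expect_error(paired_t(y + 1, y), "zero-variance")
  expect_error(paired_t(1, 2), "length")
})

test_that("consistency ICC is 1 under agreement and shift, and matches aov", {
  x <- c(3, 1, 4, 5, 2, 4, 3, 5)
  expect_equal(icc_consistency(cbind(x, x))$icc, 1)
  expect_equal(icc_consistency(cbind(x, x + 2))$icc, 1)
  # invariance: per-rater constants and positive affine rescaling
  set.seed(21)
  m <- matrix(stats::rnorm(40), 20, 2)
  base <- icc_consistency(m)$icc
  expect_equal(icc_consistency(sweep(m, 2, c(5, -3), "+"))$icc, base)
  expect_equal(icc_consistency(3.2 * m + 7)$icc, base)
  expect_equal(icc_consistency(m, unit = "single")$icc,
               (icc_consistency(m)$ms_items - icc_consistency(m)$ms_error) /
                 (icc_consistency(m)$ms_items + icc_consistency(m)$ms_error))
  # cross-check mean squares against stats::aov on long format
  long <- data.frame(score = c(m), item = factor(rep(1:20, 2)),
                     rater = factor(rep(1:2, each = 20)))
  tab <- summary(stats::aov(score ~ item + rater, data = long))[[1]]
  ms_items <- tab["item", "Mean Sq"]
  ms_error <- tab["Residuals", "Mean Sq"]
  expect_equal(base, (ms_items - ms_error) / ms_items, tolerance = 1e-10)
  # no between-item variance -> flagged NaN
  flat <- icc_consistency(matrix(c(1, 1, 2, 2), 2, 2))
  expect_true(flat$undefined)
  expect_true(is.nan(flat$icc))
})

test_that("Shapiro-Wilk screening enforces its domain", {
  set.seed(31)
  expect_gt(normality_check(stats::rnorm(500))$p_value, 0.05)
  rejections <- mean(vapply(1:100, function(i) {
    normality_check(stats::rexp(50))$p_value < 0.05
  }, logical(1)))
  expect_gt(rejections, 0.9)
  expect_error(normality_check(rep(1, 10)), "constant")
  expect_error(normality_check(c(1, 2)), "3 <= n")
  expect_error(normality_check(stats::rnorm(5001)), "n <= 5000")
})

test_that("wilcoxon has power against a 1.5-point Likert shift at n = 8", {
  set.seed(41)
  rej <- mean(vapply(1:200, function(i) {
    eid <- sample(1:3, 8, replace = TRUE)
    si <- pmin(5L, eid + stats::rbinom(8, 3, 0.5))  # mean shift 1.5
    wilcoxon_signed_rank(si, eid)$p_value < 0.05
  }, logical(1)))
  expect_gt(rej, 0.8)
})

test_that("the comparison report reproduces order statistics and pairing", {
  sc <- c(4, 4, 4, 4, 5, 4, 4, 2)
  scores <- tibble::tibble(
    metric = "stent_appearance", fov = "150",
    system = rep(c("a", "b"), each = 8),
    item = rep(1:8, 2), reader = 1L, session = 1L,
    score = c(sc, sc - c(0, 1, 1, 0, 1, 2, 1, 0)))
  rep1 <- summarize_comparison(scores = scores)
  row_a <- rep1[rep1$system == "a", ]
  expect_identical(row_a$median, 4)
  expect_identical(c(row_a$q1, row_a$q3), c(4, 4))
  expect_identical(row_a$test, "wilcoxon_signed_rank")

  # identical inputs for both systems: p = 1, identical cells
  meas <- do.call(rbind, lapply(c("blooming_pct", "diameter_abs_error_mm"),
    function(mm) tibble::tibble(
      metric = mm, fov = "150", system = rep(c("a", "b"), each = 4),
      stent = rep(c("s1", "s1", "s2", "s2"), 2),
      location = rep(c(1, 2, 1, 2), 2), value = rep(c(20, 22, 30, 31), 2))))
  rep2 <- summarize_comparison(measurements = meas)
  expect_true(all(rep2$p_value == 1))
  expect_false(any(rep2$significant))
  expect_equal(rep2$mean[rep2$system == "a"], rep2$mean[rep2$system == "b"])

  # schema: 3 metrics x 2 FOVs x 2 systems
  big <- do.call(rbind, lapply(c("150", "50"), function(fv) {
    do.call(rbind, lapply(c("m1", "m2", "m3"), function(mm) {
      tibble::tibble(metric = mm, fov = fv,
                     system = rep(c("a", "b"), each = 3),
                     stent = "s", location = rep(1:3, 2),
                     value = stats::rnorm(6, 10))
    }))
  }))
  rep3 <- summarize_comparison(measurements = big)
  expect_identical(nrow(rep3), 12L)
  expect_identical(sort(unique(rep3$metric)), c("m1", "m2", "m3"))

  # unpaired designs are refused
  bad <- meas[-1, ]
  expect_error(summarize_comparison(measurements = bad), "pairing error")
})
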