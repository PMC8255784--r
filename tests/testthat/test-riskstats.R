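test_that("sensitivity/specificity fractions and presentations are exact", {
  perfect <- sensitivity_specificity(tp = 5, fp = 0, tn = 7, fn = 0)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)

  r <- sensitivity_specificity(tp = 12, fn = 2, tn = 19, fp = 4)
  expect_equal(r$sensitivity, 12 / 14)
  expect_equal(r$specificity, 19 / 23)
  expect_equal(r$sensitivity_2dp, 0.86)
  expect_equal(r$specificity_2dp, 0.83)

  expect_equal(sensitivity_specificity(tp = 0, fn = 1, tn = 1, fp = 0)$sensitivity, 0)
  none <- sensitivity_specificity(tp = 0, fn = 0, tn = 3, fp = 1)
  expect_true(is.na(none$sensitivity))
})

test_that("a (0.86, 0.83) table is consistent with group sizes 14 and 23", {
  # enumerate all integer confusion tables with tp+fn = 14, tn+fp = 23
  hits <- list()
  for (tp in 0:14) for (tn in 0:23) {
    se <- round_half_up(tp / 14, 2)
    sp <- round_half_up(tn / 23, 2)
    if (se == 0.86 && sp == 0.83) {
      hits[[length(hits) + 1]] <- c(tp = tp, tn = tn)
    }
  }
  expect_equal(length(hits), 1L)
  expect_equal(hits[[1]], c(tp = 12, tn = 19))
})

test_that("swapping class labels swaps sensitivity and specificity", {
  set.seed(9)
  for (i in 1:20) {
    cnt <- sample(0:20, 4, replace = TRUE)
    cnt[cnt == 0] <- 1
    a <- sensitivity_specificity(cnt[1], cnt[2], cnt[3], cnt[4])
    b <- sensitivity_specificity(tp = cnt[3], fp = cnt[4], tn = cnt[1],
                                 fn = cnt[2])
    expect_equal(a$sensitivity, b$specificity)
    expect_equal(a$specificity, b$sensitivity)
  }
})

test_that("quadrant rule is strict and monotone in its thresholds", {
  expect_true(quadrant_low_risk(1.5, 500))
  expect_false(quadrant_low_risk(1.975, 500)) # boundary: strict
  expect_false(quadrant_low_risk(1.5, 670))
  expect_true(is.na(quadrant_low_risk(NA, 500)))
  set.seed(10)
  for (i in 1:30) {
    a <- runif(1, 1, 3); s <- runif(1, 100, 900)
    thr1 <- quadrant_thresholds(runif(1, 1, 3), runif(1, 100, 900))
    thr2 <- quadrant_thresholds(thr1$aape_threshold - runif(1, 0, 0.5),
                                thr1$iein_threshold - runif(1, 0, 200))
    if (quadrant_low_risk(a, s, thr2)) {
      expect_true(quadrant_low_risk(a, s, thr1))
    }
  }
})

test_that("midpoint threshold calibration separates disjoint classes", {
  v <- c(1.1, 1.2, 1.3, 1.8, 1.9)
  pos <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  thr <- choose_threshold(v, pos)
  expect_equal(thr, (1.3 + 1.8) / 2)
  expect_true(all(v[pos] < thr) && all(v[!pos] >= thr))
  expect_error(choose_threshold(v, rep(TRUE, 5)), "both classes")
})

test_that("pooled proportion z test matches direct evaluation and prop.test", {
  same <- two_sample_proportion_test(5, 10, 10, 20)
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 1)

  r <- two_sample_proportion_test(10, 12, 2, 11)
  expect_equal(r$z, 3.12, tolerance = 0.005)
  expect_equal(r$p_value, 0.0018, tolerance = 0.05)
  expect_lt(r$p_value, 0.05)
  # symmetric in group order
  r2 <- two_sample_proportion_test(2, 11, 10, 12)
  expect_equal(r2$p_value, r$p_value)
  expect_equal(r2$z, -r$z)
  # z^2 equals the uncorrected chi-squared statistic
  pt <- suppressWarnings(prop.test(c(10, 2), c(12, 11), correct = FALSE))
  expect_equal(r$z^2, unname(pt$statistic), tolerance = 1e-12)

  weak <- two_sample_proportion_test(3, 14, 2, 11)
  expect_gt(weak$p_value, 0.05)
})

test_that("Grubbs test flags the gross outlier and is monotone in alpha", {
  expect_equal(nrow(grubbs_test(c(1, 1, 1))), 0L)
  out <- grubbs_test(c(10, 10.1, 9.9, 25), alpha = 0.05)
  expect_equal(out$index, 4L)
  expect_equal(out$value, 25)
  # a moderate outlier in a larger sample: flagged at 0.05, not at 0.001
  x <- c(10, 10.2, 9.8, 10.1, 9.9, 10.3, 9.7, 10.0, 10.05, 11.2)
  expect_equal(grubbs_test(x, alpha = 0.05)$index, 10L)
  expect_equal(nrow(grubbs_test(x, alpha = 0.001)), 0L)
  # monotonicity: anything flagged at the stricter level is flagged at 0.05
  set.seed(12)
  for (i in 1:20) {
    y <- rnorm(12)
    strict <- grubbs_test(y, alpha = 0.001)$index
    loose <- grubbs_test(y, alpha = 0.05)$index
    expect_true(all(strict %in% loose))
  }
})

test_that("Grubbs critical value agrees with a Monte Carlo null", {
  n <- 8; alpha <- 0.05
  tcrit <- qt(1 - alpha / (2 * n), n - 2)
  gcrit <- (n - 1) / sqrt(n) * sqrt(tcrit^2 / (n - 2 + tcrit^2))
  set.seed(11)
  g_null <- vapply(1:4000, function(i) {
    x <- rnorm(n)
    max(abs(x - mean(x))) / sd(x)
  }, numeric(1))
  expect_lt(abs(unname(stats::quantile(g_null, 1 - alpha)) - gcrit), 0.06)
})

test_that("Friedewald LDL reproduces the published lipid arithmetic", {
  expect_equal(round_half_up(friedewald_ldl(1.65, 1.1, 0.36), 2), 0.39)
  expect_equal(friedewald_ldl(2, 0, 0), 2)
  # back-solved triglycerides consistent with the printed baseline LDL
  tag <- (1.85 - 0.85 - 0.57) * 2.2
  expect_equal(friedewald_ldl(1.85, 0.85, tag), 0.57, tolerance = 1e-12)
  expect_equal(round_half_up(friedewald_ldl(1.85, 0.85, 0.95), 2), 0.57)
  expect_warning(neg <- friedewald_ldl(1, 0.9, 1), "validity")
  expect_lt(neg, 0)
  expect_error(friedewald_ldl(-1, 0, 0), "non-negative")
})
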