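# Diagnostic accuracy statistics, group comparisons, logistic odds ratios.

test_that("diagnostic summary matches hand computation and published cells", {
  # <80 mm^3 rule-out from a published baseline screening table
  ds <- diagnostic_summary(threshold_counts(tp = 198, fp = 1975,
                                            fn = 30, tn = 3726))
  g <- glance(ds)
  expect_equal(round_half_up(g$sensitivity, 1), 86.8)
  expect_equal(round_half_up(g$specificity, 1), 65.4)
  expect_equal(round_half_up(g$npv, 1), 99.2)
  # >=300 mm^3 rule-in PPV
  ds2 <- diagnostic_summary(threshold_counts(tp = 152, fp = 359,
                                             fn = 76, tn = 5342))
  expect_equal(round_half_up(glance(ds2)$ppv, 1), 29.7)
})

test_that("undefined metrics are reported absent, not zero", {
  ds <- diagnostic_summary(threshold_counts(tp = 0, fp = 3, fn = 0, tn = 7))
  m <- tidy(ds)
  expect_true(is.na(m$estimate[m$metric == "sensitivity"]))
  expect_false(is.na(m$estimate[m$metric == "specificity"]))
  expect_error(threshold_counts(tp = -1, fp = 0, fn = 0, tn = 0),
               "non-negative")
})

test_that("sens/spec and ppv/npv swap under the tp<->tn, fp<->fn exchange", {
  withr::local_seed(99)
  for (i in 1:10) {
    v <- sample(0:200, 4, replace = TRUE)
    a <- glance(diagnostic_summary(threshold_counts(v[1], v[2], v[3], v[4])))
    b <- glance(diagnostic_summary(threshold_counts(v[4], v[3], v[2], v[1])))
    expect_equal(a$sensitivity, b$specificity)
    expect_equal(a$ppv, b$npv)
  }
})

test_that("Clopper-Pearson agrees with binom.test and Wilson stays inside it", {
  for (xn in list(c(37, 4809), c(8, 3823), c(0, 50), c(50, 50), c(3, 10))) {
    got <- binom_ci(xn[1], xn[2])
    ref <- binom.test(xn[1], xn[2])$conf.int
    expect_equal(got$lower, ref[1], tolerance = 1e-9)
    expect_equal(got$upper, ref[2], tolerance = 1e-9)
  }
  w <- binom_ci(37, 4809, method = "wilson")
  cp <- binom_ci(37, 4809)
  expect_gt(w$lower, cp$lower)
  expect_lt(w$upper, cp$upper)
})

test_that("crude risks reproduce published values and degenerate cases", {
  r <- crude_risk(228, 5929)
  expect_equal(round_half_up(r$risk_pct, 2), 3.85)
  r2 <- crude_risk(37, 4809)
  expect_equal(round_half_up(r2$risk_pct, 2), 0.77)
  expect_equal(round_half_up(r2$conf.low, 2), 0.54)
  expect_equal(round_half_up(r2$conf.high, 2), 1.06)
  r0 <- crude_risk(0, 100)
  expect_equal(r0$risk_pct, 0)
  expect_equal(r0$conf.low, 0)
  expect_error(crude_risk(5, 4), "events")
})

test_that("Pearson chi-squared equals its closed form and handles degenerate tables", {
  # identical row proportions: statistic 0, p 1
  flat <- pearson_chi2(matrix(c(10, 100, 20, 200), 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  # closed-form cross-product identity on assorted tables
  withr::local_seed(5)
  for (i in 1:10) {
    m <- matrix(sample(1:500, 4), 2)
    got <- pearson_chi2(m)
    expect_equal(got$statistic, chi2_closed(m[1, 1], m[1, 2], m[2, 1], m[2, 2]),
                 tolerance = 1e-10)
    expect_equal(got$p_value, pchisq(got$statistic, 1, lower.tail = FALSE))
  }
  expect_error(pearson_chi2(matrix(c(0, 0, 5, 10), 2, byrow = TRUE)),
               "margin")
})

test_that("exact McNemar agrees with full binomial enumeration", {
  expect_equal(mcnemar_test(7, 7)$p_value, 1)
  expect_equal(mcnemar_test(0, 15)$p_value, 2 * 0.5^15)
  for (b in 0:10) for (cc in 0:10) {
    if (b + cc == 0) next
    expect_equal(mcnemar_test(b, cc)$p_value, mcnemar_enum(b, cc),
                 tolerance = 1e-12,
                 label = sprintf("b=%d c=%d", b, cc))
  }
  # chi-squared variants defer to the classical statistic
  expect_equal(mcnemar_test(5, 15, variant = "chi2")$statistic,
               (5 - 15)^2 / 20)
  expect_equal(mcnemar_test(5, 15, variant = "chi2_corrected")$statistic,
               (abs(5 - 15) - 1)^2 / 20)
  expect_error(mcnemar_test(0, 0), "undefined")
})

test_that("binary-predictor logistic OR equals the cross-product ratio", {
  d <- tidyr::uncount(
    tibble::tibble(x = c(0, 0, 1, 1), y = c(FALSE, TRUE, FALSE, TRUE),
                   w = c(200, 15, 60, 25)), w)
  or <- tidy(size_odds_ratio(d, x, y))$odds_ratio
  expect_equal(or, (25 * 200) / (60 * 15), tolerance = 1e-6)
})

test_that("logistic OR is null when outcome is independent of size", {
  withr::local_seed(31)
  d <- tibble::tibble(x = rlnorm(4000, 4, 1), y = runif(4000) < 0.05)
  t <- tidy(size_odds_ratio(d, x, y))
  expect_true(t$conf.low < 1 && 1 < t$conf.high)
})

test_that("perfect separation raises an explicit error", {
  d <- tibble::tibble(x = c(1:10, 21:30), y = rep(c(FALSE, TRUE), each = 10))
  expect_error(size_odds_ratio(d, x, y), "separat")
})

test_that("odds ratios rescale exactly with unit_scale", {
  withr::local_seed(8)
  d <- tibble::tibble(x = rlnorm(2000, 4.5, 1))
  d$y <- runif(2000) < plogis(-4 + 0.004 * d$x)
  t1 <- tidy(size_odds_ratio(d, x, y, unit_scale = 1))
  t10 <- tidy(size_odds_ratio(d, x, y, unit_scale = 10))
  expect_equal(t10$odds_ratio, t1$odds_ratio^10, tolerance = 1e-8)
})

test_that("perifissural risk delegates to crude_risk with registry extras", {
  idx <- reduce_to_index(reconstruct_fixture(baseline_marginals()))
  r <- perifissural_risk(idx)
  expect_equal(r$events, 8L)
  expect_equal(r$n, 3823L)
  expect_equal(round_half_up(r$risk_pct, 2), 0.21)
  expect_equal(r, crude_risk(8, 3823))
  r2 <- perifissural_risk(idx, extra_events = 2)
  expect_equal(r2$events, 10L)
})
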