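# ROC construction, DeLong inference, Youden cut-points.

sim_scores <- function(n, auc_sep = 1, p_pos = 0.3, seed = 1) {
  withr::with_seed(seed, {
    y <- runif(n) < p_pos
    tibble::tibble(s = rnorm(n, mean = ifelse(y, auc_sep, 0)), y = y)
  })
}

test_that("ROC endpoints, separation and the null behave", {
  sep <- tibble::tibble(s = c(1, 2, 10, 11), y = c(FALSE, FALSE, TRUE, TRUE))
  rc <- roc_curve(sep, s, y)
  expect_equal(auc(rc), 1)
  expect_equal(rc$sensitivity[1], 0)
  expect_equal(rc$fpr[1], 0)
  expect_equal(rc$sensitivity[nrow(rc)], 1)
  expect_equal(rc$fpr[nrow(rc)], 1)

  null <- sim_scores(4000, auc_sep = 0, seed = 2)
  expect_lt(abs(auc(roc_curve(null, s, y)) - 0.5), 0.03)

  expect_error(roc_curve(tibble::tibble(s = 1:3, y = c(TRUE, TRUE, TRUE)),
                         s, y), "both outcome classes")
})

test_that("AUC equals the brute-force Mann-Whitney statistic, with ties", {
  withr::local_seed(12)
  for (i in 1:8) {
    n <- sample(20:200, 1)
    d <- tibble::tibble(
      s = sample(round(rnorm(n), 1)),  # coarse values force ties
      y = runif(n) < 0.4
    )
    if (!any(d$y) || all(d$y)) next
    rc <- roc_curve(d, s, y)
    expect_equal(auc(rc), auc_pairs(d$s, d$y), tolerance = 1e-12)
    # curve's trapezoidal area is the stored auc
    tr <- sum(diff(rc$fpr) * (head(rc$sensitivity, -1) +
                                rc$sensitivity[-1]) / 2)
    expect_equal(attr(rc, "auc"), tr)
  }
})

test_that("AUC is invariant under monotone transforms and flips with labels", {
  d <- sim_scores(500, auc_sep = 1.2, seed = 3)
  a <- auc(roc_curve(d, s, y))
  expect_equal(auc(roc_curve(dplyr::mutate(d, s = exp(s)), s, y)), a)
  expect_equal(auc(roc_curve(dplyr::mutate(d, s = 5 * s - 2), s, y)), a)
  expect_equal(auc(roc_curve(dplyr::mutate(d, y = !y), s, y)), 1 - a,
               tolerance = 1e-12)
})

test_that("implementation agrees with an independent ROC library", {
  skip_if_not_installed("pROC")
  d <- sim_scores(600, auc_sep = 1, seed = 4)
  ours <- auc(roc_curve(d, s, y))
  theirs <- as.numeric(pROC::auc(pROC::roc(d$y, d$s, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-10)

  d$s2 <- withr::with_seed(5, d$s + rnorm(600, sd = 1.2))
  cmp <- delong_compare(d, s, s2, y)
  ref <- pROC::roc.test(pROC::roc(d$y, d$s, quiet = TRUE, direction = "<"),
                        pROC::roc(d$y, d$s2, quiet = TRUE, direction = "<"),
                        method = "delong", paired = TRUE)
  expect_equal(cmp$p_value, unname(ref$p.value), tolerance = 1e-8)
  expect_equal(cmp$statistic, unname(ref$statistic), tolerance = 1e-8)
})

test_that("DeLong comparison is symmetric and null on identical scores", {
  d <- sim_scores(300, auc_sep = 1, seed = 6)
  same <- delong_compare(d, s, s, y)
  expect_equal(same$difference, 0)
  expect_equal(same$p_value, 1)
  d$s2 <- withr::with_seed(7, d$s + rnorm(300))
  ab <- delong_compare(d, s, s2, y)
  ba <- delong_compare(d, s2, s, y)
  expect_equal(ab$difference, -ba$difference)
  expect_equal(ab$p_value, ba$p_value)
  expect_error(delong_compare(tibble::tibble(s = 1:3, s2 = 1:3,
                                             y = c(TRUE, TRUE, TRUE)),
                              s, s2, y), "both outcome classes")
})

test_that("DeLong variance tracks the bootstrap variance of the AUC", {
  d <- sim_scores(2000, auc_sep = 1, seed = 8)
  dv <- delong_auc_variance(d, s, y)$variance
  boot <- withr::with_seed(9, replicate(400, {
    i <- sample.int(nrow(d), replace = TRUE)
    di <- d[i, ]
    if (!any(di$y) || all(di$y)) return(NA_real_)
    auc(roc_curve(di, s, y))
  }))
  bv <- var(boot, na.rm = TRUE)
  expect_lt(abs(dv - bv) / bv, 0.15)
})

test_that("Youden threshold matches the exhaustive scan and its invariances", {
  # perfect separation: J = 1 at the lowest separating threshold
  sep <- tibble::tibble(s = c(1, 2, 10, 11), y = c(FALSE, FALSE, TRUE, TRUE))
  yj <- youden_optimal(sep, s, y)
  expect_equal(yj$j, 1)
  expect_equal(yj$threshold, 10)
  withr::local_seed(13)
  for (i in 1:8) {
    d <- tibble::tibble(s = round(rnorm(150), 1), y = runif(150) < 0.35)
    if (!any(d$y) || all(d$y)) next
    got <- youden_optimal(d, s, y)
    expect_equal(got$j, youden_scan(d$s, d$y), tolerance = 1e-12)
    # J unchanged under a strictly monotone transform of the scores
    got_t <- youden_optimal(dplyr::mutate(d, s = exp(s / 2)), s, y)
    expect_equal(got_t$j, got$j, tolerance = 1e-12)
    expect_equal(got_t$threshold, exp(got$threshold / 2), tolerance = 1e-12)
  }
})
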