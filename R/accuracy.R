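# Diagnostic accuracy statistics with exact binomial confidence intervals.

#' Binomial proportion confidence interval
#'
#' Clopper-Pearson (exact, the default: guaranteed at-least-nominal
#' coverage, and the interval type that reproduces published screening
#' tables) or Wilson score.
#'
#' @param x Successes.
#' @param n Trials.
#' @param level Confidence level (default 0.95).
#' @param method `"clopper-pearson"` or `"wilson"`.
#' @return Tibble with `lower`, `upper` on the proportion (0-1) scale.
#' @export
#' @examples
#' binom_ci(37, 4809)
binom_ci <- function(x, n, level = 0.95,
                     method = c("clopper-pearson", "wilson")) {
  method <- match.arg(method)
  if (any(x < 0) || any(x > n)) stop_domain("need 0 <= x <= n")
  a <- (1 - level) / 2
  if (method == "clopper-pearson") {
    lower <- ifelse(x == 0, 0, qbeta(a, x, n - x + 1))
    upper <- ifelse(x == n, 1, qbeta(1 - a, x + 1, n - x))
  } else {
    z <- qnorm(1 - a)
    p <- x / n
    den <- 1 + z^2 / n
    ctr <- (p + z^2 / (2 * n)) / den
    hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
    lower <- pmax(0, ctr - hw)
    upper <- pmin(1, ctr + hw)
  }
  tibble(lower = lower, upper = upper)
}

#' Diagnostic accuracy summary of a 2x2 table
#'
#' Sensitivity, specificity, PPV and NPV computed conventionally from
#' [threshold_counts()], on the percentage scale with exact binomial
#' confidence intervals. A metric whose denominator is empty (e.g.
#' sensitivity with no cases) is reported absent (`NA`), not zero.
#'
#' @param counts A [threshold_counts()] object.
#' @param ci_level Confidence level (default 0.95).
#' @param ci_method Passed to [binom_ci()].
#' @return A `diagnostic_summary` object; see [tidy()] for the tibble of
#'   `(metric, estimate, conf.low, conf.high)` rows in percent.
#' @export
#' @examples
#' diagnostic_summary(threshold_counts(tp = 198, fp = 1975, fn = 30, tn = 3726))
diagnostic_summary <- function(counts, ci_level = 0.95,
                               ci_method = c("clopper-pearson", "wilson")) {
  stopifnot(inherits(counts, "threshold_counts"))
  ci_method <- match.arg(ci_method)
  cells <- list(
    sensitivity = c(counts$tp, counts$tp + counts$fn),
    specificity = c(counts$tn, counts$tn + counts$fp),
    ppv = c(counts$tp, counts$tp + counts$fp),
    npv = c(counts$tn, counts$tn + counts$fn)
  )
  rows <- purrr::imap(cells, function(xn, nm) {
    if (xn[2] == 0) {
      return(tibble(metric = nm, estimate = NA_real_,
                    conf.low = NA_real_, conf.high = NA_real_))
    }
    ci <- binom_ci(xn[1], xn[2], ci_level, ci_method)
    tibble(metric = nm, estimate = 100 * xn[1] / xn[2],
           conf.low = 100 * ci$lower, conf.high = 100 * ci$upper)
  })
  structure(list(metrics = bind_rows(rows), counts = counts,
                 ci_level = ci_level, ci_method = ci_method),
            class = "diagnostic_summary")
}

#' @export
print.diagnostic_summary <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<diagnostic_summary> (%.0f%% CI, %s)\n",
              100 * x$ci_level, x$ci_method))
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  %-11s %s (%s to %s)\n", m$metric[i],
                fmt_pct(m$estimate[i]), fmt_pct(m$conf.low[i]),
                fmt_pct(m$conf.high[i])))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.diagnostic_summary <- function(x, ...) x$metrics

#' @exportS3Method generics::glance
glance.diagnostic_summary <- function(x, ...) {
  est <- setNames(x$metrics$estimate, x$metrics$metric)
  bind_cols(as_tibble(as.list(est)), tidy(x$counts))
}

#' Crude risk with exact confidence interval
#'
#' Events over participants on the percentage scale.
#'
#' @param events Number of cancers.
#' @param n Number of participants (>= 1).
#' @param ci_level Confidence level.
#' @param ci_method Passed to [binom_ci()].
#' @return One-row tibble: `events`, `n`, `risk_pct`, `conf.low`,
#'   `conf.high` (percent).
#' @export
#' @examples
#' crude_risk(228, 5929)
crude_risk <- function(events, n, ci_level = 0.95,
                       ci_method = c("clopper-pearson", "wilson")) {
  if (n < 1) stop_domain("n must be at least 1")
  if (events > n || events < 0) stop_domain("need 0 <= events <= n")
  ci <- binom_ci(events, n, ci_level, match.arg(ci_method))
  tibble(events = as.integer(events), n = as.integer(n),
         risk_pct = 100 * events / n,
         conf.low = 100 * ci$lower, conf.high = 100 * ci$upper)
}

#' Pearson chi-squared test on a 2x2 table
#'
#' Classical Pearson statistic without continuity correction, compared to
#' the chi-squared distribution with 1 degree of freedom.
#'
#' @param table 2x2 matrix of counts, or a length-4 vector `(a, b, c, d)`
#'   filling the table by column.
#' @return One-row tibble: `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' pearson_chi2(matrix(c(15, 1406, 37, 4772), 2))
pearson_chi2 <- function(table) {
  m <- if (is.matrix(table)) table else matrix(table, 2)
  if (!all(dim(m) == 2) || any(m < 0)) {
    stop_domain("pearson_chi2 needs a 2x2 table of non-negative counts")
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop_domain("chi-squared test undefined: a margin of the table is zero")
  }
  ht <- stats::chisq.test(m, correct = FALSE)
  tibble(statistic = unname(ht$statistic), df = 1L,
         p_value = unname(ht$p.value))
}

#' McNemar's test from discordant counts
#'
#' Paired comparison of two classifiers' sensitivity (or specificity)
#' needs only the discordant pair counts `b` and `c`. The default exact
#' variant is the two-sided binomial test of `b` successes in `b + c`
#' trials at probability one half (small discordant counts are common in
#' these comparisons); the chi-squared variants are the classical
#' large-sample approximations.
#'
#' @param b,c Discordant counts (`b + c >= 1`).
#' @param variant `"exact"` (default), `"chi2"` or
#'   `"chi2_corrected"` (continuity corrected).
#' @return One-row tibble: `b`, `c`, `variant`, `statistic` (`NA` for the
#'   exact variant), `p_value`.
#' @export
#' @examples
#' mcnemar_test(0, 15)
mcnemar_test <- function(b, c, variant = c("exact", "chi2", "chi2_corrected")) {
  variant <- match.arg(variant)
  if (b < 0 || c < 0) stop_domain("discordant counts must be non-negative")
  n <- b + c
  if (n == 0) stop_domain("McNemar test undefined: no discordant pairs")
  if (variant == "exact") {
    p <- min(1, 2 * pbinom(min(b, c), n, 0.5))
    stat <- NA_real_
  } else {
    m <- matrix(c(0, c, b, 0), 2)
    ht <- stats::mcnemar.test(m, correct = variant == "chi2_corrected")
    stat <- unname(ht$statistic)
    p <- unname(ht$p.value)
  }
  tibble(b = as.integer(b), c = as.integer(c), variant = variant,
         statistic = stat, p_value = p)
}

#' Paired discordant counts for two rules
#'
#' Helper producing the `(b, c)` inputs of [mcnemar_test()] for comparing
#' two rules' sensitivity (`among = "cases"`) or specificity
#' (`among = "noncases"`) on the same participants.
#'
#' @param indexed Indexed cohort.
#' @param rule_a,rule_b Rules (see [rule_positive()]).
#' @param among `"cases"` or `"noncases"`.
#' @return Named list `b` (a positive only) and `c` (b positive only).
#' @export
discordant_counts <- function(indexed, rule_a, rule_b,
                              among = c("cases", "noncases")) {
  among <- match.arg(among)
  nod <- indexed |> filter(.data$has_nodule)
  keep <- if (among == "cases") nod$cancer_outcome else !nod$cancer_outcome
  pa <- rule_positive(nod, rule_a)[keep]
  pb <- rule_positive(nod, rule_b)[keep]
  list(b = sum(pa & !pb), c = sum(!pa & pb))
}

#' Univariable logistic odds ratio per unit size
#'
#' Maximum-likelihood logistic fit of outcome on a single size predictor,
#' reporting the odds ratio per `unit_scale` units (e.g. per 10 mm^3 of
#' volume, per 1 mm of diameter). Perfect separation raises an explicit
#' error rather than returning a silently divergent fit.
#'
#' @param data Data frame (rows with `NA` size are dropped).
#' @param size Column with the size values (tidy-eval).
#' @param outcome Column with the binary outcome (default
#'   `cancer_outcome`).
#' @param unit_scale Units per reported odds ratio (default 1).
#' @param ci_level Confidence level for the Wald interval.
#' @return A `size_logistic` object; `tidy()` gives
#'   `(odds_ratio, conf.low, conf.high, p_value, per)`.
#' @export
#' @examples
#' d <- tibble::tibble(x = c(1, 2, 3, 4, 5, 6, 7, 8),
#'                     y = c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE))
#' tidy(size_odds_ratio(d, x, y))
size_odds_ratio <- function(data, size, outcome = cancer_outcome,
                            unit_scale = 1, ci_level = 0.95) {
  x <- dplyr::pull(data, {{ size }}) / unit_scale
  y <- dplyr::pull(data, {{ outcome }})
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- as.logical(y[keep])
  if (length(unique(y)) < 2) {
    stop_domain("both outcome classes must be present")
  }
  fit <- suppressWarnings(glm(y ~ x, family = binomial()))
  eta <- fit$linear.predictors
  separated <- fit$deviance < 1e-6 ||
    min(eta[y]) > max(eta[!y]) + 1e-8 ||
    max(eta[y]) < min(eta[!y]) - 1e-8
  if (separated || !fit$converged) {
    stop_domain("logistic fit did not converge: predictor perfectly separates the outcome classes")
  }
  structure(list(fit = fit, unit_scale = unit_scale, ci_level = ci_level,
                 n = length(y), n_events = sum(y)),
            class = "size_logistic")
}

#' @exportS3Method generics::tidy
tidy.size_logistic <- function(x, ...) {
  est <- coef(x$fit)[["x"]]
  se <- sqrt(vcov(x$fit)["x", "x"])
  z <- qnorm(1 - (1 - x$ci_level) / 2)
  tibble(
    odds_ratio = exp(est),
    conf.low = exp(est - z * se),
    conf.high = exp(est + z * se),
    p_value = 2 * stats::pnorm(-abs(est / se)),
    per = x$unit_scale
  )
}

#' @exportS3Method generics::glance
glance.size_logistic <- function(x, ...) {
  tibble(n = x$n, n_events = x$n_events,
         deviance = x$fit$deviance, aic = x$fit$aic,
         converged = x$fit$converged)
}

#' @export
print.size_logistic <- function(x, ...) {
  t <- tidy(x)
  cat(sprintf("<size_logistic> OR %.4f (%.4f to %.4f) per %g units, p %s (n=%d, events=%d)\n",
              t$odds_ratio, t$conf.low, t$conf.high, t$per,
              fmt_p(t$p_value), x$n, x$n_events))
  invisible(x)
}

#' Malignancy risk among perifissural-nodule participants
#'
#' Crude risk over participants carrying at least one perifissural-typical
#' nodule. `extra_events` adds registry-identified cancers not recorded as
#' outcomes in the cohort (participants diagnosed outside the study whose
#' perifissural nodule is assumed malignant).
#'
#' @param indexed Indexed cohort (carries `any_perifissural`).
#' @param extra_events Additional events (default 0).
#' @param ci_level Confidence level.
#' @return One-row tibble as [crude_risk()].
#' @export
perifissural_risk <- function(indexed, extra_events = 0, ci_level = 0.95) {
  if (extra_events < 0) stop_domain("extra_events must be non-negative")
  peri <- indexed |> filter(.data$has_nodule, .data$any_perifissural)
  crude_risk(sum(peri$cancer_outcome) + extra_events, nrow(peri), ci_level)
}

utils::globalVariables("cancer_outcome")
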