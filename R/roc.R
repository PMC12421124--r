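# Empirical ROC curves, DeLong AUC inference, Youden cut-points.
#
# Higher scores must indicate malignancy. Thresholds sit at the distinct
# observed score values (positive = score >= threshold); tied scores are
# grouped into a single operating point, so ties contribute diagonal
# segments and the trapezoidal area equals the Mann-Whitney statistic
# with ties counted one half.

roc_inputs <- function(data, score, outcome) {
  s <- dplyr::pull(data, {{ score }})
  y <- as.logical(dplyr::pull(data, {{ outcome }}))
  keep <- !is.na(s) & !is.na(y)
  s <- s[keep]; y <- y[keep]
  if (!any(y) || all(y)) {
    stop_domain("ROC undefined: both outcome classes must be present")
  }
  list(score = s, label = y)
}

#' Empirical ROC curve
#'
#' @param data Data frame; rows with missing scores are dropped (e.g.
#'   volume scored on the segmentable subset).
#' @param score Score column (tidy-eval); higher = more suspicious.
#' @param outcome Binary outcome column.
#' @return A `roc_curve` object: a tibble of operating points
#'   `(threshold, sensitivity, specificity, fpr)` from (0,0) to (1,1),
#'   with attributes `auc`, `n_pos`, `n_neg`.
#' @export
#' @examples
#' d <- tibble::tibble(s = c(1, 2, 3, 4), y = c(FALSE, FALSE, TRUE, TRUE))
#' auc(roc_curve(d, s, y))
roc_curve <- function(data, score, outcome) {
  inp <- roc_inputs(data, {{ score }}, {{ outcome }})
  s <- inp$score; y <- inp$label
  n_pos <- sum(y); n_neg <- sum(!y)
  thr <- sort(unique(s), decreasing = TRUE)
  idx <- match(s, thr)
  pos_at <- tabulate(idx[y], nbins = length(thr))
  n_at <- tabulate(idx, nbins = length(thr))
  tp <- cumsum(pos_at)
  fp <- cumsum(n_at - pos_at)
  pts <- tibble(
    threshold = c(Inf, thr),
    sensitivity = c(0, tp / n_pos),
    fpr = c(0, fp / n_neg)
  ) |>
    mutate(specificity = 1 - .data$fpr)
  auc <- sum(diff(pts$fpr) * (head(pts$sensitivity, -1) +
                                pts$sensitivity[-1]) / 2)
  structure(pts, class = c("roc_curve", class(pts)),
            auc = auc, n_pos = n_pos, n_neg = n_neg)
}

#' Area under a ROC curve
#'
#' @param x A `roc_curve`.
#' @return The trapezoidal AUC in `[0, 1]`.
#' @export
auc <- function(x) {
  stopifnot(inherits(x, "roc_curve"))
  attr(x, "auc")
}

#' @exportS3Method generics::tidy
tidy.roc_curve <- function(x, ...) as_tibble(x)

#' @exportS3Method generics::glance
glance.roc_curve <- function(x, ...) {
  tibble(auc = attr(x, "auc"), n_pos = attr(x, "n_pos"),
         n_neg = attr(x, "n_neg"), n_thresholds = nrow(x) - 1L)
}

#' @exportS3Method ggplot2::autoplot
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$fpr, y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("AUC = %.3f", attr(object, "auc"))) +
    ggplot2::theme_minimal()
}

# placement values: V10[i] = mean_j psi(x_pos_i, x_neg_j), ties = 1/2
delong_placements <- function(s, y) {
  pos <- s[y]; neg <- s[!y]
  m <- length(pos); n <- length(neg)
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_pos) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong variance of a single AUC
#'
#' @param data,score,outcome As in [roc_curve()].
#' @return One-row tibble: `auc`, `variance`, `n_pos`, `n_neg`.
#' @export
delong_auc_variance <- function(data, score, outcome) {
  inp <- roc_inputs(data, {{ score }}, {{ outcome }})
  pl <- delong_placements(inp$score, inp$label)
  v <- stats::var(pl$v10) / length(pl$v10) +
    stats::var(pl$v01) / length(pl$v01)
  tibble(auc = pl$auc, variance = v,
         n_pos = length(pl$v10), n_neg = length(pl$v01))
}

#' AUC with confidence interval
#'
#' DeLong normal-approximation interval (default) or percentile
#' bootstrap.
#'
#' @param data,score,outcome As in [roc_curve()].
#' @param ci_level Confidence level.
#' @param method `"delong"` or `"bootstrap"`.
#' @param B Bootstrap resamples (method `"bootstrap"`).
#' @param seed Optional seed for the bootstrap.
#' @return One-row tibble: `auc`, `conf.low`, `conf.high`, `method`.
#' @export
auc_ci <- function(data, score, outcome, ci_level = 0.95,
                   method = c("delong", "bootstrap"), B = 1000,
                   seed = NULL) {
  method <- match.arg(method)
  inp <- roc_inputs(data, {{ score }}, {{ outcome }})
  pl <- delong_placements(inp$score, inp$label)
  if (method == "delong") {
    v <- stats::var(pl$v10) / length(pl$v10) +
      stats::var(pl$v01) / length(pl$v01)
    z <- qnorm(1 - (1 - ci_level) / 2)
    lo <- max(0, pl$auc - z * sqrt(v))
    hi <- min(1, pl$auc + z * sqrt(v))
  } else {
    s <- inp$score; y <- inp$label
    draws <- with_substream(seed, "auc_boot", {
      replicate(B, {
        i <- sample.int(length(s), replace = TRUE)
        if (!any(y[i]) || all(y[i])) NA_real_
        else delong_placements(s[i], y[i])$auc
      })
    })
    qs <- quantile(draws, c((1 - ci_level) / 2, 1 - (1 - ci_level) / 2),
                   na.rm = TRUE, names = FALSE)
    lo <- qs[1]; hi <- qs[2]
  }
  tibble(auc = pl$auc, conf.low = lo, conf.high = hi, method = method)
}

#' DeLong test comparing two paired AUCs
#'
#' Nonparametric comparison of the AUCs of two scores measured on the
#' same participants, via placement-value covariance. Rows missing either
#' score are dropped, so the comparison runs on the common subset (e.g.
#' volume vs diameter restricted to reliably segmented nodules).
#'
#' @param data Data frame.
#' @param score_a,score_b Score columns (tidy-eval).
#' @param outcome Binary outcome column.
#' @return A `delong_test` object; `tidy()` gives `auc_a`, `auc_b`,
#'   `difference`, `var_diff`, `statistic`, `p_value`, `n`.
#' @export
delong_compare <- function(data, score_a, score_b, outcome) {
  sa <- dplyr::pull(data, {{ score_a }})
  sb <- dplyr::pull(data, {{ score_b }})
  y <- as.logical(dplyr::pull(data, {{ outcome }}))
  if (length(sa) != length(sb)) stop_domain("scores must be paired")
  keep <- !is.na(sa) & !is.na(sb) & !is.na(y)
  sa <- sa[keep]; sb <- sb[keep]; y <- y[keep]
  if (!any(y) || all(y)) {
    stop_domain("DeLong test undefined: both outcome classes must be present")
  }
  pa <- delong_placements(sa, y)
  pb <- delong_placements(sb, y)
  m <- sum(y); n <- sum(!y)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  diff <- pa$auc - pb$auc
  if (var_diff <= 0) {
    z <- if (abs(diff) < 1e-12) 0 else sign(diff) * Inf
  } else {
    z <- diff / sqrt(var_diff)
  }
  p <- 2 * stats::pnorm(-abs(z))
  structure(list(auc_a = pa$auc, auc_b = pb$auc, difference = diff,
                 var_a = s10[1, 1] / m + s01[1, 1] / n,
                 var_b = s10[2, 2] / m + s01[2, 2] / n,
                 var_diff = var_diff, statistic = z, p_value = p,
                 n = length(y), n_pos = m, n_neg = n),
            class = "delong_test")
}

#' @exportS3Method generics::tidy
tidy.delong_test <- function(x, ...) {
  tibble(auc_a = x$auc_a, auc_b = x$auc_b, difference = x$difference,
         var_diff = x$var_diff, statistic = x$statistic,
         p_value = x$p_value, n = x$n)
}

#' @export
print.delong_test <- function(x, ...) {
  cat(sprintf("<delong_test> AUC %.4f vs %.4f, diff %.4f, z=%.3f, p=%s (n=%d)\n",
              x$auc_a, x$auc_b, x$difference, x$statistic, fmt_p(x$p_value),
              x$n))
  invisible(x)
}

#' Youden-optimal cut-point
#'
#' The threshold maximising J = sensitivity + specificity - 1 over the
#' ROC operating points. Ties break to the smallest threshold achieving
#' the maximum (favouring sensitivity); thresholds are the raw distinct
#' score values.
#'
#' @param data,score,outcome As in [roc_curve()].
#' @return One-row tibble: `threshold`, `j`, `sensitivity`,
#'   `specificity`.
#' @export
youden_optimal <- function(data, score, outcome) {
  rc <- roc_curve(data, {{ score }}, {{ outcome }})
  pts <- as_tibble(rc) |> filter(is.finite(.data$threshold))
  j <- pts$sensitivity - pts$fpr
  best <- which(j >= max(j) - 1e-12)
  pick <- best[which.min(pts$threshold[best])]
  tibble(threshold = pts$threshold[pick], j = j[pick],
         sensitivity = pts$sensitivity[pick],
         specificity = pts$specificity[pick])
}
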