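# Weighted net-benefit comparison of two stratification rules.

#' Weighted net-benefit point estimate
#'
#' Scalar trade-off when switching from a reference rule to a new rule:
#'
#' `100 * [ (sens_new - sens_ref) + (spec_new - spec_ref) * (1/W) * (1-p)/p ]`
#'
#' where `p` is the cancer prevalence and `W` a weighting factor
#' down-weighting specificity gains (a larger `W` prioritises
#' sensitivity; `W` is interpreted as the number of test positives one
#' accepts per cancer found). Positive values favour the new rule. The
#' result is on the percentage-point scale and is linear in each delta
#' and antisymmetric under swapping the two rules.
#'
#' @param sens_ref,spec_ref,sens_new,spec_new Fractions in `[0, 1]`.
#' @param prevalence Cancer prevalence `p`, strictly inside (0, 1).
#' @param weight Weighting factor `W > 0` (typical choices: 50 for a
#'   rule-out comparison, 5 for a rule-in comparison, reflecting a
#'   screening programme with around 2% cancer prevalence).
#' @return Numeric scalar (percentage points).
#' @export
#' @examples
#' net_benefit_point(0.776, 0.706, 0.654, 0.942, prevalence = 0.0385,
#'                   weight = 5)
net_benefit_point <- function(sens_ref, spec_ref, sens_new, spec_new,
                              prevalence, weight) {
  fracs <- c(sens_ref, spec_ref, sens_new, spec_new)
  if (any(fracs < 0 | fracs > 1)) {
    stop_domain("sensitivities and specificities must be fractions in [0, 1]")
  }
  if (any(prevalence <= 0 | prevalence >= 1)) {
    stop_domain("prevalence must lie strictly inside (0, 1)")
  }
  if (any(weight <= 0)) stop_domain("weight must be positive")
  100 * ((sens_new - sens_ref) +
           (spec_new - spec_ref) * (1 / weight) * (1 - prevalence) / prevalence)
}

sens_spec_of <- function(pos, out) {
  c(sens = sum(pos & out) / sum(out),
    spec = sum(!pos & !out) / sum(!out))
}

#' Bootstrap net benefit of switching rules
#'
#' Point estimate and percentile bootstrap confidence interval of the
#' weighted net benefit comparing `rule_new` to `rule_ref`. Resampling is
#' at participant level, matching the per-participant analysis unit;
#' sensitivity and specificity are evaluated among nodule participants of
#' each resample. A resample without cancers (or without benign nodule
#' participants) cannot yield the statistic and is redrawn; the number of
#' redraws is reported.
#'
#' The prevalence entering the weighting term must be chosen explicitly:
#' `"nodule_participants"` (cancers / nodule participants),
#' `"whole_cohort"` (cancers / all participants supplied, including
#' no-nodule rows), `"size_eligible"` (prevalence among participants
#' positive under the reference rule), or `"fixed_value"` with
#' `prevalence_fixed`.
#'
#' @param indexed Indexed cohort from [reduce_to_index()].
#' @param rule_ref,rule_new Rules (see [rule_positive()]).
#' @param weight Weighting factor `W > 0`.
#' @param prevalence_source One of `"nodule_participants"`,
#'   `"whole_cohort"`, `"size_eligible"`, `"fixed_value"`.
#' @param prevalence_fixed Prevalence when `prevalence_source =
#'   "fixed_value"`.
#' @param B Bootstrap resamples (default 1000).
#' @param seed Optional integer seed; fixed seed gives identical CIs.
#' @param ci_level Confidence level (default 0.95).
#' @return A `net_benefit` object; `tidy()` gives the point estimate,
#'   CI, prevalence used, `W`, `B` and redraw count.
#' @export
bootstrap_net_benefit <- function(indexed, rule_ref, rule_new, weight,
                                  prevalence_source = c(
                                    "nodule_participants", "whole_cohort",
                                    "size_eligible", "fixed_value"),
                                  prevalence_fixed = NULL, B = 1000,
                                  seed = NULL, ci_level = 0.95) {
  prevalence_source <- match.arg(prevalence_source)
  if (prevalence_source == "fixed_value" &&
      (is.null(prevalence_fixed) || prevalence_fixed <= 0 ||
         prevalence_fixed >= 1)) {
    stop_domain("prevalence_source = 'fixed_value' needs prevalence_fixed in (0, 1)")
  }
  has <- indexed$has_nodule
  out_all <- indexed$cancer_outcome
  pos_ref <- rule_positive(indexed, rule_ref)
  pos_new <- rule_positive(indexed, rule_new)
  if (!any(out_all[has]) || all(out_all[has])) {
    stop_domain("cohort must contain both outcomes among nodule participants")
  }

  eval_nb <- function(i) {
    h <- has[i]; o <- out_all[i]
    if (!any(o[h]) || all(o[h])) return(NA_real_)
    ss_ref <- sens_spec_of(pos_ref[i][h], o[h])
    ss_new <- sens_spec_of(pos_new[i][h], o[h])
    p <- switch(prevalence_source,
      nodule_participants = mean(o[h]),
      whole_cohort = mean(o),
      size_eligible = {
        el <- pos_ref[i]
        if (!any(el)) return(NA_real_)
        mean(o[el])
      },
      fixed_value = prevalence_fixed)
    if (p <= 0 || p >= 1) return(NA_real_)
    unname(net_benefit_point(ss_ref[["sens"]], ss_ref[["spec"]],
                             ss_new[["sens"]], ss_new[["spec"]], p, weight))
  }

  n <- nrow(indexed)
  point <- eval_nb(seq_len(n))
  if (is.na(point)) {
    stop_domain("net benefit undefined on the full cohort under prevalence_source '%s'",
                prevalence_source)
  }
  redraws <- 0L
  draws <- with_substream(seed, "net_benefit", {
    vapply(seq_len(B), function(b) {
      repeat {
        v <- eval_nb(sample.int(n, replace = TRUE))
        if (!is.na(v)) return(v)
        redraws <<- redraws + 1L
        if (redraws > 100L * B) {
          stop_domain("bootstrap resamples keep missing an outcome class; cohort too small")
        }
      }
    }, numeric(1))
  })
  a <- (1 - ci_level) / 2
  ci <- quantile(draws, c(a, 1 - a), names = FALSE)
  structure(list(point = point, conf.low = ci[1], conf.high = ci[2],
                 draws = draws, B = B, seed = seed, weight = weight,
                 prevalence_source = prevalence_source,
                 prevalence_fixed = prevalence_fixed,
                 n_redraws = redraws, ci_level = ci_level,
                 n = n),
            class = "net_benefit")
}

#' @exportS3Method generics::tidy
tidy.net_benefit <- function(x, ...) {
  tibble(estimate = x$point, conf.low = x$conf.low, conf.high = x$conf.high,
         weight = x$weight, prevalence_source = x$prevalence_source,
         n_bootstrap = x$B, n_redraws = x$n_redraws, n = x$n)
}

#' @exportS3Method generics::glance
glance.net_benefit <- function(x, ...) tidy(x)

#' @export
print.net_benefit <- function(x, ...) {
  cat(sprintf("<net_benefit> %+0.2f (%.0f%% CI %+0.2f to %+0.2f) [W=%g, p from %s, B=%d]\n",
              x$point, 100 * x$ci_level, x$conf.low, x$conf.high,
              x$weight, x$prevalence_source, x$B))
  if (x$n_redraws > 0) {
    cat(sprintf("  %d resample(s) redrawn for missing outcome classes\n",
                x$n_redraws))
  }
  invisible(x)
}

#' @exportS3Method ggplot2::autoplot
autoplot.net_benefit <- function(object, ...) {
  ggplot2::ggplot(tibble(nb = object$draws), ggplot2::aes(x = .data$nb)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$point, linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = c(object$conf.low, object$conf.high),
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 0, colour = "red", linetype = "dotted") +
    ggplot2::labs(x = "Net benefit (percentage points)", y = "Resamples") +
    ggplot2::theme_minimal()
}
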