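# Baseline management classification and threshold 2x2 tables.

#' A size threshold rule
#'
#' Describes a binary stratification rule: positive when the index
#' nodule's size meets the threshold (`direction = "ge"`, the rule-in
#' convention) or lies strictly below it (`"lt"`, the rule-out
#' convention), optionally additionally gated on the Brock probability.
#' On the volume scale an index nodule without a reliable volume is
#' assessed through the sphere-equivalent volume of its diameter.
#'
#' @param threshold Cut-off value (mm^3 for `scale = "volume"`, mm for
#'   `"diameter"`).
#' @param scale `"volume"` or `"diameter"`.
#' @param direction `"ge"` (default; positive = at/above) or `"lt"`.
#' @param brock_threshold Optional Brock gate; positive then additionally
#'   requires `brock_probability >= brock_threshold`.
#' @return A `threshold_rule` object.
#' @export
#' @examples
#' threshold_rule(300, "volume")
#' threshold_rule(8, "diameter", brock_threshold = 0.10)
threshold_rule <- function(threshold, scale = c("volume", "diameter"),
                           direction = c("ge", "lt"),
                           brock_threshold = NULL) {
  scale <- match.arg(scale)
  direction <- match.arg(direction)
  stopifnot(is.numeric(threshold), length(threshold) == 1, threshold > 0)
  structure(list(threshold = threshold, scale = scale,
                 direction = direction, brock_threshold = brock_threshold),
            class = "threshold_rule")
}

#' @export
print.threshold_rule <- function(x, ...) {
  cat(sprintf("<threshold_rule> %s %s %g %s%s\n",
              x$scale, if (x$direction == "ge") ">=" else "<", x$threshold,
              if (x$scale == "volume") "mm^3" else "mm",
              if (!is.null(x$brock_threshold))
                sprintf(" & Brock >= %g", x$brock_threshold) else ""))
  invisible(x)
}

rule_size_value <- function(indexed, scale) {
  if (scale == "volume") {
    ifelse(isTRUE_v(indexed$segmentation_reliable), indexed$volume_mm3,
           sphere_volume(indexed$diameter_mm))
  } else {
    indexed$diameter_mm
  }
}

#' Evaluate a rule on an indexed cohort
#'
#' @param indexed Indexed cohort from [reduce_to_index()].
#' @param rule A [threshold_rule()] or [protocol_config()] (for a
#'   protocol, positive means MDT referral under [classify_baseline()]).
#' @return Logical vector, one element per row (`FALSE` for participants
#'   without a nodule).
#' @export
rule_positive <- function(indexed, rule) {
  if (inherits(rule, "protocol_config")) {
    return(classify_baseline(indexed, rule)$action == "mdt_referral")
  }
  stopifnot(inherits(rule, "threshold_rule"))
  v <- rule_size_value(indexed, rule$scale)
  pos <- if (rule$direction == "ge") v >= rule$threshold else v < rule$threshold
  pos[!indexed$has_nodule] <- FALSE
  if (!is.null(rule$brock_threshold)) {
    if (!"brock_probability" %in% names(indexed) ||
        any(indexed$has_nodule & pos & is.na(indexed$brock_probability))) {
      stop_domain("rule has a Brock gate but brock_probability is missing for size-positive participants; run brock_probability() first")
    }
    pos <- pos & brock_gate(indexed$brock_probability, rule$brock_threshold)
    pos[is.na(pos)] <- FALSE
  }
  pos
}

#' Classify baseline management actions
#'
#' Applies a nodule management protocol to each indexed participant:
#' no nodule or rule-out-sized gives routine recall to the next screening
#' round; rule-in-sized with Brock probability at/above the protocol gate
#' gives MDT referral, below it a 3-month interval CT; intermediate sizes
#' give a 3-month interval CT. Size is resolved by [assess_size()]
#' (volumetric with diameter fallback, or diameter-primary). The `reason`
#' column traces every rule fired so each decision can be audited.
#'
#' @param indexed Indexed cohort from [reduce_to_index()].
#' @param protocol A [protocol_config()].
#' @param brock Optional vector of Brock probabilities; defaults to the
#'   cohort's `brock_probability` column. Required (non-`NA`) for
#'   rule-in-sized nodules when the protocol carries a Brock gate.
#' @return `indexed` with `action` (`routine_recall`,
#'   `interval_ct_3month`, `mdt_referral`) and `reason` columns.
#' @export
classify_baseline <- function(indexed, protocol, brock = NULL) {
  stopifnot(inherits(protocol, "protocol_config"))
  a <- assess_size(indexed, protocol)
  brock <- brock %||% a$brock_probability %||% rep(NA_real_, nrow(a))
  gate_on <- !is.na(protocol$brock_threshold)
  needs_brock <- isTRUE_v(a$rule_in_pass) & gate_on
  if (any(needs_brock & is.na(brock))) {
    stop_domain("protocol has a Brock gate (>=%g) but %d rule-in-sized participant(s) have no Brock probability",
                protocol$brock_threshold, sum(needs_brock & is.na(brock)))
  }
  gated <- if (gate_on) {
    needs_brock & brock_gate(brock, protocol$brock_threshold) %in% TRUE
  } else {
    rep(FALSE, nrow(a))
  }

  action <- rep("routine_recall", nrow(a))
  reason <- rep("no solid nodule -> routine_recall", nrow(a))
  has <- a$has_nodule

  sz <- function(i) sprintf("%s %g %s", a$size_mode[i], a$size_value[i],
                            a$size_unit[i])
  ro <- which(has & a$rule_out_pass)
  action[ro] <- "routine_recall"
  reason[ro] <- sprintf("%s below rule-out cut-off -> routine_recall", sz(ro))

  mid <- which(has & !a$rule_out_pass & !a$rule_in_pass)
  action[mid] <- "interval_ct_3month"
  reason[mid] <- sprintf("%s intermediate -> interval_ct_3month", sz(mid))

  ri <- which(has & a$rule_in_pass)
  if (gate_on) {
    hi <- ri[gated[ri]]
    lo <- setdiff(ri, hi)
    action[hi] <- "mdt_referral"
    reason[hi] <- sprintf("%s rule-in; Brock %.4f >= %g -> mdt_referral",
                          sz(hi), brock[hi], protocol$brock_threshold)
    action[lo] <- "interval_ct_3month"
    reason[lo] <- sprintf("%s rule-in; Brock %.4f < %g -> interval_ct_3month",
                          sz(lo), brock[lo], protocol$brock_threshold)
  } else {
    action[ri] <- "mdt_referral"
    reason[ri] <- sprintf("%s rule-in; no Brock gate -> mdt_referral", sz(ri))
  }
  indexed$action <- action
  indexed$reason <- reason
  indexed
}

#' 2x2 threshold counts
#'
#' @param tp,fp,fn,tn Non-negative integer counts (positive = meets the
#'   rule / is referred; condition = malignant).
#' @return A `threshold_counts` object.
#' @export
#' @examples
#' threshold_counts(tp = 198, fp = 1975, fn = 30, tn = 3726)
threshold_counts <- function(tp, fp, fn, tn) {
  v <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(is.na(v)) || any(v < 0) || any(v != round(v))) {
    stop_domain("tp, fp, fn, tn must be non-negative integers")
  }
  structure(as.list(setNames(as.integer(v), names(v))),
            class = "threshold_counts")
}

#' @export
print.threshold_counts <- function(x, ...) {
  cat(sprintf("<threshold_counts> tp=%d fp=%d fn=%d tn=%d (n=%d)\n",
              x$tp, x$fp, x$fn, x$tn, x$tp + x$fp + x$fn + x$tn))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.threshold_counts <- function(x, ...) {
  tibble(tp = x$tp, fp = x$fp, fn = x$fn, tn = x$tn)
}

#' Stratify an indexed cohort against a rule
#'
#' Cross-tabulates rule positivity against malignancy outcome at the
#' participant level. By default the denominator is participants with at
#' least one solid nodule (the convention of published threshold tables,
#' where specificity is computed among benign nodule participants);
#' `population = "all"` includes no-nodule participants as rule-negative.
#'
#' @param indexed Indexed cohort from [reduce_to_index()].
#' @param rule A [threshold_rule()] or [protocol_config()].
#' @param population `"nodule_participants"` (default) or `"all"`.
#' @return A [threshold_counts()] object.
#' @export
stratify <- function(indexed, rule,
                     population = c("nodule_participants", "all")) {
  population <- match.arg(population)
  if (population == "nodule_participants") {
    indexed <- indexed |> filter(.data$has_nodule)
  }
  pos <- rule_positive(indexed, rule)
  out <- indexed$cancer_outcome
  threshold_counts(tp = sum(pos & out), fp = sum(pos & !out),
                   fn = sum(!pos & out), tn = sum(!pos & !out))
}
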