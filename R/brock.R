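# Brock (PanCan) malignancy probability for solid nodules.

#' Brock model coefficients (full model, with spiculation)
#'
#' Coefficients of the published Brock (PanCan) logistic model for the
#' probability that a screen-detected nodule is malignant, as transcribed
#' from the model's original publication: full model with spiculation.
#' This package is solid-nodule only, so the part-solid / non-solid type
#' terms do not apply (solid is the reference level).
#'
#' The linear predictor is
#' `intercept + age*(age_years-62) + sex_female*[female] + family_history
#'  + emphysema + upper_lobe + spiculation + count*(nodule_count-4)
#'  + size*((size_mm/10)^(-1/2) - 1.58113883)`
#' where the size term is the published non-linear transform (centred at
#' its value for a 4 mm nodule) and bracketed terms are 0/1 indicators.
#'
#' @return A `brock_coefficients` object (named list).
#' @export
#' @examples
#' brock_coefficients()
brock_coefficients <- function() {
  structure(list(
    intercept        = -6.7892,
    age              = 0.0287,    # per year, centred at 62
    sex_female       = 0.6011,
    family_history   = 0.2961,
    emphysema        = 0.2953,
    size             = -5.3854,   # on (size/10)^(-1/2), centred
    size_center      = 1.58113883,
    upper_lobe       = 0.6581,
    nodule_count     = -0.0824,   # per nodule, centred at 4
    spiculation      = 0.7729,
    variant          = "full_with_spiculation"
  ), class = "brock_coefficients")
}

brock_linear_predictor <- function(age_years, female, family_history,
                                   emphysema, size_mm, upper_lobe,
                                   nodule_count, spiculated,
                                   coef = brock_coefficients()) {
  if (any(size_mm <= 0, na.rm = TRUE)) {
    stop_domain("size_mm must be strictly positive for the Brock model")
  }
  if (any(nodule_count < 1, na.rm = TRUE)) {
    stop_domain("nodule_count must be at least 1")
  }
  coef$intercept +
    coef$age * (age_years - 62) +
    coef$sex_female * as.numeric(female) +
    coef$family_history * as.numeric(family_history) +
    coef$emphysema * as.numeric(emphysema) +
    coef$upper_lobe * as.numeric(upper_lobe) +
    coef$spiculation * as.numeric(spiculated) +
    coef$nodule_count * (nodule_count - 4) +
    coef$size * ((size_mm / 10)^(-0.5) - coef$size_center)
}

#' Brock malignancy probability
#'
#' Adds a `brock_probability` column: the inverse-logit of the Brock
#' linear predictor evaluated on the index nodule. The size entering the
#' model is the long-axis diameter (the sizing this kind of cohort
#' records) by default, even when gating a volume-defined nodule; set
#' `size = "sphere_equivalent"` to use the diameter of a sphere with the
#' nodule's volume instead (falls back to the measured diameter where
#' volume is absent).
#'
#' The probability is strictly increasing in nodule size and strictly
#' higher under spiculation, emphysema, family history, female sex and
#' upper-lobe location, per the published model.
#'
#' @param data Indexed cohort (from [reduce_to_index()]), or any tibble
#'   with columns `age_years`, `sex`, `family_history`, `emphysema`,
#'   `diameter_mm`, `upper_lobe`, `spiculated` and optionally `n_nodules`
#'   (assumed 1 when missing).
#' @param coefficients A [brock_coefficients()] object.
#' @param size `"diameter"` (default) or `"sphere_equivalent"`.
#' @param overwrite Recompute even where a `brock_probability` column is
#'   already populated (default `TRUE`).
#' @return `data` with a `brock_probability` column in (0, 1); rows
#'   without a nodule get `NA`.
#' @export
brock_probability <- function(data, coefficients = brock_coefficients(),
                              size = c("diameter", "sphere_equivalent"),
                              overwrite = TRUE) {
  size <- match.arg(size)
  has <- !is.na(data$diameter_mm)
  size_mm <- data$diameter_mm
  if (size == "sphere_equivalent" && "volume_mm3" %in% names(data)) {
    size_mm <- ifelse(is.na(data$volume_mm3), size_mm,
                      sphere_diameter(data$volume_mm3))
  }
  count <- if ("n_nodules" %in% names(data)) pmax(data$n_nodules, 1) else 1
  lp <- rep(NA_real_, nrow(data))
  if (any(has)) {
    lp[has] <- brock_linear_predictor(
      age_years = data$age_years[has],
      female = data$sex[has] == "female",
      family_history = isTRUE_v(data$family_history[has]),
      emphysema = isTRUE_v(data$emphysema[has]),
      size_mm = size_mm[has],
      upper_lobe = isTRUE_v(data$upper_lobe[has]),
      nodule_count = if (length(count) == 1) count else count[has],
      spiculated = isTRUE_v(data$spiculated[has]),
      coef = coefficients
    )
  }
  prob <- plogis(lp)
  if (!overwrite && "brock_probability" %in% names(data)) {
    data$brock_probability <- ifelse(is.na(data$brock_probability),
                                     prob, data$brock_probability)
  } else {
    data$brock_probability <- prob
  }
  data
}

#' Apply the Brock referral gate
#'
#' `TRUE` iff the probability meets the threshold (inclusive: a score of
#' exactly 10% is referred under the usual 10% gate). Probabilities are
#' compared at full precision; nothing is rounded before gating.
#'
#' @param prob Brock probabilities.
#' @param threshold Gate (default 0.10). The mathematically "optimal"
#'   alternatives reported for such cohorts (e.g. 0.09905) are supported
#'   by passing them here.
#' @return Logical vector (`NA` where `prob` is `NA`).
#' @export
#' @examples
#' brock_gate(c(0.0999, 0.10, 0.12))
brock_gate <- function(prob, threshold = 0.10) {
  stopifnot(is.numeric(threshold), length(threshold) == 1, threshold >= 0)
  prob >= threshold
}
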