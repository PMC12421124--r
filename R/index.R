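# Per-participant reduction and effective-size assessment.

#' Reduce a cohort to one index nodule per participant
#'
#' Every analysis in this package is per participant. A participant with
#' several solid nodules is represented by the malignant one when present,
#' otherwise by the largest. Benign retronodules (nodules only recognised
#' retrospectively) are never selected as index, since participants were
#' stratified by their largest *reported* nodule; malignant retronodules
#' participate fully.
#'
#' "Largest" is resolved on the scale named by `size_key`; ties break by
#' the other scale, then by lexicographically smallest `nodule_id`, so the
#' reduction is deterministic. Nodules without a volume sort below any
#' nodule with one on the volume scale.
#'
#' @param cohort Cohort tibble from [as_cohort()] / [read_cohort()] /
#'   [generate_cohort()].
#' @param size_key `"volume"` (default) or `"diameter"`.
#' @return Tibble with one row per participant: participant columns,
#'   `has_nodule`, `n_nodules` (reported, non-retronodule), the index
#'   nodule's fields, and `any_perifissural` (any perifissural-typical
#'   nodule among the participant's reported nodules).
#' @export
#' @examples
#' coh <- generate_cohort(generator_params(n_participants = 50, seed = 1))
#' reduce_to_index(coh)
reduce_to_index <- function(cohort, size_key = c("volume", "diameter")) {
  size_key <- match.arg(size_key)
  flat <- flatten_cohort(cohort)
  has <- !is.na(flat$nodule_id) | !is.na(flat$diameter_mm)
  nods <- flat[has, , drop = FALSE]

  n_mal <- tapply(nods$malignant, nods$participant_id, sum)
  if (any(n_mal > 1)) {
    stop_domain("participant %s has more than one malignant nodule",
                names(n_mal)[which(n_mal > 1)[1]])
  }

  # candidates for index selection: malignant always; benign only if reported
  cand <- nods |>
    filter(.data$malignant | !.data$retronodule) |>
    mutate(
      .vol = ifelse(is.na(.data$volume_mm3), -Inf, .data$volume_mm3),
      .dia = ifelse(is.na(.data$diameter_mm), -Inf, .data$diameter_mm)
    )
  if (size_key == "volume") {
    cand <- arrange(cand, .data$participant_id, !.data$malignant,
                    desc(.data$.vol), desc(.data$.dia), .data$nodule_id)
  } else {
    cand <- arrange(cand, .data$participant_id, !.data$malignant,
                    desc(.data$.dia), desc(.data$.vol), .data$nodule_id)
  }
  idx <- cand |>
    group_by(.data$participant_id) |>
    slice(1) |>
    ungroup() |>
    select(-"age_years", -"sex", -"family_history", -"emphysema",
           -"cancer_outcome", -".vol", -".dia")

  extras <- nods |>
    group_by(.data$participant_id) |>
    summarise(
      n_nodules = sum(!.data$retronodule),
      any_perifissural = any(.data$perifissural & !.data$retronodule,
                             na.rm = TRUE),
      .groups = "drop"
    )

  out <- cohort |>
    as_tibble() |>
    select(all_of(PARTICIPANT_COLS)) |>
    left_join(idx, by = "participant_id") |>
    left_join(extras, by = "participant_id") |>
    mutate(
      has_nodule = !is.na(.data$nodule_id),
      n_nodules = ifelse(is.na(.data$n_nodules), 0L, .data$n_nodules),
      any_perifissural = isTRUE_v(.data$any_perifissural)
    ) |>
    relocate("has_nodule", .after = "cancer_outcome")
  class(out) <- c("indexed_cohort", class(out))
  out
}

#' Assess nodule size against protocol cut-offs
#'
#' Resolves which size scale applies to each nodule under a protocol and
#' tests the rule-out and rule-in cut-offs. Under a volumetric protocol a
#' nodule with reliable segmentation is assessed on volume; an
#' unsegmentable nodule falls back to the protocol's fallback diameter
#' cut-offs. A diameter protocol always assesses diameter. Rule-out is
#' strict (`< cut-off`), rule-in inclusive (`>= cut-off`); a size exactly
#' at the rule-out cut-off therefore fails rule-out.
#'
#' @param data Tibble with columns `volume_mm3`, `diameter_mm`,
#'   `segmentation_reliable` (e.g. an indexed cohort, or an unnested
#'   nodule table). Rows without a nodule get `NA` assessments.
#' @param protocol A [protocol_config()].
#' @return `data` with columns `size_mode` (`"volumetric"` or
#'   `"diameter_fallback"` or `"diameter"`), `size_value`, `size_unit`,
#'   `rule_out_pass`, `rule_in_pass`.
#' @export
assess_size <- function(data, protocol) {
  stopifnot(inherits(protocol, "protocol_config"))
  has <- !is.na(data$diameter_mm)
  if (protocol$mode == "volumetric") {
    reliable <- isTRUE_v(data$segmentation_reliable)
    mode <- ifelse(reliable, "volumetric", "diameter_fallback")
    value <- ifelse(reliable, data$volume_mm3, data$diameter_mm)
    unit <- ifelse(reliable, "mm3", "mm")
    out_cut <- ifelse(reliable, protocol$rule_out_volume_mm3,
                      protocol$fallback_rule_out_diameter_mm)
    in_cut <- ifelse(reliable, protocol$rule_in_volume_mm3,
                     protocol$fallback_rule_in_diameter_mm)
  } else {
    mode <- rep("diameter", nrow(data))
    value <- data$diameter_mm
    unit <- rep("mm", nrow(data))
    out_cut <- rep(protocol$rule_out_diameter_mm, nrow(data))
    in_cut <- rep(protocol$rule_in_diameter_mm, nrow(data))
  }
  data$size_mode <- ifelse(has, mode, NA_character_)
  data$size_value <- ifelse(has, value, NA_real_)
  data$size_unit <- ifelse(has, unit, NA_character_)
  data$rule_out_pass <- ifelse(has, value < out_cut, NA)
  data$rule_in_pass <- ifelse(has, value >= in_cut, NA)
  data
}
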