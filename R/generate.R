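# Synthetic screening-cohort generator.
#
# Emulates the statistical structure the downstream analyses assume: a
# baseline LDCT screening population of which roughly half carry at least
# one solid nodule, a few percent of nodule participants prove malignant,
# nodule volumes are log-normal with a heavier right tail in the malignant
# class, diameters follow volume through the sphere relation with
# multiplicative noise, and a small fraction of nodules cannot be
# segmented reliably.

#' Parameters of the synthetic cohort generator
#'
#' Defaults emulate a large UK baseline LDCT screening cohort: 11 355
#' participants, 52.2% with at least one solid nodule, malignancy risk
#' 3.85% among nodule participants and 0.77% among participants with no
#' nodules, and a 2.1% segmentation-failure rate. The class-conditional
#' log-volume parameters are solved from that cohort's cumulative size
#' distribution (benign: 65.4% below 80 mm^3, 93.7% below 300 mm^3;
#' malignant: 13.2% and 33.3%), giving meanlog 3.92 / sdlog 1.16 for
#' benign and 6.53 / 1.92 for malignant nodules.
#'
#' @param n_participants Number of participants.
#' @param p_any_nodule Probability a participant has >=1 solid nodule.
#' @param p_cancer_given_nodule,p_cancer_no_nodule Malignancy
#'   probabilities conditional on nodule status.
#' @param log_volume_mean,log_volume_sd Benign log-volume (mm^3) location
#'   and scale.
#' @param cancer_log_volume_mean,cancer_log_volume_sd Malignant log-volume
#'   location and scale.
#' @param volume_to_diameter_noise_sd SD of the multiplicative log-normal
#'   noise linking diameter to the sphere-equivalent diameter of the
#'   volume (captures non-sphericity of real nodules).
#' @param p_segmentation_failure Per-nodule probability that volumetry is
#'   unreliable (such nodules carry a diameter only).
#' @param mean_extra_nodules Poisson mean of additional benign nodules per
#'   nodule participant (so nodule count is 1 + Poisson).
#' @param covariate_prevalences Named list of baseline prevalences:
#'   `male`, `family_history`, `emphysema` (participant level);
#'   `upper_lobe`, `spiculated`, `perifissural` (nodule level).
#' @param cancer_odds_multipliers Named list of odds multipliers applied
#'   to covariate prevalences for malignant nodules / their hosts
#'   (`spiculated`, `emphysema`, `upper_lobe`, `family_history`), so Brock
#'   gating separates classes. Malignant nodules are never flagged
#'   perifissural-typical by the generator.
#' @param age_range Uniform age range in years.
#' @param seed Integer seed; every random draw stream is derived from it.
#' @return A `generator_params` object (validated list).
#' @export
generator_params <- function(n_participants = 11355,
                             p_any_nodule = 0.522,
                             p_cancer_given_nodule = 0.0385,
                             p_cancer_no_nodule = 0.0077,
                             log_volume_mean = 3.92,
                             log_volume_sd = 1.16,
                             cancer_log_volume_mean = 6.53,
                             cancer_log_volume_sd = 1.92,
                             volume_to_diameter_noise_sd = 0.12,
                             p_segmentation_failure = 0.021,
                             mean_extra_nodules = 0.3,
                             covariate_prevalences = list(
                               male = 0.577, family_history = 0.15,
                               emphysema = 0.30, upper_lobe = 0.45,
                               spiculated = 0.05, perifissural = 0.40),
                             cancer_odds_multipliers = list(
                               spiculated = 8, emphysema = 1.8,
                               upper_lobe = 2, family_history = 1.3),
                             age_range = c(55, 77),
                             seed = 1L) {
  p <- list(n_participants = n_participants, p_any_nodule = p_any_nodule,
            p_cancer_given_nodule = p_cancer_given_nodule,
            p_cancer_no_nodule = p_cancer_no_nodule,
            log_volume_mean = log_volume_mean, log_volume_sd = log_volume_sd,
            cancer_log_volume_mean = cancer_log_volume_mean,
            cancer_log_volume_sd = cancer_log_volume_sd,
            volume_to_diameter_noise_sd = volume_to_diameter_noise_sd,
            p_segmentation_failure = p_segmentation_failure,
            mean_extra_nodules = mean_extra_nodules,
            covariate_prevalences = covariate_prevalences,
            cancer_odds_multipliers = cancer_odds_multipliers,
            age_range = age_range, seed = seed)
  probs <- c(p_any_nodule, p_cancer_given_nodule, p_cancer_no_nodule,
             p_segmentation_failure, unlist(covariate_prevalences))
  if (any(probs < 0 | probs > 1)) {
    stop_domain("all probabilities must lie in [0, 1]")
  }
  sds <- c(log_volume_sd, cancer_log_volume_sd, volume_to_diameter_noise_sd)
  if (any(sds < 0)) stop_domain("sd parameters must be non-negative")
  if (n_participants < 0 || n_participants != round(n_participants)) {
    stop_domain("n_participants must be a non-negative integer")
  }
  structure(p, class = "generator_params")
}

# prevalence shifted by an odds multiplier
shift_odds <- function(p, mult) {
  o <- p / (1 - p) * mult
  o / (1 + o)
}

bern <- function(n, p) runif(n) < p

#' Generate a synthetic screening cohort
#'
#' Draws a cohort under [generator_params()]. Reproducible: a fixed seed
#' yields a byte-identical cohort; every draw uses its own sub-stream
#' derived from the seed, so changing one component of the generator does
#' not perturb the others.
#'
#' Malignant participants with nodules carry exactly one malignant nodule
#' drawn from the malignant size distribution (plus possible benign
#' extras), preserving the one participant : one nodule : one cancer
#' accounting. Diameter is `(6 volume / pi)^(1/3)` times log-normal noise.
#' Unsegmentable nodules keep their diameter and lose the volume.
#'
#' @param params A [generator_params()] object.
#' @return A cohort tibble (see [as_cohort()]); zero participants gives an
#'   empty cohort.
#' @export
#' @examples
#' coh <- generate_cohort(generator_params(n_participants = 200, seed = 7))
#' mean(purrr::map_int(coh$nodules, nrow) > 0)
generate_cohort <- function(params = generator_params()) {
  stopifnot(inherits(params, "generator_params"))
  n <- params$n_participants
  seed <- params$seed
  cv <- params$covariate_prevalences
  om <- params$cancer_odds_multipliers

  if (n == 0) {
    return(as_cohort(cbind(
      tibble(participant_id = character(), age_years = double(),
             sex = character(), family_history = logical(),
             emphysema = logical(), cancer_outcome = logical()),
      empty_nodule_tbl()
    ), validate = FALSE))
  }

  id <- sprintf("S%06d", seq_len(n))
  has_nodule <- with_substream(seed, "has_nodule", bern(n, params$p_any_nodule))
  cancer <- with_substream(
    seed, "cancer",
    bern(n, ifelse(has_nodule, params$p_cancer_given_nodule,
                   params$p_cancer_no_nodule)))
  age <- with_substream(
    seed, "age", runif(n, params$age_range[1], params$age_range[2]))
  male <- with_substream(seed, "sex", bern(n, cv$male))
  fhx <- with_substream(
    seed, "family_history",
    bern(n, ifelse(cancer, shift_odds(cv$family_history, om$family_history),
                   cv$family_history)))
  emph <- with_substream(
    seed, "emphysema",
    bern(n, ifelse(cancer & has_nodule,
                   shift_odds(cv$emphysema, om$emphysema), cv$emphysema)))

  participants <- tibble(
    participant_id = id, age_years = round(age, 1),
    sex = ifelse(male, "male", "female"),
    family_history = fhx, emphysema = emph,
    cancer_outcome = cancer
  )

  nod_host <- which(has_nodule)
  n_extra <- with_substream(
    seed, "n_extra", rpois(length(nod_host), params$mean_extra_nodules))
  host_cancer <- cancer[nod_host]
  # one primary nodule per host (malignant for cancer hosts) + benign extras
  n_per <- 1L + n_extra
  host_of <- rep(nod_host, n_per)
  is_primary <- unlist(lapply(n_per, function(k) c(TRUE, rep(FALSE, k - 1L))))
  malignant <- is_primary & cancer[host_of]
  m <- length(host_of)

  logvol <- with_substream(seed, "volume", {
    lv <- rnorm(m, params$log_volume_mean, params$log_volume_sd)
    mal <- which(malignant)
    lv[mal] <- rnorm(length(mal), params$cancer_log_volume_mean,
                     params$cancer_log_volume_sd)
    lv
  })
  volume <- exp(logvol)
  diameter <- with_substream(
    seed, "diameter",
    sphere_diameter(volume) *
      exp(rnorm(m, 0, params$volume_to_diameter_noise_sd)))
  seg_fail <- with_substream(
    seed, "segmentation", bern(m, params$p_segmentation_failure))
  upper <- with_substream(
    seed, "upper_lobe",
    bern(m, ifelse(malignant, shift_odds(cv$upper_lobe, om$upper_lobe),
                   cv$upper_lobe)))
  spic <- with_substream(
    seed, "spiculated",
    bern(m, ifelse(malignant, shift_odds(cv$spiculated, om$spiculated),
                   cv$spiculated)))
  perifissural <- with_substream(
    seed, "perifissural", bern(m, cv$perifissural) & !malignant)

  nodules <- tibble(
    participant_id = id[host_of],
    nodule_id = paste0(id[host_of], "-N",
                       unlist(lapply(n_per, seq_len))),
    volume_mm3 = ifelse(seg_fail, NA_real_, round(volume, 1)),
    diameter_mm = round(diameter, 1),
    segmentation_reliable = !seg_fail,
    spiculated = spic, upper_lobe = upper,
    perifissural = perifissural, retronodule = FALSE,
    malignant = malignant,
    brock_probability = NA_real_
  )

  flat <- participants |>
    left_join(nodules, by = "participant_id")
  as_cohort(flat, validate = FALSE)
}
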