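# Marginal-count specifications and exact fixture reconstruction.
#
# Published threshold tables report *cumulative* counts: how many
# participants, and how many cancers, fall below each size threshold on
# each scale. Raw participant-level data are typically unavailable, but a
# participant-level cohort can be reconstructed that reproduces every
# printed cumulative cell exactly. The construction couples the two size
# scales comonotonically *within each outcome class* (see the methods
# vignette for why a single global comonotone coupling cannot exist for
# real tables): within cancers, and separately within benign
# participants, volume rank order equals diameter rank order, and bin
# membership on each scale is read directly off that scale's cumulative
# counts.

#' Cumulative marginal-count specification
#'
#' @param total_participants Participants with >=1 solid nodule.
#' @param total_cancers Cancers among them.
#' @param bins Tibble/data frame with columns `scale` (`"volume"` or
#'   `"diameter"`), `threshold`, `participants_below`, `cancers_below`:
#'   cumulative counts strictly below each threshold, per scale.
#' @param no_nodule_participants,no_nodule_cancers Participants with no
#'   solid nodule at baseline and cancers among them (0 to omit).
#' @param unsegmentable_count Nodule participants whose nodule has no
#'   reliable volume (diameter only).
#' @param unsegmentable_diameter_range Diameter band (mm) in which
#'   unsegmentable nodules sit; used both to place them and to check
#'   consistency of the volume-scale counts.
#' @param brock_gates Optional tibble with columns `scale`, `threshold`,
#'   `gated_cancers`, `gated_benign`: of the participants at/above the
#'   size threshold on that scale, how many are Brock-gate positive.
#' @param perifissural_participants,perifissural_cancers Participants with
#'   >=1 perifissural-typical nodule and cancers among them (0 to omit).
#' @return A `marginal_spec` object.
#' @export
marginal_spec <- function(total_participants, total_cancers, bins,
                          no_nodule_participants = 0, no_nodule_cancers = 0,
                          unsegmentable_count = 0,
                          unsegmentable_diameter_range = c(6, 8),
                          brock_gates = NULL,
                          perifissural_participants = 0,
                          perifissural_cancers = 0) {
  bins <- as_tibble(bins)
  stopifnot(all(c("scale", "threshold", "participants_below",
                  "cancers_below") %in% names(bins)))
  bins <- bins |>
    mutate(scale = as.character(.data$scale)) |>
    arrange(.data$scale, .data$threshold)
  if (!all(bins$scale %in% c("volume", "diameter"))) {
    stop_domain("bin scale must be 'volume' or 'diameter'")
  }
  spec <- structure(list(
    total_participants = as.integer(total_participants),
    total_cancers = as.integer(total_cancers),
    bins = bins,
    no_nodule_participants = as.integer(no_nodule_participants),
    no_nodule_cancers = as.integer(no_nodule_cancers),
    unsegmentable_count = as.integer(unsegmentable_count),
    unsegmentable_diameter_range = as.numeric(unsegmentable_diameter_range),
    brock_gates = if (!is.null(brock_gates)) as_tibble(brock_gates),
    perifissural_participants = as.integer(perifissural_participants),
    perifissural_cancers = as.integer(perifissural_cancers)
  ), class = "marginal_spec")
  validate_marginal_spec(spec)
  spec
}

validate_marginal_spec <- function(spec) {
  b <- spec$bins
  if (any(b$cancers_below > b$participants_below)) {
    i <- which(b$cancers_below > b$participants_below)[1]
    stop_domain("infeasible spec: bin (%s < %g) has more cancers (%d) than participants (%d)",
                b$scale[i], b$threshold[i], b$cancers_below[i], b$participants_below[i])
  }
  for (s in unique(b$scale)) {
    bb <- b[b$scale == s, ]
    for (col in c("participants_below", "cancers_below")) {
      d <- diff(bb[[col]])
      if (any(d < 0)) {
        i <- which(d < 0)[1] + 1
        stop_domain("infeasible spec: %s decreases at bin (%s < %g)",
                    col, s, bb$threshold[i])
      }
    }
    benign <- bb$participants_below - bb$cancers_below
    if (any(diff(benign) < 0)) {
      i <- which(diff(benign) < 0)[1] + 1
      stop_domain("infeasible spec: benign count decreases at bin (%s < %g)",
                  s, bb$threshold[i])
    }
    if (any(bb$participants_below > spec$total_participants) ||
        any(bb$cancers_below > spec$total_cancers)) {
      stop_domain("infeasible spec: cumulative counts exceed totals on scale %s", s)
    }
  }
  if (spec$total_cancers > spec$total_participants) {
    stop_domain("infeasible spec: more cancers than participants")
  }
  invisible(spec)
}

#' @export
print.marginal_spec <- function(x, ...) {
  cat(sprintf("<marginal_spec> %d participants with nodules, %d cancers (+%d/%d with no nodules)\n",
              x$total_participants, x$total_cancers,
              x$no_nodule_cancers, x$no_nodule_participants))
  print(x$bins)
  invisible(x)
}

#' Read / write a marginal-count specification file
#'
#' YAML serialisation of [marginal_spec()].
#'
#' @param path File path.
#' @return [read_marginal_spec()] a `marginal_spec`;
#'   [write_marginal_spec()] `path` invisibly.
#' @export
read_marginal_spec <- function(path) {
  v <- yaml::read_yaml(path)
  v$bins <- bind_rows(lapply(v$bins, as_tibble))
  if (!is.null(v$brock_gates)) {
    v$brock_gates <- bind_rows(lapply(v$brock_gates, as_tibble))
  }
  do.call(marginal_spec, v)
}

#' @param spec A `marginal_spec`.
#' @rdname read_marginal_spec
#' @export
write_marginal_spec <- function(spec, path) {
  v <- unclass(spec)
  v$bins <- lapply(seq_len(nrow(v$bins)), function(i) as.list(v$bins[i, ]))
  if (!is.null(v$brock_gates)) {
    v$brock_gates <- lapply(seq_len(nrow(v$brock_gates)),
                            function(i) as.list(v$brock_gates[i, ]))
  } else {
    v$brock_gates <- NULL
  }
  yaml::write_yaml(v, path)
  invisible(path)
}

#' Published baseline screening-cohort marginal counts
#'
#' The packaged transcription of cumulative threshold counts from a large
#' prospective baseline LDCT screening cohort (11 355 participants, 5 929
#' with a solid nodule, 228 cancers): rule-out cells at <5/<6 mm and
#' <80/<100 mm^3, rule-in complements at >=8 mm and >=300 mm^3, the
#' with-Brock referral counts, the 144 unsegmentable nodules, and the
#' perifissural sub-cohort. [reconstruct_fixture()] turns it into a
#' synthetic participant-level cohort reproducing every cell exactly.
#'
#' @return A `marginal_spec`.
#' @export
#' @examples
#' baseline_marginals()
baseline_marginals <- function() {
  read_marginal_spec(system.file("extdata", "baseline_cohort_marginals.yaml",
                                 package = "nodulestrat", mustWork = TRUE))
}

# --- reconstruction -------------------------------------------------------

# cumulative counts -> bin index per rank (1 = below the first threshold)
rank_bin <- function(ranks, cum_counts) {
  findInterval(ranks - 0.5, cum_counts) + 1L
}

# geometric midpoints of the bins implied by thresholds, strictly inside
bin_values <- function(thresholds, lo, hi) {
  lo <- min(lo, thresholds[1] / 4)
  hi <- max(hi, thresholds[length(thresholds)] * 4)
  edges <- c(lo, thresholds, hi)
  sqrt(edges[-length(edges)] * edges[-1])
}

#' Reconstruct a participant-level fixture from marginal counts
#'
#' Builds a synthetic cohort, one single-nodule participant per spec
#' participant, whose cumulative counts reproduce the spec exactly:
#' `marginal_counts(reduce_to_index(reconstruct_fixture(spec)), spec)`
#' returns the spec's own bins.
#'
#' Within each outcome class the two size scales are coupled
#' comonotonically: members are ranked once, and each scale's cumulative
#' counts partition the ranks into that scale's bins. Sizes are placed at
#' the geometric midpoint of their bin, strictly inside it.
#' Unsegmentable nodules are benign, carry a diameter at the midpoint of
#' `unsegmentable_diameter_range` and no volume; on the volume scale they
#' are counted through their sphere-equivalent diameter (see
#' [marginal_counts()]). Where the spec carries `brock_gates`, a synthetic
#' `brock_probability` column is added (`brock_pos` / `brock_neg` either
#' side of the 10% gate) placed by rank so each gated count is exact;
#' covariate columns are constant synthetic defaults.
#'
#' @param spec A [marginal_spec()].
#' @param size_limits Named list of outer bin edges used for midpoint
#'   placement: `min_volume`, `max_volume` (mm^3), `min_diameter`,
#'   `max_diameter` (mm).
#' @param brock_pos,brock_neg Synthetic Brock probabilities assigned to
#'   gate-positive / gate-negative participants.
#' @return A cohort tibble (see [as_cohort()]).
#' @export
#' @examples
#' fx <- reconstruct_fixture(baseline_marginals())
#' nrow(fx)
reconstruct_fixture <- function(spec,
                                size_limits = list(min_volume = 5,
                                                   max_volume = 30000,
                                                   min_diameter = 2,
                                                   max_diameter = 40),
                                brock_pos = 0.25, brock_neg = 0.02) {
  stopifnot(inherits(spec, "marginal_spec"))
  validate_marginal_spec(spec)
  n_cancer <- spec$total_cancers
  n_benign <- spec$total_participants - n_cancer
  u <- spec$unsegmentable_count
  if (u > n_benign) {
    stop_domain("infeasible spec: more unsegmentable nodules (%d) than benign participants (%d)",
                u, n_benign)
  }
  d_unseg <- sqrt(prod(spec$unsegmentable_diameter_range))
  v_unseg <- sphere_volume(d_unseg)

  vol_bins <- spec$bins |> filter(.data$scale == "volume")
  dia_bins <- spec$bins |> filter(.data$scale == "diameter")

  class_counts <- function(bins, cancers) {
    if (cancers) bins$cancers_below
    else bins$participants_below - bins$cancers_below
  }

  # benign cumulative counts with the unsegmentable block carved out;
  # unsegmentables sit above every threshold not exceeding their implied size
  adj <- function(counts, thresholds, implied) {
    out <- counts - ifelse(thresholds > implied, u, 0L)
    out
  }
  ben_vol <- adj(class_counts(vol_bins, FALSE), vol_bins$threshold, v_unseg)
  ben_dia <- adj(class_counts(dia_bins, FALSE), dia_bins$threshold, d_unseg)
  for (s in list(list(ben_vol, vol_bins), list(ben_dia, dia_bins))) {
    cnt <- s[[1]]; bb <- s[[2]]
    if (length(cnt) && (any(cnt < 0) || any(diff(cnt) < 0))) {
      i <- which(c(cnt[1] < 0, diff(cnt) < 0))[1]
      stop_domain("infeasible spec: unsegmentable placement empties bin (%s < %g)",
                  bb$scale[i], bb$threshold[i])
    }
  }

  build_class <- function(n, vol_cum, dia_cum, malignant) {
    if (n == 0) {
      return(tibble(volume_mm3 = double(), diameter_mm = double(),
                    malignant = logical()))
    }
    r <- seq_len(n)
    vol <- if (nrow(vol_bins) > 0) {
      bin_values(vol_bins$threshold, size_limits$min_volume,
                 size_limits$max_volume)[rank_bin(r, vol_cum)]
    } else {
      rep(sqrt(size_limits$min_volume * size_limits$max_volume), n)
    }
    dia <- if (nrow(dia_bins) > 0) {
      bin_values(dia_bins$threshold, size_limits$min_diameter,
                 size_limits$max_diameter)[rank_bin(r, dia_cum)]
    } else {
      rep(sqrt(size_limits$min_diameter * size_limits$max_diameter), n)
    }
    tibble(volume_mm3 = vol, diameter_mm = dia, malignant = malignant)
  }

  cancers <- build_class(n_cancer, class_counts(vol_bins, TRUE),
                         class_counts(dia_bins, TRUE), TRUE)
  benign_seg <- build_class(n_benign - u, ben_vol, ben_dia, FALSE)
  benign_unseg <- tibble(volume_mm3 = rep(NA_real_, u),
                         diameter_mm = rep(d_unseg, u),
                         malignant = rep(FALSE, u))

  cancers$segmentation_reliable <- TRUE
  benign_seg$segmentation_reliable <- TRUE
  benign_unseg$segmentation_reliable <- FALSE
  cancers$.rank <- seq_len(nrow(cancers))
  benign_seg$.rank <- seq_len(nrow(benign_seg))
  benign_unseg$.rank <- NA_integer_

  # Brock gate assignment by rank within class
  assign_gate <- function(tab, gates, col) {
    gate_pos <- rep(FALSE, nrow(tab))
    if (is.null(gates) || nrow(gates) == 0 || nrow(tab) == 0) {
      return(gate_pos)
    }
    sets <- lapply(seq_len(nrow(gates)), function(i) {
      g <- gates[i, ]
      val <- if (g$scale == "volume") {
        ifelse(is.na(tab$volume_mm3), sphere_volume(tab$diameter_mm),
               tab$volume_mm3)
      } else {
        tab$diameter_mm
      }
      which(val >= g$threshold)
    })
    need <- gates[[col]]
    ord <- order(lengths(sets))  # smallest (most restrictive) set first
    sets <- sets[ord]; need <- need[ord]
    if (length(sets) > 2) {
      stop_domain("at most two brock gate rows (one per scale) are supported")
    }
    if (length(sets) == 1) {
      s <- sets[[1]]
      if (need[1] > length(s)) {
        stop_domain("infeasible brock gate: need %d positives among %d members",
                    need[1], length(s))
      }
      gate_pos[utils::tail(s, need[1])] <- TRUE
      return(gate_pos)
    }
    if (!all(sets[[1]] %in% sets[[2]])) {
      stop_domain("brock gates require nested threshold sets (rule-in volume set within rule-in diameter set)")
    }
    if (need[2] < need[1]) {
      stop_domain("infeasible brock gates: fewer positives above the wider threshold")
    }
    outer_only <- setdiff(sets[[2]], sets[[1]])
    if (need[1] > length(sets[[1]]) || need[2] - need[1] > length(outer_only)) {
      stop_domain("infeasible brock gate counts for the given bins")
    }
    gate_pos[utils::tail(sets[[1]], need[1])] <- TRUE
    gate_pos[utils::tail(outer_only, need[2] - need[1])] <- TRUE
    gate_pos
  }

  cancers$gate <- assign_gate(cancers, spec$brock_gates, "gated_cancers")
  ben_all <- bind_rows(benign_seg, benign_unseg)
  ben_all$gate <- assign_gate(ben_all, spec$brock_gates, "gated_benign")

  # perifissural flags: smallest-ranked members of each class
  cancers$perifissural <- cancers$.rank <= spec$perifissural_cancers
  n_peri_ben <- spec$perifissural_participants - spec$perifissural_cancers
  if (n_peri_ben < 0 || n_peri_ben > nrow(ben_all)) {
    stop_domain("infeasible perifissural counts")
  }
  ben_all$perifissural <- !is.na(ben_all$.rank) & ben_all$.rank <= n_peri_ben

  nod <- bind_rows(cancers, ben_all) |> select(-".rank")
  nod$brock_probability <- ifelse(nod$gate, brock_pos, brock_neg)
  n_nod <- nrow(nod)

  no_nod_n <- spec$no_nodule_participants
  flat <- tibble(
    participant_id = sprintf("F%05d", seq_len(n_nod + no_nod_n)),
    age_years = 65, sex = "male", family_history = FALSE, emphysema = FALSE,
    cancer_outcome = c(nod$malignant,
                       rep(c(TRUE, FALSE),
                           c(spec$no_nodule_cancers,
                             no_nod_n - spec$no_nodule_cancers))),
    nodule_id = c(sprintf("F%05d-N1", seq_len(n_nod)), rep(NA, no_nod_n)),
    volume_mm3 = c(round(nod$volume_mm3, 2), rep(NA, no_nod_n)),
    diameter_mm = c(round(nod$diameter_mm, 2), rep(NA, no_nod_n)),
    segmentation_reliable = c(nod$segmentation_reliable, rep(NA, no_nod_n)),
    spiculated = c(rep(FALSE, n_nod), rep(NA, no_nod_n)),
    upper_lobe = c(rep(FALSE, n_nod), rep(NA, no_nod_n)),
    perifissural = c(nod$perifissural, rep(NA, no_nod_n)),
    retronodule = c(rep(FALSE, n_nod), rep(NA, no_nod_n)),
    malignant = c(nod$malignant, rep(NA, no_nod_n)),
    brock_probability = c(nod$brock_probability, rep(NA, no_nod_n))
  )
  as_cohort(flat)
}

#' Cumulative marginal counts of an indexed cohort
#'
#' Counts, per size threshold, how many nodule participants (and cancers)
#' fall strictly below it — the inverse of [reconstruct_fixture()]. On the
#' volume scale a participant whose index nodule has no reliable volume is
#' counted through the sphere-equivalent volume of its diameter
#' (`unsegmentable = "sphere"`, the default, mirroring how such nodules
#' are folded into a volumetric analysis) or dropped from the volume rows
#' (`"exclude"`).
#'
#' @param indexed Indexed cohort from [reduce_to_index()].
#' @param thresholds Tibble with columns `scale`, `threshold`, or a
#'   [marginal_spec()] whose bins supply them.
#' @param unsegmentable `"sphere"` or `"exclude"`.
#' @return A `marginal_spec` with computed counts and totals.
#' @export
marginal_counts <- function(indexed, thresholds,
                            unsegmentable = c("sphere", "exclude")) {
  unsegmentable <- match.arg(unsegmentable)
  if (inherits(thresholds, "marginal_spec")) {
    thresholds <- thresholds$bins[, c("scale", "threshold")]
  }
  thresholds <- as_tibble(thresholds)
  nod <- indexed |> filter(.data$has_nodule)
  seg <- isTRUE_v(nod$segmentation_reliable)
  vol_eff <- ifelse(seg, nod$volume_mm3,
                    if (unsegmentable == "sphere")
                      sphere_volume(nod$diameter_mm) else NA_real_)
  bins <- thresholds |>
    rowwise() |>
    mutate(
      participants_below = {
        v <- if (.data$scale == "volume") vol_eff else nod$diameter_mm
        sum(v < .data$threshold, na.rm = TRUE)
      },
      cancers_below = {
        v <- if (.data$scale == "volume") vol_eff else nod$diameter_mm
        sum(v < .data$threshold & nod$cancer_outcome, na.rm = TRUE)
      }
    ) |>
    ungroup()
  marginal_spec(
    total_participants = nrow(nod),
    total_cancers = sum(nod$cancer_outcome),
    bins = bins,
    no_nodule_participants = sum(!indexed$has_nodule),
    no_nodule_cancers = sum(indexed$cancer_outcome & !indexed$has_nodule),
    unsegmentable_count = sum(!seg),
    perifissural_participants = sum(nod$any_perifissural),
    perifissural_cancers = sum(nod$any_perifissural & nod$cancer_outcome)
  )
}
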