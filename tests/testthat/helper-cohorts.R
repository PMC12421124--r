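# Builders and independent oracles shared across test files.

make_flat_row <- function(participant_id = "P1", age_years = 65,
                          sex = "male", family_history = FALSE,
                          emphysema = FALSE, cancer_outcome = FALSE,
                          nodule_id = NA_character_, volume_mm3 = NA_real_,
                          diameter_mm = NA_real_,
                          segmentation_reliable = NA, spiculated = FALSE,
                          upper_lobe = FALSE, perifissural = FALSE,
                          retronodule = FALSE, malignant = FALSE,
                          brock_probability = NA_real_) {
  if (is.na(segmentation_reliable)) {
    segmentation_reliable <- !is.na(volume_mm3)
  }
  tibble::tibble(
    participant_id = participant_id, age_years = age_years, sex = sex,
    family_history = family_history, emphysema = emphysema,
    cancer_outcome = cancer_outcome, nodule_id = nodule_id,
    volume_mm3 = volume_mm3, diameter_mm = diameter_mm,
    segmentation_reliable = segmentation_reliable, spiculated = spiculated,
    upper_lobe = upper_lobe, perifissural = perifissural,
    retronodule = retronodule, malignant = malignant,
    brock_probability = brock_probability
  )
}

# a small hand-built cohort: 1 cancer, 2 benign nodule participants (one
# multi-nodule, one unsegmentable), 1 no-nodule participant
toy_cohort <- function() {
  as_cohort(dplyr::bind_rows(
    make_flat_row("P1", cancer_outcome = TRUE, nodule_id = "P1-N1",
                  volume_mm3 = 420, diameter_mm = 9.3, malignant = TRUE,
                  spiculated = TRUE),
    make_flat_row("P2", nodule_id = "P2-N1", volume_mm3 = 50,
                  diameter_mm = 4.5),
    make_flat_row("P2", nodule_id = "P2-N2", volume_mm3 = 120,
                  diameter_mm = 6.1),
    make_flat_row("P3", nodule_id = "P3-N1", diameter_mm = 7.0,
                  segmentation_reliable = FALSE),
    make_flat_row("P4")
  ))
}

# random feasible marginal spec under a fixed-size population
random_marginal_spec <- function(n_participants = 400, n_cancers = 40,
                                 unsegmentable = 0) {
  vol_thr <- sort(sample(c(30, 80, 100, 200, 300, 500), 3))
  dia_thr <- sort(sample(c(3, 4, 5, 6, 8, 10), 3))
  cum_counts <- function(total, k) sort(sample(0:total, k, replace = TRUE))
  mk_scale <- function(scale, thr) {
    repeat {
      cb <- cum_counts(n_cancers, length(thr))
      pb <- cb + cum_counts(n_participants - n_cancers, length(thr))
      if (all(diff(pb - cb) >= 0)) {
        return(tibble::tibble(scale = scale, threshold = thr,
                              participants_below = pb, cancers_below = cb))
      }
    }
  }
  marginal_spec(
    total_participants = n_participants, total_cancers = n_cancers,
    bins = dplyr::bind_rows(mk_scale("volume", vol_thr),
                            mk_scale("diameter", dia_thr)),
    unsegmentable_count = unsegmentable
  )
}

# --- independent oracles --------------------------------------------------

# AUC by brute force over all positive/negative pairs, ties counted 1/2
auc_pairs <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# closed-form Pearson chi-squared for a 2x2 table
chi2_closed <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# exact two-sided McNemar by full enumeration of Binomial(n, 1/2):
# sum of probabilities of outcomes no more likely than the observed one
mcnemar_enum <- function(b, c) {
  n <- b + c
  probs <- dbinom(0:n, n, 0.5)
  sum(probs[probs <= dbinom(b, n, 0.5) + 1e-12])
}

# Youden J by exhaustive scan over all distinct thresholds
youden_scan <- function(scores, labels) {
  best <- -Inf
  for (t in sort(unique(scores))) {
    sens <- mean(scores[labels] >= t)
    spec <- mean(scores[!labels] < t)
    best <- max(best, sens + spec - 1)
  }
  best
}
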