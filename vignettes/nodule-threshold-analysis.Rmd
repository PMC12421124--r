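---
title: "Size and risk thresholds for solid nodules at baseline screening CT: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Size and risk thresholds for solid nodules at baseline screening CT: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nodulestrat)
```

## The problem

Low-dose CT screening for lung cancer finds a solid pulmonary nodule in
roughly half of participants at the baseline scan, yet only a few percent
of those nodules prove malignant. Management guidelines therefore
stratify nodules by size: below a *rule-out* threshold the participant is
discharged to the next screening round; at or above a *rule-in*
threshold the participant is referred for definitive investigation
(PET-CT / multidisciplinary team), optionally after an additional
risk-model gate; in between, a 3-month interval CT resolves the
uncertainty. Guidelines disagree on the measurement scale (semi-automated
volumetry in mm^3 versus long-axis diameter in mm), on the cut-offs
(80 vs 100 mm^3; 5 vs 6 mm), and on whether a malignancy risk model
(the Brock/PanCan logistic model, gated at 10%) should sit on top of the
rule-in size criterion.

`nodulestrat` implements the complete evaluation pipeline for such
protocols: per-participant reduction of multi-nodule cohorts, threshold
classification with volumetric/diameter fallback logic, Brock scoring,
diagnostic accuracy statistics with exact intervals, ROC/DeLong/Youden
analyses, and a weighted net-benefit comparison of competing rules with
bootstrap confidence intervals. Because participant-level data from real
screening programmes are rarely shareable, the package also contains a
synthetic-cohort generator and an exact fixture reconstruction from
published cumulative count tables.

## Analysis unit and reduction

All statistics are per participant. A participant with several solid
nodules is represented by a single *index nodule*: the malignant one if
any (at most one by construction — one participant, one nodule, one
cancer), otherwise the largest. "Largest" is resolved on the requested
scale with a deterministic tie-break: the other scale, then the
lexicographically smallest nodule id. Benign *retronodules* — nodules
only recognised in retrospect when a later scan was reported — are never
selected as index, because participants were stratified by their largest
*reported* nodule; a retronodule that proved malignant participates
fully. Participants whose baseline scan shows no solid nodule form the
reference group for crude-risk comparisons.

## Threshold conventions

Rule-out sets are strict (`size < cut-off`) and rule-in sets inclusive
(`size >= cut-off`), matching the `<80 mm^3` / `>=300 mm^3` notation of
the guideline tables; a nodule of exactly 80 mm^3 fails the 80 mm^3
rule-out. Under a volumetric protocol, a nodule whose segmentation was
not reliable carries no volume and is classified by fallback diameter
cut-offs, 6 mm (rule-out) and 8 mm (rule-in) by default. The literal
guideline fallback rule-out is 5 mm; 6 mm is the categorisation used
when unsegmentable nodules are folded into a volumetric analysis, and
both are available in `protocol_config()` — the discrepancy is a fact
about the guidelines, documented rather than resolved. Whether an
unsegmentable nodule of 8 mm or more should be referred on size alone or
Brock-gated is likewise configurable; the default gates it, mirroring
the volumetric arm.

For *counting* (not protocol classification) on the volume scale, a
diameter-only nodule is imputed the volume of a sphere with its diameter
(`pi/6 d^3`), which places the default 6–8 mm band strictly between the
100 and 300 mm^3 cut-offs; `marginal_counts()` can instead exclude such
nodules from volume rows.

## The Brock (PanCan) model

The referral gate uses the published full-with-spiculation variant of
the Brock logistic model, transcribed into `brock_coefficients()`:
intercept −6.7892; age +0.0287 per year (centred at 62); female sex
+0.6011; family history +0.2961; emphysema +0.2953; upper lobe +0.6581;
spiculation +0.7729; nodule count −0.0824 per nodule (centred at 4); and
the non-linear size term −5.3854 · ((d/10)^−1/2 − 1.58113883) with d the
long-axis diameter in mm. The transcription is pinned by a unit test
holding one hand-computed evaluation (a plain 10 mm solid nodule in a
62-year-old man, count 4: linear predictor −3.65953454, probability
0.02509834) plus direction and monotonicity checks for every covariate.
The model is applied, never refitted. The size entering the model is the
long-axis diameter even when the rule-in size was volume-defined — the
sizing such cohorts record — with a sphere-equivalent-diameter option.
Probabilities are gated at full precision (`>=` threshold, default 10%);
nothing is rounded before gating.

## Accuracy statistics

Sensitivity, specificity, PPV and NPV are computed conventionally from
the participant-level 2×2 table; a metric with an empty denominator is
reported absent, not zero. Confidence intervals are Clopper–Pearson by
default: the exact interval guarantees at-least-nominal coverage (the
package verifies this by complete enumeration of the binomial outcome
distribution over a grid of p and n) and reproduces the printed
intervals of published screening tables (e.g. 37/4809 → 0.54% to 1.06%);
Wilson is available behind a flag. Group comparisons use Pearson's
chi-squared without continuity correction; paired sensitivity and
specificity comparisons use McNemar's test, defaulting to the exact
two-sided binomial form because discordant counts can be small, with the
classical chi-squared variants selectable. Univariable odds ratios per
unit size come from a maximum-likelihood logistic fit; perfect
separation raises an explicit error rather than returning a divergent
fit.

ROC curves are empirical, with thresholds at the distinct score values
and ties grouped into single operating points, so the trapezoidal AUC
equals the Mann–Whitney statistic with ties counted one half. AUC
variances and paired comparisons use DeLong placement values; the
Youden-optimal cut-point maximises J = sensitivity + specificity − 1
with ties broken to the smallest threshold (favouring sensitivity) and
thresholds reported as raw score values. The volume-versus-diameter AUC
comparison needs paired scores, so it runs on the reliably segmented
subset — volume simply does not exist for the rest.

## Net benefit

Switching from rule A to rule B trades sensitivity against specificity.
The scalar summary used here is

> net benefit = ΔSensitivity + ΔSpecificity · (1/W) · (1−p)/p,

reported in percentage points, where W down-weights specificity gains
(W = 50 for rule-out comparisons, W = 5 for rule-in, the convention for
a screening programme with around 2% cancer prevalence) and p is the
cancer prevalence. The prevalence definition is the one genuinely open
choice: published analyses rarely state which population's prevalence
enters p, and the choice changes the answer materially. The package
therefore makes `prevalence_source` an explicit, mandatory configuration
— whole cohort, nodule participants, the reference-rule-positive subset,
or a fixed value — and reports which was used. Confidence intervals are
percentile bootstrap over participant-level resamples (default B = 1000,
seeded); a resample lacking an outcome class is redrawn and counted. The
full-sample point estimate is always evaluated and reported alongside
the interval.

## The synthetic generator

`generator_params()` defaults describe the baseline screening cohort the
analyses target: 11 355 participants, 52.2% with at least one solid
nodule, malignancy risk 3.85% among nodule participants and 0.77%
without nodules, and 2.1% segmentation failure. Class-conditional
log-volume distributions were solved once from the published cumulative
size fractions — benign nodules 65.4% below 80 mm^3 and 93.7% below
300 mm^3 give meanlog 3.92, sdlog 1.16; malignant nodules 13.2% and
33.3% give meanlog 6.53, sdlog 1.92 — implying a binormal
volume AUC of Φ(2.61/√(1.16² + 1.92²)) ≈ 0.88, which the recovery tests
use as their closed-form target. Diameters follow the sphere relation
times log-normal noise (sd 0.12 on the log scale, a modest
non-sphericity). Nodule counts are 1 + Poisson(0.3); covariates are
Bernoulli draws whose odds are multiplied in the malignant class
(spiculation ×8, upper lobe ×2, emphysema ×1.8, family history ×1.3) so
that Brock gating separates the classes. All draws derive sub-streams
from one seed, so adding a covariate never perturbs earlier draws and a
fixed seed reproduces the cohort byte for byte.

What the generator does **not** emulate: correlated nodule multiplicity,
reader variability in diameter measurement, scanner or software effects,
interval growth, and the real joint distribution of Brock covariates.
Passing recovery tests on generated cohorts therefore demonstrates
correctness of the estimators under the stated model, not performance on
any particular real screening population.

## Exact fixture reconstruction

Published threshold tables print cumulative counts — participants and
cancers strictly below each cut-off on each scale. `reconstruct_fixture()`
builds a participant-level cohort reproducing every such cell exactly.
One might hope to couple the two size scales comonotonically across the
whole cohort (a single latent size rank driving both scales), but for
real tables that coupling need not exist, and for the packaged table it
provably does not: fewer participants lie below 8 mm (4074) than below
100 mm^3 (4183), yet more *cancers* lie below 8 mm (51) than below
100 mm^3 (34) — no single rank ordering satisfies both cumulative cancer
constraints. The construction therefore couples comonotonically *within
each outcome class*: cancers are ranked once and each scale's cumulative
cancer counts partition those ranks into bins, and likewise for benign
participants. Such a coupling exists whenever the spec's own
monotonicity invariants hold (cumulative participants, cancers and
benign counts each non-decreasing per scale), it matches every cell
exactly, and a property test verifies the round trip on randomly
generated feasible specs. Sizes are placed at the geometric midpoint of
their bin, strictly inside it, so strict-below counting is unambiguous;
this closed-form placement is deterministic and needs no optimisation.

Unsegmentable nodules (144 in the packaged table) are placed as benign,
diameter-only records in the 6–8 mm fallback band — their outcome
composition is not published, and all-benign is the simplest placement
consistent with every printed cell. Where the table reports with-Brock
referral counts, the fixture carries a synthetic `brock_probability`
column (0.25/0.02 either side of the 10% gate) assigned by rank so that
the gated counts are exact on both scales simultaneously; real covariate
joints are unavailable, so probabilities, not covariates, are pinned,
and the constant demographic columns of the fixture are synthetic
placeholders. The perifissural sub-cohort (3823 participants, 8 cancers)
is flagged on the smallest-ranked members of each class. Everything
about the fixture beyond the printed cells — the joint distribution, the
within-bin positions, the flags' correlation structure — is a modelling
convention, not an estimate.

## Numerical and design choices

* Rounding: computation at full precision; table rendering rounds
  half-up to one decimal for percentages and prints p-values at four
  decimals with a `<0.0001` floor.
* `diagnostic_summary()` denominators follow the published convention:
  specificity among benign *nodule* participants; `stratify()` can
  include no-nodule participants as rule-negative via its population
  selector.
* Degenerate inputs: empty cohorts, single-class outcomes, zero
  discordant pairs, zero margins and non-positive Brock sizes raise
  typed errors naming the problem; they are never silently coerced.
* Determinism: every random stage (generator, bootstrap, pipeline)
  derives labelled sub-streams from one top-level seed.
* Problem sizes: the test suite generates cohorts of 1 200–32 000
  participants, uses 10 000 for parameter recovery, brute-force oracles
  at n ≤ 200, bootstrap sizes of 50–1000, and complete enumeration for
  exact-test and coverage checks — sizes chosen so the whole suite runs
  in minutes on one core while keeping Monte-Carlo slack at 3 standard
  errors.

## Known limitations

* The real-data headline numbers that depend on the full unpublished
  joint distribution — AUROCs, the mathematically optimal Brock
  threshold, crude odds ratios, test p-values, and the published
  net-benefit points (whose prevalence definition is ambiguous) — cannot
  be recovered from printed cumulative counts and are deliberately not
  asserted; the corresponding machinery is validated against independent
  oracles and synthetic cohorts with known truth instead.
* No interval-scan logic: the ≥200 mm^3 growth referral exists only as a
  protocol constant; multi-timepoint surveillance, volume doubling times
  and multi-round screening are out of scope.
* Solid nodules only; subsolid terms of the Brock model are not
  implemented. The parsimonious Brock variant is not shipped: only
  coefficient values that could be verified against the original
  publication are included, and the full-with-spiculation model is the
  variant the gating protocol uses.
* Mean-diameter (as opposed to long-axis) protocols cannot be emulated
  from long-axis data.

## A worked example

```{r example, eval = FALSE}
library(nodulestrat)

# exact fixture from the packaged cumulative counts
idx <- reduce_to_index(reconstruct_fixture(baseline_marginals()))

# rule-out performance of the 80 mm^3 volumetric threshold
diagnostic_summary(stratify(idx, threshold_rule(80, "volume")))

# add the Brock gate to the 300 mm^3 rule-in threshold
stratify(idx, threshold_rule(300, "volume", brock_threshold = 0.10))

# the full report
run_pipeline(pipeline_config(seed = 1, n_bootstrap = 1000))
```
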