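# Baseline management classification and threshold stratification.

mk_indexed <- function(volume, brock = NA_real_, diameter = NULL,
                       reliable = !is.na(volume)) {
  if (is.null(diameter)) {
    diameter <- round(sphere_diameter(ifelse(is.na(volume), 100, volume)), 1)
  }
  rows <- purrr::pmap(list(seq_along(volume), volume, diameter, reliable,
                           brock),
                      function(i, v, d, r, b) {
    make_flat_row(sprintf("P%03d", i),
                  nodule_id = sprintf("P%03d-N1", i),
                  volume_mm3 = if (r) v else NA_real_, diameter_mm = d,
                  segmentation_reliable = r, brock_probability = b)
  })
  reduce_to_index(as_cohort(dplyr::bind_rows(rows)))
}

test_that("classification follows the management protocol", {
  idx <- mk_indexed(volume = c(40, 90, 350, 350, NA, NA),
                    brock = c(NA, NA, 0.12, 0.08, NA, 0.15),
                    diameter = c(4, 5.5, 9, 9, 7, 8.5),
                    reliable = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  cls <- classify_baseline(idx, bts_protocol())
  expect_equal(cls$action, c("routine_recall",      # <80
                             "interval_ct_3month",  # 80-300 band
                             "mdt_referral",        # >=300, Brock 12%
                             "interval_ct_3month",  # >=300, Brock 8%
                             "interval_ct_3month",  # unsegmentable 7 mm
                             "mdt_referral"))       # unsegmentable >=8 mm, gated
  # the trace names the rule that fired
  expect_match(cls$reason[3], "Brock 0.12.*mdt_referral")
  expect_match(cls$reason[1], "rule-out")
  # no-nodule participants are routine recall
  idx2 <- reduce_to_index(as_cohort(make_flat_row("Z")))
  expect_equal(classify_baseline(idx2, bts_protocol())$action,
               "routine_recall")
})

test_that("a rule-in-sized nodule without a Brock probability is a configuration error", {
  idx <- mk_indexed(volume = 400)
  expect_error(classify_baseline(idx, bts_protocol()), "Brock gate")
  # disabling the gate refers on size alone
  ungated <- bts_protocol(brock_threshold = NA)
  expect_equal(classify_baseline(idx, ungated)$action, "mdt_referral")
})

test_that("stratify cross-tabulates rules, protocols and populations", {
  idx <- mk_indexed(volume = c(40, 90, 350, 350, 500),
                    brock = c(NA, NA, 0.12, 0.08, 0.30))
  idx$cancer_outcome <- c(FALSE, FALSE, TRUE, FALSE, TRUE)
  cnt <- stratify(idx, threshold_rule(300, "volume"))
  expect_equal(tidy(cnt), tibble::tibble(tp = 2L, fp = 1L, fn = 0L, tn = 2L))
  # protocol rule: positive = referred
  cnt_p <- stratify(idx, bts_protocol())
  expect_equal(tidy(cnt_p), tibble::tibble(tp = 2L, fp = 0L, fn = 0L, tn = 3L))
  # all-benign cohort: tp = fn = 0 under any rule
  ben <- mk_indexed(volume = c(40, 500))
  cnt_b <- stratify(ben, threshold_rule(80, "volume"))
  expect_equal(cnt_b$tp + cnt_b$fn, 0L)
  # population selector: no-nodule participants count as rule-negative
  with_none <- reduce_to_index(as_cohort(dplyr::bind_rows(
    make_flat_row("A", nodule_id = "a", volume_mm3 = 400, diameter_mm = 9),
    make_flat_row("B")
  )))
  expect_equal(stratify(with_none, threshold_rule(300, "volume"),
                        population = "all")$tn, 1L)
  expect_equal(stratify(with_none, threshold_rule(300, "volume"))$tn, 0L)
})

test_that("nested thresholds are monotone and a Brock gate only shrinks positives", {
  idx <- reduce_to_index(generate_cohort(
    generator_params(n_participants = 3000, seed = 21)))
  idx <- brock_probability(idx)
  prev_pos <- Inf; prev_tp <- Inf
  for (t in c(50, 80, 150, 300, 600)) {
    cnt <- stratify(idx, threshold_rule(t, "volume"))
    expect_lte(cnt$tp + cnt$fp, prev_pos)
    expect_lte(cnt$tp, prev_tp)
    prev_pos <- cnt$tp + cnt$fp; prev_tp <- cnt$tp
    gated <- stratify(idx, threshold_rule(t, "volume", brock_threshold = 0.1))
    expect_lte(gated$tp, cnt$tp)
    expect_lte(gated$fp, cnt$fp)
  }
})

test_that("protocol configs validate and round-trip through files", {
  p <- bts_protocol()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_protocol(p, path)
  expect_equal(read_protocol(path), p)
  expect_error(protocol_config(rule_out_volume_mm3 = "eighty"),
               "single number")
  expect_equal(eups_protocol()$rule_out_volume_mm3, 100)
})
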