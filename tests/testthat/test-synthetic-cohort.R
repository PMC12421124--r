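# Synthetic generator and exact fixture reconstruction.

test_that("generator hits its probability dials and is seed-reproducible", {
  params <- generator_params(n_participants = 20000, seed = 42)
  coh <- generate_cohort(params)
  expect_equal(nrow(coh), 20000)

  frac_nod <- mean(purrr::map_int(coh$nodules, nrow) > 0)
  se <- sqrt(params$p_any_nodule * (1 - params$p_any_nodule) / 20000)
  expect_lt(abs(frac_nod - params$p_any_nodule), 3 * se)

  idx <- reduce_to_index(coh)
  prev <- mean(idx$cancer_outcome[idx$has_nodule])
  se_p <- sqrt(params$p_cancer_given_nodule *
                 (1 - params$p_cancer_given_nodule) / sum(idx$has_nodule))
  expect_lt(abs(prev - params$p_cancer_given_nodule), 3 * se_p)

  # byte-identical under the same seed, different under another
  again <- generate_cohort(params)
  expect_identical(as.data.frame(coh), as.data.frame(again))
  other <- generate_cohort(generator_params(n_participants = 20000, seed = 43))
  expect_false(identical(as.data.frame(coh), as.data.frame(other)))
})

test_that("degenerate generator settings behave", {
  none <- generate_cohort(generator_params(n_participants = 50,
                                           p_any_nodule = 0, seed = 1))
  expect_true(all(purrr::map_int(none$nodules, nrow) == 0))
  empty <- generate_cohort(generator_params(n_participants = 0, seed = 1))
  expect_equal(nrow(empty), 0)
  expect_error(generator_params(p_any_nodule = 1.2), "probabilities")
  expect_error(generator_params(log_volume_sd = -1), "sd parameters")
})

test_that("unsegmentable nodules from the generator carry a diameter only", {
  coh <- generate_cohort(generator_params(n_participants = 5000, seed = 11,
                                          p_segmentation_failure = 0.2))
  nods <- dplyr::bind_rows(coh$nodules)
  unseg <- nods[!nods$segmentation_reliable, ]
  expect_gt(nrow(unseg), 0)
  expect_true(all(is.na(unseg$volume_mm3)))
  expect_true(all(!is.na(unseg$diameter_mm)))
})

test_that("fixture reconstruction reproduces any feasible marginal spec exactly", {
  withr::local_seed(7)
  for (i in 1:15) {
    spec <- random_marginal_spec(n_participants = 300 + 20 * i,
                                 n_cancers = 10 + 2 * i)
    fx <- reconstruct_fixture(spec)
    got <- marginal_counts(reduce_to_index(fx), spec)
    expect_equal(as.data.frame(got$bins), as.data.frame(spec$bins))
    expect_equal(got$total_participants, spec$total_participants)
    expect_equal(got$total_cancers, spec$total_cancers)
  }
})

test_that("single-bin all-cancer spec gives an all-malignant cohort", {
  spec <- marginal_spec(
    total_participants = 12, total_cancers = 12,
    bins = tibble::tibble(scale = "volume", threshold = 1e6,
                          participants_below = 12, cancers_below = 12))
  fx <- reconstruct_fixture(spec)
  expect_true(all(fx$cancer_outcome))
  expect_true(all(purrr::map_lgl(fx$nodules, ~ all(.x$malignant))))
})

test_that("infeasible specs are rejected with the offending bin named", {
  bins <- tibble::tibble(scale = "volume", threshold = c(80, 100),
                         participants_below = c(50, 60),
                         cancers_below = c(20, 10))
  expect_error(marginal_spec(100, 30, bins), "cancers_below decreases.*100")
  bins2 <- tibble::tibble(scale = "volume", threshold = 80,
                          participants_below = 10, cancers_below = 20)
  expect_error(marginal_spec(100, 30, bins2), "more cancers")
  # benign must be monotone too
  bins3 <- tibble::tibble(scale = "volume", threshold = c(80, 100),
                          participants_below = c(50, 52),
                          cancers_below = c(10, 20))
  expect_error(marginal_spec(100, 30, bins3), "benign count decreases")
})

test_that("size ranks are comonotone within each outcome class", {
  fx <- reconstruct_fixture(baseline_marginals())
  idx <- reduce_to_index(fx)
  seg <- idx[idx$has_nodule & idx$segmentation_reliable %in% TRUE, ]
  for (cls in c(TRUE, FALSE)) {
    sub <- seg[seg$cancer_outcome == cls, ]
    ord_v <- order(sub$volume_mm3)
    # weak comonotonicity: sorting by volume never decreases diameter rank
    expect_true(all(diff(sub$diameter_mm[ord_v]) >= 0))
  }
})

test_that("marginal counts conserve totals and vanish on empty thresholds", {
  idx <- reduce_to_index(generate_cohort(
    generator_params(n_participants = 500, seed = 5)))
  got <- marginal_counts(idx, tibble::tibble(scale = c("volume", "diameter"),
                                             threshold = c(Inf, Inf)))
  expect_equal(unique(got$bins$participants_below), sum(idx$has_nodule))
  expect_equal(unique(got$bins$cancers_below),
               sum(idx$cancer_outcome & idx$has_nodule))
  zero <- marginal_counts(idx, tibble::tibble(scale = "volume",
                                              threshold = 0))
  expect_equal(zero$bins$participants_below, 0L)
})

test_that("packaged marginal file round-trips through its YAML serialisation", {
  spec <- baseline_marginals()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_marginal_spec(spec, path)
  back <- read_marginal_spec(path)
  expect_equal(as.data.frame(back$bins), as.data.frame(spec$bins))
  expect_equal(back$unsegmentable_count, spec$unsegmentable_count)
  expect_equal(as.data.frame(back$brock_gates), as.data.frame(spec$brock_gates))
})
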