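# Cohort container, delimited I/O and per-participant reduction.

test_that("nodule rows group by participant and round-trip through files", {
  coh <- toy_cohort()
  expect_equal(nrow(coh), 4)
  expect_equal(nrow(coh$nodules[[which(coh$participant_id == "P2")]]), 2)
  expect_equal(nrow(coh$nodules[[which(coh$participant_id == "P4")]]), 0)

  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_cohort(path, layout = "nodule_rows")
  expect_equal(as.data.frame(back), as.data.frame(coh))

  # tab-delimited round trip too
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(coh, path2)
  expect_equal(as.data.frame(read_cohort(path2)), as.data.frame(coh))
})

test_that("participant_rows layout round-trips single-nodule cohorts and rejects multi-nodule ones", {
  single <- as_cohort(dplyr::bind_rows(
    make_flat_row("A", nodule_id = "A-N1", volume_mm3 = 90, diameter_mm = 5.5),
    make_flat_row("B"),
    make_flat_row("C", nodule_id = "C-N1", diameter_mm = 4,
                  segmentation_reliable = FALSE)
  ))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(single, path, layout = "participant_rows")
  expect_equal(as.data.frame(read_cohort(path, layout = "participant_rows")),
               as.data.frame(single))
  # absent volume survives the round trip as absent, reliability FALSE
  c_back <- read_cohort(path)
  cn <- c_back$nodules[[which(c_back$participant_id == "C")]]
  expect_true(is.na(cn$volume_mm3))
  expect_false(cn$segmentation_reliable)

  expect_error(write_cohort(toy_cohort(), path, layout = "participant_rows"),
               "multi-nodule")
})

test_that("schema and row-level validation name the problem", {
  expect_error(
    as_cohort(make_flat_row("P1")[, -2]),
    "age_years"
  )
  # volume present but segmentation flagged unreliable
  expect_error(
    as_cohort(make_flat_row("P1", nodule_id = "n", volume_mm3 = 50,
                            diameter_mm = 4, segmentation_reliable = FALSE)),
    "segmentation_reliable"
  )
  # reliable segmentation must come with a volume
  expect_error(
    as_cohort(make_flat_row("P1", nodule_id = "n", diameter_mm = 4,
                            segmentation_reliable = TRUE)),
    "volume_mm3 is absent"
  )
  # diameter is mandatory for every nodule
  expect_error(
    as_cohort(make_flat_row("P1", nodule_id = "n", volume_mm3 = 50)),
    "diameter_mm is mandatory"
  )
  # malformed file rows are reported with their position
  bad <- dplyr::bind_rows(
    make_flat_row("P1", nodule_id = "n1", volume_mm3 = 10, diameter_mm = 3),
    make_flat_row("P2", nodule_id = "n2", volume_mm3 = 20, diameter_mm = 4,
                  segmentation_reliable = FALSE)
  )
  expect_error(as_cohort(bad), "row 2")
})

test_that("two malignant nodules in one participant violate the 1:1:1 invariant", {
  bad <- dplyr::bind_rows(
    make_flat_row("P1", cancer_outcome = TRUE, nodule_id = "n1",
                  volume_mm3 = 100, diameter_mm = 6, malignant = TRUE),
    make_flat_row("P1", cancer_outcome = TRUE, nodule_id = "n2",
                  volume_mm3 = 50, diameter_mm = 4, malignant = TRUE)
  )
  expect_error(as_cohort(bad), "more than one malignant")
})

test_that("index nodule is the malignant one, else the largest, never a benign retronodule", {
  coh <- as_cohort(dplyr::bind_rows(
    # benign multi-nodule: largest by volume wins
    make_flat_row("A", nodule_id = "A-N1", volume_mm3 = 50, diameter_mm = 4.6),
    make_flat_row("A", nodule_id = "A-N2", volume_mm3 = 120, diameter_mm = 6),
    # malignant 90 mm3 beats benign 500 mm3
    make_flat_row("B", cancer_outcome = TRUE, nodule_id = "B-N1",
                  volume_mm3 = 500, diameter_mm = 10),
    make_flat_row("B", cancer_outcome = TRUE, nodule_id = "B-N2",
                  volume_mm3 = 90, diameter_mm = 5.5, malignant = TRUE),
    # benign retronodule larger than the reported nodule: never index
    make_flat_row("C", nodule_id = "C-N1", volume_mm3 = 60, diameter_mm = 5),
    make_flat_row("C", nodule_id = "C-N2", volume_mm3 = 400,
                  diameter_mm = 9, retronodule = TRUE),
    make_flat_row("D")
  ))
  idx <- reduce_to_index(coh)
  expect_equal(nrow(idx), 4)  # cardinality preserved
  expect_equal(idx$nodule_id[idx$participant_id == "A"], "A-N2")
  expect_equal(idx$nodule_id[idx$participant_id == "B"], "B-N2")
  expect_equal(idx$nodule_id[idx$participant_id == "C"], "C-N1")
  expect_false(idx$has_nodule[idx$participant_id == "D"])
  # participants with an index + participants without = all participants
  expect_equal(sum(idx$has_nodule) + sum(!idx$has_nodule), nrow(idx))
})

test_that("largest is resolved by size_key with the documented tie-break", {
  coh <- as_cohort(dplyr::bind_rows(
    make_flat_row("A", nodule_id = "A-N2", volume_mm3 = 100, diameter_mm = 8),
    make_flat_row("A", nodule_id = "A-N1", volume_mm3 = 100, diameter_mm = 8),
    make_flat_row("B", nodule_id = "B-N1", volume_mm3 = 100, diameter_mm = 9),
    make_flat_row("B", nodule_id = "B-N2", volume_mm3 = 90, diameter_mm = 12)
  ))
  idx_v <- reduce_to_index(coh, size_key = "volume")
  # full tie: lexicographically smallest id
  expect_equal(idx_v$nodule_id[idx_v$participant_id == "A"], "A-N1")
  expect_equal(idx_v$nodule_id[idx_v$participant_id == "B"], "B-N1")
  idx_d <- reduce_to_index(coh, size_key = "diameter")
  expect_equal(idx_d$nodule_id[idx_d$participant_id == "B"], "B-N2")
})

test_that("assess_size applies the boundary conventions and fallback cut-offs", {
  rows <- dplyr::bind_rows(
    make_flat_row("A", nodule_id = "a", volume_mm3 = 79, diameter_mm = 5.2),
    make_flat_row("B", nodule_id = "b", volume_mm3 = 80, diameter_mm = 5.3),
    make_flat_row("C", nodule_id = "c", volume_mm3 = 300, diameter_mm = 8.2),
    make_flat_row("D", nodule_id = "d", diameter_mm = 7,
                  segmentation_reliable = FALSE),
    make_flat_row("E")
  )
  idx <- reduce_to_index(as_cohort(rows))
  a <- assess_size(idx, bts_protocol())
  g <- function(id, col) a[[col]][a$participant_id == id]
  expect_true(g("A", "rule_out_pass"))          # 79 < 80
  expect_false(g("B", "rule_out_pass"))         # exactly 80: strict <
  expect_false(g("B", "rule_in_pass"))
  expect_true(g("C", "rule_in_pass"))           # exactly 300: inclusive >=
  # unsegmentable 7 mm against the 6/8 fallback: neither rule fires
  expect_equal(g("D", "size_mode"), "diameter_fallback")
  expect_false(g("D", "rule_out_pass"))
  expect_false(g("D", "rule_in_pass"))
  expect_true(is.na(g("E", "rule_out_pass")))
  # total: every nodule row gets an assessment under every config
  for (p in list(bts_protocol(), eups_protocol(), diameter_protocol())) {
    aa <- assess_size(idx, p)
    expect_true(all(!is.na(aa$rule_out_pass[aa$has_nodule])))
  }
  # diameter-primary mode ignores volumes entirely
  d <- assess_size(idx, diameter_protocol())
  expect_true(all(d$size_unit[d$has_nodule] == "mm"))
})
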