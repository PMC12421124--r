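# Cohort container and delimited-text I/O.
#
# A cohort is a tibble with one row per screening participant and a
# `nodules` list-column holding a tibble of that participant's solid
# nodules (possibly zero rows). Two delimited layouts are supported:
#   * nodule_rows      — one row per nodule, participant columns repeated;
#                        participants with no nodules appear once with the
#                        nodule fields empty. Faithful for multi-nodule
#                        participants.
#   * participant_rows — one row per participant carrying a single (index)
#                        nodule's fields; only valid when no participant
#                        has more than one nodule.
# Empty string means "absent" throughout.

PARTICIPANT_COLS <- c("participant_id", "age_years", "sex", "family_history",
                      "emphysema", "cancer_outcome")
NODULE_COLS <- c("nodule_id", "volume_mm3", "diameter_mm",
                 "segmentation_reliable", "spiculated", "upper_lobe",
                 "perifissural", "retronodule", "malignant")
NODULE_LGL <- c("segmentation_reliable", "spiculated", "upper_lobe",
                "perifissural", "retronodule", "malignant")

empty_nodule_tbl <- function() {
  tibble(
    nodule_id = character(), volume_mm3 = double(), diameter_mm = double(),
    segmentation_reliable = logical(), spiculated = logical(),
    upper_lobe = logical(), perifissural = logical(),
    retronodule = logical(), malignant = logical(),
    brock_probability = double()
  )
}

parse_bool <- function(x) {
  if (is.logical(x)) return(x)
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes", "y")] <- TRUE
  out[x %in% c("false", "f", "0", "no", "n")] <- FALSE
  out[x %in% c("", "na")] <- NA
  bad <- !is.na(x) & x != "" & x != "na" & is.na(out)
  if (any(bad)) {
    stop_schema("cannot interpret '%s' as a logical value", x[which(bad)[1]])
  }
  out
}

#' Assemble a cohort from a flat per-nodule table
#'
#' Groups nodule rows by participant and nests the nodule columns into a
#' `nodules` list-column. Rows whose nodule fields are all empty contribute
#' a participant with zero nodules.
#'
#' @param data Data frame with the participant and nodule columns
#'   (`participant_id`, `age_years`, `sex`, `family_history`, `emphysema`,
#'   `cancer_outcome`, `nodule_id`, `volume_mm3`, `diameter_mm`,
#'   `segmentation_reliable`, `spiculated`, `upper_lobe`, `perifissural`,
#'   `retronodule`, `malignant`, optionally `brock_probability`).
#' @param validate Run invariant checks (default `TRUE`).
#' @return A cohort tibble: one row per participant, nodules nested.
#' @export
as_cohort <- function(data, validate = TRUE) {
  data <- as_tibble(data)
  missing_cols <- setdiff(c(PARTICIPANT_COLS, NODULE_COLS), names(data))
  # brock_probability is optional
  if (length(missing_cols) > 0) {
    stop_schema("missing mandatory column(s): %s",
                paste(missing_cols, collapse = ", "))
  }
  if (!"brock_probability" %in% names(data)) {
    data$brock_probability <- NA_real_
  }
  data <- data |>
    mutate(
      participant_id = as.character(.data$participant_id),
      nodule_id = as.character(.data$nodule_id),
      age_years = as.numeric(.data$age_years),
      sex = tolower(as.character(.data$sex)),
      volume_mm3 = as.numeric(.data$volume_mm3),
      diameter_mm = as.numeric(.data$diameter_mm),
      brock_probability = as.numeric(.data$brock_probability),
      across(all_of(c("family_history", "emphysema", "cancer_outcome",
                      NODULE_LGL)), parse_bool),
      .row = dplyr::row_number()
    )
  if (validate) validate_cohort_rows(data)
  has_nodule_row <- !is.na(data$nodule_id) | !is.na(data$diameter_mm)
  nested <- data |>
    mutate(.has = has_nodule_row) |>
    group_by(.data$participant_id) |>
    summarise(
      age_years = first(.data$age_years),
      sex = first(.data$sex),
      family_history = first(.data$family_history),
      emphysema = first(.data$emphysema),
      cancer_outcome = first(.data$cancer_outcome),
      nodules = list({
        g <- pick(all_of(c(NODULE_COLS, "brock_probability", ".has")))
        if (!any(g$.has)) empty_nodule_tbl() else
          as_tibble(g[g$.has, c(NODULE_COLS, "brock_probability")])
      }),
      .groups = "drop"
    ) |>
    arrange(match(.data$participant_id, unique(data$participant_id)))
  class(nested) <- c("nodule_cohort", class(nested))
  nested
}

validate_cohort_rows <- function(data) {
  has_nod <- !is.na(data$nodule_id) | !is.na(data$diameter_mm)
  problems <- character()
  add <- function(rows, msg) {
    if (length(rows) > 0) {
      problems <<- c(problems, sprintf("row %d: %s", data$.row[rows], msg))
    }
  }
  add(which(has_nod & is.na(data$diameter_mm)),
      "diameter_mm is mandatory for every nodule (manual measurement when segmentation fails)")
  add(which(has_nod & !is.na(data$volume_mm3) &
              !isTRUE_v(data$segmentation_reliable)),
      "volume_mm3 present but segmentation_reliable is not TRUE")
  add(which(has_nod & is.na(data$volume_mm3) &
              isTRUE_v(data$segmentation_reliable)),
      "segmentation_reliable is TRUE but volume_mm3 is absent")
  add(which(has_nod & !is.na(data$volume_mm3) & data$volume_mm3 < 0),
      "volume_mm3 must be non-negative")
  add(which(has_nod & data$diameter_mm < 0), "diameter_mm must be non-negative")
  add(which(!data$sex %in% c("male", "female")),
      "sex must be 'male' or 'female'")
  add(which(has_nod & is.na(data$malignant)),
      "malignant flag is mandatory for every nodule")
  # at most one malignant nodule per participant; malignant nodule implies
  # cancer outcome (1 participant : 1 nodule : 1 cancer)
  per <- data |>
    filter(has_nod) |>
    group_by(.data$participant_id) |>
    summarise(n_mal = sum(.data$malignant, na.rm = TRUE),
              outcome = first(.data$cancer_outcome), .groups = "drop")
  bad_mult <- per$participant_id[per$n_mal > 1]
  if (length(bad_mult) > 0) {
    problems <- c(problems, sprintf(
      "participant %s: more than one malignant nodule", bad_mult))
  }
  bad_out <- per$participant_id[per$n_mal == 1 & !isTRUE_v(per$outcome)]
  if (length(bad_out) > 0) {
    problems <- c(problems, sprintf(
      "participant %s: malignant nodule but cancer_outcome is not TRUE", bad_out))
  }
  if (length(problems) > 0) {
    stop_schema("invalid cohort rows:\n%s",
                paste(head(problems, 10), collapse = "\n"))
  }
  invisible(data)
}

isTRUE_v <- function(x) !is.na(x) & x

#' Read a cohort from delimited text
#'
#' Comma- or tab-delimited UTF-8 text with a mandatory header row. The
#' delimiter is inferred from the header unless given. Empty fields are
#' absent values. Malformed rows are reported with their line numbers.
#'
#' @param path File path.
#' @param layout `"auto"` (default), `"participant_rows"` or
#'   `"nodule_rows"`. `participant_rows` additionally asserts that no
#'   participant id is repeated.
#' @param delim Field delimiter; inferred when `NULL`.
#' @return A cohort tibble (see [as_cohort()]).
#' @export
read_cohort <- function(path, layout = c("auto", "participant_rows", "nodule_rows"),
                        delim = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop_schema("cohort file not found: %s", path)
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           na = character(), progress = FALSE,
                           show_col_types = FALSE)
  raw[raw == ""] <- NA
  if (layout == "participant_rows" && anyDuplicated(raw$participant_id)) {
    stop_schema("layout 'participant_rows' but participant_id '%s' is repeated",
                raw$participant_id[duplicated(raw$participant_id)][1])
  }
  as_cohort(raw)
}

#' Write a cohort to delimited text
#'
#' Inverse of [read_cohort()]: `read_cohort(write_cohort(x, p), layout)`
#' recovers `x` for any valid cohort (the `participant_rows` layout
#' requires every participant to carry at most one nodule).
#'
#' @param cohort Cohort tibble.
#' @param path Output path; a `.tsv` extension selects tab delimiting.
#' @param layout `"nodule_rows"` (default) or `"participant_rows"`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path,
                         layout = c("nodule_rows", "participant_rows")) {
  layout <- match.arg(layout)
  flat <- flatten_cohort(cohort)
  if (layout == "participant_rows" && anyDuplicated(flat$participant_id)) {
    stop_schema("participant_rows layout cannot represent multi-nodule participants; use nodule_rows")
  }
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  readr::write_delim(flat, path, delim = delim, na = "")
  invisible(path)
}

# one row per nodule (participants without nodules keep one all-NA nodule row)
flatten_cohort <- function(cohort) {
  cohort |>
    mutate(nodules = map(.data$nodules, function(n) {
      if (nrow(n) == 0) empty_nodule_tbl()[NA_integer_, ] else n
    })) |>
    tidyr::unnest("nodules") |>
    select(all_of(PARTICIPANT_COLS), all_of(NODULE_COLS), "brock_probability")
}

#' @export
print.nodule_cohort <- function(x, ...) {
  n_nod <- sum(map_lgl(x$nodules, ~ nrow(.x) > 0))
  cat(sprintf("<nodule_cohort> %d participants (%d with >=1 solid nodule, %d cancers)\n",
              nrow(x), n_nod, sum(x$cancer_outcome, na.rm = TRUE)))
  NextMethod()
}
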