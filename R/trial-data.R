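ANALYTES <- c("ALT", "AST", "TB", "ALP")

#' Describe a two-arm trial
#'
#' @param active label of the active (study drug) arm.
#' @param comparator label of the comparator/placebo arm.
#' @param treatment_end_day last dosing day (global). `NULL` means the last
#'   observed study day in the data.
#' @param followup_lag_days days past `treatment_end_day` still counted as
#'   on-treatment follow-up (default 30).
#' @return An object of class `trial_manifest`.
#' @export
trial_manifest <- function(active, comparator, treatment_end_day = NULL,
                           followup_lag_days = 30) {
  stopifnot(is.character(active), length(active) == 1,
            is.character(comparator), length(comparator) == 1,
            followup_lag_days >= 0)
  if (identical(active, comparator)) {
    stop("active and comparator arm labels must differ", call. = FALSE)
  }
  structure(list(active = active, comparator = comparator,
                 treatment_end_day = treatment_end_day,
                 followup_lag_days = followup_lag_days),
            class = "trial_manifest")
}

#' @export
print.trial_manifest <- function(x, ...) {
  cat("<trial_manifest> active =", x$active, "| comparator =", x$comparator,
      "| end day =", x$treatment_end_day %||% "last observed",
      "| follow-up lag =", x$followup_lag_days, "days\n")
  invisible(x)
}

#' Column mapping presets for laboratory CSVs
#'
#' `standard` expects columns named after the record fields themselves;
#' `sdtm` maps SDTM LB-domain style columns (USUBJID, ARM, LBTESTCD, LBDY,
#' LBSTRESN, LBSTNRHI), translating the test code `BILI` to `TB`.
#'
#' @param preset `"standard"` or `"sdtm"`.
#' @return Named character vector `c(<record field> = <source column>)`.
#' @export
lab_column_preset <- function(preset = c("standard", "sdtm")) {
  preset <- match.arg(preset)
  switch(preset,
    standard = c(subject_id = "subject_id", arm = "arm", analyte = "analyte",
                 study_day = "study_day", value = "value", uln = "uln"),
    sdtm = c(subject_id = "USUBJID", arm = "ARM", analyte = "LBTESTCD",
             study_day = "LBDY", value = "LBSTRESN", uln = "LBSTNRHI")
  )
}

#' Read and validate long-format laboratory data
#'
#' Reads a subject-level long CSV of serial liver tests, validates it, and
#' resolves duplicates. Rows whose numeric fields do not parse, whose analyte
#' is not one of ALT/AST/TB/ALP, or whose value/ULN violate `value >= 0`,
#' `uln > 0` are dropped and tallied in the ingest report. Duplicate
#' (subject, analyte, day) triples keep the maximum value (conservative for
#' safety screening); collisions are counted.
#'
#' @param path CSV file path.
#' @param column_map named character vector mapping record fields
#'   (`subject_id`, `arm`, `analyte`, `study_day`, `value`, `uln`) to source
#'   column names; defaults to [lab_column_preset()] for `preset`.
#' @param preset used when `column_map` is `NULL`.
#' @param active_arm label of the active arm; defaults to the last arm label
#'   in sort order (override for real data).
#' @param treatment_end_day,followup_lag_days passed to [trial_manifest()].
#' @return A list of class `lab_data`: `records` (tibble of validated
#'   records), `manifest` ([trial_manifest]) and `report` (tibble of ingest
#'   drop/collision counts).
#' @export
read_lab_csv <- function(path, column_map = NULL,
                         preset = c("standard", "sdtm"),
                         active_arm = NULL, treatment_end_day = NULL,
                         followup_lag_days = 30) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  column_map <- column_map %||% lab_column_preset(match.arg(preset))
  needed <- c("subject_id", "arm", "analyte", "study_day", "value", "uln")
  missing_fields <- setdiff(needed, names(column_map))
  if (length(missing_fields)) {
    stop("column_map lacks field(s): ", paste(missing_fields, collapse = ", "),
         call. = FALSE)
  }
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  if (nrow(raw) == 0) stop("empty laboratory file: ", path, call. = FALSE)
  missing_cols <- setdiff(unname(column_map[needed]), names(raw))
  if (length(missing_cols)) {
    stop("mapped column(s) absent from file: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  recs <- tibble(
    subject_id = as.character(raw[[column_map[["subject_id"]]]]),
    arm = as.character(raw[[column_map[["arm"]]]]),
    analyte = toupper(as.character(raw[[column_map[["analyte"]]]])),
    study_day = suppressWarnings(as.integer(raw[[column_map[["study_day"]]]])),
    value = suppressWarnings(as.numeric(raw[[column_map[["value"]]]])),
    uln = suppressWarnings(as.numeric(raw[[column_map[["uln"]]]]))
  )
  recs$analyte[recs$analyte == "BILI"] <- "TB"
  validated <- validate_lab_records(recs)
  arms <- sort(unique(validated$records$arm))
  active <- active_arm %||% arms[length(arms)]
  comparator <- setdiff(arms, active)[1]
  if (is.na(comparator)) {
    stop("need two arms; found: ", paste(arms, collapse = ", "), call. = FALSE)
  }
  structure(list(records = validated$records,
                 manifest = trial_manifest(active, comparator,
                                           treatment_end_day,
                                           followup_lag_days),
                 report = validated$report),
            class = "lab_data")
}

#' Validate in-memory laboratory records
#'
#' Applies the same drop and duplicate-resolution rules as [read_lab_csv()]
#' to a tibble of records.
#'
#' @param records tibble with columns `subject_id`, `arm`, `analyte`,
#'   `study_day`, `value`, `uln`.
#' @return List with `records` (clean tibble) and `report` (tibble of
#'   `reason`, `n`).
#' @export
validate_lab_records <- function(records) {
  records <- as_tibble(records)
  n0 <- nrow(records)
  bad_parse <- is.na(records$value) | is.na(records$uln) |
    is.na(records$study_day) | is.na(records$subject_id) | is.na(records$arm)
  bad_analyte <- !(records$analyte %in% ANALYTES) & !bad_parse
  bad_range <- !bad_parse & !bad_analyte &
    (records$value < 0 | records$uln <= 0)
  keep <- records[!(bad_parse | bad_analyte | bad_range), , drop = FALSE]

  deduped <- keep |>
    group_by(.data$subject_id, .data$arm, .data$analyte, .data$study_day) |>
    summarise(uln = .data$uln[which.max(.data$value)],
              value = max(.data$value), .n = n(), .groups = "drop")
  collisions <- sum(deduped$.n > 1)
  records_out <- deduped |>
    select("subject_id", "arm", "analyte", "study_day", "value", "uln") |>
    arrange(.data$subject_id, .data$analyte, .data$study_day)

  report <- tibble(
    reason = c("unparseable", "unknown_analyte", "out_of_range",
               "duplicate_collision"),
    n = c(sum(bad_parse), sum(bad_analyte), sum(bad_range), collisions)
  )
  list(records = records_out, report = report)
}

#' Write laboratory records back to CSV
#'
#' Writes the standard-dialect CSV that [read_lab_csv()] reads, so simulated
#' trials and fixtures round-trip.
#'
#' @param records tibble of validated records.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lab_csv <- function(records, path) {
  readr::write_csv(records, path)
  invisible(path)
}

#' Derive per-subject per-analyte baselines
#'
#' Baseline is the value at the largest `study_day <= 0` (a day-0 pre-dose
#' draw counts as baseline). Subjects without any pre-dose value for an
#' analyte have no row for it; [derive_profiles()] flags them.
#'
#' @param records validated records tibble (or a `lab_data` bundle).
#' @return Tibble with `subject_id`, `arm`, `analyte`, `baseline_day`,
#'   `baseline`, `uln`, `baseline_xuln`.
#' @export
derive_baseline <- function(records) {
  records <- as_lab_records(records)
  records |>
    filter(.data$study_day <= 0) |>
    group_by(.data$subject_id, .data$arm, .data$analyte) |>
    slice_max(.data$study_day, n = 1, with_ties = FALSE) |>
    ungroup() |>
    mutate(baseline_xuln = .data$value / .data$uln) |>
    select("subject_id", "arm", "analyte",
           baseline_day = "study_day", baseline = "value", "uln",
           "baseline_xuln")
}

as_lab_records <- function(x) {
  if (inherits(x, "lab_data")) x$records else as_tibble(x)
}

#' Derive subject profiles: baselines, on-treatment peaks and troughs
#'
#' The on-treatment window is `study_day` in `(0, treatment_end_day +
#' followup_lag_days]`. For each subject and analyte the profile carries the
#' baseline, the on-treatment peak (and its day) and trough, and the peak in
#' multiples of ULN (`peak_xuln`) and of the subject's own baseline
#' (`peak_xbl`; `NA` and flagged when the baseline is zero or missing).
#'
#' A pseudo-analyte `AT` is added for quadrant work. Under the default
#' ALT-only policy it duplicates the ALT rows. Under `max_alt_ast` the AT
#' value on each study day is the larger of the ALT and AST multiples of ULN
#' (the classical eDISH convention "ALT or AST"); AT rows then store xULN
#' directly with `uln = 1`, since an absolute unit is ill-defined across two
#' enzymes.
#'
#' @param records validated records tibble or `lab_data` bundle.
#' @param manifest a [trial_manifest()]; taken from the bundle if absent.
#' @param at_policy `"ALT"` or `"max_alt_ast"`.
#' @return Tibble of class `subject_profiles`, one row per subject x analyte
#'   (including `AT`), with flags `has_baseline`, `has_on_treatment`,
#'   `analyzable` and `xbl_defined`.
#' @export
derive_profiles <- function(records, manifest = NULL,
                            at_policy = c("ALT", "max_alt_ast")) {
  at_policy <- match.arg(at_policy)
  if (inherits(records, "lab_data") && is.null(manifest)) {
    manifest <- records$manifest
  }
  records <- as_lab_records(records)
  if (is.null(manifest)) stop("a trial_manifest is required", call. = FALSE)
  end_day <- manifest$treatment_end_day %||% max(records$study_day)
  window_end <- end_day + manifest$followup_lag_days

  recs <- records |> mutate(xuln = .data$value / .data$uln)
  at_rows <- if (at_policy == "ALT") {
    recs |> filter(.data$analyte == "ALT") |> mutate(analyte = "AT")
  } else {
    recs |>
      filter(.data$analyte %in% c("ALT", "AST")) |>
      group_by(.data$subject_id, .data$arm, .data$study_day) |>
      summarise(xuln = max(.data$xuln), .groups = "drop") |>
      mutate(analyte = "AT", value = .data$xuln, uln = 1)
  }
  recs <- bind_rows(recs, at_rows)

  base <- recs |>
    filter(.data$study_day <= 0) |>
    group_by(.data$subject_id, .data$arm, .data$analyte) |>
    slice_max(.data$study_day, n = 1, with_ties = FALSE) |>
    ungroup() |>
    select("subject_id", "arm", "analyte", baseline_day = "study_day",
           baseline = "value", baseline_xuln = "xuln")

  on_trt <- recs |>
    filter(.data$study_day > 0, .data$study_day <= window_end) |>
    group_by(.data$subject_id, .data$arm, .data$analyte) |>
    summarise(uln = .data$uln[1],
              peak = max(.data$value),
              peak_day = .data$study_day[which.max(.data$value)],
              trough = min(.data$value),
              trough_day = .data$study_day[which.min(.data$value)],
              .groups = "drop") |>
    mutate(peak_xuln = .data$peak / .data$uln,
           trough_xuln = .data$trough / .data$uln)

  enrolled <- recs |> distinct(.data$subject_id, .data$arm, .data$analyte)
  prof <- enrolled |>
    left_join(base, by = c("subject_id", "arm", "analyte")) |>
    left_join(on_trt, by = c("subject_id", "arm", "analyte")) |>
    mutate(
      has_baseline = !is.na(.data$baseline),
      has_on_treatment = !is.na(.data$peak),
      analyzable = .data$has_baseline & .data$has_on_treatment,
      xbl_defined = .data$has_baseline & !is.na(.data$baseline) &
        .data$baseline > 0,
      peak_xbl = ifelse(.data$xbl_defined & .data$has_on_treatment,
                        .data$peak / .data$baseline, NA_real_)
    ) |>
    arrange(.data$subject_id, .data$analyte)

  structure(prof, class = c("subject_profiles", class(prof)),
            at_policy = at_policy, manifest = manifest)
}

#' Spread profiles to one row per subject
#'
#' Convenience pivot used by the categorization and plotting layers: peak and
#' baseline multiples for the AT, ALT, TB (and ALP if present) analytes as
#' columns.
#'
#' @param profiles a [derive_profiles()] result.
#' @return Tibble, one row per subject.
#' @export
profiles_wide <- function(profiles) {
  profiles |>
    as_tibble() |>
    select("subject_id", "arm", "analyte", "baseline", "baseline_xuln",
           "peak", "peak_xuln", "peak_xbl", "trough", "analyzable",
           "xbl_defined") |>
    tidyr::pivot_wider(
      names_from = "analyte",
      values_from = c("baseline", "baseline_xuln", "peak", "peak_xuln",
                      "peak_xbl", "trough", "analyzable", "xbl_defined"),
      names_glue = "{tolower(analyte)}_{.value}"
    )
}

#' Write the derived-profile audit CSV
#'
#' @param profiles a [derive_profiles()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profiles_csv <- function(profiles, path) {
  readr::write_csv(as_tibble(profiles), path)
  invisible(path)
}
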