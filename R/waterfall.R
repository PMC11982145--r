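#' Check modified-waterfall applicability
#'
#' The modified waterfall plot assumes baseline total bilirubin is in the
#' normal/near-normal range for (essentially) all subjects, as when trial
#' entry criteria exclude jaundice. It is applicable when the fraction of
#' subjects with baseline TB above the jaundice cut is at most
#' `max_baseline_jaundice_fraction`.
#'
#' @param profiles a [derive_profiles()] result.
#' @param scheme a [banding_scheme()] (supplies the TB jaundice cut).
#' @param max_baseline_jaundice_fraction tolerated fraction of
#'   baseline-jaundiced subjects (default 0.02).
#' @return List of class `waterfall_applicability`: `applicable`,
#'   `jaundice_fraction`, `n_subjects` and `offenders` (tibble naming the
#'   baseline-jaundiced subjects).
#' @export
check_applicability <- function(profiles, scheme = banding_scheme(),
                                max_baseline_jaundice_fraction = 0.02) {
  wide <- profiles_wide(profiles)
  if (!"tb_baseline_xuln" %in% names(wide)) {
    stop("profiles lack TB rows", call. = FALSE)
  }
  with_tb <- wide |> filter(!is.na(.data$tb_baseline_xuln))
  if (nrow(with_tb) == 0) stop("no subjects with TB baselines", call. = FALSE)
  offenders <- with_tb |>
    filter(.data$tb_baseline_xuln > scheme$tb_cut) |>
    select("subject_id", "arm", "tb_baseline_xuln")
  frac <- nrow(offenders) / nrow(with_tb)
  structure(list(applicable = frac <= max_baseline_jaundice_fraction,
                 jaundice_fraction = frac,
                 n_subjects = nrow(with_tb),
                 threshold = max_baseline_jaundice_fraction,
                 offenders = offenders),
            class = "waterfall_applicability")
}

#' @export
print.waterfall_applicability <- function(x, ...) {
  cat("<waterfall_applicability>",
      if (x$applicable) "applicable" else "NOT applicable",
      sprintf("(baseline jaundice %d of %d = %.2f%%, threshold %.2f%%)\n",
              nrow(x$offenders), x$n_subjects, 100 * x$jaundice_fraction,
              100 * x$threshold))
  invisible(x)
}

#' Build the modified waterfall plot data
#'
#' Subjects are ordered along the horizontal axis by baseline ALT (U/L):
#' comparator (placebo) subjects first, lowest to highest, then active-arm
#' subjects highest to lowest, so the black baseline profile peaks in the
#' middle of the figure. Each subject's bar shows the on-treatment ALT
#' change from baseline:
#'
#' * `max_magnitude` (default): the signed change of largest absolute size
#'   (increase or decrease); when the two magnitudes tie, the increase is
#'   kept (safety-conservative). This captures efficacy but can mask a DILI
#'   rise smaller than the subject's largest decline.
#' * `max_increase`: always `max(on-treatment ALT) - baseline`, focusing on
#'   DILI risk.
#'
#' `new_jaundice` marks subjects whose peak TB crossed the jaundice cut on
#' treatment from a non-jaundiced baseline.
#'
#' @param profiles a [derive_profiles()] result.
#' @param manifest a [trial_manifest()]; defaults to the one stored on
#'   `profiles`.
#' @param mode `"max_magnitude"` or `"max_increase"`.
#' @param scheme a [banding_scheme()] (jaundice cut).
#' @return Object of class `dili_waterfall`: list with `entries` (ordered
#'   tibble: `subject_id`, `arm`, `baseline_alt`, `bar_value`,
#'   `new_jaundice`, `rank`), `summaries` (per-arm Tukey box-whisker stats
#'   of `bar_value`) and `mode`.
#' @export
build_waterfall <- function(profiles, manifest = NULL,
                            mode = c("max_magnitude", "max_increase"),
                            scheme = banding_scheme()) {
  mode <- match.arg(mode)
  manifest <- manifest %||% attr(profiles, "manifest")
  if (is.null(manifest)) stop("a trial_manifest is required", call. = FALSE)
  wide <- profiles_wide(profiles)
  if (!all(c("alt_analyzable", "alt_baseline", "alt_peak", "alt_trough") %in%
             names(wide))) {
    stop("profiles lack ALT rows", call. = FALSE)
  }
  dat <- wide |> filter(.data$alt_analyzable)
  rise <- dat$alt_peak - dat$alt_baseline
  fall <- dat$alt_trough - dat$alt_baseline
  bar <- switch(mode,
    max_magnitude = ifelse(abs(rise) >= abs(fall), rise, fall),
    max_increase = rise
  )
  tb_base <- if ("tb_baseline_xuln" %in% names(wide)) dat$tb_baseline_xuln else NA_real_
  tb_peak <- if ("tb_peak_xuln" %in% names(wide)) dat$tb_peak_xuln else NA_real_
  new_jaundice <- !is.na(tb_peak) & tb_peak > scheme$tb_cut &
    !is.na(tb_base) & tb_base <= scheme$tb_cut

  entries <- dat |>
    mutate(baseline_alt = .data$alt_baseline, bar_value = .env$bar,
           new_jaundice = .env$new_jaundice) |>
    select("subject_id", "arm", "baseline_alt", "bar_value", "new_jaundice")
  placebo <- entries |>
    filter(.data$arm == manifest$comparator) |>
    arrange(.data$baseline_alt, .data$subject_id)
  active <- entries |>
    filter(.data$arm == manifest$active) |>
    arrange(desc(.data$baseline_alt), .data$subject_id)
  entries <- bind_rows(placebo, active) |> mutate(rank = row_number())

  summaries <- entries |>
    group_by(.data$arm) |>
    summarise(box = list(grDevices::boxplot.stats(.data$bar_value)),
              .groups = "drop") |>
    mutate(n = purrr::map_int(.data$box, ~ .x$n),
           whisker_low = purrr::map_dbl(.data$box, ~ .x$stats[1]),
           q1 = purrr::map_dbl(.data$box, ~ .x$stats[2]),
           median = purrr::map_dbl(.data$box, ~ .x$stats[3]),
           q3 = purrr::map_dbl(.data$box, ~ .x$stats[4]),
           whisker_high = purrr::map_dbl(.data$box, ~ .x$stats[5]),
           outliers = purrr::map(.data$box, ~ .x$out)) |>
    select(-"box")

  structure(list(entries = entries, summaries = summaries, mode = mode,
                 manifest = manifest, scheme = scheme),
            class = "dili_waterfall")
}

#' @export
print.dili_waterfall <- function(x, ...) {
  cat("<dili_waterfall> mode:", x$mode, "|", nrow(x$entries), "subjects |",
      sum(x$entries$new_jaundice), "with new-onset jaundice\n")
  print(x$summaries |> select(-"outliers"))
  invisible(x)
}

#' @export
tidy.dili_waterfall <- function(x, ...) x$entries

#' @export
glance.dili_waterfall <- function(x, ...) {
  x$summaries |>
    select(-"outliers") |>
    mutate(mode = x$mode, .before = 1)
}

#' Export waterfall entries as CSV
#'
#' @param waterfall a [build_waterfall()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_waterfall_csv <- function(waterfall, path) {
  readr::write_csv(waterfall$entries, path)
  invisible(path)
}
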