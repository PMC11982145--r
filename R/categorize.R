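#' Build per-subject baseline-to-peak shift records
#'
#' Assigns each analyzable subject an origin category (baseline AT and TB in
#' xULN) and a destination category (on-treatment peak AT and TB in xULN),
#' then classifies the shift direction on the category lattice.
#'
#' @param profiles a [derive_profiles()] result.
#' @param scheme a [banding_scheme()].
#' @return Tibble of class `shift_records`: `subject_id`, `arm`, `origin`,
#'   `destination`, `direction`, plus the four multiples used. Subjects not
#'   analyzable for both AT and TB are excluded; they are listed in the
#'   `excluded` attribute with a reason.
#' @export
shift_records <- function(profiles, scheme = banding_scheme()) {
  wide <- profiles_wide(profiles)
  need <- c("at_analyzable", "tb_analyzable")
  miss <- setdiff(need, names(wide))
  if (length(miss)) {
    stop("profiles lack analytes required for categorization (AT, TB)",
         call. = FALSE)
  }
  ok <- wide$at_analyzable & wide$tb_analyzable
  excluded <- wide |>
    filter(!.env$ok) |>
    mutate(reason = ifelse(!.data$at_analyzable,
                           "AT baseline or on-treatment value missing",
                           "TB baseline or on-treatment value missing")) |>
    select("subject_id", "arm", "reason")
  dat <- wide |> filter(.env$ok)
  out <- dat |>
    mutate(
      origin = assign_quadrant(.data$at_baseline_xuln, .data$tb_baseline_xuln,
                               scheme),
      destination = assign_quadrant(.data$at_peak_xuln, .data$tb_peak_xuln,
                                    scheme),
      direction = classify_shift(.data$origin, .data$destination, scheme)
    ) |>
    select("subject_id", "arm", "origin", "destination", "direction",
           baseline_at_xuln = "at_baseline_xuln",
           baseline_tb_xuln = "tb_baseline_xuln",
           peak_at_xuln = "at_peak_xuln", peak_tb_xuln = "tb_peak_xuln")
  structure(out, class = c("shift_records", class(out)),
            excluded = excluded, scheme = scheme)
}

#' Classify a trial's baseline status (NNN-BL vs ABN-BL)
#'
#' A trial is abnormal-baseline (ABN-BL) when more than
#' `abnormal_fraction_threshold` of its subjects have baseline ALT at or
#' above `nnn_alt_cut` xULN or baseline TB at or above `nnn_tb_cut` xULN;
#' otherwise it is normal/near-normal-baseline (NNN-BL). The ALT cut may be
#' set anywhere in the conventional 2-3 xULN range.
#'
#' @param profiles a [derive_profiles()] result.
#' @param nnn_alt_cut ALT cut in xULN (default 3; 2 is also conventional).
#' @param nnn_tb_cut TB cut in xULN (default 2).
#' @param abnormal_fraction_threshold fraction of abnormal-baseline subjects
#'   above which the trial is called ABN-BL (default 0.05).
#' @param scheme banding scheme used for the per-category baseline summary.
#' @return List of class `trial_baseline_class`: `status` (`"NNN-BL"` or
#'   `"ABN-BL"`), `abnormal_fraction`, `n_subjects`, `baseline_categories`
#'   (per-arm counts and whole-number percents) and the [baseline_pattern()]
#'   consumed by [recommend_tools()].
#' @export
classify_trial_baseline <- function(profiles, nnn_alt_cut = 3,
                                    nnn_tb_cut = 2,
                                    abnormal_fraction_threshold = 0.05,
                                    scheme = banding_scheme()) {
  stopifnot(nnn_alt_cut >= 2, nnn_alt_cut <= 3)
  wide <- profiles_wide(profiles)
  wide <- wide |>
    filter(!is.na(.data$alt_baseline_xuln) | !is.na(.data$tb_baseline_xuln))
  if (nrow(wide) == 0) stop("no subjects with baseline values", call. = FALSE)
  abn <- (!is.na(wide$alt_baseline_xuln) &
            wide$alt_baseline_xuln >= nnn_alt_cut) |
    (!is.na(wide$tb_baseline_xuln) & wide$tb_baseline_xuln >= nnn_tb_cut)
  frac <- mean(abn)

  with_cat <- wide |>
    filter(!is.na(.data$at_baseline_xuln), !is.na(.data$tb_baseline_xuln)) |>
    mutate(category = assign_quadrant(.data$at_baseline_xuln,
                                      .data$tb_baseline_xuln, scheme))
  cats <- with_cat |>
    count(.data$arm, .data$category, .drop = FALSE) |>
    group_by(.data$arm) |>
    mutate(arm_n = sum(.data$n),
           percent = report_proportion(.data$n, pmax(.data$arm_n, 1L))) |>
    ungroup()

  structure(list(
    status = if (frac > abnormal_fraction_threshold) "ABN-BL" else "NNN-BL",
    abnormal_fraction = frac,
    n_subjects = nrow(wide),
    nnn_alt_cut = nnn_alt_cut, nnn_tb_cut = nnn_tb_cut,
    abnormal_fraction_threshold = abnormal_fraction_threshold,
    baseline_categories = cats,
    pattern = baseline_pattern(profiles, scheme = scheme)
  ), class = "trial_baseline_class")
}

#' @export
print.trial_baseline_class <- function(x, ...) {
  cat("<trial_baseline_class>", x$status,
      sprintf("(abnormal-baseline fraction %.1f%% over %d subjects)\n",
              100 * x$abnormal_fraction, x$n_subjects))
  print(x$baseline_categories)
  invisible(x)
}

#' @export
tidy.trial_baseline_class <- function(x, ...) x$baseline_categories

#' @export
glance.trial_baseline_class <- function(x, ...) {
  tibble(status = x$status, abnormal_fraction = x$abnormal_fraction,
         n_subjects = x$n_subjects)
}
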