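#' Summarise a trial's baseline ALT/TB pattern
#'
#' Computes the fractions the tool advisor consumes: the fraction of
#' subjects with baseline ALT at or above the elevated cut, and the
#' fractions of subjects in the three baseline TB bands (<= 1.5, (1.5, 2],
#' > 2 xULN).
#'
#' @param profiles a [derive_profiles()] result.
#' @param scheme a [banding_scheme()] (supplies the ALT cut; the TB bands
#'   use the conventional 1.5/2 xULN edges).
#' @return List of class `baseline_pattern`: `alt_high_fraction`,
#'   `tb_bands` (named fractions summing to 1), `n_subjects`.
#' @export
baseline_pattern <- function(profiles, scheme = banding_scheme()) {
  wide <- profiles_wide(profiles)
  dat <- wide |>
    filter(!is.na(.data$alt_baseline_xuln), !is.na(.data$tb_baseline_xuln))
  if (nrow(dat) == 0) stop("no subjects with ALT and TB baselines", call. = FALSE)
  tb <- dat$tb_baseline_xuln
  tb_bands <- c(le_1.5 = mean(tb <= scheme$tb_mid),
                mid_1.5_2 = mean(tb > scheme$tb_mid & tb <= scheme$tb_cut),
                gt_2 = mean(tb > scheme$tb_cut))
  structure(list(
    alt_high_fraction = mean(dat$alt_baseline_xuln >= scheme$alt_cut),
    tb_bands = tb_bands,
    n_subjects = nrow(dat)
  ), class = "baseline_pattern")
}

#' Construct a baseline pattern from known fractions
#'
#' Useful for asking "what would the advisor say" about an archetypal
#' population without subject-level data.
#'
#' @param alt_high_fraction fraction of subjects with baseline ALT at or
#'   above the elevated cut.
#' @param tb_le_1.5,tb_mid_1.5_2,tb_gt_2 fractions of subjects in the three
#'   baseline TB bands; must sum to 1.
#' @param n_subjects nominal population size.
#' @return A `baseline_pattern` object.
#' @export
as_baseline_pattern <- function(alt_high_fraction, tb_le_1.5, tb_mid_1.5_2,
                                tb_gt_2, n_subjects = NA_integer_) {
  tb <- c(le_1.5 = tb_le_1.5, mid_1.5_2 = tb_mid_1.5_2, gt_2 = tb_gt_2)
  if (abs(sum(tb) - 1) > 1e-6 || any(tb < 0)) {
    stop("TB band fractions must be non-negative and sum to 1", call. = FALSE)
  }
  stopifnot(alt_high_fraction >= 0, alt_high_fraction <= 1)
  structure(list(alt_high_fraction = alt_high_fraction, tb_bands = tb,
                 n_subjects = n_subjects),
            class = "baseline_pattern")
}

#' @export
print.baseline_pattern <- function(x, ...) {
  cat(sprintf("<baseline_pattern> n = %d | ALT >= cut: %.1f%% | TB bands <=1.5 / 1.5-2 / >2: %.1f%% / %.1f%% / %.1f%%\n",
              x$n_subjects, 100 * x$alt_high_fraction,
              100 * x$tb_bands[1], 100 * x$tb_bands[2], 100 * x$tb_bands[3]))
  invisible(x)
}

#' Recommend screening tools from the baseline pattern
#'
#' Encodes the applicability rules for the two toolsets by the degree and
#' type of baseline abnormality present in a substantial proportion of
#' subjects:
#'
#' * Sankey plots with cross-tables and composite plotting apply across all
#'   abnormal-baseline patterns.
#' * The modified waterfall applies only when the substantial baseline TB
#'   mass sits at or below 2 xULN (no substantial baseline jaundice), e.g.
#'   non-cirrhotic chronic liver disease with low TB; it is not recommended
#'   when baseline TB > 2 xULN is substantial (e.g. alcoholic hepatitis,
#'   biliary atresia, or quiescent cirrhosis with high TB).
#'
#' When no baseline abnormality is substantial at all, the trial is a
#' normal/near-normal-baseline trial and classical eDISH applies.
#'
#' @param pattern a [baseline_pattern()] (or a [derive_profiles()] result,
#'   from which one is computed).
#' @param substantial_threshold fraction above which a baseline pattern
#'   counts as "substantial" (default 0.05).
#' @return Object of class `tool_recommendation`: tibble with one row per
#'   tool (`tool`, `recommendation`, `rationale`), plus attributes
#'   `edish_applies` and the input fractions.
#' @export
recommend_tools <- function(pattern, substantial_threshold = 0.05) {
  if (inherits(pattern, "subject_profiles")) {
    pattern <- baseline_pattern(pattern)
  }
  stopifnot(inherits(pattern, "baseline_pattern"))
  subst <- function(f) f > substantial_threshold
  alt_high <- subst(pattern$alt_high_fraction)
  tb_high <- subst(pattern$tb_bands[["gt_2"]])
  tb_mid <- subst(pattern$tb_bands[["mid_1.5_2"]])
  any_abnormal <- alt_high || tb_high || tb_mid
  edish_applies <- !any_abnormal

  sankey_rat <- if (any_abnormal) {
    "baseline abnormality is substantial; category-shift Sankey plots with cross-tables and composite plotting retain all three screening functions"
  } else {
    "baselines are normal/near-normal; classical eDISH suffices, but shift plots remain valid"
  }
  waterfall_ok <- !tb_high
  waterfall_rat <- if (!waterfall_ok) {
    sprintf("baseline TB > 2xULN in a substantial proportion (%.1f%% > %.1f%%); baseline-anchored ALT bars cannot separate new-onset jaundice",
            100 * pattern$tb_bands[["gt_2"]], 100 * substantial_threshold)
  } else {
    "baseline TB is restricted to <= 2xULN (no substantial baseline jaundice); a single modified waterfall can show shift, severity and case identification"
  }

  out <- tibble(
    tool = c("sankey_crosstab_composite", "modified_waterfall"),
    recommendation = c("recommended",
                       if (waterfall_ok) "recommended" else "not_recommended"),
    rationale = c(sankey_rat, waterfall_rat)
  )
  structure(out, class = c("tool_recommendation", class(out)),
            edish_applies = edish_applies, pattern = pattern,
            substantial_threshold = substantial_threshold)
}

#' @export
print.tool_recommendation <- function(x, ...) {
  cat("<tool_recommendation>\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-26s %s\n    %s\n", x$tool[i], x$recommendation[i],
                x$rationale[i]))
  }
  if (isTRUE(attr(x, "edish_applies"))) {
    cat("  note: no substantial baseline abnormality; classical eDISH applies\n")
  }
  invisible(x)
}

#' @export
tidy.tool_recommendation <- function(x, ...) as_tibble(x)
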