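## tiny builders for hand-constructed laboratory records

lab_rows <- function(subject_id, arm, analyte, study_day, value,
                     uln = if (analyte == "TB") 1.2 else 40) {
  tibble::tibble(subject_id = subject_id, arm = arm, analyte = analyte,
                 study_day = as.integer(study_day), value = value, uln = uln)
}

## one subject with ALT and TB series; days/values given as named lists
make_subject <- function(id, arm, alt, tb, alt_uln = 40, tb_uln = 1.2) {
  dplyr::bind_rows(
    lab_rows(id, arm, "ALT", as.integer(names(alt)), unname(unlist(alt)),
             alt_uln),
    lab_rows(id, arm, "TB", as.integer(names(tb)), unname(unlist(tb)),
             tb_uln)
  )
}

default_manifest <- function(end = 100, lag = 0) {
  trial_manifest("Active", "Placebo", treatment_end_day = end,
                 followup_lag_days = lag)
}

## independent brute-force categorizer: two plain if statements on the
## classical cuts, written without reference to banding_scheme()
oracle_quadrant <- function(at, tb) {
  if (at >= 3) {
    if (tb > 2) "HyLaw" else "Temple"
  } else {
    if (tb > 2) "Cholestasis" else "NNN"
  }
}

## two-arm toy trial: named vectors baseline/peak multiples per subject
two_arm_profiles <- function(tbl, end = 100) {
  recs <- purrr::pmap_dfr(tbl, function(id, arm, alt_b, alt_p, tb_b, tb_p,
                                        ...) {
    make_subject(id, arm,
                 alt = stats::setNames(c(alt_b, alt_p) * 40, c(-1, 28)),
                 tb = stats::setNames(c(tb_b, tb_p) * 1.2, c(-1, 28)))
  })
  derive_profiles(recs, default_manifest(end))
}
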