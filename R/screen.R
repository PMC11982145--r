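#' Build a screening run configuration
#'
#' A plain, YAML-serializable list of everything [run_screen()] needs. The
#' `input` is either a lab CSV path or one of the built-in sources
#' `"study1"`, `"study2"` (deterministic fixtures) or `"simulate"` (a
#' [simulate_trial()] draw using `seed`).
#'
#' @param input CSV path or `"study1"`, `"study2"`, `"simulate"`.
#' @param out_dir output directory (created if missing).
#' @param column_preset `"standard"` or `"sdtm"` (CSV inputs).
#' @param active_arm active-arm label for CSV inputs.
#' @param alt_cut,tb_cut,extra_tb_band,split_nnn banding scheme parameters
#'   (see [banding_scheme()]).
#' @param at_policy `"ALT"` or `"max_alt_ast"`.
#' @param treatment_end_day,followup_lag_days on-treatment window (see
#'   [trial_manifest()]).
#' @param waterfall_mode `"max_magnitude"` or `"max_increase"`.
#' @param severity_lines waterfall ALT cut-offs in U/L.
#' @param jaundice_threshold waterfall applicability threshold (fraction of
#'   baseline-jaundiced subjects).
#' @param substantial_threshold advisor "substantial proportion" threshold.
#' @param force_waterfall build the waterfall even when not applicable.
#' @param active_only restrict the priority list to the active arm.
#' @param seed RNG seed (only used by `input = "simulate"`).
#' @return List of class `run_config`.
#' @export
run_config <- function(input, out_dir,
                       column_preset = "standard", active_arm = NULL,
                       alt_cut = 3, tb_cut = 2, extra_tb_band = FALSE,
                       split_nnn = FALSE, at_policy = "ALT",
                       treatment_end_day = NULL, followup_lag_days = 30,
                       waterfall_mode = "max_magnitude",
                       severity_lines = c(300, 600, 900),
                       jaundice_threshold = 0.02,
                       substantial_threshold = 0.05,
                       force_waterfall = FALSE, active_only = FALSE,
                       seed = 1) {
  structure(list(
    input = input, out_dir = out_dir, column_preset = column_preset,
    active_arm = active_arm, alt_cut = alt_cut, tb_cut = tb_cut,
    extra_tb_band = extra_tb_band, split_nnn = split_nnn,
    at_policy = at_policy, treatment_end_day = treatment_end_day,
    followup_lag_days = followup_lag_days,
    waterfall_mode = waterfall_mode, severity_lines = severity_lines,
    jaundice_threshold = jaundice_threshold,
    substantial_threshold = substantial_threshold,
    force_waterfall = force_waterfall, active_only = active_only,
    seed = seed
  ), class = "run_config")
}

#' Save / load a run configuration as YAML
#'
#' `load_run_config(save_run_config(cfg, path))` reproduces `cfg`.
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return `save_run_config()` returns `path` invisibly;
#'   `load_run_config()` returns the `run_config`.
#' @export
save_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw[!vapply(raw, is.null, logical(1))])
}

screen_input <- function(config) {
  switch(config$input,
    study1 = study1_fixture(),
    study2 = study2_fixture(),
    simulate = simulate_trial(synthetic_spec(seed = config$seed)),
    read_lab_csv(config$input, preset = config$column_preset,
                 active_arm = config$active_arm,
                 treatment_end_day = config$treatment_end_day,
                 followup_lag_days = config$followup_lag_days)
  )
}

#' Prioritize subjects in upward shifts for in-depth review
#'
#' Orders subjects whose category shifted upward by destination severity
#' (most severe first), then peak TB xULN, then peak AT xULN, all
#' descending.
#'
#' @param shifts a [shift_records()] tibble.
#' @param scheme the scheme used to build `shifts`.
#' @param active_only restrict to the active arm of `manifest`.
#' @param manifest required when `active_only = TRUE`.
#' @return Tibble of prioritized subjects.
#' @export
priority_list <- function(shifts, scheme = NULL, active_only = FALSE,
                          manifest = NULL) {
  scheme <- scheme %||% attr(shifts, "scheme") %||% banding_scheme()
  sev <- scheme$categories |> select("label", "severity_rank")
  out <- shifts |>
    as_tibble() |>
    filter(.data$direction == "upward") |>
    left_join(sev, by = c(destination = "label")) |>
    arrange(desc(.data$severity_rank), desc(.data$peak_tb_xuln),
            desc(.data$peak_at_xuln)) |>
    select(-"severity_rank")
  if (active_only) {
    if (is.null(manifest)) stop("manifest required for active_only",
                                call. = FALSE)
    out <- out |> filter(.data$arm == manifest$active)
  }
  out
}

#' Run the full screening pipeline
#'
#' Ingests (or generates) the trial data, derives profiles, classifies the
#' trial baseline, runs the tool advisor, and writes the screening bundle to
#' `config$out_dir`: Sankey SVG with per-arm cross-tables, cross-table and
#' scatter CSVs, one composite CSV per destination category, the modified
#' waterfall (when applicable or forced), a prioritized subject list, a JSON
#' summary and a plain-text log. Outputs are byte-stable for a fixed
#' configuration and input.
#'
#' @param config a [run_config()] or a YAML path to one.
#' @return Object of class `dili_screen` (all intermediate results),
#'   invisibly.
#' @export
run_screen <- function(config) {
  if (is.character(config)) config <- load_run_config(config)
  stopifnot(inherits(config, "run_config"))
  log_lines <- character()
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))

  dat <- screen_input(config)
  if (config$input %in% c("study1", "study2", "simulate")) {
    dat$manifest$followup_lag_days <- config$followup_lag_days
  }
  if (nrow(dat$records) == 0) stop("empty trial: no laboratory records",
                                   call. = FALSE)
  scheme <- banding_scheme(alt_cut = config$alt_cut, tb_cut = config$tb_cut,
                           extra_tb_band = config$extra_tb_band,
                           split_nnn = config$split_nnn)
  profiles <- derive_profiles(dat$records, dat$manifest,
                              at_policy = config$at_policy)
  shifts <- shift_records(profiles, scheme)
  if (nrow(shifts) == 0) stop("empty trial: no analyzable subjects",
                              call. = FALSE)
  note("input: %s | %d records | %d analyzable subjects", config$input,
       nrow(dat$records), nrow(shifts))
  excl <- attr(shifts, "excluded")
  if (nrow(excl)) note("excluded from categorization: %d subjects", nrow(excl))

  bl_class <- classify_trial_baseline(profiles, scheme = scheme,
                                      abnormal_fraction_threshold =
                                        config$substantial_threshold)
  advice <- recommend_tools(baseline_pattern(profiles, scheme),
                            substantial_threshold =
                              config$substantial_threshold)
  note("trial baseline: %s (abnormal fraction %.3f)", bl_class$status,
       bl_class$abnormal_fraction)

  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- list()
  add <- function(name, p) paths[[name]] <<- p

  flows <- build_flows(shifts, dat$manifest, scheme)
  arms <- c(dat$manifest$comparator, dat$manifest$active)
  xtabs <- purrr::map(setNames(arms, arms),
                      ~ build_cross_table(shifts, .x, scheme))
  add("sankey", render_sankey(flows, file.path(out_dir, "sankey.svg"),
                              crosstabs = xtabs))
  for (arm in arms) {
    add(paste0("crosstab_", arm),
        write_crosstab_csv(xtabs[[arm]],
                           file.path(out_dir,
                                     sprintf("crosstab_%s.csv", arm))))
  }

  epts <- edish_points(profiles, scheme)
  mpts <- mdish_points(profiles, scheme)
  add("edish", write_points_csv(epts, file.path(out_dir, "edish.csv")))
  add("mdish", write_points_csv(mpts, file.path(out_dir, "mdish.csv")))
  composites <- purrr::map(
    setNames(quadrant_levels(scheme), quadrant_levels(scheme)),
    ~ composite_points(profiles, .x, scheme))
  for (cat in names(composites)) {
    add(paste0("composite_", cat),
        write_points_csv(composites[[cat]],
                         file.path(out_dir,
                                   sprintf("composite_%s.csv", cat))))
  }

  applic <- check_applicability(profiles, scheme,
                                max_baseline_jaundice_fraction =
                                  config$jaundice_threshold)
  waterfall <- NULL
  if (applic$applicable || config$force_waterfall) {
    if (!applic$applicable) {
      note("waterfall forced despite baseline jaundice fraction %.3f",
           applic$jaundice_fraction)
    }
    waterfall <- build_waterfall(profiles, dat$manifest,
                                 mode = config$waterfall_mode,
                                 scheme = scheme)
    add("waterfall_svg",
        render_waterfall(waterfall, file.path(out_dir, "waterfall.svg"),
                         severity_lines = config$severity_lines))
    add("waterfall_csv",
        write_waterfall_csv(waterfall, file.path(out_dir, "waterfall.csv")))
  } else {
    note("waterfall skipped: baseline jaundice fraction %.3f exceeds %.3f",
         applic$jaundice_fraction, applic$threshold)
  }

  prio <- priority_list(shifts, scheme, active_only = config$active_only,
                        manifest = dat$manifest)
  add("priority", {
    readr::write_csv(prio, file.path(out_dir, "priority_list.csv"))
    file.path(out_dir, "priority_list.csv")
  })
  note("priority list: %d subjects in upward shifts", nrow(prio))

  summary <- list(
    input = config$input,
    n_records = nrow(dat$records),
    n_subjects = nrow(shifts),
    trial_baseline = bl_class$status,
    abnormal_fraction = bl_class$abnormal_fraction,
    upward_shifts = upward_shift_summary(xtabs),
    waterfall_applicable = applic$applicable,
    waterfall_built = !is.null(waterfall),
    n_priority = nrow(prio),
    recommendations = as_tibble(advice)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  add("summary", file.path(out_dir, "summary.json"))
  writeLines(log_lines, file.path(out_dir, "screen.log"))
  add("log", file.path(out_dir, "screen.log"))

  invisible(structure(list(
    config = config, manifest = dat$manifest, profiles = profiles,
    shifts = shifts, baseline_class = bl_class, advice = advice,
    flows = flows, cross_tables = xtabs, edish = epts, mdish = mpts,
    composites = composites, applicability = applic, waterfall = waterfall,
    priority = prio, paths = paths, log = log_lines
  ), class = "dili_screen"))
}

#' @export
print.dili_screen <- function(x, ...) {
  cat("<dili_screen>", x$config$input, "->", x$config$out_dir, "\n")
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  invisible(x)
}

#' @export
glance.dili_screen <- function(x, ...) {
  tibble(input = x$config$input,
         n_subjects = nrow(x$shifts),
         trial_baseline = x$baseline_class$status,
         waterfall_built = !is.null(x$waterfall),
         n_priority = nrow(x$priority))
}
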