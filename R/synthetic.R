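## ULNs used by all synthetic data; constant within analyte
SYN_ULN <- c(ALT = 40, AST = 40, TB = 1.2, ALP = 120)

## run code under a fixed seed without disturbing the caller's RNG
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Specify a synthetic two-arm trial
#'
#' Defines the generative model [simulate_trial()] draws from: per-arm sizes
#' (unequal randomization supported), a baseline severity mix over the
#' quadrant categories, a visit schedule, visit-to-visit lognormal noise,
#' and per-arm on-treatment signal events:
#'
#' * `dili`: hepatocellular injury — at one random on-treatment visit ALT is
#'   surged to `alt_xbl` times baseline (with an optional absolute floor
#'   `alt_min_xuln`), and TB to `tb_xbl` times baseline (floor
#'   `tb_min_xuln`).
#' * `efficacy`: a multiplicative decline of ALT and TB across the
#'   on-treatment period (factor `decline` < 1).
#' * `hemolysis`: an isolated TB rise (`tb_xbl`, floor `tb_min_xuln`) with
#'   no ALT rise — the jaundice-without-hepatocellular-injury pattern.
#'
#' Each signal has a per-subject probability within its arm. Baseline values
#' are drawn log-uniformly within the assigned category's band (bands capped
#' at 10 xULN for ALT and 6 xULN for TB), so the baseline draw lands in its
#' assigned category with probability 1.
#'
#' @param n_placebo,n_active arm sizes.
#' @param baseline_mix named fractions over `NNN`, `Temple`, `Cholestasis`,
#'   `HyLaw` (must sum to 1); either one vector for both arms or a list with
#'   `placebo` and `active` elements.
#' @param visit_days integer schedule; days <= 0 are pre-dose.
#' @param noise_sdlog sd of the lognormal visit-to-visit variation.
#' @param signals list with `placebo` and `active` elements, each a list of
#'   `dili`, `efficacy`, `hemolysis` parameter lists (see Details; `prob = 0`
#'   disables).
#' @param scheme a [banding_scheme()] defining the bands.
#' @param seed integer RNG seed.
#' @param arm_labels character vector `c(placebo, active)`.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_placebo = 100, n_active = 100,
                           baseline_mix = c(NNN = 0.85, Temple = 0.10,
                                            Cholestasis = 0.04, HyLaw = 0.01),
                           visit_days = c(-14, -1, seq(28, 336, by = 28)),
                           noise_sdlog = 0.15,
                           signals = list(
                             placebo = list(),
                             active = list(
                               dili = list(prob = 0.02, alt_xbl = 4,
                                           tb_xbl = 2.5,
                                           alt_min_xuln = 5, tb_min_xuln = 2.5),
                               efficacy = list(prob = 0.3, decline = 0.6),
                               hemolysis = list(prob = 0.01, tb_xbl = 3,
                                                tb_min_xuln = 2.5)
                             )
                           ),
                           scheme = banding_scheme(), seed = 1,
                           arm_labels = c("Placebo", "Active")) {
  if (!is.list(baseline_mix)) {
    baseline_mix <- list(placebo = baseline_mix, active = baseline_mix)
  }
  for (arm in names(baseline_mix)) {
    mix <- baseline_mix[[arm]]
    if (abs(sum(mix) - 1) > 1e-6 || any(mix < 0)) {
      stop("baseline_mix fractions must be non-negative and sum to 1",
           call. = FALSE)
    }
  }
  probs <- unlist(purrr::map(signals, ~ purrr::map_dbl(.x, "prob")))
  if (length(probs) && (any(probs < 0) || any(probs > 1))) {
    stop("signal probabilities must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(n_placebo >= 1, n_active >= 1, noise_sdlog >= 0,
            any(visit_days <= 0), any(visit_days > 0))
  structure(list(n_placebo = n_placebo, n_active = n_active,
                 baseline_mix = baseline_mix, visit_days = sort(visit_days),
                 noise_sdlog = noise_sdlog, signals = signals,
                 scheme = scheme, seed = seed, arm_labels = arm_labels),
            class = "synthetic_spec")
}

## log-uniform draw within a band; errors if the band region is empty
band_draw <- function(n, lo, hi) {
  if (!(lo > 0) || lo >= hi) {
    stop("infeasible band: empty region [", lo, ", ", hi, "]", call. = FALSE)
  }
  exp(stats::runif(n, log(lo), log(hi)))
}

## band boundaries in xULN for one analyte axis of a category
syn_bands <- function(scheme) {
  list(
    alt = list(lo = c(0.2, scheme$alt_cut),
               hi = c(scheme$alt_cut * 0.999, 10)),
    tb = list(lo = c(0.2, scheme$tb_cut * 1.001),
              hi = c(scheme$tb_cut, 6))
  )
}

category_bands <- function(label) {
  switch(label,
         NNN = c(alt = 0, tb = 0), Temple = c(alt = 1, tb = 0),
         Cholestasis = c(alt = 0, tb = 1), HyLaw = c(alt = 1, tb = 1),
         stop("simulator supports the four classical categories; got ",
              label, call. = FALSE))
}

#' Simulate a two-arm trial
#'
#' Draws subject-level laboratory records (ALT and TB) from a
#' [synthetic_spec()]. Deterministic for a fixed seed; the caller's RNG
#' state is left untouched.
#'
#' @param spec a [synthetic_spec()].
#' @return List of class `lab_data`: `records`, `manifest` and an ingest
#'   `report` of zeros (simulated data is already clean).
#' @export
simulate_trial <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_local_seed(spec$seed, {
    bands <- syn_bands(spec$scheme)
    arms <- tibble(
      arm = rep(spec$arm_labels, c(spec$n_placebo, spec$n_active)),
      role = rep(c("placebo", "active"), c(spec$n_placebo, spec$n_active))
    ) |>
      mutate(subject_id = sprintf("SIM-%s%04d", substr(.data$role, 1, 1),
                                  row_number()))

    pre_days <- spec$visit_days[spec$visit_days <= 0]
    post_days <- spec$visit_days[spec$visit_days > 0]
    baseline_day <- max(pre_days)

    records <- purrr::map_dfr(seq_len(nrow(arms)), function(i) {
      role <- arms$role[i]
      mix <- spec$baseline_mix[[role]]
      cat <- sample(names(mix), 1, prob = mix)
      bnd <- category_bands(cat)
      alt_base <- band_draw(1, bands$alt$lo[bnd[["alt"]] + 1],
                            bands$alt$hi[bnd[["alt"]] + 1])
      tb_base <- band_draw(1, bands$tb$lo[bnd[["tb"]] + 1],
                           bands$tb$hi[bnd[["tb"]] + 1])

      sig <- spec$signals[[role]] %||% list()
      has <- function(s) !is.null(sig[[s]]) &&
        stats::runif(1) < sig[[s]]$prob
      ev_dili <- has("dili")
      ev_eff <- has("efficacy")
      ev_hem <- has("hemolysis")
      dili_visit <- if (ev_dili) sample(seq_along(post_days), 1) else NA
      hem_visit <- if (ev_hem) sample(seq_along(post_days), 1) else NA

      noise <- function(n) exp(stats::rnorm(n, 0, spec$noise_sdlog))
      mk_traj <- function(base_xuln, uln, surge_visit, xbl, min_xuln,
                          decline_on) {
        pre <- base_xuln * c(noise(length(pre_days) - 1), 1)
        post <- base_xuln * noise(length(post_days))
        if (decline_on) post <- post * sig$efficacy$decline
        if (!is.na(surge_visit)) {
          target <- max(base_xuln * (xbl %||% 1),
                        (min_xuln %||% 0))
          post[surge_visit] <- max(post[surge_visit], target)
        }
        c(pre, post) * uln
      }

      alt_vals <- mk_traj(alt_base, SYN_ULN[["ALT"]],
                          if (ev_dili) dili_visit else NA,
                          sig$dili$alt_xbl, sig$dili$alt_min_xuln, ev_eff)
      tb_surge_visit <- if (ev_dili) dili_visit else if (ev_hem) hem_visit else NA
      tb_sig <- if (ev_dili) sig$dili else if (ev_hem) sig$hemolysis else NULL
      tb_vals <- mk_traj(tb_base, SYN_ULN[["TB"]], tb_surge_visit,
                         tb_sig$tb_xbl, tb_sig$tb_min_xuln, ev_eff)

      days <- c(pre_days, post_days)
      tibble(subject_id = arms$subject_id[i], arm = arms$arm[i],
             analyte = rep(c("ALT", "TB"), each = length(days)),
             study_day = rep(days, 2),
             value = unname(round(c(alt_vals, tb_vals), 4)),
             uln = unname(rep(SYN_ULN[c("ALT", "TB")], each = length(days))))
    })

    structure(list(
      records = records |>
        arrange(.data$subject_id, .data$analyte, .data$study_day),
      manifest = trial_manifest(active = spec$arm_labels[2],
                                comparator = spec$arm_labels[1],
                                treatment_end_day = max(post_days),
                                followup_lag_days = 0),
      report = tibble(reason = c("unparseable", "unknown_analyte",
                                 "out_of_range", "duplicate_collision"),
                      n = 0L)
    ), class = "lab_data")
  })
}

## ---- deterministic study fixtures --------------------------------------
## The fixtures are constructed, not sampled: only the published marginals
## pin cells, and all remaining mass sits on the diagonal (no shift).

## band value ranges (xULN) used for deterministic placement
FX_BANDS <- list(
  alt = list(lo = c(0.4, 3.2), hi = c(2.8, 9.0)),
  tb = list(lo = c(0.4, 2.2), hi = c(1.8, 5.0))
)

## log-spaced value i of n within band b (0/1) of an axis
fx_val <- function(axis, band, i, n) {
  lo <- FX_BANDS[[axis]]$lo[band + 1]
  hi <- FX_BANDS[[axis]]$hi[band + 1]
  exp(log(lo) + (log(hi) - log(lo)) * i / (n + 1))
}

## build LabRecords for one cell of the shift table
fx_cell <- function(arm, prefix, origin, destination, n, start_index,
                    alt_decline = FALSE) {
  if (n == 0) return(NULL)
  ob <- category_bands(origin)
  db <- category_bands(destination)
  purrr::map_dfr(seq_len(n), function(i) {
    id <- sprintf("%s%04d", prefix, start_index + i)
    base_alt <- fx_val("alt", ob[["alt"]], i, n)
    base_tb <- fx_val("tb", ob[["tb"]], i, n)

    traj <- function(axis, b_band, d_band, base, decline) {
      if (decline) return(c(0.80, 0.85) * base)      # max change below BL
      if (d_band > b_band) {
        peak <- fx_val(axis, d_band, i, n)
        c(peak, base)                                # rise, then back toward BL
      } else if (d_band < b_band) {
        dest <- fx_val(axis, d_band, i, n)
        c(dest, dest * 0.95)                         # improvement
      } else {
        hi <- FX_BANDS[[axis]]$hi[b_band + 1]
        c(pmin(base * 1.05, hi), base * 0.95)        # stable, mild wobble
      }
    }
    alt_on <- traj("alt", ob[["alt"]], db[["alt"]], base_alt, alt_decline)
    tb_on <- traj("tb", ob[["tb"]], db[["tb"]], base_tb, FALSE)

    days <- c(-14L, -1L, 28L, 56L)
    tibble(subject_id = id, arm = arm,
           analyte = rep(c("ALT", "TB"), each = 4),
           study_day = rep(days, 2),
           value = unname(round(c(base_alt, base_alt, alt_on,
                                  base_tb, base_tb, tb_on) *
                                  rep(SYN_ULN[c("ALT", "TB")], each = 4), 4)),
           uln = unname(rep(SYN_ULN[c("ALT", "TB")], each = 4)))
  })
}

fx_build <- function(cells, arm_labels) {
  recs <- purrr::map_dfr(split(cells, cells$arm), function(arm_cells) {
    prefix <- arm_cells$prefix[1]
    idx <- cumsum(c(0, utils::head(arm_cells$n, -1)))
    purrr::map_dfr(seq_len(nrow(arm_cells)), function(j) {
      fx_cell(arm_cells$arm[j], prefix, arm_cells$origin[j],
              arm_cells$destination[j], arm_cells$n[j], idx[j],
              alt_decline = arm_cells$alt_decline[j])
    })
  })
  structure(list(
    records = recs |> arrange(.data$subject_id, .data$analyte, .data$study_day),
    manifest = trial_manifest(active = arm_labels[2],
                              comparator = arm_labels[1],
                              treatment_end_day = 56, followup_lag_days = 0),
    report = tibble(reason = c("unparseable", "unknown_analyte",
                               "out_of_range", "duplicate_collision"),
                    n = 0L)
  ), class = "lab_data")
}

fx_cells <- function(arm, prefix, ...) {
  tibble(arm = arm, prefix = prefix, ...)
}

#' Deterministic fixture emulating a severe chronic liver disease trial
#'
#' A 92-subject, 1:1 two-arm trial with markedly abnormal baselines: 13 of
#' 46 placebo (28%) and 17 of 46 active (37%) subjects start in the Hy's Law
#' category. On-treatment upward shifts follow five distinct paths totalling
#' 15 in the placebo arm (including two NNN-to-HyLaw shifts) and three paths
#' totalling 13 in the active arm (none from NNN to HyLaw). Cells not pinned
#' by those marginals stay on the diagonal.
#'
#' @return A `lab_data` list (`records`, `manifest`, `report`).
#' @export
study1_fixture <- function() {
  placebo <- fx_cells(
    "Placebo", "S1P",
    origin = c("NNN", "NNN", "NNN", "NNN", "Temple", "Temple",
               "Cholestasis", "Cholestasis", "HyLaw"),
    destination = c("NNN", "HyLaw", "Temple", "Cholestasis", "Temple",
                    "HyLaw", "Cholestasis", "HyLaw", "HyLaw"),
    n = c(2L, 2L, 4L, 2L, 11L, 4L, 5L, 3L, 13L),
    alt_decline = FALSE
  )
  active <- fx_cells(
    "Active", "S1A",
    origin = c("NNN", "NNN", "Temple", "Temple", "Cholestasis",
               "Cholestasis", "HyLaw"),
    destination = c("NNN", "Temple", "Temple", "HyLaw", "Cholestasis",
                    "HyLaw", "HyLaw"),
    n = c(1L, 6L, 9L, 5L, 6L, 2L, 17L),
    alt_decline = FALSE
  )
  fx_build(bind_rows(placebo, active), c("Placebo", "Active"))
}

#' Deterministic fixture emulating a mostly normal-baseline 1:3 trial
#'
#' A 1019-subject trial (254 placebo, 765 active) with most subjects in the
#' NNN category at baseline but 26 of 254 placebo (10%) and 81 of 765 active
#' (11%) subjects starting in Temple's category, and exactly one subject
#' (placebo) with baseline jaundice. The active arm shows five subjects
#' reaching the Hy's Law category (four from NNN, one from Temple), three
#' hemolysis-type subjects with new jaundice but maximum ALT change below
#' baseline (NNN to Cholestasis), and substantial downward (improvement)
#' shifts; placebo upward shifts use none of the active arm's paths.
#'
#' @return A `lab_data` list (`records`, `manifest`, `report`).
#' @export
study2_fixture <- function() {
  placebo <- fx_cells(
    "Placebo", "S2P",
    origin = c("NNN", "NNN", "Temple", "Temple", "Cholestasis"),
    destination = c("NNN", "Temple", "Temple", "NNN", "Cholestasis"),
    n = c(223L, 4L, 24L, 2L, 1L),
    alt_decline = FALSE
  )
  active <- fx_cells(
    "Active", "S2A",
    origin = c("NNN", "NNN", "NNN", "Temple", "Temple", "Temple"),
    destination = c("NNN", "HyLaw", "Cholestasis", "Temple", "HyLaw", "NNN"),
    n = c(677L, 4L, 3L, 40L, 1L, 40L),
    alt_decline = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE)
  )
  fx_build(bind_rows(placebo, active), c("Placebo", "Active"))
}
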