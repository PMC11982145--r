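fast_days <- c(-14, -1, 28, 56, 84)

test_that("the same seed reproduces the simulation byte for byte", {
  a <- simulate_trial(synthetic_spec(n_placebo = 15, n_active = 15,
                                     visit_days = fast_days, seed = 9))
  b <- simulate_trial(synthetic_spec(n_placebo = 15, n_active = 15,
                                     visit_days = fast_days, seed = 9))
  expect_identical(a$records, b$records)
  c <- simulate_trial(synthetic_spec(n_placebo = 15, n_active = 15,
                                     visit_days = fast_days, seed = 10))
  expect_false(identical(a$records, c$records))
})

test_that("all-NNN baselines with no signals stay NNN to NNN", {
  spec <- synthetic_spec(
    n_placebo = 20, n_active = 20,
    baseline_mix = c(NNN = 1, Temple = 0, Cholestasis = 0, HyLaw = 0),
    visit_days = fast_days, noise_sdlog = 0,
    signals = list(placebo = list(), active = list()), seed = 2)
  sim <- simulate_trial(spec)
  sh <- shift_records(derive_profiles(sim$records, sim$manifest))
  expect_true(all(sh$origin == "NNN"))
  expect_true(all(sh$destination == "NNN"))
  expect_true(all(sh$direction == "none"))
})

test_that("a certain hepatocellular surge forces every active subject into HyLaw", {
  spec <- synthetic_spec(
    n_placebo = 10, n_active = 10,
    baseline_mix = c(NNN = 1, Temple = 0, Cholestasis = 0, HyLaw = 0),
    visit_days = fast_days, noise_sdlog = 0.1,
    signals = list(placebo = list(),
                   active = list(dili = list(prob = 1, alt_xbl = 1,
                                             tb_xbl = 1, alt_min_xuln = 6,
                                             tb_min_xuln = 3))),
    seed = 4)
  sim <- simulate_trial(spec)
  sh <- tibble::as_tibble(shift_records(derive_profiles(sim$records,
                                                        sim$manifest)))
  active <- dplyr::filter(sh, arm == "Active")
  expect_true(all(active$destination == "HyLaw"))
})

test_that("baseline draws always land in their assigned category band", {
  spec <- synthetic_spec(n_placebo = 60, n_active = 60,
                         baseline_mix = c(NNN = 0.25, Temple = 0.25,
                                          Cholestasis = 0.25, HyLaw = 0.25),
                         visit_days = fast_days, seed = 6)
  sim <- simulate_trial(spec)
  bl <- derive_baseline(sim$records) |>
    tidyr::pivot_wider(id_cols = c("subject_id", "arm"),
                       names_from = "analyte",
                       values_from = "baseline_xuln")
  cat <- assign_quadrant(bl$ALT, bl$TB)
  expect_true(all(table(cat) > 0))
  ## positivity and constant ULN within analyte
  expect_true(all(sim$records$value > 0))
  uln_per <- dplyr::distinct(sim$records, analyte, uln)
  expect_equal(nrow(uln_per), dplyr::n_distinct(sim$records$analyte))
})

test_that("empirical baseline category fractions track the specified mix", {
  mix <- c(NNN = 0.6, Temple = 0.2, Cholestasis = 0.15, HyLaw = 0.05)
  n_per <- 60
  seeds <- 1:50
  counts <- purrr::map(seeds, function(s) {
    sim <- simulate_trial(synthetic_spec(
      n_placebo = n_per / 2, n_active = n_per / 2, baseline_mix = mix,
      visit_days = c(-1, 28), seed = s))
    bl <- derive_baseline(sim$records) |>
      tidyr::pivot_wider(id_cols = "subject_id", names_from = "analyte",
                         values_from = "baseline_xuln")
    table(assign_quadrant(bl$ALT, bl$TB))
  })
  total <- Reduce(`+`, counts)
  n <- sum(total)
  for (cat in names(mix)) {
    ## 99% binomial bounds around the specified fraction
    bound <- 2.576 * sqrt(mix[[cat]] * (1 - mix[[cat]]) / n)
    expect_lt(abs(total[[cat]] / n - mix[[cat]]), bound + 1e-12)
  }
})

test_that("infeasible bands and invalid mixes are rejected", {
  expect_error(synthetic_spec(baseline_mix = c(NNN = 0.5, Temple = 0.2,
                                               Cholestasis = 0.2,
                                               HyLaw = 0.2)),
               "sum to 1")
  expect_error(
    synthetic_spec(signals = list(placebo = list(),
                                  active = list(dili = list(prob = 1.4)))),
    "probabilities")
  ## an AT cut beyond the band cap leaves an empty elevated band
  spec <- synthetic_spec(n_placebo = 4, n_active = 4,
                         baseline_mix = c(NNN = 0, Temple = 1,
                                          Cholestasis = 0, HyLaw = 0),
                         scheme = banding_scheme(alt_cut = 12),
                         visit_days = fast_days, seed = 1)
  expect_error(simulate_trial(spec), "infeasible band")
})

test_that("fixture records pass ingest validation unchanged", {
  for (fx in list(study1_fixture(), study2_fixture())) {
    v <- validate_lab_records(fx$records)
    expect_equal(v$records, fx$records)
    expect_true(all(v$report$n == 0))
  }
})
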