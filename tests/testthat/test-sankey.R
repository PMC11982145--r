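toy_shifts <- function() {
  prof <- two_arm_profiles(tibble::tibble(
    id = sprintf("S%d", 1:10),
    arm = rep(c("Placebo", "Active"), each = 5),
    alt_b = c(0.8, 0.8, 4, 0.9, 0.7, 0.8, 0.8, 4, 4, 0.9),
    tb_b = 0.5,
    alt_p = c(0.9, 4, 4, 1, 0.8, 5, 5, 0.9, 4, 1),
    tb_p = c(0.6, 0.6, 0.6, 0.6, 0.6, 3, 0.7, 0.7, 3, 0.6)
  ))
  shift_records(prof)
}

test_that("flow sets conserve per-category outflow and tag directions", {
  sh <- toy_shifts()
  fl <- build_flows(sh, default_manifest())
  for (a in c("Placebo", "Active")) {
    out_by_origin <- fl$flows |>
      dplyr::filter(arm == a) |>
      dplyr::group_by(origin) |>
      dplyr::summarise(n = sum(n))
    base <- dplyr::count(tibble::as_tibble(sh) |> dplyr::filter(arm == a),
                         origin, name = "count")
    joined <- dplyr::left_join(base, out_by_origin, by = "origin")
    expect_equal(joined$n, joined$count)
  }
  one_up <- fl$flows |>
    dplyr::filter(arm == "Active", origin == "NNN", destination == "HyLaw")
  expect_equal(one_up$n, 1)
  expect_equal(as.character(one_up$direction), "upward")
  expect_equal(one_up$side, "right")
})

test_that("build_flows rejects arms missing from the manifest", {
  sh <- toy_shifts()
  man <- trial_manifest("DrugX", "Control")
  expect_error(build_flows(sh, man), "not in manifest")
})

test_that("cross-tables tally shifts with the colour-class convention", {
  prof <- two_arm_profiles(tibble::tibble(
    id = c("P1", "P2", "P3", "A1"),
    arm = c("Placebo", "Placebo", "Placebo", "Active"),
    alt_b = c(0.8, 0.8, 4, 0.8),
    alt_p = c(0.9, 4, 0.9, 0.9),
    tb_b = 0.5, tb_p = 0.6
  ))
  sh <- shift_records(prof)
  xt <- build_cross_table(sh, "Placebo")
  m <- crosstab_matrix(xt)
  expect_equal(m["NNN", "NNN"], 1L)
  expect_equal(m["NNN", "Temple"], 1L)
  expect_equal(m["Temple", "NNN"], 1L)
  expect_equal(sum(m), 3L)
  cls <- crosstab_matrix(xt, "color_class")
  expect_equal(cls["NNN", "Temple"], "red")
  expect_equal(cls["Temple", "NNN"], "green")
  expect_true(all(diag(cls) == "grey"))
  expect_equal(cls["Temple", "Cholestasis"], "yellow")
  ## an arm with no subjects gives an all-zero table
  empty <- build_cross_table(sh, "ArmZ")
  expect_equal(sum(empty$n), 0L)
})

test_that("upward_shift_summary totals red cells and counts distinct paths", {
  sh <- toy_shifts()
  xts <- purrr::map(c(Placebo = "Placebo", Active = "Active"),
                    ~ build_cross_table(sh, .x))
  smry <- upward_shift_summary(xts)
  all_diag <- build_cross_table(
    shift_records(two_arm_profiles(tibble::tibble(
      id = c("P1", "A1"), arm = c("Placebo", "Active"),
      alt_b = 0.8, alt_p = 0.9, tb_b = 0.5, tb_p = 0.6))),
    "Placebo")
  smry0 <- upward_shift_summary(all_diag)
  expect_equal(smry0$upward_total, 0)
  expect_equal(smry0$upward_paths, 0)
  ## toy actives: NNN->HyLaw (1), NNN->Temple (1), Temple->HyLaw (1)
  act <- dplyr::filter(smry, arm == "Active")
  expect_equal(act$upward_total, 3)
  expect_equal(act$upward_paths, 3)
})

test_that("cross-table counts agree with flow-set counts for the same arm", {
  sim <- simulate_trial(synthetic_spec(n_placebo = 40, n_active = 40,
                                       visit_days = c(-14, -1, 28, 56),
                                       seed = 5))
  prof <- derive_profiles(sim$records, sim$manifest)
  sh <- shift_records(prof)
  fl <- build_flows(sh, sim$manifest)
  for (a in unique(sh$arm)) {
    xt <- build_cross_table(sh, a)
    from_tab <- tibble::as_tibble(xt) |>
      dplyr::filter(n > 0) |>
      dplyr::mutate(origin = as.character(origin),
                    destination = as.character(destination)) |>
      dplyr::arrange(origin, destination)
    from_fl <- fl$flows |>
      dplyr::filter(arm == a) |>
      dplyr::mutate(origin = as.character(origin),
                    destination = as.character(destination)) |>
      dplyr::select(origin, destination, n) |>
      dplyr::arrange(origin, destination)
    expect_equal(from_tab[c("origin", "destination", "n")],
                 from_fl, ignore_attr = TRUE)
  }
})

test_that("within-arm proportions are invariant to arm-size imbalance", {
  ## identical shift distributions, active arm three times the placebo size
  base <- tibble::tibble(
    alt_b = c(0.8, 0.8, 4), alt_p = c(0.9, 4, 4.5),
    tb_b = 0.5, tb_p = 0.6
  )
  placebo <- base |> dplyr::mutate(arm = "Placebo",
                                   id = sprintf("P%d", dplyr::row_number()))
  active <- dplyr::bind_rows(base, base, base) |>
    dplyr::mutate(arm = "Active", id = sprintf("A%d", dplyr::row_number()))
  prof <- two_arm_profiles(dplyr::bind_rows(placebo, active))
  fl <- build_flows(shift_records(prof), default_manifest())
  left <- fl$flows |> dplyr::filter(side == "left") |>
    dplyr::arrange(origin, destination)
  right <- fl$flows |> dplyr::filter(side == "right") |>
    dplyr::arrange(origin, destination)
  expect_equal(left$fraction, right$fraction)
  expect_equal(right$n, 3L * left$n)
})

test_that("rendered Sankey SVGs are byte-stable and single flows draw", {
  sh <- toy_shifts()
  fl <- build_flows(sh, default_manifest())
  dir <- withr::local_tempdir()
  p1 <- render_sankey(fl, file.path(dir, "a.svg"))
  p2 <- render_sankey(fl, file.path(dir, "b.svg"))
  expect_true(file.exists(p1))
  expect_identical(readBin(p1, raw(), file.size(p1)),
                   readBin(p2, raw(), file.size(p2)))
  expect_error(render_sankey(fl, file.path(dir, "no_dir", "x.svg")),
               "directory")
})
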