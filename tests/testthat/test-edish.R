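## Subjects A and B: identical relative changes (ALT 5xBL, TB 4xBL) but very
## different absolute values (B reaches ALT 1000 U/L with jaundice).
ab_profiles <- function() {
  recs <- dplyr::bind_rows(
    make_subject("A", "Active", alt = list(`-1` = 40, `28` = 200),
                 tb = list(`-1` = 0.5, `28` = 2.0)),
    make_subject("B", "Active", alt = list(`-1` = 200, `28` = 1000),
                 tb = list(`-1` = 1.5, `28` = 6.0)),
    make_subject("P", "Placebo", alt = list(`-1` = 40, `28` = 44),
                 tb = list(`-1` = 0.6, `28` = 0.6))
  )
  derive_profiles(recs, default_manifest())
}

test_that("subjects with equal xBL changes coincide on mDISH and separate on eDISH", {
  prof <- ab_profiles()
  mp <- tibble::as_tibble(mdish_points(prof))
  a <- dplyr::filter(mp, subject_id == "A")
  b <- dplyr::filter(mp, subject_id == "B")
  expect_equal(a$x, 5)   # peak ALT five times baseline
  expect_equal(a$y, 4)   # peak TB four times baseline
  expect_equal(b$x, a$x)
  expect_equal(b$y, a$y)

  ep <- tibble::as_tibble(edish_points(prof))
  ea <- dplyr::filter(ep, subject_id == "A")
  eb <- dplyr::filter(ep, subject_id == "B")
  expect_false(ea$x == eb$x && ea$y == eb$y)
  expect_equal(eb$x, 25)                       # 1000 U/L over ULN 40
  expect_equal(as.character(eb$destination), "HyLaw")
})

test_that("a subject whose tests nearly triple and double lands at (2.9, 1.9) on mDISH", {
  recs <- make_subject("C", "Active", alt = list(`-1` = 300, `28` = 870),
                       tb = list(`-1` = 3.0, `28` = 5.7))
  prof <- derive_profiles(recs, default_manifest())
  mp <- tibble::as_tibble(mdish_points(prof))
  expect_equal(mp$x, 2.9)
  expect_equal(mp$y, 1.9)
})

test_that("no-change subjects sit at the mDISH identity point (1, 1)", {
  recs <- make_subject("S", "Active", alt = list(`-1` = 90, `28` = 90),
                       tb = list(`-1` = 1.8, `28` = 1.8))
  mp <- tibble::as_tibble(mdish_points(derive_profiles(recs, default_manifest())))
  expect_equal(mp$x, 1)
  expect_equal(mp$y, 1)
})

test_that("eDISH destination categories agree with assign_quadrant on the coordinates", {
  sim <- simulate_trial(synthetic_spec(n_placebo = 25, n_active = 25,
                                       visit_days = c(-14, -1, 28, 56),
                                       seed = 11))
  prof <- derive_profiles(sim$records, sim$manifest)
  ep <- tibble::as_tibble(edish_points(prof))
  expect_identical(as.character(ep$destination),
                   as.character(assign_quadrant(ep$x, ep$y)))
  counts <- quadrant_counts(edish_points(prof))
  expect_equal(sum(counts$n), nrow(ep))
})

test_that("toy arm quadrant counts match a hand tally", {
  prof <- two_arm_profiles(tibble::tibble(
    id = sprintf("S%d", 1:5),
    arm = c("Active", "Active", "Active", "Active", "Placebo"),
    alt_b = 0.8, tb_b = 0.5,
    alt_p = c(10, 0.7, 4, 1, 5),
    tb_p = c(4, 0.4, 1, 3, 2.5)
  ))
  counts <- quadrant_counts(edish_points(prof))
  active <- dplyr::filter(counts, arm == "Active")
  got <- stats::setNames(active$n, as.character(active$category))
  ## hand tally: (10,4) HyLaw, (0.7,0.4) NNN, (4,1) Temple, (1,3) Cholestasis
  expect_equal(got[["HyLaw"]], 1L)
  expect_equal(got[["NNN"]], 1L)
  expect_equal(got[["Temple"]], 1L)
  expect_equal(got[["Cholestasis"]], 1L)
})

test_that("potential Hy's Law flags follow the destination with ALP as annotation only", {
  recs <- dplyr::bind_rows(
    make_subject("H", "Active", alt = list(`-1` = 40, `28` = 400),
                 tb = list(`-1` = 0.6, `28` = 4.0)),
    lab_rows("H", "Active", "ALP", c(-1, 28), c(100, 480), uln = 120),
    make_subject("T", "Active", alt = list(`-1` = 40, `28` = 400),
                 tb = list(`-1` = 0.6, `28` = 1.0))
  )
  fl <- flag_potential_hys_law(derive_profiles(recs, default_manifest()))
  h <- dplyr::filter(fl, subject_id == "H")
  expect_true(h$potential_hys_law)
  expect_equal(h$annotation, "ALP 4.0xULN")
  expect_false(dplyr::filter(fl, subject_id == "T")$potential_hys_law)
})

test_that("composite plots partition the mDISH-eligible subjects exactly once", {
  sim <- simulate_trial(synthetic_spec(n_placebo = 30, n_active = 30,
                                       visit_days = c(-14, -1, 28, 56),
                                       seed = 3))
  prof <- derive_profiles(sim$records, sim$manifest)
  mp <- mdish_points(prof)
  eligible <- tibble::as_tibble(mp) |> dplyr::filter(!is.na(destination))
  parts <- purrr::map(quadrant_levels(banding_scheme()),
                      ~ composite_points(prof, .x))
  ids <- unlist(purrr::map(parts, "subject_id"))
  expect_setequal(ids, eligible$subject_id)
  expect_equal(length(ids), length(unique(ids)))
})

test_that("composite marker encoding is a fixed function of the origin category", {
  prof <- two_arm_profiles(tibble::tibble(
    id = sprintf("S%d", 1:3),
    arm = "Active",
    alt_b = c(0.8, 4, 8), tb_b = c(0.5, 0.6, 4),
    alt_p = c(5, 5, 8), tb_p = c(3, 3, 4)
  ))
  cp <- tibble::as_tibble(composite_points(prof, "HyLaw"))
  cp <- dplyr::arrange(cp, subject_id)
  expect_equal(cp$marker_colour, c("forestgreen", "blue", "red"))
  expect_equal(cp$marker_shape, c("square", "plus", "star"))
  expect_equal(nrow(composite_points(prof, "Cholestasis")), 0)
  expect_error(composite_points(prof, "Bogus"), "unknown destination")
})
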