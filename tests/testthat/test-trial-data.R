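test_that("read_lab_csv parses a toy file and reports dropped rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "subject_id,arm,analyte,study_day,value,uln",
    "P1,Placebo,ALT,-1,80,40",
    "P1,Placebo,ALT,28,120,40",
    "P1,Placebo,TB,-1,0.8,1.2",
    "A1,Active,ALT,-1,50,40",
    "A1,Active,ALT,28,NA,40"
  ), path)
  out <- read_lab_csv(path, active_arm = "Active")
  expect_s3_class(out$manifest, "trial_manifest")
  expect_equal(nrow(out$records), 4)
  expect_equal(dplyr::n_distinct(out$records$subject_id), 2)
  expect_equal(out$report$n[out$report$reason == "unparseable"], 1)
})

test_that("read_lab_csv fails hard on missing columns and empty files", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,arm,analyte,study_day,value",
               "P1,Placebo,ALT,-1,80"), path)
  expect_error(read_lab_csv(path), "uln")
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("subject_id,arm,analyte,study_day,value,uln", empty)
  expect_error(read_lab_csv(empty), "empty")
  expect_error(read_lab_csv(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("the SDTM preset maps LB-style columns and BILI -> TB", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "USUBJID,ARM,LBTESTCD,LBDY,LBSTRESN,LBSTNRHI",
    "P1,Placebo,ALT,-1,80,40",
    "P1,Placebo,BILI,-1,0.8,1.2",
    "A1,Active,ALT,-1,90,40"
  ), path)
  out <- read_lab_csv(path, preset = "sdtm", active_arm = "Active")
  expect_setequal(unique(out$records$analyte), c("ALT", "TB"))
})

test_that("duplicate (subject, analyte, day) keeps the maximum value", {
  recs <- dplyr::bind_rows(
    lab_rows("P1", "Placebo", "ALT", -1, 100),
    lab_rows("P1", "Placebo", "ALT", -1, 120)
  )
  v <- validate_lab_records(recs)
  expect_equal(nrow(v$records), 1)
  expect_equal(v$records$value, 120)
  expect_equal(v$report$n[v$report$reason == "duplicate_collision"], 1)
})

test_that("baseline is the latest pre-dose value, day 0 included", {
  recs <- dplyr::bind_rows(
    make_subject("P1", "Placebo", alt = list(`-14` = 80, `-1` = 95, `28` = 200),
                 tb = list(`-1` = 0.8, `28` = 1.0)),
    make_subject("P2", "Placebo", alt = list(`-7` = 100, `0` = 110, `28` = 150),
                 tb = list(`-1` = 0.8, `28` = 1.0)),
    make_subject("P3", "Placebo", alt = list(`28` = 400),  # post-dose only
                 tb = list(`-1` = 0.8, `28` = 1.0))
  )
  bl <- derive_baseline(recs)
  expect_equal(bl$baseline[bl$subject_id == "P1" & bl$analyte == "ALT"], 95)
  expect_equal(bl$baseline[bl$subject_id == "P2" & bl$analyte == "ALT"], 110)
  expect_false(any(bl$subject_id == "P3" & bl$analyte == "ALT"))
  prof <- derive_profiles(recs, default_manifest())
  p3 <- dplyr::filter(tibble::as_tibble(prof), subject_id == "P3",
                      analyte == "ALT")
  expect_false(p3$has_baseline)
  expect_false(p3$analyzable)
})

test_that("peaks, xULN and xBL derive from the on-treatment window", {
  recs <- make_subject("P1", "Placebo",
                       alt = list(`-1` = 200, `10` = 50, `20` = 400,
                                  `30` = 200),
                       tb = list(`-1` = 0.8, `20` = 1.0))
  prof <- tibble::as_tibble(derive_profiles(recs, default_manifest()))
  alt <- dplyr::filter(prof, analyte == "ALT")
  expect_equal(alt$peak, 400)
  expect_equal(alt$peak_day, 20)
  expect_equal(alt$peak_xuln, 10)
  expect_equal(alt$peak_xbl, 2)   # 400 / baseline 200
  expect_equal(alt$trough, 50)
  ## values past the window end are ignored
  recs2 <- make_subject("P2", "Placebo",
                        alt = list(`-1` = 80, `10` = 100, `200` = 900),
                        tb = list(`-1` = 0.8, `10` = 1.0))
  prof2 <- tibble::as_tibble(derive_profiles(recs2, default_manifest(end = 100)))
  expect_equal(dplyr::filter(prof2, analyte == "ALT")$peak, 100)
})

test_that("the max(ALT, AST) policy takes the per-day larger xULN, then the max over days", {
  recs <- dplyr::bind_rows(
    make_subject("P1", "Placebo",
                 alt = list(`-1` = 40, `10` = 160, `12` = 80),
                 tb = list(`-1` = 0.8, `10` = 1.0)),
    lab_rows("P1", "Placebo", "AST", c(-1, 10, 12), c(40, 40, 240), uln = 40)
  )
  prof <- tibble::as_tibble(
    derive_profiles(recs, default_manifest(), at_policy = "max_alt_ast"))
  at <- dplyr::filter(prof, analyte == "AT")
  ## day 10: ALT 4x vs AST 1x -> 4; day 12: ALT 2x vs AST 6x -> 6; max = 6
  expect_equal(at$peak_xuln, 6)
  alt_only <- tibble::as_tibble(derive_profiles(recs, default_manifest()))
  expect_equal(dplyr::filter(alt_only, analyte == "AT")$peak_xuln, 4)
})

test_that("zero baseline leaves xBL undefined but keeps xULN analyses", {
  recs <- make_subject("P1", "Placebo",
                       alt = list(`-1` = 0, `10` = 100),
                       tb = list(`-1` = 0.8, `10` = 1.0))
  prof <- tibble::as_tibble(derive_profiles(recs, default_manifest()))
  alt <- dplyr::filter(prof, analyte == "ALT")
  expect_false(alt$xbl_defined)
  expect_true(is.na(alt$peak_xbl))
  expect_equal(alt$peak_xuln, 2.5)
  mp <- mdish_points(derive_profiles(recs, default_manifest()))
  expect_equal(nrow(mp), 0)
  expect_equal(nrow(attr(mp, "excluded")), 1)
})

test_that("profiles round-trip through the CSV writer and reader", {
  sim <- simulate_trial(synthetic_spec(n_placebo = 8, n_active = 8,
                                       visit_days = c(-14, -1, 28, 56),
                                       seed = 42))
  path <- withr::local_tempfile(fileext = ".csv")
  write_lab_csv(sim$records, path)
  back <- read_lab_csv(path, active_arm = sim$manifest$active,
                       treatment_end_day = sim$manifest$treatment_end_day,
                       followup_lag_days = sim$manifest$followup_lag_days)
  p1 <- tibble::as_tibble(derive_profiles(sim$records, sim$manifest))
  p2 <- tibble::as_tibble(derive_profiles(back$records, back$manifest))
  expect_equal(p1, p2)
})

test_that("analyzable plus flagged subjects account for every enrolled subject", {
  recs <- dplyr::bind_rows(
    make_subject("P1", "Placebo", alt = list(`-1` = 80, `28` = 90),
                 tb = list(`-1` = 0.8, `28` = 1.0)),
    make_subject("P2", "Placebo", alt = list(`28` = 90),      # no baseline
                 tb = list(`-1` = 0.8, `28` = 1.0)),
    make_subject("P3", "Active", alt = list(`-1` = 80),        # no on-trt
                 tb = list(`-1` = 0.8, `28` = 1.0))
  )
  prof <- tibble::as_tibble(derive_profiles(recs, default_manifest()))
  alt <- dplyr::filter(prof, analyte == "ALT")
  expect_equal(sum(alt$analyzable) + sum(!alt$analyzable), 3)
  expect_equal(sum(alt$analyzable), 1)
})
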