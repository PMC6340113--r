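# Fold changes, CI-overlap comparisons, I/O, and the pipeline driver.

test_that("fold change is symmetric, >= 1, and rounds to 2 s.f.", {
  expect_equal(fold_change(390e-9, 1e-9), 390)
  expect_equal(fold_label(fold_change(530e-9, 7e-9)), 76)
  expect_identical(fold_change(20e-9, 20e-9), 1)
  expect_identical(fold_change(3e-9, 7e-9), fold_change(7e-9, 3e-9))
  expect_gte(fold_change(2e-9, 5e-9), 1)
  expect_error(fold_change(0, 1e-9), "affinities")
})

test_that("non-overlapping-CI rule is conservative at shared endpoints", {
  mk <- function(est, lo, hi) list(estimate = est, ci = c(lo, hi))
  expect_true(compare_nonoverlapping_ci(mk(1.5, 1, 2), mk(3.5, 3, 4))$significant)
  expect_false(compare_nonoverlapping_ci(mk(2, 1, 3), mk(3, 2, 4))$significant)
  # boundary touch counts as overlap
  expect_false(compare_nonoverlapping_ci(mk(2.5, 2, 3), mk(3.5, 3, 4))$significant)
  cmp <- compare_nonoverlapping_ci(mk(2, 1, 3), mk(8, 7, 9))
  expect_equal(cmp$fold, 4)
  # non-converged fits refuse comparison
  flat <- fit_one_site(titration_curve(nominal_cam_series(), rep(150, 24)))
  ref <- compare_nonoverlapping_ci(flat, mk(2, 1, 3))
  expect_false(ref$comparable)
  expect_true(is.na(ref$significant))
  expect_match(ref$flag, "refused")
})

test_that("plate CSV round-trips exactly", {
  pl <- simulate_plate(plate_design(), simulation_truth(), seed = 4)
  path <- tempfile(fileext = ".csv")
  write_plate_csv(pl, path)
  back <- read_plate_csv(path)
  expect_equal(back$fa, pl$fa, tolerance = 0)
  expect_equal(back$cam_tot_M, pl$cam_tot_M, tolerance = 0)
  expect_identical(back$peptide_id, pl$peptide_id)
})

test_that("YAML configs map onto the constructors", {
  dpath <- tempfile(fileext = ".yaml")
  writeLines(c("peptide_id: CaMBD3", "stock_conc: 1.0e-3",
               "n_rows: 8", "ca_lo: 1.0e-9", "ca_hi: 1.0e-4"), dpath)
  d <- design_from_yaml(dpath)
  expect_identical(d$peptide_id, "CaMBD3")
  expect_equal(d$n_rows, 8)
  expect_equal(range(d$row_ca_free), c(1e-9, 1e-4))
  tpath <- tempfile(fileext = ".yaml")
  writeLines(c("kd_apo: 5.3e-7", "kd_sat: 7.0e-9", "noise_sd: 2"), tpath)
  tr <- truth_from_yaml(tpath)
  expect_equal(tr$kd_apo, 530e-9)
  expect_equal(tr$noise_sd, 2)
})

test_that("pipeline runs end to end, deterministically, with artifacts", {
  out1 <- tempfile(); out2 <- tempfile()
  b1 <- run_pipeline(plate_design(), simulation_truth(), seed = 9,
                     replicates = 2, outdir = out1)
  b2 <- run_pipeline(plate_design(), simulation_truth(), seed = 9,
                     replicates = 2, outdir = out2)
  expect_identical(b1$plates, b2$plates)
  expect_identical(b1$row_fits, b2$row_fits)
  expect_identical(b1$profile, b2$profile)
  # emitted artifact set
  files <- list.files(out1)
  expect_true(all(c("plate01.csv", "plate02.csv", "row_fits.json",
                    "profile.csv", "hill_fits.json", "metadata.json")
                  %in% files))
  # written bundles are byte-identical across same-seed runs
  for (f in files)
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  # a different seed changes the data
  b3 <- run_pipeline(plate_design(), simulation_truth(), seed = 10)
  expect_false(identical(b1$plates, b3$plates))
})

test_that("refitting persisted plate CSVs reproduces the fits exactly", {
  out <- tempfile()
  b <- run_pipeline(plate_design(), simulation_truth(), seed = 12,
                    replicates = 2, outdir = out)
  back <- rbind(read_plate_csv(file.path(out, "plate01.csv")),
                read_plate_csv(file.path(out, "plate02.csv")))
  refits <- lapply(plate_curves(back), function(cv) {
    f1 <- fit_one_site(cv)
    f2 <- fit_two_mode(cv)
    select_model(f1, f2)
  })
  s1 <- jsonlite::toJSON(lapply(b$row_fits, unclass), digits = NA)
  s2 <- jsonlite::toJSON(lapply(refits, unclass), digits = NA)
  expect_identical(s1, s2)
})
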