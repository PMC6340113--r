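# Plate simulator, peptide registry, and concentration helpers.

test_that("serial dilution follows the 3:68 then 38:68 volume scheme", {
  d <- plate_design(stock_conc = 680e-6)
  cs <- dilution_series(d)
  expect_length(cs, 24)
  expect_equal(cs[1], 680e-6 * 3 / 68)              # 30 uM top
  expect_equal(cs[2], 30e-6 * 38 / 68)              # 16.7647 uM
  expect_equal(cs[24], 30e-6 * (38 / 68)^23)        # ~46.2 pM
  expect_true(all(diff(cs) < 0))
  # the series spans more than five orders of magnitude
  expect_gt(cs[1] / cs[24], 1e5)
  expect_error(plate_design(v_transfer = 0), "volumes")
})

test_that("K_D linkage profile interpolates monotonically between plateaus", {
  tr <- simulation_truth(kd_apo = 390e-9, kd_sat = 1e-9, pca_mid = 30e-9)
  expect_equal(kd_linkage_profile(tr, 0), 390e-9)
  expect_equal(kd_linkage_profile(tr, 1), 1e-9, tolerance = 1e-6)
  expect_equal(kd_linkage_profile(tr, 30e-9), sqrt(390e-9 * 1e-9),
               tolerance = 1e-12)
  ca <- 10^seq(-10, -4, length.out = 50)
  expect_true(all(diff(kd_linkage_profile(tr, ca)) <= 0))
  expect_error(simulation_truth(kd_apo = 1e-9, kd_sat = 390e-9), "kd_sat")
})

test_that("simulated plates are reproducible and noiselessly exact", {
  d <- plate_design()
  tr0 <- simulation_truth(noise_sd = 0, pipette_cv = 0)
  pl <- simulate_plate(d, tr0, seed = 1)
  expect_equal(nrow(pl), 16 * 24)
  # noiseless table equals the forward model exactly
  kd <- kd_linkage_profile(tr0, pl$ca_free_M)
  y <- mapply(one_site_saturation, kd, 50e-9, pl$cam_tot_M)
  expect_equal(pl$fa, fa_mixture(y, 150, 250), tolerance = 1e-15)
  # noiseless rows are monotone non-decreasing in CaM
  for (r in unique(pl$row)) {
    pr <- pl[pl$row == r, ]
    expect_true(all(diff(pr$fa[order(pr$cam_tot_M)]) >= 0))
  }
  # same seed, bit-identical output
  tr <- simulation_truth()
  expect_identical(simulate_plate(d, tr, seed = 7),
                   simulate_plate(d, tr, seed = 7))
  expect_false(identical(simulate_plate(d, tr, seed = 7),
                         simulate_plate(d, tr, seed = 8)))
})

test_that("a non-binding probe yields flat rows at the free-peptide signal", {
  d <- plate_design(peptide_id = "null_probe")
  tr <- simulation_truth(kd_apo = Inf, kd_sat = Inf, noise_sd = 3,
                         pipette_cv = 0)
  pl <- simulate_plate(d, tr, seed = 2)
  expect_true(all(abs(pl$fa - 150) < 5 * 3))
  expect_lt(abs(mean(pl$fa) - 150), 1)
})

test_that("pipetting error compounds but preserves monotone dilution", {
  d <- plate_design()
  tr <- simulation_truth(noise_sd = 0, pipette_cv = 0.02)
  pl <- simulate_plate(d, tr, seed = 3)
  nominal <- dilution_series(d)
  for (r in unique(pl$row)) {
    cam <- pl$cam_tot_M[pl$row == r]
    expect_true(all(diff(cam) < 0))
    expect_false(all(cam == nominal))
    # relative deviation grows down the series but stays modest at 2% CV
    expect_lt(max(abs(log(cam / nominal))), 0.02 * sqrt(2 * 24) * 4)
  }
})

test_that("peptide registry reproduces the assay's peptide panel", {
  reg <- ryr2_peptides()
  assay <- reg[reg$id != "null_probe", ]
  expect_equal(nrow(assay), 8)
  expect_equal(assay$length[match(
    c("CaMBD1a", "CaMBD1b", "CaMBD1b+P", "CaMBD2", "CaMBD2(+)",
      "CaMBD2(+)-W/A", "CaMBD2(+)-F/A", "CaMBD3"), assay$id)],
    c(25, 31, 31, 27, 31, 31, 31, 31))
  # sequence length equals the residue span
  expect_equal(assay$length, assay$ryr2_end - assay$ryr2_start + 1)
  # CaMBD2 is the N-terminal 27 residues of CaMBD2(+)
  wt <- assay$sequence[assay$id == "CaMBD2(+)"]
  expect_identical(assay$sequence[assay$id == "CaMBD2"], substr(wt, 1, 27))
  # point substitutions sit at W3587 and F3603 of the wild type
  wa <- assay$sequence[assay$id == "CaMBD2(+)-W/A"]
  fa_ <- assay$sequence[assay$id == "CaMBD2(+)-F/A"]
  diff_at <- function(a, b) which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  expect_identical(diff_at(wt, wa), 3587L - 3581L + 1L)
  expect_identical(substr(wt, 7, 7), "W"); expect_identical(substr(wa, 7, 7), "A")
  expect_identical(diff_at(wt, fa_), 3603L - 3581L + 1L)
  expect_identical(substr(wt, 23, 23), "F"); expect_identical(substr(fa_, 23, 23), "A")
  # phosphosite of CaMBD1b+P falls inside its span, on a serine
  mod <- reg$modifications[reg$id == "CaMBD1b+P"][[1]][[1]]
  expect_identical(mod$type, "phospho")
  seq1b <- reg$sequence[reg$id == "CaMBD1b"]
  expect_identical(substr(seq1b, mod$position - 2022 + 1,
                          mod$position - 2022 + 1), "S")
})

test_that("Beer-Lambert helper converts absorbance to concentration", {
  expect_identical(conc_from_absorbance(0, 103000), 0)
  expect_equal(conc_from_absorbance(0.103, 103000), 1e-6)
  expect_equal(conc_from_absorbance(0.00515, 103000), 50e-9)
  expect_error(conc_from_absorbance(0.1, -1), "epsilon")
  expect_error(conc_from_absorbance(-0.1, 103000), "absorbance")
})
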