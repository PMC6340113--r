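# Row-wise K_D estimation, model selection, and affinity profiles.

test_that("noiseless one-site data are recovered exactly", {
  for (kd in c(1e-9, 100e-9, 1e-6)) {
    f <- fit_one_site(make_one_site_curve(kd, sigma = 0))
    expect_true(f$converged)
    expect_equal(f$kd, kd, tolerance = 1e-3 * 1e-3)  # well below 0.1%
    expect_equal(f$fa_p, 150, tolerance = 1e-8)
    expect_equal(f$fa_pcam, 250, tolerance = 1e-8)
    expect_lt(f$rss, 1e-18)
    # exact data: the asymptotic CI collapses onto the estimate
    expect_true(f$ci95$kd[1] <= f$kd & f$kd <= f$ci95$kd[2])
  }
})

test_that("K_D recovery is unbiased and CIs calibrated across the window", {
  # 200 noisy rows per generating K_D spanning the measurable window
  for (kd in c(1e-9, 10e-9, 100e-9, 1e-6, 5e-6)) {
    set.seed(round(1e6 * log10(kd)) %% 10000)
    fits <- replicate(200, fit_one_site(make_one_site_curve(kd)),
                      simplify = FALSE)
    est <- vapply(fits, function(f) f$kd, numeric(1))
    expect_lt(abs(stats::median(est) / kd - 1), 0.15)
    cover <- mean(vapply(fits, function(f)
      is.finite(f$ci95$kd[1]) && f$ci95$kd[1] <= kd && kd <= f$ci95$kd[2],
      logical(1)))
    expect_gte(cover, 0.90)
    expect_lte(cover, 0.99)
    expect_true(all(vapply(fits, function(f) isTRUE(f$converged), logical(1))))
  }
})

test_that("affinities outside the measurable window are flagged unreliable", {
  for (kd in c(0.1e-9, 50e-6)) {
    set.seed(if (kd < 1e-9) 101 else 102)
    unreliable <- mean(replicate(100, {
      f <- fit_one_site(make_one_site_curve(kd))
      !isTRUE(f$reliable)
    }))
    expect_gt(unreliable, 0.90)
  }
})

test_that("flat curves yield a no-binding flag instead of a K_D", {
  set.seed(11)
  for (i in 1:25) {
    cam <- nominal_cam_series()
    f <- fit_one_site(titration_curve(cam, rep(150, 24) + rnorm(24, 0, 3)))
    expect_false(f$converged)
    expect_identical(f$flag, "no-binding/unresolvable")
    expect_true(is.na(f$kd))
  }
  # exactly flat noiseless curve
  f0 <- fit_one_site(titration_curve(nominal_cam_series(), rep(150, 24)))
  expect_identical(f0$flag, "no-binding/unresolvable")
})

test_that("two-mode fits recover both modes and enforce their order", {
  f <- fit_two_mode(make_two_mode_curve(2e-6, 20e-6, sigma = 0))
  expect_true(f$converged)
  expect_equal(f$kd_I, 2e-6, tolerance = 1e-4)
  expect_equal(f$kd_II, 20e-6, tolerance = 1e-4)
  expect_gte(f$kd_II, f$kd_I)   # enforced by the r >= 1 parameterisation
  expect_identical(f$kd, f$kd_I)
  # far sub-K_D concentrations: nothing binds
  cam <- nominal_cam_series() * 1e-4
  f2 <- fit_two_mode(titration_curve(cam, rep(150, 24)))
  expect_identical(f2$flag, "no-binding/unresolvable")
})

test_that("model selection has power on two-mode data", {
  set.seed(21)
  picked <- mean(replicate(200, {
    cv <- make_two_mode_curve(2e-6, 20e-6, sigma = 3)
    select_model(fit_one_site(cv), fit_two_mode(cv))$model == "two_mode"
  }))
  expect_gte(picked, 0.80)
})

test_that("model selection controls false two-mode calls on one-site data", {
  set.seed(22)
  res <- replicate(500, {
    cv <- make_one_site_curve(390e-9, sigma = 3)
    ch <- select_model(fit_one_site(cv), fit_two_mode(cv))
    s <- attr(ch, "selection")
    c(two = ch$model == "two_mode",
      flagged = identical(s$two_mode_flag, "two-mode unsupported"))
  })
  # selection rate well under the nominal level (ratio gate is conservative)
  expect_lte(mean(res["two", ]), 0.05 * 1.5)
  # the superfluous second mode is usually identifiably unsupported
  expect_gt(mean(res["flagged", ]), 0.75)
})

test_that("selection tie-breaks to the one-site model", {
  cv <- make_one_site_curve(100e-9, sigma = 0)
  f1 <- fit_one_site(cv)
  f2 <- fit_two_mode(cv)
  ch <- select_model(f1, f2)
  expect_identical(ch$model, "one_site")
  # non-converged inputs propagate
  flat <- titration_curve(nominal_cam_series(), rep(150, 24))
  nb <- fit_one_site(flat)
  ch2 <- select_model(nb, f2)
  expect_identical(ch2$model, "two_mode")
  expect_match(attr(ch2, "selection")$reason, "non-converged")
})

test_that("affinity profiles summarise replicates on the log scale", {
  mk <- function(kd, ca, rep) {
    f <- fit_one_site(make_one_site_curve(kd, sigma = 0))
    f$ca_free <- ca; f$replicate <- rep
    f
  }
  # replicates {100, 200, 400} nM: geometric mean 200 nM
  prof <- build_affinity_profile(list(
    mk(100e-9, 1e-8, 1), mk(200e-9, 1e-8, 2), mk(400e-9, 1e-8, 3)))
  expect_equal(prof$kd_M, 200e-9, tolerance = 1e-6)
  expect_equal(prof$n_replicates, 3)
  expect_true(prof$ci_lo_M < prof$kd_M & prof$kd_M < prof$ci_hi_M)

  # three identical replicates: zero-width CI at the common value
  prof2 <- build_affinity_profile(list(
    mk(100e-9, 1e-8, 1), mk(100e-9, 1e-8, 2), mk(100e-9, 1e-8, 3)))
  expect_equal(prof2$ci_lo_M, prof2$kd_M, tolerance = 1e-9)
  expect_equal(prof2$ci_hi_M, prof2$kd_M, tolerance = 1e-9)

  # single replicate: passthrough with its asymptotic CI
  f <- mk(100e-9, 1e-8, 1)
  prof3 <- build_affinity_profile(list(f))
  expect_equal(prof3$kd_M, f$kd)
  expect_equal(c(prof3$ci_lo_M, prof3$ci_hi_M), f$ci95$kd)

  # unreliable fits are excluded and counted; empty input errors
  out <- mk(100e-9, 1e-8, 1); out$reliable <- FALSE
  prof4 <- build_affinity_profile(list(mk(100e-9, 2e-8, 1), out))
  expect_equal(attr(prof4, "n_excluded"), 1)
  expect_equal(nrow(prof4), 1)
  expect_error(build_affinity_profile(list(out)), "no converged")
})

test_that("plate rows round-trip into curves sorted by Ca2+", {
  pl <- simulate_plate(plate_design(), simulation_truth(), seed = 5)
  curves <- plate_curves(pl)
  expect_length(curves, 16)
  expect_true(all(diff(vapply(curves, function(cv) cv$ca_free,
                              numeric(1))) > 0))
  expect_true(all(vapply(curves, function(cv) all(diff(cv$cam_tot) < 0),
                         logical(1))))
  expect_error(plate_curves(pl[, -5]), "lacks columns")
})
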