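# Shared fixtures: all data are generated in code at test time.

# The assay's nominal 24-point CaM dilution (30 uM top, 38:68 steps).
nominal_cam_series <- function() dilution_series(plate_design())

# One noisy one-site titration row at a fixed generating K_D.
make_one_site_curve <- function(kd, sigma = 3, fa_lo = 150, fa_hi = 250,
                                p_tot = 50e-9, cam = nominal_cam_series()) {
  fa <- fa_mixture(one_site_saturation(kd, p_tot, cam), fa_lo, fa_hi)
  if (sigma > 0) fa <- fa + stats::rnorm(length(cam), 0, sigma)
  titration_curve(cam, fa, peptide_conc = p_tot)
}

# One noisy two-mode titration row.
make_two_mode_curve <- function(kd_I, kd_II, sigma = 3, fa_lo = 150,
                                fa_hi = 250, cam = nominal_cam_series()) {
  fa <- fa_mixture(two_mode_saturation(kd_I, kd_II, cam), fa_lo, fa_hi)
  if (sigma > 0) fa <- fa + stats::rnorm(length(cam), 0, sigma)
  titration_curve(cam, fa)
}

# One noisy Hill Ca2+ response on the 16-point pCa grid.
make_hill_curve <- function(app_kd, n = 2, sigma = 3, fa_lo = 150,
                            fa_hi = 250, ca = default_ca_series(16)) {
  fa <- fa_mixture(hill_saturation(app_kd, n, ca), fa_lo, fa_hi)
  if (sigma > 0) fa <- fa + stats::rnorm(length(ca), 0, sigma)
  ca_response(ca, fa)
}

# Median fitted K_D (molar) over n_rep seeded noisy rows.
median_recovered_kd <- function(kd, n_rep = 200, sigma = 3) {
  stats::median(replicate(n_rep, fit_one_site(make_one_site_curve(kd, sigma))$kd))
}
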