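# Synthetic 384-well plate generator: 16 pCa rows x 24 CaM-dilution columns,
# plus the peptide registry and absorbance-based concentration helpers.

#' RyR2 CaMBD peptide registry
#'
#' Loads the packaged registry of RyR2-derived CaM-binding-domain peptides
#' (human RyR2 numbering): sequences, residue spans, modifications, and the
#' free-dye control `null_probe`. All assay peptides carry an N-terminal
#' 5-TAMRA label.
#'
#' @return A data frame with columns `id`, `ryr2_start`, `ryr2_end`,
#'   `sequence`, `length`, `modifications` (list column).
#' @examples
#' ryr2_peptides()[, c("id", "length")]
#' @export
ryr2_peptides <- function() {
  path <- system.file("extdata", "ryr2_peptides.json", package = "camtitr",
                      mustWork = TRUE)
  reg <- jsonlite::read_json(path)
  pep <- reg$peptides
  data.frame(
    id = vapply(pep, `[[`, character(1), "id"),
    ryr2_start = vapply(pep, function(p) ifelse(is.null(p$ryr2_start), NA_integer_,
                                                as.integer(p$ryr2_start)), integer(1)),
    ryr2_end = vapply(pep, function(p) ifelse(is.null(p$ryr2_end), NA_integer_,
                                              as.integer(p$ryr2_end)), integer(1)),
    sequence = vapply(pep, `[[`, character(1), "sequence"),
    length = vapply(pep, function(p) nchar(p$sequence), integer(1)),
    modifications = I(lapply(pep, `[[`, "modifications")),
    stringsAsFactors = FALSE)
}

#' Plate design for the two-dimensional titration
#'
#' Encodes the physical layout of one 384-well titration plate: one free
#' Ca2+ per row, a serial CaM dilution across the 24 columns, and a fixed
#' labelled-peptide concentration everywhere. Column 1 receives 3 ul of
#' CaM stock into 65 ul of buffer; each subsequent column is made by
#' transferring 38 ul into 30 ul of buffer (dilution factor 38/68).
#'
#' @param peptide_id Peptide label (see [ryr2_peptides()]).
#' @param peptide_conc Labelled peptide concentration (molar; ~50 nM).
#' @param stock_conc CaM stock concentration (molar; assay range
#'   600-1200 uM, default 680 uM so the top well is 30 uM).
#' @param row_ca_free Free Ca2+ per row (molar), default the 16-point
#'   log-spaced series 0.3 nM-400 uM.
#' @param n_cols Number of dilution columns (24).
#' @param v_stock,v_first,v_well,v_transfer Pipetting volumes in ul.
#' @return An object of class `plate_design`.
#' @export
plate_design <- function(peptide_id = "CaMBD2", peptide_conc = 50e-9,
                         stock_conc = 680e-6,
                         row_ca_free = default_ca_series(16),
                         n_cols = 24L, v_stock = 3, v_first = 65,
                         v_well = 30, v_transfer = 38) {
  if (any(c(v_stock, v_first, v_well, v_transfer) <= 0))
    stop("all volumes must be > 0", call. = FALSE)
  stopifnot(peptide_conc > 0, stock_conc > 0, n_cols >= 2,
            all(row_ca_free >= 0))
  structure(
    list(peptide_id = peptide_id, peptide_conc = peptide_conc,
         stock_conc = stock_conc, row_ca_free = as.numeric(row_ca_free),
         n_rows = length(row_ca_free), n_cols = as.integer(n_cols),
         v_stock = v_stock, v_first = v_first, v_well = v_well,
         v_transfer = v_transfer),
    class = "plate_design")
}

#' Nominal serial-dilution series of a plate design
#'
#' Column 1: `stock * v_stock / (v_stock + v_first)`; each later column is
#' the previous times `v_transfer / (v_transfer + v_well)` (38/68 by
#' default). The 24-point series spans more than five orders of magnitude.
#'
#' @param design A [plate_design()].
#' @return Numeric vector of `n_cols` total CaM concentrations (molar),
#'   strictly decreasing.
#' @examples
#' dilution_series(plate_design(stock_conc = 680e-6))[1]  # 30 uM top
#' @export
dilution_series <- function(design) {
  stopifnot(inherits(design, "plate_design"))
  c1 <- design$stock_conc * design$v_stock / (design$v_stock + design$v_first)
  d <- design$v_transfer / (design$v_transfer + design$v_well)
  c1 * d^(seq_len(design$n_cols) - 1)
}

#' Generating truth for plate simulation
#'
#' Bundles the parameters of the data-generating process: a monotone
#' Ca2+-dependent K_D profile (log-logistic between the apo and
#' Ca2+-saturated affinities), FA endpoint signals, and the two noise
#' sources (additive Gaussian anisotropy noise; compounding per-transfer
#' pipetting error).
#'
#' Defaults emulate the CaM-CaMBD2 interaction: K_D 390 nM at vanishing
#' Ca2+ falling to 1 nM at saturating Ca2+, transition midpoint 30 nM free
#' Ca2+, slope 2 (two EF-hands per CaM domain), bound-state FA in the
#' observed 240-260 plateau range. Setting both affinities to `Inf` makes
#' a non-binding probe (free-dye control).
#'
#' @param kd_apo K_D at zero Ca2+ (molar).
#' @param kd_sat K_D at saturating Ca2+ (molar; must be <= `kd_apo`).
#' @param pca_mid Free Ca2+ at the log-K_D transition midpoint (molar).
#' @param slope Transition steepness (dimensionless).
#' @param fa_free,fa_bound FA signal of free and fully bound peptide.
#' @param noise_sd Additive anisotropy noise SD (signal units).
#' @param pipette_cv Relative SD of every pipetted volume.
#' @return An object of class `simulation_truth`.
#' @export
simulation_truth <- function(kd_apo = 390e-9, kd_sat = 1e-9,
                             pca_mid = 30e-9, slope = 2,
                             fa_free = 150, fa_bound = 250,
                             noise_sd = 3, pipette_cv = 0.02) {
  if (!is.na(kd_sat) && !is.na(kd_apo) && kd_sat > kd_apo)
    stop("kd_sat must be <= kd_apo (affinity increases with Ca2+)",
         call. = FALSE)
  stopifnot(noise_sd >= 0, pipette_cv >= 0, pca_mid > 0, slope > 0)
  structure(
    list(kd_apo = kd_apo, kd_sat = kd_sat, pca_mid = pca_mid, slope = slope,
         fa_free = fa_free, fa_bound = fa_bound,
         noise_sd = noise_sd, pipette_cv = pipette_cv),
    class = "simulation_truth")
}

#' Ca2+-dependent generating K_D profile
#'
#' Smooth monotone non-increasing profile on the log scale:
#' `log10 K_D(ca) = log10 kd_sat + (log10 kd_apo - log10 kd_sat) /
#' (1 + (ca / pca_mid)^slope)`. At `ca = pca_mid` the profile passes
#' through the geometric mean of the two plateaus.
#'
#' @param truth A [simulation_truth()].
#' @param ca Free Ca2+ concentration(s) (molar, >= 0); vectorised.
#' @return K_D value(s) in molar (`Inf` for a non-binding truth).
#' @export
kd_linkage_profile <- function(truth, ca) {
  stopifnot(inherits(truth, "simulation_truth"), all(ca >= 0))
  if (is.infinite(truth$kd_apo) && is.infinite(truth$kd_sat))
    return(rep(Inf, length(ca)))
  lsat <- log10(truth$kd_sat)
  lapo <- log10(truth$kd_apo)
  10^(lsat + (lapo - lsat) / (1 + (ca / truth$pca_mid)^truth$slope))
}

#' Simulate one two-dimensional titration plate
#'
#' For every well: the row's free Ca2+ sets the generating K_D through
#' [kd_linkage_profile()], the fractional saturation comes from the exact
#' ligand-depletion isotherm, the FA signal from the mole-fraction mixture
#' of the endpoint signals, plus additive Gaussian noise. When
#' `pipette_cv > 0` every pipetted volume in the serial dilution carries an
#' independent relative error, so concentration errors compound down each
#' row exactly as in a real serial dilution. The same `seed` reproduces the
#' table bit for bit.
#'
#' @param design A [plate_design()].
#' @param truth A [simulation_truth()].
#' @param seed Integer seed for the plate's random number stream
#'   (`NULL` uses the current RNG state).
#' @param plate_id,replicate Identifiers copied into the output table.
#' @return Long-format data frame with columns `plate_id`, `replicate`,
#'   `row`, `col`, `ca_free_M`, `cam_tot_M`, `peptide_id`,
#'   `peptide_conc_M`, `fa`.
#' @export
simulate_plate <- function(design, truth, seed = NULL,
                           plate_id = "plate1", replicate = 1L) {
  stopifnot(inherits(design, "plate_design"), inherits(truth, "simulation_truth"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  nr <- design$n_rows; nc <- design$n_cols
  rows <- vector("list", nr)
  for (r in seq_len(nr)) {
    cam <- .noisy_dilution(design, truth$pipette_cv)
    kd <- kd_linkage_profile(truth, design$row_ca_free[r])
    y <- one_site_saturation(kd, design$peptide_conc, cam)
    fa <- fa_mixture(y, truth$fa_free, truth$fa_bound)
    if (truth$noise_sd > 0) fa <- fa + stats::rnorm(nc, 0, truth$noise_sd)
    rows[[r]] <- data.frame(
      plate_id = plate_id, replicate = as.integer(replicate),
      row = r, col = seq_len(nc),
      ca_free_M = design$row_ca_free[r], cam_tot_M = cam,
      peptide_id = design$peptide_id, peptide_conc_M = design$peptide_conc,
      fa = fa, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# One row's dilution series with per-transfer volume errors compounding
# down the series. cv = 0 reduces to the nominal dilution_series().
.noisy_dilution <- function(design, cv) {
  if (cv == 0) return(dilution_series(design))
  jitter <- function(v) v * (1 + stats::rnorm(1, 0, cv))
  vs <- jitter(design$v_stock); vf <- jitter(design$v_first)
  conc <- numeric(design$n_cols)
  conc[1] <- design$stock_conc * vs / (vs + vf)
  for (k in 2:design$n_cols) {
    vt <- jitter(design$v_transfer); vw <- jitter(design$v_well)
    conc[k] <- conc[k - 1] * vt / (vt + vw)
  }
  conc
}

#' Concentration from absorbance (Beer-Lambert)
#'
#' `c = A / (epsilon * path)`. Used with epsilon_556 = 103,000 /M/cm for
#' 5-TAMRA-labelled peptides and epsilon_280 = 2,560 /M/cm for intact CaM.
#'
#' @param a Absorbance (>= 0).
#' @param epsilon Molar extinction coefficient (/M/cm, > 0).
#' @param path Path length in cm (> 0).
#' @return Concentration in molar.
#' @examples
#' conc_from_absorbance(0.00515, 103000)  # 50 nM working peptide
#' @export
conc_from_absorbance <- function(a, epsilon, path = 1) {
  if (any(a < 0)) stop("absorbance must be >= 0", call. = FALSE)
  if (epsilon <= 0 || path <= 0)
    stop("epsilon and path must be > 0", call. = FALSE)
  a / (epsilon * path)
}
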