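#!/usr/bin/env Rscript
# Simulate duplicate 384-well titration plates for the two high-affinity
# RyR2 peptides. Each plate: 16 free-Ca2+ rows (0.3 nM-400 uM), 24-point
# CaM serial dilution (30 uM top), 50 nM labelled peptide, FA noise sd 3,
# 2% pipetting CV. The generating K_D profiles interpolate between the
# published apo and Ca2+-saturated affinities (CaMBD2: 390 -> 1 nM;
# CaMBD3: 530 -> 7 nM), with transition midpoints at the published
# apparent Ca2+ affinities of the complexes (20 and 67 nM).

library(camtitr)

outdir <- "results/plates"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

scenarios <- list(
  CaMBD2 = simulation_truth(kd_apo = 390e-9, kd_sat = 1e-9,
                            pca_mid = 20e-9, slope = 2),
  CaMBD3 = simulation_truth(kd_apo = 530e-9, kd_sat = 7e-9,
                            pca_mid = 67e-9, slope = 2))

set.seed(101)
for (pep in names(scenarios)) {
  design <- plate_design(peptide_id = pep)
  for (rep in 1:2) {
    plate <- simulate_plate(design, scenarios[[pep]],
                            plate_id = sprintf("%s_rep%d", pep, rep),
                            replicate = rep)
    path <- file.path(outdir, sprintf("%s_rep%d.csv", pep, rep))
    write_plate_csv(plate, path)
    cat(sprintf("%s replicate %d: %d wells, FA %.0f-%.0f -> %s\n",
                pep, rep, nrow(plate), min(plate$fa), max(plate$fa), path))
  }
}

series <- dilution_series(plate_design())
cat(sprintf("CaM dilution series: %.3g uM down to %.3g pM (%d points)\n",
            series[1] * 1e6, series[24] * 1e12, length(series)))
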