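# camtitr

Two-dimensional fluorescence-anisotropy (FA) titration analysis of
calmodulin (CaM) binding to RyR2-derived CaM-binding-domain (CaMBD)
peptides.

CaM inhibits the cardiac ryanodine receptor RyR2 in a Ca²⁺-dependent
manner. The assay this package analyses measures that regulation on one
384-well plate: 16 rows, each clamped at a different free Ca²⁺
(0.3 nM–400 µM) by an EGTA/NTA buffer system, crossed with a 24-point
serial dilution of CaM against a fixed ~50 nM 5-TAMRA-labelled peptide.
Row-wise fits give the CaM–peptide dissociation constant K_D as a
function of free Ca²⁺; column-wise fits give the apparent Ca²⁺ affinity
(appK_D) of the CaM/peptide complex. The package is for quantitative
binding biophysicists running (or simulating) such plate titrations.

## The models

Because bound CaM is never negligible against 50 nM peptide, the
fractional saturation uses the exact ligand-depletion isotherm — the
physical root of the mass-action quadratic:

    Y = [ b − sqrt(b² − 4·P·C) ] / (2·P),   b = K_D + P + C

with P = [peptide]_tot and C = [CaM]_tot, evaluated in a
cancellation-free form that is stable down to K_D ≪ P. The measured
signal is the affine mixture FA = FA_P·(1−Y) + FA_PCaM·Y. Rows that a
1:1 model cannot describe are offered a two-mode alternative
Y = C/(K_DI+C) + C/(K_DII+C) behind an F-test with a required mode
separation K_DII/K_DI ≥ 5. Column-wise Ca²⁺ responses are summarised by
the Hill model Y = 1/((appK_D/[Ca²⁺])ⁿ + 1). All fits are nonlinear
least squares on raw FA with asymptotic 95 % CIs; affinities are fitted
on the log₁₀ scale. A seeded synthetic-plate generator (serial-dilution
mechanics, log-logistic K_D-versus-Ca²⁺ linkage, FA noise, compounding
pipetting error) backs every stage with parameter-recovery tests.

See `vignettes/camtitr-methods.Rmd` for the full account of the models,
numerical choices and limitations.

## Worked example

```r
library(camtitr)

design <- plate_design(peptide_id = "CaMBD2")                  # 16 x 24 wells
truth  <- simulation_truth(kd_apo = 390e-9, kd_sat = 1e-9,     # K_D profile
                           pca_mid = 20e-9)
plate  <- simulate_plate(design, truth, seed = 42)

row1 <- plate_curves(plate)[[1]]          # lowest-Ca2+ row
fit  <- fit_one_site(row1)
sprintf("K_D at %.2g nM free Ca2+: %.0f nM (95%% CI %.0f-%.0f nM)",
        row1$ca_free * 1e9, fit$kd * 1e9,
        fit$ci95$kd[1] * 1e9, fit$ci95$kd[2] * 1e9)
#> "K_D at 0.3 nM free Ca2+: 407 nM (95% CI 343-483 nM)"

resp <- extract_ca_response(plate, target_ratio = 4)
hill <- fit_hill(resp)
sprintf("appK_D (column %d, CaM:peptide %.1f): %.1f nM, Hill n = %.2f",
        resp$column_index, resp$ratio, hill$app_kd * 1e9, hill$n)
#> "appK_D (column 10, CaM:peptide 3.2): 13.0 nM, Hill n = 2.89"

fold_label(fold_change(390e-9, 1e-9))
#> 390
```

The first fit recovers the generating apo affinity (390 nM) from one
noisy 24-point row, with its asymptotic CI. The Hill fit summarises the
Ca²⁺ response of the complex at a CaM:peptide ratio of ~4; its appK_D is
an apparent quantity that tracks, but does not exactly equal, the
generating transition midpoint. `fold_change()`/`fold_label()` implement
the 2-significant-figure fold-reporting convention.

## Analysis workflow

Numbered drivers under `analysis/` run the full study over synthetic
plates and write their tables under `results/`:

```sh
Rscript analysis/01_simulate_plates.R    # duplicate CaMBD2/CaMBD3 plates
Rscript analysis/02_fit_titrations.R     # row-wise K_D profiles + CIs
Rscript analysis/03_calcium_affinity.R   # column-wise Hill appK_D fits
Rscript analysis/04_headline_numbers.R   # fold changes, CI comparisons
```

Each script states what it found on stdout; all computation lives in the
package functions.

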