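#!/usr/bin/env Rscript
# Column-wise Ca2+ affinity of the CaM/peptide complexes: extract the
# FA-versus-Ca2+ curve at a CaM:peptide ratio of ~4 from each replicate
# plate and fit the Hill model for the apparent Ca2+ affinity (appK_D).

library(camtitr)

outdir <- "results/hill"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

summary_rows <- list()
for (pep in c("CaMBD2", "CaMBD3")) {
  for (rep in 1:2) {
    plate <- read_plate_csv(sprintf("results/plates/%s_rep%d.csv", pep, rep))
    crv <- extract_ca_response(plate, target_ratio = 4)
    fit <- fit_hill(crv)
    cat(sprintf(
      "%s rep %d (column %d, ratio %.1f): appK_D %.1f nM (95%% CI %.1f-%.1f), n = %.2f\n",
      pep, rep, crv$column_index, crv$ratio, fit$app_kd * 1e9,
      fit$ci95$app_kd[1] * 1e9, fit$ci95$app_kd[2] * 1e9, fit$n))
    utils::write.csv(normalize_response(crv, fit),
                     file.path(outdir, sprintf("%s_rep%d_response.csv", pep, rep)),
                     row.names = FALSE)
    summary_rows[[paste(pep, rep)]] <- data.frame(
      peptide = pep, replicate = rep, column = crv$column_index,
      ratio = crv$ratio, app_kd_M = fit$app_kd, hill_n = fit$n,
      ci_lo = fit$ci95$app_kd[1], ci_hi = fit$ci95$app_kd[2],
      converged = fit$converged)
  }
}
hill <- do.call(rbind, summary_rows)
utils::write.csv(hill, file.path(outdir, "hill_summary.csv"),
                 row.names = FALSE)
cat("Hill summaries written under", outdir, "\n")
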