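# Headline-number computation (fold changes, CI-overlap comparisons),
# result tables, file I/O, and the end-to-end pipeline driver.

#' Fold change between two affinities
#'
#' `max(kd_a, kd_b) / min(kd_a, kd_b)`: symmetric in its arguments and
#' always >= 1. Reported folds follow the 2-significant-figure convention
#' (see [fold_label()]).
#'
#' @param kd_a,kd_b Affinities (molar or any common unit, > 0).
#' @return Dimensionless fold change >= 1.
#' @examples
#' fold_change(390e-9, 1e-9)   # 390
#' fold_label(fold_change(530e-9, 7e-9))  # 76
#' @export
fold_change <- function(kd_a, kd_b) {
  if (!is.finite(kd_a) || !is.finite(kd_b) || kd_a <= 0 || kd_b <= 0)
    stop("affinities must be finite and > 0", call. = FALSE)
  max(kd_a, kd_b) / min(kd_a, kd_b)
}

#' @rdname fold_change
#' @param fold A fold change from [fold_change()].
#' @export
fold_label <- function(fold) signif(fold, 2)

# Pull (estimate, 95% CI, converged) out of a fit object or plain list.
.est_ci <- function(x) {
  if (inherits(x, "binding_fit"))
    return(list(estimate = x$kd, ci = x$ci95$kd,
                converged = isTRUE(x$converged)))
  if (inherits(x, "hill_fit"))
    return(list(estimate = x$app_kd, ci = x$ci95$app_kd,
                converged = isTRUE(x$converged)))
  if (is.list(x) && !is.null(x$estimate) && !is.null(x$ci))
    return(list(estimate = x$estimate, ci = x$ci,
                converged = !isFALSE(x$converged)))
  stop("cannot extract an estimate and CI from this object", call. = FALSE)
}

#' Compare two fitted affinities by the non-overlapping-95%-CI rule
#'
#' The conservative significance rule used throughout the assay: two
#' affinities differ significantly only when their 95% confidence
#' intervals are disjoint. Intervals sharing an endpoint count as
#' overlapping. Non-converged fits refuse comparison (`comparable =
#' FALSE`, `significant = NA`).
#'
#' @param a,b `binding_fit` or `hill_fit` objects, or lists with elements
#'   `estimate` and `ci` (length-2 numeric).
#' @param a_label,b_label Labels for the report.
#' @return An object of class `ci_comparison`: labels, estimates, CIs,
#'   `fold` (>= 1), `significant`, `comparable`.
#' @export
compare_nonoverlapping_ci <- function(a, b, a_label = "A", b_label = "B") {
  ea <- .est_ci(a); eb <- .est_ci(b)
  out <- list(a_label = a_label, b_label = b_label,
              estimate_a = ea$estimate, estimate_b = eb$estimate,
              ci_a = ea$ci, ci_b = eb$ci,
              fold = NA_real_, significant = NA, comparable = FALSE,
              flag = "")
  if (!ea$converged || !eb$converged) {
    out$flag <- "comparison refused: non-converged input"
    return(structure(out, class = "ci_comparison"))
  }
  if (any(!is.finite(c(ea$ci, eb$ci)))) {
    out$flag <- "comparison refused: non-finite CI"
    return(structure(out, class = "ci_comparison"))
  }
  out$fold <- fold_change(ea$estimate, eb$estimate)
  out$significant <- ea$ci[2] < eb$ci[1] || eb$ci[2] < ea$ci[1]
  out$comparable <- TRUE
  structure(out, class = "ci_comparison")
}

#' Plate table CSV I/O
#'
#' Round-trip the long-format plate schema (`plate_id`, `replicate`,
#' `row`, `col`, `ca_free_M`, `cam_tot_M`, `peptide_id`,
#' `peptide_conc_M`, `fa`).
#'
#' @param plate Plate table.
#' @param path File path.
#' @return `read_plate_csv()` returns the plate data frame;
#'   `write_plate_csv()` returns `path` invisibly.
#' @export
write_plate_csv <- function(plate, path) {
  out <- plate
  for (nm in names(out))   # 17 significant digits: doubles round-trip exactly
    if (is.double(out[[nm]])) out[[nm]] <- sprintf("%.17g", out[[nm]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_plate_csv
#' @export
read_plate_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a plate design or simulation truth from YAML
#'
#' The YAML maps field names directly onto the [plate_design()] /
#' [simulation_truth()] constructor arguments; omitted fields take the
#' constructor defaults. `row_ca_free` may be given explicitly or as
#' `n_rows`/`ca_lo`/`ca_hi` for a log-spaced series.
#'
#' @param path YAML file path.
#' @return A `plate_design` or `simulation_truth` object.
#' @export
design_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$n_rows) && is.null(cfg$row_ca_free)) {
    cfg$row_ca_free <- default_ca_series(
      cfg$n_rows,
      lo = if (is.null(cfg$ca_lo)) 0.3e-9 else cfg$ca_lo,
      hi = if (is.null(cfg$ca_hi)) 400e-6 else cfg$ca_hi)
  }
  cfg$n_rows <- cfg$ca_lo <- cfg$ca_hi <- NULL
  do.call(plate_design, cfg)
}

#' @rdname design_from_yaml
#' @export
truth_from_yaml <- function(path) {
  do.call(simulation_truth, yaml::read_yaml(path))
}

#' Run the full simulate-fit-report pipeline
#'
#' Simulates `replicates` plates under the given design and truth,
#' fits every row (one-site, optionally with two-mode model selection),
#' assembles the K_D-versus-Ca2+ affinity profile, extracts the Ca2+
#' response column at `ratio` from each replicate and fits the Hill
#' model. Deterministic for a given `seed`. When `outdir` is given the
#' bundle is written out: plate CSVs, row fits and Hill fits as JSON, the
#' profile and normalised Ca2+ response as CSV, and a run-metadata log.
#'
#' @param design A [plate_design()].
#' @param truth A [simulation_truth()].
#' @param seed Integer seed controlling all randomness.
#' @param replicates Number of plate replicates (assay: at least 2).
#' @param model `"auto"` (F-test selection), `"one_site"`, or
#'   `"two_mode"`.
#' @param ratio CaM:peptide ratio for the Ca2+ response extraction.
#' @param alpha Significance level for model selection.
#' @param outdir Optional output directory.
#' @return Invisibly, a list with `plates`, `row_fits`, `profile`,
#'   `hill_fits`, `ca_curves`, `metadata`.
#' @export
run_pipeline <- function(design, truth, seed = 1L, replicates = 2L,
                         model = c("auto", "one_site", "two_mode"),
                         ratio = 4, alpha = 0.05, outdir = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(design, "plate_design"), inherits(truth, "simulation_truth"),
            replicates >= 1)
  set.seed(as.integer(seed))
  plates <- lapply(seq_len(replicates), function(r) {
    simulate_plate(design, truth, seed = NULL,
                   plate_id = sprintf("plate%02d", r), replicate = r)
  })
  curves <- plate_curves(do.call(rbind, plates))
  row_fits <- lapply(curves, function(cv) {
    f1 <- fit_one_site(cv)
    if (model == "one_site") return(f1)
    f2 <- fit_two_mode(cv)
    if (model == "two_mode") return(f2)
    select_model(f1, f2, alpha = alpha)
  })
  profile <- tryCatch(build_affinity_profile(row_fits),
                      error = function(e) NULL)
  ca_curves <- lapply(plates, extract_ca_response, target_ratio = ratio)
  hill_fits <- lapply(ca_curves, fit_hill)
  metadata <- list(
    package = "camtitr",
    version = as.character(utils::packageVersion("camtitr")),
    seed = as.integer(seed), replicates = as.integer(replicates),
    model = model, ratio = ratio, alpha = alpha,
    design = unclass(design), truth = unclass(truth),
    kd_window_M = KD_WINDOW)
  bundle <- list(plates = plates, row_fits = row_fits, profile = profile,
                 hill_fits = hill_fits, ca_curves = ca_curves,
                 metadata = metadata)
  if (!is.null(outdir)) .write_bundle(bundle, outdir)
  invisible(bundle)
}

.fit_to_list <- function(f) {
  f <- unclass(f)
  attr(f, "selection") <- NULL
  f
}

.write_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (p in bundle$plates)
    write_plate_csv(p, file.path(outdir, paste0(p$plate_id[1], ".csv")))
  jsonlite::write_json(lapply(bundle$row_fits, .fit_to_list),
                       file.path(outdir, "row_fits.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(bundle$profile))
    utils::write.csv(bundle$profile, file.path(outdir, "profile.csv"),
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(lapply(bundle$hill_fits, .fit_to_list),
                       file.path(outdir, "hill_fits.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (i in seq_along(bundle$hill_fits)) {
    hf <- bundle$hill_fits[[i]]
    if (isTRUE(hf$converged)) {
      norm <- normalize_response(bundle$ca_curves[[i]], hf)
      utils::write.csv(norm,
                       file.path(outdir, sprintf("ca_response_rep%02d.csv", i)),
                       row.names = FALSE, quote = FALSE)
    }
  }
  jsonlite::write_json(bundle$metadata, file.path(outdir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
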