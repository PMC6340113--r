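# Column-wise analysis: FA versus free Ca2+ at a fixed CaM:peptide ratio,
# fitted with the empirical Hill model for apparent Ca2+ affinities.

#' Extract a Ca2+ response curve from a plate at a target CaM:peptide ratio
#'
#' Selects the single dilution column whose CaM:peptide ratio is nearest
#' the target in log space (the assay used a ratio of ~4 for full-length
#' CaM and ~40 for isolated CaM domains) and returns its FA signal across
#' the 16 free-Ca2+ rows. The Hill analysis presumes the complex is formed
#' throughout, so a selected ratio <= 1 (no CaM excess) triggers a warning.
#'
#' @param plate Long-format plate table (one replicate); see
#'   [simulate_plate()] for the schema.
#' @param target_ratio Target `[CaM]_tot / [P]_tot` ratio (> 0).
#' @param column Optional explicit column index, overriding the ratio
#'   search.
#' @param construct CaM construct label carried into the result.
#' @return An object of class `ca_response`: list with `ca_free`, `fa`,
#'   `cam_tot` (all length 16, sorted by `ca_free`), `ratio`,
#'   `column_index`, `construct`, `peptide_id`.
#' @export
extract_ca_response <- function(plate, target_ratio = 4, column = NULL,
                                construct = "full-length CaM") {
  stopifnot(is.data.frame(plate))
  if (length(unique(plate$replicate)) > 1L)
    stop("supply a single replicate's plate table", call. = FALSE)
  rows <- sort(unique(plate$row))
  missing_rows <- setdiff(seq_len(max(rows)), rows)
  if (length(missing_rows))
    stop("plate is missing rows: ", paste(missing_rows, collapse = ", "),
         call. = FALSE)
  ptot <- plate$peptide_conc_M[1]
  # per-column ratio from the geometric-mean CaM concentration across rows
  col_cam <- tapply(plate$cam_tot_M, plate$col, function(x) exp(mean(log(x))))
  ratios <- col_cam / ptot
  if (is.null(column)) {
    if (!is.finite(target_ratio) || target_ratio <= 0)
      stop("target_ratio must be > 0", call. = FALSE)
    column <- as.integer(names(ratios))[
      which.min(abs(log(ratios) - log(target_ratio)))]
  }
  ratio <- unname(ratios[as.character(column)])
  if (is.na(ratio)) stop("column ", column, " not present", call. = FALSE)
  if (ratio <= 1)
    warning("selected column has CaM:peptide ratio <= 1; ",
            "the Hill analysis presumes excess CaM", call. = FALSE)
  d <- plate[plate$col == column, ]
  d <- d[order(d$ca_free_M), ]
  structure(
    list(ca_free = d$ca_free_M, fa = d$fa, cam_tot = d$cam_tot_M,
         ratio = ratio, column_index = as.integer(column),
         construct = construct, peptide_id = d$peptide_id[1]),
    class = "ca_response")
}

#' Build a Ca2+ response curve directly from vectors
#'
#' Convenience constructor for simulated or externally supplied
#' FA-versus-free-Ca2+ curves.
#'
#' @param ca_free Free Ca2+ concentrations (molar, > 0).
#' @param fa FA signals.
#' @param ratio CaM:peptide ratio of the curve (if known).
#' @param construct,peptide_id Labels.
#' @return A `ca_response` object.
#' @export
ca_response <- function(ca_free, fa, ratio = NA_real_,
                        construct = "full-length CaM",
                        peptide_id = NA_character_) {
  stopifnot(length(ca_free) == length(fa), all(ca_free > 0))
  o <- order(ca_free)
  structure(
    list(ca_free = as.numeric(ca_free[o]), fa = as.numeric(fa[o]),
         cam_tot = rep(NA_real_, length(fa)), ratio = ratio,
         column_index = NA_integer_, construct = construct,
         peptide_id = peptide_id),
    class = "ca_response")
}

#' Fit the Hill model to a Ca2+ response curve
#'
#' Unweighted nonlinear least squares of
#' `FA = FA_lowCa + (FA_highCa - FA_lowCa) * Y` with
#' `Y = 1 / ((appK_D / [Ca2+])^n + 1)` over
#' `(log10 appK_D, n, FA_lowCa, FA_highCa)` on the raw FA signals.
#' appK_D is fitted on the log scale; the Hill coefficient is free within
#' `[0.5, 4]`; FA endpoints within `[0, 500]`. 95% CIs are asymptotic.
#' Curves whose fitted amplitude does not exceed 3x the residual noise are
#' flagged `"no Ca2+ response"`; fits resolving a decreasing response
#' (`FA_highCa < FA_lowCa`) are rejected with the flag
#' `"inverted response"`.
#'
#' @param curve A `ca_response` with at least 8 points.
#' @return An object of class `hill_fit` with `app_kd`, `n`, `fa_low_ca`,
#'   `fa_high_ca`, `ci95`, `rss`, `sigma`, `converged`, `flag`, plus the
#'   curve's labels.
#' @export
fit_hill <- function(curve) {
  stopifnot(inherits(curve, "ca_response"))
  ca <- curve$ca_free; fa <- curve$fa
  if (length(fa) < 8)
    stop("need at least 8 points spanning the transition", call. = FALSE)
  # orient the initials by the observed trend so a decreasing curve
  # converges to (and is then rejected for) the inverted solution
  increasing <- stats::cor(fa, log10(ca)) >= 0
  mid <- (min(fa) + max(fa)) / 2
  crossing <- if (increasing) which(fa >= mid) else which(fa <= mid)
  lka0 <- if (length(crossing)) log10(ca[min(crossing)]) else mean(log10(ca))
  lka0 <- min(max(lka0, -12), -2)
  par0 <- c(lka = lka0, n = 1.5,
            fa_lo = if (increasing) min(fa) else max(fa),
            fa_hi = if (increasing) max(fa) else min(fa))
  resfn <- function(p) {
    fa - fa_mixture(hill_saturation(10^p[1], p[2], ca), p[3], p[4])
  }
  fit <- .lm_fit(resfn, par0, lower = c(-12, 0.5, 0, 0),
                 upper = c(-2, 4, 500, 500))
  base <- list(construct = curve$construct, peptide_id = curve$peptide_id,
               ratio = curve$ratio, n_points = length(fa))
  amp <- fit$par[4] - fit$par[3]
  se_amp <- .se_diff(fit$cov, 3, 4)
  if (.amplitude_unresolved(abs(amp), fit$sigma, se_amp))
    return(structure(c(base, list(
      app_kd = NA_real_, n = NA_real_, fa_low_ca = NA_real_,
      fa_high_ca = NA_real_, ci95 = list(app_kd = c(NA_real_, NA_real_)),
      rss = fit$rss, sigma = fit$sigma, converged = FALSE,
      flag = "no Ca2+ response")), class = "hill_fit"))
  if (amp < 0)
    return(structure(c(base, list(
      app_kd = NA_real_, n = NA_real_,
      fa_low_ca = unname(fit$par[3]), fa_high_ca = unname(fit$par[4]),
      ci95 = list(app_kd = c(NA_real_, NA_real_)),
      rss = fit$rss, sigma = fit$sigma, converged = FALSE,
      flag = "inverted response")), class = "hill_fit"))
  ci <- list(app_kd = 10^.ci95(fit$par[1], fit$se[1], fit$df),
             n = .ci95(fit$par[2], fit$se[2], fit$df),
             fa_low_ca = .ci95(fit$par[3], fit$se[3], fit$df),
             fa_high_ca = .ci95(fit$par[4], fit$se[4], fit$df))
  structure(c(base, list(
    app_kd = unname(10^fit$par[1]), n = unname(fit$par[2]),
    fa_low_ca = unname(fit$par[3]), fa_high_ca = unname(fit$par[4]),
    ci95 = ci, rss = fit$rss, sigma = fit$sigma,
    converged = fit$converged,
    flag = if (fit$converged) "ok" else fit$message)),
    class = "hill_fit")
}

#' Normalise a Ca2+ response to fractional saturation
#'
#' Maps raw FA onto `Y = (FA - FA_lowCa) / (FA_highCa - FA_lowCa)` using
#' the fitted endpoints, and evaluates the fitted Hill curve at each free
#' Ca2+; the fitted curve passes through 0.5 at `[Ca2+] = appK_D`.
#'
#' @param curve The fitted `ca_response`.
#' @param fit A converged [fit_hill()] result for that curve.
#' @return Data frame with columns `ca_free_M`, `y_norm` (normalised
#'   data), `y_fit` (fitted Hill saturation).
#' @export
normalize_response <- function(curve, fit) {
  stopifnot(inherits(curve, "ca_response"), inherits(fit, "hill_fit"))
  if (!isTRUE(fit$converged))
    stop("fit is not converged", call. = FALSE)
  span <- fit$fa_high_ca - fit$fa_low_ca
  if (span == 0) stop("degenerate FA endpoints", call. = FALSE)
  data.frame(
    ca_free_M = curve$ca_free,
    y_norm = (curve$fa - fit$fa_low_ca) / span,
    y_fit = hill_saturation(fit$app_kd, fit$n, curve$ca_free))
}
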