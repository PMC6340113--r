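# Forward binding models shared by the simulator and the fitters.
# All concentrations are molar; FA signals are in instrument anisotropy units.

#' Fractional saturation under the exact 1:1 ligand-depletion isotherm
#'
#' For the stoichiometric complex `P + CaM <-> PCaM` with dissociation
#' constant `kd`, the fractional saturation of peptide,
#' `Y = [PCaM]/[P]_tot`, is the physical (smaller) root of the quadratic
#' mass-action system. With ~50 nM labelled peptide and K_D down to 1 nM
#' the assay operates deep in the ligand-depletion regime, so the
#' hyperbolic approximation is invalid and the exact root is required.
#' The root is evaluated in the cancellation-free (Citardauq) form
#' `Y = 2 * cam_tot / (b + sqrt(b^2 - 4 * p_tot * cam_tot))` with
#' `b = kd + p_tot + cam_tot`, which stays accurate for `kd << p_tot`.
#'
#' @param kd Dissociation constant (molar, > 0; `Inf` gives Y = 0).
#' @param p_tot Total peptide concentration (molar, > 0).
#' @param cam_tot Total CaM concentration(s) (molar, >= 0); vectorised.
#' @return Fractional saturation in `[0, min(1, cam_tot/p_tot)]`.
#' @examples
#' one_site_saturation(50e-9, 50e-9, 50e-9)  # (3 - sqrt(5))/2
#' @export
one_site_saturation <- function(kd, p_tot, cam_tot) {
  if (!is.finite(p_tot) || p_tot <= 0)
    stop("p_tot must be finite and > 0", call. = FALSE)
  if (is.na(kd) || kd <= 0) stop("kd must be > 0", call. = FALSE)
  if (any(!is.finite(cam_tot) & !is.infinite(cam_tot)) || any(cam_tot < 0))
    stop("cam_tot must be >= 0", call. = FALSE)
  if (is.infinite(kd)) return(rep(0, length(cam_tot)))
  b <- kd + p_tot + cam_tot
  disc <- pmax(b^2 - 4 * p_tot * cam_tot, 0)
  y <- 2 * cam_tot / (b + sqrt(disc))
  # guard against one-ulp overshoot of the stoichiometric ceiling
  pmin(y, 1, cam_tot / p_tot)
}

#' Two-mode binding saturation (free-ligand approximation)
#'
#' Sum of two independent binding hyperbolas, for curves where a single
#' 1:1 isotherm fits poorly and a second, weaker binding mode is invoked.
#' Valid in low-affinity regimes where free CaM is well approximated by
#' total CaM. As written the sum can exceed 1 (it approaches 2 at
#' saturating CaM); the downstream FA mixture then treats the fitted
#' bound-state FA as an effective amplitude. See the methods vignette.
#'
#' @param kd_I,kd_II Dissociation constants of the two modes (molar, > 0).
#' @param cam_tot Total CaM concentration(s) (molar, >= 0); vectorised.
#' @return Saturation values in `[0, 2)`.
#' @export
two_mode_saturation <- function(kd_I, kd_II, cam_tot) {
  if (is.na(kd_I) || kd_I <= 0 || is.na(kd_II) || kd_II <= 0)
    stop("kd_I and kd_II must be > 0", call. = FALSE)
  if (any(cam_tot < 0)) stop("cam_tot must be >= 0", call. = FALSE)
  cam_tot / (kd_I + cam_tot) + cam_tot / (kd_II + cam_tot)
}

#' Anisotropy signal as a mole-fraction mixture of endpoint signals
#'
#' `FA = fa_lo * (1 - y) + fa_hi * y`: the measured anisotropy is the
#' saturation-weighted mixture of the free-peptide and fully-bound
#' signals. The same affine form serves the Ca2+ response curves with
#' low-/high-Ca2+ endpoint signals.
#'
#' @param y Fractional saturation (vectorised).
#' @param fa_lo Signal of the free (or low-Ca2+) state.
#' @param fa_hi Signal of the bound (or high-Ca2+) state.
#' @return Anisotropy signal(s).
#' @export
fa_mixture <- function(y, fa_lo, fa_hi) {
  if (!is.finite(fa_lo) || !is.finite(fa_hi))
    stop("FA endpoints must be finite", call. = FALSE)
  fa_lo * (1 - y) + fa_hi * y
}

#' Hill saturation of a CaM/peptide complex with Ca2+
#'
#' `Y = 1 / ((app_kd / ca)^n + 1)`: empirical Hill model for the Ca2+
#' response of a preformed CaM/peptide complex, where `app_kd` is the free
#' Ca2+ at half-saturation and `n` the Hill coefficient. `Y(ca = 0) = 0`
#' by continuity.
#'
#' @param app_kd Apparent Ca2+ affinity (molar, > 0).
#' @param n Hill coefficient (> 0).
#' @param ca Free Ca2+ concentration(s) (molar, >= 0); vectorised.
#' @return Saturation values in `[0, 1)`.
#' @export
hill_saturation <- function(app_kd, n, ca) {
  if (!is.finite(app_kd) || app_kd <= 0) stop("app_kd must be > 0", call. = FALSE)
  if (!is.finite(n) || n <= 0) stop("n must be > 0", call. = FALSE)
  if (any(ca < 0)) stop("ca must be >= 0", call. = FALSE)
  ifelse(ca == 0, 0, 1 / ((app_kd / ca)^n + 1))
}

#' Brute-force mass-action equilibrium solver
#'
#' Independent oracle for the 1:1 system: solves for free CaM by bracketed
#' bisection of the CaM mass balance
#' `cam_free + p_tot * cam_free / (kd + cam_free) = cam_tot`
#' on `[0, cam_tot]`, then recovers the complex and free peptide by
#' conservation. Used to cross-check the closed-form isotherm; it shares
#' no algebra with [one_site_saturation()].
#'
#' @inheritParams one_site_saturation
#' @return A list with components `p_free`, `cam_free`, `complex` (molar).
#' @export
equilibrium_oracle <- function(kd, p_tot, cam_tot) {
  if (!is.finite(p_tot) || p_tot <= 0)
    stop("p_tot must be finite and > 0", call. = FALSE)
  if (is.na(kd) || kd <= 0) stop("kd must be > 0", call. = FALSE)
  if (length(cam_tot) != 1L || cam_tot < 0)
    stop("cam_tot must be a single value >= 0", call. = FALSE)
  if (cam_tot == 0 || is.infinite(kd))
    return(list(p_free = p_tot, cam_free = cam_tot, complex = 0))
  h <- function(cf) cf + p_tot * cf / (kd + cf) - cam_tot
  lo <- 0; hi <- cam_tot
  for (i in 1:200) {          # plain bisection run to interval exhaustion
    mid <- (lo + hi) / 2
    if (mid <= lo || mid >= hi) break
    if (h(mid) > 0) hi <- mid else lo <- mid
  }
  cam_free <- (lo + hi) / 2
  # recover the complex through the binding hyperbola rather than by
  # subtracting near-equal totals, which would cancel when p_tot << cam_tot
  complex <- p_tot * cam_free / (kd + cam_free)
  list(p_free = p_tot * kd / (kd + cam_free), cam_free = cam_free,
       complex = complex)
}
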