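#' Chelator specification
#'
#' Describes a Ca2+ chelator by its total concentration, absolute (pH
#' independent) log10 Ca2+ association constant and the proton pKa values
#' that compete with Ca2+ binding at the working pH.
#'
#' @param name Chelator label, e.g. `"EGTA"` or `"NTA"`.
#' @param total_conc Total chelator concentration in molar (>= 0).
#' @param abs_logK_ca Absolute log10 Ca2+ association constant (> 0).
#' @param pKa Numeric vector of proton pKa values relevant at the working
#'   pH, sorted descending (most basic first). Values are re-sorted if
#'   supplied out of order.
#' @return An object of class `chelator_spec`.
#' @examples
#' egta_spec()
#' chelator_spec("custom", 1e-3, 8.0, c(9.0, 7.5))
#' @export
chelator_spec <- function(name, total_conc, abs_logK_ca, pKa) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(total_conc) || total_conc < 0)
    stop("total_conc must be finite and >= 0", call. = FALSE)
  if (!is.finite(abs_logK_ca) || abs_logK_ca <= 0)
    stop("abs_logK_ca must be finite and > 0", call. = FALSE)
  if (length(pKa) < 1L || any(!is.finite(pKa)))
    stop("pKa values must be finite", call. = FALSE)
  structure(
    list(name = name, total_conc = total_conc,
         abs_logK_ca = abs_logK_ca, pKa = sort(pKa, decreasing = TRUE)),
    class = "chelator_spec")
}

#' @rdname chelator_spec
#' @details `egta_spec()` and `nta_spec()` return the assay's default
#'   chelators with NIST-style constants at ionic strength ~0.15 M, 25 degC:
#'   EGTA pKa 9.40/8.79, logK(CaEGTA) 10.86; NTA pKa 9.73, logK(CaNTA) 6.41.
#'   Defaults match the assay buffer (0.5 mM EGTA, 2 mM NTA).
#' @export
egta_spec <- function(total_conc = 0.5e-3) {
  chelator_spec("EGTA", total_conc, 10.86, c(9.40, 8.79))
}

#' @rdname chelator_spec
#' @export
nta_spec <- function(total_conc = 2e-3) {
  chelator_spec("NTA", total_conc, 6.41, 9.73)
}

#' Conditional Ca2+ dissociation constant of a chelator at a given pH
#'
#' Applies the Schwarzenbach proton-competition correction: the conditional
#' dissociation constant is `alphaH / 10^abs_logK_ca`, where
#' `alphaH = 1 + sum_i 10^(pKa_1 + ... + pKa_i - i * pH)` accumulates the
#' successive protonation states of the free ligand. Only the 1:1 Ca:chelator
#' complex is considered (no CaHL or Mg2+ species).
#'
#' @param chelator A [chelator_spec()].
#' @param pH Working pH, in `[5, 9]`.
#' @return Conditional dissociation constant in molar.
#' @examples
#' conditional_kd(egta_spec(), 7.2)  # ~8.7e-8 M
#' conditional_kd(nta_spec(), 7.2)   # ~1.3e-4 M
#' @export
conditional_kd <- function(chelator, pH = 7.2) {
  stopifnot(inherits(chelator, "chelator_spec"))
  if (!is.finite(pH) || pH < 5 || pH > 9)
    stop("pH must be in [5, 9]", call. = FALSE)
  i <- seq_along(chelator$pKa)
  alphaH <- 1 + sum(10^(cumsum(chelator$pKa) - i * pH))
  kd <- alphaH / 10^chelator$abs_logK_ca
  if (!is.finite(kd)) stop("non-finite conditional constant", call. = FALSE)
  kd
}

# Ca2+ mass balance at free concentration f:
#   g(f) = f + sum_j L_j * f / (K_j + f) - ca_total
# monotone increasing in f, so the root on [0, ca_total] is unique.
.ca_mass_balance <- function(f, ca_total, L, K) {
  f + sum(L * f / (K + f)) - ca_total
}

.ca_mass_balance_deriv <- function(f, L, K) {
  1 + sum(L * K / (K + f)^2)
}

#' Solve free Ca2+ in a chelator-buffered solution
#'
#' Finds the unique nonnegative root of the Ca2+ mass balance
#' `ca_total = f + sum_j L_j * f / (K_Dj + f)` over the 1:1 Ca:chelator
#' complexes, by bracketed root-finding on `[0, ca_total]` followed by
#' Newton polishing to machine precision.
#'
#' @param ca_total Total Ca2+ concentration in molar (>= 0).
#' @param chelators List of [chelator_spec()] objects (may be empty).
#' @param pH Working pH used for the conditional constants.
#' @return Free Ca2+ concentration in molar.
#' @examples
#' solve_free_calcium(1e-3, list())            # no chelator: 1 mM
#' solve_free_calcium(0.25e-3, list(egta_spec()))
#' @export
solve_free_calcium <- function(ca_total, chelators = list(egta_spec(), nta_spec()),
                               pH = 7.2) {
  if (!is.finite(ca_total) || ca_total < 0)
    stop("ca_total must be finite and >= 0", call. = FALSE)
  if (ca_total == 0 || length(chelators) == 0L) return(ca_total)
  L <- vapply(chelators, function(ch) ch$total_conc, numeric(1))
  K <- vapply(chelators, conditional_kd, numeric(1), pH = pH)
  if (any(K <= 0)) stop("conditional K_D must be > 0", call. = FALSE)
  g <- function(f) .ca_mass_balance(f, ca_total, L, K)
  if (g(ca_total) < 0) stop("no sign change in bracket", call. = FALSE)
  f <- stats::uniroot(g, c(0, ca_total), tol = .Machine$double.eps * ca_total)$root
  # Newton polish: a few steps drive the residual to rounding level
  for (i in 1:4) {
    step <- g(f) / .ca_mass_balance_deriv(f, L, K)
    f_new <- min(max(f - step, 0), ca_total)
    if (abs(f_new - f) <= .Machine$double.eps * f) { f <- f_new; break }
    f <- f_new
  }
  f
}

# Exact inverse of the mass balance: total Ca2+ needed for a target free Ca2+.
.ca_total_for_free <- function(ca_free, L, K) {
  ca_free + sum(L * ca_free / (K + ca_free))
}

#' Default 16-point free-Ca2+ row series
#'
#' Log-spaced free Ca2+ targets spanning the assay's printed range,
#' 0.3 nM to 400 uM, one per plate row.
#'
#' @param n Number of rows (default 16).
#' @param lo,hi Range endpoints in molar.
#' @return Numeric vector of free Ca2+ concentrations (molar), increasing.
#' @export
default_ca_series <- function(n = 16, lo = 0.3e-9, hi = 400e-6) {
  stopifnot(n >= 2, lo > 0, hi > lo)
  10^seq(log10(lo), log10(hi), length.out = n)
}

#' Design the pCa-buffer mixing series
#'
#' The assay prepares one buffer batch without added Ca2+ and one with
#' 3 mM total Ca2+, then mixes them. Forward mode (`fractions` given):
#' each mixing fraction `f` yields `ca_total = f * ca_stock` and the solved
#' free Ca2+. Inverse mode (`targets` given): for each target free Ca2+,
#' the required fraction is obtained from the exact mass-balance inverse
#' `ca_total(target) = target + sum_j L_j * target / (K_Dj + target)`,
#' so that `solve_free_calcium(f * ca_stock)` returns the target to
#' machine precision.
#'
#' @param fractions Mixing fractions in `[0, 1]` (forward mode).
#' @param targets Target free Ca2+ concentrations in molar (inverse mode).
#'   Exactly one of `fractions`/`targets` must be supplied.
#' @param chelators List of [chelator_spec()]; defaults to the assay's
#'   0.5 mM EGTA + 2 mM NTA.
#' @param ca_stock Total Ca2+ of the high-Ca2+ batch (molar; 3 mM).
#' @param pH Working pH.
#' @return A data frame with columns `row_index`, `mix_fraction`,
#'   `ca_total_M`, `ca_free_M`.
#' @examples
#' design_mixing_series(fractions = c(0, 0.5, 1))
#' design_mixing_series(targets = default_ca_series(4))
#' @export
design_mixing_series <- function(fractions = NULL, targets = NULL,
                                 chelators = list(egta_spec(), nta_spec()),
                                 ca_stock = 3e-3, pH = 7.2) {
  if (is.null(fractions) == is.null(targets))
    stop("supply exactly one of 'fractions' or 'targets'", call. = FALSE)
  L <- vapply(chelators, function(ch) ch$total_conc, numeric(1))
  K <- vapply(chelators, conditional_kd, numeric(1), pH = pH)
  if (!is.null(fractions)) {
    if (any(!is.finite(fractions)) || any(fractions < 0 | fractions > 1))
      stop("fractions must lie in [0, 1]", call. = FALSE)
    ca_total <- fractions * ca_stock
    ca_free <- vapply(ca_total, solve_free_calcium, numeric(1),
                      chelators = chelators, pH = pH)
    f <- fractions
  } else {
    if (any(!is.finite(targets)) || any(targets < 0))
      stop("targets must be finite and >= 0", call. = FALSE)
    max_free <- solve_free_calcium(ca_stock, chelators, pH)
    if (any(targets > max_free))
      stop(sprintf(
        "target free Ca2+ outside achievable range [0, %.3g M] at f in [0, 1]",
        max_free), call. = FALSE)
    ca_total <- vapply(targets, .ca_total_for_free, numeric(1), L = L, K = K)
    f <- ca_total / ca_stock
    ca_free <- targets
  }
  data.frame(row_index = seq_along(f), mix_fraction = f,
             ca_total_M = ca_total, ca_free_M = ca_free)
}
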