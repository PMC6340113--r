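---
title: "Models and methods behind camtitr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind camtitr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camtitr)
```

# The assay and the estimation problem

Calmodulin (CaM) inhibits the cardiac ryanodine receptor (RyR2) in a
Ca^2+^-dependent manner, and the strength of the interaction is probed
with RyR2-derived CaM-binding-domain (CaMBD) peptides carrying a 5-TAMRA
fluorophore. When CaM binds, the labelled peptide tumbles more slowly and
its fluorescence anisotropy (FA) rises. A single 384-well plate encodes a
two-dimensional titration: each of the 16 rows is clamped at one free
Ca^2+^ concentration by an EGTA/NTA buffer system (0.3 nM to 400 µM), and
the 24 columns carry a serial dilution of CaM against a fixed ~50 nM
peptide concentration. Fitting the rows yields the CaM–peptide
dissociation constant $K_D$ as a function of free Ca^2+^; fitting a fixed
column against Ca^2+^ yields the apparent Ca^2+^ affinity
($\mathrm{app}K_D$) of the preformed CaM/peptide complex.

camtitr implements every stage of this analysis — buffer speciation,
forward binding models, row- and column-wise fitting with confidence
intervals, model selection, and reporting — together with a seeded
synthetic-plate generator so that the whole pipeline can be validated by
parameter recovery without access to instrument data.

# Free-Ca^2+^ buffering

Free Ca^2+^ in each row is set by mixing a 0.5 mM EGTA + 2 mM NTA buffer
with and without 3 mM total Ca^2+^. The chelators' absolute stability
constants are corrected for proton competition at the working pH (7.2)
with the Schwarzenbach side-reaction coefficient
$\alpha_H = 1 + \sum_i 10^{\,\sum_{j \le i} pK_{a,j} - i\,\mathrm{pH}}$,
giving the conditional dissociation constant
$K_{D,\mathrm{cond}} = \alpha_H / 10^{\log K_{abs}}$. With the default
NIST-style constants (ionic strength 0.15 M, 25 °C: EGTA $pK_a$
9.40/8.79, $\log K_{CaEGTA}$ 10.86; NTA $pK_a$ 9.73, $\log K_{CaNTA}$
6.41) this yields conditional $K_D$ values of ≈87 nM (EGTA) and ≈132 µM
(NTA) at pH 7.2 — one chelator buffering the nanomolar range, the other
the tens-of-micromolar range. The constants are configurable because
published tabulations differ at the 0.1-log level between ionic-strength
and temperature conventions; whatever set is used is recorded in the run
metadata.

Free Ca^2+^ is the unique root of the mass balance
$[\mathrm{Ca}]_{tot} = f + \sum_j L_{j,tot}\, f / (K_{D,j} + f)$,
solved by bracketed root-finding on $[0, [\mathrm{Ca}]_{tot}]$ and
polished by Newton steps so the relative mass-balance residual sits at
rounding level (well below $10^{-12}$). The mixing design supports both
directions; notably the *inverse* design (find the mixing fraction that
realises a target free Ca^2+^) uses the closed-form inverse of the same
mass balance, $[\mathrm{Ca}]_{tot}(f^\ast) = f^\ast + \sum_j
L_{j,tot} f^\ast/(K_{D,j}+f^\ast)$, rather than numerical root-finding:
the mass balance is strictly monotone, so this is exact and removes one
tolerance from the pipeline.

Only 1:1 Ca:chelator complexes and the two most relevant protonations are
modelled; Mg^2+^ competition, ternary CaHL species and
activity-coefficient corrections are out of scope (none are present in
the assay buffers). The 16 default row targets are log-spaced over
0.3 nM–400 µM; the instrument-facing workflow could override them with a
measured series, and the empirical recalibration of buffer batches
against CaM titrations that a wet lab would perform is deliberately not
modelled.

# Binding models

**One-site ligand depletion.** With ~50 nM labelled peptide and
affinities down to 1 nM, bound CaM is never a negligible fraction of
total, so the hyperbolic isotherm is invalid. The fractional saturation
of peptide is the physical root of the quadratic mass-action system,

$$Y = \frac{K_D + [P]_{tot} + [CaM]_{tot}
      - \sqrt{(K_D + [P]_{tot} + [CaM]_{tot})^2 - 4[P]_{tot}[CaM]_{tot}}}
      {2[P]_{tot}},$$

evaluated internally in the cancellation-free (Citardauq) form
$Y = 2[CaM]_{tot}/(b + \sqrt{b^2 - 4[P]_{tot}[CaM]_{tot}})$ with
$b = K_D + [P]_{tot} + [CaM]_{tot}$. The naive "minus" root loses all
precision when $K_D \ll [P]_{tot}$; the test suite rejects it by
comparing against an independent mass-action bisection oracle at
$K_D = 10^{-15}$ M.

**FA mixture.** The measured signal is the saturation-weighted affine
mixture $FA = FA_P (1 - Y) + FA_{PCaM}\, Y$ of the free- and bound-state
signals; the same algebra serves the Ca^2+^ response curves with low- and
high-Ca^2+^ endpoints. The empirical intensity enhancement of the probe
upon binding is not modelled: FA is treated as a pure mole-fraction
signal, which is also why the absolute $FA_{PCaM}$ level is never used to
infer complex size.

**Two-mode model.** Curves that a single 1:1 isotherm cannot describe are
offered a sum of two binding hyperbolas,
$Y = [CaM]/(K_{DI} + [CaM]) + [CaM]/(K_{DII} + [CaM])$, valid in
low-affinity regimes where free CaM ≈ total CaM. As written this $Y$
ranges over $[0, 2)$ while the FA mixture treats $Y$ as a fraction; no
normalisation is applied — the model is used exactly as stated, and the
fitted $FA_{PCaM}$ is interpreted as an effective amplitude. This is a
documented modelling asymmetry, not an implementation choice.

**Hill model.** The Ca^2+^ response of a complex is summarised by
$Y = 1/((\mathrm{app}K_D/[\mathrm{Ca}^{2+}])^n + 1)$, where
$\mathrm{app}K_D$ is the free Ca^2+^ at half-saturation and $n$ an
empirical cooperativity exponent.

# Fitting

All fits are unweighted nonlinear least squares on the raw FA signals
(Levenberg–Marquardt with box bounds). $K_D$ and $\mathrm{app}K_D$ are
fitted as $\log_{10}$ quantities — the scale on which their sampling
distribution is near-normal across a five-decade dilution — with bounds
$[10^{-12}, 10^{-3}]$ M; FA endpoints are bounded to $[0, 500]$
anisotropy units; the Hill coefficient is free within $[0.5, 4]$ (two
EF-hands per CaM domain motivate the simulated default of $n = 2$; the
bound keeps the exponent in a physically interpretable range). Initial
values are robust by construction: $K_D$ starts at the geometric mean of
the dilution series, endpoints at the observed FA extremes, and the Hill
midpoint at the concentration where the signal crosses half-range, with
the endpoint initials oriented by the observed trend so that decreasing
curves converge to (and are then rejected for) the inverted solution.

95% confidence intervals are asymptotic: parameter covariance from the
Jacobian at the optimum, t quantiles on the residual degrees of freedom,
intervals on $\log_{10} K_D$ exponentiated back. This matches standard
nonlinear-regression practice; no profile-likelihood or bootstrap
intervals are computed. Across replicates, profiles report the geometric
mean with a t-based CI on $\log_{10} K_D$. Each replicate is fitted
separately and then summarised (rather than pooled into one fit), and
both the per-fit and across-replicate intervals are exported.

Three guards make the fits honest at the edges:

* **No-binding detection.** A fit is reported as
  `"no-binding/unresolvable"` — with no $K_D$ — when the fitted FA
  amplitude fails to exceed three times the residual noise, or when the
  amplitude is not significantly resolved (non-finite or dominating
  standard error, the signature of parameters parked on a bound with a
  singular Jacobian). This catches both flat free-dye controls and noise
  masquerading as a step.
* **Reliability window.** Fitted $K_D$ outside ~1 nM–5 µM is flagged
  unreliable: below the window the curve is purely stoichiometric in the
  50 nM peptide, above it the 30 µM top concentration cannot saturate.
  Unreliable fits are excluded (and counted) in affinity profiles.
* **Model selection.** The two-mode model is adopted only when the
  extra-sum-of-squares F-test rejects the one-site fit at $\alpha = 0.05$
  *and* the fitted mode separation $K_{DII}/K_{DI} \ge 5$; ties and
  boundary cases go to the one-site model. Rejected two-mode fits whose
  ratio collapses to 1 or whose $K_{DII}$ CI spans more than three
  decades are marked `"two-mode unsupported"`. In simulation this rule
  selects the second mode in >80% of strongly two-mode rows
  ($K_{DI} = 2$ µM, $K_{DII} = 20$ µM, σ = 3) while keeping false
  two-mode calls on one-site rows well under the nominal level.

Significance between any two fitted affinities uses the conservative
non-overlapping-95%-CI rule; intervals sharing an endpoint count as
overlapping.

# The synthetic plate generator

The generator reproduces the assay mechanics rather than an instrument:

* **Dilution.** Column 1 receives 3 µl of CaM stock (default 680 µM,
  inside the assay's 600–1200 µM range, chosen to give a round 30 µM top
  concentration) into 65 µl of buffer; each subsequent column transfers
  38 µl into 30 µl, a 38/68 step repeated 23 times down to ~46 pM — more
  than five decades.
* **Ca^2+^ linkage.** The generating $K_D$ follows a log-logistic
  profile between an apo and a Ca^2+^-saturated plateau,
  $\log_{10}K_D(\mathrm{Ca}) = \log_{10}K_{D,sat} +
  (\log_{10}K_{D,apo} - \log_{10}K_{D,sat}) / (1 + (\mathrm{Ca}/c_{1/2})^s)$
  — a smooth monotone stand-in for the empirical affinity-versus-Ca^2+^
  curves. Defaults emulate the CaM–CaMBD2 interaction (390 nM → 1 nM,
  midpoint 30 nM, slope 2).
* **Noise.** Additive Gaussian FA noise (default σ = 3 anisotropy units)
  plus an optional relative error on every pipetted volume (default CV
  2%) that compounds down the serial dilution, as in a real robot run.
  Both values are unprinted in any protocol we emulate; they were chosen
  once as a realistic instrument noise floor at which fitted-$K_D$
  scatter is clearly visible, and are configurable and logged.
* **FA endpoints.** Bound-state FA defaults to 250, inside the observed
  240–260 plateau of genuine CaM/CaMBD complexes; the free-peptide
  baseline (150) is an assumption, as baselines depend on probe and
  viscosity.

One seeded generator drives each plate, so identical seeds give
bit-identical tables. What the simulator deliberately omits: the
fluorescence intensity enhancement on binding, instrument factors
(G-factor, gain, flash count), evaporation and edge effects, and any
empirical miscalibration of the buffer series. Passing recovery tests on
synthetic plates therefore demonstrates that the estimators are correct
and calibrated *for the stated data-generating process*; they cannot rule
out instrument systematics that the generator does not contain.

# Numerical choices and degenerate inputs

* Concentrations are carried in molar units internally; report layers
  convert to nM/µM.
* The equilibrium oracle bisects the free-CaM mass balance to interval
  exhaustion and recovers the complex through the binding hyperbola
  (never by subtracting near-equal totals); agreement with the
  closed-form isotherm is enforced at $10^{-10}$ over a $10^3$-point
  grid spanning $10^{-12}$–$10^{-3}$ M.
* Optimiser tolerances are set to machine epsilon with a generous
  iteration cap, so noiseless synthetic data are recovered to rounding
  error (RSS below $10^{-18}$); "tolerance unachievable" return codes at
  that setting indicate convergence and are treated as such.
* Zero total Ca^2+^, zero CaM, empty chelator lists, exactly flat
  curves, infinite generating $K_D$ (the free-dye control) and inverted
  Ca^2+^ responses all have defined, tested behaviour rather than
  optimiser failure.
* Plate CSVs are written with 17 significant digits so that persisted
  intermediates round-trip exactly and refitting them reproduces the
  original results byte for byte.

# Problem sizes used in validation

The recovery benchmarks in the test-suite and the acceptance script use
200 simulated rows (or response curves) per condition, which puts the
Monte-Carlo error of a median-recovered $K_D$ near 1% — comfortably
inside the 10–15% acceptance bands — while keeping a full validation run
in the tens of seconds. Coverage checks use 200 fits per $K_D$ decade;
model-selection error rates use 200 (power) and 500 (false-call)
simulated curves.

# Known limitations

* The two-mode model inherits the stated free-ligand approximation; at
  high affinity it is the wrong model, and the package only offers it
  where the one-site fit demonstrably fails.
* Asymptotic CIs undercover slightly in strongly nonlinear corners of
  parameter space (coverage ~91–95% at nominal 95% in our simulations);
  profile-likelihood intervals would be the upgrade path.
* No global fit across rows with a shared thermodynamic linkage model is
  attempted: each row is treated independently, as in the underlying
  analysis workflow, and the Ca^2+^ linkage enters only through the
  simulator and the column-wise Hill summaries.
* The Hill $\mathrm{app}K_D$ of a simulated plate is an *apparent*
  quantity: at a CaM:peptide ratio of ~4 it reflects where the falling
  $K_D(\mathrm{Ca})$ curve crosses the relevant CaM concentration, so it
  sits near, but not exactly at, the generating transition midpoint.
  The end-to-end consistency test asserts exactly this containment
  (within a factor of 5 of the midpoint), not equality.
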