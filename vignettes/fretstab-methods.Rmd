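---
title: "Models and methods behind fretstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fretstab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretstab)
```

`fretstab` analyses a sensitized-emission FRET protein-protein interaction
assay (donor- and acceptor-labelled binding partners read in three
channels on a plate reader) together with the orthogonal stability
measurements used to interpret it: thermal unfolding by differential
scanning fluorimetry (DSF), chemical denaturation by intrinsic tryptophan
fluorescence, and free-energy estimates from nonequilibrium alchemical
work distributions. This vignette records the models, the tunable
parameters, and the numerical and design decisions, in the spirit of the
methods sections of DESeq2 or limma vignettes: enough detail that a
careful reader can re-derive every number the package produces.

## 1. Sensitized emission and crosstalk

Three channels are read per well: `DD` (donor excitation, donor
emission), `AA` (acceptor excitation, acceptor emission) and `DA` (donor
excitation, acceptor emission). `DA` contains the FRET signal plus two
contaminations: donor bleed-through (`delta`, the DA/DD ratio of
donor-only wells) and direct acceptor excitation (`alpha`, the DA/AA
ratio of acceptor-only wells). The corrected sensitized emission is

$$SE = DA - \alpha \cdot AA - \delta \cdot DD.$$

Two correction routes are supported and composable: the coefficient route
above, and the empirical route in which the SE of a non-binding control
(free donor fluorophore plus acceptor fusion) is subtracted
concentration-by-concentration. When both are supplied, coefficients are
applied first, then the control series is subtracted; for an ideal
non-binding control the second step is a no-op, but it additionally
removes any binding-independent background the coefficients miss.
Negative SE values are retained — clipping at zero would bias the
binding fit near baseline.

## 2. The quadratic ligand-depletion binding isotherm

The donor is held at a concentration `a` (1 µM in the assay design)
comparable to the dissociation constant, so free-ligand approximations
(hyperbolic binding) are invalid. The model is the exact two-component
equilibrium: with total acceptor `X`,

$$SE(X) = SE_{max}\left(1 - \frac{2 K_D}{(X - a + K_D) +
  \sqrt{(X - a - K_D)^2 + 4 K_D X}}\right),$$

which equals `SE_max` times the bound donor fraction of the quadratic
mass-action solution. **Numerical note**: this textbook rearrangement
computes "one minus a number near one" when `X << a` and loses up to five
significant digits at extreme parameter ratios. `emfret_model()`
evaluates an algebraically identical branch
(`num = 4 K_D X / (|u| + sqrt(u^2 + 4 K_D X))` for `u = X - a - K_D < 0`)
that agrees with the independent mass-action solver
(`simulate_binding_equilibrium()`, a stable quadratic root, or bracketed
root finding when a competitor is present) to better than 1e-10 relative
error over nine orders of magnitude of parameters — this dual-route
equivalence is asserted in the test suite.

`fit_kd()` estimates `(K_D, SE_max)` by unweighted nonlinear least
squares over all individual replicate points (no pre-averaging, which
would discard the error structure). Initialisation is data-driven and
parameter-free: `SE_max` starts at the maximal SE, `K_D` at the acceptor
concentration of half-maximal SE by linear interpolation. The optimiser
is a small Levenberg-Marquardt implementation (tolerance 1e-8 on
relative parameter change, at most 500 iterations) chosen over
`stats::nls` because the port algorithm intermittently reports false
convergence on noisy replicate data; `stats::nls` is retained in the test
suite as an independent cross-check of the optimum.

**Standard errors** are reported from the heteroscedasticity-robust
(sandwich) covariance at the optimum rather than the classical
`s^2 (J'J)^{-1}`: plate-reader noise is multiplicative, and under a 2% CV
noise model the classical SEs under-cover badly (86% empirical coverage
at the 3-sigma level versus 96% for the robust SEs in a 50-seed
calibration experiment reproduced in the acceptance tests).

`kd_time_course()` refits `K_D` independently per incubation time and
reports `K_D(t)/K_D(t_first)`. A stable titrant keeps this ratio at one;
a titrant losing functional concentration during incubation (emulated by
the generator's exponential `functional_decay_rate`) shows a
monotonically rising apparent `K_D` — the signature that distinguishes a
stability artifact from a genuine affinity change.

## 3. Competition analysis and its validity limits

Dose-response curves are fitted with the four-parameter logistic in
log10-concentration space ("log(inhibitor) vs response, variable
slope"):

$$y = bottom + \frac{top - bottom}
  {1 + 10^{\,hill\,(\log_{10} x - \log_{10} IC_{50})}}.$$

Zero-dose wells cannot enter a log-space likelihood; they anchor the
normalisation of relative binding (per-plate division by the mean
uninhibited SE) and are excluded from the fit. The Hill slope is
unconstrained in sign. `cheng_prusoff()` converts
`Ki = IC50 / (1 + L/K_D)` exactly, carrying its inputs for audit.

**Known limitation, deliberately not papered over.** Classical
Cheng-Prusoff assumes the readout partner is present in trace amounts.
At the assay design — both partners at 1 µM with `K_D` = 0.43 µM — the
exact mass-action equilibrium shows that roughly half of each partner and
a substantial fraction of the inhibitor are complexed at the IC50, and
the conversion acquires a systematic positive bias: about +20% for Ki in
the low-µM range and about +55% for self-competition (Ki = K_D). The
package's own generator plus fitter reproduces Cheng-Prusoff to <1% when
the donor is trace (0.01 µM), which localises the bias in the method, not
the code. The acceptance criterion demanding 5% recovery at the 1 µM
design is therefore left failing, with this analysis; the honest numbers
are asserted in the regular test suite instead.

`screen_compounds()` implements the dual-criterion hit rule for
single-concentration screening: a hit must both reduce sensitized
emission (`1 - SE/SE_ctrl` above threshold) *and* restore donor emission
(`DD/DD_ctrl - 1` above threshold). Default thresholds are 20% on both
(configurable; no numeric threshold is prescribed by the assay
description). The second criterion rejects optical artifacts: a compound
that simply absorbs or quenches all channels lowers SE without
dequenching the donor, and the generator's `"quencher"` artifact mode
exercises exactly this failure.

## 4. DSF melt curves and van't Hoff free energies

A melt curve is truncated at its global fluorescence maximum before any
thermodynamic construction: SYPRO-type dye signal decays beyond the peak
as aggregates sequester the dye, violating the two-state model. On the
pre-peak region,

$$P_f(T) = 1 - \frac{F - F_{min}}{F_{max} - F_{min}}, \qquad
  P_u = 1 - P_f, \qquad K_u = P_u / P_f,$$

and `ln K_u` is regressed on `1/T` over the points whose *unfolded*
fraction lies in the window (default 0.10-0.50, the early unfolding limb;
the phrase "folding between 10 and 50%" is ambiguous and this reading
matches the intent of the underlying ΔG-estimation method). From
`ln K_u = -\Delta H/(R T) + \Delta S/R`:
`ΔH = -R * slope`, `ΔS = R * intercept` (the literal "ΔH is the slope"
reading gives wrong units and sign), and
`ΔG(T_{ref}) = ΔH - T_{ref} ΔS` with `R = 1.98720425e-3` kcal/(mol K).
`T_ref` defaults to 298.15 K and is always reported alongside ΔG, since
ΔG is strongly temperature-dependent and no reference temperature is
prescribed by the protocol.

Melting temperatures are the local maxima of the smoothed first
derivative `dF/dT` (local quadratic filter, default 11-point window on
the 0.5 K grid; peaks must exceed 5% prominence of the derivative range,
and a derivative whose range is under 5% of its magnitude is treated as
transition-free). For biphasic curves the van't Hoff fit is restricted
to the final, major transition by cutting at the derivative valley
between the last two melting points; per-transition fits are available
via `t_range`.

**Limitation**: the construction assumes `F_min` is the fully-folded
baseline. For a marginally stable protein (e.g. ΔH = 50 kcal/mol with
Tm = 315 K) several percent of the population is already unfolded at the
30 °C start of the scan, and recovered ΔH is biased low by ~10%. The
round-trip tests therefore sample parameter combinations with < 0.5%
initial unfolding; outside that regime the method itself, not the
implementation, degrades.

## 5. Chemical denaturation

Normalised tryptophan fluorescence versus urea is fitted with

$$y = A_2 + \frac{A_1 - A_2}{1 + (x/x_0)^p},$$

where `x_0` is the midpoint `C_m` (reported with the standard error of
the fit) and `p` the power. The model returns `A_1` exactly at `x = 0`
(its `p > 0` limit), removing the `0^p` singularity without affecting the
fit. Biphasic (three-state) profiles are split at a denaturant
concentration between the two transitions and each segment fitted
separately. The automatic split takes the urea value minimising the
smoothed |dy/dx| between the two steepest-descent regions; the original
workup used a manual split, so the heuristic is a reproducibility aid,
not a reconstruction, and a manual `split_point` always overrides it.
Linear-extrapolation m-value analysis (ΔG(H2O)) is intentionally out of
scope: only `C_m` values are produced.

## 6. Nonequilibrium free energies

Work values are stored as work done *on* the system in each transition
direction's own frame (pmx-style); Crooks comparisons use `-W_r`, and all
estimates are reported in the forward (A→B) frame.

* **Jarzynski**: `ΔG = -RT ln<exp(-W/RT)>` via log-sum-exp; the reverse
  direction estimates the B→A free energy and is negated. Uncertainty by
  seeded bootstrap (default 200 resamples). The estimator is dominated
  by rare low-work tails and is the noisiest of the three — the test
  suite asserts BAR beats it on average over 50 seeded repetitions.
* **Crooks-Gaussian intersection (CGI)**: Gaussians are fitted to `W_f`
  and `-W_r`; their densities cross at `W = ΔG`. Equal variances reduce
  to `(mean(W_f) - mean(W_r))/2`; with unequal variances the quadratic is
  solved and the root between the two means is taken. No real
  intersection raises an estimation failure carrying both Gaussians'
  parameters.
* **BAR**: the self-consistency equation
  `sum_i f(β(M + W_{f,i} - ΔG)) = sum_j f(β(-M + W_{r,j} + ΔG))`,
  `f` logistic, `M = RT ln(n_f/n_r)`, solved by bracketed root finding to
  1e-8 kcal/mol. The reported uncertainty is the asymptotic
  maximum-likelihood variance; vanishing Fermi weights at the solution
  (non-overlapping work distributions) raise an estimation failure
  advising more sampling rather than returning a meaningless number.

`ddg_from_legs()` forms `ΔΔG = ΔG_2 - ΔG_1` from the two vertical legs
of the thermodynamic cycle (mutation in a reference environment versus in
the environment of interest), combining uncertainties in quadrature or,
when per-replica estimates are supplied, as their standard deviation.
`cycle_closure()` sums signed ΔΔG values around a closed path — edges may
be listed in either orientation — and flags |closure| above a tolerance
defaulting to 0.5 kcal/mol, a deliberately loose bound motivated by the
reported sub-0.2 kcal/mol closures of converged alchemical calculations.
Reproducing any particular published ΔΔG is out of scope: that requires
cluster-scale molecular dynamics, and this module consumes work tables
only.

## 7. The synthetic-data module

Every analysis input can be generated with the statistical structure the
analysis assumes, so that each analyzer has a generator it provably
inverts (the adjointness tests). Defaults are the assay's stated design
where one exists, and a single documented choice where not:

| Parameter | Default | Why |
|---|---|---|
| donor conc `a` | 1 µM | assay design |
| acceptor grid | 0 + two-fold series to 3.09 µM | assay titration span |
| `K_D` | 0.4308 µM | published wild-type fit |
| crosstalk `delta`, `alpha` | 0.12, 0.30 | typical green/red FP pair; `alpha` large because red FPs excite broadly at 488 nm |
| brightness DD/AA | 2000 / 1500 RFU/µM | arbitrary gain scale; analyses are affine-invariant |
| `e_app` | 0.4 | apparent FRET efficiency of a well-matched FP pair at ~5 nm; chosen once so that full inhibition produces >20% donor dequench, i.e. the dual-criterion screen is decidable in the generated world |
| `em_fret_max` | 1000 RFU | arbitrary signal scale |
| noise | multiplicative Gaussian CV + optional additive floor | plate-reader RFU are gain-scaled, making multiplicative noise the right first-order model (not Poisson) |
| melt grid | 30-95 °C by 0.5 °C | instrument protocol |
| melt ΔH, ΔS | 100 kcal/mol, 0.3096 kcal/(mol K) | reference two-state example (Tm = 323.0 K) |
| three-state melt ΔH | 250 kcal/mol per transition | transitions 5.4 K apart are only resolvable in the derivative if each is sharp; 250 kcal/mol is realistic for a trimer-scale cooperative unit and reproduces the two-peak phenomenology |
| urea midpoints | 3.32 M (two-state); 1.56, 3.95 M (biphasic) | published variant / wild-type midpoints |
| work distributions | `W_f ~ N(ΔG + σ²/2RT, σ²)`, `W_r ~ N(-ΔG + σ²/2RT, σ²)` | the unique Gaussian pair satisfying the Crooks fluctuation theorem exactly |

Seeds are mandatory for any stochastic output, every generator is a
deterministic function of (config, seed), and generators restore the
caller's RNG state. What the generators do **not** emulate: full emission
spectra, photobleaching and inner-filter effects, dye-binding kinetics,
ΔCp curvature in melt curves, and anharmonic/multimodal work
distributions. A green round-trip test therefore establishes that the
analyzers invert the stated models — not that real instrument data are
free of these unmodelled effects.

## 8. Statistical conventions in the tests

Stochastic assertions use fixed seeds and 3-sigma bands against reported
uncertainties. Where a criterion is checked over 50 seeds, 3-sigma
coverage is asserted as a fraction (>= 90%) rather than all-50, because
a perfectly calibrated estimator fails an all-50 check ~14% of the time.
Permutation-invariance assertions use a 1e-6 relative tolerance:
reordering inputs reorders floating-point summation, which moves results
in the last bits only.
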