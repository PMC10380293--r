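# fretstab

Quantitative analysis of sensitized-emission FRET binding assays and
protein-stability measurements, built for interaction-inhibitor screening
campaigns and for dissecting destabilising protein variants (the
motivating system is the PCNA–p15 interaction and a disease-associated
PCNA variant, but nothing in the code is specific to it).

The package covers five connected analyses plus the generators that make
them testable without instrument data:

1. **FRET binding** — three-channel crosstalk correction
   (`SE = DA − α·AA − δ·DD`) and nonlinear fitting of the exact quadratic
   ligand-depletion isotherm

   ```
   SE(X) = SE_max · [ 1 − 2·K_D / ((X − a + K_D) + √((X − a − K_D)² + 4·K_D·X)) ]
   ```

   for a donor held at concentration `a` titrated with acceptor `X`,
   including incubation-time-resolved K_D series that flag unstable
   titrants.
2. **Competition** — four-parameter logistic IC50 fits in
   log-concentration space, Cheng–Prusoff conversion
   `Ki = IC50 / (1 + L/K_D)`, and a dual-criterion (SE reduction *and*
   donor dequenching) single-concentration hit rule that rejects optical
   artifacts.
3. **Thermal stability (DSF)** — melting points from the smoothed
   derivative of melt curves, fraction-folded construction, and van't
   Hoff regression of `ln K_u` on `1/T` giving ΔH, ΔS and
   `ΔG(T_ref) = ΔH − T_ref·ΔS`, with ΔΔG comparison between variants.
4. **Chemical denaturation** — logistic midpoint (`C_m`) fits of
   urea-denaturation curves, `y = A₂ + (A₁ − A₂)/(1 + (x/x₀)^p)`, with
   two-segment splitting for biphasic three-state profiles.
5. **Nonequilibrium free energies** — Jarzynski, Crooks-Gaussian
   intersection and Bennett-acceptance-ratio estimators on forward/
   reverse work distributions, ΔΔG assembly from thermodynamic-cycle legs
   and closed-cycle consistency checks.

See `vignettes/fretstab-methods.Rmd` for the full model descriptions,
parameter defaults with their rationale, and known limitations (notably
the quantified depletion bias of classical Cheng–Prusoff at
non-trace assay concentrations).

## Worked example

Simulate a noisy titration plate at the assay design (1 µM donor,
0–3.09 µM acceptor, K_D = 0.4308 µM, 2% CV noise, technical triplicates),
estimate crosstalk from its control wells, correct, and fit:

```r
library(fretstab)
plate <- simulate_titration_plate(fret_sim_config(noise_cv = 0.02, seed = 42))
xt <- estimate_crosstalk(plate[plate$sample_id == "donor_only", ],
                         plate[plate$sample_id == "acceptor_only", ])
se  <- sensitized_emission(plate[plate$sample_id == "sample", ], xt)
fit <- fit_kd(as_titration_series(se))
fit
#> Binding fit (sample): Kd = 0.3638 +/- 0.104 uM, EmFRETmax = 936.4 +/- 69.9 RFU (n = 33, a = 1 uM)
```

The generating K_D (0.4308 µM) is recovered within the reported
uncertainty; on a noiseless plate the same pipeline recovers it to
machine precision. Converting a competitor's IC50 with the published
assay constants:

```r
cheng_prusoff(ic50 = 1.24, labeled_conc = 1, kd = 0.4308)
#> Ki = 0.3734 uM  (IC50 = 1.24 uM, L = 1 uM, Kd = 0.4308 uM)
```

A DSF melt curve with ΔH = 100 kcal/mol and ΔS = 0.3096 kcal/(mol·K)
analysed by the van't Hoff route, and a Crooks-consistent work set
analysed with BAR:

```r
vant_hoff_fit(simulate_melt_curve(melt_sim_config(delta_h = 100, delta_s = 0.3096)))
#> van't Hoff stability fit (sim):
#>   Tm: 323.15 K (50.00 C)
#>   dH = 100.013 kcal/mol, dS = 0.30964 kcal/(mol K)
#>   dG(298.15 K) = 7.694 kcal/mol  (R^2 = 1.00000, n = 9 in window [0.1, 0.5])

bar(simulate_work_values(work_sim_config(true_dg = 1.0, sigma = 0.5,
                                         n_per_direction = 10000, seed = 7)))
#> dG = 0.9982 +/- 0.0036 kcal/mol  [bar, nF = 10000, nR = 10000, T = 300 K]
```

`7.694 kcal/mol` is the analytic `100 − 298.15 × 0.3096`; the BAR
estimate sits half a standard error from the generating 1.0 kcal/mol.

## Command line

An umbrella CLI (`inst/cli/fretstab`, or `fretstab_cli()` from R) exposes
the stages as subcommands — `simulate`, `fit-kd`, `fit-ic50`, `screen`,
`dsf`, `chem-denat`, `neq-ddg`, `cycle` — reading/writing the plain CSV
dialects documented in the readers' help pages, and writing a
`manifest.json` (options, input checksums, seed, version) next to every
output for bit-identical reruns.

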