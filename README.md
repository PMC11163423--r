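# bilayerkit

Quantitative analysis of four assays used to study how amphiphiles —
surfactant-like ionic liquids, detergents, peptides — perturb lipid
membranes, and how cholesterol modulates that perturbation:

1. **Calcein dye-leakage kinetics.** Vesicle leakage traces are
   normalised against baseline and Triton-lysed reference channels,
   `%leak(t) = 100 (I_t − I_0,t)/(I_max,t − I_0,t)`, smoothed by a
   three-point moving average, and fitted with the logistic model
   `%leak(t) = a0 / (1 + exp(−(t − tc)·k))`, giving the plateau
   leakage `a0` (%), rate constant `k` (1/min) and half-leakage time
   `tc` (min). Flat traces are reported as non-identifiable ("N.D.")
   rather than fitted blindly.
2. **FRET probe-dilution lipid mixing.** NBD-PE dequenching at a fixed
   read time, normalised to a correction-factor-adjusted Triton
   reference (default ×1.5).
3. **Solid-state NMR chain order.** ²H powder spectra are dePaked
   (regularised non-negative inversion of the Pake kernel), converted
   to smoothed per-carbon order-parameter profiles |S_CD| via the
   cumulative deuteron-weighted quantile construction, and summarised
   as the mean order parameter ⟨S⟩ and the mean-torque chain extent
   L\*_c = Σ l_cc⟨cos βᵢ⟩ (l_cc = 1.27 Å). ³¹P spectra are fitted with
   an axially symmetric powder line shape to estimate the chemical
   shift anisotropy Δσ (ppm).
4. **Langmuir monolayer thermodynamics.** From pressure–area
   isotherms: the compressional modulus C_s⁻¹ = −A(∂π/∂A)_T, the
   lift-off area, and the excess Gibbs free energy of binary mixing
   ΔG_exc = ∫(A₁₂ − χ₁A₁ − χ₂A₂) dπ (1 Å²·mN/m = 6.022 J/mol).

No raw instrument data are required: every input class has a seeded
forward generator (`gen_leakage_traces()`, `gen_mixing_traces()`,
`gen_pake_spectrum()`, `gen_csa_spectrum()`, `gen_isotherm()`,
`gen_mixed_isotherm()`) with retained ground truth, so each analysis
stage is verified by parameter recovery, analytic limits and
closed-form oracles. See the vignette
(`vignettes/bilayer-assays.Rmd`) for the models, conventions and
numerical choices.

## Worked example

Simulate a fast near-complete leakage experiment, normalise and refit:

```r
library(bilayerkit)
spec <- leakage_trace_spec(a0 = 99.1, k = 0.52, tc = 0.87, t_end = 40)
tr <- gen_leakage_traces(spec)
fit <- fit_sigmoid(normalize_leakage(tr$sample, tr$baseline, tr$triton))
summary(fit)
#> Sigmoidal leakage fit on 396 points (converged: TRUE)
#>    Estimate Std. Error
#> a0 99.10160     0.0018
#> k   0.51903     0.0002
#> tc  0.86635     0.0006
#> Residual RMS: 0.0307 %
```

The generating triple (a0 = 99.1 %, k = 0.52 min⁻¹, tc = 0.87 min) is
recovered to ≲0.4 %; the small bias relative to machine precision is
the documented effect of fitting the smoothed series (use
`smooth = FALSE` for an exact round trip).

A full ²H round trip — simulate a powder spectrum from a plateau-decay
order profile, dePake it, rebuild the profile:

```r
prof <- order_profile(2:16, 0.161 / 0.131 *
                      c(rep(0.16, 7), seq(0.15, 0.05, length.out = 8)),
                      check_monotone = FALSE)
sp  <- gen_pake_spectrum(pake_spec(prof))
rec <- smoothed_profile(depake(sp), n_carbons = 16)
c(truth = mean(prof$s_cd), recovered = average_order(rec))
#>     truth recovered
#> 0.1573130 0.1570636
chain_extent(rec)
#> Chain summary: <S> = 0.157, L_c* = 11.98 A (15 segments, l_cc = 1.27 A)
estimate_csa(gen_csa_spectrum(csa_spec(45.9, broadening = 1)))
#> 31P CSA line-shape fit: |Delta sigma| = 45.90 ppm (sigma_iso = -0.00 ppm, HWHM = 1.00 ppm)
#>   residual RMS 1.56e-07, converged: TRUE
liftoff_area(gen_isotherm(isotherm_model_spec(111)))
#> [1] 110.9
```

⟨S⟩ comes back within 0.0003 of the ground truth, the chemical shift
anisotropy within 0.01 ppm, and the lift-off area to the area-grid
step (0.1 Å²).

`run_pipeline()` chains generator → analysis → report for any of the
five assay types from a single R list or JSON config, echoing truth
versus recovered parameters so every number is replayable.

## Acceptance script

`scripts/acceptance.R` re-runs the four pipelines end to end: it
generates synthetic data whose ground-truth parameters are set to
published reference values for PC/PG–cholesterol vesicle and monolayer
systems (leakage kinetics triples, mean chain order parameters, a ³¹P
CSA width, and lipid lift-off areas), runs the corresponding analysis
chain, and writes the recovered quantities as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
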