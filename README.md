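# bmcest

Two-state Bloch–McConnell analysis of imino ¹H CEST and off-resonance
R1ρ profiles, for quantifying transient Watson–Crick ↔ Hoogsteen
base-pair exchange in nucleic acid duplexes without isotopic enrichment.

Watson–Crick pairs flip transiently into Hoogsteen geometry — an excited
state (ES) with population `pES` of typically 0.05–0.5 % exchanging at
`kex = k1 + k-1` of 500–25 000 s⁻¹, its imino proton shifted upfield by
`Δω ≈ −1` to `−2` ppm. A high-power CEST experiment reads this out as a
minor dip in the normalized peak intensity versus RF offset. The package
provides, for users of such experiments:

* a 6×6 Bloch–McConnell propagator (matrix exponential of the generator
  combining precession, nutation, relaxation and exchange), with
  Gaussian RF-field inhomogeneity averaging and a nutation-based
  calibration of the inhomogeneity width;
* triplicate-based normalization and uncertainty estimation, offset
  windowing, joint multi-power Levenberg–Marquardt fitting with and
  without exchange (free parameters `pES`, `kex`, `Δω`, `R1`, `R2`
  versus `R1`, `R2` only);
* model selection by `AIC = N ln(RSS/N) + 2K` (small-sample corrected
  when `N/K < 40`), `BIC = N ln(RSS/N) + K ln N`, and the weight
  `w = e^{−Δ/2}/(1 + e^{−Δ/2})`, with exchange accepted only when both
  weights exceed 0.995 **and** the reduced χ² drops;
* reduced-χ² degeneracy scans of `kex`, `Δω`, `pES`;
* mono-exponential R1ρ decay fitting with Monte Carlo errors, the
  dispersion transform `(R2+Rex) = (R1ρ − R1 cos²θ)/sin²θ`, and
  Bloch–McConnell fitting of R1ρ values;
* van 't Hoff analysis of `k1`, `k−1` versus temperature,
  `ln(k/T) = ln(kB κ/h) − ΔG‡(Thm)/(R Thm) − (ΔH‡/R)(1/T − 1/Thm)`,
  referenced at the harmonic-mean temperature;
* a seeded synthetic-data generator reproducing the acquisition and
  noise structure of the experiments, so the whole pipeline is testable
  without spectrometer data.

See `vignettes/hoogsteen-cest-methods.Rmd` for the model, assumptions,
parameter defaults and numerical choices.

## Worked example

Simulate a G6-like resonance (pES = 0.3 %, kex = 3000 s⁻¹,
Δω = −1.5 ppm) on the default acquisition grid and fit it back:

```r
library(bmcest)
truth <- two_state_model(0.003, 3000, -1.5, r1_gs = 2, r2_gs = 20)
spec  <- simulation_spec(truth, seed = 2)
raw   <- generate_cest_dataset(spec)
prof  <- restrict_offsets(normalize_profile(raw), 6)
fit   <- fit_two_state(prof, with_exchange = TRUE)
fit
#> Bloch-McConnell CEST fit (with exchange)
#>   pES = 0.2978 %  kex = 3196.2 s-1  dw = -1.505 ppm
#>   R1 = 1.983 s-1  R2 = 20.020 s-1
#>   N = 363  K = 5  RSS = 0.009839  rchi2 = 4.718  AIC = -3807.22  BIC = -3787.75
select_models(fit, fit_two_state(prof, with_exchange = FALSE))
#> Model selection (exchange vs no exchange)
#>   wAIC+ex = 1.00000  wBIC+ex = 1.00000  (threshold 0.995)
#>   rchi2: 4.718 (ex) vs 105.8 (no ex)
#>   decision: exchange-significant
```

The fitted population (0.298 %), exchange rate (3196 s⁻¹) and shift
difference (−1.505 ppm) recover the generating values to well within
their uncertainties at the 0.5 % noise level; both model-selection
weights saturate at 1, so the exchange contribution is called
significant under the dual-threshold rule.

The `analysis/` directory holds the numbered workflow drivers
(`01_simulate.R` … `06_thermo.R`): benchmark dataset generation, CEST
fitting, model selection, degeneracy scans, R1ρ cross-validation and
van 't Hoff thermodynamics. Run them in order from the repository root;
each writes its tables under `results/` and prints a short summary of
what it found.

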