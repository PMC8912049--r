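# quenchbind

Analysis of spectroscopic protein–ligand binding titrations, built around
the serum-albumin / small-drug workup: inner-filter-effect correction,
Stern–Volmer quenching analysis, double-logarithm binding fits, van't Hoff
thermodynamics, far-UV CD helicity estimation and site-marker competition.
It is written for spectroscopists and med-chem groups who titrate a
quencher into a fluorescent protein (HSA and its tryptophan emission being
the canonical case) and need the full chain from raw emission spectra to a
binding-site call, with every step testable against synthetic data of
known ground truth.

## The models

For a titration at fixed protein concentration with quencher
concentrations `[Q]` (first point `[Q] = 0` defining `F0`):

* **Inner-filter correction** — `F_corr = F_obs · 10^((A_ex + A_em)/2)`,
  applied per point before any fit; an absorbing ligand otherwise inflates
  apparent quenching.
* **Stern–Volmer** — `F0/F = 1 + Ksv[Q]`, OLS; `Kq = Ksv/τ0` with
  `τ0 = 5.7 × 10⁻⁹ s` by default. Rising `Ksv` with temperature and
  `Kq` near the diffusion limit (`~10¹⁰ M⁻¹s⁻¹`) → dynamic quenching.
* **Double-log binding** — `log((F0−F)/F) = log Kb + n log[Q]`, OLS;
  `Kb` the apparent binding constant, `n` the site number (`n > 1`:
  cooperative).
* **Van't Hoff** — `ln Kb` vs `1/T`: `ΔH = −R·slope`, `ΔS = R·intercept`,
  `ΔG = ΔH − TΔS`; positive `ΔH` and `ΔS` → hydrophobic forces dominate.
* **CD helicity** — `MRE = θ/(10·c·l·N)`;
  `helix% = 100·(−MRE₂₀₈ − 4000)/29000`.
* **Site competition** — relative drop of `Kb` in the presence of a
  site marker (warfarin: drug site 1; ibuprofen: drug site 2); a ≥30%
  drop at the highest marker concentration calls a shared or proximal
  site.

A seeded synthetic-data generator produces absorbance spectra, emission
titrations (with a controllable inner-filter artifact), temperature series
and CD spectra from known ground truth, so each estimator is validated by
exact round-trip recovery.

## Worked example

```r
library(quenchbind)

# Temperature-resolved binding constants (M^-1) -> thermodynamics
kb <- c("293.15" = 820, "303.15" = 960, "313.15" = 1010, "323.15" = 1120)
vh <- fit_vant_hoff(kb)
vh
#> van't Hoff fit: dH = 7.79 kJ mol^-1, dS = 82.50 J mol^-1 K^-1, R^2 = 0.9666
#>   dG(293.15 K) = -16.40 kJ mol^-1
#>   dG(303.15 K) = -17.22 kJ mol^-1
#>   dG(313.15 K) = -18.05 kJ mol^-1
#>   dG(323.15 K) = -18.87 kJ mol^-1
classify_binding_forces(coef(vh)[1], coef(vh)[2])
#> [1] "hydrophobic"
```

Positive enthalpy and entropy changes with negative free energies at all
temperatures: spontaneous binding dominated by hydrophobic interactions,
growing slightly more favourable with temperature.

```r
# Simulated titration with an absorbing ligand: the inner filter inflates
# the naive Stern-Volmer constant; correction recovers the truth.
gt <- ground_truth(ksv_M_inv = 500, ife_enabled = TRUE)
ser <- simulate_emission_titration(gt, seq(0, 200e-6, by = 20e-6))
fit_stern_volmer(extract_intensities(ser))$ksv_M_inv
#> [1] 2176.077
corr <- correct_inner_filter(ser)$series
fit_stern_volmer(extract_intensities(corr))
#> Stern-Volmer fit: Ksv = 500 M^-1, Kq = 8.772e+10 M^-1 s^-1 (tau0 = 5.7e-09 s), R^2 = 1.0000
```

The full chain (simulate → correct → fit → thermo → CD → competition) is
one call:

```r
report <- run_pipeline(pipeline_config(seed = 1, out_dir = "report"))
report$mechanism$label          # "dynamic"
report$competition$warfarin$assignment   # "shared_or_proximal"
report$competition$ibuprofen$assignment  # "independent"
```

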