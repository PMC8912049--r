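---
title: "Models and methods: fluorescence quenching, binding thermodynamics and site competition"
author: "quenchbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quenchbind)
```

## The problem

When a drug binds a carrier protein such as human serum albumin (HSA), the
protein's intrinsic tryptophan fluorescence is quenched as the ligand is
titrated in. A standard spectroscopic workup extracts, from one series of
emission spectra per temperature:

* the Stern–Volmer quenching constant $K_{SV}$ and the bimolecular quenching
  constant $K_q = K_{SV}/\tau_0$, which together with the temperature trend
  distinguish collisional (dynamic) from ground-state-complex (static)
  quenching;
* an apparent binding constant $K_b$ and binding-site number $n$ from the
  double-logarithm plot;
* van't Hoff thermodynamics ($\Delta H$, $\Delta S$, $\Delta G$) across
  temperatures, whose sign pattern indicates the dominant binding forces;
* far-UV CD helicity changes reporting on ligand-induced unfolding; and
* a binding-site assignment from competition with site-specific markers
  (warfarin for Sudlow drug site 1, ibuprofen for site 2).

`quenchbind` implements this pipeline as composable fitting functions
returning classed S3 objects (`sv_fit`, `binding_fit`, `vant_hoff`,
`competition_table`) with the usual `print`/`coef`/`predict`/`plot`/
`residuals` methods, plus a synthetic-data generator with known ground
truth so every stage can be validated end to end.

## Models fitted

**Inner-filter correction.** A ligand that absorbs at the excitation or
emission wavelength attenuates the beam and inflates apparent quenching.
Before any fitting, recorded intensities are corrected with the standard
half-path form
$$F_\mathrm{corr} = F_\mathrm{obs}\,10^{(A_{ex}+A_{em})/2},$$
using per-point absorbances at the excitation wavelength and at the single
read (peak) emission wavelength. Several algebraically equivalent forms of
this correction circulate; the half-path cuvette-geometry form is the one
implemented, and it is exactly the inverse of the attenuation model the
simulator applies, so correction of noiseless synthetic data is exact. When
$A_{ex}+A_{em} > 0.3$ the correction becomes geometry-sensitive; the package
flags such points but still corrects them, since real titrations of
strongly absorbing drugs routinely operate there. A corrected series is
marked as corrected and refuses a second correction (which would square the
factor).

**Stern–Volmer.** Ordinary least squares of $F_0/F$ on $[Q]$:
$F_0/F = 1 + K_{SV}[Q]$. The intercept is free by default — reported fit
quality in this field implies unconstrained regression — and a fitted
intercept more than 5% from 1 triggers a data-quality warning; a
through-$(0,1)$ mode is available. $K_q = K_{SV}/\tau_0$ with
$\tau_0 = 5.7\times10^{-9}$ s by default (the literature HSA tryptophan
lifetime); the identity $K_q\tau_0 = K_{SV}$ holds to machine precision by
construction. Intensities are read at the emission maximum of the
zero-quencher spectrum (peak mode); an integrated-band-area mode exists
behind a flag but peak mode is the default because the classical plots use
peak intensities.

**Mechanism call.** Dynamic quenching grows with temperature, static
quenching shrinks. With fits at three or more temperatures, the call is
*dynamic* when $K_{SV}$ is non-decreasing in temperature (ties tolerated
within 2% relative — adjacent constants a few percent apart are within fit
noise) and the largest $K_q$ stays below $10^{12}$ M$^{-1}$s$^{-1}$;
*static* when $K_{SV}$ is non-increasing or $K_q$ exceeds that threshold;
*indeterminate* otherwise. The $10^{12}$ cutoff sits two orders above the
diffusion-controlled limit ($\sim10^{10}$): moderately super-diffusional
$K_q$ values are routinely reported for dynamic quenchers, so between
$10^{10}$ and $10^{12}$ the temperature trend decides.

**Double-log binding.** OLS of $\log_{10}((F_0-F)/F)$ on $\log_{10}[Q]$;
intercept $=\log_{10}K_b$, slope $=n$. Points with $F_0-F\le 0$ have no
defined transform; they are excluded and reported, never clamped, because
clamping would bias $K_b$. $n>1.05$ is read as cooperative, $n<0.95$
anticooperative (the 0.05 band absorbs slope noise). $K_b$ is an apparent
association constant: the double-log model presumes complex formation even
when the mechanism call is dynamic, and the package reports it as such.

**Van't Hoff.** OLS of $\ln K_b$ on $1/T$ (linear form; $\Delta H$ assumed
temperature-independent over the 30 K range studied):
$\Delta H = -R\cdot\mathrm{slope}$, $\Delta S = R\cdot\mathrm{intercept}$,
$R = 8.314$ J mol$^{-1}$K$^{-1}$. $\Delta G$ is reported at exactly the
input temperatures as $\Delta H - T\Delta S$, which is algebraically
$-RT\ln K_b$ along the fitted line; $-RT\ln K_b$ at the *observed* $K_b$
is emitted as a diagnostic column. Force classification:
$\Delta H>2$ kJ/mol and $\Delta S>0$ → hydrophobic; both negative (beyond
the band) → hydrogen bonding / van der Waals; $|\Delta H|\le 2$ kJ/mol →
electrostatic ("very low or zero" enthalpy); anything else → mixed. The
2 kJ/mol band operationalises "near zero" at the scale of typical
protein–drug enthalpies (tens of kJ/mol).

A caution this package surfaces by design: at a 4-temperature design
spanning 293–323 K, the standard error of $\Delta H$ under 5% lognormal
noise in $K_b$ is about 1.8 kJ/mol ($\sigma/\sqrt{S_{xx}}$ propagated
through $-R\cdot$slope). Enthalpies of a few kJ/mol extracted from such
designs are therefore sign-reliable but not precise; the test suite pins
this sampling behaviour rather than pretending tighter recovery.

**CD helicity.** Mean residue ellipticity
$\mathrm{MRE} = \theta_\mathrm{mdeg}/(10\,c\,l\,N)$ with molar
concentration $c$, path $l$ in cm and residue count $N$ (585 for HSA) —
note the 10, not the 100 of the g/L dialect. Helix content uses the common
single-wavelength two-point estimator at 208 nm,
$$h = \frac{-\mathrm{MRE}_{208} - 4000}{33000 - 4000}\times 100,$$
clamped to [0, 100]. The anchors are the conventional disordered
(−4000 deg cm²dmol$^{-1}$) and fully helical (−33000) values; applied to a
native HSA-like spectrum the estimator returns the literature ~67% helix.
No deconvolution (CONTIN/CDSSTR-style) is attempted; only the helix
fraction is estimated, and comparisons against a native reference call
*partial unfolding* when any treated spectrum drops more than 3 percentage
points (smaller changes are within the estimator's reproducibility).

**Site competition.** Each marker-present titration is corrected and
fitted like the baseline; the assignment keys on the relative drop of
$K_b$, not $K_{SV}$, because the site conclusion rests on binding
affinity. The displacement threshold is 0.30: marker competition at a
shared site typically collapses $K_b$ by an order of magnitude (~90%),
while an independent site leaves it within ~15%, so 0.30 separates the two
regimes with margin on both sides. The call is *shared_or_proximal* when
the drop at the highest marker concentration reaches the threshold,
*independent* when every change stays below it in magnitude, and
*inconclusive* for mixed patterns.

## The synthetic-data generator

The package does not bundle instrument data; the generator emulates the
standard HSA–gemcitabine-style study conditions and carries its ground
truth explicitly:

* **Design**: 3 µM protein, 0–200 µM ligand in 20 µM steps (11 points),
  excitation 280 or 295 nm, temperatures 293.15–323.15 K.
* **Ligand absorbance**: two Gaussian bands at 232 nm (σ = 12 nm,
  ε = 9000 M$^{-1}$cm$^{-1}$) and 268 nm (σ = 13 nm, ε = 10⁴), giving
  A ≈ 1 at 100 µM at the maximum, strong absorbance at 280 nm, modest at
  295 nm, and <1% of the peak at 310 nm — the gemcitabine-like profile
  that makes the inner-filter artifact large at 280 nm excitation and
  small past 300 nm.
* **Emission**: a single tryptophan-like Gaussian band at 340 nm
  (σ = 12 nm). Only the peak intensity matters to the fits, so band shape
  beyond smooth unimodality is not modelled.
* **Quenching law**: either the Stern–Volmer form
  $F = F_0/(1+K_{SV}[Q])$ or the double-log form
  $F = F_0/(1+K_b[Q]^n)$, chosen explicitly — the two analyses are fitted
  to the same data in practice, and making the generating model explicit
  is what lets each fit be tested for exact recovery.
* **Inner-filter artifact**: recorded intensities are multiplied by
  $10^{-(A_{ex}+A_{em})/2}$ with ligand-only absorbances from the band
  model (Beer–Lambert in concentration); the correction step inverts this
  exactly.
* **Noise**: additive Gaussian on intensities, truncated at zero, seeded.
  The default "replicate-scale" level used in stochastic tests is
  0.05 au on a 1000 au unquenched peak. This is calibrated to the
  *reproducibility of extracted binding constants* in repeated titrations
  of this kind (a few percent coefficient of variation on $K_b$), the
  quantity that matters for competition calls: the double-log intercept
  extrapolates ~4 decades in $\log[Q]$, so even this small intensity noise
  yields ~4% scatter in $K_b$. Published regression $R^2$ values around
  0.96–0.99 for such data reflect mostly systematic (curvature) deviation,
  which this white-noise generator deliberately does not model.
* **CD**: ellipticity is a helix-fraction mixture of an α-helix basis
  (minima at 208 and 222 nm, pinned to −33000 at 208) and a disordered
  basis (pinned to −4000 at 208), so the 208 nm MRE is exactly linear in
  helix fraction between the estimator's anchors and the
  simulate → estimate round trip is exact at zero noise.

What passing tests on these data do **not** show: robustness to scatter
and Raman peaks, photobleaching or drift, Poisson photon statistics,
protein absorbance contributions to the inner filter, or systematic
curvature in Stern–Volmer plots. The generator is a correctness harness
for the estimators, not an instrument model.

## Numerical and design choices

* All fits are ordinary least squares via `lm`; $R^2$ is computed about
  the mean with a zero-variance response defined as $R^2 = 1$ (a flat
  line fitted exactly).
* Concentrations are molar internally (manifests may declare µM),
  temperatures kelvin (manifests may declare °C); $K_{SV}$, $K_b$ in
  M$^{-1}$ throughout.
* Manifests are YAML with per-point two-column CSV spectra; numeric
  round-trips are exact to 12 significant digits, making save → load →
  save byte-stable.
* The per-point absorbances used for correction may be measured (mixture)
  values supplied in the manifest or computed from a ligand spectrum by
  Beer–Lambert additivity; the simulator uses ligand-only absorbances.
* Degenerate inputs fail loudly with the offending field named: unsorted
  or duplicate concentrations, missing zero-quencher anchor, mismatched
  emission grids, nonpositive intensities in a Stern–Volmer fit, fewer
  than three usable double-log points.
* Problem sizes in the test suite and acceptance script mirror the study
  design (11-point titrations, 4 temperatures); stochastic classification
  properties use 200 seeded replicates per condition.

## Worked pipeline

`run_pipeline()` wires the stages together on generated data whose ground
truth mirrors the study conditions and writes CSV/JSON tables plus plots;
every threshold and seed it used is recorded in the report's provenance
block.

```{r pipeline}
report <- run_pipeline(pipeline_config(seed = 1))
report$thermo
report$mechanism
report$competition$warfarin$assignment
report$competition$ibuprofen$assignment
```

## Known limitations

* The helicity estimator is a two-point convention; absolute helix
  percentages inherit its anchor choice, and only changes vs. a reference
  measured with the same convention are meaningful.
* $K_b$ from the double-log plot is an apparent constant with large
  leverage-driven variance; confidence in site-competition calls comes
  from the size of the warfarin-style collapse, not from the precision of
  any single $K_b$.
* No modified (Lehrer) Stern–Volmer, time-resolved lifetimes, ternary
  mass-action competition models, or CD deconvolution.
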