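---
title: "Methods: voltammetric characterization of a molecularly imprinted sensor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voltammetric characterization of a molecularly imprinted sensor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voltmip)
```

## Scope

`voltmip` implements the computational chain used to characterize and
validate an electrochemical sensor built on a molecularly imprinted polymer
(MIP), with the oxidation of chlorferron — the major hydrolysis metabolite of
the pesticide coumaphos — as the motivating system. The chain has four
stages: (1) extraction of anodic peak descriptors from cyclic (CV) or
differential-pulse (DPV) voltammograms, (2) inference of the electron-transfer
mechanism from pH and scan-rate series, (3) screening of candidate functional
monomers by template–monomer binding energy, and (4) analytical method
validation (calibration with detection limits, precision, spike recovery,
interference, comparison against a reference method). A seeded synthetic
voltammogram generator with attached ground truth makes the whole chain
testable without instrument data.

## Peak extraction

A voltammogram is a strictly monotone potential series (V vs Ag/AgCl) with a
matching current series (µA). `detect_peak()` fits a straight baseline by
least squares over a pre-peak potential window — by default the first 20% of
the sweep — subtracts it, and reports:

* `ep`, the potential of the maximum corrected current (argmax on the raw
  acquisition grid; no resampling),
* `ip`, that maximum (baseline-corrected),
* `ep_half`, the half-peak potential: the rising-flank potential where the
  corrected current crosses `ip/2`, interpolated linearly between the
  bracketing samples.

Design choices worth making explicit:

* **Linear baseline.** Instrument background in the pre-peak region of a DPV
  or CV trace is locally smooth; a straight line over a user-controllable
  window is the minimal defensible model, and it makes peak extraction
  exactly invariant (to within one grid step) under addition of any linear
  function of potential to the current. No published convention constrains
  this choice, so it is kept as simple as possible and exposed as a
  parameter.
* **No sub-grid refinement by default.** `ep` is tied to the acquisition
  grid so results are exactly reproducible and independent of any
  interpolation model. An optional parabolic apex refinement
  (`refine = TRUE`) is available but off by default.
* **Rising-flank convention for `ep_half`.** The half-peak width
  `ep - ep_half` feeds the transfer-coefficient relation below, which is
  stated for the rising flank of an irreversible anodic wave.

Degenerate inputs (corrected maximum on the sweep boundary, non-positive
peak, no half-height crossing) raise explicit "no peak" errors rather than
returning unusable numbers.

## Mechanism inference

Three regressions, all ordinary least squares (`stats::lm.fit` under a thin
`fit_linear()` wrapper that also reports r², residual SD and a 95% slope
confidence interval):

1. **Ep vs pH.** A slope magnitude of at least 20 mV/pH flags the reaction
   as proton-coupled. A Nernstian one-proton/one-electron process gives
   ~59 mV/pH at 25 °C; the permissive 20 mV threshold flags any meaningful
   pH dependence while ignoring fit noise.
2. **log₁₀(Ip) vs log₁₀(v).** The power-law exponent classifies the current:
   0.5 is the diffusion-controlled signature, 1.0 the adsorption-controlled
   one, intermediate values mixed control. `classify_control()` uses a
   tolerance band of 0.05 around each anchor, inclusive toward the pure
   regimes, so printed two-decimal slopes of 0.50 or 1.00 classify as pure.
   The classical Ip vs √v linearity check is reported as an auxiliary fit
   but is not used as a decision rule: the log-log exponent carries the same
   information on a scale where both pure regimes are linear.
3. **Ep vs log₁₀(v).** For an irreversible electrode reaction the slope is
   `2.303·R·T/(α·n·F)` (Laviron), inverted by `laviron_alpha_n()` to give
   the transfer-coefficient product `α·n`. Ep enters untransformed (volts):
   the kinetic relation is linear in log v, not log-log, even though peak
   potentials are sometimes tabulated on a log axis. Scan rates are taken in
   V/s; the unit choice shifts intercepts only, never slopes.

The transfer coefficient itself comes from the half-peak width of the peak
measured nearest the reference scan rate (default 0.1 V/s, the usual working
condition): `α = 47.7 mV / (Ep − Ep₁/₂)` for an irreversible wave at 25 °C.
The electron count is then `n = (α·n)/α`, rounded to the nearest integer
with ties away from zero. Constants default to R = 8.314 J K⁻¹ mol⁻¹,
F = 96480 C mol⁻¹, T = 298 K (overridable).

With the package defaults, an Ep-vs-log v slope of 0.1016 V/decade gives
`α·n = 0.582`. The rounded literature value for this system is 0.57; the
difference is rounding in the published chain (0.582 is the direct
evaluation of the same expression), and the package reports the computed
value rather than reproducing the rounding. Similarly, a 90 mV half-peak
width gives α = 0.53, and `n = 0.582/0.53 ≈ 1.10 → 1`: a one-electron,
proton-coupled, mixed diffusion–adsorption oxidation.

## Monomer screening

For each candidate functional monomer the stabilization energy of the
pre-polymerization complex is the pure difference
`ΔE = E(complex) − E(template) − ΣE(monomer)`, computed from externally
supplied quantum-chemistry totals; the package never runs quantum chemistry
and never converts units — ΔE is returned in the units of the input table,
whose label is passed through untouched. Candidates are ranked ascending
(most negative ΔE = most stable complex = best imprinting monomer); exact
ties, which have no physical basis, break lexicographically with a warning.
The packaged eight-monomer energy table reproduces its printed ΔE column to
1e-6 and selects pyrrole (Py), with ethylenedioxythiophene (ETOP) second.

Template:monomer stoichiometry selection (`select_ratio()`) is an argmin
over externally computed complex-energy scores. No published per-ratio
energies exist for this system, so the shipped ratio scan
(`ratio_scan_synthetic.csv`) is a synthetic fixture — labelled as such —
whose minimum sits at 1:4, the ratio reported optimal for
chlorferron:pyrrole; it exercises the selection logic without claiming
measured energies.

## Validation statistics

* **Calibration**: OLS of peak current on concentration. Detection limits
  use the 3.3σ/S and 10σ/S convention (σ = blank standard deviation when
  supplied, else the residual SD of the fit — the source is recorded in the
  output). The convention is adopted because the validated sensor's printed
  LOD/LOQ pair (0.158 and 0.48 µM) satisfies LOQ/LOD ≈ 10/3.3; by
  construction every fitted model has LOQ/LOD = 3.0303 exactly. The absolute
  LOD depends on instrument noise that no published number pins down, so the
  package makes no claim to reproduce 0.158 µM itself.
* **Recovery**: `100·mean(measured)/spiked`, with %RSD as `100·sd/mean`
  (sample SD, n−1). Both are invariant under common unit rescaling.
* **Precision**: per-level %RSD plus the median across levels, the usual
  summary statistic; levels with fewer than two replicates are skipped with
  a warning.
* **Interference**: signed current change `ΔI` and unsigned percent change
  `100·|ΔI|/I_ref`. `derive_interference_reference()` inverts a published
  summary table (ΔI and percent per row) to the common analyte-only
  reference current each row implies — a consistency check on published
  numbers. For the packaged twelve-row table the consensus is ≈0.2311 µA
  with all rows within 5% relative and exactly one row (propoxur at 50 µM)
  deviating by ~4%, which the default 2% flag threshold singles out.
* **Method comparison**: OLS of the reference method (e.g. GC-MS) on the
  sensor, matching the conventional orientation of published comparison
  equations; agreement is flagged for slope in [0.9, 1.1] with r² ≥ 0.99.
  Errors-in-variables regression (Deming) is out of scope.

Display rounding (two decimals for percents, three significant figures for
detection limits) happens only in print methods and at the report boundary;
all stored values are raw doubles.

## The synthetic-data generator

`generate_voltammogram()` is phenomenological, not a physical simulation: no
diffusion equation, no Butler–Volmer kinetics. It enforces the empirical
laws the analysis stage is supposed to recover:

* peak potential linear in pH (default slope 0.0567 V/pH) and in log₁₀ scan
  rate (default 0.1016 V/decade), composed additively around the reference
  condition pH 7, 0.1 V/s, Ep = 0.736 V. The two laws are published as
  separate one-dimensional fits whose joint form is unknown; the additive
  composition around the working point is the simplest joint model
  consistent with both.
* peak current `Ip = S·c·(v/v_ref)^b` with exponent b = 0.7677 and the
  sensitivity S ≈ 0.127 µA/µM derived from the published log-log intercept
  (1.5706 at 1 V/s) spread over the 50 µM working concentration.
* an asymmetric peak whose rising-flank half-width is exactly 90 mV
  (equivalently α = 0.53), falling flank 0.6× narrower.

Numerical choices that make the noiseless closure property exact rather than
approximate:

* **Truncated, rescaled Gaussian flanks.** Each flank is a Gaussian shifted
  and rescaled to vanish identically beyond 4 flank-SDs. The peak therefore
  has compact support and contributes exactly zero to the pre-peak baseline
  window, so the fitted baseline is exact and the analyzer's (Ep, Ip,
  Ep₁/₂) equal the generator's ground truth to floating-point precision.
  An untruncated Gaussian tail under the baseline window would bias Ip at
  the 1e-3 relative level — harmless in practice but large against a 1e-9
  closure bound.
* **Grid through the peak center.** The sweep runs from 0.5 V below to
  0.3 V above the (jittered) peak center in 2 mV steps, so the true Ep lies
  on the grid and the argmax is exact; 90 mV is a whole number of steps, so
  the half-height crossing falls on a sample. At the reference condition
  this window is 0.236–1.036 V, close to the usual 0.3–1.3 V CV window. The
  2 mV step is an implementation default (published work rarely states
  acquisition density), and the window tracks the peak so that the
  default baseline window stays peak-free across the whole pH 3–9 and
  0.05–1.0 V/s design.
* **Noise model.** Two seeded components: a Gaussian jitter of the peak
  center (σ_E = 2 mV) and additive current noise. Current noise is
  band-limited — white on knots every 25 grid samples, cubic-spline
  interpolated — because the current channel of a pulse-voltammetry
  acquisition is heavily low-pass filtered; sample-wise white noise at a
  2 mV grid would be unphysical and would also bias the argmax estimator
  upward through max-of-noise selection. The noise level (σ_I = 0.02 µA at
  the reference signal scale) scales with each measurement's signal
  amplitude, emulating instrument auto-ranging, with a floor of 10% of the
  reference range for near-blank signals. Under this model the OLS slope
  CIs of the pH and power-law fits attain close to nominal 95% coverage,
  which the test suite checks over 200 seeded replicates.
* **Reproducibility.** One root seed; each trace draws from a decorrelated
  stream derived from `(seed, seed_offset)` by a fixed integer recurrence.
  Identical configuration and seed give byte-identical CSV output. The
  global RNG state is saved and restored around every draw.

The validation-table generator works at table level (it does not synthesize
a trace per replicate): calibration currents and recovered concentrations
get the trace-level current noise propagated through the sensitivity
(σ_conc = σ_trace/S); matrix effects are multiplicative (plasma 0.95, urine
0.96); the interference block is deterministic, built from per-interferent
response coefficients fitted to the published selectivity table (hence a
maximum percent change of 16.88% for disulfoton-sulfoxide at tenfold
excess); the method-comparison table applies the configured linear relation
(slope 0.9972, intercept 1.6067) exactly.

### What the generator does and does not emulate

Passing tests on generator output demonstrate that the analysis chain
recovers the laws it assumes, with correct uncertainty statements under the
stated noise model. They do not demonstrate robustness to features of real
voltammetry the generator deliberately omits: curved or stepped backgrounds,
overlapping peaks, electrode fouling drift between replicates, pH-dependent
peak widths, non-linear interferent interactions, or matrix effects that
vary with concentration. Replicate dispersion in the synthetic recovery
tables (≈0.2–0.5% RSD) is optimistic compared with the 4–9% typical of
biological matrices, because the generator's only stochastic component is
instrument current noise. The pH optimum of the peak *current* (reported in
the motivating study at pH 6–7, with the two statements disagreeing) is not
modelled at all: the generator holds current independent of pH, and the
package takes pH 7 as the reference condition.

## Problem sizes and runtime

The default study sizes mirror the experimental design: 7 pH points × 7
scan rates for the mechanism stage (401-sample traces), 7 calibration
levels × 3 replicates, 2 spikes × 2 matrices × 3 replicates, 12
interference rows, 5 comparison points. The coverage property is checked at
200 replicates of the full mechanism pipeline, and the replicate-scaling
property at 60 seeds × two replicate counts; the complete test suite runs
in a few seconds on one core.
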