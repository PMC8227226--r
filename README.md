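# voltmip

Characterization and validation toolkit for electrochemical sensors built on
molecularly imprinted polymers (MIPs), written for electroanalytical
chemists developing such sensors — the motivating system is a
pyrrole-imprinted glassy-carbon sensor for chlorferron, the major metabolite
of the pesticide coumaphos, and a biomarker of exposure to it.

The package covers the full computational chain around such a sensor:

* **Peak analysis** — anodic peak extraction from CV/DPV traces with linear
  baseline correction: peak potential *E*ₚ, baseline-corrected peak current
  *I*ₚ, and half-peak potential *E*ₚ₁/₂.
* **Mechanism inference** — from a pH series and a scan-rate series:
  proton coupling from the *E*ₚ–pH slope; control regime from the power-law
  exponent of log *I*ₚ vs log *v* (0.5 = diffusion, 1 = adsorption);
  the Laviron transfer-coefficient product
  *αn* = 2.303 *RT* / (*F* · d*E*ₚ/dlog *v*) for an irreversible reaction;
  the transfer coefficient *α* = 47.7 mV / (*E*ₚ − *E*ₚ₁/₂); and the
  electron count *n* = *αn*/*α*.
* **Monomer screening** — ranking of candidate functional monomers by the
  binding energy of the pre-polymerization complex,
  Δ*E* = *E*(template–monomer) − *E*(template) − Σ*E*(monomer),
  from externally computed quantum-chemistry energy tables, plus
  template:monomer ratio selection from a stoichiometry scan.
* **Method validation** — calibration with LOD = 3.3σ/S and LOQ = 10σ/S,
  per-level %RSD precision, spike recovery, interferent percent change, and
  OLS comparison against a reference method (e.g. GC-MS).
* **Synthetic data** — a seeded generator producing voltammograms and
  validation tables that obey the laws above, with ground truth attached,
  so every stage of the pipeline is testable end to end without an
  instrument.

## Worked example

Screen the packaged eight-monomer DFT energy table, then run the full
mechanism and validation pipeline on a seeded synthetic study:

```r
library(voltmip)

energies <- read_energy_table(system.file("extdata", "table1_energies.csv",
                                          package = "voltmip"))
screen_monomers(energies)
#> Monomer screening by template-monomer binding energy
#>  rank monomer   delta_e
#>     1      Py -0.012061
#>     2    ETOP -0.011916
#>     3     IPA -0.010974
#>     4     OAP -0.010432
#>     5       A -0.008635
#>     6     MBT -0.007080
#>     7     H-A -0.005138
#>     8     OPD -0.004755
#> selected: Py (runner-up: ETOP)

cfg <- synthetic_config()   # default study conditions, seeded noise
analyze_mechanism_study(generate_mechanism_study(cfg, seed = 42))
#> Electron-transfer mechanism report
#>   Ep vs pH slope:        0.05617 V/pH (proton-coupled: TRUE)
#>   log Ip vs log v slope: 0.7652  -> mixed control
#>   Ep vs log v slope:     0.1014 V/decade
#>   alpha*n = 0.583, alpha = 0.529 (at 0.0823774 V/s), n = 1.102 ~ 1

val <- analyze_validation_study(generate_validation_study(cfg, seed = 42))
val$recovery
#>   matrix spiked_uM  mean_uM recovery_pct    rsd_pct n
#> 1 plasma        25 23.71687     94.86748 0.16172357 3
#> 2 plasma        40 38.03838     95.09596 0.15230853 3
#> 3  urine        25 23.94873     95.79491 0.24133732 3
#> 4  urine        40 38.40066     96.00166 0.08683816 3
```

Reading the output: pyrrole forms the most stable complex with the template
(most negative ΔE), so it is the monomer of choice for imprinting. The
recovered pH slope (~56 mV/pH) flags a proton-coupled oxidation; the
log-log exponent 0.77 sits between the diffusion (0.5) and adsorption (1.0)
signatures, i.e. mixed control; and *αn* ≈ 0.58 with *α* ≈ 0.53 gives
*n* ≈ 1 — a one-electron oxidation. Spike recoveries near 95–96% reflect
the configured multiplicative matrix effects (plasma 0.95, urine 0.96).

A thin command-line layer wraps the same functions:

```sh
Rscript inst/cli/voltmip screen --energies inst/extdata/table1_energies.csv
Rscript inst/cli/voltmip simulate --seed 1 --out study/
Rscript inst/cli/voltmip report --in study/ --energies inst/extdata/table1_energies.csv --out report.json
```

## Package layout

* `R/` — voltammogram data model and I/O, peak extraction, mechanism
  regressions, screening, validation statistics, synthetic generator,
  JSON reporting, CLI.
* `inst/extdata/` — packaged energy, interference and recovery tables; the
  ratio scan is a synthetic fixture (see `vignettes/voltmip-methods.Rmd`).
* `vignettes/voltmip-methods.Rmd` — models, conventions, generator design,
  numerical choices, and known limitations.
* `tests/testthat/` — unit, property and end-to-end suites.
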