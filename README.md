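# pdnptrace

Multi-modal quantification of metal-doped nanoplastic tracers in biological
samples.

## The problem

Nanoplastics (< 1 µm) cannot be counted directly in tissue at trace
concentrations. A practical strategy is to dope model polystyrene particles
(~200 nm) with a rare metal — palladium at ~0.3 wt.% — and quantify the metal
instead with three complementary read-outs:

* **XFI** — scanning X-ray fluorescence imaging: Pd K-shell fluorescence
  (Kα 21.12 keV, Kβ 23.82 keV) excited by a monochromatic pencil beam gives
  a non-destructive, quantitative Pd mass map at beam-size (1 mm) resolution.
* **ICP-MS** — bulk Pd mass after acid digestion: the most sensitive
  measurement, with limit-of-detection censoring, but spatially blind.
* **IMC** — imaging mass cytometry: laser ablation at 1 µm per pixel with
  TOF detection of Pd ions; at low signal one dual count ≈ one ion ≈ one
  particle.

`pdnptrace` is aimed at analysts of such tracer studies. It implements each
quantification stage, the dose-fraction mass-balance accounting that ties
them together (percent of applied/daily dose, cumulative excretion, total
recovery, group comparison, cross-method agreement), and a synthetic-data
generator — first-order gastrointestinal transit of oral boluses with
partial systemic uptake, plus virtual XFI/ICP-MS/IMC readouts with the right
counting statistics — so the whole chain is testable against known ground
truth.

## Core models

* Transit: linear chain stomach → small intestine → cecum → colon → feces
  with rate constants *k* (1/h) and a systemic pool fed a fraction *f* of
  the small-intestine outflow; integrated with `deSolve` to < 1e-9 relative
  mass-balance error.
* XFI: per-line expected counts
  `mu_L = flux · dwell · m · (N_A/A_Pd) · sigma_L · (Omega/4pi) · eps`,
  Poisson counting; quantification by linear least-squares peak fitting
  (fixed centroids, shared detector-resolution width, linear background) and
  reference-target calibration `K = counts/(µg · s)`, so results are
  independent of the absolute cross section. Attenuation is reported as a
  Beer–Lambert bias bound (NIST water table, log-log interpolation); LOD is
  `3·sqrt(B)/(K·dwell)`.
* ICP-MS: internal-standard drift correction, OLS calibration on the 0–25
  µg/L daily grid, `mass = conc × dilution × volume`, censoring
  bdl / between-LOD-LOQ→LOD / quantified.
* IMC: uniform 0–1 dual-count detector noise, Poisson ion counts split
  across isotope channels by natural Pd abundances, strict noise-ceiling
  thresholding, `floor(pixel/diameter)` packing bound, two-fold titration
  series with exact integer dilution factors.

## Worked example

```r
library(pdnptrace)

# acute scenario: single gavage of 3.3817 mg NPs / 9.976 µg Pd
reg <- dose_regimen(3.3817, 9.976, schedule_h = 0)
study <- simulate_biodistribution(reg, times_h = c(0, 2, 4), seed = 1)
round(study$masses, 3)
#>   time_h stomach small_intestine cecum colon feces systemic administered_ug
#> 1      0   9.976           0.000 0.000 0.000 0.000        0           9.976
#> 2      2   0.497           3.252 4.022 1.542 0.663        0           9.976
#> 3      4   0.025           0.818 3.119 2.621 3.393        0           9.976

# virtual XFI scan of a 2x2 sample, quantified back
scan  <- generate_xfi_scan(matrix(c(0.04, 0.08, 0.06, 0.10), 2, 2), seed = 1)
calib <- calibrate_flux(xfi_scan_references(scan), scan$beam$area_mm2)
calib
#> XFI flux calibration: K = 1.265e+04 counts/(ug s) (+/- 0.73 %), 2 reference(s)
build_mass_map(scan, calib)
#> XFI mass map: 2 x 2 pixels, total 0.2829 ug Pd (0 failed fits)

100 * estimate_attenuation_bias(21.1, path_length_cm = 0.3)
#> [1] 19.70447   # percent of K-alpha photons lost in 3 mm water-equivalent

# virtual ICP-MS batch with drift correction, calibration and censoring
quantify_batch(generate_icpms_batch(c(0.5, 2), seed = 1))
#>         id   mass_ng     status sample_lod_ng sample_loq_ng
#> 1 sample_1  6.503352 quantified   0.003341723    0.01113908
#> 2 sample_2 26.004813 quantified   0.003341723    0.01113908
```

At 2 h post-gavage only 0.66 µg (6.6 % of the dose) has reached the feces
while 4 µg sits in the cecum; by 4 h excretion reaches 34 % — the
fast-front/slow-bulk transit pattern the simulator is tuned to. The XFI map
reconstructs the 0.28 µg ground truth within counting noise, and the ICP-MS
masses are `conc × (13/3) × 3 mL` with their per-sample detection limits.

The full pipeline (simulate → XFI → ICP-MS → IMC → report) runs from one
config:

```r
man <- run_pipeline(default_pipeline_config(), "demo_run", seed = 1)
man
#> pdnptrace run (seed 1, config 9a5e3b03)
#>   dose 9.976 ug; excreted 99.0 %; organ recovery 1.01 %; XFI feces 9.859 ug; 5 IMC positives
#>   outputs: 8 file(s)
```

A thin CLI over the same functions is at `inst/cli/pdnp.R`
(`Rscript pdnp.R run --config cfg.yaml --out dir --seed 1`).

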