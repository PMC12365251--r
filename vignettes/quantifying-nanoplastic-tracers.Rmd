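---
title: "Quantifying metal-doped nanoplastic tracers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying metal-doped nanoplastic tracers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdnptrace)
```

# The measurement problem

Nanoplastics are too small and too dilute to be counted directly in tissue.
A practical workaround is to dope model polystyrene particles (~200 nm) with
a rare metal — here palladium at roughly 0.3 % by weight — and to quantify
the metal instead, with three complementary read-outs:

* **XFI** (X-ray fluorescence imaging): a monochromatic pencil beam excites
  Pd K-shell fluorescence; a scan at 1 mm steps gives a quantitative,
  non-destructive Pd mass map of a whole sample.
* **ICP-MS** after acid digestion: the most sensitive bulk measurement, but
  destructive and spatially blind.
* **IMC** (imaging mass cytometry): UV laser ablation at 1 µm per pixel with
  time-of-flight detection of Pd ions, resolving single particles at
  cellular scale.

`pdnptrace` implements the quantification stage of each read-out plus the
dose-fraction accounting that ties them together, and a synthetic-data
generator that reproduces the statistical structure each instrument sees, so
that every stage can be exercised end-to-end against known ground truth.

# The transit simulator

Oral gavage deposits a bolus in the stomach. The generator models transit as
a linear chain of first-order compartments,

$$\text{stomach} \xrightarrow{k_1} \text{SI} \xrightarrow{k_2}
  \text{cecum} \xrightarrow{k_3} \text{colon} \xrightarrow{k_4}
  \text{feces},$$

with a fraction $f$ of the small-intestine outflow diverted to a single
systemic pool. This is deliberately the simplest model that reproduces the
"fast front, slow bulk" excretion pattern of oral boluses: traces appear in
feces about 2 h post-gavage while the bulk follows over many hours. The
default rates ($k = 1.5, 0.8, 0.5, 0.6\,\mathrm{h^{-1}}$,
`default_transit_rates()`) were chosen once so that the first fecal signal
appears near 2 h and roughly 30 % of a bolus is excreted by 4 h; they are
configuration values, not measured physiology. The system is integrated with
`deSolve::lsoda` at `rtol = 1e-11`, `atol = 1e-13`, which keeps the mass
balance (administered = compartments + excreted) below $10^{-9}$ relative
error — the tolerance the test suite asserts. Outputs requested exactly at a
later gavage time report the pre-gavage state; the time-zero bolus is part
of the initial condition.

What the simulator does **not** emulate: physiologically based kinetics,
inter-animal variability, enterohepatic recirculation, or particle
aggregation. Passing tests therefore demonstrate correctness of the
quantification chain, not biological realism.

```{r}
reg <- dose_regimen(3.3817, 9.976, schedule_h = 0)
study <- simulate_biodistribution(reg, times_h = c(0, 2, 4, 24))
round(study$masses, 3)
```

# XFI: forward model, peak fitting, calibration

The virtual instrument draws, per pixel, Poisson counts around

$$\mu_L = \Phi\, t\, m\, \frac{N_A}{A_{\mathrm{Pd}}}\, \sigma_L\,
  \frac{\Omega}{4\pi}\, \varepsilon$$

for each K line ($\Phi$ flux density, $t$ dwell, $m$ pixel mass,
$\sigma_L$ an effective fluorescence-production cross section at 53 keV
excitation), on a flat continuum background. The packaged $\sigma_L$ values
(K-shell photoionization × fluorescence yield $\omega_K \approx 0.82$ ×
branching 0.77/0.23) only set the forward scale: quantification calibrates
the system constant $K$ (counts per µg per s) from reference targets with
known deposited masses, so reconstructed masses are insensitive to the
absolute cross section. The test suite asserts this calibration invariance
by changing the simulated flux and recalibrating.

Peak fitting uses two Gaussians with **fixed centroids** (K$\alpha$
21.12 keV, K$\beta$ 23.82 keV) and a **shared width** from the detector
resolution model $\mathrm{FWHM}(E) = \sqrt{w_e^2 + 2.355^2 F \epsilon E}$
(defaults give ≈ 180 eV at 21 keV), plus a linear background — the model is
then linear in its parameters and solved by ordinary least squares, with
Poisson-propagated uncertainties from the sandwich covariance. Design
choices worth recording:

* the background is linear inside the window by default (an exponential
  option exists behind a flag);
* negative fitted areas are clipped to zero and flagged rather than
  propagated;
* a singular fit returns a flagged non-converged result with `NA` areas,
  never a silent zero.

Attenuation of the ~21 keV fluorescence inside the sample is **reported as a
bias bound, not applied as a correction**: 2D scans lack the geometry needed
for a per-pixel correction, so reconstructed masses systematically
underestimate truth. `estimate_attenuation_bias()` evaluates the
Beer–Lambert loss with the packaged NIST water attenuation table (15–60 keV,
log-log interpolation); 3 mm of water-equivalent tissue at 21.1 keV loses
about 19.7 % — inside the expected 10–25 % band for representative sample
geometries. An optional uniform-slab correction
(`apply_attenuation_correction()`) exists for users who want it. Detection
limits use the 3σ-of-background criterion,
$m_{\mathrm{LOD}} = 3\sqrt{B}/(K t)$, which scales as $1/\sqrt{t}$ for a
constant background rate.

The calibration restriction: reference targets are treated as Pd-equivalent.
Cross-element calibration transfer (fluorescence yield and cross-section
ratios between elements) is out of scope.

# ICP-MS: drift correction, calibration, censoring

Digests are calibrated daily against standards at 0, 0.1, 0.5, 1.0, 2.5,
5.0, 12.5 and 25.0 µg Pd/L. Internal standards (Y/Sc at constant nominal
concentration) are acquired with every record; `drift_correct()` divides
each analyte intensity by the record's internal-standard intensity relative
to the mean over the standards, removing any multiplicative sensitivity
drift. The virtual run injects a linear drift so the correction can be
verified to give unbiased recovery.

Quantification back-calculates
`mass [ng] = conc [µg/L] × dilution × volume [mL]` (digest dilution 13:3 is
interpreted as multiply-back by 13/3 ≈ 4.33; the alternative 16/3 reading is
available via the argument). Censoring follows the standard
left-censoring convention: instrument LOD/LOQ default to 3σ and 10σ of the
blanks over the slope (the multipliers are configurable because printed
LOD/LOQ pairs in practice often imply other ratios); sample LOD/LOQ are the
instrument values times the digest volume; masses below the sample LOD are
reported as `bdl` (value `NA`, never 0), masses between LOD and LOQ are set
to the LOD value. In downstream sums `bdl` contributes 0 and in-band values
contribute the LOD, both flagged, so totals carry a censoring annotation.
Half-organ digests are rescaled by total/partial weight with the status
preserved. Only the ^106^Pd channel is used for reporting; the isotope
ratios in the IMC module cover the other channels.

# IMC: dual counts, thresholds, titration

The detector reports *dual counts*; below ~30 dual counts one dual count is
one detected ion, and empirically one ~200 nm particle yields about one
detected Pd ion. The generator draws per-channel uniform noise in
$[0, \mathrm{noise_{max}}]$ (the observed 0–1 dual-count noise band; the
uniform shape is this package's choice and is configurable) and, at particle
sites, Poisson ion counts split multinomially across the six Pd isotope
channels by natural abundances — which is why ^106^Pd (27.3 %) and ^108^Pd
(26.5 %) are the most sensitive channels, as the channel-ranking test
asserts. A direct consequence of the Poisson model is that a single particle
at unit ion yield is detected with probability $1 - e^{-1} \approx 0.632$;
the suite verifies this against $10^4$ simulated pixels.

Thresholding counts pixels strictly above a noise ceiling. No single
ceiling is canonical in practice — 1.0 (the noise band edge), 1.5 and 2.0
are all used as read-offs — so all three ship as presets
(`imc_noise_presets()`) with 1.0 the default. The packing bound
`max_particles_per_pixel()` uses linear (diameter-wise) packing,
$\lfloor 1000/200 \rfloor = 5$ per 1 µm pixel; area packing would allow ~25
and does not match the observed 1–6 dual-count range.

The titration module encodes a 1:1 serial dilution spotted at 0.2 µL. Two
indexing conventions exist for the cumulative factor relative to the
pre-dilution suspension: counting spot 1 as the first dilution gives
$2^k$ (default; after 40 spots, $2^{40} \approx 1.10 \times 10^{12}$),
counting it as undiluted gives $2^{k-1}$. Both are implemented behind
`spot1_is_first_dilution` because the two printed anchor values of such
series (spot-1 mass from the undiluted concentration, yet a 40-step factor
of $2^{40}$) are mutually inconsistent; the default matches the factor. A
Trypan-blue addition of 1 µL into 10 µL would add an 11/10 factor that the
spot-mass arithmetic conventionally ignores; this package ignores it too.

# Accounting

All recovery accounting is in percent of the applied (acute) or daily
(repeated-dosing) dose — an explicit regimen attribute, never inferred.
Values above 100 % are legal (counting noise on a large denominator) and
flagged. Cumulative excretion is the running sum of per-interval masses;
censored entries contribute per the ICP-MS rule. Group comparison is an
unpaired pooled-variance t-test (`stats::t.test`; Welch behind a flag), with
the degenerate both-groups-constant case returning $p = 1$ by convention.
Cross-method agreement reports the ratio statistics, the mean relative
difference and the concordance slope through the origin
$\sum m_1 m_2 / \sum m_1^2$.

`fit_transit_rates()` recovers the chain rate constants from observed
compartment time series by Levenberg–Marquardt (`minpack.lm`). One
identifiability caveat matters: the fecal curve of a linear chain is nearly
invariant under exchange of the rate constants, so feces-only fits constrain
individual rates poorly (equal-rate solutions can fit a noisy fecal curve
better than the truth). Fitting against the GI compartment curves — the
form in which transit data are actually measured — identifies each rate
directly; at the default measurement noise for this check (additive
Gaussian, sd = 1 % of the administered dose per observation, matching the
virtual instruments' precision at these masses) all four rates are recovered
within 10 %, typically within 3 %. Rates are bounded to
$[10^{-3}, 50]\,\mathrm{h^{-1}}$ during optimization to keep the ODE solver
well-conditioned.

# Problem sizes and numerical choices

The shipped tests run the full chain at desk scale, chosen as the smallest
sizes at which the asserted statistics are stable: XFI maps of 2×2 pixels
with ~0.02 keV bins over 18–26.5 keV (coverage over 100 Poisson seeds),
ICP-MS batches over 500 seeds, IMC detection probability over $10^4$
single-pixel draws, and rate recovery from 12 hourly observations of five
compartments. Randomness derives from one top-level integer seed per
generator with deterministic child streams per virtual instrument
(`derive_seed`), so identical seeds give bit-identical outputs — a property
the pipeline test asserts on file digests.

# Known limitations

* The XFI spectral model omits Compton/Rayleigh scattering, escape peaks and
  pile-up; the continuum background is flat per bin.
* Reference targets must be Pd-equivalent; no cross-element transfer.
* The ICP-MS module covers bulk quantification only (no single-particle
  mode, no interference modeling).
* IMC spillover correction beyond channel summation, cell segmentation and
  the vendor's binary MCD format are out of scope; the TXT pixel dialect is
  supported.
* The transit model is a descriptive first-order chain, not a
  physiologically based model; uptake is a single lumped systemic pool.
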