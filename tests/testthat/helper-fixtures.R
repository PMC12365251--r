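# Shared fixtures: small virtual-instrument objects built in code.

acute_regimen <- function() dose_regimen(3.3817, 9.976, schedule_h = 0)

# Synthetic spectrum with known line areas on a flat background.
synthetic_spectrum <- function(kalpha_area = 1000, kbeta_area = 0,
                               background = 5, poisson = FALSE, seed = 1,
                               energy = seq(18, 26.5, by = 0.02),
                               detector = xfi_detector()) {
  lines <- pd_line_energies()
  sig <- pdnptrace:::detector_sigma_kev(detector, lines[["kalpha"]])
  dE <- energy[2] - energy[1]
  mu <- kalpha_area * dnorm(energy, lines[["kalpha"]], sig) * dE +
    kbeta_area * dnorm(energy, lines[["kbeta"]], sig) * dE + background
  counts <- if (poisson) {
    set.seed(seed)
    rpois(length(mu), mu)
  } else mu
  xfi_spectrum(energy, counts, dwell_s = 1)
}

# A calibration curve with prescribed parameters (for censoring-rule tests).
manual_curve <- function(slope = 1000, intercept = 0, lod_ug_l = 0.043,
                         loq_ug_l = 0.056) {
  structure(list(slope = slope, intercept = intercept, r_squared = 1,
                 residual_sd = 0, lod_ug_l = lod_ug_l, loq_ug_l = loq_ug_l,
                 lod_k = 3, loq_k = 10),
            class = "calibration_curve")
}
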