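# Virtual ICP-MS batch generator.

#' Calibration grid used for daily ICP-MS calibration
#'
#' @return Nominal standard concentrations in ug Pd/L, including the zero
#'   standard: 0, 0.1, 0.5, 1.0, 2.5, 5.0, 12.5, 25.0.
#' @export
icpms_calibration_grid <- function() {
  c(0, 0.1, 0.5, 1.0, 2.5, 5.0, 12.5, 25.0)
}

#' Generate a virtual ICP-MS batch
#'
#' Emulates one acquisition run: calibration standards on the daily grid,
#' blanks, then samples, acquired in that order. Analyte signal is
#' `slope * conc + intercept`, multiplied by a linear instrumental drift
#' factor that decays by `drift` from the first to the last acquired record;
#' the internal-standard channel (Y/Sc mean, nominal `is_intensity`) decays
#' by the same factor and is noiseless by construction so the injected drift
#' is exactly recoverable. Gaussian noise with sd `blank_sd` is added to all
#' analyte intensities.
#'
#' @param sample_concs True sample concentrations as measured (ug Pd/L).
#' @param slope Sensitivity (counts per ug/L, > 0).
#' @param intercept Background intensity (counts).
#' @param blank_sd Gaussian noise sd on analyte intensities (counts, >= 0).
#' @param drift Fractional sensitivity loss across the run (0 = stable).
#' @param n_blanks Number of blank records.
#' @param dilution_factor Dilution applied to the digests before measurement
#'   (multiply-back factor; default 13/3).
#' @param digest_volume_ml Total digested sample volume (mL).
#' @param is_intensity Nominal internal-standard intensity (counts).
#' @param seed Integer RNG seed.
#' @return Object of class `icpms_batch`: `records` data frame with columns
#'   `record_type`, `id`, `nominal_conc`, `intensity_106`, `intensity_IS`,
#'   `dilution_factor`, `digest_volume_mL`, `order`; plus the generating
#'   parameters under `params` and the true concentrations under
#'   `true_concs`.
#' @export
#' @examples
#' b <- generate_icpms_batch(c(1, 5), blank_sd = 0, drift = 0, seed = 1)
#' subset(b$records, record_type == "sample")$intensity_106  # slope*conc+intercept
generate_icpms_batch <- function(sample_concs,
                                 slope = 2e4, intercept = 50,
                                 blank_sd = 10, drift = 0.05,
                                 n_blanks = 5,
                                 dilution_factor = 13 / 3,
                                 digest_volume_ml = 3,
                                 is_intensity = 1e5,
                                 seed = 1L) {
  if (slope <= 0) stop("slope must be positive")
  if (blank_sd < 0) stop("blank_sd must be non-negative")
  set.seed(derive_seed(seed, "icpms"))
  std <- icpms_calibration_grid()
  conc <- c(std, rep(0, n_blanks), sample_concs)
  type <- c(rep("standard", length(std)), rep("blank", n_blanks),
            rep("sample", length(sample_concs)))
  id <- c(sprintf("std_%g", std), sprintf("blank_%d", seq_len(n_blanks)),
          sprintf("sample_%d", seq_along(sample_concs)))
  n <- length(conc)
  ord <- seq_len(n)
  drift_factor <- if (n > 1) 1 - drift * (ord - 1) / (n - 1) else rep(1, n)
  intensity <- (slope * conc + intercept) * drift_factor +
    stats::rnorm(n, 0, blank_sd)
  records <- data.frame(
    record_type = type, id = id,
    nominal_conc = ifelse(type == "sample", NA_real_, conc),
    intensity_106 = intensity,
    intensity_IS = is_intensity * drift_factor,
    dilution_factor = ifelse(type == "sample", dilution_factor, 1),
    digest_volume_mL = ifelse(type == "sample", digest_volume_ml, NA_real_),
    order = ord)
  structure(list(records = records,
                 params = list(slope = slope, intercept = intercept,
                               blank_sd = blank_sd, drift = drift,
                               is_intensity = is_intensity),
                 true_concs = sample_concs, seed = as.integer(seed)),
            class = "icpms_batch")
}

#' @export
print.icpms_batch <- function(x, ...) {
  tab <- table(x$records$record_type)
  cat(sprintf("ICP-MS batch: %d standards, %d blanks, %d samples\n",
              tab[["standard"]], tab[["blank"]],
              if ("sample" %in% names(tab)) tab[["sample"]] else 0L))
  invisible(x)
}
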