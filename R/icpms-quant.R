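# ICP-MS quantification: drift correction, calibration, censored sample
# quantification and half-organ scaling.

#' Internal-standard drift correction
#'
#' Divides each analyte intensity by the record's internal-standard intensity
#' relative to the mean internal-standard intensity over the calibration
#' standards, removing linear (or any multiplicative) instrumental drift.
#' Records with a non-positive internal standard are rejected: they are
#' dropped from the batch and reported in the `diagnostics` attribute.
#'
#' @param batch An `icpms_batch`.
#' @return The batch with corrected `intensity_106`; dropped records, if any,
#'   are listed in `attr(, "diagnostics")`.
#' @export
#' @examples
#' b <- generate_icpms_batch(1, drift = 0.1, blank_sd = 0)
#' drift_correct(b)
drift_correct <- function(batch) {
  stopifnot(inherits(batch, "icpms_batch"))
  rec <- batch$records
  bad <- !(rec$intensity_IS > 0)
  diag <- NULL
  if (any(bad)) {
    diag <- sprintf("record %s (order %d): non-positive internal standard, rejected",
                    rec$id[bad], rec$order[bad])
    rec <- rec[!bad, , drop = FALSE]
  }
  ref <- mean(rec$intensity_IS[rec$record_type == "standard"])
  rec$intensity_106 <- rec$intensity_106 / (rec$intensity_IS / ref)
  batch$records <- rec
  batch$drift_corrected <- TRUE
  attr(batch, "diagnostics") <- diag
  batch
}

#' Fit the ICP-MS calibration curve
#'
#' Ordinary least squares of intensity on nominal concentration over the
#' calibration standards. Instrument detection and quantification limits
#' default to the blank-sd criteria `LOD = lod_k * sd(blanks) / slope` and
#' `LOQ = loq_k * sd(blanks) / slope` (`lod_k = 3`, `loq_k = 10`); the
#' multipliers are configurable because reported LOD/LOQ conventions vary.
#'
#' @param batch An `icpms_batch` (ideally after [drift_correct()]); or pass
#'   `standards` and `blanks` data frames directly.
#' @param standards Data frame with `nominal_conc`, `intensity_106`.
#' @param blanks Numeric vector of blank intensities.
#' @param lod_k,loq_k Blank-sd multipliers for LOD and LOQ.
#' @return Object of class `calibration_curve`: `slope`, `intercept`,
#'   `r_squared`, `residual_sd`, `lod_ug_l`, `loq_ug_l`.
#' @export
#' @examples
#' b <- drift_correct(generate_icpms_batch(1, seed = 2))
#' fit_calibration(b)
fit_calibration <- function(batch = NULL, standards = NULL, blanks = NULL,
                            lod_k = 3, loq_k = 10) {
  if (!is.null(batch)) {
    stopifnot(inherits(batch, "icpms_batch"))
    rec <- batch$records
    standards <- rec[rec$record_type == "standard",
                     c("nominal_conc", "intensity_106")]
    blanks <- rec$intensity_106[rec$record_type == "blank"]
  }
  if (loq_k < lod_k) stop("loq_k must be >= lod_k so that LOD <= LOQ")
  nz <- unique(standards$nominal_conc[standards$nominal_conc > 0])
  if (length(nz) < 3) stop("need >= 3 distinct non-zero standards")
  fit <- stats::lm(intensity_106 ~ nominal_conc, data = standards)
  slope <- unname(stats::coef(fit)[["nominal_conc"]])
  if (!is.finite(slope) || slope <= 0)
    stop("calibration slope is not positive; check the standards")
  blank_sd <- if (length(blanks) > 1) stats::sd(blanks) else 0
  smry <- suppressWarnings(summary(fit))  # noiseless data fits perfectly
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[["(Intercept)"]]),
                 r_squared = smry$r.squared,
                 residual_sd = smry$sigma,
                 lod_ug_l = lod_k * blank_sd / slope,
                 loq_ug_l = loq_k * blank_sd / slope,
                 lod_k = lod_k, loq_k = loq_k),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("ICP-MS calibration: slope %.4g counts/(ug/L), intercept %.4g, R2 %.6f\n",
              x$slope, x$intercept, x$r_squared))
  cat(sprintf("  instrument LOD %.3g ug/L (%.3g ng/L), LOQ %.3g ug/L (%.3g ng/L)\n",
              x$lod_ug_l, 1000 * x$lod_ug_l, x$loq_ug_l, 1000 * x$loq_ug_l))
  invisible(x)
}

#' Quantify one sample with LOD/LOQ censoring
#'
#' Back-calculates the Pd mass of a digested sample:
#' `conc_measured = (intensity - intercept) / slope`;
#' `conc_digest = conc_measured * dilution_factor`;
#' `mass_ng = conc_digest [ug/L] * digest_volume [mL]`.
#' Sample LOD/LOQ (ng) are the instrument values (ug/L) multiplied by the
#' digest volume (mL). Censoring rule: masses below the sample LOD are
#' reported as below detection (`bdl`, value `NA`, never 0); masses between
#' the LOD and LOQ are set to the sample LOD; otherwise the value is
#' quantified.
#'
#' @param intensity Drift-corrected analyte intensity (counts).
#' @param curve A `calibration_curve`.
#' @param dilution_factor Multiply-back dilution factor (>= 1); the 13:3
#'   dilution of digests is 13/3.
#' @param digest_volume_ml Total digested sample volume (mL, > 0).
#' @return Object of class `measured_mass`: `value_ng` (NA when below
#'   detection), `status` (`"quantified"`, `"between_lod_loq_set_to_lod"`,
#'   `"below_detection"`), `sample_lod_ng`, `sample_loq_ng`, `conc_ug_l`.
#' @export
quantify_sample <- function(intensity, curve, dilution_factor = 13 / 3,
                            digest_volume_ml = 3) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (dilution_factor < 1) stop("dilution_factor must be >= 1")
  if (digest_volume_ml <= 0) stop("digest_volume_ml must be positive")
  conc <- (intensity - curve$intercept) / curve$slope
  mass_ng <- conc * dilution_factor * digest_volume_ml
  lod_ng <- curve$lod_ug_l * digest_volume_ml
  loq_ng <- curve$loq_ug_l * digest_volume_ml
  censor_mass(mass_ng, lod_ng, loq_ng, conc_ug_l = conc)
}

# Apply the censoring rule to a raw mass value.
censor_mass <- function(mass_ng, lod_ng, loq_ng, conc_ug_l = NA_real_) {
  if (!is.finite(mass_ng) || mass_ng < lod_ng) {
    status <- "below_detection"; value <- NA_real_
  } else if (mass_ng < loq_ng) {
    status <- "between_lod_loq_set_to_lod"; value <- lod_ng
  } else {
    status <- "quantified"; value <- mass_ng
  }
  structure(list(value_ng = value, status = status,
                 sample_lod_ng = lod_ng, sample_loq_ng = loq_ng,
                 conc_ug_l = conc_ug_l),
            class = "measured_mass")
}

#' @export
print.measured_mass <- function(x, ...) {
  shown <- if (x$status == "below_detection") "bdl"
  else sprintf("%.4g ng", x$value_ng)
  cat(sprintf("Pd mass: %s [%s; sample LOD %.3g ng, LOQ %.3g ng]\n",
              shown, x$status, x$sample_lod_ng, x$sample_loq_ng))
  invisible(x)
}

#' Numeric contribution of a censored mass to a sum
#'
#' Downstream accounting rule: below-detection contributes 0 (flagged),
#' between-LOD/LOQ contributes the LOD value, quantified contributes itself.
#'
#' @param x A `measured_mass`.
#' @return Single numeric (ng).
#' @export
measured_mass_value <- function(x) {
  stopifnot(inherits(x, "measured_mass"))
  if (x$status == "below_detection") 0 else x$value_ng
}

#' Quantify all samples of a batch
#'
#' @param batch An `icpms_batch` (drift-corrected or not; correction is
#'   applied if it has not been).
#' @param curve Optional pre-fitted `calibration_curve`; fitted from the
#'   batch when omitted.
#' @param ... Passed to [fit_calibration()].
#' @return Data frame with one row per sample: `id`, `mass_ng` (NA for bdl),
#'   `status`, `sample_lod_ng`, `sample_loq_ng`.
#' @export
#' @examples
#' b <- generate_icpms_batch(c(0.5, 2), seed = 4)
#' quantify_batch(b)
quantify_batch <- function(batch, curve = NULL, ...) {
  stopifnot(inherits(batch, "icpms_batch"))
  if (!isTRUE(batch$drift_corrected)) batch <- drift_correct(batch)
  if (is.null(curve)) curve <- fit_calibration(batch, ...)
  smp <- batch$records[batch$records$record_type == "sample", , drop = FALSE]
  res <- lapply(seq_len(nrow(smp)), function(i)
    quantify_sample(smp$intensity_106[i], curve,
                    dilution_factor = smp$dilution_factor[i],
                    digest_volume_ml = smp$digest_volume_mL[i]))
  data.frame(id = smp$id,
             mass_ng = vapply(res, function(r) r$value_ng, 0),
             status = vapply(res, function(r) r$status, ""),
             sample_lod_ng = vapply(res, function(r) r$sample_lod_ng, 0),
             sample_loq_ng = vapply(res, function(r) r$sample_loq_ng, 0))
}

#' Rescale a half-organ measurement to the whole organ
#'
#' Organs are cut in half before digestion; the measured mass corresponds to
#' the digested part only. Value and sample LOD/LOQ are multiplied by
#' `total_weight / partial_weight`; the censoring status is preserved.
#'
#' @param measured A `measured_mass`.
#' @param partial_weight Weight of the digested part (> 0).
#' @param total_weight Total organ weight (>= partial).
#' @return The rescaled `measured_mass`.
#' @export
scale_half_organ <- function(measured, partial_weight, total_weight) {
  stopifnot(inherits(measured, "measured_mass"))
  if (!(partial_weight > 0 && partial_weight <= total_weight))
    stop("need 0 < partial_weight <= total_weight")
  f <- total_weight / partial_weight
  if (!is.na(measured$value_ng)) measured$value_ng <- measured$value_ng * f
  measured$sample_lod_ng <- measured$sample_lod_ng * f
  measured$sample_loq_ng <- measured$sample_loq_ng * f
  measured
}
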