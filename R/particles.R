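# Particle batch and dose-regimen descriptions.

#' Describe a batch of metal-doped nanoplastic tracer particles
#'
#' A `particle_batch` records the physical properties of the Pd-doped
#' polystyrene tracer: core-shell particles of roughly 200 nm diameter with a
#' palladium loading of about 0.3 % by weight, administered as an aqueous
#' suspension.
#'
#' @param diameter_nm Particle diameter in nm (> 0).
#' @param polymer_density_g_cm3 Density of the polymer matrix in g/cm^3.
#' @param pd_mass_fraction Pd mass fraction of a particle (0 < f < 1; a
#'   fraction, not a percentage).
#' @param stock_concentration_ug_ml Pd concentration of the stock suspension
#'   in ug Pd/mL (>= 0).
#' @return Object of class `particle_batch`.
#' @export
#' @examples
#' particle_batch()
particle_batch <- function(diameter_nm = 200,
                           polymer_density_g_cm3 = 1.05,
                           pd_mass_fraction = 0.00295,
                           stock_concentration_ug_ml = 99.76) {
  stopifnot(diameter_nm > 0, polymer_density_g_cm3 > 0)
  if (!(pd_mass_fraction > 0 && pd_mass_fraction < 1))
    stop("pd_mass_fraction must lie strictly between 0 and 1")
  if (stock_concentration_ug_ml < 0)
    stop("stock_concentration_ug_ml must be >= 0")
  structure(list(diameter_nm = diameter_nm,
                 polymer_density_g_cm3 = polymer_density_g_cm3,
                 pd_mass_fraction = pd_mass_fraction,
                 stock_concentration_ug_ml = stock_concentration_ug_ml),
            class = "particle_batch")
}

#' @export
print.particle_batch <- function(x, ...) {
  cat(sprintf("Pd-NP batch: d = %g nm, rho = %g g/cm3, %.3g wt.%% Pd, stock %g ug Pd/mL\n",
              x$diameter_nm, x$polymer_density_g_cm3,
              100 * x$pd_mass_fraction, x$stock_concentration_ug_ml))
  invisible(x)
}

#' Define a gavage dosing regimen
#'
#' Encodes the oral dosing schedule of a study arm: the nanoplastic mass and
#' Pd mass per gavage and the gavage times. `dose_type` records whether the
#' percent-of-dose denominator is the single applied dose (acute arm) or the
#' daily dose (repeated arms); it is an explicit attribute, never inferred.
#'
#' @param daily_np_mass_mg NP mass per gavage (mg).
#' @param daily_pd_mass_ug Pd mass per gavage (ug).
#' @param schedule_h Strictly increasing gavage times (h from study start).
#' @param gavage_volume_ul Administered volume per gavage (uL).
#' @param pd_mass_fraction Pd mass fraction of the batch, used only to check
#'   self-consistency of the NP/Pd dose pair.
#' @param dose_type `"applied"` or `"daily"`.
#' @param tol Relative tolerance for the NP/Pd consistency check.
#' @return Object of class `dose_regimen`.
#' @export
#' @examples
#' # acute arm: single gavage of 100 uL stock
#' dose_regimen(3.3817, 9.976, schedule_h = 0)
dose_regimen <- function(daily_np_mass_mg, daily_pd_mass_ug,
                         schedule_h = 0, gavage_volume_ul = 100,
                         pd_mass_fraction = NULL,
                         dose_type = c("applied", "daily"),
                         tol = 0.02) {
  stopifnot(daily_np_mass_mg > 0, daily_pd_mass_ug > 0)
  if (is.unsorted(schedule_h, strictly = TRUE))
    stop("schedule_h must be strictly increasing")
  dose_type <- match.arg(dose_type)
  if (!is.null(pd_mass_fraction)) {
    implied <- pd_dose_from_np_mass(daily_np_mass_mg, pd_mass_fraction)
    if (abs(implied - daily_pd_mass_ug) / daily_pd_mass_ug > tol)
      stop(sprintf("Pd dose %.4g ug inconsistent with %.4g mg NPs at fraction %.4g (implies %.4g ug)",
                   daily_pd_mass_ug, daily_np_mass_mg, pd_mass_fraction, implied))
  }
  structure(list(daily_np_mass_mg = daily_np_mass_mg,
                 daily_pd_mass_ug = daily_pd_mass_ug,
                 schedule_h = as.numeric(schedule_h),
                 gavage_volume_ul = gavage_volume_ul,
                 dose_type = dose_type),
            class = "dose_regimen")
}

#' @export
print.dose_regimen <- function(x, ...) {
  cat(sprintf("Dose regimen (%s dose): %g mg NPs / %g ug Pd per gavage, %d gavage(s)\n",
              x$dose_type, x$daily_np_mass_mg, x$daily_pd_mass_ug,
              length(x$schedule_h)))
  invisible(x)
}

#' Pd dose implied by a nanoplastic mass
#'
#' @param np_mass_mg NP mass (mg, > 0).
#' @param pd_fraction Pd mass fraction (dimensionless, > 0).
#' @return Pd mass in ug.
#' @export
#' @examples
#' pd_dose_from_np_mass(1, 0.003)  # 3 ug Pd
pd_dose_from_np_mass <- function(np_mass_mg, pd_fraction) {
  stopifnot(all(np_mass_mg > 0), all(pd_fraction > 0))
  np_mass_mg * 1000 * pd_fraction
}

#' Particle number implied by a nanoplastic mass
#'
#' Converts a bulk NP mass to a particle count assuming monodisperse spheres:
#' `count = mass / (density * (pi/6) * d^3)`.
#'
#' @param np_mass_mg NP mass (mg, > 0).
#' @param diameter_nm Particle diameter (nm, > 0).
#' @param density_g_cm3 Particle density (g/cm^3, > 0).
#' @return Particle count (numeric, generally very large).
#' @export
#' @examples
#' np_count_from_mass(3.3817, 200, 1.05)
np_count_from_mass <- function(np_mass_mg, diameter_nm = 200,
                               density_g_cm3 = 1.05) {
  stopifnot(all(np_mass_mg > 0), diameter_nm > 0, density_g_cm3 > 0)
  d_cm <- diameter_nm * 1e-7
  particle_mass_g <- density_g_cm3 * (pi / 6) * d_cm^3
  (np_mass_mg * 1e-3) / particle_mass_g
}
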