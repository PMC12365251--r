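# Virtual XFI instrument: forward model and scan generator.
#
# Expected net counts in line L for a pixel holding m ug Pd:
#   counts_L = (flux / beam_area) * dwell * m * atoms_per_ug * sigma_L
#             * (Omega / 4 pi) * efficiency
# with sigma_L the effective fluorescence-production cross section of the
# line at the excitation energy. Photon counting is Poisson; a flat continuum
# background (counts/bin/s) is added per bin.

#' XFI beam configuration
#'
#' @param flux_ph_s Photons per second delivered in the beam footprint.
#' @param energy_kev Monochromatic excitation energy (keV).
#' @param area_mm2 Beam footprint area (mm^2); pixel size equals beam size.
#' @return Object of class `xfi_beam`.
#' @export
xfi_beam <- function(flux_ph_s = 1e10, energy_kev = 53, area_mm2 = 1) {
  stopifnot(flux_ph_s > 0, energy_kev > 0, area_mm2 > 0)
  structure(list(flux_ph_s = flux_ph_s, energy_kev = energy_kev,
                 area_mm2 = area_mm2), class = "xfi_beam")
}

#' XFI detector configuration
#'
#' Defaults describe an array of 10 silicon drift detectors of 50 mm^2
#' collimated area each at 6 cm from the sample. The resolution model is
#' `FWHM(E) = sqrt(fwhm_electronic^2 + 2.355^2 * fano * pair_energy * E)`;
#' default parameters give ~180 eV FWHM at 21 keV.
#'
#' @param n_detectors Number of detector elements.
#' @param area_cm2 Collimated area per element (cm^2).
#' @param distance_cm Sample-detector distance (cm).
#' @param efficiency Photopeak detection efficiency at the Pd K lines (0-1].
#' @param fwhm_electronic_kev Electronic noise contribution to FWHM (keV).
#' @param fano Effective Fano factor.
#' @param pair_energy_kev Mean energy per charge pair (keV).
#' @return Object of class `xfi_detector`.
#' @export
xfi_detector <- function(n_detectors = 10, area_cm2 = 0.5, distance_cm = 6,
                         efficiency = 0.9, fwhm_electronic_kev = 0.05,
                         fano = 0.07, pair_energy_kev = 0.00365) {
  stopifnot(n_detectors >= 1, area_cm2 > 0, distance_cm > 0,
            efficiency > 0, efficiency <= 1)
  structure(list(n_detectors = n_detectors, area_cm2 = area_cm2,
                 distance_cm = distance_cm, efficiency = efficiency,
                 fwhm_electronic_kev = fwhm_electronic_kev, fano = fano,
                 pair_energy_kev = pair_energy_kev), class = "xfi_detector")
}

#' Total solid-angle fraction of the detector array
#'
#' Exact on-axis solid angle of each circular collimated aperture,
#' `Omega = 2 pi (1 - d / sqrt(d^2 + r^2))`, summed over elements and
#' divided by 4 pi.
#'
#' @param detector An [xfi_detector()].
#' @return Dimensionless fraction Omega / 4 pi.
#' @export
#' @examples
#' solid_angle_fraction(xfi_detector())  # ~ 10 * 0.5 / (4 * pi * 36)
solid_angle_fraction <- function(detector) {
  r <- sqrt(detector$area_cm2 / pi)
  d <- detector$distance_cm
  omega <- 2 * pi * (1 - d / sqrt(d^2 + r^2))
  detector$n_detectors * omega / (4 * pi)
}

# Energy resolution (Gaussian sigma, keV) at line energy E.
detector_sigma_kev <- function(detector, energy_kev) {
  fwhm <- sqrt(detector$fwhm_electronic_kev^2 +
                 2.355^2 * detector$fano * detector$pair_energy_kev * energy_kev)
  fwhm / 2.355
}

#' Expected net line counts for a pixel mass
#'
#' Noise-free forward model: counts per fitted line for `mass_ug` of Pd in
#' the beam footprint. Exactly linear in mass, flux and dwell time.
#'
#' @param mass_ug Pd mass in the beam footprint (ug).
#' @param beam An [xfi_beam()].
#' @param detector An [xfi_detector()].
#' @param dwell_s Dwell time (s).
#' @return Named vector of expected counts, `kalpha` and `kbeta`.
#' @export
xfi_expected_counts <- function(mass_ug, beam, detector, dwell_s = 1) {
  stopifnot(all(mass_ug >= 0), dwell_s > 0)
  flux_density <- beam$flux_ph_s / (beam$area_mm2 / 100)  # ph / cm^2 / s
  base <- flux_density * dwell_s * mass_ug * pd_atoms_per_ug() *
    solid_angle_fraction(detector) * detector$efficiency
  c(kalpha = base * .pd_const$sigma_f_kalpha_cm2,
    kbeta = base * .pd_const$sigma_f_kbeta_cm2)
}

# Expected counts per bin for one pixel spectrum (lines + flat background).
xfi_expected_spectrum <- function(mass_ug, energy_kev, beam, detector,
                                  dwell_s, background_rate) {
  net <- xfi_expected_counts(mass_ug, beam, detector, dwell_s)
  lines <- pd_line_energies()
  sigma <- detector_sigma_kev(detector, lines[["kalpha"]])
  dE <- energy_kev[2] - energy_kev[1]
  mu <- net[["kalpha"]] * stats::dnorm(energy_kev, lines[["kalpha"]], sigma) * dE +
    net[["kbeta"]] * stats::dnorm(energy_kev, lines[["kbeta"]], sigma) * dE +
    background_rate * dwell_s
  mu
}

#' Construct an XFI spectrum object
#'
#' @param energy_kev Strictly increasing uniform energy grid (keV).
#' @param counts Non-negative counts per bin.
#' @param dwell_s Dwell time (s).
#' @return Object of class `xfi_spectrum`.
#' @export
xfi_spectrum <- function(energy_kev, counts, dwell_s = 1) {
  stopifnot(length(energy_kev) == length(counts), dwell_s > 0)
  if (is.unsorted(energy_kev, strictly = TRUE))
    stop("energy bins must be strictly increasing")
  if (any(counts < 0)) stop("counts must be non-negative")
  structure(list(energy_kev = energy_kev, counts = counts, dwell_s = dwell_s),
            class = "xfi_spectrum")
}

#' Generate a virtual XFI scan from a ground-truth mass map
#'
#' Produces a grid of per-pixel spectra: Gaussian Pd K-alpha/K-beta lines on a
#' flat continuum background, with Poisson photon counting (or the noise-free
#' expectation when `poisson = FALSE`). Reference-target spectra with known
#' Pd mass in the beam are appended for flux calibration.
#'
#' @param truth_map Numeric matrix of per-pixel Pd masses (ug, >= 0); rows are
#'   scan rows (row-major, 0-based pixel coordinates).
#' @param beam An [xfi_beam()].
#' @param detector An [xfi_detector()].
#' @param background_rate Continuum background (counts/bin/s).
#' @param dwell_s Per-pixel dwell time (s, > 0).
#' @param energy_kev Energy grid (keV) covering the Pd K lines.
#' @param references Data frame of reference targets with columns
#'   `areal_mass_ug_cm2` and `dwell_s`; Pd-equivalent targets only.
#' @param seed Integer RNG seed.
#' @param poisson Draw Poisson counts (`TRUE`) or return the continuous
#'   noise-free expectation (`FALSE`).
#' @return Object of class `xfi_scan`: `spectra` (list-matrix indexed
#'   `[[row]][[col]]`), `energy_kev`, `dwell_s`, `beam`, `detector`,
#'   `background_rate`, `truth_map`, `references` (table + spectra).
#' @export
#' @examples
#' scan <- generate_xfi_scan(matrix(c(0, 0.05, 0.1, 0), 2, 2), seed = 7)
generate_xfi_scan <- function(truth_map,
                              beam = xfi_beam(),
                              detector = xfi_detector(),
                              background_rate = 5,
                              dwell_s = 1,
                              energy_kev = seq(18, 26.5, by = 0.02),
                              references = data.frame(
                                areal_mass_ug_cm2 = c(5, 10), dwell_s = 10),
                              seed = 1L,
                              poisson = TRUE) {
  truth_map <- as.matrix(truth_map)
  if (any(truth_map < 0)) stop("truth_map must be non-negative")
  if (dwell_s <= 0) stop("dwell_s must be positive")
  if (background_rate < 0) stop("background_rate must be non-negative")
  set.seed(derive_seed(seed, "xfi"))
  draw <- function(mu) if (poisson) stats::rpois(length(mu), mu) else mu
  spectra <- vector("list", nrow(truth_map))
  for (i in seq_len(nrow(truth_map))) {
    spectra[[i]] <- vector("list", ncol(truth_map))
    for (j in seq_len(ncol(truth_map))) {
      mu <- xfi_expected_spectrum(truth_map[i, j], energy_kev, beam, detector,
                                  dwell_s, background_rate)
      spectra[[i]][[j]] <- xfi_spectrum(energy_kev, draw(mu), dwell_s)
    }
  }
  ref_spectra <- list()
  if (nrow(references) > 0) {
    if (is.null(references$dwell_s)) references$dwell_s <- dwell_s
    references$mass_in_beam_ug <-
      references$areal_mass_ug_cm2 * (beam$area_mm2 / 100)
    for (k in seq_len(nrow(references))) {
      mu <- xfi_expected_spectrum(references$mass_in_beam_ug[k], energy_kev,
                                  beam, detector, references$dwell_s[k],
                                  background_rate)
      ref_spectra[[k]] <- xfi_spectrum(energy_kev, draw(mu),
                                       references$dwell_s[k])
    }
  }
  structure(list(spectra = spectra, energy_kev = energy_kev,
                 dwell_s = dwell_s, beam = beam, detector = detector,
                 background_rate = background_rate, truth_map = truth_map,
                 references = list(table = references, spectra = ref_spectra),
                 seed = as.integer(seed)),
            class = "xfi_scan")
}

#' @export
print.xfi_scan <- function(x, ...) {
  cat(sprintf("XFI scan: %d x %d pixels, %d bins (%.2f-%.2f keV), dwell %g s, %d reference target(s)\n",
              nrow(x$truth_map), ncol(x$truth_map), length(x$energy_kev),
              min(x$energy_kev), max(x$energy_kev), x$dwell_s,
              nrow(x$references$table)))
  invisible(x)
}
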