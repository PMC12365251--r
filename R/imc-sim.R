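# Virtual IMC region-of-interest and titration-series generators.

#' Generate a virtual IMC region of interest
#'
#' Emulates laser-ablation imaging mass cytometry at 1 um/pixel. Every pixel
#' of every Pd isotope channel draws uniform detector noise in
#' `[0, noise_max]` dual counts; at particle sites an integer ion count drawn
#' as `Poisson(n_particles * ions_per_particle)` is split across the isotope
#' channels by the natural Pd abundances and added on top.
#'
#' @param width,height Grid size in pixels (1 um each).
#' @param particle_pixels Data frame with columns `x`, `y` (0-based pixel
#'   coordinates inside the grid) and `n_particles`.
#' @param ions_per_particle Mean detected ions per particle (> 0); the
#'   default 1 encodes the empirical one-ion-per-particle sensitivity.
#' @param noise_max Upper edge of the uniform per-channel noise band in dual
#'   counts (0 <= noise_max <= 1).
#' @param seed Integer RNG seed; outputs are bit-identical for equal seeds.
#' @param roi_id,tissue Labels carried through to outputs.
#' @return Object of class `imc_roi`: named list `channels` of
#'   `height x width` matrices (names `Pd102` ... `Pd110`), `width`,
#'   `height`, `roi_id`, `tissue`, `truth` (the particle table).
#' @export
#' @examples
#' roi <- generate_imc_roi(8, 8, data.frame(x = 3, y = 4, n_particles = 2),
#'                         seed = 5)
generate_imc_roi <- function(width, height,
                             particle_pixels = data.frame(x = integer(),
                                                          y = integer(),
                                                          n_particles = integer()),
                             ions_per_particle = 1, noise_max = 1,
                             seed = 1L, roi_id = "roi1", tissue = "tissue") {
  stopifnot(width >= 1, height >= 1)
  if (ions_per_particle <= 0) stop("ions_per_particle must be positive")
  if (noise_max < 0 || noise_max > 1) stop("noise_max must lie in [0, 1]")
  pp <- as.data.frame(particle_pixels)
  if (nrow(pp) > 0 &&
      (any(pp$x < 0) || any(pp$x >= width) || any(pp$y < 0) ||
       any(pp$y >= height)))
    stop("particle coordinates must lie inside the grid (0-based)")
  set.seed(derive_seed(seed, "imc"))
  ab <- pd_isotope_abundances()
  channels <- lapply(ab, function(a)
    matrix(stats::runif(width * height, 0, noise_max), nrow = height))
  names(channels) <- names(ab)
  for (k in seq_len(nrow(pp))) {
    n_ions <- stats::rpois(1, pp$n_particles[k] * ions_per_particle)
    if (n_ions > 0) {
      split <- stats::rmultinom(1, n_ions, ab)[, 1]
      for (ch in names(ab)) {
        channels[[ch]][pp$y[k] + 1, pp$x[k] + 1] <-
          channels[[ch]][pp$y[k] + 1, pp$x[k] + 1] + split[[ch]]
      }
    }
  }
  structure(list(channels = channels, width = width, height = height,
                 roi_id = roi_id, tissue = tissue, truth = pp,
                 seed = as.integer(seed)),
            class = "imc_roi")
}

#' @export
print.imc_roi <- function(x, ...) {
  cat(sprintf("IMC ROI %s (%s): %d x %d px, channels %s\n", x$roi_id,
              x$tissue, x$width, x$height,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Generate a two-fold titration series
#'
#' Serial 1:1 dilution series spotted at a fixed volume: spot 1 holds
#' `start_conc * spot_volume` ng Pd and every subsequent spot halves the
#' prior mass. The cumulative dilution factor of spot k is `2^(k-1)` relative
#' to spot 1; relative to the pre-dilution suspension it is `2^k` under the
#' default convention (`spot1_is_first_dilution = TRUE`, matching a reported
#' 40-step factor of ~1.1e12) or `2^(k-1)` otherwise. Factors are computed in
#' exact integer arithmetic up to 2^53.
#'
#' @param start_conc_ng_ul Concentration of the spotted suspension (ng/uL).
#' @param n_dilutions Number of two-fold dilution steps after spot 1 (>= 0);
#'   the series has `n_dilutions + 1` spots.
#' @param spot_volume_ul Volume per spot (uL).
#' @param spot1_is_first_dilution Convention flag for the factor relative to
#'   the pre-dilution suspension (see above).
#' @return Object of class `titration_series`: data frame `spots` with
#'   columns `index`, `pd_mass_ng`, `factor_vs_spot1`, `factor_vs_stock`,
#'   plus the inputs.
#' @export
#' @examples
#' s <- generate_titration_series(91, 39, 0.2)
#' s$spots$pd_mass_ng[1]           # 18.2 ng in spot 1
#' s$spots$factor_vs_stock[40]     # 2^40 ~ 1.1e12
generate_titration_series <- function(start_conc_ng_ul = 91,
                                      n_dilutions = 39,
                                      spot_volume_ul = 0.2,
                                      spot1_is_first_dilution = TRUE) {
  if (start_conc_ng_ul <= 0) stop("start_conc_ng_ul must be positive")
  if (n_dilutions < 0) stop("n_dilutions must be >= 0")
  k <- seq_len(n_dilutions + 1)
  mass1 <- start_conc_ng_ul * spot_volume_ul
  spots <- data.frame(
    index = k,
    pd_mass_ng = mass1 / 2^(k - 1),
    factor_vs_spot1 = 2^(k - 1),
    factor_vs_stock = if (spot1_is_first_dilution) 2^k else 2^(k - 1))
  structure(list(spots = spots, start_conc_ng_ul = start_conc_ng_ul,
                 spot_volume_ul = spot_volume_ul,
                 spot1_is_first_dilution = spot1_is_first_dilution),
            class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  n <- nrow(x$spots)
  cat(sprintf("Titration series: %d spots, %.3g ng (spot 1) to %.3g ng (spot %d)\n",
              n, x$spots$pd_mass_ng[1], x$spots$pd_mass_ng[n], n))
  invisible(x)
}
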