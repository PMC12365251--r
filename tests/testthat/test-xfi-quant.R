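test_that("peak fitting recovers known line areas", {
  # all-zero spectrum
  fit0 <- fit_pd_peak(synthetic_spectrum(0, 0, background = 0))
  expect_true(fit0$converged)
  expect_equal(unname(fit0$net_counts), c(0, 0))

  # Poisson spectrum, K-alpha area 1000 on flat background 5 counts/bin:
  # oracle is direct summation of (counts - injected background)
  sp <- synthetic_spectrum(1000, 0, background = 5, poisson = TRUE, seed = 42)
  fit <- fit_pd_peak(sp)
  expect_true(fit$converged)
  expect_lt(abs(fit$net_counts[["kalpha"]] - 1000), 3 * fit$sigma[["kalpha"]])
  sel <- sp$energy_kev >= 19.5 & sp$energy_kev <= 25.5
  oracle <- sum(sp$counts[sel] - 5)
  expect_lt(abs(sum(fit$net_counts) - oracle), 4 * sqrt(sum(sp$counts[sel])))

  # noise-free 5:1 line ratio is recovered
  fit51 <- fit_pd_peak(synthetic_spectrum(5000, 1000, background = 2))
  ratio <- fit51$net_counts[["kalpha"]] / fit51$net_counts[["kbeta"]]
  expect_lt(abs(ratio - 5) / 5, 0.1)
})

test_that("peak fitting rejects unusable windows", {
  sp <- synthetic_spectrum(100, 20, background = 1)
  expect_error(fit_pd_peak(sp, window = c(22, 25)), "centroid")
  coarse <- xfi_spectrum(seq(19, 26, by = 1), rep(0, 8))
  expect_error(fit_pd_peak(coarse), "few bins")
})

test_that("flux calibration is the counts-per-mass-dwell constant", {
  one <- calibrate_flux(data.frame(mass_in_beam_ug = 0.05, net_counts = 5000,
                                   dwell_s = 1))
  expect_equal(one$k_counts_per_ug_s, 1e5)
  two <- calibrate_flux(data.frame(mass_in_beam_ug = c(0.05, 0.1),
                                   net_counts = c(5000, 10000),
                                   dwell_s = 1))
  expect_equal(two$k_counts_per_ug_s, 1e5)
  expect_error(calibrate_flux(data.frame(mass_in_beam_ug = 0,
                                         net_counts = 10, dwell_s = 1)),
               "positive")

  # Monte-Carlo bias of the weighted estimator under Poisson counting
  set.seed(11)
  k_true <- 1e5
  est <- replicate(200, {
    m <- c(0.05, 0.1); t <- c(2, 1)
    counts <- rpois(2, k_true * m * t)
    calibrate_flux(data.frame(mass_in_beam_ug = m, net_counts = counts,
                              dwell_s = t))$k_counts_per_ug_s
  })
  expect_lt(abs(mean(est) - k_true) / k_true, 0.01)
})

test_that("pixel reconstruction inverts the forward model", {
  cal <- calibrate_flux(data.frame(mass_in_beam_ug = 1, net_counts = 1e5,
                                   dwell_s = 1))
  fit0 <- fit_pd_peak(synthetic_spectrum(0, 0, background = 0))
  expect_equal(reconstruct_pixel_mass(fit0, cal, 1)$mass_ug, 0)

  fit <- fit_pd_peak(synthetic_spectrum(5000, 1500, background = 3))
  m1 <- reconstruct_pixel_mass(fit, cal, 1)$mass_ug
  m2 <- reconstruct_pixel_mass(fit, cal, 2)$mass_ug
  expect_equal(m2, m1 / 2)

  # noise-free generate -> fit -> reconstruct round trip
  tm <- matrix(c(0.02, 0.05, 0.085, 0.04), 2, 2)
  scan <- generate_xfi_scan(tm, poisson = FALSE, seed = 1)
  calib <- calibrate_flux(xfi_scan_references(scan), scan$beam$area_mm2)
  map <- build_mass_map(scan, calib)
  expect_lt(max(abs(map$mass_ug - tm) / tm), 1e-3)
})

test_that("mass maps are calibration-invariant and additive", {
  tm <- matrix(c(0.03, 0.06, 0.09, 0.12), 2, 2)
  # multiplying the flux by c and recalibrating leaves masses unchanged
  for (flux in c(1e10, 3e10)) {
    scan <- generate_xfi_scan(tm, beam = xfi_beam(flux_ph_s = flux),
                              poisson = FALSE)
    calib <- calibrate_flux(xfi_scan_references(scan), scan$beam$area_mm2)
    map <- build_mass_map(scan, calib)
    expect_equal(map$mass_ug, tm, tolerance = 1e-10)
  }
  # totals are additive over disjoint regions
  region <- map$mass_ug[1, ]; complement <- map$mass_ug[2, ]
  expect_equal(sum(region) + sum(complement), map$total_ug)
})

test_that("Poisson-noise map totals cover the truth", {
  tm <- matrix(c(0.04, 0.08, 0.06, 0.1), 2, 2)
  hits <- 0L
  for (s in 1:100) {
    scan <- generate_xfi_scan(tm, seed = s)
    calib <- calibrate_flux(xfi_scan_references(scan), scan$beam$area_mm2)
    map <- build_mass_map(scan, calib)
    sigma_tot <- sqrt(sum(map$sigma_ug^2))
    if (abs(map$total_ug - sum(tm)) <= 3 * sigma_tot) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("attenuation bias follows Beer-Lambert on the packaged table", {
  expect_equal(estimate_attenuation_bias(21.1, 0), 0)
  # 2 mm of water: closed-form oracle with independently interpolated
  # mu/rho(21.1 keV) = 0.73152 cm^2/g (log-log between the 20 and 30 keV rows)
  expect_equal(estimate_attenuation_bias(21.1, 0.2), 1 - exp(-0.73152 * 0.2),
               tolerance = 1e-4)
  # monotone in path length, bounded in (0, 1)
  losses <- vapply(c(0.1, 0.2, 0.3, 0.5, 1), function(L)
    estimate_attenuation_bias(21.1, L), 0)
  expect_true(all(diff(losses) > 0))
  expect_true(all(losses > 0 & losses < 1))
  expect_error(estimate_attenuation_bias(5, 0.1), "outside")
  expect_error(estimate_attenuation_bias(70, 0.1), "outside")

  # uniform-slab correction divides by the transmitted fraction
  tm <- matrix(0.05, 1, 1)
  scan <- generate_xfi_scan(tm, poisson = FALSE)
  map <- build_mass_map(scan, calibrate_flux(xfi_scan_references(scan), 1))
  corr <- apply_attenuation_correction(map, 0.3)
  expect_equal(corr$total_ug,
               map$total_ug / (1 - estimate_attenuation_bias(21.12, 0.3)))
})

test_that("detection limit follows the 3-sigma background criterion", {
  cal <- calibrate_flux(data.frame(mass_in_beam_ug = 1, net_counts = 100,
                                   dwell_s = 1))
  cal$k_counts_per_ug_s <- 100  # fixed K for the arithmetic check
  expect_equal(xfi_detection_limit(0, cal, 1), 0)
  expect_equal(xfi_detection_limit(900, cal, 1), 0.9)
  # with background = rate * dwell, LOD scales as 1/sqrt(dwell)
  rate <- 100
  lod1 <- xfi_detection_limit(rate * 1, cal, 1)
  lod4 <- xfi_detection_limit(rate * 4, cal, 4)
  expect_equal(lod4, lod1 / 2)
})
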