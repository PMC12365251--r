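test_that("ROI generation respects the noise band and the grid", {
  roi <- generate_imc_roi(20, 20, noise_max = 1, seed = 1)
  for (ch in names(roi$channels))
    expect_true(all(roi$channels[[ch]] <= 1 & roi$channels[[ch]] >= 0))
  # all-noise ROI has zero positives at the default ceiling
  expect_equal(nrow(threshold_pixels(roi, "Pd108", 1)$positives), 0)

  a <- generate_imc_roi(5, 5, data.frame(x = 2, y = 3, n_particles = 4),
                        seed = 9)
  b <- generate_imc_roi(5, 5, data.frame(x = 2, y = 3, n_particles = 4),
                        seed = 9)
  expect_identical(a$channels, b$channels)
  expect_error(generate_imc_roi(5, 5, data.frame(x = 5, y = 0,
                                                 n_particles = 1)),
               "inside the grid")
  expect_error(generate_imc_roi(5, 5, noise_max = 2), "noise_max")
})

test_that("isotope split places Pd106 and Pd108 on top", {
  ranked_first_two <- replicate(100, {
    roi <- generate_imc_roi(3, 3, data.frame(x = 1, y = 1, n_particles = 200),
                            noise_max = 0, seed = sample.int(1e6, 1))
    totals <- attr(combine_isotope_channels(
      roi, c("Pd104", "Pd106", "Pd108", "Pd110")), "channel_totals")
    names(totals)[1:2]
  })
  expect_true(all(apply(ranked_first_two, 2, function(x)
    setequal(x, c("Pd106", "Pd108")))))
})

test_that("thresholding counts strictly-above pixels and is monotone", {
  m <- matrix(c(0.3, 0.9, 1.4, 2.0), 2, 2)
  expect_equal(nrow(threshold_pixels(m, noise_ceiling = 1.0)$positives), 2)
  expect_equal(threshold_pixels(m, noise_ceiling = 1.5)$positives$dual_counts,
               2.0)
  roi <- generate_imc_roi(10, 10, data.frame(x = 0:4, y = 0:4,
                                             n_particles = 1:5), seed = 4)
  n_pos <- vapply(c(0, 0.5, 1, 1.5, 2), function(ceil)
    nrow(threshold_pixels(roi, "Pd106", ceil)$positives), 0L)
  expect_true(all(diff(n_pos) <= 0))
  expect_error(threshold_pixels(roi, "Pd199"), "not present")
})

test_that("particle estimates follow the one-ion-one-count rule", {
  expect_equal(estimate_particles_per_pixel(1, 1), 1L, ignore_attr = TRUE)
  expect_equal(estimate_particles_per_pixel(6, 1), 6L, ignore_attr = TRUE)
  expect_equal(estimate_particles_per_pixel(0, 1), 0L, ignore_attr = TRUE)
  # any positive dual count is at least one particle
  expect_equal(estimate_particles_per_pixel(0.4, 1), 1L, ignore_attr = TRUE)
  # non-decreasing in dual counts
  est <- estimate_particles_per_pixel(seq(0, 10, 0.5), 1)
  expect_true(all(diff(est) >= 0))
  expect_true(attr(estimate_particles_per_pixel(35, 1),
                   "above_ion_counting_range"))
  expect_error(estimate_particles_per_pixel(1, 0), "positive")
})

test_that("pixel packing bound is the linear diameter count", {
  expect_equal(max_particles_per_pixel(1000, 200), 5L, ignore_attr = TRUE)
  expect_equal(max_particles_per_pixel(1000, 250), 4L, ignore_attr = TRUE)
  small <- max_particles_per_pixel(150, 200)
  expect_equal(as.integer(small), 0L)
  expect_match(attr(small, "advisory"), "exceeds")
})

test_that("channel combination conserves dual counts", {
  roi <- generate_imc_roi(6, 6, data.frame(x = c(1, 4), y = c(2, 5),
                                           n_particles = c(3, 7)), seed = 2)
  one <- combine_isotope_channels(roi, "Pd108")
  expect_equal(unclass(one), roi$channels$Pd108, ignore_attr = TRUE)
  all6 <- combine_isotope_channels(roi)
  expect_equal(sum(all6), sum(attr(all6, "channel_totals")))
  expect_equal(sum(all6), sum(vapply(roi$channels, sum, 0)))
})

test_that("titration series halves masses and tracks exact factors", {
  s <- generate_titration_series(91, 39, 0.2)
  expect_equal(s$spots$pd_mass_ng[1], 18.2)
  expect_equal(nrow(s$spots), 40)
  # strictly decreasing geometric with ratio 1/2
  expect_equal(s$spots$pd_mass_ng[-1] / s$spots$pd_mass_ng[-40],
               rep(0.5, 39))
  # factors exact in integer arithmetic; both indexing conventions
  expect_identical(s$spots$factor_vs_stock[40], 2^40)
  expect_gte(s$spots$factor_vs_stock[40], 1.09e12)
  alt <- generate_titration_series(91, 39, 0.2,
                                   spot1_is_first_dilution = FALSE)
  expect_identical(alt$spots$factor_vs_stock[40], 2^39)
  single <- generate_titration_series(91, 0, 0.2)
  expect_equal(nrow(single$spots), 1)
  expect_equal(single$spots$factor_vs_spot1, 1)
})

test_that("titration analysis reports the last detected spot as the LOD", {
  s <- generate_titration_series(91, 11, 0.2)  # 12 spots
  summaries <- lapply(1:12, function(i) {
    n <- if (i <= 10) 3 else 0  # particles only down to spot 10
    roi <- generate_imc_roi(8, 8,
                            if (n > 0) data.frame(x = 1:n, y = 1:n,
                                                  n_particles = 40)
                            else data.frame(x = integer(), y = integer(),
                                            n_particles = integer()),
                            seed = 100 + i)
    threshold_pixels(roi, "Pd106", 1)
  })
  rep10 <- analyze_titration(s, summaries)
  expect_true(rep10$lod_defined)
  expect_equal(rep10$lod_spot_index, 10)
  expect_equal(rep10$lod_mass_ng, s$spots$pd_mass_ng[10])

  empties <- lapply(1:12, function(i)
    threshold_pixels(generate_imc_roi(4, 4, seed = i), "Pd106", 1))
  rep0 <- analyze_titration(s, empties)
  expect_false(rep0$lod_defined)
  expect_true(is.na(rep0$lod_mass_ng))
  expect_error(analyze_titration(s, empties[1:3]), "misaligned")
})
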