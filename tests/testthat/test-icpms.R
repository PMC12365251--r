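test_that("the virtual run reproduces its construction rules", {
  b <- generate_icpms_batch(c(1, 5), blank_sd = 0, drift = 0, seed = 1)
  smp <- subset(b$records, record_type == "sample")
  expect_equal(smp$intensity_106, 2e4 * c(1, 5) + 50)

  b10 <- generate_icpms_batch(1, drift = 0.10, blank_sd = 0, seed = 1)
  is <- b10$records$intensity_IS
  expect_equal(is[length(is)] / is[1], 0.9)
})

test_that("internal-standard correction removes multiplicative drift", {
  b <- generate_icpms_batch(2, drift = 0, blank_sd = 0, seed = 1)
  expect_equal(drift_correct(b)$records$intensity_106,
               b$records$intensity_106)

  # halving one record's internal standard doubles its analyte intensity
  b2 <- b
  i <- which(b2$records$record_type == "sample")[1]
  b2$records$intensity_IS[i] <- b2$records$intensity_IS[i] / 2
  corrected <- drift_correct(b2)
  expect_equal(corrected$records$intensity_106[i],
               2 * b$records$intensity_106[i])

  # zero internal standard rejects the record with a diagnostic
  b3 <- b
  b3$records$intensity_IS[i] <- 0
  out <- drift_correct(b3)
  expect_equal(nrow(out$records), nrow(b$records) - 1)
  expect_match(attr(out, "diagnostics"), "rejected")

  # injected 10 % linear drift: corrected recovery is unbiased
  errs <- vapply(1:200, function(s) {
    bb <- generate_icpms_batch(5, drift = 0.10, blank_sd = 10, seed = s)
    quantify_batch(bb)$mass_ng / (5 * (13 / 3) * 3) - 1
  }, 0)
  expect_lt(abs(mean(errs)), 3 * sd(errs) / sqrt(length(errs)) + 0.002)
})

test_that("calibration matches the closed-form least-squares solution", {
  std <- data.frame(nominal_conc = icpms_calibration_grid())
  std$intensity_106 <- 100 * std$nominal_conc + 2
  cal <- fit_calibration(standards = std, blanks = rep(2, 4))
  expect_equal(cal$slope, 100)
  expect_equal(cal$intercept, 2)
  expect_equal(cal$r_squared, 1)
  expect_equal(cal$lod_ug_l, 0)  # blank sd 0
  expect_equal(cal$loq_ug_l, 0)

  set.seed(3)
  std$intensity_106 <- 100 * std$nominal_conc + 2 + rnorm(nrow(std), 0, 5)
  cal <- fit_calibration(standards = std, blanks = rnorm(5, 2, 3))
  # normal-equations oracle
  x <- std$nominal_conc; y <- std$intensity_106
  slope_hat <- (sum(x * y) - sum(x) * sum(y) / length(x)) /
    (sum(x^2) - sum(x)^2 / length(x))
  intercept_hat <- mean(y) - slope_hat * mean(x)
  expect_equal(cal$slope, slope_hat, tolerance = 1e-10)
  expect_equal(cal$intercept, intercept_hat, tolerance = 1e-10)
  expect_lte(cal$lod_ug_l, cal$loq_ug_l)
  expect_error(fit_calibration(standards = std[1:2, ], blanks = 1:3),
               "3 distinct")
  expect_error(fit_calibration(standards = std, blanks = 1:3, lod_k = 5,
                               loq_k = 3), "loq_k")
})

test_that("sample quantification applies dilution, volume and censoring", {
  curve <- manual_curve(slope = 1000, intercept = 0,
                        lod_ug_l = 0.043, loq_ug_l = 0.056)
  # 1.0 ug/L measured, 13:3 dilution, 3 mL digest -> 13.0 ng
  m <- quantify_sample(1000, curve, dilution_factor = 13 / 3,
                       digest_volume_ml = 3)
  expect_equal(m$value_ng, 13.0)
  expect_equal(m$status, "quantified")
  expect_equal(m$sample_lod_ng, 0.129)
  expect_equal(m$sample_loq_ng, 0.168)

  # intensity at the intercept -> concentration 0 -> below detection, NA not 0
  m0 <- quantify_sample(0, curve, digest_volume_ml = 3)
  expect_equal(m0$status, "below_detection")
  expect_true(is.na(m0$value_ng))
  expect_equal(measured_mass_value(m0), 0)
  expect_output(print(m0), "bdl")

  # a mass between the sample LOD and LOQ is set to the LOD value
  int_between <- 0.15 / ((13 / 3) * 3) * 1000
  mb <- quantify_sample(int_between, curve, digest_volume_ml = 3)
  expect_equal(mb$status, "between_lod_loq_set_to_lod")
  expect_equal(mb$value_ng, 0.129)
})

test_that("censoring is idempotent and order-preserving", {
  lod <- 0.129; loq <- 0.168
  masses <- c(-0.1, 0, 0.05, 0.129, 0.15, 0.168, 0.2, 13)
  first <- lapply(masses, pdnptrace:::censor_mass, lod_ng = lod, loq_ng = loq)
  again <- lapply(first, function(m)
    pdnptrace:::censor_mass(measured_mass_value(m), lod, loq))
  # re-censoring a censored value never changes status class downward
  v1 <- vapply(first, measured_mass_value, 0)
  v2 <- vapply(again, measured_mass_value, 0)
  expect_equal(v2[v1 >= loq], v1[v1 >= loq])
  # reported values are non-decreasing in the underlying mass
  expect_true(all(diff(v1) >= 0))
  # statuses partition correctly
  st <- vapply(first, function(m) m$status, "")
  expect_equal(st, c("below_detection", "below_detection", "below_detection",
                     "between_lod_loq_set_to_lod", "between_lod_loq_set_to_lod",
                     "quantified", "quantified", "quantified"))
})

test_that("half-organ scaling preserves status and scales limits", {
  curve <- manual_curve()
  m <- quantify_sample(1000, curve)  # 13 ng quantified
  expect_equal(scale_half_organ(m, 0.5, 1.0)$value_ng, 26)
  expect_equal(scale_half_organ(m, 1, 1)$value_ng, m$value_ng)
  m2 <- m; m2$value_ng <- 2.0
  expect_equal(scale_half_organ(m2, 0.4, 1.0)$value_ng, 5.0)
  s <- scale_half_organ(m, 0.5, 1.0)
  expect_equal(s$sample_lod_ng, 2 * m$sample_lod_ng)
  expect_equal(s$status, m$status)
  expect_error(scale_half_organ(m, 1.5, 1.0), "partial_weight")
})
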