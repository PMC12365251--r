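test_that("percent of dose is linear, additive and flags >100 %", {
  expect_equal(as.numeric(percent_of_dose(9.976, 9.976)), 100)
  expect_equal(as.numeric(percent_of_dose(0, 9.976)), 0)
  over <- percent_of_dose(12.532, 9.976)
  expect_gt(as.numeric(over), 100)
  expect_true(attr(over, "over_100"))
  expect_error(percent_of_dose(1, 0), "positive")
  a <- as.numeric(percent_of_dose(c(1, 2), 10))
  expect_equal(sum(a), as.numeric(percent_of_dose(3, 10)))
})

test_that("cumulative excretion accumulates to the administered dose", {
  one <- cumulative_excretion(data.frame(time_h = 4, pd_mass_ug = 10), 10)
  expect_equal(one$cum_pct, 100)
  flat <- cumulative_excretion(data.frame(time_h = c(1, 2, 3),
                                          pd_mass_ug = c(0, 0, 0)), 10)
  expect_equal(flat$cum_pct, c(0, 0, 0))
  expect_error(cumulative_excretion(data.frame(time_h = c(3, 1),
                                               pd_mass_ug = c(1, 1)), 10),
               "sorted")
  # conservation: zero uptake over a long horizon excretes everything
  st <- simulate_biodistribution(acute_regimen(), uptake_fraction = 0,
                                 times_h = seq(0, 96, 4))
  series <- data.frame(time_h = st$masses$time_h,
                       pd_mass_ug = c(0, diff(st$masses$feces)))
  cum <- cumulative_excretion(series, 9.976)
  expect_true(all(diff(cum$cum_pct) >= 0))
  expect_equal(cum$cum_pct[nrow(cum)], 100, tolerance = 1e-5)
})

test_that("total recovery sums whole-organ percent of dose with censoring", {
  reg <- dose_regimen(0.48, 1.41, schedule_h = 0, dose_type = "daily")
  om <- data.frame(mouse = "m1",
                   organ = c("liver", "kidney", "brain"),
                   method = "ICPMS",
                   mass = c(0.141, 0.2115, NA),  # 10 %, 15 %, bdl
                   unit = "ug",
                   status = c("quantified", "quantified", "below_detection"))
  led <- study_ledger(reg, organ_masses = om)
  rec <- total_recovery(led, "m1")
  expect_equal(rec$recovery_pct, 25)
  expect_equal(rec$n_censored, 1)

  allbdl <- om; allbdl$mass <- NA; allbdl$status <- "below_detection"
  rec0 <- total_recovery(study_ledger(reg, organ_masses = allbdl), "m1")
  expect_equal(rec0$recovery_pct, 0)
  expect_equal(rec0$n_censored, 3)

  mixed <- om; mixed$unit <- c("ug", "ng", "ug")
  expect_error(total_recovery(study_ledger(reg, organ_masses = mixed), "m1"),
               "mixed")
  expect_error(total_recovery(led, "nope"), "no rows")
})

test_that("group comparison matches the pooled-variance closed form", {
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  res <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  # closed form: pooled sp^2 = 1, t = -3 / sqrt(2/3), df = 4
  t_hand <- (2 - 5) / sqrt(1 * (1 / 3 + 1 / 3))
  expect_equal(res$t, t_hand)
  expect_equal(res$df, 4)
  expect_equal(res$p, 2 * pt(t_hand, 4))

  expect_error(compare_groups(1, c(1, 2)), "n >= 2")
  welch <- compare_groups(c(1, 2, 3), c(4, 5, 60), var_equal = FALSE)
  expect_lt(welch$df, 4)
})

test_that("t-test p agrees with an exhaustive permutation oracle", {
  a <- c(1.2, 2.4, 3.1, 4.0); b <- c(2.0, 3.5, 4.6, 5.1)
  res <- compare_groups(a, b)
  pool <- c(a, b)
  idx <- combn(8, 4)
  t_obs <- abs(res$t)
  t_perm <- apply(idx, 2, function(ii) {
    x <- pool[ii]; y <- pool[-ii]
    sp2 <- (3 * var(x) + 3 * var(y)) / 6
    abs((mean(x) - mean(y)) / sqrt(sp2 * (1 / 4 + 1 / 4)))
  })
  p_perm <- mean(t_perm >= t_obs - 1e-12)
  expect_lt(abs(res$p - p_perm), 0.1)
})

test_that("method agreement reports ratio slope and relative difference", {
  ident <- method_agreement(data.frame(sample = 1:3,
                                       mass_method1 = c(1, 2, 3),
                                       mass_method2 = c(1, 2, 3)))
  expect_equal(ident$slope, 1)
  expect_equal(ident$mean_relative_difference, 0)

  scaled <- method_agreement(data.frame(sample = 1:4,
                                        mass_method1 = c(1, 2, 3, 4),
                                        mass_method2 = 0.8 * c(1, 2, 3, 4)))
  expect_equal(scaled$slope, 0.8)

  with_cens <- data.frame(sample = 1:4, mass_method1 = c(1, 2, 3, NA),
                          mass_method2 = c(1, 2, 3, 4),
                          status_method1 = c(rep("quantified", 3),
                                             "below_detection"),
                          status_method2 = "quantified")
  out <- method_agreement(with_cens)
  expect_equal(out$n_pairs, 3)
  expect_equal(out$n_excluded, 1)
  expect_error(method_agreement(with_cens[1:2, ]), ">= 3")
})

test_that("paired virtual-instrument outputs agree near slope 1", {
  # XFI and ICP-MS virtual measurements of the same fecal masses
  set.seed(5)
  masses <- c(0.05, 0.1, 0.15, 0.2)
  xfi <- vapply(seq_along(masses), function(i) {
    scan <- generate_xfi_scan(matrix(masses[i], 1, 1), seed = 50 + i)
    build_mass_map(scan, calibrate_flux(xfi_scan_references(scan), 1))$total_ug
  }, 0)
  concs <- masses * 1000 / ((13 / 3) * 3)
  icp <- quantify_batch(generate_icpms_batch(concs, seed = 99))$mass_ng / 1000
  out <- method_agreement(data.frame(sample = seq_along(masses),
                                     mass_method1 = xfi, mass_method2 = icp))
  expect_lt(abs(out$slope - 1), 0.1)
})
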