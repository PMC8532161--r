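# Two-stage joint NMRD fitting, deconvolution, derived quantities and the
# low-frequency discriminant.

test_that("noiseless profiles are recovered exactly by the two-stage fit", {
  pr <- noiseless_suc_profiles()
  fit <- fit_nmrd_joint(pr$p25, pr$p4, fit_protocol(seed = 1))
  est25 <- fit$temperatures[["25"]]$estimates
  est4 <- fit$temperatures[["4"]]$estimates
  expect_equal(unname(est25), unname(suc_truth_25()), tolerance = 0.01)
  expect_equal(unname(est4), unname(suc_truth_4()), tolerance = 0.01)
  # residual norm below 1e-6 of the data norm at each stage
  w25 <- fit$temperatures[["25"]]$residuals * pr$p25$rel_error * pr$p25$R1
  expect_lt(sqrt(sum(w25^2)), 1e-6 * sqrt(sum(pr$p25$R1^2)))
  # frozen quantities are carried bit-identically
  expect_identical(est4[["N_MM"]], fit$shared_N[["N_MM"]])
  expect_identical(est4[["N_LM"]], fit$shared_N[["N_LM"]])
  expect_identical(fit$temperatures[["25"]]$params$mm$d, angstrom_to_m(3.6))
  # labeling rule holds at both temperatures
  expect_gt(est25[["D_MM"]], est25[["D_LM"]])
  expect_gt(est4[["D_MM"]], est4[["D_LM"]])
})

test_that("fit rejects undersized profiles", {
  g <- make_frequency_grid(1e4, 2e7, 5)
  p <- simulate_nmrd_profile(fixture_params("SUC", 25), g, 0)
  expect_error(fit_nmrd_joint(p, NULL), "fewer than 8")
})

test_that("fit result is invariant to the order of profile points", {
  grid <- study_grid()
  p <- simulate_nmrd_profile(fixture_params("SUC", 25), grid, 0.02, seed = 9,
                             sample_id = "SUC", temperature_C = 25)
  perm <- withr::with_seed(2, sample(nrow(p)))
  p_shuf <- nmrd_profile(p$frequency_Hz[perm], p$R1[perm],
                         p$rel_error[perm], sample_id = "SUC",
                         temperature_C = 25)
  proto <- fit_protocol(seed = 9, n_multistart = 4)
  f1 <- suppressWarnings(fit_nmrd_joint(p, NULL, proto))
  f2 <- suppressWarnings(fit_nmrd_joint(p_shuf, NULL, proto))
  expect_identical(f1$temperatures[[1]]$estimates,
                   f2$temperatures[[1]]$estimates)
})

test_that("deconvolved contributions sum exactly to the total", {
  pr <- noiseless_suc_profiles()
  fit <- fit_nmrd_joint(pr$p25, pr$p4, fit_protocol(seed = 1,
                                                    n_multistart = 4))
  grid <- study_grid()
  dc <- deconvolve_contributions(fit, grid)
  expect_identical(dc$total, dc$rotational + dc$trans_MM + dc$trans_LM)
  expect_setequal(unique(dc$temperature_C), c(25, 4))
  # at 500 MHz the rotational contribution dominates for these parameters
  hi <- dc[dc$frequency_Hz == 5e8 & dc$temperature_C == 25, ]
  expect_gt(hi$rotational / hi$total, 0.9)
})

test_that("a zeroed LM pool contributes an identically zero curve", {
  params <- fixture_params("SUC", 25)
  fake <- structure(list(temperatures = list(`25` = list(params =
    composite_params(params$rot, params$mm,
                     translational_params(params$lm$D, 0))))),
    class = "nmrd_joint_fit")
  dc <- deconvolve_contributions(fake, study_grid())
  expect_true(all(dc$trans_LM == 0))
  expect_identical(dc$total, dc$rotational + dc$trans_MM)
})

test_that("derived quantities reproduce the reported spin-density columns", {
  suc <- derive_quantities(c(N_MM = 4.39e28, N_LM = 1.33e28))
  expect_equal(suc$N_total, 5.72e28)
  expect_equal(suc$ratio_reported, 3.3)
  sbf <- derive_quantities(c(N_MM = 6.57e28, N_LM = 3.79e28),
                           reference = c(N_MM = 4.39e28, N_LM = 1.33e28),
                           moisture_pct = 8.2, reference_moisture_pct = 4)
  expect_equal(sbf$N_total, 10.36e28)
  expect_equal(sbf$relative_change_N, 1.81, tolerance = 0.005)
  expect_equal(sbf$ratio_reported, 1.7)
  expect_equal(sbf$relative_change_moisture, 2.05)
  # identity reference
  self <- derive_quantities(c(N_MM = 4.39e28, N_LM = 1.33e28),
                            reference = c(N_MM = 4.39e28, N_LM = 1.33e28))
  expect_equal(self$relative_change_N, 1.0)
  # undefined ratio
  z <- derive_quantities(c(N_MM = 1e28, N_LM = 0))
  expect_true(is.na(z$ratio))
})

test_that("low-frequency discriminant ranks, ties and validates", {
  grid <- study_grid()
  profs <- lapply(c("SUC", "SBF10"), function(s)
    simulate_nmrd_profile(fixture_params(s, 25), grid, 0, sample_id = s,
                          temperature_C = 25))
  d <- low_frequency_discriminant(profs)
  expect_identical(d$original_like, "SUC")
  expect_false(d$tie)
  # statistic is invariant to point order
  p <- profs[[1]]
  perm <- withr::with_seed(4, sample(nrow(p)))
  p_shuf <- nmrd_profile(p$frequency_Hz[perm], p$R1[perm], p$rel_error[perm],
                         sample_id = "SUC", temperature_C = 25)
  d2 <- low_frequency_discriminant(list(p_shuf, profs[[2]]))
  expect_identical(d2$ranking$mean_R1_low, d$ranking$mean_R1_low)
  # two identical profiles tie explicitly
  dt <- low_frequency_discriminant(list(profs[[1]], profs[[1]]))
  expect_true(dt$tie)
  expect_true(is.na(dt$original_like))
  # cutoff with no points below errors
  expect_error(low_frequency_discriminant(profs, cutoff_Hz = 1e3),
               "no points below")
  expect_error(low_frequency_discriminant(profs[1]), "at least 2")
})
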