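# Time-domain analysis: mono-exponential fits, zero-method conversion,
# discrete multi-exponential decomposition and the inverse-Laplace spectrum.

test_that("zero method converts the crossing time exactly", {
  expect_equal(zero_method_t1(0.693147), 1.0, tolerance = 1e-6)
  expect_equal(zero_method_t1(log(2) * 0.05), 0.05)
  expect_error(zero_method_t1(0), "positive")
})

test_that("mono-exponential fits recover noiseless curves to optimizer precision", {
  dec <- simulate_cpmg_decay(list(T2 = 10e-3, fraction = 1),
                             acq_spec("CPMG", n_echoes = 256))
  f <- fit_monoexp(dec)
  expect_equal(f$relaxation_time, 10e-3, tolerance = 1e-8)
  sr <- simulate_magnetization_curve(0.1, acq_spec("SR"))
  fs <- fit_monoexp(sr)
  expect_equal(fs$relaxation_time, 0.1, tolerance = 1e-8)
  # amplitude scale equivariance with identical time constant
  dec3 <- magnetization_curve(dec$time_s, 3 * dec$amplitude,
                              attr(dec, "spec"))
  f3 <- fit_monoexp(dec3)
  expect_equal(f3$amplitude, 3 * f$amplitude, tolerance = 1e-6)
  expect_equal(f3$relaxation_time, f$relaxation_time, tolerance = 1e-6)
  # failure contracts
  flat <- magnetization_curve(dec$time_s, rep(1, nrow(dec)),
                              attr(dec, "spec"))
  expect_error(fit_monoexp(flat), "flat curve")
  rising <- magnetization_curve(dec$time_s, seq_len(nrow(dec)),
                                attr(dec, "spec"))
  expect_error(fit_monoexp(rising), "does not decay")
})

test_that("a mono-exponential fit of a bi-exponential decay lies between the true times", {
  dec <- simulate_cpmg_decay(suc_t2_components(),
                             acq_spec("CPMG", n_echoes = 256))
  f <- fit_monoexp(dec)
  expect_gt(f$relaxation_time, 2.31e-3)
  expect_lt(f$relaxation_time, 13.17e-3)
})

test_that("discrete decomposition recovers the two SUC components exactly when noiseless", {
  dec <- simulate_cpmg_decay(suc_t2_components(),
                             acq_spec("CPMG", n_echoes = 256))
  f <- fit_discrete_multiexp(dec, 2)
  expect_equal(f$components$T2_ms, c(2.31, 13.17), tolerance = 1e-5)
  expect_equal(f$components$RA_pct, c(54.5, 45.5), tolerance = 1e-4)
  expect_equal(sum(f$components$RA_pct), 100, tolerance = 1e-9)
  expect_true(all(diff(f$components$T2_s) > 0))
})

test_that("relative areas are normalized for any input", {
  for (s in 1:5) {
    dec <- simulate_cpmg_decay(suc_t2_components(),
                               acq_spec("CPMG", n_echoes = 256),
                               noise_sd = 0.02, seed = s)
    f <- fit_discrete_multiexp(dec, 2)
    expect_equal(sum(f$components$RA_pct), 100, tolerance = 1e-9)
  }
})

test_that("degenerate inputs collapse to a reduced model with a warning", {
  mono <- simulate_cpmg_decay(list(T2 = 5e-3, fraction = 1),
                              acq_spec("CPMG", n_echoes = 256))
  expect_warning(f <- fit_discrete_multiexp(mono, 2), "collapsed")
  expect_identical(f$n_components, 1L)
  expect_equal(f$components$T2_ms, 5, tolerance = 1e-6)
  short <- magnetization_curve((1:4) * 1e-4, exp(-(1:4) * 1e-4 / 5e-3),
                               acq_spec("CPMG", n_echoes = 4))
  expect_error(fit_discrete_multiexp(short, 2), "at least")
})

test_that("inverse-Laplace spectrum is non-negative and locates noiseless peaks", {
  dec <- simulate_cpmg_decay(suc_t2_components(),
                             acq_spec("CPMG", n_echoes = 256))
  sp <- ilt_t2_spectrum(dec)
  expect_true(all(sp$spectrum$amplitude >= 0))
  pk <- spectrum_peaks(sp)
  expect_identical(pk$n_components, 2L)
  # peak maxima within one grid step of the generating values
  step <- sp$spectrum$T2_s[2] / sp$spectrum$T2_s[1]
  expect_lt(abs(log(pk$components$T2_mode_s[1] / 2.31e-3)), log(step) * 1.5)
  expect_lt(abs(log(pk$components$T2_mode_s[2] / 13.17e-3)), log(step) * 1.5)
  expect_error(
    ilt_t2_spectrum(magnetization_curve((1:5) * 1e-4, numeric(5),
                                        acq_spec("CPMG", n_echoes = 5))),
    "all-zero")
  expect_error(ilt_t2_spectrum(dec, regularization_strength = -1), ">= 0")
})

test_that("unregularized spectrum reproduces a noiseless decay when re-projected", {
  dec <- simulate_cpmg_decay(suc_t2_components(),
                             acq_spec("CPMG", n_echoes = 256))
  sp <- ilt_t2_spectrum(dec, regularization_strength = 0)
  K <- exp(-outer(dec$time_s, sp$spectrum$T2_s, `/`))
  recon <- as.vector(K %*% sp$spectrum$amplitude)
  # the generating T2 values fall between grid atoms, so reconstruction is
  # limited by the grid resolution, not by the solver
  expect_lt(sqrt(sum((recon - dec$amplitude)^2)),
            2e-3 * sqrt(sum(dec$amplitude^2)))
})

test_that("stronger regularization never adds peaks", {
  dec <- simulate_cpmg_decay(suc_t2_components(),
                             acq_spec("CPMG", n_echoes = 256))
  ladder <- c(0.01, 0.1, 1, 3)
  n_peaks <- vapply(ladder, function(l)
    spectrum_peaks(ilt_t2_spectrum(dec, regularization_strength = l))$n_components,
    integer(1))
  expect_true(all(diff(n_peaks) <= 0))
})

test_that("peak segmentation partitions the spectrum area exactly", {
  dec <- simulate_cpmg_decay(suc_t2_components(),
                             acq_spec("CPMG", n_echoes = 256),
                             noise_sd = 0.01, seed = 2)
  sp <- ilt_t2_spectrum(dec)
  pk <- spectrum_peaks(sp)
  expect_equal(sum(pk$components$amplitude), sum(sp$spectrum$amplitude))
  expect_equal(sum(pk$components$RA_pct), 100)
  # single-peak spectrum reports one component at RA 100
  mono <- simulate_cpmg_decay(list(T2 = 5e-3, fraction = 1),
                              acq_spec("CPMG", n_echoes = 256))
  pk1 <- spectrum_peaks(ilt_t2_spectrum(mono))
  expect_identical(pk1$n_components, 1L)
  expect_equal(pk1$components$RA_pct, 100)
  empty <- structure(list(spectrum = data.frame(T2_s = c(1e-3, 1e-2),
                                                amplitude = c(0, 0)),
                          regularization_strength = 0.1),
                     class = "t2_spectrum")
  expect_error(spectrum_peaks(empty), "empty")
})

test_that("simulate -> spectrum -> peaks recovers the SUC pools at 1% noise", {
  ras <- sapply(1:5, function(s) {
    dec <- simulate_cpmg_decay(suc_t2_components(),
                               acq_spec("CPMG", n_echoes = 256),
                               noise_sd = 0.01, seed = s)
    pk <- spectrum_peaks(ilt_t2_spectrum(dec))
    cmp <- pk$components[pk$components$RA_pct > 5, ]
    if (nrow(cmp) != 2) return(c(NA, NA))
    cmp$RA_pct
  })
  med <- apply(ras, 1, stats::median, na.rm = TRUE)
  expect_lt(abs(med[1] - 54.5), 3)
  expect_lt(abs(med[2] - 45.5), 3)
})
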