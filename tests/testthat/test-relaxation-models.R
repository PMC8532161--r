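# Forward-model components: BPP rotational term, log-Gaussian distribution,
# Torrey translational term and the composite total.

test_that("single-tau BPP rate matches its closed-form limits", {
  C <- 1e9
  tau <- 1e-9
  # zero-frequency limit R1 = 5 C tau
  expect_equal(lorentzian_bpp_r1(0, tau, C), 5 * C * tau)
  # at omega*tau = 1: C tau (1/2 + 4/5)
  expect_equal(lorentzian_bpp_r1(1 / tau, tau, C), C * tau * 1.3)
  # high-frequency asymptote 2 C / (omega^2 tau), within 0.01% at wt = 1e3
  omega <- 1e3 / tau
  expect_equal(lorentzian_bpp_r1(omega, tau, C), 2 * C / (omega^2 * tau),
               tolerance = 1e-4)
  # strictly decreasing in omega
  om <- 10^seq(3, 10, length.out = 40)
  expect_true(all(diff(lorentzian_bpp_r1(om, tau, C)) < 0))
  expect_error(lorentzian_bpp_r1(1, -1e-9, C), "tau")
  expect_error(lorentzian_bpp_r1(1, tau, 0), "C_intra")
  expect_error(lorentzian_bpp_r1(-1, tau, C), "omega")
})

test_that("log-Gaussian quadrature is normalized, symmetric and centred", {
  q <- log_gaussian_weights(1e-9, 1.5, n_nodes = 128)
  expect_true(all(q$weights >= 0))
  expect_equal(sum(q$weights), 1, tolerance = 1e-9)
  # node symmetry about log(tau_center)
  lg <- log(q$tau) - log(1e-9)
  expect_equal(lg, -rev(lg))
  # weight symmetry
  expect_equal(q$weights, rev(q$weights))
  # point-mass limit
  q0 <- log_gaussian_weights(5e-10, 0)
  expect_identical(q0$tau, 5e-10)
  expect_identical(q0$weights, 1)
  # weighted median equals tau_center within one node spacing of a dense
  # quadrature oracle
  qd <- log_gaussian_weights(1e-9, 1.5, n_nodes = 1e4)
  cum <- cumsum(qd$weights)
  med <- qd$tau[which.min(abs(cum - 0.5))]
  spacing <- qd$tau[2] / qd$tau[1]
  expect_lt(abs(log(med / 1e-9)), log(spacing) * 2)
  expect_error(log_gaussian_weights(1e-9, -0.1), "delta_rot")
})

test_that("distributed rotational rate reduces to and extends the BPP form", {
  om <- larmor_to_omega(10^seq(3, 9, length.out = 25))
  # degenerate distribution: identical to single-tau BPP
  p0 <- rotational_params(2e9, 0.8, delta_rot = 0)
  expect_equal(rotational_r1_distributed(om, p0),
               lorentzian_bpp_r1(om, 0.8e-9, 2e9), tolerance = 1e-6)
  # linearity in C_intra
  p1 <- rotational_params(1e9, 0.57, 1.5)
  p2 <- rotational_params(2e9, 0.57, 1.5)
  expect_equal(2 * rotational_r1_distributed(om, p1),
               rotational_r1_distributed(om, p2))
  # zero-frequency value equals 5 C <tau> against a dense quadrature oracle
  qd <- log_gaussian_weights(0.57e-9, 1.5, n_nodes = 1e4)
  mean_tau <- sum(qd$weights * qd$tau)
  expect_equal(rotational_r1_distributed(0, p1), 5 * 1e9 * mean_tau,
               tolerance = 1e-3)
  # non-increasing in frequency
  r <- rotational_r1_distributed(om, p1)
  expect_true(all(diff(r) <= 0))
})

test_that("intermolecular dipolar constant follows from CODATA constants", {
  # independent evaluation of (9/8) (mu0 gamma^2 hbar / 4 pi)^2
  gamma <- 2.6752218744e8
  hbar <- 1.054571817e-34
  expected <- (9 / 8) * (1e-7 * gamma^2 * hbar)^2
  expect_equal(c_inter(physical_constants()), expected, tolerance = 1e-3)
  expect_equal(expected, 6.4e-49, tolerance = 2e-2)
})

test_that("translational parameters derive tau_trans and delta_jump from a = d", {
  p <- translational_params(D = 1.70e-12, N = 4.39e28, d_A = 3.6)
  expect_equal(p$tau_trans, (3.6e-10)^2 / (6 * 1.70e-12))
  expect_equal(p$tau_trans, 1.27e-8, tolerance = 1e-2)
  expect_identical(p$delta_jump, 1 / 12)
  expect_error(translational_params(-1e-12, 1e28), "D")
})

test_that("Torrey translational rate is finite, monotone and linear in N", {
  om <- larmor_to_omega(10^seq(3, 9, length.out = 30))
  p <- translational_params(3.9e-13, 1.33e28)
  r <- torrey_translational_r1(om, p)
  expect_true(all(is.finite(r)) && all(r > 0))
  expect_true(all(diff(r) <= 0))
  r0 <- torrey_translational_r1(0, p)
  expect_true(is.finite(r0) && r0 >= r[1])
  # linear in spin density
  p3 <- translational_params(3.9e-13, 3 * 1.33e28)
  expect_equal(torrey_translational_r1(om, p3), 3 * r)
  expect_error(torrey_translational_r1(-1, p), "omega")
})

test_that("composite total is the exact sum of its components", {
  params <- fixture_params("SUC", 25)
  withr::with_seed(11, {
    nu <- 10^stats::runif(50, 4, 8.7)
  })
  om <- larmor_to_omega(sort(nu))
  comp <- r1_components(om, params)
  expect_identical(total_r1(om, params),
                   as.vector(comp[, 1] + comp[, 2] + comp[, 3]))
  # zeroing both spin densities leaves the rotational term alone
  pz <- composite_params(params$rot,
                         translational_params(params$mm$D, 0),
                         translational_params(params$lm$D, 0))
  expect_equal(total_r1(om, pz), rotational_r1_distributed(om, params$rot))
  # on the study parameters the curve is positive and non-increasing over
  # 0.01 - 500 MHz
  om_grid <- larmor_to_omega(10^seq(4, log10(5e8), length.out = 60))
  r <- total_r1(om_grid, params)
  expect_true(all(r > 0))
  expect_true(all(diff(r) <= 0))
})

test_that("Lorentzian spectral density integrates to pi/2 over frequency", {
  for (tau in c(1e-10, 1e-9, 1e-7)) {
    J <- function(w) tau / (1 + (w * tau)^2)
    val <- stats::integrate(J, 0, 10 / tau, rel.tol = 1e-9)$value +
      stats::integrate(J, 10 / tau, 1e5 / tau, rel.tol = 1e-9)$value
    expect_equal(val, pi / 2, tolerance = 1e-4)
  }
})

test_that("frequency conversion round-trips losslessly", {
  nu <- c(1e4, 2e7, 5e8)
  expect_identical(omega_to_larmor(larmor_to_omega(nu)), nu)
})

test_that("parameters serialize to and from unit-suffixed key-value form", {
  params <- fixture_params("SBF10", 4)
  kv <- params_to_kv(params)
  expect_named(kv, c("C_intra_s2", "tau_rot_ns", "delta_rot", "D_mm_m2s",
                     "N_mm_m3", "D_lm_m2s", "N_lm_m3", "d_angstrom"))
  back <- params_from_kv(kv)
  expect_equal(back, params)
  expect_error(params_from_kv(kv[-1]), "missing parameter keys")
})

test_that("composite constructor enforces the pool labeling rule", {
  rot <- rotational_params(4e9, 0.5, 1.5)
  expect_error(composite_params(rot,
                                translational_params(1e-13, 1e28),
                                translational_params(1e-12, 1e28)),
               "labeling")
  expect_error(composite_params(rot,
                                translational_params(1e-12, 1e28, d_A = 3.6),
                                translational_params(1e-13, 1e28, d_A = 3.0)),
               "closest-approach")
})
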