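# Shared test fixtures, built in code.

# study frequency grid: 31 log-spaced points 10 kHz - 20 MHz plus 500 MHz
study_grid <- function() make_frequency_grid(1e4, 2e7, 31, extra_points = 5e8)

suc_truth_25 <- function() {
  c(C_intra = 4.20e9, tau_rot = 0.57e-9, D_MM = 1.70e-12, N_MM = 4.39e28,
    D_LM = 3.90e-13, N_LM = 1.33e28)
}

suc_truth_4 <- function() {
  c(C_intra = 3.86e9, tau_rot = 1.08e-9, D_MM = 1.11e-12, N_MM = 4.39e28,
    D_LM = 2.71e-13, N_LM = 1.33e28)
}

# SUC discrete T2 ground truth: short component 2.31 ms at 54.5%, long
# component 13.17 ms at 45.5%
suc_t2_components <- function() {
  list(T2 = c(2.31e-3, 13.17e-3), fraction = c(0.545, 0.455))
}

noiseless_suc_profiles <- function(grid = study_grid()) {
  list(p25 = simulate_nmrd_profile(fixture_params("SUC", 25), grid,
                                   noise_fraction = 0, sample_id = "SUC",
                                   temperature_C = 25),
       p4 = simulate_nmrd_profile(fixture_params("SUC", 4), grid,
                                  noise_fraction = 0, sample_id = "SUC",
                                  temperature_C = 4))
}
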