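# gelrelax

NMR relaxometry analysis of water dynamics in starch–sugar confectionery
gels, built for food scientists and NMR relaxometrists who need to
characterize — or authenticate — sucrose versus corn-syrup formulations.

Fast field cycling (FFC) NMR measures the proton spin–lattice relaxation
rate R1 ≡ 1/T1 across Larmor frequencies (an NMRD profile).  `gelrelax`
models such profiles as a sum of three contributions,

    R1(ω) = R1_rot(ω) + R1_trans,MM(ω) + R1_trans,LM(ω)

* **Rotational**: a BPP-type term C_intra·[J(ω) + 4J(2ω)] with the
  Lorentzian spectral density J(ω) = τ/(1+ω²τ²), averaged over a
  log-Gaussian distribution of correlation times (centre τ_rot, width
  δ_rot).
* **Translational** (one term per proton pool, more mobile MM and less
  mobile LM): Torrey's jump-diffusion model,
  C_inter·(N·τ_trans/d³)·[f(δ, ωτ_trans) + 4f(δ, 2ωτ_trans)], with
  C_inter = (9/8)(μ₀γ²ℏ/4π)² fixed by fundamental constants, and — under the
  closest-approach assumption a = d — τ_trans = d²/(6D) and δ = 1/12, so
  each pool contributes exactly two free parameters (D, N).

The joint fit follows a two-stage protocol: six free parameters at 25 °C
(C_intra, τ_rot, D_MM, D_LM, N_MM, N_LM) with d = 3.6 Å and δ_rot fixed,
then four at 4 °C with the spin densities frozen at their 25 °C values.
The package also provides CPMG T2 decomposition (discrete bi-exponential
fit and Tikhonov-regularized inverse Laplace spectrum via non-negative least
squares), synthetic-data generators that emulate the FFC/CPMG acquisitions,
a low-frequency authenticity discriminant, and the closed-form quality
metrics (CIE76 ΔE color change, TPA gumminess/chewiness, Pearson
correlation).

## Worked example

Simulate noiseless NMRD profiles for the sucrose formulation (built-in
fixture `"SUC"`) and run the two-stage joint fit:

```r
library(gelrelax)

grid <- make_frequency_grid(1e4, 2e7, 31, extra_points = 5e8)
p25 <- simulate_nmrd_profile(fixture_params("SUC", 25), grid,
                             noise_fraction = 0, sample_id = "SUC",
                             temperature_C = 25)
p4  <- simulate_nmrd_profile(fixture_params("SUC", 4), grid,
                             noise_fraction = 0, sample_id = "SUC",
                             temperature_C = 4)
fit <- fit_nmrd_joint(p25, p4, fit_protocol(seed = 1))
fit
#> Joint NMRD fit for SUC
#>   25 degC: C_intra = 4.2e+09 s^-2, tau_rot = 0.57 ns, D_MM = 1.7e-12, D_LM = 3.9e-13 m^2/s
#>           chi^2 = 4.34e-26 (reduced 1.67e-27, 6 free parameters)
#>   4 degC: C_intra = 3.86e+09 s^-2, tau_rot = 1.08 ns, D_MM = 1.11e-12, D_LM = 2.71e-13 m^2/s
#>           chi^2 = 5.785e-26 (reduced 2.07e-27, 4 free parameters)
#>   shared N_MM = 4.39e+28, N_LM = 1.33e+28 m^-3
derive_quantities(fit)
#> N_total = 5.72e+28 m^-3, N_MM/N_LM = 3.3
```

The fit recovers the generating parameters exactly (χ² at machine
precision): two distinct self-diffusion coefficients (1.7×10⁻¹² and
3.9×10⁻¹³ m²/s at 25 °C) for the more- and less-mobile water pools, a total
spin density N = 5.72×10²⁸ m⁻³ and a pool ratio N_MM/N_LM ≈ 3.3 — the
sucrose gel keeps about three times more protons in fast pools than in
confined ones.  On noisy profiles the same call returns parameter standard
errors; note that D_MM and N_MM are strongly correlated at realistic noise
levels (see the methods vignette).

Decomposing a CPMG decay built from the sucrose gel's two T2 pools
(2.31 ms / 54.5 %, 13.17 ms / 45.5 %; 100 µs echo spacing, 256 echoes, 1 %
noise):

```r
dec <- simulate_cpmg_decay(list(T2 = c(2.31e-3, 13.17e-3),
                                fraction = c(0.545, 0.455)),
                           acq_spec("CPMG", n_echoes = 256),
                           noise_sd = 0.01, seed = 1)
fit_discrete_multiexp(dec, 2)
#> Discrete T2 decomposition (2 components):
#>         T2_s     T2_ms amplitude   RA_pct
#>  0.002318787  2.318787 0.5437482 54.34928
#>  0.013116995 13.116995 0.4567217 45.65072
#> residual norm: 0.1522
```

The short pool (rigid, solid–solid interactions) and the long pool (mobile
water entrapped in the gel network) come back within a fraction of a percent
of the generating values.

The authenticity screen ranks samples by mean R1 below 1 MHz — the sucrose
gel relaxes slowest at low field:

```r
profs <- lapply(sample_names(), function(s)
  simulate_nmrd_profile(fixture_params(s, 4), grid, 0,
                        sample_id = s, temperature_C = 4))
low_frequency_discriminant(profs)
#> Low-frequency discriminant (mean R1 below 1e+06 Hz)
#>   sample_id temperature_C mean_R1_low n_low rank
#> 1       SUC             4    124.7957    19    1
#> 2     SBF10             4    276.6929    19    2
#> 3     SCG60             4    276.7884    19    3
#> 4     SCG40             4    310.0792    19    4
#> original-like sample: SUC
```

An end-to-end pipeline (simulate → fit → report, with CSV/JSON outputs) is
available through `pipeline_config()` + `cmd_simulate()` / `cmd_fit()` /
`cmd_t2()`, or from a shell via `inst/scripts/run_pipeline.R`.

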