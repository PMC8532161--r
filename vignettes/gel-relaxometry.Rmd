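---
title: "Composite relaxation modelling of confectionery gels: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite relaxation modelling of confectionery gels: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gelrelax)
```

## The problem

Starch-sugar confectionery gels (Turkish delight, *lokum*) are traditionally
made with sucrose; cheaper formulations substitute corn syrups.  The two can
be told apart by how water moves inside the gel network.  Fast field cycling
(FFC) NMR relaxometry measures the proton spin-lattice relaxation rate
`R1 = 1/T1` as a function of Larmor frequency (an NMRD profile), which
encodes the rotational and translational dynamics of the mobile (water and
dissolved sugar) protons.  Time-domain NMR at a single field complements this
with the transverse relaxation time `T2`, whose multi-exponential structure
reports on distinct proton pools.  `gelrelax` implements the full analysis
chain for both experiments, along with generators for synthetic data with the
same acquisition structure, so that every estimator in the package can be
exercised and validated end to end.

## The composite R1 model

The observed rate is modelled as a sum of three contributions,

```
R1(omega) = R1_rot(omega) + R1_trans,MM(omega) + R1_trans,LM(omega)
```

where `omega = 2 pi nu` is the angular Larmor frequency.

**Rotational term.**  Molecular tumbling modulates intramolecular dipolar
couplings.  For a single correlation time the rate takes the BPP form
`C_intra [J(omega) + 4 J(2 omega)]` with the Lorentzian spectral density
`J(omega) = tau/(1 + omega^2 tau^2)`.  Gels are heterogeneous, so the package
averages this over a log-Gaussian distribution of correlation times centred
on `tau_rot` with width `delta_rot` (the standard deviation of the Gaussian
in `ln tau`).  `C_intra` (s^-2) scales inversely with the sixth power of the
mean intra-molecular proton-proton distance.

A note on the width convention.  The width is quoted in the source material
as "1.5 decade", which could be read either as a standard deviation of 1.5
in `log10(tau)` or as the conventional log-Gaussian width parameter
(sd of `ln tau`) equal to 1.5, i.e. about 0.65 decades.  The package adopts
the latter, for two reasons.  First, it is the standard parameterization of
the distributed-BPP literature.  Second, it is the only reading consistent
with the physics being described: with a 1.5-decade log10 width and the
reported parameter values, the forward model produces low-frequency rates in
the thousands of s^-1 and ranks the sucrose sample *above* two corn-syrup
samples at low frequency — contradicting both the reported dispersion
magnitudes and the central authenticity finding that the sucrose gel has the
lowest low-frequency relaxation rate at both temperatures.  With
`delta_rot = 1.5` in `ln tau`, the model reproduces that ordering at 25 and
4 degC and plausible magnitudes throughout.  The width is a regular
parameter (`rotational_params()`), so users can adopt any convention they
prefer; it is held fixed during fitting.

**Translational terms.**  Translational diffusion modulates intermolecular
dipolar couplings between protons on different molecules.  The package uses
Torrey's jump-diffusion model: molecules perform random jumps with mean time
`tau_trans` between jumps and mean-square jump length `<a^2>`, giving

```
R1_trans = C_inter (N tau_trans / d^3) [f(delta, omega tau_trans) +
                                        4 f(delta, 2 omega tau_trans)]
```

with `C_inter = (9/8)(mu0 gamma^2 hbar / 4 pi)^2` fixed by fundamental
constants (`c_inter()` computes it from CODATA values; ~6.41e-49 m^6 s^-2),
`N` the proton density of the pool, and `d` the distance of closest
approach.  Under the simplifying assumption that the jump length equals `d`
(`a = d`), the jump time and reduced jump parameter are *derived*, not
fitted: `tau_trans = d^2/(6 D)` and `delta = <a>^2/(12 d^2) = 1/12`.  Each
translational pool therefore exposes exactly two free parameters, the
self-diffusion coefficient `D` and the spin density `N`.  Two pools are
modelled: more mobile (MM, larger `D`, water in large pores) and less mobile
(LM, water confined in small pores), with the labelling rule `D_MM > D_LM`
enforced after every fit.

The reduced spectral function `f(delta, x)` is evaluated from its k-space
definition: the dipolar lattice sum over a uniform spin density outside `d`
gives mode amplitudes proportional to `[j1(y)/y]^2` (`j1` the spherical
Bessel function, `y = k d`), each mode relaxing with the jump-model lifetime
from the structure factor `A(k) = 1/(1 + k^2 <a^2>/6)` with both partners
jumping.  The normalization is fixed by requiring the zero-time correlation
to equal the exact lattice sum `4 pi N/(3 d^3)`, so the prefactor follows
from the derivation rather than from a convention choice; the same function
is used in simulation and fitting, making all recovery studies
self-consistent.  Numerically, the integral is evaluated by composite
Gauss-Legendre quadrature (200 panels of width 0.5 up to `y = 100`, 6 nodes
per panel, cached per `delta`) plus an analytic large-`y` tail correction;
the integrand is smooth and the rule is deterministic.

## Fitting protocol

`fit_nmrd_joint()` reproduces the two-temperature protocol:

* Stage 1 fits the 25 degC profile with six free parameters — `C_intra`,
  `tau_rot`, `D_MM`, `D_LM`, `N_MM`, `N_LM` — with `d = 3.6 A` and
  `delta_rot = 1.5` fixed.
* Stage 2 fits the 4 degC profile with four free parameters, the spin
  densities frozen bit-identically at their stage-1 values.  (The source
  protocol states that the spin densities were fitted only at 25 degC and
  held constant at the lower temperature; whether that fit was sequential or
  iterated is not stated, and the sequential reading is adopted.)

Each stage minimizes the error-weighted sum of squares with per-point
`sigma = rel_error * R1_obs` (5% assumed when a profile carries no error
column), using bounded Levenberg-Marquardt on `log10` parameters.  Default
bounds — `C_intra` in [1e8, 1e10] s^-2, `tau_rot` in [1 ps, 1 us], `D` in
[1e-14, 1e-9] m^2/s, `N` in [1e27, 1e29] m^-3 — bracket typical gel values
widely while keeping `N` below the proton density of pure water's order of
magnitude.  The optimizer is a seeded two-phase multistart: a triage pass
from `2 * n_multistart` log-uniform starts (40 iterations each), then a full
polish of the best few candidates.  The default `n_multistart = 16` was
chosen by checking that the returned optimum matches Levenberg-Marquardt
started at the generating parameters on noisy synthetic profiles; eight
full-length random starts, an obvious simpler choice, measurably missed the
global optimum on a fraction of noisy realizations.  Standard errors come
from the Jacobian-based covariance at the optimum, delta-transformed from
the `log10` scale.

A word on identifiability.  The three contributions overlap heavily in
frequency: within the 10 kHz - 20 MHz window the rotational term is nearly
flat, and the MM and LM dispersion knees sit less than a decade apart.  The
Fisher information at typical gel parameters with 2% relative errors gives
single-profile standard errors above 50% for `D_MM` and strong (0.9-0.99)
parameter correlations.  Point estimates from a single noisy profile are
therefore volatile even at the global optimum, and Monte-Carlo medians over
a modest number of noise realizations remain noticeably seed-dependent.
This is a property of the experimental design, not of the optimizer; the
parameter-recovery tests in the package measure it rather than hide it.

Derived quantities (`derive_quantities()`) are the total spin density
`N = N_MM + N_LM`, the pool ratio `N_MM/N_LM` (reported to one decimal), and
relative changes against a reference sample.  The authenticity screen
(`low_frequency_discriminant()`) averages `R1` over all points below a
cutoff (default 1 MHz) and flags the profile with the lowest mean as the
original-like (sucrose-type) sample; exact ties are reported as ties.

## Time-domain analysis

CPMG decays are decomposed two ways:

* `fit_discrete_multiexp()` fits `sum_i A_i exp(-t/T2_i)` by variable
  projection — non-negative amplitudes solved by Lawson-Hanson NNLS inside a
  Levenberg-Marquardt loop over `log10 T2_i`.  Components are reported in
  ascending `T2` with relative areas `RA_i = 100 A_i / sum(A)`.  Components
  collapsing within 1% in `T2`, or losing all amplitude, trigger a warning
  and a refit with one component fewer.  This discrete fit is the primary
  reproduction path for the reported two-pool `T2`/RA tables.
* `ilt_t2_spectrum()` computes a quasi-continuous spectrum by
  Tikhonov-regularized NNLS on an exponential kernel over 100 log-spaced
  `T2` values in [10 us, 1 s] (neither grid nor range is documented for the
  original analysis; these defaults cover the CPMG window with margin).
  The default penalty `lambda = 0.1` was chosen once from an L-curve scan
  (`ilt_lambda_scan()`) on synthetic two-component decays: small enough to
  keep two well-separated pools resolved, large enough to suppress spurious
  sub-echo-time peaks when noise is present.  `spectrum_peaks()` segments
  the spectrum at zeros and interior local minima and reports per-peak
  amplitude-weighted `T2`, peak maxima and relative areas.  Spectral peaks
  are intrinsically broadened by the regularization, so RA values from the
  spectrum carry a few percentage points of tolerance.

Mono-exponential fits (`fit_monoexp()`) choose decay or recovery form from
the curve's sequence tag, and `zero_method_t1()` converts an
inversion-recovery zero crossing via `T1 = t0 / ln 2`.

## What the synthetic data emulate — and what they do not

`simulate_nmrd_profile()` evaluates the forward model on a frequency grid
(default study grid: 31 log-spaced points from 10 kHz to 20 MHz plus a
500 MHz high-field point) and applies independent relative Gaussian noise;
the default 5% equals the stated acquisition error bound, and recovery
studies use 2% where that condition is specified.  The noise model is
relative because the acquisition error is quoted as a relative bound;
amplitudes of magnetization curves instead carry additive noise.
`simulate_magnetization_curve()` follows the acquisition structure:
pre-polarized (PP) below 10 MHz, non-polarized (NP) above, 22
logarithmically spaced delays; the delay span [T1/50, 5 T1] is a package
choice, since only the number of points is documented.
`simulate_cpmg_decay()` samples echo maxima at `t_k = k * echo_time` (100 us
default, no `t = 0` sample), which is standard CPMG sampling.

The instrument's 128-echo setting covers only 12.8 ms and so undersamples a
~13 ms slow component; synthetic validation decays therefore default to 256
echoes, with 128 available.  The generators do not emulate field-switching
transients, FID dead time, receiver gain, or any multi-exponential T1
structure within a single FFC curve (the acquisitions are described as
mono-exponential).  Passing recovery tests on these synthetic data shows
that the estimators invert the stated model at the stated noise; it does not
certify behaviour under instrument artifacts absent from the model, nor the
unmodelled relaxation enhancement observed around 0.15-2 MHz in some
corn-syrup samples, which the fitter only tolerates as structured residual
(optionally down-weighted via `fit_protocol(downweight_window_Hz = ...)`).

## Quality metrics

`delta_e()` is the CIE76 Euclidean color difference in L\*a\*b\* space —
the standard form, which reproduces all three reported color-change values
from the printed coordinates.  `tpa_derived()` computes gumminess
(hardness x cohesiveness) and chewiness (gumminess x springiness); the
product is computed in the units supplied, and no attempt is made to
reconcile reported chewiness magnitudes whose unit convention is internally
inconsistent.  `pearson_r()` wraps the standard correlation estimator; on
the printed sample means the hardness/short-T2 correlation evaluates to
about -0.95, whereas the reported -0.94 was computed from replicate-level
data that are not available.

## Problem sizes and reproducibility

Every stochastic routine takes an explicit integer seed and is a pure
function of (parameters, seed).  The packaged studies use the problem sizes
stated with the study conditions: 20 noise realizations for NMRD parameter
recovery at 2% noise and 100 realizations for the discrete T2 recovery at 1%
noise; pipeline outputs embed the package version, seed and a configuration
fingerprint.  All internal computation is SI; interfaces accept MHz, ns and
Angstrom and convert once at the boundary, and the rotational-width /
jump-parameter symbols are kept as distinct typed fields (`delta_rot` vs
`delta_jump`) precisely because they are different physical quantities that
happen to share a symbol in the field's notation.

## Known limitations

* The MM/LM decomposition is a two-pool idealization fixed by protocol;
  model selection between one and two translational pools is out of scope.
* `D_MM`, `N_MM` and the rotational parameters are strongly correlated at
  realistic noise levels (see the identifiability note above); single-fit
  uncertainties should be taken seriously and Monte-Carlo medians
  interpreted with their spread.
* The Torrey spectral function is evaluated by quadrature of the model's
  defining integral with a fixed deterministic rule; its absolute prefactor
  follows from the uniform-density derivation and may differ from other
  published conventions by a constant factor, which is absorbed by `N` when
  fitting real data but matters when comparing absolute simulated magnitudes
  across conventions.
* Chemical exchange, quadrupolar dips and the relaxation of rigid gelator
  protons are outside the model.
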