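# Synthetic-data generators emulating the acquisition structure of the study:
# fast field cycling NMRD profiles (pre-polarized below 10 MHz, non-polarized
# above, mono-exponential magnetization evolution sampled at 22 log-scaled
# delays, relative error on R1 bounded by 5%), CPMG decays (100 us echo time,
# 128 echoes) and saturation-recovery curves.  All generators are pure
# functions of (parameters, seed).

#' Acquisition specification
#'
#' Describes one acquisition: the sequence type and its timing parameters.
#' Pre-polarized (PP) acquisition is used for evolution frequencies below
#' 10 MHz only, non-polarized (NP) at or above; the PP polarizing field
#' corresponds to 20 MHz, applied for 5 T1.
#'
#' @param sequence One of \code{"PP"}, \code{"NP"}, \code{"SR"}, \code{"CPMG"}.
#' @param n_points Number of magnetization samples (default 22; ignored for
#'   CPMG where \code{n_echoes} rules).
#' @param evolution_frequency_Hz Evolution (relaxation) field as Larmor
#'   frequency, used to enforce the PP/NP rule (optional).
#' @param polarization_equivalent_frequency_Hz PP polarizing field as Larmor
#'   frequency (default 20 MHz).
#' @param polarization_duration_multiple PP polarization duration in units of
#'   T1 (default 5).
#' @param echo_time_s CPMG echo spacing (default 100 us).
#' @param n_echoes CPMG echo count (default 128).
#' @param relaxation_period_s SR relaxation period (default 300 ms).
#' @return An object of class \code{acq_spec}.
#' @export
acq_spec <- function(sequence = c("PP", "NP", "SR", "CPMG"),
                     n_points = 22,
                     evolution_frequency_Hz = NULL,
                     polarization_equivalent_frequency_Hz = 20e6,
                     polarization_duration_multiple = 5,
                     echo_time_s = 100e-6,
                     n_echoes = 128,
                     relaxation_period_s = 0.3) {
  sequence <- match.arg(sequence)
  if (!is.null(evolution_frequency_Hz)) {
    if (sequence == "PP" && evolution_frequency_Hz >= 10e6)
      stop("PP sequence is used only below 10 MHz", call. = FALSE)
    if (sequence == "NP" && evolution_frequency_Hz < 10e6)
      stop("NP sequence is used only at or above 10 MHz", call. = FALSE)
  }
  structure(list(sequence = sequence, n_points = n_points,
                 evolution_frequency_Hz = evolution_frequency_Hz,
                 polarization_equivalent_frequency_Hz =
                   polarization_equivalent_frequency_Hz,
                 polarization_duration_multiple = polarization_duration_multiple,
                 echo_time_s = echo_time_s, n_echoes = n_echoes,
                 relaxation_period_s = relaxation_period_s),
            class = "acq_spec")
}

#' NMRD profile container
#'
#' A sample's dispersion curve: Larmor frequency, R1 and per-point relative
#' error, with sample and temperature metadata.
#'
#' @param frequency_Hz Positive, pairwise-distinct Larmor frequencies; points
#'   are stored sorted by frequency, so analyses are invariant to input
#'   order.
#' @param R1 Positive relaxation rates (s^-1).
#' @param rel_error Per-point relative errors (default 0.05, the acquisition
#'   bound).
#' @param sample_id Sample label.
#' @param temperature_C Temperature (degC).
#' @return A data.frame of class \code{nmrd_profile} with attributes
#'   \code{sample_id} and \code{temperature_C}.
#' @export
nmrd_profile <- function(frequency_Hz, R1, rel_error = 0.05,
                         sample_id = NA_character_, temperature_C = NA_real_) {
  if (any(frequency_Hz <= 0)) stop("frequencies must be positive", call. = FALSE)
  if (anyDuplicated(frequency_Hz))
    stop("frequencies must be pairwise distinct", call. = FALSE)
  if (any(R1 <= 0)) stop("R1 must be positive", call. = FALSE)
  rel_error <- rep_len(rel_error, length(frequency_Hz))
  if (any(rel_error < 0)) stop("relative errors must be >= 0", call. = FALSE)
  ord <- order(frequency_Hz)
  structure(data.frame(frequency_Hz = frequency_Hz[ord], R1 = R1[ord],
                       rel_error = rel_error[ord]),
            sample_id = sample_id, temperature_C = temperature_C,
            class = c("nmrd_profile", "data.frame"))
}

#' @export
print.nmrd_profile <- function(x, ...) {
  cat(sprintf("NMRD profile: %s at %s degC, %d points (%.3g Hz - %.3g Hz)\n",
              attr(x, "sample_id"), format(attr(x, "temperature_C")),
              nrow(x), min(x$frequency_Hz), max(x$frequency_Hz)))
  print.data.frame(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("  ...\n")
  invisible(x)
}

#' Magnetization curve container
#'
#' @param times_s Strictly increasing sampling times (s).
#' @param amplitudes Signal amplitudes (arbitrary units).
#' @param spec The \code{\link{acq_spec}} the curve was acquired with.
#' @param truth Optional list of generating parameters.
#' @return A data.frame of class \code{magnetization_curve} with attributes
#'   \code{spec} and \code{truth}.
#' @export
magnetization_curve <- function(times_s, amplitudes, spec, truth = NULL) {
  stopifnot(inherits(spec, "acq_spec"))
  if (is.unsorted(times_s, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  if (length(times_s) != length(amplitudes))
    stop("times and amplitudes differ in length", call. = FALSE)
  structure(data.frame(time_s = times_s, amplitude = amplitudes),
            spec = spec, truth = truth,
            class = c("magnetization_curve", "data.frame"))
}

#' @export
print.magnetization_curve <- function(x, ...) {
  sp <- attr(x, "spec")
  cat(sprintf("Magnetization curve: %s sequence, %d points, t in [%.3g, %.3g] s\n",
              sp$sequence, nrow(x), min(x$time_s), max(x$time_s)))
  invisible(x)
}

#' Logarithmic frequency grid with extra points
#'
#' \code{n} log-spaced Larmor frequencies between \code{f_min} and
#' \code{f_max}, merged with \code{extra_points}, deduplicated and sorted.
#'
#' @param f_min,f_max Grid bounds (Hz, positive, \code{f_max > f_min}).
#' @param n Number of log-spaced points (>= 2).
#' @param extra_points Additional frequencies (Hz), e.g. a high-field point
#'   at 500 MHz.
#' @return Sorted numeric vector of frequencies (Hz).
#' @examples
#' make_frequency_grid(1e4, 2e7, 31, extra_points = 5e8)
#' @export
make_frequency_grid <- function(f_min, f_max, n, extra_points = numeric(0)) {
  if (f_min <= 0 || f_max <= f_min) stop("need 0 < f_min < f_max", call. = FALSE)
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  if (length(extra_points) && any(extra_points <= 0))
    stop("extra points must be positive", call. = FALSE)
  grid <- 10^seq(log10(f_min), log10(f_max), length.out = n)
  grid[c(1, n)] <- c(f_min, f_max)  # exact endpoints
  out <- sort(c(grid, extra_points))
  # drop near-duplicates (relative spacing below 1e-12)
  keep <- c(TRUE, diff(out) / out[-length(out)] > 1e-12)
  out[keep]
}

#' Simulate an NMRD profile from composite model parameters
#'
#' Evaluates the forward model on the frequency grid and applies independent
#' relative Gaussian noise: \code{R1 = total_r1 * (1 + N(0, noise_fraction))}.
#' The per-point relative error stored in the profile equals
#' \code{noise_fraction}; fitters fall back to the 5% acquisition bound when
#' it is zero.
#'
#' @param params A \code{\link{composite_params}} object.
#' @param grid Frequencies (Hz).
#' @param noise_fraction Relative noise level (default 0.05, the stated
#'   acquisition bound; must be >= 0).
#' @param seed Integer seed; same seed, same profile.
#' @param sample_id,temperature_C Metadata carried into the profile.
#' @param constants \code{\link{physical_constants}}.
#' @return An \code{\link{nmrd_profile}}.
#' @export
simulate_nmrd_profile <- function(params, grid, noise_fraction = 0.05,
                                  seed = 1L, sample_id = NA_character_,
                                  temperature_C = NA_real_,
                                  constants = physical_constants()) {
  if (noise_fraction < 0) stop("noise_fraction must be >= 0", call. = FALSE)
  r1 <- total_r1(larmor_to_omega(grid), params, constants)
  if (noise_fraction > 0) {
    r1 <- withr::with_seed(as.integer(seed),
                           r1 * (1 + stats::rnorm(length(r1), 0, noise_fraction)))
  }
  nmrd_profile(grid, r1, rel_error = noise_fraction,
               sample_id = sample_id, temperature_C = temperature_C)
}

#' Simulate a mono-exponential magnetization curve
#'
#' \code{M(t) = M_inf + (M0 - M_inf) exp(-t/T1)} sampled at
#' \code{spec$n_points} log-spaced delays spanning [T1/50, 5 T1], with
#' additive Gaussian noise.  PP acquisition decays from the pre-polarized
#' level (\code{M0 > M_inf}); NP and SR recover from \code{M0} (~0) towards
#' \code{M_inf}.
#'
#' @param T1 Spin-lattice relaxation time (s, > 0).
#' @param spec An \code{\link{acq_spec}} with sequence PP, NP or SR.
#' @param M0 Initial amplitude (default: sequence-appropriate).
#' @param M_inf Asymptotic amplitude.
#' @param noise_sd Additive noise standard deviation (amplitude units).
#' @param seed Integer seed.
#' @return A \code{\link{magnetization_curve}} whose \code{truth} attribute
#'   records the generating parameters.
#' @export
simulate_magnetization_curve <- function(T1, spec, M0 = NULL, M_inf = NULL,
                                         noise_sd = 0, seed = 1L) {
  stopifnot(inherits(spec, "acq_spec"))
  if (T1 <= 0) stop("T1 must be positive", call. = FALSE)
  if (!spec$sequence %in% c("PP", "NP", "SR"))
    stop("unknown sequence for a T1 curve: ", spec$sequence, call. = FALSE)
  if (is.null(M0)) M0 <- if (spec$sequence == "PP") 1 else 0
  if (is.null(M_inf)) M_inf <- if (spec$sequence == "PP") 0.2 else 1
  times <- exp(seq(log(T1 / 50), log(5 * T1), length.out = spec$n_points))
  amp <- M_inf + (M0 - M_inf) * exp(-times / T1)
  if (noise_sd > 0) {
    amp <- withr::with_seed(as.integer(seed),
                            amp + stats::rnorm(length(amp), 0, noise_sd))
  }
  magnetization_curve(times, amp, spec,
                      truth = list(T1 = T1, M0 = M0, M_inf = M_inf,
                                   noise_sd = noise_sd, seed = seed))
}

#' Simulate a CPMG echo-decay curve
#'
#' Multi-exponential transverse decay sampled at the echo maxima
#' \code{t_k = k * echo_time}, k = 1..n_echoes:
#' \code{A(t_k) = sum_i fraction_i exp(-t_k/T2_i)} plus additive Gaussian
#' noise expressed as a fraction of the initial (t = 0) amplitude.
#'
#' @param components Two-column object (list or matrix) with \code{T2} (s)
#'   and \code{fraction}; fractions must sum to 1.
#' @param spec An \code{\link{acq_spec}} with sequence CPMG.
#' @param noise_sd Noise standard deviation as a ratio of the initial
#'   amplitude (default 0).
#' @param seed Integer seed.
#' @return A \code{\link{magnetization_curve}}.
#' @examples
#' sp <- acq_spec("CPMG", n_echoes = 256)
#' simulate_cpmg_decay(list(T2 = c(2.31e-3, 13.17e-3),
#'                          fraction = c(0.545, 0.455)), sp)
#' @export
simulate_cpmg_decay <- function(components, spec = acq_spec("CPMG"),
                                noise_sd = 0, seed = 1L) {
  stopifnot(inherits(spec, "acq_spec"))
  if (spec$sequence != "CPMG")
    stop("spec$sequence must be CPMG", call. = FALSE)
  T2 <- components$T2
  frac <- components$fraction
  if (any(T2 <= 0)) stop("T2 values must be positive", call. = FALSE)
  if (abs(sum(frac) - 1) > 1e-9)
    stop("fractions must sum to 1", call. = FALSE)
  times <- seq_len(spec$n_echoes) * spec$echo_time_s
  amp <- as.vector(exp(-outer(times, T2, `/`)) %*% frac)
  if (noise_sd > 0) {
    amp <- withr::with_seed(as.integer(seed),
                            amp + stats::rnorm(length(amp), 0, noise_sd))
  }
  magnetization_curve(times, amp, spec,
                      truth = list(T2 = T2, fraction = frac,
                                   noise_sd = noise_sd, seed = seed))
}
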