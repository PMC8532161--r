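# Weighted nonlinear fitting of the composite relaxation model to NMRD
# profiles: a two-stage protocol in which the reference-temperature (25 degC)
# profile is fitted with six free parameters (C_intra, tau_rot, D_MM, D_LM,
# N_MM, N_LM) and the low-temperature profile with four, the spin densities
# frozen at their reference values.  d and delta_rot are fixed throughout.

#' Fitting protocol for the joint NMRD fit
#'
#' @param d_A Closest-approach distance, fixed during fitting (Angstrom,
#'   default 3.6).
#' @param delta_rot_fixed Width of the log-Gaussian correlation-time
#'   distribution, fixed during fitting (default 1.5).
#' @param share_spin_densities If TRUE (default), N_MM and N_LM are free only
#'   at the reference temperature and frozen for the other.
#' @param bounds Named list of c(lower, upper) parameter ranges in natural
#'   units: \code{C_intra} (s^-2), \code{tau_rot} (s), \code{D} (m^2/s),
#'   \code{N} (m^-3).  Defaults bracket typical gel values by at least two
#'   orders of magnitude.
#' @param n_multistart Number of multistart optimizations per stage (default
#'   16): one start at the centre of the log-parameter box, the rest
#'   log-uniform over the bounds.
#' @param seed Integer seed controlling the multistart draws.
#' @param maxiter Maximum Levenberg-Marquardt iterations per start.
#' @param downweight_window_Hz Optional c(lo, hi) frequency window whose
#'   points are down-weighted (for unmodeled structured residuals such as a
#'   low-frequency relaxation enhancement).
#' @param downweight_factor Multiplier on the weight of points inside the
#'   window (default 0.1).
#' @return An object of class \code{fit_protocol}.
#' @export
fit_protocol <- function(d_A = 3.6, delta_rot_fixed = 1.5,
                         share_spin_densities = TRUE,
                         bounds = list(C_intra = c(1e8, 1e10),
                                       tau_rot = c(1e-12, 1e-6),
                                       D = c(1e-14, 1e-9),
                                       N = c(1e27, 1e29)),
                         n_multistart = 16, seed = 1L, maxiter = 200,
                         downweight_window_Hz = NULL,
                         downweight_factor = 0.1) {
  stopifnot(d_A > 0, delta_rot_fixed >= 0, n_multistart >= 1)
  for (b in bounds) stopifnot(length(b) == 2, b[1] > 0, b[2] > b[1])
  structure(list(d_A = d_A, delta_rot_fixed = delta_rot_fixed,
                 share_spin_densities = share_spin_densities,
                 bounds = bounds, n_multistart = n_multistart,
                 seed = as.integer(seed), maxiter = maxiter,
                 downweight_window_Hz = downweight_window_Hz,
                 downweight_factor = downweight_factor),
            class = "fit_protocol")
}

# forward model without container overhead, used inside the optimizer
.model_r1_raw <- function(nu_Hz, C_intra, tau_rot, D_mm, N_mm, D_lm, N_lm,
                          d, delta_rot, constants) {
  omega <- larmor_to_omega(nu_Hz)
  rot <- rotational_r1_distributed(
    omega, structure(list(C_intra = C_intra, tau_rot = tau_rot,
                          delta_rot = delta_rot), class = "rotational_params"))
  ci <- c_inter(constants)
  tr <- function(D, N) {
    if (N == 0) return(0)
    tau <- d^2 / (6 * D)
    x <- omega * tau
    ci * N * tau / d^3 * (torrey_f(x) + 4 * torrey_f(2 * x))
  }
  rot + tr(D_mm, N_mm) + tr(D_lm, N_lm)
}

.profile_sigma <- function(profile, protocol) {
  rel <- profile$rel_error
  rel[!is.finite(rel) | rel <= 0] <- 0.05  # acquisition bound fallback
  sigma <- rel * profile$R1
  if (!is.null(protocol$downweight_window_Hz)) {
    win <- protocol$downweight_window_Hz
    inside <- profile$frequency_Hz >= win[1] & profile$frequency_Hz <= win[2]
    sigma[inside] <- sigma[inside] / protocol$downweight_factor
  }
  sigma
}

# Multistart Levenberg-Marquardt over log10 parameters, in two phases:
# a broad triage pass (many starts, few iterations) followed by a full
# polish of the best few candidates.  This finds the global optimum far more
# reliably than the same budget spent on full runs from every start.
.multistart_lm <- function(resid_fn, lower_log, upper_log, protocol,
                           stage_seed) {
  n_par <- length(lower_log)
  mid <- (lower_log + upper_log) / 2
  n_triage <- max(2L * protocol$n_multistart, 8L)
  starts <- withr::with_seed(stage_seed, {
    rand <- matrix(stats::runif((n_triage - 1) * n_par), ncol = n_par)
    rbind(mid, sweep(sweep(rand, 2, upper_log - lower_log, `*`),
                     2, lower_log, `+`))
  })
  run <- function(par, iter) {
    tryCatch(
      minpack.lm::nls.lm(par = par, lower = lower_log, upper = upper_log,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = iter)),
      error = function(e) e)
  }
  triage <- lapply(seq_len(nrow(starts)), function(i)
    run(starts[i, ], min(40L, protocol$maxiter)))
  ok <- !vapply(triage, inherits, logical(1), "error")
  if (!any(ok))
    stop("no multistart converged; attempt diagnostics: ",
         paste(vapply(triage, conditionMessage, character(1)),
               collapse = "; "), call. = FALSE)
  dev <- vapply(triage[ok], function(f) f$deviance, numeric(1))
  keep <- order(dev)[seq_len(min(max(4L, protocol$n_multistart %/% 4L),
                                 sum(ok)))]
  best <- NULL
  for (cand in triage[ok][keep]) {
    fit <- run(cand$par, protocol$maxiter)
    if (inherits(fit, "error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) best <- triage[ok][[which.min(dev)]]
  best
}

.se_from_fit <- function(fit) {
  # one-standard-error estimates in log10 space -> relative errors in natural
  # units via the delta method
  dof <- max(length(fit$fvec) - length(fit$par), 1)
  s2 <- fit$deviance / dof
  cov_log <- tryCatch(s2 * solve(fit$hessian), error = function(e) NULL)
  if (is.null(cov_log)) return(rep(NA_real_, length(fit$par)))
  se_log <- sqrt(pmax(diag(cov_log), 0))
  se_log * log(10) * 10^fit$par
}

#' Two-stage joint fit of NMRD profiles at two temperatures
#'
#' Stage 1 fits the reference-temperature profile with six free parameters
#' (C_intra, tau_rot, D_MM, D_LM, N_MM, N_LM); stage 2 fits the
#' low-temperature profile with four free parameters, the spin densities
#' frozen at their stage-1 values.  Each stage minimizes the
#' error-weighted sum of squares sum(((R1_obs - R1_model)/(rel_error *
#' R1_obs))^2) by bounded Levenberg-Marquardt with seeded multistart;
#' parameters are optimized on a log10 scale.  After each stage the
#' translational pools are relabelled so that D_MM > D_LM.
#'
#' @param profile_25C Reference-temperature \code{\link{nmrd_profile}}
#'   (>= 8 points).
#' @param profile_4C Low-temperature profile, or NULL for a
#'   reference-temperature-only fit.
#' @param protocol A \code{\link{fit_protocol}}.
#' @param constants \code{\link{physical_constants}}.
#' @return An object of class \code{nmrd_joint_fit}: per-temperature
#'   \code{\link{composite_params}}, shared spin densities, per-point
#'   residuals, parameter standard errors, and goodness-of-fit summaries.
#' @export
fit_nmrd_joint <- function(profile_25C, profile_4C = NULL,
                           protocol = fit_protocol(),
                           constants = physical_constants()) {
  stopifnot(inherits(profile_25C, "nmrd_profile"),
            inherits(protocol, "fit_protocol"))
  if (nrow(profile_25C) < 8)
    stop("reference profile has fewer than 8 points", call. = FALSE)
  if (!is.null(profile_4C)) {
    stopifnot(inherits(profile_4C, "nmrd_profile"))
    if (nrow(profile_4C) < 8)
      stop("low-temperature profile has fewer than 8 points", call. = FALSE)
  }
  d <- angstrom_to_m(protocol$d_A)
  delta_rot <- protocol$delta_rot_fixed
  b <- protocol$bounds

  # ---- stage 1: six free parameters at the reference temperature ----
  sig1 <- .profile_sigma(profile_25C, protocol)
  nu1 <- profile_25C$frequency_Hz
  obs1 <- profile_25C$R1
  resid1 <- function(p) {
    v <- 10^p
    (obs1 - .model_r1_raw(nu1, v[1], v[2], v[3], v[4], v[5], v[6],
                          d, delta_rot, constants)) / sig1
  }
  lower1 <- log10(c(b$C_intra[1], b$tau_rot[1], b$D[1], b$N[1], b$D[1], b$N[1]))
  upper1 <- log10(c(b$C_intra[2], b$tau_rot[2], b$D[2], b$N[2], b$D[2], b$N[2]))
  fit1 <- .multistart_lm(resid1, lower1, upper1, protocol, protocol$seed)
  v1 <- 10^fit1$par
  se1 <- .se_from_fit(fit1)
  # relabel so that pool 1 is the faster-diffusing (MM) one
  if (v1[3] < v1[5]) {
    v1 <- v1[c(1, 2, 5, 6, 3, 4)]
    se1 <- se1[c(1, 2, 5, 6, 3, 4)]
  }
  names(v1) <- names(se1) <- c("C_intra", "tau_rot", "D_MM", "N_MM",
                               "D_LM", "N_LM")
  N_shared <- v1[c("N_MM", "N_LM")]

  params_ref <- composite_params(
    rotational_params(v1[["C_intra"]], v1[["tau_rot"]] * 1e9, delta_rot),
    translational_params(v1[["D_MM"]], v1[["N_MM"]], protocol$d_A),
    translational_params(v1[["D_LM"]], v1[["N_LM"]], protocol$d_A))

  out <- list(
    sample_id = attr(profile_25C, "sample_id"),
    protocol = protocol,
    shared_N = N_shared,
    temperatures = list())
  t_ref <- attr(profile_25C, "temperature_C")
  if (is.na(t_ref)) t_ref <- 25
  out$temperatures[[as.character(t_ref)]] <- list(
    params = params_ref, estimates = v1, se = se1,
    residuals = fit1$fvec, chisq = fit1$deviance,
    reduced_chisq = fit1$deviance / max(nrow(profile_25C) - 6, 1),
    n_free = 6L, profile = profile_25C)

  # ---- stage 2: four free parameters, spin densities frozen ----
  if (!is.null(profile_4C)) {
    sig2 <- .profile_sigma(profile_4C, protocol)
    nu2 <- profile_4C$frequency_Hz
    obs2 <- profile_4C$R1
    if (protocol$share_spin_densities) {
      resid2 <- function(p) {
        v <- 10^p
        (obs2 - .model_r1_raw(nu2, v[1], v[2], v[3], N_shared[["N_MM"]],
                              v[4], N_shared[["N_LM"]],
                              d, delta_rot, constants)) / sig2
      }
      lower2 <- log10(c(b$C_intra[1], b$tau_rot[1], b$D[1], b$D[1]))
      upper2 <- log10(c(b$C_intra[2], b$tau_rot[2], b$D[2], b$D[2]))
      fit2 <- .multistart_lm(resid2, lower2, upper2, protocol,
                             protocol$seed + 1L)
      v2raw <- 10^fit2$par
      se2raw <- .se_from_fit(fit2)
      # frozen N are carried over bit-identically
      v2 <- c(v2raw[1:3], N_shared[["N_MM"]], v2raw[4], N_shared[["N_LM"]])
      se2 <- c(se2raw[1:3], NA_real_, se2raw[4], NA_real_)
      n_free2 <- 4L
    } else {
      fit2 <- .multistart_lm(function(p) {
        v <- 10^p
        (obs2 - .model_r1_raw(nu2, v[1], v[2], v[3], v[4], v[5], v[6],
                              d, delta_rot, constants)) / sig2
      }, lower1, upper1, protocol, protocol$seed + 1L)
      v2 <- 10^fit2$par
      se2 <- .se_from_fit(fit2)
      n_free2 <- 6L
    }
    if (v2[3] < v2[5]) {
      v2 <- v2[c(1, 2, 5, 6, 3, 4)]
      se2 <- se2[c(1, 2, 5, 6, 3, 4)]
    }
    names(v2) <- names(se2) <- names(v1)
    params_low <- composite_params(
      rotational_params(v2[["C_intra"]], v2[["tau_rot"]] * 1e9, delta_rot),
      translational_params(v2[["D_MM"]], v2[["N_MM"]], protocol$d_A),
      translational_params(v2[["D_LM"]], v2[["N_LM"]], protocol$d_A))
    t_low <- attr(profile_4C, "temperature_C")
    if (is.na(t_low)) t_low <- 4
    out$temperatures[[as.character(t_low)]] <- list(
      params = params_low, estimates = v2, se = se2,
      residuals = fit2$fvec, chisq = fit2$deviance,
      reduced_chisq = fit2$deviance / max(nrow(profile_4C) - n_free2, 1),
      n_free = n_free2, profile = profile_4C)
    # physical-consistency check: slower dynamics at the lower temperature
    if (v2[["tau_rot"]] < v1[["tau_rot"]] ||
        v2[["D_MM"]] > v1[["D_MM"]] || v2[["D_LM"]] > v1[["D_LM"]])
      warning("fitted dynamics at the lower temperature are faster than at ",
              "the reference temperature; check the fit", call. = FALSE)
  }
  class(out) <- "nmrd_joint_fit"
  out
}

#' @export
print.nmrd_joint_fit <- function(x, ...) {
  cat(sprintf("Joint NMRD fit%s\n",
              if (is.na(x$sample_id)) "" else paste0(" for ", x$sample_id)))
  for (tc in names(x$temperatures)) {
    st <- x$temperatures[[tc]]
    v <- st$estimates
    cat(sprintf("  %s degC: C_intra = %.3g s^-2, tau_rot = %.3g ns, D_MM = %.3g, D_LM = %.3g m^2/s\n",
                tc, v[["C_intra"]], v[["tau_rot"]] * 1e9, v[["D_MM"]],
                v[["D_LM"]]))
    cat(sprintf("          chi^2 = %.4g (reduced %.3g, %d free parameters)\n",
                st$chisq, st$reduced_chisq, st$n_free))
  }
  cat(sprintf("  shared N_MM = %.3g, N_LM = %.3g m^-3\n",
              x$shared_N[["N_MM"]], x$shared_N[["N_LM"]]))
  invisible(x)
}

#' Deconvolve a fitted model into its component contributions
#'
#' Evaluates the rotational, MM-translational and LM-translational
#' contributions of a fitted model on a frequency grid; their pointwise sum
#' equals the fitted total exactly.
#'
#' @param result An \code{\link{nmrd_joint_fit}}.
#' @param grid Frequencies (Hz).
#' @param constants \code{\link{physical_constants}}.
#' @return A data.frame with columns \code{temperature_C},
#'   \code{frequency_Hz}, \code{rotational}, \code{trans_MM},
#'   \code{trans_LM}, \code{total}.
#' @export
deconvolve_contributions <- function(result, grid,
                                     constants = physical_constants()) {
  stopifnot(inherits(result, "nmrd_joint_fit"))
  do.call(rbind, lapply(names(result$temperatures), function(tc) {
    comp <- r1_components(larmor_to_omega(grid),
                          result$temperatures[[tc]]$params, constants)
    data.frame(temperature_C = as.numeric(tc), frequency_Hz = grid,
               rotational = comp[, "rotational"],
               trans_MM = comp[, "trans_MM"], trans_LM = comp[, "trans_LM"],
               total = comp[, "rotational"] + comp[, "trans_MM"] +
                 comp[, "trans_LM"])
  }))
}

#' Derived spin-density quantities
#'
#' Total proton density N = N_MM + N_LM, the pool ratio N_MM/N_LM (reported
#' rounded to one decimal), and relative changes of N and moisture against a
#' reference sample.
#'
#' @param result An \code{\link{nmrd_joint_fit}} or a list/vector with
#'   elements \code{N_MM} and \code{N_LM}.
#' @param reference Optional reference in the same forms; relative change in
#'   N is computed against its total.
#' @param moisture_pct Optional sample moisture (%).
#' @param reference_moisture_pct Optional reference moisture (%).
#' @return An object of class \code{derived_quantities} with fields
#'   \code{N_total}, \code{ratio}, \code{ratio_reported},
#'   \code{relative_change_N}, \code{relative_change_moisture}.
#' @export
derive_quantities <- function(result, reference = NULL,
                              moisture_pct = NA_real_,
                              reference_moisture_pct = NA_real_) {
  getN <- function(x) {
    if (inherits(x, "nmrd_joint_fit")) return(x$shared_N)
    c(N_MM = x[["N_MM"]], N_LM = x[["N_LM"]])
  }
  N <- getN(result)
  N_total <- N[["N_MM"]] + N[["N_LM"]]
  ratio <- if (N[["N_LM"]] == 0) NA_real_ else N[["N_MM"]] / N[["N_LM"]]
  rel_N <- NA_real_
  if (!is.null(reference)) {
    Nref <- getN(reference)
    rel_N <- relative_change(N_total, Nref[["N_MM"]] + Nref[["N_LM"]])
  }
  rel_m <- if (is.na(moisture_pct) || is.na(reference_moisture_pct))
    NA_real_ else relative_change(moisture_pct, reference_moisture_pct)
  structure(list(N_total = N_total, ratio = ratio,
                 ratio_reported = round(ratio, 1),
                 relative_change_N = rel_N,
                 relative_change_moisture = rel_m),
            class = "derived_quantities")
}

#' @export
print.derived_quantities <- function(x, ...) {
  cat(sprintf("N_total = %.3g m^-3, N_MM/N_LM = %s\n", x$N_total,
              if (is.na(x$ratio)) "undefined (N_LM = 0)"
              else format(x$ratio_reported)))
  if (!is.na(x$relative_change_N))
    cat(sprintf("relative change in N vs reference: %.3g\n",
                x$relative_change_N))
  if (!is.na(x$relative_change_moisture))
    cat(sprintf("relative change in moisture vs reference: %.3g\n",
                x$relative_change_moisture))
  invisible(x)
}

#' Low-frequency authenticity discriminant
#'
#' Computes the mean R1 over all profile points below the cutoff frequency
#' and ranks the profiles; the one with the lowest low-frequency amplitude is
#' flagged as the original-like (sucrose-type) sample.
#'
#' @param profiles List of \code{\link{nmrd_profile}} objects at the same
#'   temperature (>= 2).
#' @param cutoff_Hz Frequency cutoff (default 1 MHz).
#' @return An object of class \code{lf_discriminant}: a ranking table,
#'   the flagged \code{original_like} sample and a \code{tie} flag.
#' @export
low_frequency_discriminant <- function(profiles, cutoff_Hz = 1e6) {
  if (length(profiles) < 2)
    stop("need at least 2 profiles", call. = FALSE)
  stats_df <- do.call(rbind, lapply(profiles, function(p) {
    stopifnot(inherits(p, "nmrd_profile"))
    low <- p$frequency_Hz < cutoff_Hz
    if (!any(low))
      stop("profile '", attr(p, "sample_id"), "' has no points below ",
           cutoff_Hz, " Hz", call. = FALSE)
    data.frame(sample_id = attr(p, "sample_id"),
               temperature_C = attr(p, "temperature_C"),
               mean_R1_low = mean(p$R1[low]), n_low = sum(low))
  }))
  stats_df <- stats_df[order(stats_df$mean_R1_low), ]
  stats_df$rank <- seq_len(nrow(stats_df))
  rownames(stats_df) <- NULL
  lowest <- stats_df$mean_R1_low[1]
  tie <- sum(stats_df$mean_R1_low == lowest) > 1
  structure(list(ranking = stats_df,
                 original_like = if (tie) NA_character_ else
                   stats_df$sample_id[1],
                 tie = tie, cutoff_Hz = cutoff_Hz),
            class = "lf_discriminant")
}

#' @export
print.lf_discriminant <- function(x, ...) {
  cat(sprintf("Low-frequency discriminant (mean R1 below %.3g Hz)\n",
              x$cutoff_Hz))
  print(x$ranking)
  if (x$tie) cat("tie: no unique original-like sample\n")
  else cat("original-like sample:", x$original_like, "\n")
  invisible(x)
}
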