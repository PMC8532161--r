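# End-to-end pipeline: synthetic generation -> NMRD fitting -> T2 analysis
# -> reporting.  The cmd_* functions are also the backend of the thin
# command-line wrapper shipped under inst/scripts/.

#' Pipeline configuration
#'
#' @param samples Sample names drawn from the built-in fixture registry
#'   (default: all of \code{\link{sample_names}()}).
#' @param out_dir Output directory (created if absent).
#' @param seed Global integer seed; per-sample seeds are derived from it.
#' @param reference Reference sample for relative changes (default "SUC").
#' @param noise_fraction Relative noise on simulated R1 (default 0.05, the
#'   acquisition error bound).
#' @param grid Frequency grid for simulated profiles (default 31 log-spaced
#'   points 10 kHz - 20 MHz plus 500 MHz).
#' @param cpmg_echoes CPMG echo count for simulated decays (default 256; the
#'   instrument's 128-echo setting is available but undersamples the slow
#'   component).
#' @param cpmg_noise_sd CPMG noise (ratio of initial amplitude, default 0.01).
#' @param protocol A \code{\link{fit_protocol}} used by \code{cmd_fit}.
#' @param temperatures Temperatures to simulate/fit (degC).
#' @param verbose Print per-stage progress.
#' @return An object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(samples = sample_names(), out_dir = tempdir(),
                            seed = 1L, reference = "SUC",
                            noise_fraction = 0.05,
                            grid = make_frequency_grid(1e4, 2e7, 31,
                                                       extra_points = 5e8),
                            cpmg_echoes = 256, cpmg_noise_sd = 0.01,
                            protocol = fit_protocol(seed = seed),
                            temperatures = c(25, 4), verbose = FALSE) {
  for (s in samples) sample_fixture(s)  # validates names early
  structure(list(samples = samples, out_dir = out_dir,
                 seed = as.integer(seed), reference = reference,
                 noise_fraction = noise_fraction, grid = grid,
                 cpmg_echoes = cpmg_echoes, cpmg_noise_sd = cpmg_noise_sd,
                 protocol = protocol, temperatures = temperatures,
                 verbose = verbose),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of \code{\link{pipeline_config}};
#' a \code{protocol} block mirrors \code{\link{fit_protocol}}.
#'
#' @param path YAML file.
#' @return A \code{\link{pipeline_config}}.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), "protocol")]
  if (!is.null(y$protocol))
    args$protocol <- do.call(fit_protocol, y$protocol)
  if (!is.null(args$grid)) args$grid <- as.numeric(args$grid)
  do.call(pipeline_config, args)
}

.cfg_note <- function(config) {
  sprintf("# seed: %d | config: %s", config$seed, config_fingerprint(
    config[c("samples", "seed", "noise_fraction", "cpmg_echoes",
             "cpmg_noise_sd", "temperatures")]))
}

.sample_seed <- function(config, sample, offset = 0L) {
  # deterministic per-sample seed, kept within 32-bit range
  (config$seed * 1009L + match(sample, sample_names()) * 101L + offset) %%
    2147483647L
}

#' Simulate the full synthetic data set
#'
#' For every configured sample, writes one NMRD profile CSV per temperature
#' (with a ground-truth JSON sidecar) and one CPMG decay CSV.  Idempotent
#' given the seed: numeric columns are byte-identical across reruns.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @return Invisibly, a character vector of the files written.
#' @export
cmd_simulate <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(config$out_dir, 2) != 0)
    stop("output directory is not writable: ", config$out_dir, call. = FALSE)
  written <- character(0)
  for (s in config$samples) {
    fx <- sample_fixture(s)
    truth <- list(sample = s, seed = config$seed,
                  noise_fraction = config$noise_fraction, nmrd = list())
    for (tc in config$temperatures) {
      p <- simulate_nmrd_profile(
        fixture_params(s, tc), config$grid,
        noise_fraction = config$noise_fraction,
        seed = .sample_seed(config, s, as.integer(tc)),
        sample_id = s, temperature_C = tc)
      f <- file.path(config$out_dir, sprintf("%s_nmrd_%gC.csv", s, tc))
      write_nmrd_profile(p, f, extra_comments = .cfg_note(config))
      truth$nmrd[[as.character(tc)]] <- as.list(fx$nmrd[[as.character(tc)]])
      written <- c(written, f)
    }
    decay <- simulate_cpmg_decay(
      list(T2 = fx$t2$T2_ms / 1e3, fraction = fx$t2$RA_pct / 100),
      acq_spec("CPMG", n_echoes = config$cpmg_echoes),
      noise_sd = config$cpmg_noise_sd,
      seed = .sample_seed(config, s, 999L))
    fd <- file.path(config$out_dir, sprintf("%s_cpmg.csv", s))
    write_curve(decay, fd, extra_comments = .cfg_note(config))
    truth$t2 <- fx$t2
    fj <- file.path(config$out_dir, sprintf("%s_truth.json", s))
    jsonlite::write_json(truth, fj, auto_unbox = TRUE, digits = NA)
    written <- c(written, fd, fj)
    if (config$verbose) message("simulated ", s)
  }
  invisible(written)
}

#' Fit NMRD profiles and report derived quantities
#'
#' Runs the two-stage joint fit per sample on the profile CSVs under the
#' configured output directory, derives the spin-density quantities against
#' the reference sample, applies the low-frequency discriminant across
#' samples at each temperature, and writes a fitted-parameter summary
#' (CSV + JSON) plus a tidy CSV of deconvolved component curves.  A fit
#' failure is recorded per sample without aborting the batch; a missing
#' low-temperature profile degrades to a reference-temperature-only fit with
#' a warning.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @return Invisibly, a list with the per-sample fits, the summary
#'   data.frame and the discriminant results.
#' @export
cmd_fit <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t_ref <- config$temperatures[1]
  t_low <- if (length(config$temperatures) > 1) config$temperatures[2] else NULL
  fits <- list()
  failures <- list()
  profiles_by_temp <- stats::setNames(
    vector("list", length(config$temperatures)),
    as.character(config$temperatures))
  for (s in config$samples) {
    f_ref <- file.path(config$out_dir, sprintf("%s_nmrd_%gC.csv", s, t_ref))
    if (!file.exists(f_ref)) {
      failures[[s]] <- paste("missing profile file", f_ref)
      next
    }
    p_ref <- read_nmrd_profile(f_ref)
    p_low <- NULL
    if (!is.null(t_low)) {
      f_low <- file.path(config$out_dir, sprintf("%s_nmrd_%gC.csv", s, t_low))
      if (file.exists(f_low)) p_low <- read_nmrd_profile(f_low)
      else warning("missing ", t_low, " degC profile for ", s,
                   "; fitting the reference temperature only", call. = FALSE)
    }
    for (tc in as.character(config$temperatures)) {
      pp <- if (tc == as.character(t_ref)) p_ref else p_low
      if (!is.null(pp))
        profiles_by_temp[[tc]] <- c(profiles_by_temp[[tc]], list(pp))
    }
    fit <- tryCatch(fit_nmrd_joint(p_ref, p_low, config$protocol),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      failures[[s]] <- conditionMessage(fit)
    } else {
      fits[[s]] <- fit
    }
    if (config$verbose) message("fitted ", s)
  }
  ref_fit <- fits[[config$reference]]
  summary_rows <- list()
  for (s in names(fits)) {
    fx <- sample_fixture(s)
    ref_fx <- sample_fixture(config$reference)
    dq <- derive_quantities(
      fits[[s]],
      reference = ref_fit,
      moisture_pct = fx$moisture_pct,
      reference_moisture_pct = ref_fx$moisture_pct)
    for (tc in names(fits[[s]]$temperatures)) {
      v <- fits[[s]]$temperatures[[tc]]$estimates
      se <- fits[[s]]$temperatures[[tc]]$se
      summary_rows[[length(summary_rows) + 1]] <- data.frame(
        sample = s, moisture_pct = fx$moisture_pct,
        relative_change_moisture = dq$relative_change_moisture,
        temperature_C = as.numeric(tc),
        C_intra_1e9_s2 = v[["C_intra"]] / 1e9,
        C_intra_se_1e9_s2 = se[["C_intra"]] / 1e9,
        tau_rot_ns = v[["tau_rot"]] * 1e9,
        tau_rot_se_ns = se[["tau_rot"]] * 1e9,
        D_MM_1e12_m2s = v[["D_MM"]] / 1e-12,
        D_MM_se_1e12_m2s = se[["D_MM"]] / 1e-12,
        D_LM_1e13_m2s = v[["D_LM"]] / 1e-13,
        D_LM_se_1e13_m2s = se[["D_LM"]] / 1e-13,
        N_MM_1e28_m3 = v[["N_MM"]] / 1e28,
        N_LM_1e28_m3 = v[["N_LM"]] / 1e28,
        N_total_1e28_m3 = dq$N_total / 1e28,
        relative_change_N = dq$relative_change_N,
        ratio_N_MM_N_LM = dq$ratio_reported,
        reduced_chisq = fits[[s]]$temperatures[[tc]]$reduced_chisq)
    }
  }
  summary_df <- if (length(summary_rows)) do.call(rbind, summary_rows)
  else data.frame()
  discriminants <- lapply(profiles_by_temp, function(pl) {
    if (length(pl) >= 2) low_frequency_discriminant(pl) else NULL
  })
  # outputs
  fcsv <- file.path(config$out_dir, "nmrd_fit_summary.csv")
  con <- file(fcsv, "w", encoding = "UTF-8")
  writeLines(c(.provenance_header(), .cfg_note(config)), con)
  utils::write.table(summary_df, con, sep = ",", row.names = FALSE,
                     quote = FALSE)
  close(con)
  report <- list(seed = config$seed,
                 config = config_fingerprint(config$samples),
                 summary = summary_df,
                 failures = failures,
                 discriminant = lapply(discriminants, function(d)
                   if (is.null(d)) NULL else
                     list(original_like = d$original_like,
                          ranking = d$ranking)))
  jsonlite::write_json(report,
                       file.path(config$out_dir, "nmrd_fit_report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  curves <- do.call(rbind, lapply(names(fits), function(s) {
    cc <- deconvolve_contributions(fits[[s]], config$grid)
    cbind(sample = s, cc)
  }))
  if (!is.null(curves))
    utils::write.csv(curves,
                     file.path(config$out_dir, "nmrd_components.csv"),
                     row.names = FALSE)
  invisible(list(fits = fits, summary = summary_df, failures = failures,
                 discriminant = discriminants))
}

#' Discrete and spectral T2 analysis of simulated decays
#'
#' For every sample with a CPMG decay CSV in the output directory: discrete
#' two-component decomposition, regularized inverse-Laplace spectrum and its
#' peak table; writes a per-sample spectrum CSV and a pooled component table
#' (CSV + JSON) shaped like the reported T2/RA tables.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @param n_components Discrete components to fit (default 2).
#' @return Invisibly, a list with per-sample \code{discrete}, \code{spectrum}
#'   and \code{peaks} results.
#' @export
cmd_t2 <- function(config, n_components = 2) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- list()
  rows <- list()
  for (s in config$samples) {
    f <- file.path(config$out_dir, sprintf("%s_cpmg.csv", s))
    if (!file.exists(f)) next
    decay <- read_curve(f)
    disc <- fit_discrete_multiexp(decay, n_components)
    spec <- ilt_t2_spectrum(decay)
    peaks <- spectrum_peaks(spec)
    utils::write.csv(
      data.frame(T2_ms = spec$spectrum$T2_s * 1e3,
                 amplitude = spec$spectrum$amplitude),
      file.path(config$out_dir, sprintf("%s_t2_spectrum.csv", s)),
      row.names = FALSE)
    out[[s]] <- list(discrete = disc, spectrum = spec, peaks = peaks)
    cmp <- disc$components
    rows[[s]] <- data.frame(
      sample = s,
      T2a_ms = cmp$T2_ms[1],
      T2b_ms = if (nrow(cmp) > 1) cmp$T2_ms[2] else NA_real_,
      RA1_pct = cmp$RA_pct[1],
      RA2_pct = if (nrow(cmp) > 1) cmp$RA_pct[2] else NA_real_)
    if (config$verbose) message("T2 analysis: ", s)
  }
  tab <- do.call(rbind, rows)
  if (!is.null(tab)) {
    fcsv <- file.path(config$out_dir, "t2_components.csv")
    con <- file(fcsv, "w", encoding = "UTF-8")
    writeLines(c(.provenance_header(), .cfg_note(config)), con)
    utils::write.table(tab, con, sep = ",", row.names = FALSE, quote = FALSE)
    close(con)
    jsonlite::write_json(tab, file.path(config$out_dir, "t2_components.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(out)
}
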