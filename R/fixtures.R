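# Built-in parameter library for the four confectionery gel formulations:
# SUC (sucrose, original), SBF10 and SCG40/SCG60 (corn-syrup, adulterated).
# NMRD model parameters per temperature, discrete T2 components, moisture,
# CIELAB color and TPA descriptors, keyed by sample name so that tests and
# pipelines can reference them symbolically.

.sample_registry <- list(
  SUC = list(
    moisture_pct = 4,
    nmrd = list(
      `25` = c(C_intra_s2 = 4.20e9, tau_rot_ns = 0.57, delta_rot = 1.5,
               D_mm_m2s = 1.70e-12, N_mm_m3 = 4.39e28,
               D_lm_m2s = 3.90e-13, N_lm_m3 = 1.33e28, d_angstrom = 3.6),
      `4`  = c(C_intra_s2 = 3.86e9, tau_rot_ns = 1.08, delta_rot = 1.5,
               D_mm_m2s = 1.11e-12, N_mm_m3 = 4.39e28,
               D_lm_m2s = 2.71e-13, N_lm_m3 = 1.33e28, d_angstrom = 3.6)),
    t2 = list(T2_ms = c(2.31, 13.17), RA_pct = c(54.5, 45.5)),
    color = c(L = 30.98, a = 0.18, b = 1.05),
    tpa = c(hardness_N = 0.64, cohesiveness = 0.19, springiness_mm = 2.08)
  ),
  SBF10 = list(
    moisture_pct = 8.2,
    nmrd = list(
      `25` = c(C_intra_s2 = 4.95e9, tau_rot_ns = 0.29, delta_rot = 1.5,
               D_mm_m2s = 2.83e-12, N_mm_m3 = 6.57e28,
               D_lm_m2s = 5.43e-13, N_lm_m3 = 3.79e28, d_angstrom = 3.6),
      `4`  = c(C_intra_s2 = 3.86e9, tau_rot_ns = 1.44, delta_rot = 1.5,
               D_mm_m2s = 0.58e-12, N_mm_m3 = 6.57e28,
               D_lm_m2s = 2.06e-13, N_lm_m3 = 3.79e28, d_angstrom = 3.6)),
    t2 = list(T2_ms = c(1.14, 7.38), RA_pct = c(59.5, 40.5)),
    color = c(L = 37.35, a = 0.38, b = 1.29),
    tpa = c(hardness_N = 1.78, cohesiveness = 0.43, springiness_mm = 6.36)
  ),
  SCG40 = list(
    moisture_pct = 7.5,
    nmrd = list(
      `25` = c(C_intra_s2 = 4.45e9, tau_rot_ns = 0.35, delta_rot = 1.5,
               D_mm_m2s = 2.67e-12, N_mm_m3 = 4.48e28,
               D_lm_m2s = 6.65e-13, N_lm_m3 = 5.37e28, d_angstrom = 3.6),
      `4`  = c(C_intra_s2 = 3.43e9, tau_rot_ns = 1.66, delta_rot = 1.5,
               D_mm_m2s = 0.62e-12, N_mm_m3 = 4.48e28,
               D_lm_m2s = 1.84e-13, N_lm_m3 = 5.37e28, d_angstrom = 3.6)),
    t2 = list(T2_ms = c(0.51, 5.59), RA_pct = c(67.5, 32.5)),
    color = c(L = 30.20, a = 0.14, b = 0.38),
    tpa = c(hardness_N = 2.60, cohesiveness = 0.37, springiness_mm = 5.08)
  ),
  SCG60 = list(
    moisture_pct = 9.1,
    nmrd = list(
      `25` = c(C_intra_s2 = 4.01e9, tau_rot_ns = 0.11, delta_rot = 1.5,
               D_mm_m2s = 6.51e-12, N_mm_m3 = 7.24e28,
               D_lm_m2s = 7.11e-13, N_lm_m3 = 6.2e28, d_angstrom = 3.6),
      `4`  = c(C_intra_s2 = 3.19e9, tau_rot_ns = 0.52, delta_rot = 1.5,
               D_mm_m2s = 1.83e-12, N_mm_m3 = 7.24e28,
               D_lm_m2s = 1.62e-13, N_lm_m3 = 6.2e28, d_angstrom = 3.6)),
    t2 = list(T2_ms = c(0.58, 5.17), RA_pct = c(74.5, 25.5)),
    color = c(L = 33.67, a = 0.25, b = 0.65),
    tpa = c(hardness_N = 1.92, cohesiveness = 0.28, springiness_mm = 3.74)
  )
)

#' Names of the built-in sample fixtures
#'
#' @return Character vector of sample names.
#' @export
sample_names <- function() names(.sample_registry)

#' Built-in sample fixture
#'
#' Returns the reported characterization of one gel formulation: NMRD model
#' parameters at 25 and 4 degC (spin densities shared between temperatures),
#' discrete T2 components and relative areas, moisture content, CIELAB color
#' and TPA descriptors.
#'
#' @param name Sample name, one of \code{\link{sample_names}()}.
#' @return A list with elements \code{moisture_pct}, \code{nmrd} (key-value
#'   parameter vectors by temperature, see \code{\link{params_from_kv}}),
#'   \code{t2}, \code{color}, \code{tpa}.
#' @examples
#' fx <- sample_fixture("SUC")
#' params_from_kv(fx$nmrd[["25"]])
#' @export
sample_fixture <- function(name) {
  if (!is.character(name) || length(name) != 1 ||
      !(name %in% names(.sample_registry)))
    stop("unknown sample '", name, "'; available fixtures: ",
         paste(names(.sample_registry), collapse = ", "), call. = FALSE)
  .sample_registry[[name]]
}

#' Composite model parameters of a built-in sample
#'
#' @param name Sample name.
#' @param temperature_C Temperature in degC (25 or 4).
#' @return A \code{\link{composite_params}} object.
#' @export
fixture_params <- function(name, temperature_C = 25) {
  fx <- sample_fixture(name)
  key <- as.character(temperature_C)
  if (!key %in% names(fx$nmrd))
    stop("no fixture parameters at ", temperature_C, " degC; available: ",
         paste(names(fx$nmrd), collapse = ", "), call. = FALSE)
  params_from_kv(fx$nmrd[[key]])
}
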