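#' Physical constants for dipolar relaxation
#'
#' CODATA values of the proton gyromagnetic ratio, the magnetic constant
#' factor mu0/(4 pi) and the reduced Planck constant, bundled so that the
#' intermolecular dipolar constant \code{C_inter = (9/8) (mu0 gamma^2 hbar /
#' (4 pi))^2} entering the translational relaxation contribution is computed,
#' never hard-coded.
#'
#' @param gamma Proton gyromagnetic ratio (rad s^-1 T^-1).
#' @param mu0_over_4pi Magnetic constant factor mu0/(4 pi) (T m A^-1).
#' @param hbar Reduced Planck constant (J s).
#' @return An object of class \code{physical_constants}.
#' @examples
#' const <- physical_constants()
#' c_inter(const)  # ~6.4e-49 m^6 s^-2
#' @export
physical_constants <- function(gamma = 2.6752218744e8,
                               mu0_over_4pi = 1e-7,
                               hbar = 1.054571817e-34) {
  stopifnot(gamma > 0, mu0_over_4pi > 0, hbar > 0)
  structure(list(gamma = gamma, mu0_over_4pi = mu0_over_4pi, hbar = hbar),
            class = "physical_constants")
}

#' Intermolecular dipolar relaxation constant
#'
#' \code{C_inter = (9/8) (mu0 gamma^2 hbar / (4 pi))^2}, the fixed prefactor
#' of the translational (intermolecular) relaxation contribution for like
#' spin-1/2 nuclei.
#'
#' @param constants A \code{\link{physical_constants}} object.
#' @return C_inter in m^6 s^-2.
#' @export
c_inter <- function(constants = physical_constants()) {
  stopifnot(inherits(constants, "physical_constants"))
  (9 / 8) * (constants$mu0_over_4pi * constants$gamma^2 * constants$hbar)^2
}

#' @export
print.physical_constants <- function(x, ...) {
  cat("Physical constants (proton dipolar relaxation)\n")
  cat(sprintf("  gamma        : %.10e rad s^-1 T^-1\n", x$gamma))
  cat(sprintf("  mu0/(4 pi)   : %.3e T m A^-1\n", x$mu0_over_4pi))
  cat(sprintf("  hbar         : %.9e J s\n", x$hbar))
  cat(sprintf("  C_inter      : %.4e m^6 s^-2\n", c_inter(x)))
  invisible(x)
}
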