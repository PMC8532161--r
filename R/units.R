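# Unit conversions. All internal computation is SI (s, m, rad/s); user-facing
# interfaces accept MHz, ns and Angstrom and convert exactly once, here.

#' Convert Larmor frequency to angular frequency
#'
#' @param nu_Hz Larmor frequency in Hz.
#' @return Angular frequency omega = 2 pi nu in rad/s.
#' @export
larmor_to_omega <- function(nu_Hz) 2 * pi * nu_Hz

#' Convert angular frequency to Larmor frequency
#'
#' @param omega Angular frequency in rad/s.
#' @return Larmor frequency in Hz.
#' @export
omega_to_larmor <- function(omega) omega / (2 * pi)

#' @rdname unit_helpers
#' @name unit_helpers
#' @title Small unit helpers
#' @description \code{mhz_to_hz}, \code{ns_to_s} and \code{angstrom_to_m}
#'   convert the interface units (MHz, ns, Angstrom) to SI.
#' @param x Numeric vector.
#' @return Numeric vector in SI units.
#' @export
mhz_to_hz <- function(x) x * 1e6

#' @rdname unit_helpers
#' @export
ns_to_s <- function(x) x * 1e-9

#' @rdname unit_helpers
#' @export
angstrom_to_m <- function(x) x * 1e-10
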