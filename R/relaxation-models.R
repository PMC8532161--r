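# Forward model of the composite spin-lattice relaxation rate:
# a BPP-type rotational contribution averaged over a log-Gaussian
# distribution of correlation times, plus two Torrey-type translational
# (intermolecular) contributions for a more-mobile (MM) and a less-mobile
# (LM) proton pool.  R1(omega) = R1_rot + R1_trans,MM + R1_trans,LM.

# ---- parameter containers ---------------------------------------------------

#' Rotational relaxation parameters
#'
#' Parameters of the distributed BPP rotational contribution: the
#' intramolecular dipolar relaxation constant \code{C_intra}, the centre
#' \code{tau_rot} of a log-Gaussian distribution of rotational correlation
#' times, and the distribution width \code{delta_rot} in decades of tau.
#'
#' @param C_intra Intramolecular dipolar relaxation constant (s^-2).
#' @param tau_rot_ns Centre of the correlation-time distribution (ns).
#' @param delta_rot Width of the log-Gaussian distribution: the standard
#'   deviation of the Gaussian in ln(tau) (dimensionless, >= 0; the default
#'   1.5 corresponds to about 0.65 decades of tau).
#' @return An object of class \code{rotational_params}; \code{tau_rot} is
#'   stored in seconds.
#' @export
rotational_params <- function(C_intra, tau_rot_ns, delta_rot = 1.5) {
  if (!is.numeric(C_intra) || C_intra <= 0)
    stop("C_intra must be a positive number", call. = FALSE)
  if (!is.numeric(tau_rot_ns) || tau_rot_ns <= 0)
    stop("tau_rot_ns must be a positive number", call. = FALSE)
  if (!is.numeric(delta_rot) || delta_rot < 0)
    stop("delta_rot must be >= 0", call. = FALSE)
  structure(list(C_intra = C_intra, tau_rot = ns_to_s(tau_rot_ns),
                 delta_rot = delta_rot),
            class = "rotational_params")
}

#' Translational relaxation parameters
#'
#' Parameters of one Torrey translational pool.  Only the self-diffusion
#' coefficient \code{D} and the proton density \code{N} are free; under the
#' closest-approach assumption a = d the jump time is derived as
#' \code{tau_trans = d^2/(6 D)} and the reduced jump parameter is fixed at
#' \code{delta_jump = 1/12} (from delta = <a>^2/(12 d^2) with <a>^2 = 6 D tau).
#'
#' @param D Translational self-diffusion coefficient (m^2/s).
#' @param N Proton (spin) density (m^-3).
#' @param d_A Closest approach distance between interacting molecules
#'   (Angstrom, default 3.6).
#' @return An object of class \code{translational_params} with derived
#'   \code{tau_trans} (s) and \code{delta_jump}.
#' @export
translational_params <- function(D, N, d_A = 3.6) {
  if (!is.numeric(D) || D <= 0) stop("D must be positive", call. = FALSE)
  if (!is.numeric(N) || N < 0) stop("N must be non-negative", call. = FALSE)
  if (!is.numeric(d_A) || d_A <= 0) stop("d_A must be positive", call. = FALSE)
  d <- angstrom_to_m(d_A)
  structure(list(D = D, N = N, d = d,
                 tau_trans = d^2 / (6 * D),
                 delta_jump = 1 / 12),
            class = "translational_params")
}

#' Composite relaxation model parameters
#'
#' Bundles the rotational parameters with the two translational pools.  The
#' labelling rule D_MM > D_LM (the more-mobile pool diffuses faster) and the
#' shared closest-approach distance are enforced.
#'
#' @param rot A \code{\link{rotational_params}} object.
#' @param mm,lm \code{\link{translational_params}} for the more-mobile and
#'   less-mobile pools.
#' @return An object of class \code{composite_params}.
#' @export
composite_params <- function(rot, mm, lm) {
  stopifnot(inherits(rot, "rotational_params"),
            inherits(mm, "translational_params"),
            inherits(lm, "translational_params"))
  if (!(mm$D > lm$D))
    stop("labeling rule violated: mm$D must exceed lm$D", call. = FALSE)
  if (mm$d != lm$d)
    stop("both translational pools must share the closest-approach distance d",
         call. = FALSE)
  structure(list(rot = rot, mm = mm, lm = lm), class = "composite_params")
}

#' @export
print.composite_params <- function(x, ...) {
  cat("Composite R1 model parameters\n")
  cat(sprintf("  rotational   : C_intra = %.3g s^-2, tau_rot = %.3g ns, delta = %.2g (ln tau)\n",
              x$rot$C_intra, x$rot$tau_rot * 1e9, x$rot$delta_rot))
  cat(sprintf("  MM pool      : D = %.3g m^2/s, N = %.3g m^-3 (tau_trans = %.3g s)\n",
              x$mm$D, x$mm$N, x$mm$tau_trans))
  cat(sprintf("  LM pool      : D = %.3g m^2/s, N = %.3g m^-3 (tau_trans = %.3g s)\n",
              x$lm$D, x$lm$N, x$lm$tau_trans))
  cat(sprintf("  d            : %.3g Angstrom\n", x$mm$d * 1e10))
  invisible(x)
}

#' Serialize composite parameters to a flat key-value vector
#'
#' Keys carry unit suffixes (e.g. \code{tau_rot_ns}, \code{D_mm_m2s}) so that
#' parameter files are unambiguous.
#'
#' @param params A \code{\link{composite_params}} object.
#' @return A named numeric vector.
#' @seealso \code{\link{params_from_kv}}
#' @export
params_to_kv <- function(params) {
  stopifnot(inherits(params, "composite_params"))
  c(C_intra_s2   = params$rot$C_intra,
    tau_rot_ns   = params$rot$tau_rot * 1e9,
    delta_rot    = params$rot$delta_rot,
    D_mm_m2s     = params$mm$D,
    N_mm_m3      = params$mm$N,
    D_lm_m2s     = params$lm$D,
    N_lm_m3      = params$lm$N,
    d_angstrom   = params$mm$d * 1e10)
}

#' Deserialize composite parameters from a flat key-value vector
#'
#' @param kv Named numeric vector as produced by \code{\link{params_to_kv}}.
#' @return A \code{\link{composite_params}} object.
#' @export
params_from_kv <- function(kv) {
  need <- c("C_intra_s2", "tau_rot_ns", "delta_rot",
            "D_mm_m2s", "N_mm_m3", "D_lm_m2s", "N_lm_m3", "d_angstrom")
  missing <- setdiff(need, names(kv))
  if (length(missing))
    stop("missing parameter keys: ", paste(missing, collapse = ", "),
         call. = FALSE)
  composite_params(
    rot = rotational_params(kv[["C_intra_s2"]], kv[["tau_rot_ns"]],
                            kv[["delta_rot"]]),
    mm  = translational_params(kv[["D_mm_m2s"]], kv[["N_mm_m3"]],
                               kv[["d_angstrom"]]),
    lm  = translational_params(kv[["D_lm_m2s"]], kv[["N_lm_m3"]],
                               kv[["d_angstrom"]]))
}

# ---- rotational contribution ------------------------------------------------

#' Single-correlation-time BPP spin-lattice relaxation rate
#'
#' \code{R1 = C_intra [J(omega) + 4 J(2 omega)]} with the Lorentzian spectral
#' density \code{J(omega) = tau/(1 + omega^2 tau^2)}.
#'
#' @param omega Angular frequency (rad/s, >= 0); vectorized.
#' @param tau Rotational correlation time (s, > 0).
#' @param C_intra Intramolecular dipolar relaxation constant (s^-2, > 0).
#' @return Relaxation rate (s^-1), same length as \code{omega}.
#' @examples
#' lorentzian_bpp_r1(0, 1e-9, 1e9)  # zero-frequency limit 5 C tau = 5
#' @export
lorentzian_bpp_r1 <- function(omega, tau, C_intra) {
  if (!is.numeric(tau) || any(tau <= 0))
    stop("tau must be positive", call. = FALSE)
  if (!is.numeric(C_intra) || any(C_intra <= 0))
    stop("C_intra must be positive", call. = FALSE)
  if (any(omega < 0)) stop("omega must be >= 0", call. = FALSE)
  J1 <- tau / (1 + (omega * tau)^2)
  J2 <- tau / (1 + (2 * omega * tau)^2)
  C_intra * (J1 + 4 * J2)
}

#' Quadrature nodes and weights for the log-Gaussian correlation-time
#' distribution
#'
#' The distribution is Gaussian in ln(tau) with standard deviation
#' \code{delta_rot}, centred on \code{ln(tau_center)} (the standard
#' log-Gaussian of the distributed-BPP literature).  A uniform grid in
#' ln(tau) spanning \code{span} on each side carries trapezoid-rule weights,
#' renormalized to sum to one.
#'
#' @param tau_center Centre of the distribution (s).
#' @param delta_rot Width: standard deviation of the Gaussian in ln(tau)
#'   (>= 0).
#' @param n_nodes Number of quadrature nodes (default 128, >= 16 unless
#'   \code{delta_rot == 0}).
#' @param span Half-width of the node grid in ln(tau) units (default
#'   \code{4 * delta_rot}).
#' @return A list with numeric vectors \code{tau} and \code{weights}
#'   (non-negative, summing to 1).
#' @export
log_gaussian_weights <- function(tau_center, delta_rot, n_nodes = 128,
                                 span = 4 * delta_rot) {
  if (!is.numeric(tau_center) || tau_center <= 0)
    stop("tau_center must be positive", call. = FALSE)
  if (!is.numeric(delta_rot) || delta_rot < 0)
    stop("delta_rot must be >= 0", call. = FALSE)
  if (delta_rot == 0)
    return(list(tau = tau_center, weights = 1))
  if (n_nodes < 16) stop("n_nodes must be >= 16", call. = FALSE)
  if (span < 4 * delta_rot)
    stop("span must cover at least 4*delta_rot on each side", call. = FALSE)
  lg <- seq(log(tau_center) - span, log(tau_center) + span,
            length.out = n_nodes)
  dens <- stats::dnorm(lg, mean = log(tau_center), sd = delta_rot)
  w <- dens
  # trapezoid end-point halving on the uniform grid
  w[1] <- w[1] / 2
  w[n_nodes] <- w[n_nodes] / 2
  w <- w / sum(w)
  list(tau = exp(lg), weights = w)
}

#' Rotational relaxation rate with a distribution of correlation times
#'
#' The single-tau BPP rate averaged over the log-Gaussian distribution of
#' rotational correlation times.
#'
#' @param omega Angular frequency (rad/s); vectorized.
#' @param params A \code{\link{rotational_params}} object.
#' @param n_nodes Quadrature nodes (default 128).
#' @return Relaxation rate (s^-1), same length as \code{omega}.
#' @export
rotational_r1_distributed <- function(omega, params, n_nodes = 128) {
  stopifnot(inherits(params, "rotational_params"))
  q <- log_gaussian_weights(params$tau_rot, params$delta_rot,
                            n_nodes = if (params$delta_rot == 0) 1 else n_nodes)
  if (any(!is.finite(q$weights)) || any(q$weights < 0))
    stop("quadrature failure: non-finite or negative weights", call. = FALSE)
  # matrix of J over (omega x tau) nodes
  ot <- outer(omega, q$tau)
  J1 <- sweep(1 / (1 + ot^2), 2, q$tau, `*`)
  J2 <- sweep(1 / (1 + 4 * ot^2), 2, q$tau, `*`)
  params$C_intra * as.vector((J1 + 4 * J2) %*% q$weights)
}

# ---- translational (Torrey) contribution ------------------------------------

# Quadrature backbone for Torrey's jump-diffusion spectral density.  The
# reduced spectral function is
#   f(delta, x) = (32/(15 pi)) Int_0^Inf j1(y)^2 * u(y)/(1 + x^2 u(y)^2) dy
# with u(y) = (1 + 2 delta y^2)/(4 delta y^2): y = k d is the reduced wave
# number, j1 the spherical Bessel function (from the Fourier transform of the
# dipolar lattice sum over a uniform spin density outside the closest-approach
# distance d), and u(y) the reduced lifetime of mode k under jumps with
# structure factor A(k) = 1/(1 + k^2 <a^2>/6) performed by both partners
# (relative rate 2/tau).  The normalization makes the full translational rate
#   R1 = C_inter (N tau/d^3) [f(delta, omega tau) + 4 f(delta, 2 omega tau)]
# with C_inter = (9/8)(mu0 gamma^2 hbar/(4 pi))^2 consistent with the exact
# zero-time sum G(0) = 4 pi N/(3 d^3) and the standard like-spin dipolar
# prefactor.
.torrey_env <- new.env(parent = emptyenv())

.torrey_backbone <- function(delta_jump, y_max = 100, panels = 200,
                             nodes_per_panel = 6) {
  key <- sprintf("%.12g_%g_%d_%d", delta_jump, y_max, panels, nodes_per_panel)
  hit <- .torrey_env[[key]]
  if (!is.null(hit)) return(hit)
  gl <- pracma::gaussLegendre(nodes_per_panel, 0, 1)
  edges <- seq(0, y_max, length.out = panels + 1)
  width <- diff(edges)
  y <- as.vector(outer(gl$x, width) + rep(edges[-length(edges)],
                                          each = nodes_per_panel))
  w <- as.vector(outer(gl$w, width))
  # Gauss-Legendre nodes are interior, so y > 0 throughout
  j1 <- ifelse(y < 1e-6, y / 3, sin(y) / y^2 - cos(y) / y)
  u <- (1 + 2 * delta_jump * y^2) / (4 * delta_jump * y^2)
  bb <- list(y = y, w = w, j1sq = j1^2, u = u, y_max = y_max,
             a = w * j1^2 * u)
  .torrey_env[[key]] <- bb
  bb
}

#' Torrey reduced spectral function f(delta, x)
#'
#' Reduced spectral density of the Torrey jump-diffusion model, evaluated by
#' deterministic composite Gauss-Legendre quadrature of the k-space integral
#' with an analytic large-k tail correction.  Monotonically non-increasing in
#' \code{x} and finite at \code{x = 0}.
#'
#' @param x Reduced frequency omega * tau_trans (>= 0); vectorized.
#' @param delta_jump Reduced jump parameter delta = <a>^2/(12 d^2); fixed at
#'   1/12 under the a = d assumption.
#' @return Values of f (dimensionless), same length as \code{x}.
#' @export
torrey_f <- function(x, delta_jump = 1 / 12) {
  if (any(x < 0)) stop("x must be >= 0", call. = FALSE)
  if (delta_jump <= 0) stop("delta_jump must be positive", call. = FALSE)
  bb <- .torrey_backbone(delta_jump)
  ginf <- 0.5 / (1 + 0.25 * x^2)  # u(y) -> 1/2 as y -> Inf
  core <- as.vector(crossprod(bb$a, 1 / (1 + outer(bb$u^2, x^2))))
  tail <- ginf / (2 * bb$y_max)
  (32 / (15 * pi)) * (core + tail)
}

#' Torrey translational spin-lattice relaxation rate
#'
#' Intermolecular relaxation contribution of one translational pool:
#' \code{R1 = C_inter (N tau_trans / d^3) [f(delta, omega tau) +
#' 4 f(delta, 2 omega tau)]} with the jump time \code{tau_trans = d^2/(6 D)}
#' and \code{delta_jump = 1/12} derived from the a = d assumption.
#'
#' @param omega Angular frequency (rad/s, >= 0); vectorized.
#' @param params A \code{\link{translational_params}} object.
#' @param constants A \code{\link{physical_constants}} object.
#' @return Relaxation rate (s^-1); linear in \code{params$N}.
#' @export
torrey_translational_r1 <- function(omega, params,
                                    constants = physical_constants()) {
  stopifnot(inherits(params, "translational_params"))
  if (any(omega < 0)) stop("omega must be >= 0", call. = FALSE)
  if (params$N == 0) return(rep(0, length(omega)))
  x <- omega * params$tau_trans
  pref <- c_inter(constants) * params$N * params$tau_trans / params$d^3
  pref * (torrey_f(x, params$delta_jump) + 4 * torrey_f(2 * x, params$delta_jump))
}

# ---- composite model --------------------------------------------------------

#' Component relaxation rates of the composite model
#'
#' Evaluates the rotational and the two translational contributions
#' separately; their row sums equal \code{\link{total_r1}} exactly.
#'
#' @param omega Angular frequency (rad/s); vectorized.
#' @param params A \code{\link{composite_params}} object.
#' @param constants A \code{\link{physical_constants}} object.
#' @param n_nodes Rotational quadrature nodes.
#' @return A matrix with columns \code{rotational}, \code{trans_MM},
#'   \code{trans_LM}.
#' @export
r1_components <- function(omega, params, constants = physical_constants(),
                          n_nodes = 128) {
  stopifnot(inherits(params, "composite_params"))
  cbind(rotational = rotational_r1_distributed(omega, params$rot, n_nodes),
        trans_MM = torrey_translational_r1(omega, params$mm, constants),
        trans_LM = torrey_translational_r1(omega, params$lm, constants))
}

#' Total composite spin-lattice relaxation rate
#'
#' Sum of the distributed rotational contribution and the MM and LM
#' translational contributions.
#'
#' @inheritParams r1_components
#' @return Relaxation rate (s^-1), same length as \code{omega}.
#' @export
total_r1 <- function(omega, params, constants = physical_constants(),
                     n_nodes = 128) {
  comp <- r1_components(omega, params, constants, n_nodes)
  as.vector(comp[, 1] + comp[, 2] + comp[, 3])
}
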