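# Time-domain relaxometry: mono-exponential T1/T2 fits, discrete
# multi-exponential T2 decomposition, regularized inverse-Laplace T2 spectra
# and the zero-method T1 conversion.

#' Zero-method T1 conversion
#'
#' Converts the inversion-recovery zero-crossing time to T1 via
#' \code{t(Mz = 0) = T1 ln 2}.
#'
#' @param t_zero Zero-crossing time (s, > 0).
#' @return T1 (s).
#' @examples
#' zero_method_t1(log(2) * 0.05)  # 50 ms
#' @export
zero_method_t1 <- function(t_zero) {
  if (any(t_zero <= 0)) stop("t_zero must be positive", call. = FALSE)
  t_zero / log(2)
}

#' Mono-exponential relaxation fit
#'
#' Least-squares fit of \code{offset + amplitude * exp(-t/T)} (decay form,
#' CPMG/PP) or \code{offset - amplitude * exp(-t/T)} (recovery form, SR/NP)
#' to a magnetization curve; the form is chosen from the curve's sequence
#' tag.
#'
#' @param curve A \code{\link{magnetization_curve}} with >= 4 points.
#' @return An object of class \code{monoexp_fit} with fields
#'   \code{relaxation_time} (s), \code{amplitude}, \code{offset},
#'   \code{residual_norm}.
#' @export
fit_monoexp <- function(curve) {
  stopifnot(inherits(curve, "magnetization_curve"))
  if (nrow(curve) < 4) stop("need at least 4 points", call. = FALSE)
  t <- curve$time_s
  y <- curve$amplitude
  if (stats::sd(y) == 0)
    stop("flat curve: no positive time constant can be bracketed",
         call. = FALSE)
  seqc <- attr(curve, "spec")$sequence
  decay <- seqc %in% c("CPMG", "PP")
  a0 <- mean(utils::tail(y, 3))
  b0 <- y[1] - a0
  if ((decay && b0 <= 0) || (!decay && b0 >= 0))
    stop("curve does not ", if (decay) "decay" else "recover",
         ": cannot bracket a positive time constant", call. = FALSE)
  # initial T from the 1/e point of the span
  target <- a0 + b0 / exp(1)
  idx <- if (decay) which(y <= target) else which(y >= target)
  T0 <- if (length(idx)) t[idx[1]] else stats::median(t)
  lower <- c(log10(min(diff(t)) / 100), -Inf, -Inf)
  upper <- c(log10(max(t) * 100), Inf, Inf)
  fit <- minpack.lm::nls.lm(
    par = c(log10(T0), b0, a0), lower = lower, upper = upper,
    fn = function(p) y - (p[3] + p[2] * exp(-t / 10^p[1])),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  b <- fit$par[2]
  structure(list(relaxation_time = 10^fit$par[1],
                 amplitude = abs(b), offset = fit$par[3],
                 form = if (decay) "decay" else "recovery",
                 residual_norm = sqrt(fit$deviance)),
            class = "monoexp_fit")
}

#' @export
print.monoexp_fit <- function(x, ...) {
  cat(sprintf("Mono-exponential %s fit: T = %.4g s, amplitude = %.4g, offset = %.4g (||r|| = %.3g)\n",
              x$form, x$relaxation_time, x$amplitude, x$offset,
              x$residual_norm))
  invisible(x)
}

# Lawson-Hanson active-set non-negative least squares: min ||Ax - b||, x >= 0
.nnls <- function(A, b, tol = NULL) {
  n <- ncol(A)
  x <- numeric(n)
  passive <- logical(n)
  w <- crossprod(A, b - A %*% x)
  if (is.null(tol)) tol <- 10 * .Machine$double.eps * sum(abs(A)) * nrow(A)
  iter <- 0
  max_iter <- 30 * n
  while (any(!passive) && any(w[!passive] > tol) && iter < max_iter) {
    iter <- iter + 1
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      s <- numeric(n)
      P <- which(passive)
      s[P] <- qr.coef(qr(A[, P, drop = FALSE]), b)
      s[P][is.na(s[P])] <- 0
      if (all(s[P] > tol)) break
      neg <- P[s[P] <= tol]
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      passive[x <= tol & passive] <- FALSE
      x[!passive] <- 0
    }
    x <- s
    w <- crossprod(A, b - A %*% x)
  }
  x
}

#' Discrete multi-exponential T2 decomposition
#'
#' Fits \code{sum_i A_i exp(-t/T2_i)} with non-negative amplitudes by
#' variable projection: the time constants are optimized by
#' Levenberg-Marquardt on a log scale while the amplitudes are solved by
#' non-negative least squares at each step.  Components are reported sorted
#' by ascending T2 with relative areas RA_i = 100 A_i / sum(A).  Components
#' collapsing within 1% in T2 (or losing all amplitude) trigger a warning
#' and a refit with one component fewer.
#'
#' @param decay A \code{\link{magnetization_curve}} (CPMG decay).
#' @param n_components Number of exponential components (default 2).
#' @return An object of class \code{discrete_t2}: data.frame
#'   \code{components} with \code{T2_s}, \code{T2_ms}, \code{amplitude},
#'   \code{RA_pct}, plus \code{residual_norm} and \code{n_components}.
#' @export
fit_discrete_multiexp <- function(decay, n_components = 2) {
  stopifnot(inherits(decay, "magnetization_curve"))
  if (n_components < 1) stop("n_components must be >= 1", call. = FALSE)
  t <- decay$time_s
  y <- decay$amplitude
  if (length(t) < 2 * n_components + 1)
    stop("need at least 2*n_components + 1 points", call. = FALSE)
  lT_lo <- log10(t[1] / 10)
  lT_hi <- log10(max(t) * 10)
  amps_for <- function(lT) {
    K <- exp(-outer(t, 10^lT, `/`))
    a <- .nnls(K, y)
    list(K = K, a = a)
  }
  if (n_components == 1) {
    fit <- minpack.lm::nls.lm(
      par = stats::median(log10(range(t))), lower = lT_lo, upper = lT_hi,
      fn = function(p) {
        m <- amps_for(p)
        y - as.vector(m$K %*% m$a)
      }, control = minpack.lm::nls.lm.control(maxiter = 200))
    lT <- fit$par
  } else {
    span <- log10(max(t)) - log10(t[1])
    lT0 <- log10(t[1]) + span * seq(0.25, 0.85, length.out = n_components)
    fit <- minpack.lm::nls.lm(
      par = lT0, lower = rep(lT_lo, n_components),
      upper = rep(lT_hi, n_components),
      fn = function(p) {
        m <- amps_for(p)
        y - as.vector(m$K %*% m$a)
      }, control = minpack.lm::nls.lm.control(maxiter = 200))
    lT <- fit$par
  }
  m <- amps_for(lT)
  T2 <- 10^lT
  A <- m$a
  ord <- order(T2)
  T2 <- T2[ord]
  A <- A[ord]
  collapsed <- (n_components > 1) &&
    (any(diff(T2) / T2[-length(T2)] < 0.01) || any(A <= 1e-9 * max(A)))
  if (collapsed) {
    warning("components collapsed; reporting the reduced model with ",
            n_components - 1, " component(s)", call. = FALSE)
    return(fit_discrete_multiexp(decay, n_components - 1))
  }
  RA <- 100 * A / sum(A)
  structure(list(components = data.frame(T2_s = T2, T2_ms = T2 * 1e3,
                                         amplitude = A, RA_pct = RA),
                 residual_norm = sqrt(sum((y - as.vector(m$K %*% A))^2)),
                 n_components = length(T2)),
            class = "discrete_t2")
}

#' @export
print.discrete_t2 <- function(x, ...) {
  cat(sprintf("Discrete T2 decomposition (%d component%s):\n",
              x$n_components, if (x$n_components > 1) "s" else ""))
  print(x$components, row.names = FALSE)
  cat(sprintf("residual norm: %.4g\n", x$residual_norm))
  invisible(x)
}

#' Regularized inverse-Laplace T2 spectrum
#'
#' Solves the non-negative least-squares problem
#' \code{min ||K a - y||^2 + lambda ||a||^2, a >= 0} on an exponential-kernel
#' design matrix \code{K[j, i] = exp(-t_j / T2_i)} over a log-spaced T2 grid
#' (Tikhonov-regularized NNLS).
#'
#' @param decay A \code{\link{magnetization_curve}}.
#' @param grid Log-spaced T2 grid (s); default 100 points over [10 us, 1 s].
#'   Should span at least [echo_time/10, 10 * max time].
#' @param regularization_strength Tikhonov penalty lambda (>= 0, default
#'   0.1, chosen by an L-curve scan on synthetic two-component decays).
#' @return An object of class \code{t2_spectrum}: data.frame
#'   \code{spectrum} (\code{T2_s}, \code{amplitude} >= 0) plus the penalty
#'   used.
#' @export
ilt_t2_spectrum <- function(decay, grid = NULL,
                            regularization_strength = 0.1) {
  stopifnot(inherits(decay, "magnetization_curve"))
  if (regularization_strength < 0)
    stop("regularization_strength must be >= 0", call. = FALSE)
  t <- decay$time_s
  y <- decay$amplitude
  if (all(y == 0)) stop("all-zero decay", call. = FALSE)
  if (is.null(grid)) grid <- 10^seq(log10(1e-5), log10(1), length.out = 100)
  if (min(grid) > t[1] / 10 || max(grid) < 10 * max(t))
    warning("T2 grid does not span [first time/10, 10*max time]",
            call. = FALSE)
  K <- exp(-outer(t, grid, `/`))
  if (regularization_strength > 0) {
    A <- rbind(K, sqrt(regularization_strength) * diag(length(grid)))
    b <- c(y, numeric(length(grid)))
  } else {
    A <- K
    b <- y
  }
  a <- .nnls(A, b)
  structure(list(spectrum = data.frame(T2_s = grid, amplitude = a),
                 regularization_strength = regularization_strength),
            class = "t2_spectrum")
}

#' @export
print.t2_spectrum <- function(x, ...) {
  nz <- sum(x$spectrum$amplitude > 0)
  cat(sprintf("T2 spectrum: %d grid points (%d non-zero), lambda = %g\n",
              nrow(x$spectrum), nz, x$regularization_strength))
  invisible(x)
}

#' Regularization ladder for the inverse-Laplace spectrum
#'
#' Evaluates residual and solution norms over a ladder of penalties (an
#' L-curve scan) to support choosing the regularization strength.
#'
#' @param decay A \code{\link{magnetization_curve}}.
#' @param lambdas Penalty values to scan.
#' @param grid T2 grid passed to \code{\link{ilt_t2_spectrum}}.
#' @return data.frame with \code{lambda}, \code{residual_norm},
#'   \code{solution_norm}, \code{n_peaks}.
#' @export
ilt_lambda_scan <- function(decay, lambdas = 10^seq(-4, 1, by = 0.5),
                            grid = NULL) {
  t <- decay$time_s
  y <- decay$amplitude
  do.call(rbind, lapply(lambdas, function(l) {
    sp <- ilt_t2_spectrum(decay, grid = grid, regularization_strength = l)
    K <- exp(-outer(t, sp$spectrum$T2_s, `/`))
    pk <- spectrum_peaks(sp)
    data.frame(lambda = l,
               residual_norm = sqrt(sum((y - as.vector(
                 K %*% sp$spectrum$amplitude))^2)),
               solution_norm = sqrt(sum(sp$spectrum$amplitude^2)),
               n_peaks = pk$n_components)
  }))
}

#' Peak table of a T2 spectrum
#'
#' Segments the spectrum into peaks (contiguous non-zero regions, split at
#' interior local minima) and reports, per peak, the amplitude-weighted
#' T2 (geometric mean over the log-spaced grid), the location of the peak
#' maximum, and the relative area RA = 100 * peak area / total area.
#'
#' @param spectrum A \code{\link{ilt_t2_spectrum}} result.
#' @return An object of class \code{discrete_t2} whose components carry
#'   \code{T2_s}, \code{T2_ms}, \code{T2_mode_s}, \code{amplitude} (peak
#'   area) and \code{RA_pct}.
#' @export
spectrum_peaks <- function(spectrum) {
  stopifnot(inherits(spectrum, "t2_spectrum"))
  T2 <- spectrum$spectrum$T2_s
  amp <- spectrum$spectrum$amplitude
  if (all(amp == 0)) stop("empty spectrum", call. = FALSE)
  nz <- amp > 0
  # label contiguous non-zero runs
  run <- cumsum(c(nz[1], diff(nz)) == 1) * nz
  segments <- list()
  for (r in setdiff(unique(run), 0)) {
    idx <- which(run == r)
    # split the run at interior local minima
    if (length(idx) > 2) {
      a <- amp[idx]
      mins <- which(a[-c(1, length(a))] < a[-c(length(a) - 1, length(a))] &
                      a[-c(1, length(a))] < a[-c(1, 2)]) + 1
      cuts <- c(0, mins, length(idx))
      for (k in seq_len(length(cuts) - 1))
        segments[[length(segments) + 1]] <-
          idx[(cuts[k] + 1):cuts[k + 1]]
    } else {
      segments[[length(segments) + 1]] <- idx
    }
  }
  comp <- do.call(rbind, lapply(segments, function(idx) {
    area <- sum(amp[idx])
    data.frame(T2_s = exp(sum(amp[idx] * log(T2[idx])) / area),
               T2_mode_s = T2[idx[which.max(amp[idx])]],
               amplitude = area)
  }))
  comp <- comp[order(comp$T2_s), ]
  comp$T2_ms <- comp$T2_s * 1e3
  comp$RA_pct <- 100 * comp$amplitude / sum(comp$amplitude)
  rownames(comp) <- NULL
  structure(list(components = comp[, c("T2_s", "T2_ms", "T2_mode_s",
                                       "amplitude", "RA_pct")],
                 residual_norm = NA_real_, n_components = nrow(comp)),
            class = "discrete_t2")
}
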