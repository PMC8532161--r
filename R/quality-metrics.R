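# Closed-form quality computations: CIELAB total color change, TPA-derived
# descriptors, relative changes against a reference sample, and a Pearson
# correlation utility.

#' CIELAB color coordinates
#'
#' @param L Lightness (0-100).
#' @param a Red/green axis.
#' @param b Yellow/blue axis.
#' @return An object of class \code{color_lab}.
#' @export
color_lab <- function(L, a, b) {
  if (L < 0 || L > 100) stop("L must lie in [0, 100]", call. = FALSE)
  structure(list(L = L, a = a, b = b), class = "color_lab")
}

#' Total color change (CIE76 delta E)
#'
#' Euclidean distance in L*a*b* space between a sample and a reference:
#' sqrt(dL^2 + da^2 + db^2).
#'
#' @param sample,reference \code{\link{color_lab}} objects (or plain lists
#'   with L, a, b).
#' @return Non-negative total color change; zero iff the inputs coincide.
#' @examples
#' delta_e(color_lab(37.35, 0.38, 1.29), color_lab(30.98, 0.18, 1.05))
#' @export
delta_e <- function(sample, reference) {
  sqrt((sample$L - reference$L)^2 + (sample$a - reference$a)^2 +
         (sample$b - reference$b)^2)
}

#' TPA-derived texture descriptors
#'
#' Gumminess is the product of hardness and cohesiveness; chewiness the
#' product of gumminess and springiness.
#'
#' @param hardness Peak force of the first compression (N, >= 0).
#' @param cohesiveness Dimensionless ratio in [0, 1].
#' @param springiness Recovered height (mm, >= 0).
#' @return A named numeric vector with \code{gumminess} (N) and
#'   \code{chewiness} (N mm).
#' @export
tpa_derived <- function(hardness, cohesiveness, springiness) {
  if (any(c(hardness, cohesiveness, springiness) < 0))
    stop("TPA inputs must be non-negative", call. = FALSE)
  if (cohesiveness > 1) stop("cohesiveness must lie in [0, 1]", call. = FALSE)
  gumminess <- hardness * cohesiveness
  c(gumminess = gumminess, chewiness = gumminess * springiness)
}

#' Relative change against a reference value
#'
#' @param value Sample value.
#' @param reference Reference value (> 0).
#' @return \code{value / reference}.
#' @export
relative_change <- function(value, reference) {
  if (!is.numeric(reference) || reference <= 0)
    stop("reference must be positive", call. = FALSE)
  value / reference
}

#' Pearson product-moment correlation
#'
#' Thin validated wrapper around \code{stats::cor}.
#'
#' @param x,y Numeric vectors of equal length (>= 3) with non-zero variance.
#' @return Correlation coefficient in [-1, 1].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input vector", call. = FALSE)
  stats::cor(x, y, method = "pearson")
}
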