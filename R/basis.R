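## Legendre polynomial basis and curve preprocessing used by the ODE
## network-reconstruction machinery.

#' Legendre polynomial basis on a rescaled argument
#'
#' Evaluates Legendre polynomials \eqn{P_1, \dots, P_r} (optionally including
#' the constant \eqn{P_0}) at `x` after affinely rescaling the observed range
#' `range` to \eqn{[-1, 1]}.  A degenerate range (width below `1e-12`) yields
#' an all-zero basis, so constant curves contribute nothing.
#'
#' @param x Numeric vector of evaluation points.
#' @param r Maximum polynomial degree (`>= 1`).
#' @param range Length-2 numeric range used for rescaling (default
#'   `range(x)`).
#' @param include_constant Include the degree-0 column (default `FALSE`).
#' @return A `length(x) x r` (or `r + 1`) matrix of basis values.
#' @export
legendre_basis <- function(x, r, range = base::range(x),
                           include_constant = FALSE) {
  stopifnot(r >= 1)
  width <- range[2] - range[1]
  if (!is.finite(width) || width < 1e-12) {
    ncol_out <- r + as.integer(include_constant)
    return(matrix(0, length(x), ncol_out))
  }
  u <- 2 * (x - range[1]) / width - 1
  P <- matrix(0, length(x), r + 1L)
  P[, 1] <- 1
  if (r >= 1) P[, 2] <- u
  if (r >= 2) {
    for (k in 2:r) {
      ## (k) P_k = (2k - 1) u P_{k-1} - (k - 1) P_{k-2}
      P[, k + 1] <- ((2 * k - 1) * u * P[, k] - (k - 1) * P[, k - 1]) / k
    }
  }
  if (include_constant) P else P[, -1, drop = FALSE]
}

## Scalar fast path used inside the RK4 integrator.
legendre_eval <- function(x, coef, range, include_constant) {
  width <- range[2] - range[1]
  if (width < 1e-12) return(if (include_constant) coef[1] else 0)
  u <- 2 * (x - range[1]) / width - 1
  r <- length(coef) - as.integer(include_constant)
  pkm1 <- 1; pk <- u
  acc <- if (include_constant) coef[1] + coef[2] * u else coef[1] * u
  if (r >= 2) {
    off <- as.integer(include_constant)
    for (k in 2:r) {
      pk1 <- ((2 * k - 1) * u * pk - (k - 1) * pkm1) / k
      acc <- acc + coef[k + off] * pk1
      pkm1 <- pk; pk <- pk1
    }
  }
  acc
}

#' Numerical derivative of a sampled curve
#'
#' Central differences on interior points, one-sided differences at the two
#' ends.
#'
#' @param t Strictly increasing grid.
#' @param y Curve values on `t`.
#' @return Numeric vector of derivative estimates, same length as `y`.
#' @export
numeric_deriv <- function(t, y) {
  n <- length(t)
  stopifnot(length(y) == n, n >= 2)
  d <- numeric(n)
  d[1] <- (y[2] - y[1]) / (t[2] - t[1])
  d[n] <- (y[n] - y[n - 1]) / (t[n] - t[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    d[i] <- (y[i + 1] - y[i - 1]) / (t[i + 1] - t[i - 1])
  }
  d
}

## Smoothing-spline presmoothing of a noisy curve.  The default equivalent
## degrees of freedom follow min(10, T - 2): enough flexibility for the one
## or two turning points an effect curve shows, while suppressing
## measurement noise on densely sampled series.  df = NULL requests
## GCV-chosen smoothness; falls back to the raw values when the series is
## too short or degenerate.
smooth_curve <- function(t, y, df = default_smooth_df(length(y))) {
  n <- length(y)
  if (n < 5 || stats::sd(y) < 1e-12) return(y)
  fit <- tryCatch({
    if (is.null(df)) stats::smooth.spline(t, y, cv = FALSE)
    else stats::smooth.spline(t, y, df = max(3, min(df, n - 2)))
  }, error = function(e) NULL)
  if (is.null(fit)) return(y)
  stats::predict(fit, t)$y
}

default_smooth_df <- function(T_) min(10, max(3, T_ - 2))

## Dependent-component basis, anchored so every basis function vanishes at
## argument 0: fixes the gauge between the independent term (which carries
## the free constant) and the dependent terms ("no regulator level, no
## contribution"), making the decomposition identified.
anchored_legendre <- function(x, r, range) {
  B <- legendre_basis(x, r, range)
  B0 <- legendre_basis(0, r, range)
  sweep(B, 2, as.vector(B0))
}

anchored_eval <- function(x, coef, range) {
  legendre_eval(x, coef, range, FALSE) - legendre_eval(0, coef, range, FALSE)
}

## Cumulative trapezoidal integral anchored at 0.
cumtrapz0 <- function(t, f) {
  n <- length(t)
  out <- numeric(n)
  if (n > 1) {
    inc <- diff(t) * (f[-n] + f[-1]) / 2
    out[-1] <- cumsum(inc)
  }
  out
}
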