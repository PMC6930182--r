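#' First-order autoregressive covariance parameters
#'
#' Stationary AR(1) longitudinal covariance: constant variance `sigma2` and
#' lag-1 correlation `rho`, giving covariance \eqn{\sigma^2 \rho^{|s-t|}}
#' between occasions `s` and `t`.
#'
#' @param rho Lag-1 correlation, `|rho| < 1`.
#' @param sigma2 Time-constant variance, `> 0`.
#' @return An object of class `ar1_params`.
#' @export
ar1_params <- function(rho, sigma2) {
  if (!is.finite(rho) || abs(rho) >= 1) {
    stop("rho must satisfy |rho| < 1", call. = FALSE)
  }
  if (!is.finite(sigma2) || sigma2 <= 0) {
    stop("sigma2 must be positive", call. = FALSE)
  }
  structure(list(rho = rho, sigma2 = sigma2), class = "ar1_params")
}

#' @export
print.ar1_params <- function(x, ...) {
  cat(sprintf("<ar1_params> rho = %.6g, sigma2 = %.6g\n", x$rho, x$sigma2))
  invisible(x)
}

#' AR(1) covariance matrix
#'
#' @param p An [ar1_params()] object.
#' @param T_ Number of measurement occasions.
#' @return A `T_ x T_` symmetric positive-definite matrix with entry
#'   \eqn{\sigma^2 \rho^{|s-t|}}.
#' @export
ar1_matrix <- function(p, T_) {
  stopifnot(inherits(p, "ar1_params"), T_ >= 1)
  idx <- seq_len(T_)
  p$sigma2 * p$rho^abs(outer(idx, idx, "-"))
}

#' AR(1) multivariate-normal log-density
#'
#' Log-density of a mean-zero multivariate normal with AR(1) covariance,
#' computed in closed form through the Markov factorisation
#' \eqn{f(r_1) \prod_t f(r_{t+1} \mid r_t)} — equivalently, via the AR(1)
#' determinant \eqn{|\Sigma| = \sigma^{2T} (1-\rho^2)^{T-1}} and tridiagonal
#' inverse — rather than a generic \eqn{O(T^3)} solve.  Supports irregular
#' occasion gaps: with gaps \eqn{\delta_k} between consecutive observed
#' occasions the conditional correlation is \eqn{\rho^{\delta_k}}, which is
#' exactly the marginal law of the observed sub-vector under AR(1).
#'
#' @param residuals Numeric vector of length `T` (mean-zero residuals).
#' @param p An [ar1_params()] object.
#' @param occasions Optional integer occasions of the residuals (default
#'   `1:T`); used when some occasions are missing.
#' @return The log-density (scalar).
#' @export
ar1_logpdf <- function(residuals, p, occasions = seq_along(residuals)) {
  stopifnot(inherits(p, "ar1_params"))
  if (!all(is.finite(residuals))) stop("non-finite residuals", call. = FALSE)
  T_ <- length(residuals)
  if (T_ == 0L) return(0)
  q <- ar1_quadform(residuals, p$rho, occasions)
  ld <- T_ * log(p$sigma2) + q$logdet_corr
  out <- -0.5 * (T_ * log(2 * pi) + ld + q$q / p$sigma2)
  if (!is.finite(out)) stop("AR(1) log-density is non-finite", call. = FALSE)
  out
}

## Unit-variance quadratic form r' R^{-1} r and log|R| for the AR(1)
## correlation matrix R over (possibly gapped) occasions; O(T).
ar1_quadform <- function(r, rho, occasions = seq_along(r)) {
  T_ <- length(r)
  if (T_ == 1L) return(list(q = r[1]^2, logdet_corr = 0))
  gaps <- diff(occasions)
  rr <- rho^gaps
  v <- 1 - rr^2
  q <- r[1]^2 + sum((r[-1] - rr * r[-T_])^2 / v)
  list(q = q, logdet_corr = sum(log(v)))
}
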