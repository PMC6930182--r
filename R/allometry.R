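#' Bidirectional height-diameter allometry parameters
#'
#' Container for one parameterisation of the height-diameter allometric
#' scaling equation, in one of its two directions:
#'
#' * `H_FROM_D`: \eqn{H = H_0 + \exp(a + d/(b + D))} — stem height as a
#'   function of stem diameter ("pioneering" direction);
#' * `D_FROM_H`: \eqn{D = d/(a - \ln(H - H_0)) - b} — stem diameter as a
#'   function of stem height ("maintaining" direction).
#'
#' The two forms are exact algebraic inverses of each other under the matched
#' parameterisation `(h0, a, b, d)` with the sign convention
#' \eqn{d_{H \leftarrow D} = -d_{D \leftarrow H}}.  `a` controls the late-stage
#' asymptote (`h0 + exp(a)` for `H_FROM_D`), `b` the early-stage behaviour,
#' and `d` is the relative rate that sets the spread of the curve along the
#' predictor axis.
#'
#' @param direction `"H_FROM_D"` or `"D_FROM_H"`.
#' @param h0 Baseline height (cm) at the initial time point.
#' @param a,b,d Scale, offset and rate coefficients (see Details).
#' @return An object of class `allometry_params`.
#' @examples
#' p <- allometry_params("H_FROM_D", h0 = 20, a = 3, b = 1, d = -4)
#' predict_h_from_d(p, c(1, 5, 50))
#' @export
allometry_params <- function(direction = c("H_FROM_D", "D_FROM_H"),
                             h0 = 0, a = 1, b = 1, d = 1) {
  direction <- match.arg(direction)
  stopifnot(is.finite(h0), is.finite(a), is.finite(b), is.finite(d))
  structure(
    list(direction = direction, h0 = h0, a = a, b = b, d = d),
    class = "allometry_params"
  )
}

#' @export
print.allometry_params <- function(x, ...) {
  eq <- if (x$direction == "H_FROM_D") {
    "H = h0 + exp(a + d/(b + D))"
  } else {
    "D = d/(a - ln(H - h0)) - b"
  }
  cat("<allometry_params> ", eq, "\n", sep = "")
  cat(sprintf("  h0 = %.6g, a = %.6g, b = %.6g, d = %.6g\n", x$h0, x$a, x$b, x$d))
  invisible(x)
}

#' Predict stem height from stem diameter
#'
#' Evaluates the allometry equation \eqn{H = H_0 + \exp(a + d/(b + D))}.
#' As \eqn{D \to \infty} the prediction tends to the asymptote
#' \eqn{H_0 + e^a}.
#'
#' @param params An [allometry_params()] object with direction `H_FROM_D`.
#' @param d_values Numeric vector of diameters; `b + D` must be positive.
#' @return Numeric vector of predicted heights, same length as `d_values`.
#' @export
predict_h_from_d <- function(params, d_values) {
  stopifnot(inherits(params, "allometry_params"))
  if (params$direction != "H_FROM_D") {
    stop("predict_h_from_d() requires direction H_FROM_D", call. = FALSE)
  }
  if (!all(is.finite(d_values))) {
    stop("non-finite diameter value at index ",
         which(!is.finite(d_values))[1], call. = FALSE)
  }
  den <- params$b + d_values
  if (any(den <= 0)) {
    stop("domain error: b + D <= 0 at index ", which(den <= 0)[1], call. = FALSE)
  }
  params$h0 + exp(params$a + params$d / den)
}

#' Predict stem diameter from stem height
#'
#' Evaluates the allometry equation \eqn{D = d/(a - \ln(H - H_0)) - b}.
#' Valid for \eqn{H > H_0} with \eqn{a - \ln(H - H_0) > 0}; a negative
#' predicted diameter is flagged as out of domain rather than returned.
#'
#' @param params An [allometry_params()] object with direction `D_FROM_H`.
#' @param h_values Numeric vector of heights.
#' @param allow_negative If `TRUE`, negative predicted diameters are returned
#'   rather than raising a domain error (used internally by fitting routines,
#'   where the optimizer must be able to evaluate poor parameter values).
#' @return Numeric vector of predicted diameters.
#' @export
predict_d_from_h <- function(params, h_values, allow_negative = FALSE) {
  stopifnot(inherits(params, "allometry_params"))
  if (params$direction != "D_FROM_H") {
    stop("predict_d_from_h() requires direction D_FROM_H", call. = FALSE)
  }
  if (!all(is.finite(h_values))) {
    stop("non-finite height value at index ",
         which(!is.finite(h_values))[1], call. = FALSE)
  }
  excess <- h_values - params$h0
  if (any(excess <= 0)) {
    stop("domain error: H <= h0 at index ", which(excess <= 0)[1], call. = FALSE)
  }
  den <- params$a - log(excess)
  if (any(den <= 0)) {
    stop("domain error: a - ln(H - h0) <= 0 at index ",
         which(den <= 0)[1], call. = FALSE)
  }
  out <- params$d / den - params$b
  if (!allow_negative && any(out < 0)) {
    stop("domain error: negative predicted diameter at index ",
         which(out < 0)[1], call. = FALSE)
  }
  out
}

## Mean-curve evaluation usable inside optimizers: returns NA (not an error)
## where the parameter value leaves the domain, so the objective can penalize.
allometry_mean <- function(direction, h0, a, b, d, x) {
  if (direction == "H_FROM_D") {
    den <- b + x
    out <- ifelse(den > 0, h0 + exp(a + d / den), NA_real_)
  } else {
    excess <- x - h0
    lg <- ifelse(excess > 0, log(excess), NA_real_)
    den <- a - lg
    out <- ifelse(!is.na(den) & den > 0, d / den - b, NA_real_)
  }
  out
}

## Log-scale linearisation used to initialise the nonlinear fits: for fixed b,
## H_FROM_D gives log(y - h0) = a + d/(b + x) (linear in a, d) and D_FROM_H
## gives 1/(y + b) = a/d - ln(x - h0)/d.  A coarse grid over b plus linear
## regression yields a robust starting triple.
allometry_init <- function(x, y, direction, h0) {
  b_grid <- c(0.2, 0.5, 1, 2, 5, 10)
  best <- NULL
  if (direction == "H_FROM_D") {
    w <- y - h0
    w <- pmax(w, max(w, na.rm = TRUE) * 1e-3, 1e-6)
    lw <- log(w)
    for (b in b_grid) {
      if (any(b + x <= 0)) next
      z <- 1 / (b + x)
      fit <- stats::lm.fit(cbind(1, z), lw)
      rss <- sum(fit$residuals^2)
      if (is.null(best) || rss < best$rss) {
        best <- list(a = fit$coefficients[[1]], b = b,
                     d = fit$coefficients[[2]], rss = rss)
      }
    }
    if (is.null(best)) best <- list(a = log(max(mean(w), 1e-6)), b = 1, d = 0)
  } else {
    lx <- log(pmax(x - h0, 1e-6))
    for (b in b_grid) {
      if (any(y + b <= 0)) next
      z <- 1 / (y + b)
      ## z = a/d - lx/d
      fit <- stats::lm.fit(cbind(1, lx), z)
      slope <- fit$coefficients[[2]]
      if (!is.finite(slope) || abs(slope) < 1e-12) next
      d0 <- -1 / slope
      a0 <- fit$coefficients[[1]] * d0
      if (!all(a0 - lx > 0)) next
      rss <- sum((d0 / (a0 - lx) - b - y)^2)
      if (is.null(best) || rss < best$rss) {
        best <- list(a = a0, b = b, d = d0, rss = rss)
      }
    }
    if (is.null(best)) best <- list(a = max(lx) + 1, b = 1, d = 1)
  }
  c(a = best$a, b = best$b, d = best$d)
}

#' Fit the allometry equation to paired trait measurements
#'
#' Least-squares fit of the height-diameter allometry equation (in either
#' scaling direction) to a predictor/response pair, typically the mean
#' trajectories of a mapping population.  Optimisation uses a derivative-free
#' Nelder-Mead simplex started from a log-scale linearisation, with five
#' additional jittered restarts to escape poor local minima.
#'
#' @param x Predictor values (diameters for `H_FROM_D`, heights for
#'   `D_FROM_H`).
#' @param y Response values; `length(y) == length(x) >= 4`.
#' @param direction `"H_FROM_D"` or `"D_FROM_H"`.
#' @param h0 Baseline height. For `H_FROM_D` this is the response baseline;
#'   for `D_FROM_H` it offsets the predictor. Ignored when `fit_h0 = TRUE`.
#' @param init Optional [allometry_params()] start; when supplied the returned
#'   fit is at least as good (in RSS) as the initial value.
#' @param fit_h0 If `TRUE`, `h0` is treated as a fourth free parameter
#'   (mean-curve use case); default is a fixed input.
#' @param n_starts Number of jittered restarts (default 5).
#' @param seed Seed for the restart jitter (fits are deterministic given it).
#' @return An object of class `allometry_fit`: a list with elements `params`
#'   ([allometry_params()]), `rss`, `fitted`, `residuals`, `converged`,
#'   `n`, `k` (free parameter count) and `direction`.
#' @examples
#' d <- seq(1, 15)
#' h <- 20 + exp(3 - 5 / (2 + d))
#' fit <- fit_allometry(d, h, "H_FROM_D", h0 = 20)
#' glance(fit)
#' @export
fit_allometry <- function(x, y, direction = c("H_FROM_D", "D_FROM_H"),
                          h0 = 0, init = NULL, fit_h0 = FALSE,
                          n_starts = 5, seed = 1L) {
  direction <- match.arg(direction)
  stopifnot(length(x) == length(y))
  n <- length(y)
  k <- 3L + as.integer(fit_h0)
  if (n < k + 1L) stop("need at least ", k + 1L, " observations", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("non-finite values in x or y", call. = FALSE)
  }

  ## degenerate response: flat curve, d = 0 solution
  if (stats::sd(y) < 1e-12) {
    c0 <- mean(y)
    h0_use <- if (fit_h0) c0 - 1 else h0
    if (direction == "H_FROM_D" && c0 > h0_use) {
      p <- allometry_params(direction, h0 = h0_use, a = log(c0 - h0_use),
                            b = 1, d = 0)
      fitted <- rep(c0, n)
      return(new_allometry_fit(p, y, fitted, converged = TRUE, k = k))
    }
  }

  obj <- function(theta) {
    h0_t <- if (fit_h0) theta[4] else h0
    mu <- allometry_mean(direction, h0_t, theta[1], theta[2], theta[3], x)
    if (any(!is.finite(mu))) return(1e12 + sum(!is.finite(mu)) * 1e6)
    sum((y - mu)^2)
  }

  start0 <- allometry_init(x, y, direction, if (fit_h0) min(y) - 1 else h0)
  if (fit_h0) start0 <- c(start0, h0 = if (direction == "H_FROM_D") min(y) - 1 else min(x) - 1)
  starts <- list(start0)
  if (!is.null(init)) {
    stopifnot(inherits(init, "allometry_params"))
    s <- c(a = init$a, b = init$b, d = init$d)
    if (fit_h0) s <- c(s, h0 = init$h0)
    starts <- c(starts, list(s))
  }
  rng <- local({ set.seed(seed); function(n) stats::rnorm(n) })
  for (i in seq_len(n_starts)) {
    jit <- start0 * (1 + 0.2 * rng(length(start0))) + 0.1 * rng(length(start0))
    starts <- c(starts, list(jit))
  }

  best <- NULL
  for (s in starts) {
    opt <- stats::optim(s, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-10))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  ## honour the contract rss(fit) <= rss(init)
  if (!is.null(init)) {
    s <- c(a = init$a, b = init$b, d = init$d)
    if (fit_h0) s <- c(s, h0 = init$h0)
    if (obj(s) < best$value) best <- list(par = s, value = obj(s), convergence = 0L)
  }

  theta <- best$par
  h0_hat <- if (fit_h0) theta[[4]] else h0
  p <- allometry_params(direction, h0 = h0_hat, a = theta[[1]],
                        b = theta[[2]], d = theta[[3]])
  fitted <- allometry_mean(direction, h0_hat, p$a, p$b, p$d, x)
  converged <- best$convergence == 0L && all(is.finite(fitted))
  if (!converged) {
    warning("allometry fit did not converge; returning best parameters found",
            call. = FALSE)
  }
  new_allometry_fit(p, y, fitted, converged = converged, k = k, x = x)
}

new_allometry_fit <- function(params, y, fitted, converged, k, x = NULL) {
  structure(
    list(params = params, rss = sum((y - fitted)^2), fitted = fitted,
         residuals = y - fitted, converged = converged,
         n = length(y), k = k, direction = params$direction, x = x, y = y),
    class = "allometry_fit"
  )
}

#' @export
print.allometry_fit <- function(x, ...) {
  cat("<allometry_fit> n =", x$n, " rss =", signif(x$rss, 6),
      if (!x$converged) " (NOT converged)" else "", "\n")
  print(x$params)
  invisible(x)
}

## ---- model comparison ------------------------------------------------------

fit_power_law <- function(x, y) {
  ok <- x > 0 & y > 0
  if (sum(ok) < 3) stop("power-law fit needs positive data", call. = FALSE)
  lf <- stats::lm.fit(cbind(1, log(x[ok])), log(y[ok]))
  start <- c(alpha = exp(lf$coefficients[[1]]), beta = lf$coefficients[[2]])
  obj <- function(th) {
    mu <- th[1] * x^th[2]
    if (any(!is.finite(mu))) return(1e12)
    sum((y - mu)^2)
  }
  opt <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  list(coef = opt$par, rss = opt$value, k = 2L)
}

#' Compare allometry model candidates by AIC
#'
#' Fits each candidate model to `(x, y)` and ranks them by
#' \eqn{AIC = n \ln(RSS/n) + 2k}, the least-squares form of AIC.  Candidates
#' are the bidirectional allometry equation (`"allometry"`), a power law
#' \eqn{y = \alpha x^\beta} (`"power"`), and a straight line (`"linear"`).
#' Ties in AIC are broken in favour of fewer parameters; a candidate whose
#' fit fails is retained with `AIC = Inf` rather than dropped.
#'
#' @inheritParams fit_allometry
#' @param models Character vector of candidate ids.
#' @return A tibble with columns `model`, `k`, `rss`, `aic`, sorted by
#'   ascending AIC (ties to smaller `k`).
#' @export
compare_models_aic <- function(x, y, direction = c("H_FROM_D", "D_FROM_H"),
                               h0 = 0,
                               models = c("allometry", "power", "linear")) {
  direction <- match.arg(direction)
  n <- length(y)
  stopifnot(length(x) == n, n >= 4)
  rows <- purrr::map(models, function(m) {
    res <- tryCatch({
      if (m == "allometry") {
        f <- fit_allometry(x, y, direction, h0 = h0)
        list(k = f$k, rss = f$rss)
      } else if (m == "power") {
        f <- fit_power_law(x, y)
        list(k = f$k, rss = f$rss)
      } else if (m == "linear") {
        f <- stats::lm.fit(cbind(1, x), y)
        list(k = 2L, rss = sum(f$residuals^2))
      } else {
        stop("unknown model id: ", m, call. = FALSE)
      }
    }, error = function(e) list(k = NA_integer_, rss = NA_real_))
    if (!is.finite(res$rss)) {
      tibble::tibble(model = m, k = res$k, rss = NA_real_, aic = Inf)
    } else {
      rss <- max(res$rss, 1e-300)  # guard log(0) for exact fits
      tibble::tibble(model = m, k = res$k, rss = res$rss,
                     aic = n * log(rss / n) + 2 * res$k)
    }
  })
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, .data$aic, .data$k)
}
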