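## QTL control-network reconstruction: each QTL's genetic-effect curve
## dynamics dP_k/dt are decomposed into an independent component U_k(P_k)
## and regulator-dependent components U_kk'(P_k'), every U a Legendre
## polynomial expansion in its own argument.  Regulators are chosen by
## group-penalized regression of the differentiated focal curve on candidate
## basis expansions; ODE parameters are then refined against a 4th-order
## Runge-Kutta solution of the focal equation with regulator curves held at
## their observed (interpolated) values.

## Curve tables are long tibbles with columns qtl, t, value (optional
## qtl_class); all curves must share the same grid.
as_curve_list <- function(curves) {
  curves <- tibble::as_tibble(curves)
  stopifnot(all(c("qtl", "t", "value") %in% names(curves)))
  ids <- unique(curves$qtl)
  grid <- sort(unique(curves$t))
  vals <- list(); cls <- character()
  for (id in ids) {
    sub <- curves[curves$qtl == id, ]
    sub <- sub[order(sub$t), ]
    if (!isTRUE(all.equal(sub$t, grid))) {
      stop("curve grids differ across QTLs (qtl ", id, ")", call. = FALSE)
    }
    vals[[id]] <- sub$value
    cls[id] <- if ("qtl_class" %in% names(sub)) as.character(sub$qtl_class[1])
      else NA_character_
  }
  if (length(grid) < 5) stop("curves need a grid of >= 5 occasions",
                             call. = FALSE)
  list(ids = ids, grid = grid, values = vals, classes = cls)
}

#' Sparse regulator selection for one focal QTL
#'
#' Regresses the numerically differentiated (optionally presmoothed) focal
#' effect curve on Legendre basis expansions of every candidate curve under a
#' group-sparsity penalty with one group per candidate; the focal QTL's own
#' basis (its independent component) enters unpenalized.  Candidates with a
#' nonzero coefficient group are selected, ordered by group norm.  The
#' penalty is chosen by BIC over a log-spaced path unless `lambda` is given.
#'
#' @param curves Long curve table (`qtl, t, value`) on a common grid of at
#'   least 5 occasions.
#' @param focal Focal QTL id (must be in `curves`).
#' @param candidates Candidate regulator ids (default: all other QTLs).
#' @param r Legendre basis order (default 4).
#' @param lambda Optional fixed penalty; `Inf` forces the empty set.
#' @param smooth Presmooth curves with a smoothing spline (equivalent
#'   degrees of freedom `min(10, T - 2)`) before differencing (default
#'   `TRUE`).
#' @param nlambda,lambda_min_ratio Path controls.
#' @param penalty_factor Optional positive per-candidate penalty
#'   multipliers (adaptive weighting); smaller values make a candidate
#'   cheaper to select.
#' @return A tibble `regulator, norm, entry_lambda` (selected regulators,
#'   decreasing norm), with attributes `lambda` (the value used), `path`
#'   (the full path tibble), `entry_lambda` (largest penalty at which each
#'   candidate is active) and `marginal` (named vector over all candidates:
#'   the fraction of the derivative's unpenalized-model residual each
#'   candidate's basis explains alone; the per-edge ROC score).
#' @export
select_regulators <- function(curves, focal, candidates = NULL, r = 4,
                              lambda = NULL, smooth = TRUE, nlambda = 20,
                              lambda_min_ratio = 1e-3,
                              penalty_factor = NULL) {
  cl <- as_curve_list(curves)
  if (!focal %in% cl$ids) stop("unknown focal QTL: ", focal, call. = FALSE)
  if (is.null(candidates)) candidates <- setdiff(cl$ids, focal)
  if (focal %in% candidates) stop("focal must not be a candidate", call. = FALSE)
  grid <- cl$grid
  sm <- function(v) if (smooth) smooth_curve(grid, v) else v
  pf <- sm(cl$values[[focal]])
  y <- numeric_deriv(grid, pf)

  empty <- tibble::tibble(regulator = character(), norm = numeric(),
                          entry_lambda = numeric())
  zero_entry <- stats::setNames(rep(0, length(candidates)), candidates)
  if (all(abs(y) < 1e-12) || identical(lambda, Inf)) {
    return(structure(empty, lambda = lambda, path = NULL,
                     entry_lambda = zero_entry, marginal = zero_entry))
  }

  X_unpen <- cbind(1, legendre_basis(pf, r))
  groups <- purrr::map(candidates, function(id) {
    legendre_basis(sm(cl$values[[id]]), r)
  })
  gp <- group_lasso_path(X_unpen, groups, y, nlambda = nlambda,
                         lambda_min_ratio = lambda_min_ratio,
                         penalty_factor = penalty_factor)
  fit <- if (is.null(lambda)) gp$best_fit else
    group_lasso_solve(gp$prep, lambda)
  lam_used <- if (is.null(lambda)) gp$best_lambda else lambda
  entry <- stats::setNames(gp$entry_lambda, candidates)
  sel <- which(fit$norms > 0)
  out <- tibble::tibble(regulator = candidates[sel],
                        norm = fit$norms[sel],
                        entry_lambda = entry[candidates[sel]])
  out <- dplyr::arrange(out, dplyr::desc(.data$norm))
  structure(out, lambda = lam_used, path = gp$path, entry_lambda = entry,
            marginal = stats::setNames(gp$marginal, candidates),
            beta = fit$beta, alpha = fit$alpha)
}

## ---- RK4 with component-wise accumulation ----------------------------------

## Stage times and per-regulator basis tables for the fixed substep grid:
## the dependent terms U_g(reg_g(t)) do not involve the state, so their
## values at every RK4 stage are precomputable once per fit.
rk4_stage_basis <- function(grid, reg_curve, reg_range, r, steps) {
  n <- length(grid)
  t0 <- c(); tm <- c(); t1 <- c()
  for (i in seq_len(n - 1)) {
    h <- (grid[i + 1] - grid[i]) / steps
    base <- grid[i] + (seq_len(steps) - 1) * h
    t0 <- c(t0, base); tm <- c(tm, base + h / 2); t1 <- c(t1, base + h)
  }
  vals <- function(tt) stats::approx(grid, reg_curve, xout = tt,
                                     rule = 2)$y
  list(B1 = anchored_legendre(vals(t0), r, reg_range),
       Bm = anchored_legendre(vals(tm), r, reg_range),
       B2 = anchored_legendre(vals(t1), r, reg_range))
}

## Solves dP/dt = U_self(P) + sum_g U_g(reg_g(t)) on the occasion grid with
## `steps` RK4 substeps per interval, accumulating each component's
## contribution with the same stage weights so that
## total(t) = P(t1) + independent(t) + sum_g dependent_g(t) exactly.
## `dep` is a list per regulator: either stage-forcing vectors
## (d1, dm, d2 over all substeps, from rk4_stage_basis tables) or the
## legacy (fun, phi, range) form.
rk4_components <- function(grid, p0, phi_self, self_range,
                           dep = list(), steps = 4) {
  n <- length(grid)
  G <- length(dep)
  nsub <- (n - 1) * steps
  ## stage-forcing matrices (nsub x G)
  if (G) {
    getd <- function(d, which) {
      if (!is.null(d$d1)) return(d[[which]])
      ## legacy interface: evaluate U_g(reg(t)) at the stage times
      tt <- c()
      for (i in seq_len(n - 1)) {
        h <- (grid[i + 1] - grid[i]) / steps
        base <- grid[i] + (seq_len(steps) - 1) * h
        tt <- c(tt, base + switch(which, d1 = 0, dm = h / 2, d2 = h))
      }
      vapply(tt, function(x) anchored_eval(d$fun(x), d$phi, d$range), 1)
    }
    D1 <- vapply(dep, getd, numeric(nsub), which = "d1")
    Dm <- vapply(dep, getd, numeric(nsub), which = "dm")
    D2 <- vapply(dep, getd, numeric(nsub), which = "d2")
    rs1 <- rowSums(D1); rsm <- rowSums(Dm); rs2 <- rowSums(D2)
  }
  total <- numeric(n); total[1] <- p0
  indep <- numeric(n)
  deps <- if (G) matrix(0, n, G) else matrix(0, n, 0)
  u_self <- function(p) legendre_eval(p, phi_self, self_range, TRUE)
  p <- p0; ind_acc <- 0; dep_acc <- rep(0, G)
  idx <- 0L
  for (i in seq_len(n - 1)) {
    h <- (grid[i + 1] - grid[i]) / steps
    for (s in seq_len(steps)) {
      idx <- idx + 1L
      ds1 <- if (G) rs1[idx] else 0
      dsm <- if (G) rsm[idx] else 0
      ds2 <- if (G) rs2[idx] else 0
      k1s <- u_self(p)
      k2s <- u_self(p + h / 2 * (k1s + ds1))
      k3s <- u_self(p + h / 2 * (k2s + dsm))
      k4s <- u_self(p + h * (k3s + dsm))
      if (!all(is.finite(c(k1s, k2s, k3s, k4s)))) return(NULL)
      inc_self <- h / 6 * (k1s + 2 * k2s + 2 * k3s + k4s)
      p <- p + inc_self + if (G) h / 6 * (ds1 + 4 * dsm + ds2) else 0
      if (!is.finite(p) || abs(p) > 1e6) return(NULL)
      ind_acc <- ind_acc + inc_self
      if (G) dep_acc <- dep_acc + h / 6 * (D1[idx, ] + 4 * Dm[idx, ] +
                                             D2[idx, ])
    }
    total[i + 1] <- p
    indep[i + 1] <- ind_acc
    if (G) deps[i + 1, ] <- dep_acc
  }
  list(total = total, independent = indep, dependent = deps)
}

#' Fit the ODE decomposition of QTL effect-curve dynamics
#'
#' For each focal QTL `k`, fits the equation
#' \eqn{dP_k/dt = U_k(P_k) + \sum_{k'} U_{kk'}(P_{k'})} where each `U` is a
#' Legendre polynomial expansion of order `r` in its own argument (the
#' independent function additionally carries a constant term).  Coefficients
#' minimise the squared distance between the observed focal curve and the
#' 4th-order Runge-Kutta solution started at the first observation, with
#' regulator curves held at their observed, linearly interpolated values;
#' fitting is per-focal (decoupled given observed regulator curves).
#' The primary estimator is integral-matching least squares (the model
#' trajectory is linear in the coefficients when every `U` is evaluated
#' along the observed curves), which is well conditioned and leaves the
#' component decomposition stable; `polish = TRUE` adds a Nelder-Mead
#' refinement of the exact RK4 trajectory objective (it can lower the
#' trajectory SSE slightly but perturbs the decomposition along weakly
#' identified directions, so it is off by default).  ODE blow-ups during
#' optimisation yield a large finite penalty, never `NaN`.
#'
#' @param curves Long curve table (`qtl, t, value`) on a common grid.
#' @param regulator_map Named list: focal id -> character vector of
#'   regulator ids (missing focals get no regulators).
#' @param r Basis order (default 4).
#' @param ode_steps RK4 substeps per grid interval (default 8).
#' @param smooth Presmooth curves before fitting (default `TRUE`).
#' @param polish Refine the integral-matching solution against the exact
#'   RK4 trajectory objective (default `FALSE`; see Details).
#' @param maxit Simplex iteration cap for the polish step.
#' @return An object of class `qdode_fit`: per-focal component parameters,
#'   fitted trajectories, and objective values.
#' @export
fit_qdode <- function(curves, regulator_map = list(), r = 4, ode_steps = 8,
                      smooth = TRUE, polish = FALSE, maxit = 400) {
  cl <- as_curve_list(curves)
  bad <- setdiff(names(regulator_map), cl$ids)
  if (length(bad)) stop("regulator_map names not in curves: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  grid <- cl$grid
  sm <- function(v) if (smooth) smooth_curve(grid, v) else v
  smoothed <- purrr::map(cl$values, sm)

  fits <- purrr::map(cl$ids, function(focal) {
    regs <- regulator_map[[focal]]
    if (is.null(regs)) regs <- character()
    pf <- smoothed[[focal]]
    obs <- cl$values[[focal]]
    self_range <- range(pf)
    reg_ranges <- purrr::map(regs, function(id) range(smoothed[[id]]))
    names(reg_ranges) <- regs

    ## integral-matching least squares for initial coefficients: the model
    ## trajectory is linear in the coefficients when every U is evaluated
    ## along the observed (smoothed) curves, so regress the observed
    ## increments on cumulatively integrated basis columns — much better
    ## conditioned than matching finite-difference derivatives
    Xs <- legendre_basis(pf, r, self_range, include_constant = TRUE)
    Xd <- purrr::map(regs, function(id) {
      anchored_legendre(smoothed[[id]], r, reg_ranges[[id]])
    })
    X <- do.call(cbind, c(list(Xs), Xd))
    Xint <- apply(X, 2, function(col) cumtrapz0(grid, col))
    yinc <- obs - obs[1]
    cf <- tryCatch({
      co <- qr.coef(qr(Xint), yinc); co[is.na(co)] <- 0; co
    }, error = function(e) rep(0, ncol(X)))

    split_coef <- function(theta) {
      phi_self <- theta[seq_len(r + 1)]
      phi_dep <- list()
      if (length(regs)) {
        for (g in seq_along(regs)) {
          phi_dep[[regs[g]]] <- theta[(r + 1) + ((g - 1) * r + 1):(g * r)]
        }
      }
      list(self = phi_self, dep = phi_dep)
    }
    ## regulator bases at all RK4 stage times, precomputed once: the
    ## dependent terms do not involve the state, so each objective
    ## evaluation only needs G small matrix-vector products
    stage <- purrr::map(regs, function(id) {
      rk4_stage_basis(grid, smoothed[[id]], reg_ranges[[id]], r, ode_steps)
    })
    make_dep <- function(phi_dep) {
      purrr::map(seq_along(regs), function(g) {
        st <- stage[[g]]; phi <- phi_dep[[regs[g]]]
        list(d1 = as.vector(st$B1 %*% phi),
             dm = as.vector(st$Bm %*% phi),
             d2 = as.vector(st$B2 %*% phi))
      })
    }
    solve_at <- function(theta) {
      sc <- split_coef(theta)
      rk4_components(grid, obs[1], sc$self, self_range,
                     make_dep(sc$dep), steps = ode_steps)
    }
    objective <- function(theta) {
      sol <- solve_at(theta)
      if (is.null(sol)) return(1e10)
      sum((sol$total - obs)^2)
    }

    ## damp an unstable initialisation toward zero until it integrates;
    ## near-collinear regressors can make the LS coefficients arbitrarily
    ## large, so keep halving until the solve succeeds
    for (k in 0:40) {
      if (objective(cf * 2^-k) < 1e10) { cf <- cf * 2^-k; break }
      if (k == 40) cf <- cf * 0
    }
    theta <- cf
    converged <- TRUE
    if (polish && stats::sd(obs) > 1e-12) {
      opt <- stats::optim(theta, objective, method = "Nelder-Mead",
                          control = list(maxit = maxit, reltol = 1e-10))
      if (opt$value <= objective(cf)) theta <- opt$par
      converged <- opt$convergence == 0L || opt$value < 1e-8
    }
    sc <- split_coef(theta)
    sol <- solve_at(theta)
    if (is.null(sol)) {  # fall back to the damped initialisation
      theta <- cf
      sc <- split_coef(theta)
      sol <- solve_at(theta)
    }
    sse <- if (is.null(sol)) 1e10 else sum((sol$total - obs)^2)
    list(qtl = focal, phi_self = sc$self, phi_dep = sc$dep,
         basis_order = r, self_range = self_range, reg_ranges = reg_ranges,
         regulators = regs, grid = grid, observed = obs,
         smoothed = pf, solution = sol, sse = sse,
         converged = converged && !is.null(sol), ode_steps = ode_steps)
  })
  names(fits) <- cl$ids
  structure(list(fits = fits, grid = grid, classes = cl$classes, r = r,
                 smooth = smooth),
            class = "qdode_fit")
}

#' @export
print.qdode_fit <- function(x, ...) {
  nreg <- vapply(x$fits, function(f) length(f$regulators), 1L)
  cat("<qdode_fit> ", length(x$fits), " QTLs, basis order ", x$r,
      ", total regulators ", sum(nreg), "\n", sep = "")
  invisible(x)
}

#' Decompose a fitted QTL effect trajectory into ODE components
#'
#' Returns the independent curve (cumulative integral of the fitted
#' \eqn{U_k(P_k(t))}), one dependent curve per regulator (cumulative
#' integral of \eqn{U_{kk'}(P_{k'}(t))}), and the fitted total trajectory.
#' By construction of the shared integrator,
#' `initial value + independent + sum(dependent) == total` to machine
#' precision.
#'
#' @param fit A [fit_qdode()] result.
#' @param focal Focal QTL id.
#' @return A tibble `qtl, component, regulator, t, value` where `component`
#'   is one of `observed`, `total`, `independent`, `dependent` (the latter
#'   with `regulator` filled in).
#' @export
decompose_effects <- function(fit, focal) {
  stopifnot(inherits(fit, "qdode_fit"))
  f <- fit$fits[[focal]]
  if (is.null(f)) stop("unknown focal QTL: ", focal, call. = FALSE)
  if (is.null(f$solution)) stop("fit for ", focal, " did not converge",
                                call. = FALSE)
  grid <- f$grid
  base <- function(component, value, regulator = NA_character_) {
    tibble::tibble(qtl = focal, component = component, regulator = regulator,
                   t = grid, value = value)
  }
  out <- dplyr::bind_rows(
    base("observed", f$observed),
    base("total", f$solution$total),
    base("independent", f$solution$independent)
  )
  if (length(f$regulators)) {
    for (g in seq_along(f$regulators)) {
      out <- dplyr::bind_rows(out, base("dependent", f$solution$dependent[, g],
                                        f$regulators[g]))
    }
  }
  out
}

## ---- network assembly ------------------------------------------------------

edge_sign <- function(dep_curve) {
  m <- mean(dep_curve)
  if (m > 0) return("+")
  if (m < 0) return("-")
  pos <- sum(pmax(dep_curve, 0)); neg <- sum(pmax(-dep_curve, 0))
  if (pos >= neg) "+" else "-"
}

## Marginal regulator-score matrix: M[from, to] is the fraction of the
## residual of focal `to`'s differentiated (smoothed) curve — after the
## unpenalized independent-component fit — explained by candidate `from`'s
## basis alone.  Cheap (no penalized path), the backbone of the two-pass
## reconstruction.
marginal_score_matrix <- function(cl, r = 4, smooth = TRUE) {
  ids <- cl$ids
  grid <- cl$grid
  sm <- function(v) if (smooth) smooth_curve(grid, v) else v
  S <- vapply(ids, function(id) sm(cl$values[[id]]), numeric(length(grid)))
  M <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (focal in ids) {
    pf <- S[, focal]
    y <- numeric_deriv(grid, pf)
    Xu <- cbind(1, legendre_basis(pf, r))
    qu <- qr(Xu)
    yp <- qr.resid(qu, y)
    den <- max(sum(yp^2), 1e-12)
    for (cand in setdiff(ids, focal)) {
      Xg <- legendre_basis(S[, cand], r)
      Xg_perp <- Xg - Xu %*% qr.coef(qu, Xg)
      Xg_perp[is.na(Xg_perp)] <- 0
      qq <- qr(Xg_perp)
      M[cand, focal] <- sum(qr.fitted(qq, yp)^2) / den
    }
  }
  M
}

#' Reconstruct a QTL control network from effect curves
#'
#' Two-pass reconstruction.  Pass one computes, for every ordered pair, the
#' marginal fraction of the focal curve's residual dynamics explained by
#' the candidate's basis, and aggregates these over focals into a
#' source-propensity weight per QTL — networks in this setting are sparse
#' with a few hub regulators, so a node's evidence of regulating many
#' targets is itself informative.  Pass two runs the group-sparsity
#' selection per focal with adaptive penalties (candidates with high source
#' propensity are cheaper to select), fits the ODE decomposition, and
#' assembles a signed, weighted, directed network.  Edge `k' -> k` carries
#' weight `mean(|U_kk'(P_k'(t))|)` (the mean absolute derivative
#' contribution over the grid) and the sign of the time-averaged dependent
#' curve (ties broken towards `+`); zero-weight edges are absent.  Hub
#' flags mark nodes whose total degree exceeds the network mean, and every
#' unordered pair is classified into one of the six epistasis interaction
#' types.  The per-pair ROC score is the marginal score times the source
#' propensity raised to `cooperation`.
#'
#' @inheritParams select_regulators
#' @inheritParams fit_qdode
#' @param fit_ode If `TRUE` (default) edges are quantified from the RK4-fitted
#'   ODE components; if `FALSE`, from the selection-stage regression
#'   coefficients (fast path used in large simulation sweeps).
#' @param cooperation Exponent on the source-propensity weight in the
#'   per-pair score (default 2).
#' @param adaptive_penalty Use propensity-based penalty multipliers in the
#'   selection pass (default `TRUE`).
#' @param pf_exponent Exponent aligning the adaptive penalties with the
#'   cooperative score (larger = selection order follows the score more
#'   closely; default 2.5).
#' @param ebic_gamma Extended-BIC overselection guard used when choosing
#'   the network-wide operating point (default 1).
#' @param max_in_degree Sparse in-degree prior: at most this many regulators
#'   are retained per focal QTL, ranked by the cooperative score (default 3).
#' @param score_floor_quantile Global evidence floor: selected pairs must
#'   score at or above this quantile of all ordered-pair scores
#'   (default 0.75).
#' @return An object of class `qtl_network`: list with tibbles `nodes`
#'   (`qtl, class, hub`), `edges` (`from, to, sign, weight`, list-column
#'   `dep_curve`), `pair_types` (`qtl1, qtl2, type`), a named `scores`
#'   vector over all ordered pairs (`"from->to"`, for ROC sweeps), and the
#'   underlying `qdode_fit` when `fit_ode = TRUE`.
#' @export
build_network <- function(curves, r = 4, lambda = NULL, smooth = TRUE,
                          nlambda = 20, lambda_min_ratio = 1e-3,
                          fit_ode = TRUE, ode_steps = 8, maxit = 400,
                          cooperation = 2, adaptive_penalty = TRUE,
                          pf_exponent = 2.5, ebic_gamma = 1,
                          max_in_degree = 3L,
                          score_floor_quantile = 0.75) {
  cl <- as_curve_list(curves)
  ids <- cl$ids
  grid <- cl$grid

  ## pass 1: marginal scores and source propensities
  M <- marginal_score_matrix(cl, r = r, smooth = smooth)
  w <- rowMeans(M)
  scores <- c()
  for (focal in ids) {
    for (cand in setdiff(ids, focal)) {
      scores[paste(cand, focal, sep = "->")] <-
        M[cand, focal] * w[cand]^cooperation
    }
  }

  ## pass 2: per-focal group-sparsity paths with adaptive, pair-specific
  ## penalties aligned with the cooperative score (high-evidence pairs are
  ## cheaper); the operating point is one common path position chosen by
  ## the network-level (summed) BIC, so the sparsity level is coordinated
  ## across focals rather than tuned focal by focal
  sm <- function(v) if (smooth) smooth_curve(grid, v) else v
  S <- vapply(ids, function(id) sm(cl$values[[id]]), numeric(length(grid)))
  s_ref <- stats::median(scores[scores > 0])
  gps <- list()
  for (focal in ids) {
    cands <- setdiff(ids, focal)
    pf <- NULL
    if (adaptive_penalty && is.finite(s_ref) && s_ref > 0) {
      s <- scores[paste(cands, focal, sep = "->")]
      pf <- unname(pmin(pmax((s_ref / pmax(s, 1e-12))^pf_exponent, 0.1), 10))
    }
    pfocal <- S[, focal]
    y <- numeric_deriv(grid, pfocal)
    if (all(abs(y) < 1e-12)) {
      gps[[focal]] <- NULL
      next
    }
    Xu <- cbind(1, legendre_basis(pfocal, r))
    groups <- purrr::map(cands, function(id) legendre_basis(S[, id], r))
    gps[[focal]] <- c(group_lasso_path(Xu, groups, y, nlambda = nlambda,
                                       lambda_min_ratio = lambda_min_ratio,
                                       lambda = if (is.null(lambda)) NULL else
                                         lambda,
                                       penalty_factor = pf,
                                       ebic_gamma = ebic_gamma),
                      list(cands = cands))
  }
  ## operating point: per focal, keep at most max_in_degree gated
  ## candidates ranked by the cooperative score, subject to a global score
  ## floor (quantile over all ordered pairs); the penalized path acts as a
  ## screening gate (a candidate never admitted anywhere on the path is out)
  floor_v <- if (length(scores)) {
    stats::quantile(scores, score_floor_quantile, names = FALSE)
  } else {
    0
  }
  ## chance-anchored floor on the raw marginal score: a rank-r basis explains
  ## about r/(T - r - 1) of a pure-noise residual; in the informative regime
  ## a candidate must beat that level by 25% to be eligible at all
  chance_frac <- r / max(length(grid) - r - 1, 1)
  marg_floor <- if (chance_frac < 0.4) 1.25 * chance_frac else 0
  focal_pos <- purrr::map(gps, function(g) {
    if (is.null(g)) return(NA_integer_)
    nrow(g$path)
  })
  reg_map <- purrr::map(stats::setNames(ids, ids), function(focal) {
    g <- gps[[focal]]
    if (is.null(g)) return(character())
    act <- g$path$active[[focal_pos[[focal]]]]
    if (!length(act)) return(character())
    cand <- g$cands[act]
    sc <- scores[paste(cand, focal, sep = "->")]
    keep <- sc >= floor_v & M[cand, focal] >= marg_floor
    cand <- cand[keep]; sc <- sc[keep]
    if (!length(cand)) return(character())
    cand[order(sc, decreasing = TRUE)][seq_len(min(max_in_degree,
                                                   length(cand)))]
  })
  sels <- purrr::imap(reg_map, function(regs, focal) {
    g <- gps[[focal]]
    if (is.null(g) || !length(regs)) {
      return(tibble::tibble(regulator = character(), norm = numeric()))
    }
    norms <- g$path$norms[[focal_pos[[focal]]]]
    tibble::tibble(regulator = regs,
                   norm = norms[match(regs, g$cands)]) |>
      dplyr::arrange(dplyr::desc(.data$norm))
  })

  edges <- tibble::tibble(from = character(), to = character(),
                          sign = character(), weight = numeric(),
                          dep_curve = list())
  qfit <- NULL
  if (fit_ode) {
    qfit <- fit_qdode(curves, reg_map, r = r, ode_steps = ode_steps,
                      smooth = smooth, maxit = maxit)
    for (focal in ids) {
      f <- qfit$fits[[focal]]
      if (is.null(f$solution) || !length(f$regulators)) next
      sm_reg <- function(id) if (smooth) smooth_curve(grid, cl$values[[id]])
        else cl$values[[id]]
      for (g in seq_along(f$regulators)) {
        reg <- f$regulators[g]
        contrib <- anchored_legendre(sm_reg(reg), f$basis_order,
                                     f$reg_ranges[[reg]]) %*% f$phi_dep[[reg]]
        w <- mean(abs(contrib))
        if (w <= 0) next
        dep <- f$solution$dependent[, g]
        edges <- dplyr::bind_rows(edges, tibble::tibble(
          from = reg, to = focal, sign = edge_sign(dep), weight = w,
          dep_curve = list(tibble::tibble(t = grid, value = dep))))
      }
    }
  } else {
    for (focal in ids) {
      g <- gps[[focal]]
      if (is.null(g) || nrow(sels[[focal]]) == 0) next
      beta <- g$fits[[focal_pos[[focal]]]]$beta
      for (reg in sels[[focal]]$regulator) {
        gi <- match(reg, g$cands)
        contrib <- as.vector(anchored_legendre(S[, reg], r,
                                               range(S[, reg])) %*% beta[[gi]])
        wt <- mean(abs(contrib))
        if (wt <= 0) next
        dep <- cumtrapz0(grid, contrib)
        edges <- dplyr::bind_rows(edges, tibble::tibble(
          from = reg, to = focal, sign = edge_sign(dep), weight = wt,
          dep_curve = list(tibble::tibble(t = grid, value = dep))))
      }
    }
  }

  nodes <- tibble::tibble(qtl = ids, class = unname(cl$classes[ids]),
                          hub = FALSE)
  net <- structure(list(nodes = nodes, edges = edges,
                        pair_types = NULL, scores = scores,
                        selection = sels, qdode = qfit),
                   class = "qtl_network")
  net$nodes$hub <- net$nodes$qtl %in% detect_hubs(net)
  net$pair_types <- classify_interactions(net)
  net
}

#' @export
print.qtl_network <- function(x, ...) {
  cat("<qtl_network> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " directed edges, hubs: ",
      paste(x$nodes$qtl[x$nodes$hub], collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Classify pairwise QTL interaction types
#'
#' Labels every unordered QTL pair by the signs of the two possible directed
#' edges between them (absent edge = neutral `0`): `+/+` symmetric positive
#' epistasis, `0/0` symbiosis, `-/-` negative epistasis, `+/0` (either
#' order) directional positive epistasis, `0/-` directional negative
#' epistasis, `+/-` altruistic/repressive epistasis.
#'
#' @param network A [build_network()] result (or a list with `nodes` and
#'   `edges` tibbles).
#' @return A tibble `qtl1, qtl2, sign12, sign21, type` covering all pairs.
#' @export
classify_interactions <- function(network) {
  nodes <- network$nodes$qtl
  edges <- network$edges
  get_sign <- function(a, b) {
    i <- which(edges$from == a & edges$to == b)
    if (length(i)) edges$sign[i[1]] else "0"
  }
  if (length(nodes) < 2) {
    return(tibble::tibble(qtl1 = character(), qtl2 = character(),
                          sign12 = character(), sign21 = character(),
                          type = character()))
  }
  pairs <- utils::combn(nodes, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    s_ab <- get_sign(a, b); s_ba <- get_sign(b, a)
    key <- paste(sort(c(s_ab, s_ba)), collapse = "")
    type <- switch(key,
      "++" = "symmetric positive epistasis",
      "00" = "symbiosis",
      "--" = "negative epistasis",
      "+0" = , "0+" = "directional positive epistasis",
      "-0" = , "0-" = "directional negative epistasis",
      "+-" = , "-+" = "altruistic/repressive epistasis")
    tibble::tibble(qtl1 = a, qtl2 = b, sign12 = s_ab, sign21 = s_ba,
                   type = type)
  })
}

#' Detect hub QTLs
#'
#' A hub is a node whose total degree (in + out) exceeds the mean total
#' degree over all nodes.
#'
#' @param network A `qtl_network`.
#' @return Character vector of hub QTL ids (empty for an edgeless network).
#' @export
detect_hubs <- function(network) {
  nodes <- network$nodes$qtl
  edges <- network$edges
  if (nrow(edges) == 0) return(character())
  deg <- stats::setNames(rep(0, length(nodes)), nodes)
  for (v in edges$from) deg[v] <- deg[v] + 1
  for (v in edges$to) deg[v] <- deg[v] + 1
  nodes[deg > mean(deg)]
}

## ---- import / export -------------------------------------------------------

#' Export a QTL network
#'
#' `"tsv"` writes the edge list (`from, to, sign, weight, pair_type`) with
#' `#` metadata headers and round-trips through [read_network()];
#' `"graphml"` and `"dot"` delegate to [igraph::write_graph()].
#'
#' @param network A `qtl_network`.
#' @param path Output file path.
#' @param format `"tsv"`, `"graphml"` or `"dot"`.
#' @param seed Optional seed recorded in the TSV header.
#' @return Invisibly, `path`.
#' @export
export_network <- function(network, path, format = c("tsv", "graphml", "dot"),
                           seed = NULL) {
  if (!format[1] %in% c("tsv", "graphml", "dot")) {
    stop("unknown format \"", format[1],
         "\"; supported formats: tsv, graphml, dot", call. = FALSE)
  }
  format <- match.arg(format)
  edges <- network$edges
  if (format == "tsv") {
    pt <- network$pair_types
    pair_type <- if (nrow(edges) && !is.null(pt)) {
      vapply(seq_len(nrow(edges)), function(i) {
        hit <- (pt$qtl1 == edges$from[i] & pt$qtl2 == edges$to[i]) |
          (pt$qtl1 == edges$to[i] & pt$qtl2 == edges$from[i])
        if (any(hit)) pt$type[which(hit)[1]] else NA_character_
      }, "")
    } else character(0)
    out <- tibble::tibble(from = edges$from, to = edges$to,
                          sign = edges$sign, weight = edges$weight,
                          pair_type = pair_type)
    writeLines(c(output_header(seed),
                 paste0("# nodes: ", paste(network$nodes$qtl, collapse = ",")),
                 paste0("# hubs: ",
                        paste(network$nodes$qtl[network$nodes$hub],
                              collapse = ","))), path)
    readr::write_tsv(out, path, append = TRUE, col_names = TRUE)
  } else {
    g <- igraph::graph_from_data_frame(
      if (nrow(edges)) edges[, c("from", "to", "sign", "weight")] else
        data.frame(from = character(), to = character()),
      directed = TRUE,
      vertices = data.frame(name = network$nodes$qtl))
    igraph::write_graph(g, path, format = format)
  }
  invisible(path)
}

#' Read a QTL network edge list written by [export_network()]
#'
#' @param path TSV path.
#' @return A `qtl_network` with nodes, edges and recomputed hub flags and
#'   pair types.
#' @export
read_network <- function(path) {
  header <- readLines(path, n = 10)
  node_line <- grep("^# nodes:", header, value = TRUE)
  edges <- read_tsv_commented(path)
  nodes_ids <- if (length(node_line)) {
    strsplit(sub("^# nodes: *", "", node_line[1]), ",")[[1]]
  } else {
    unique(c(edges$from, edges$to))
  }
  edges_tbl <- tibble::tibble(
    from = as.character(edges$from), to = as.character(edges$to),
    sign = as.character(edges$sign), weight = as.numeric(edges$weight),
    dep_curve = rep(list(NULL), nrow(edges))
  )
  net <- structure(
    list(nodes = tibble::tibble(qtl = nodes_ids, class = NA_character_,
                                hub = FALSE),
         edges = edges_tbl, pair_types = NULL, scores = NULL,
         selection = NULL, qdode = NULL),
    class = "qtl_network")
  net$nodes$hub <- net$nodes$qtl %in% detect_hubs(net)
  net$pair_types <- classify_interactions(net)
  net
}
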