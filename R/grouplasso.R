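## Group-penalized regression used for sparse regulator selection.
##
## Minimises  0.5 ||y - U alpha - sum_g X_g beta_g||^2
##            + lambda * sum_g w_g ||beta_g||
## over an unpenalized block U and penalized coefficient groups beta_g
## (one group per candidate regulator), by block coordinate descent after
## groupwise orthonormalisation (each X_g is QR-factorised so its block
## update is an exact group soft-threshold).  Group weights default to
## sqrt(group size).

group_lasso_prepare <- function(X_unpen, groups, y, penalty_factor = NULL) {
  n <- length(y)
  if (is.null(penalty_factor)) penalty_factor <- rep(1, length(groups))
  stopifnot(length(penalty_factor) == length(groups),
            all(penalty_factor > 0))
  Uq <- qr(X_unpen)
  prep_g <- purrr::map(groups, function(X) {
    stopifnot(nrow(X) == n)
    qrx <- qr(X)
    rank <- qrx$rank
    if (rank == 0L) return(list(Q = NULL, R = NULL, rank = 0L, p = ncol(X)))
    Q <- qr.Q(qrx)[, seq_len(rank), drop = FALSE]
    R <- qr.R(qrx)[seq_len(rank), , drop = FALSE]
    list(Q = Q, R = R, rank = rank, p = ncol(X), pivot = qrx$pivot)
  })
  list(y = y, Uq = Uq, X_unpen = X_unpen, groups = prep_g, n = n,
       pf = penalty_factor)
}

group_lasso_solve <- function(prep, lambda, tol = 1e-5, max_sweeps = 80,
                              warm = NULL) {
  G <- length(prep$groups)
  w <- vapply(prep$groups, function(g) sqrt(max(g$rank, 1L)), 1) * prep$pf
  gamma <- if (is.null(warm)) {
    purrr::map(prep$groups, function(g) numeric(g$rank))
  } else {
    warm
  }
  fit_g <- rep(0, prep$n)
  for (g in seq_len(G)) {
    if (prep$groups[[g]]$rank > 0L && any(gamma[[g]] != 0)) {
      fit_g <- fit_g + as.vector(prep$groups[[g]]$Q %*% gamma[[g]])
    }
  }
  alpha <- qr.coef(prep$Uq, prep$y - fit_g)
  alpha[is.na(alpha)] <- 0
  fit_u <- as.vector(prep$X_unpen %*% alpha)
  for (sweep in seq_len(max_sweeps)) {
    delta <- 0
    for (g in seq_len(G)) {
      pg <- prep$groups[[g]]
      if (pg$rank == 0L) next
      r_g <- prep$y - fit_u - fit_g + as.vector(pg$Q %*% gamma[[g]])
      z <- crossprod(pg$Q, r_g)[, 1]
      nz <- sqrt(sum(z^2))
      new_gamma <- if (nz > lambda * w[g]) (1 - lambda * w[g] / nz) * z else
        numeric(pg$rank)
      dchg <- sqrt(sum((new_gamma - gamma[[g]])^2))
      if (dchg > 0) {
        fit_g <- fit_g + as.vector(pg$Q %*% (new_gamma - gamma[[g]]))
        gamma[[g]] <- new_gamma
        delta <- max(delta, dchg)
      }
    }
    alpha_new <- qr.coef(prep$Uq, prep$y - fit_g)
    alpha_new[is.na(alpha_new)] <- 0
    fit_u_new <- as.vector(prep$X_unpen %*% alpha_new)
    delta <- max(delta, sqrt(sum((fit_u_new - fit_u)^2)))
    alpha <- alpha_new; fit_u <- fit_u_new
    if (delta < tol) break
  }
  norms <- vapply(gamma, function(g) sqrt(sum(g^2)), 1)
  ## map orthonormal coordinates back to original group coefficients
  beta <- purrr::imap(prep$groups, function(pg, g) {
    b <- numeric(pg$p)
    if (pg$rank > 0L && norms[[g]] > 0) {
      sol <- backsolve(pg$R, gamma[[g]])
      b[pg$pivot[seq_len(pg$rank)]] <- sol
    }
    b
  })
  resid <- prep$y - fit_u - fit_g
  list(alpha = alpha, beta = beta, gamma = gamma, norms = norms,
       rss = sum(resid^2), fitted = fit_u + fit_g,
       df = sum(!is.na(alpha)) + sum(vapply(seq_along(gamma), function(g)
         if (norms[g] > 0) prep$groups[[g]]$rank else 0L, 0L)))
}

## Lambda path with BIC model choice.  Returns per-lambda activity and the
## largest lambda at which each group is active (its "entry" lambda), the
## score used for ROC sweeps.
group_lasso_path <- function(X_unpen, groups, y, nlambda = 20,
                             lambda_min_ratio = 1e-3, lambda = NULL,
                             penalty_factor = NULL, ebic_gamma = 0.5) {
  prep <- group_lasso_prepare(X_unpen, groups, y, penalty_factor)
  w <- vapply(prep$groups, function(g) sqrt(max(g$rank, 1L)), 1) * prep$pf
  alpha0 <- qr.coef(prep$Uq, y); alpha0[is.na(alpha0)] <- 0
  y_perp <- y - as.vector(X_unpen %*% alpha0)
  gmax <- vapply(seq_along(prep$groups), function(g) {
    pg <- prep$groups[[g]]
    if (pg$rank == 0L) return(0)
    sqrt(sum(crossprod(pg$Q, y_perp)^2)) / w[g]
  }, 1)
  ## marginal score: fraction of the unpenalized-model residual explained by
  ## each group alone (used as the per-edge ROC score)
  ss_perp <- max(sum(y_perp^2), 1e-300)
  marginal <- vapply(seq_along(prep$groups), function(g) {
    pg <- prep$groups[[g]]
    if (pg$rank == 0L) return(0)
    sum(crossprod(pg$Q, y_perp)^2) / ss_perp
  }, 1)
  lambda_max <- max(gmax, 1e-12)
  lams <- if (is.null(lambda)) {
    exp(seq(log(lambda_max * 1.0001), log(lambda_max * lambda_min_ratio),
            length.out = nlambda))
  } else {
    sort(lambda, decreasing = TRUE)
  }
  n <- length(y)
  fits <- vector("list", length(lams))
  warm <- NULL
  for (i in seq_along(lams)) {
    fits[[i]] <- group_lasso_solve(prep, lams[i], warm = warm)
    warm <- fits[[i]]$gamma
  }
  ## extended BIC: the log-binomial term guards against overselection when
  ## the expanded design can (near-)interpolate; a relative RSS floor keeps
  ## the likelihood term finite there
  G <- length(groups)
  rss_floor <- 1e-10 * max(sum(y^2), 1e-12)
  path <- purrr::map2_dfr(lams, fits, function(l, f) {
    k <- sum(f$norms > 0)
    tibble::tibble(lambda = l, df = f$df, n_groups = k,
                   rss = f$rss,
                   bic = n * log(max(f$rss, rss_floor) / n) + f$df * log(n) +
                     2 * ebic_gamma * lchoose(G, k),
                   active = list(which(f$norms > 0)),
                   norms = list(f$norms))
  })
  entry <- vapply(seq_along(groups), function(g) {
    act <- vapply(fits, function(f) f$norms[g] > 0, TRUE)
    if (any(act)) max(lams[act]) else 0
  }, 1)
  ## restrict the information-criterion choice to identifiable path points
  eligible <- which(path$df <= max(n - 1, 1))
  if (!length(eligible)) eligible <- seq_len(nrow(path))
  best <- eligible[which.min(path$bic[eligible])]
  list(path = path, lambdas = lams, fits = fits, entry_lambda = entry,
       marginal = marginal, best_index = best, best_fit = fits[[best]],
       best_lambda = lams[best], prep = prep)
}
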