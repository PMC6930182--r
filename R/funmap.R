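#' Partition individuals by marker genotype
#'
#' Splits the non-missing individuals of a marker into genotype classes
#' (`J = 2` for testcross markers, up to `J = 3` for intercross).  A marker
#' with fewer than two observed classes, or any observed class below the
#' minimum count, is unusable for the likelihood-ratio scan.
#'
#' @param codes Character vector of genotype codes (`NA` = missing).
#' @param cross_type `"TESTCROSS"` or `"INTERCROSS"`.
#' @param min_count Minimum individuals per observed class (default 10).
#' @return A named list of integer index vectors (one per genotype class,
#'   sorted by class label), or `NULL` with attribute `"reason"` when the
#'   marker must be skipped.
#' @export
genotype_groups <- function(codes, cross_type = c("TESTCROSS", "INTERCROSS"),
                            min_count = 10) {
  cross_type <- match.arg(cross_type)
  obs <- which(!is.na(codes))
  classes <- sort(unique(codes[obs]))
  bad <- setdiff(classes, VALID_CODES[[cross_type]])
  if (length(bad)) {
    stop("unknown genotype code \"", bad[1], "\" for ", cross_type,
         call. = FALSE)
  }
  if (length(classes) < 2) {
    return(structure(list(), reason = "monomorphic"))
  }
  groups <- lapply(classes, function(cl) obs[codes[obs] == cl])
  names(groups) <- classes
  small <- vapply(groups, length, 1L) < min_count
  if (any(small)) {
    return(structure(list(),
                     reason = paste0("class below min count: ",
                                     paste(classes[small], collapse = ","))))
  }
  groups
}

## ---- likelihood kernel -----------------------------------------------------

## Residual matrix for one genotype group under the allometry mean structure.
## direction "PI": response heights, predictor diameters, per-individual
## baseline; "MI": response diameters, predictor log-height term precomputed.
funmap_residuals <- function(direction, theta, resp, pred_or_log, baseline) {
  a <- theta[1]; b <- theta[2]; d <- theta[3]
  if (direction == "PI") {
    den <- b + pred_or_log
    if (any(den <= 0, na.rm = TRUE)) return(NULL)
    mu <- exp(a + d / den)
    resp - baseline - mu
  } else {
    den <- a - pred_or_log
    if (any(den <= 0, na.rm = TRUE)) return(NULL)
    mu <- d / den - b
    resp - mu
  }
}

## Profile log-likelihood over (rho, sigma2) given a complete residual
## matrix; closed-form sigma2 profile, 1-D search over rho.  O(nT) per rho.
ar1_profile_ll <- function(R) {
  n <- nrow(R); T_ <- ncol(R); N <- n * T_
  if (T_ == 1L) {
    q0 <- max(sum(R^2), 1e-12)
    s2 <- q0 / N
    return(list(ll = -0.5 * (N * log(2 * pi) + N * log(s2) + N),
                rho = 0, sigma2 = s2))
  }
  D0 <- sum(R[, 1]^2)
  lead <- R[, -1, drop = FALSE]; lag <- R[, -T_, drop = FALSE]
  A <- sum(lead^2); B <- sum(lead * lag); C <- sum(lag^2)
  npairs <- n * (T_ - 1)
  negll <- function(rho) {
    v <- 1 - rho^2
    q <- max(D0 + (A - 2 * rho * B + rho^2 * C) / v, 1e-12)
    s2 <- q / N
    0.5 * (N * log(2 * pi) + N * log(s2) + npairs * log(v) + N)
  }
  opt <- stats::optimize(negll, interval = c(-0.99, 0.99), tol = 1e-7)
  rho <- opt$minimum
  v <- 1 - rho^2
  q <- max(D0 + (A - 2 * rho * B + rho^2 * C) / v, 1e-12)
  list(ll = -opt$objective, rho = rho, sigma2 = q / N)
}

## Missing-data variant: list of residual vectors + observed occasions.
ar1_profile_ll_gapped <- function(res_list, occ_list) {
  N <- sum(lengths(res_list))
  negll <- function(rho) {
    q <- 0; ldc <- 0
    for (i in seq_along(res_list)) {
      qf <- ar1_quadform(res_list[[i]], rho, occ_list[[i]])
      q <- q + qf$q; ldc <- ldc + qf$logdet_corr
    }
    s2 <- max(q, 1e-12) / N
    0.5 * (N * log(2 * pi) + N * log(s2) + ldc + N)
  }
  opt <- stats::optimize(negll, interval = c(-0.99, 0.99), tol = 1e-7)
  rho <- opt$minimum
  q <- 0
  for (i in seq_along(res_list)) {
    q <- q + ar1_quadform(res_list[[i]], rho, occ_list[[i]])$q
  }
  list(ll = -opt$objective, rho = rho, sigma2 = max(q, 1e-12) / N)
}

#' Fit the functional-mapping model for a set of genotype groups
#'
#' Maximises the allometry-structured multivariate-normal likelihood: the
#' genotype-`j` mean for individual `i` at occasion `t` is the allometry
#' equation evaluated at that individual's observed predictor value, and
#' residual vectors carry a shared stationary AR(1) covariance.  With a
#' single group this is the null (no-QTL) fit; with `J` groups the
#' alternative fit, nested by construction.  `(rho, sigma2)` are profiled
#' out in closed form / 1-D search; the genotype-specific `(a, b, d)`
#' triples are optimised by Nelder-Mead simplex from a log-linearised start,
#' with jittered restarts on failure.
#'
#' @param pop A [mapping_population()].
#' @param groups Named list of disjoint individual index vectors (one per
#'   genotype), e.g. from [genotype_groups()].
#' @param direction `"PI"` (response heights, predictor diameters) or `"MI"`
#'   (response diameters, predictor heights).
#' @param h0_global Baseline height for the `MI` direction (default 0); the
#'   `PI` direction always uses each individual's first height observation.
#' @param maxit,reltol Simplex control.
#' @param n_retry Jittered restarts attempted when the simplex fails.
#' @param seed Seed for the restart jitter.
#' @param extra_starts Optional list of additional starting vectors
#'   (length `3J`, groups stacked); the best final likelihood wins.  The
#'   scan uses this to start the alternative fit from the null solution,
#'   which guarantees the nesting `ll1 >= ll0`.
#' @param use_default_start Also run the alternation from the log-linearised
#'   default start (default `TRUE`; the scan disables it for the
#'   alternative fit, whose null-solution start dominates).
#' @return An object of class `funmap_fit`: per-group [allometry_params()],
#'   shared [ar1_params()], `loglik`, `converged`, `direction`, `groups`.
#' @export
fit_funmap <- function(pop, groups, direction = c("PI", "MI"),
                       h0_global = 0, maxit = 400, reltol = 1e-9,
                       n_retry = 5, seed = 1L, extra_starts = NULL,
                       use_default_start = TRUE) {
  direction <- match.arg(direction)
  stopifnot(inherits(pop, "mapping_population"))
  if (length(groups) == 0) stop("empty group list", call. = FALSE)
  idx_all <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(idx_all)) stop("groups must be disjoint", call. = FALSE)
  J <- length(groups)

  if (direction == "PI") {
    resp <- pop$heights; predx <- pop$diameters; baseline <- pop$h0
    pl <- predx
  } else {
    resp <- pop$diameters
    excess <- pop$heights - h0_global
    if (any(excess <= 0, na.rm = TRUE)) {
      stop("heights must exceed h0_global for the MI direction", call. = FALSE)
    }
    pl <- log(excess)
    baseline <- rep(0, pop$n)
  }
  complete <- !anyNA(resp[idx_all, , drop = FALSE]) &&
    !anyNA(pl[idx_all, , drop = FALSE])

  group_eval <- function(theta_j, idx) {
    funmap_residuals(direction, theta_j,
                     resp[idx, , drop = FALSE],
                     pl[idx, , drop = FALSE],
                     baseline[idx])
  }

  ## unit-variance AR(1) quadratic form of one group's residual matrix at a
  ## fixed rho (1e12 on domain violation); the group contributions decouple
  ## at fixed rho, which is what makes the block alternation below exact
  q_group <- function(theta_j, idx, rho) {
    R <- group_eval(theta_j, idx)
    if (is.null(R)) return(1e12)
    if (!anyNA(R)) {
      T_ <- ncol(R)
      if (T_ == 1L) return(sum(R^2))
      lead <- R[, -1, drop = FALSE]; lag <- R[, -T_, drop = FALSE]
      sum(R[, 1]^2) +
        (sum(lead^2) - 2 * rho * sum(lead * lag) + rho^2 * sum(lag^2)) /
        (1 - rho^2)
    } else {
      q <- 0
      for (i in seq_len(nrow(R))) {
        obs <- which(!is.na(R[i, ]))
        if (length(obs)) q <- q + ar1_quadform(R[i, obs], rho, obs)$q
      }
      q
    }
  }

  profile_at <- function(theta) {
    Rs <- lapply(seq_len(J), function(j) {
      group_eval(theta[(3 * j - 2):(3 * j)], groups[[j]])
    })
    if (any(vapply(Rs, is.null, TRUE))) return(NULL)
    Rall <- do.call(rbind, Rs)
    if (complete && !anyNA(Rall)) return(ar1_profile_ll(Rall))
    res_list <- list(); occ_list <- list()
    for (i in seq_len(nrow(Rall))) {
      obs <- which(!is.na(Rall[i, ]))
      if (length(obs)) {
        res_list[[length(res_list) + 1]] <- Rall[i, obs]
        occ_list[[length(occ_list) + 1]] <- obs
      }
    }
    ar1_profile_ll_gapped(res_list, occ_list)
  }

  ## per-group log-linearised starting values
  default_start <- unlist(lapply(groups, function(idx) {
    if (direction == "PI") {
      x <- as.vector(predx[idx, , drop = FALSE])
      y <- as.vector(resp[idx, , drop = FALSE] - baseline[idx])
      ok <- is.finite(x) & is.finite(y)
      allometry_init(x[ok], y[ok], "H_FROM_D", 0)
    } else {
      x <- as.vector(pop$heights[idx, , drop = FALSE])
      y <- as.vector(resp[idx, , drop = FALSE])
      ok <- is.finite(x) & is.finite(y)
      allometry_init(x[ok], y[ok], "D_FROM_H", h0_global)
    }
  }), use.names = FALSE)

  ## block-coordinate alternation: per-group simplex over (a, b, d) at fixed
  ## rho, then 1-D profile update of rho; monotone in the profile likelihood
  run_alternation <- function(theta0, max_outer = 8L) {
    theta <- theta0
    prof <- profile_at(theta)
    if (is.null(prof)) return(NULL)
    for (outer in seq_len(max_outer)) {
      rho <- prof$rho
      for (j in seq_len(J)) {
        sl <- (3 * j - 2):(3 * j)
        opt <- stats::optim(theta[sl], q_group, idx = groups[[j]], rho = rho,
                            method = "Nelder-Mead",
                            control = list(maxit = maxit, reltol = reltol))
        if (opt$value <= q_group(theta[sl], groups[[j]], rho)) {
          theta[sl] <- opt$par
        }
      }
      new_prof <- profile_at(theta)
      if (is.null(new_prof)) break
      improved <- new_prof$ll - prof$ll
      prof <- new_prof
      if (improved < 1e-8) break
    }
    list(theta = theta, prof = prof)
  }

  starts <- if (use_default_start || is.null(extra_starts)) {
    list(default_start)
  } else {
    list()
  }
  if (!is.null(extra_starts)) starts <- c(starts, extra_starts)
  best <- NULL
  for (s in starts) {
    cand <- run_alternation(s)
    if (!is.null(cand) && (is.null(best) || cand$prof$ll > best$prof$ll)) {
      best <- cand
    }
  }
  if (is.null(best)) {
    ## jittered retries from the default start
    rng <- local({ set.seed(seed); function(k) stats::rnorm(k) })
    for (r in seq_len(n_retry)) {
      jit <- default_start * (1 + 0.15 * rng(length(default_start))) +
        0.05 * rng(length(default_start))
      cand <- run_alternation(jit)
      if (!is.null(cand)) { best <- cand; break }
    }
  }
  if (is.null(best)) stop("functional-mapping fit failed for every start",
                          call. = FALSE)
  theta <- best$theta
  prof <- best$prof

  dir_eq <- if (direction == "PI") "H_FROM_D" else "D_FROM_H"
  ## PI baseline is per-individual (pop$h0 stays authoritative); the stored
  ## h0 slot is 0 for PI, the global baseline for MI
  params <- lapply(seq_len(J), function(j) {
    allometry_params(dir_eq,
                     h0 = if (direction == "PI") 0 else h0_global,
                     a = theta[3 * j - 2], b = theta[3 * j - 1],
                     d = theta[3 * j])
  })
  names(params) <- names(groups)

  structure(
    list(params = params, ar1 = ar1_params(prof$rho, prof$sigma2),
         loglik = prof$ll, converged = TRUE, theta = theta,
         direction = direction, groups = groups, h0_global = h0_global),
    class = "funmap_fit"
  )
}

#' @export
print.funmap_fit <- function(x, ...) {
  cat("<funmap_fit> direction ", x$direction, ", J = ", length(x$groups),
      ", loglik = ", signif(x$loglik, 8),
      if (!x$converged) " (NOT converged)" else "", "\n", sep = "")
  invisible(x)
}

## ---- genome scan -----------------------------------------------------------

#' Likelihood-ratio scan for pioneering or maintaining allometry QTLs
#'
#' For each usable marker, fits the functional-mapping model under the null
#' (one shared allometry triple) and the alternative (genotype-specific
#' triples), and tests their equality with a likelihood-ratio statistic
#' referred to a chi-square distribution with `3(J - 1)` degrees of freedom.
#' Direction `"PI"` tests how height growth scales with diameter growth
#' (significant markers are "pioneering" QTLs, piQTLs); `"MI"` tests how
#' diameter growth scales with height growth (miQTLs).  Significance flags
#' use a Bonferroni correction computed within each marker cross type by
#' default (two genome-wide thresholds), or combined across all markers.
#'
#' @inheritParams fit_funmap
#' @param alpha Genome-wide significance level (default 0.05).
#' @param min_count Minimum individuals per genotype class.
#' @param correction `"by_cross_type"` (default) or `"combined"` Bonferroni.
#' @param markers Optional character vector restricting the scan.
#' @return A tibble of class `scan_result`, one row per non-skipped marker:
#'   `marker, chrom, pos, cross_type, direction, J, df, ll0, ll1, LR, p,
#'   neg_log10_p, rho, sigma2, significant`, plus a list-column
#'   `genotype_params` of per-genotype [allometry_params()].  Skipped
#'   markers (with reasons) are in `attr(, "skipped")`; thresholds in
#'   `attr(, "thresholds")`.
#' @export
lr_scan <- function(pop, direction = c("PI", "MI"), alpha = 0.05,
                    min_count = 10, h0_global = 0,
                    correction = c("by_cross_type", "combined"),
                    markers = NULL, maxit = 800, seed = 1L) {
  direction <- match.arg(direction)
  correction <- match.arg(correction)
  stopifnot(inherits(pop, "mapping_population"))
  mk <- pop$markers
  if (!is.null(markers)) mk <- mk[mk$id %in% markers, , drop = FALSE]

  null_cache <- new.env(parent = emptyenv())
  rows <- list(); skipped <- list()
  for (i in seq_len(nrow(mk))) {
    m <- mk[i, ]
    groups <- genotype_groups(m$codes[[1]], m$cross_type, min_count)
    if (length(groups) == 0) {
      skipped[[length(skipped) + 1]] <-
        tibble::tibble(marker = m$id, reason = attr(groups, "reason"))
      next
    }
    idx <- sort(unlist(groups, use.names = FALSE))
    key <- paste(idx, collapse = ",")
    if (is.null(null_cache[[key]])) {
      null_cache[[key]] <- fit_funmap(pop, list(all = idx), direction,
                                      h0_global = h0_global, maxit = maxit,
                                      seed = seed)
    }
    f0 <- null_cache[[key]]
    J <- length(groups)
    f1 <- fit_funmap(pop, groups, direction, h0_global = h0_global,
                     maxit = maxit, seed = seed,
                     extra_starts = list(rep(f0$theta, J)),
                     use_default_start = FALSE)
    LR <- 2 * (f1$loglik - f0$loglik)
    df <- 3L * (J - 1L)
    p <- stats::pchisq(max(LR, 0), df = df, lower.tail = FALSE)
    rows[[length(rows) + 1]] <- tibble::tibble(
      marker = m$id, chrom = m$chrom, pos = m$pos,
      cross_type = m$cross_type, direction = direction,
      J = J, df = df, ll0 = f0$loglik, ll1 = f1$loglik, LR = LR, p = p,
      neg_log10_p = -log10(max(p, .Machine$double.xmin)),
      rho = f1$ar1$rho, sigma2 = f1$ar1$sigma2,
      converged = f0$converged && f1$converged,
      genotype_params = list(f1$params)
    )
  }
  if (length(rows) == 0) {
    stop("all markers were skipped; no scannable marker in the population",
         call. = FALSE)
  }
  out <- dplyr::bind_rows(rows)
  thr <- bonferroni_thresholds(out, alpha, correction)
  out <- flag_significance(out, thr)
  attr(out, "skipped") <- if (length(skipped)) dplyr::bind_rows(skipped) else
    tibble::tibble(marker = character(), reason = character())
  attr(out, "thresholds") <- thr
  attr(out, "direction") <- direction
  class(out) <- c("scan_result", class(out))
  out
}

#' Genome-wide Bonferroni thresholds
#'
#' Per-test significance levels `alpha / m` where `m` counts the scanned
#' markers of each cross type (`correction = "by_cross_type"`, mirroring the
#' two threshold lines of a testcross/intercross Manhattan plot) or all
#' markers jointly (`"combined"`).  A cross type with zero markers gets an
#' `NA` sentinel threshold.
#'
#' @param results A [lr_scan()] result (or any tibble with `cross_type`, `p`).
#' @param alpha Genome-wide level in (0, 1).
#' @param correction `"by_cross_type"` or `"combined"`.
#' @return A tibble `cross_type, n_markers, per_test_alpha,
#'   neg_log10_threshold`.
#' @export
bonferroni_thresholds <- function(results, alpha = 0.05,
                                  correction = c("by_cross_type", "combined")) {
  correction <- match.arg(correction)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)", call. = FALSE)
  types <- c("TESTCROSS", "INTERCROSS")
  if (correction == "combined") {
    m <- nrow(results)
    lev <- if (m > 0) alpha / m else NA_real_
    return(tibble::tibble(cross_type = types,
                          n_markers = m,
                          per_test_alpha = lev,
                          neg_log10_threshold = -log10(lev)))
  }
  purrr::map_dfr(types, function(ct) {
    m <- sum(results$cross_type == ct)
    lev <- if (m > 0) alpha / m else NA_real_
    tibble::tibble(cross_type = ct, n_markers = m, per_test_alpha = lev,
                   neg_log10_threshold = if (is.na(lev)) NA_real_ else -log10(lev))
  })
}

flag_significance <- function(results, thresholds) {
  thr <- thresholds$per_test_alpha[match(results$cross_type,
                                         thresholds$cross_type)]
  results$significant <- !is.na(thr) & results$p < thr
  results
}

## ---- effect curves ---------------------------------------------------------

#' Time-varying genetic-effect curves of a scanned QTL
#'
#' Computes genotype mean curves by averaging, within each genotype class,
#' the fitted allometry mean over that class's individuals at each occasion,
#' then forms effect curves.  For a testcross QTL the effect is
#' `genotype 1 - genotype 2` per occasion.  For an intercross QTL the
#' additive effect is `first homozygote - heterozygote` and the dominant
#' effect is `heterozygote - (homozygote 1 + homozygote 2)/2`; the additive
#' sub-curve doubles as the QTL's overall effect curve for network
#' reconstruction.  The grid carries both the occasion index and the
#' population-mean predictor value, so curves can be plotted against
#' diameter/height or fed to the ODE module against time.
#'
#' @param pop A [mapping_population()].
#' @param scan A [lr_scan()] result.
#' @param marker Marker id (must be present in `scan`).
#' @param min_count Passed to [genotype_groups()].
#' @return A tibble of class `effect_curve` in long format: `qtl`,
#'   `qtl_class` (`piQTL`/`miQTL`), `component` (`effect`, and for
#'   intercross also `add`/`dom`), `occasion`, `predictor_mean`, `value`,
#'   plus per-genotype mean-curve rows (`component = "mean_<genotype>"`).
#' @export
effect_curves <- function(pop, scan, marker, min_count = 10) {
  stopifnot(inherits(pop, "mapping_population"), inherits(scan, "scan_result"))
  row <- scan[scan$marker == marker, ]
  if (nrow(row) == 0) {
    stop("marker ", marker, " not present in the scan (skipped or unknown)",
         call. = FALSE)
  }
  direction <- row$direction[[1]]
  m <- pop$markers[pop$markers$id == marker, ]
  groups <- genotype_groups(m$codes[[1]], m$cross_type, min_count)
  params <- row$genotype_params[[1]]
  h0g <- if (!is.null(attr(scan, "h0_global"))) attr(scan, "h0_global") else 0

  if (direction == "PI") {
    predm <- pop$diameters
  } else {
    predm <- pop$heights
  }
  pred_mean <- colMeans(predm, na.rm = TRUE)

  geno_mean <- function(j) {
    idx <- groups[[j]]
    p <- params[[j]]
    if (direction == "PI") {
      mu <- pop$h0[idx] +
        exp(p$a + p$d / (p$b + pop$diameters[idx, , drop = FALSE]))
    } else {
      mu <- p$d / (p$a - log(pop$heights[idx, , drop = FALSE] - h0g)) - p$b
    }
    colMeans(mu, na.rm = TRUE)
  }
  mus <- lapply(seq_along(groups), geno_mean)
  names(mus) <- names(groups)
  qtl_class <- if (direction == "PI") "piQTL" else "miQTL"

  base <- tibble::tibble(qtl = marker, qtl_class = qtl_class,
                         occasion = seq_len(pop$T),
                         predictor_mean = unname(pred_mean))
  rows <- purrr::imap(mus, function(mu, nm) {
    dplyr::mutate(base, component = paste0("mean_", nm), value = unname(mu))
  })
  if (length(groups) == 2) {
    eff <- mus[[1]] - mus[[2]]
    rows <- c(rows, list(dplyr::mutate(base, component = "effect",
                                       value = unname(eff))))
  } else {
    cls <- names(groups)
    het <- grep("^(ab|np)$", cls, value = TRUE)
    hom <- setdiff(cls, het)
    if (length(het) == 1 && length(hom) == 2) {
      add <- mus[[hom[1]]] - mus[[het]]
      dom <- mus[[het]] - (mus[[hom[1]]] + mus[[hom[2]]]) / 2
      rows <- c(rows,
                list(dplyr::mutate(base, component = "add", value = unname(add)),
                     dplyr::mutate(base, component = "dom", value = unname(dom)),
                     dplyr::mutate(base, component = "effect", value = unname(add))))
    } else {
      ## heterozygote class absent: fall back to difference of the two classes
      eff <- mus[[1]] - mus[[2]]
      rows <- c(rows, list(dplyr::mutate(base, component = "effect",
                                         value = unname(eff))))
    }
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::relocate(out, "qtl", "qtl_class", "component")
  class(out) <- c("effect_curve", class(out))
  out
}

#' Manhattan-ready export of a scan
#'
#' @param scan A [lr_scan()] result.
#' @return A tibble `chrom, pos, marker, cross_type, neg_log10_p,
#'   threshold` (the cross type's genome-wide `-log10` threshold),
#'   `significant`.
#' @export
manhattan_data <- function(scan) {
  stopifnot(inherits(scan, "scan_result"))
  thr <- attr(scan, "thresholds")
  tibble::tibble(
    chrom = scan$chrom, pos = scan$pos, marker = scan$marker,
    cross_type = scan$cross_type, neg_log10_p = scan$neg_log10_p,
    threshold = thr$neg_log10_threshold[match(scan$cross_type,
                                              thr$cross_type)],
    significant = scan$significant
  )
}

#' Write scan results as TSV
#'
#' Flattens the per-genotype parameter list into `a_<g>, b_<g>, d_<g>`
#' columns and writes both the full scan table and a Manhattan-ready table.
#'
#' @param scan A [lr_scan()] result.
#' @param path Output TSV path for the scan table.
#' @param manhattan_path Optional output path for the Manhattan table.
#' @param seed Optional seed recorded in the header.
#' @return Invisibly, `path`.
#' @export
write_scan <- function(scan, path, manhattan_path = NULL, seed = NULL) {
  stopifnot(inherits(scan, "scan_result"))
  flat <- purrr::map_dfr(scan$genotype_params, function(ps) {
    vals <- purrr::imap(ps, function(p, nm) {
      stats::setNames(c(p$a, p$b, p$d), paste0(c("a_", "b_", "d_"), nm))
    })
    tibble::as_tibble(as.list(unlist(unname(vals))))
  })
  out <- dplyr::bind_cols(
    dplyr::select(tibble::as_tibble(scan), -"genotype_params"), flat
  )
  writeLines(output_header(seed), path)
  readr::write_tsv(out, path, append = TRUE, col_names = TRUE)
  if (!is.null(manhattan_path)) {
    writeLines(output_header(seed), manhattan_path)
    readr::write_tsv(manhattan_data(scan), manhattan_path, append = TRUE,
                     col_names = TRUE)
  }
  invisible(path)
}
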