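## Validation experiment: a 14-QTL control network with a designated hub
## (Q2, in-degree 0), simulated under four (T, nu2) scenarios, scored for
## directed-edge recovery (TP, FP, TPR, FPR, ROC-AUC).

EQ10_EDGES <- tibble::tibble(
  from = c(rep("Q2", 9), rep("Q10", 4), rep("Q13", 5)),
  to = c("Q1", "Q3", "Q4", "Q5", "Q6", "Q7", "Q11", "Q12", "Q13",
         "Q3", "Q4", "Q9", "Q11",
         "Q8", "Q9", "Q10", "Q12", "Q14")
)

#' Build the 14-QTL true network used by the simulation study
#'
#' Fourteen QTLs `Q1..Q14` with 18 directed edges under the minimal reading
#' of the coupled system (`Q2 -> {Q1,Q3,Q4,Q5,Q6,Q7,Q11,Q12,Q13}`,
#' `Q10 -> {Q3,Q4,Q9,Q11}`, `Q13 -> {Q8,Q9,Q10,Q12,Q14}`); `Q2` receives no
#' regulation and is the designated hub.  True component functions are
#' bistable cubic self-dynamics \eqn{U_k(Q) = \alpha_k Q (1 - (Q/K_k)^2)}
#' (genetic effects may change sign during ontogeny) and signed linear
#' couplings \eqn{U_{kk'}(Q') = \beta_{kk'} Q'}.  Regulating nodes (`Q2`,
#' `Q10`, `Q13`) get slow, sustained dynamics; regulated nodes get faster
#' dynamics with smaller attractors, so incoming regulation eventually
#' overcomes the self-restoring force and most regulated trajectories rise
#' and then fall (or vice versa).  Such non-monotone ("folded")
#' trajectories are what makes regulator identity statistically
#' recoverable: along a fold, the self-term cancels and the needed
#' correction pins down the regulator.  Parameters are drawn from the
#' declared ranges under a fixed seed; a draw is rejected and redrawn when
#' the solution blows up, leaves the declared state band, any curve is
#' nearly flat, or fewer than `min_folds` regulated curves fold.
#'
#' @param seed Seed for the parameter draw.
#' @param edges Optional directed edge tibble (`from, to`) overriding the
#'   default; edges into `Q2` or self-edges are rejected.
#' @param alpha_reg_range,alpha_target_range Self-dynamics rate ranges for
#'   regulating and regulated nodes.
#' @param K_reg_range,K_target_range Attractor-magnitude ranges.
#' @param q0_frac_range Initial value as a fraction of `K` for regulated
#'   nodes (sign random); regulators start at a small positive fraction.
#' @param beta_range Magnitude range of the linear coupling coefficients
#'   (signs drawn at random).
#' @param t_span Time interval covered by the system (default `c(0, 10)`).
#' @param min_folds Minimum number of regulated curves that must be
#'   non-monotone (default 11 of 13).
#' @param fold_depth Minimum ratio of the smaller of total rise/total fall
#'   to the curve range for a curve to count as folded.
#' @param max_redraw Bounded retries for rejected draws.
#' @return An object of class `true_network_spec`.
#' @export
build_eq10_network <- function(seed = 42L, edges = NULL,
                               alpha_reg_range = c(0.15, 0.35),
                               alpha_target_range = c(2, 4),
                               K_reg_range = c(3.5, 6),
                               K_target_range = c(2, 5),
                               q0_frac_range = c(0.3, 0.9),
                               beta_range = c(0.3, 0.6),
                               t_span = c(0, 10),
                               min_folds = 11L,
                               fold_depth = 0.15,
                               max_redraw = 20000L) {
  if (is.null(edges)) edges <- EQ10_EDGES
  edges <- tibble::as_tibble(edges)
  if (any(edges$to == "Q2")) {
    stop("the hub Q2 must have in-degree 0; edges into Q2 are not allowed",
         call. = FALSE)
  }
  if (any(edges$from == edges$to)) stop("self-edges are not allowed",
                                        call. = FALSE)
  nodes <- paste0("Q", 1:14)
  stopifnot(all(edges$from %in% nodes), all(edges$to %in% nodes))
  regulators <- unique(edges$from)

  set.seed(seed)
  draw <- function() {
    is_reg <- nodes %in% regulators
    alpha <- ifelse(is_reg,
                    stats::runif(14, alpha_reg_range[1], alpha_reg_range[2]),
                    stats::runif(14, alpha_target_range[1],
                                 alpha_target_range[2]))
    K <- ifelse(is_reg,
                stats::runif(14, K_reg_range[1], K_reg_range[2]),
                stats::runif(14, K_target_range[1], K_target_range[2]))
    ne <- dplyr::mutate(
      edges,
      beta = sample(c(-1, 1), dplyr::n(), replace = TRUE) *
        stats::runif(dplyr::n(), beta_range[1], beta_range[2])
    )
    ## start each regulated node in the basin its net incoming push will
    ## eventually overcome, so regulated trajectories fold
    push <- vapply(nodes, function(v) sum(ne$beta[ne$to == v]), 1)
    q0_sign <- ifelse(push < 0, 1, ifelse(push > 0, -1,
                                          sample(c(-1, 1), 14, replace = TRUE)))
    q0 <- ifelse(is_reg,
                 K * stats::runif(14, 0.05, 0.15),
                 K * stats::runif(14, q0_frac_range[1], q0_frac_range[2]) *
                   q0_sign)
    np <- tibble::tibble(qtl = nodes, alpha = alpha, K = K, q0 = q0)
    list(nodes = np, edges = ne)
  }

  is_folded <- function(v) {
    r <- diff(range(v))
    if (r < 1e-9) return(FALSE)
    rise <- sum(pmax(diff(v), 0))
    fall <- sum(pmax(-diff(v), 0))
    min(rise, fall) / r > fold_depth
  }

  cache_key <- paste(seed, paste(format(c(alpha_reg_range,
                                          alpha_target_range, K_reg_range,
                                          K_target_range, q0_frac_range,
                                          beta_range, t_span, min_folds,
                                          fold_depth)), collapse = ","),
                     paste(edges$from, edges$to, collapse = ";"), sep = "|")
  cached <- .spec_cache[[cache_key]]
  if (!is.null(cached)) return(cached)

  accept <- function(sol) {
    !is.null(sol) && all(is.finite(sol)) && max(abs(sol)) < 12 &&
      all(apply(sol, 2, function(v) diff(range(v)) > 0.3)) &&
      sum(apply(sol[, setdiff(nodes, "Q2")], 2, is_folded)) >= min_folds
  }
  redraws <- 0L
  repeat {
    d <- draw()
    spec <- structure(
      list(nodes = d$nodes, edges = d$edges, hub = "Q2", t_span = t_span,
           seed = seed, redraws = redraws),
      class = "true_network_spec")
    ## cheap screening solve, then a fine-resolution verification
    sol <- tryCatch(
      true_solution(spec, seq(t_span[1], t_span[2], length.out = 60),
                    substeps = 5L),
      error = function(e) NULL)
    if (accept(sol)) {
      fine <- tryCatch(
        true_solution(spec, seq(t_span[1], t_span[2], length.out = 120)),
        error = function(e) NULL)
      if (accept(fine)) {
        .spec_cache[[cache_key]] <- spec
        return(spec)
      }
    }
    redraws <- redraws + 1L
    spec$redraws <- redraws
    if (redraws > max_redraw) {
      stop("could not draw a stable, fold-rich true system within ",
           max_redraw, " retries", call. = FALSE)
    }
  }
}

.spec_cache <- new.env(parent = emptyenv())

#' @export
print.true_network_spec <- function(x, ...) {
  cat("<true_network_spec> 14 QTLs, ", nrow(x$edges),
      " directed edges, hub ", x$hub,
      if (x$redraws > 0) paste0(" (", x$redraws, " redraws)") else "",
      "\n", sep = "")
  invisible(x)
}

## Noise-free solution of the coupled true system on `times` (vectorised
## RK4 over the 14-dim state, fine substeps).
true_solution <- function(spec, times, substeps = 20L) {
  np <- spec$nodes
  B <- matrix(0, 14, 14, dimnames = list(np$qtl, np$qtl))
  for (i in seq_len(nrow(spec$edges))) {
    B[spec$edges$to[i], spec$edges$from[i]] <- spec$edges$beta[i]
  }
  rhs <- function(q) np$alpha * q * (1 - (q / np$K)^2) + as.vector(B %*% q)
  q <- np$q0
  out <- matrix(NA_real_, length(times), 14,
                dimnames = list(NULL, np$qtl))
  out[1, ] <- q
  for (i in seq_len(length(times) - 1)) {
    h <- (times[i + 1] - times[i]) / substeps
    for (s in seq_len(substeps)) {
      k1 <- rhs(q)
      k2 <- rhs(q + h / 2 * k1)
      k3 <- rhs(q + h / 2 * k2)
      k4 <- rhs(q + h * k3)
      q <- q + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      if (any(!is.finite(q)) || max(abs(q)) > 1e4) {
        stop("true system blow-up", call. = FALSE)
      }
    }
    out[i + 1, ] <- q
  }
  out
}

## Stationary AR(1) Gaussian noise vector.
ar1_noise <- function(T_, rho, sigma2) {
  e <- numeric(T_)
  e[1] <- stats::rnorm(1, 0, sqrt(sigma2))
  if (T_ > 1) {
    innov_sd <- sqrt(sigma2 * (1 - rho^2))
    for (t in 2:T_) e[t] <- rho * e[t - 1] + stats::rnorm(1, 0, innov_sd)
  }
  e
}

#' Simulate noisy effect-curve data from the true network
#'
#' The noise-free curves are the Runge-Kutta solution of the coupled true
#' system at `T_` equally spaced occasions over the spec's time span; each
#' replicate adds an independent stationary AR(1) Gaussian residual vector
#' (variance `nu2`, lag-1 correlation `rho`) to every curve.
#'
#' @param spec A [build_eq10_network()] result.
#' @param T_ Number of occasions (10 or 30 in the study design).
#' @param nu2 Residual variance (0.05 or 0.5 in the study design).
#' @param rho Residual AR(1) correlation (default 0.5).
#' @param replicates Number of replicates.
#' @param seed Seed.
#' @return A tibble `replicate, qtl, t, true_value, value`.
#' @export
simulate_network_data <- function(spec, T_, nu2, rho = 0.5,
                                  replicates = 1L, seed = 1L) {
  stopifnot(inherits(spec, "true_network_spec"), T_ >= 2, nu2 >= 0)
  times <- seq(spec$t_span[1], spec$t_span[2], length.out = T_)
  truth <- true_solution(spec, times)
  set.seed(seed)
  purrr::map_dfr(seq_len(replicates), function(rep_i) {
    purrr::map_dfr(seq_len(ncol(truth)), function(j) {
      noise <- if (nu2 > 0) ar1_noise(T_, rho, nu2) else numeric(T_)
      tibble::tibble(replicate = rep_i, qtl = colnames(truth)[j], t = times,
                     true_value = truth[, j], value = truth[, j] + noise)
    })
  })
}

#' Score an inferred network against the true edge set
#'
#' Directed-edge detection over the \eqn{14 \times 13 = 182} ordered node
#' pairs: `TP` = detected true edges, `FP` = detected non-edges,
#' `TPR = TP / 18`, `FPR = FP / 164` (under the 18-edge minimal reading),
#' and ROC-AUC from sweeping a detection threshold over the per-pair scores
#' (the selection-path entry penalties).
#'
#' @param inferred A `qtl_network` or an edge tibble with `from`, `to`.
#' @param spec The [build_eq10_network()] truth (or an edge tibble).
#' @param scores Optional named score vector (`"from->to"`); defaults to the
#'   network's `scores` attribute.  `AUC` is `NA` when unavailable.
#' @param nodes Node ids (defaults to the truth's nodes).
#' @return A one-row tibble `TP, FP, TPR, FPR, AUC`.
#' @export
evaluate_network <- function(inferred, spec, scores = NULL, nodes = NULL) {
  true_edges <- if (inherits(spec, "true_network_spec")) spec$edges else
    tibble::as_tibble(spec)
  if (is.null(nodes)) {
    nodes <- if (inherits(spec, "true_network_spec")) spec$nodes$qtl else
      sort(unique(c(true_edges$from, true_edges$to)))
  }
  inf_edges <- if (inherits(inferred, "qtl_network")) inferred$edges else
    tibble::as_tibble(inferred)
  if (inherits(inferred, "qtl_network")) {
    if (!setequal(inferred$nodes$qtl, nodes)) {
      stop("node sets of inferred network and truth differ", call. = FALSE)
    }
    if (is.null(scores)) scores <- inferred$scores
  }
  ekey <- function(f, t) paste(f, t, sep = "->")
  all_pairs <- expand.grid(from = nodes, to = nodes,
                           stringsAsFactors = FALSE)
  all_pairs <- all_pairs[all_pairs$from != all_pairs$to, ]
  keys <- ekey(all_pairs$from, all_pairs$to)
  truth_v <- keys %in% ekey(true_edges$from, true_edges$to)
  detect_v <- keys %in% ekey(inf_edges$from, inf_edges$to)
  TP <- sum(detect_v & truth_v)
  FP <- sum(detect_v & !truth_v)
  n_true <- sum(truth_v); n_false <- sum(!truth_v)
  auc <- NA_real_
  if (!is.null(scores) && length(scores)) {
    sc <- scores[keys]
    sc[is.na(sc)] <- 0
    if (length(unique(truth_v)) == 2 && stats::sd(sc) > 0) {
      roc <- pROC::roc(response = truth_v, predictor = as.numeric(sc),
                       direction = "<", quiet = TRUE)
      auc <- as.numeric(pROC::auc(roc))
    } else if (stats::sd(sc) == 0) {
      auc <- 0.5
    }
  }
  tibble::tibble(TP = TP, FP = FP,
                 TPR = TP / n_true, FPR = FP / n_false, AUC = auc)
}

#' Run the network-recovery simulation scenarios
#'
#' For each `(nu2, T)` scenario: simulate noisy effect curves from the true
#' network, reconstruct the network per replicate (sparse regulator
#' selection with BIC-chosen penalty; `fit_ode = TRUE` adds the RK4
#' component refit for edge quantification), and score directed-edge
#' recovery.  Reports replicate means with standard deviations.
#'
#' @param spec A [build_eq10_network()] truth (built from `seed` when
#'   omitted).
#' @param scenarios Tibble with columns `nu2`, `T` (default: the four-
#'   scenario grid `{0.05, 0.5} x {10, 30}`).
#' @param replicates Replicates per scenario (default 100).
#' @param seed Master seed; all randomness derives from it.
#' @param rho Residual AR(1) correlation (default 0.5).
#' @param r Basis order for reconstruction.
#' @param smooth,fit_ode Passed to [build_network()].
#' @param max_fail_frac A scenario with more than this fraction of failed
#'   replicates is flagged invalid (default 0.2).
#' @return A tibble of class `simstudy_result`, one row per scenario with
#'   mean and sd columns for TP, FP, TPR, FPR, AUC, `n_ok`, `valid`.
#'   Per-replicate metrics are in `attr(, "replicates")`.
#' @export
run_scenarios <- function(spec = NULL,
                          scenarios = tidyr::expand_grid(nu2 = c(0.05, 0.5),
                                                         T = c(10, 30)),
                          replicates = 100L, seed = 1L, rho = 0.5, r = 4,
                          smooth = TRUE, fit_ode = FALSE,
                          max_fail_frac = 0.2) {
  stopifnot(replicates >= 2)
  if (is.null(spec)) spec <- build_eq10_network(seed = 1000L + seed %% 1000L)
  per_rep <- list()
  for (si in seq_len(nrow(scenarios))) {
    nu2 <- scenarios$nu2[si]; T_ <- scenarios$T[si]
    for (rep_i in seq_len(replicates)) {
      rep_seed <- (seed * 1009L + si * 131L + rep_i) %% .Machine$integer.max
      res <- tryCatch({
        dat <- simulate_network_data(spec, T_, nu2, rho = rho,
                                     replicates = 1L, seed = rep_seed)
        net <- build_network(dat, r = r, smooth = smooth, fit_ode = fit_ode)
        ev <- evaluate_network(net, spec)
        dplyr::mutate(ev, nu2 = nu2, T = T_, replicate = rep_i, ok = TRUE)
      }, error = function(e) {
        tibble::tibble(TP = NA_real_, FP = NA_real_, TPR = NA_real_,
                       FPR = NA_real_, AUC = NA_real_, nu2 = nu2, T = T_,
                       replicate = rep_i, ok = FALSE)
      })
      per_rep[[length(per_rep) + 1]] <- res
    }
  }
  reps <- dplyr::bind_rows(per_rep)
  out <- reps |>
    dplyr::group_by(.data$nu2, .data$T) |>
    dplyr::summarise(
      dplyr::across(c("TP", "FP", "TPR", "FPR", "AUC"),
                    list(mean = ~mean(.x, na.rm = TRUE),
                         sd = ~stats::sd(.x, na.rm = TRUE))),
      n_ok = sum(.data$ok), .groups = "drop") |>
    dplyr::mutate(valid = .data$n_ok >= (1 - max_fail_frac) * replicates)
  attr(out, "replicates") <- reps
  attr(out, "spec") <- spec
  class(out) <- c("simstudy_result", class(out))
  out
}

#' Write a simulation-study report
#'
#' Writes the scenario summary (means with sds in parentheses) and the
#' per-replicate metrics as TSV.  The header states the TPR/FPR
#' denominators (18 true edges, 164 true non-edges).
#'
#' @param result A [run_scenarios()] result.
#' @param path Summary TSV path.
#' @param replicate_path Optional per-replicate metrics TSV path.
#' @param seed Optional seed recorded in the header.
#' @return Invisibly, `path`.
#' @export
write_simstudy <- function(result, path, replicate_path = NULL, seed = NULL) {
  stopifnot(inherits(result, "simstudy_result"))
  fmt <- function(m, s) sprintf("%.2f (%.2f)", m, s)
  pretty <- tibble::tibble(
    nu2 = result$nu2, T = result$T,
    TP = fmt(result$TP_mean, result$TP_sd),
    FP = fmt(result$FP_mean, result$FP_sd),
    TPR = fmt(result$TPR_mean, result$TPR_sd),
    FPR = fmt(result$FPR_mean, result$FPR_sd),
    AUC = fmt(result$AUC_mean, result$AUC_sd)
  )
  writeLines(c(output_header(seed),
               "# TPR denominator: 18 true directed edges;",
               "# FPR denominator: 164 true directed non-edges (182 ordered pairs)"),
             path)
  readr::write_tsv(pretty, path, append = TRUE, col_names = TRUE)
  if (!is.null(replicate_path)) {
    writeLines(output_header(seed), replicate_path)
    readr::write_tsv(attr(result, "replicates"), replicate_path,
                     append = TRUE, col_names = TRUE)
  }
  invisible(path)
}
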