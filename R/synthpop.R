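#' Specify a planted causal allometry QTL
#'
#' Describes one causal marker for [simulate_population()]: its marker
#' index, cross type, and per-genotype allometry parameters.  Parameter sets
#' must differ between genotypes (a causal QTL changes the allometric
#' scaling) and share one direction: `H_FROM_D` plants a piQTL, `D_FROM_H`
#' a miQTL.
#'
#' @param marker_index 1-based index of the causal marker.
#' @param cross_type `"TESTCROSS"` or `"INTERCROSS"`.
#' @param params Named list of [allometry_params()], one per genotype code
#'   (`nn`/`np` for testcross, `aa`/`ab`/`bb` for intercross).
#' @return An object of class `causal_qtl_spec`.
#' @export
causal_qtl_spec <- function(marker_index,
                            cross_type = c("TESTCROSS", "INTERCROSS"),
                            params) {
  cross_type <- match.arg(cross_type)
  need <- VALID_CODES[[cross_type]]
  if (!setequal(names(params), need)) {
    stop("params must be named ", paste(need, collapse = ", "), call. = FALSE)
  }
  stopifnot(all(vapply(params, inherits, TRUE, "allometry_params")))
  dirs <- unique(vapply(params, function(p) p$direction, ""))
  if (length(dirs) != 1) {
    stop("all genotype parameter sets must share one direction", call. = FALSE)
  }
  trip <- vapply(params, function(p) paste(p$a, p$b, p$d), "")
  if (length(unique(trip)) == 1) {
    stop("genotype parameter sets must differ for a causal marker",
         call. = FALSE)
  }
  structure(list(marker_index = as.integer(marker_index),
                 cross_type = cross_type, params = params,
                 direction = dirs),
            class = "causal_qtl_spec")
}

#' Default planted testcross piQTL
#'
#' A convenience causal spec with genotype classes `nn`/`np` differing in
#' the late-stage scale coefficient `a` by `delta_a` (on the log scale of
#' the height increment); the rate `d` is strongly negative so the height
#' increment is negligible at the first occasion and rises with diameter.
#'
#' @param marker_index Causal marker index.
#' @param delta_a Between-genotype difference in `a` (default 0.25).
#' @return A [causal_qtl_spec()].
#' @export
default_causal_piqtl <- function(marker_index = 1L, delta_a = 0.25) {
  causal_qtl_spec(
    marker_index, "TESTCROSS",
    list(nn = allometry_params("H_FROM_D", h0 = 0, a = 4.2, b = 1, d = -21),
         np = allometry_params("H_FROM_D", h0 = 0, a = 4.2 + delta_a,
                               b = 1, d = -21)))
}

#' Simulate a full-sib mapping population with planted allometry QTLs
#'
#' Genotypes segregate 1:1 at testcross markers and 1:2:1 at intercross
#' markers, independently across markers (no linkage).  The predictor trait
#' grows mechanistically: per-individual logistic trajectories with jittered
#' asymptote, rate and midpoint.  The response trait follows the
#' genotype-specific allometry equation of the individual's observed
#' predictor value plus a stationary AR(1) Gaussian residual: with
#' `H_FROM_D` causal specs (piQTLs), diameters are logistic and heights
#' allometric; with `D_FROM_H` specs (miQTLs), heights are logistic and
#' diameters allometric.  Non-causal markers segregate independently of
#' phenotype.  Fully seeded and reproducible.
#'
#' @param n Progeny count (default 180).
#' @param T_ Occasions (default 12, roughly biweekly over a growing season).
#' @param n_markers Number of markers (default 50).
#' @param causal List of [causal_qtl_spec()] (all one direction; may be
#'   empty for a null population).
#' @param noise An [ar1_params()] for the response residuals (default
#'   `ar1_params(0.5, 1.5^2)`: sd 1.5 cm, about 5% of the height range).
#' @param baseline_params [allometry_params()] used at non-causal loci
#'   (defaults match [default_causal_piqtl()]'s `nn` class for `H_FROM_D`,
#'   or `a = 4.6, b = 2, d = 10` for `D_FROM_H`).
#' @param prop_testcross Proportion of testcross markers among the
#'   non-causal ones (default 0.4).
#' @param seed Seed.
#' @return A [mapping_population()].
#' @export
simulate_population <- function(n = 180L, T_ = 12L, n_markers = 50L,
                                causal = list(), noise = ar1_params(0.5, 2.25),
                                baseline_params = NULL,
                                prop_testcross = 0.4, seed = 1L) {
  stopifnot(n >= 40, T_ >= 5, inherits(noise, "ar1_params"))
  if (inherits(causal, "causal_qtl_spec")) causal <- list(causal)
  stopifnot(all(vapply(causal, inherits, TRUE, "causal_qtl_spec")))
  if (length(causal)) {
    ci <- vapply(causal, function(cs) cs$marker_index, 1L)
    if (any(ci < 1L | ci > n_markers)) {
      stop("causal marker indices must lie in 1..n_markers", call. = FALSE)
    }
    if (anyDuplicated(ci)) stop("duplicated causal marker index", call. = FALSE)
    dirs <- unique(vapply(causal, function(cs) cs$direction, ""))
    if (length(dirs) > 1) {
      stop("causal specs must share one allometric direction per population",
           call. = FALSE)
    }
    direction <- dirs
  } else {
    direction <- "H_FROM_D"
  }
  if (is.null(baseline_params)) {
    baseline_params <- if (direction == "H_FROM_D") {
      allometry_params("H_FROM_D", h0 = 0, a = 4.2, b = 1, d = -21)
    } else {
      allometry_params("D_FROM_H", h0 = 0, a = 4.6, b = 2, d = 10)
    }
  }
  stopifnot(baseline_params$direction == direction)

  set.seed(seed)
  ids <- paste0("ind", seq_len(n))
  occ <- seq_len(T_)

  ## genotype draws (independent segregation)
  causal_idx <- vapply(causal, function(cs) cs$marker_index, 1L)
  cross_type <- ifelse(
    seq_len(n_markers) %in% causal_idx,
    vapply(seq_len(n_markers), function(i) {
      hit <- which(causal_idx == i)
      if (length(hit)) causal[[hit]]$cross_type else ""
    }, ""),
    ifelse(stats::runif(n_markers) < prop_testcross,
           "TESTCROSS", "INTERCROSS"))
  codes <- purrr::map(seq_len(n_markers), function(i) {
    if (cross_type[i] == "TESTCROSS") {
      sample(c("nn", "np"), n, replace = TRUE)
    } else {
      sample(c("aa", "ab", "bb"), n, replace = TRUE,
             prob = c(0.25, 0.5, 0.25))
    }
  })
  markers <- tibble::tibble(
    id = sprintf("m%03d", seq_len(n_markers)),
    chrom = as.character(sample(1:8, n_markers, replace = TRUE)),
    pos = sort(stats::runif(n_markers, 1, 3e7)) |> round(),
    cross_type = cross_type, codes = codes
  )

  ## mechanistic logistic growth of the predictor trait
  logistic_mat <- function(Kv, rv, midv) {
    t(vapply(seq_len(n), function(i) {
      Kv[i] / (1 + exp(-rv[i] * (occ - midv[i])))
    }, numeric(T_)))
  }
  if (direction == "H_FROM_D") {
    diam <- logistic_mat(stats::rnorm(n, 25, 2), stats::rnorm(n, 0.55, 0.05),
                         stats::rnorm(n, 6.5, 0.5))
    diam <- pmax(diam, 0.2)
    pred <- diam
    pred_range <- range(pred)
  } else {
    hbase <- stats::rnorm(n, 20, 2)
    hts <- hbase + logistic_mat(stats::rnorm(n, 40, 3),
                                stats::rnorm(n, 0.55, 0.05),
                                stats::rnorm(n, 6.5, 0.5))
    pred <- hts
    pred_range <- range(pred)
  }

  ## domain validation of every causal parameter set before generation
  check_domain <- function(p) {
    if (direction == "H_FROM_D") {
      if (p$b + pred_range[1] <= 0) {
        stop("causal parameters out of domain: b + D <= 0 over the ",
             "simulated diameter range", call. = FALSE)
      }
    } else {
      if (p$a - log(pred_range[2] - p$h0) <= 0 || pred_range[1] <= p$h0) {
        stop("causal parameters out of domain: a - ln(H - h0) <= 0 over the ",
             "simulated height range", call. = FALSE)
      }
    }
  }
  for (cs in causal) lapply(cs$params, check_domain)
  check_domain(baseline_params)

  ## per-individual parameter assignment from the (first) causal marker
  pick_params <- function(i) {
    for (cs in causal) {
      code <- codes[[cs$marker_index]][i]
      if (!is.na(code)) return(cs$params[[code]])
    }
    baseline_params
  }

  resp <- matrix(NA_real_, n, T_)
  for (i in seq_len(n)) {
    p <- pick_params(i)
    mu <- allometry_mean(direction, p$h0, p$a, p$b, p$d, pred[i, ])
    resp[i, ] <- mu + ar1_noise(T_, noise$rho, noise$sigma2)
  }

  if (direction == "H_FROM_D") {
    h0_i <- stats::rnorm(n, 20, 2)
    heights <- h0_i + resp
    heights[heights <= 0.1] <- 0.1
    diameters <- pred
  } else {
    heights <- pred
    diameters <- pmax(resp, 0.05)
  }
  rownames(heights) <- rownames(diameters) <- ids
  mapping_population(heights, diameters, markers,
                     family_id = paste0("sim", seed), ids = ids)
}
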