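test_that("the 14-QTL truth has the declared topology", {
  spec <- build_eq10_network(seed = 42)
  expect_equal(nrow(spec$nodes), 14)
  expect_equal(nrow(spec$edges), 18)
  expect_equal(sum(spec$edges$to == "Q2"), 0)       # hub in-degree 0
  expect_equal(spec$hub, "Q2")
  expect_setequal(spec$edges$to[spec$edges$from == "Q2"],
                  c("Q1", "Q3", "Q4", "Q5", "Q6", "Q7", "Q11", "Q12", "Q13"))
  expect_setequal(spec$edges$to[spec$edges$from == "Q10"],
                  c("Q3", "Q4", "Q9", "Q11"))
  expect_setequal(spec$edges$to[spec$edges$from == "Q13"],
                  c("Q8", "Q9", "Q10", "Q12", "Q14"))
  # 18 of 182 possible ordered pairs
  expect_equal(14 * 13 - nrow(spec$edges), 164)
  # requesting regulation of the hub is a spec violation
  expect_error(build_eq10_network(edges = tibble::tibble(from = "Q1",
                                                         to = "Q2")),
               "in-degree 0")
  # the drawn truth is deterministic given the seed
  spec2 <- build_eq10_network(seed = 42)
  expect_identical(spec$nodes, spec2$nodes)
  expect_identical(spec$edges, spec2$edges)
})

test_that("hub detection on the true topology flags Q2", {
  spec <- build_eq10_network(seed = 42)
  net <- list(nodes = tibble::tibble(qtl = spec$nodes$qtl, class = NA,
                                     hub = FALSE),
              edges = dplyr::mutate(spec$edges, sign = "+", weight = 1,
                                    dep_curve = list(NULL)))
  hubs <- detect_hubs(net)
  expect_true("Q2" %in% hubs)
})

test_that("the in-package coupled solver agrees with the deSolve oracle", {
  skip_if_not_installed("deSolve")
  spec <- build_eq10_network(seed = 42)
  times <- seq(spec$t_span[1], spec$t_span[2], length.out = 15)
  mine <- allonet:::true_solution(spec, times)
  B <- matrix(0, 14, 14, dimnames = list(spec$nodes$qtl, spec$nodes$qtl))
  for (i in seq_len(nrow(spec$edges))) {
    B[spec$edges$to[i], spec$edges$from[i]] <- spec$edges$beta[i]
  }
  rhs <- function(t, q, parms) {
    list(spec$nodes$alpha * q * (1 - (q / spec$nodes$K)^2) +
           as.vector(B %*% q))
  }
  ode <- deSolve::ode(y = spec$nodes$q0, times = times, func = rhs,
                      parms = NULL, method = "lsoda",
                      atol = 1e-10, rtol = 1e-10)
  expect_lt(max(abs(mine - ode[, -1])), 1e-4)
})

test_that("simulated curves have the right shape, noise level, and determinism", {
  spec <- build_eq10_network(seed = 42)
  dat <- simulate_network_data(spec, T_ = 12, nu2 = 0, replicates = 1,
                               seed = 1)
  expect_equal(nrow(dat), 14 * 12)
  expect_equal(dat$value, dat$true_value)   # nu2 = 0 is the exact solution

  # residual variance matches nu2 within 10% over replicates
  nz <- simulate_network_data(spec, T_ = 10, nu2 = 0.4, replicates = 200,
                              seed = 2)
  expect_equal(var(nz$value - nz$true_value), 0.4, tolerance = 0.1 * 0.4)

  # same seed, same data
  a <- simulate_network_data(spec, T_ = 10, nu2 = 0.05, replicates = 2,
                             seed = 9)
  b <- simulate_network_data(spec, T_ = 10, nu2 = 0.05, replicates = 2,
                             seed = 9)
  expect_identical(a, b)

  # residual lag-1 autocorrelation close to the design rho
  resid <- matrix(nz$value - nz$true_value, nrow = 10)
  r1 <- cor(as.vector(resid[-10, ]), as.vector(resid[-1, ]))
  expect_equal(r1, 0.5, tolerance = 0.1)
})

test_that("network scoring counts TP/FP over the 182 ordered pairs", {
  spec <- build_eq10_network(seed = 42)
  # perfect recovery
  perfect <- dplyr::select(spec$edges, "from", "to")
  ev <- evaluate_network(perfect, spec)
  expect_equal(ev$TP, 18); expect_equal(ev$FP, 0)
  expect_equal(ev$TPR, 1); expect_equal(ev$FPR, 0)
  # empty network
  ev0 <- evaluate_network(perfect[0, ], spec)
  expect_equal(ev0$TP, 0); expect_equal(ev0$TPR, 0); expect_equal(ev0$FPR, 0)
  # random scores give chance-level AUC
  set.seed(11)
  nodes <- spec$nodes$qtl
  pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  aucs <- replicate(100, {
    sc <- stats::setNames(runif(nrow(pairs)),
                          paste(pairs$from, pairs$to, sep = "->"))
    evaluate_network(perfect[0, ], spec, scores = sc)$AUC
  })
  expect_equal(mean(aucs), 0.5, tolerance = 0.1)
})

test_that("scenario runs are seeded, bounded, and well-shaped", {
  spec <- build_eq10_network(seed = 42)
  scen <- tibble::tibble(nu2 = 0.05, T = 10)
  r1 <- run_scenarios(spec, scen, replicates = 2, seed = 3, fit_ode = FALSE)
  r2 <- run_scenarios(spec, scen, replicates = 2, seed = 3, fit_ode = FALSE)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_true(all(r1$TPR_mean >= 0 & r1$TPR_mean <= 1))
  expect_true(all(r1$FPR_mean >= 0 & r1$FPR_mean <= 1))
  expect_true(all(r1$TP_mean <= 18))
  reps <- attr(r1, "replicates")
  expect_equal(nrow(reps), 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  fr <- withr::local_tempfile(fileext = ".tsv")
  write_simstudy(r1, f, fr, seed = 3)
  expect_true(any(grepl("164", readLines(f, n = 4))))
  expect_gt(nrow(readr::read_tsv(fr, comment = "#", show_col_types = FALSE)),
            0)
})
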