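test_that("Legendre basis follows the recurrence and handles degeneracy", {
  x <- seq(-3, 5, length.out = 11)
  B <- legendre_basis(x, 3, include_constant = TRUE)
  u <- 2 * (x - min(x)) / diff(range(x)) - 1
  expect_equal(B[, 1], rep(1, 11))
  expect_equal(B[, 2], u)
  expect_equal(B[, 3], (3 * u^2 - 1) / 2)
  expect_equal(B[, 4], (5 * u^3 - 3 * u) / 2)
  # scalar evaluator agrees with the matrix one
  cf <- c(0.3, -1, 2, 0.5)
  expect_equal(allonet:::legendre_eval(x[4], cf, range(x), TRUE),
               drop(B[4, ] %*% cf))
  # degenerate range gives an all-zero basis
  expect_equal(legendre_basis(rep(2, 5), 3), matrix(0, 5, 3))
})

test_that("numerical differentiation uses central/one-sided differences", {
  t <- c(0, 1, 2, 4)
  y <- t^2
  d <- numeric_deriv(t, y)
  expect_equal(d[1], (y[2] - y[1]) / 1)
  expect_equal(d[2], (y[3] - y[1]) / 2)
  expect_equal(d[3], (y[4] - y[2]) / 3)
  expect_equal(d[4], (y[4] - y[3]) / 2)
})

test_that("group lasso selects a planted group and shrinks fully at +Inf-ish lambda", {
  set.seed(1)
  n <- 40
  Xs <- purrr::map(1:4, ~matrix(rnorm(n * 3), n))
  y <- Xs[[2]] %*% c(1, -0.7, 0.4) + 0.05 * rnorm(n)
  gp <- allonet:::group_lasso_path(matrix(1, n, 1), Xs, y)
  expect_equal(which.max(gp$entry_lambda), 2L)
  expect_true(2L %in% which(gp$best_fit$norms > 0))
  # sparsity is monotone along the path
  sizes <- vapply(gp$path$active, length, 1L)
  expect_true(all(diff(sizes) >= 0))
  # huge lambda: nothing selected
  big <- allonet:::group_lasso_solve(gp$prep, max(gp$lambdas) * 10)
  expect_equal(sum(big$norms > 0), 0)
})

test_that("regulator selection finds a planted driver and obeys edge cases", {
  tt <- seq(0, 10, length.out = 30)
  qc <- 2 / (1 + exp(-(tt - 5)))          # candidate driver
  # focal driven by the candidate: dP/dt = 0.5 * qc(t), P(0) = 0.2
  pf <- 0.2 + 0.5 * allonet:::cumtrapz0(tt, qc)
  noisefree <- curves_tbl(tt, focal = pf, c1 = qc,
                          c2 = rep(1.7, 30), c3 = rep(0, 30))
  sel <- select_regulators(noisefree, "focal", r = 2, smooth = FALSE)
  expect_true("c1" %in% sel$regulator)
  expect_equal(sel$regulator[1], "c1")

  # lambda -> Inf gives the empty set
  sel_inf <- select_regulators(noisefree, "focal", lambda = Inf)
  expect_equal(nrow(sel_inf), 0)

  # all-zero candidates are never selected; zero focal derivative -> empty
  flat <- curves_tbl(tt, focal = rep(2, 30), c1 = rep(0, 30), c2 = rep(0, 30))
  expect_equal(nrow(select_regulators(flat, "focal", smooth = FALSE)), 0)

  # grid mismatch errors
  bad <- dplyr::bind_rows(tibble::tibble(qtl = "a", t = 1:10, value = 1:10),
                          tibble::tibble(qtl = "b", t = 2:11, value = 1:10))
  expect_error(select_regulators(bad, "a"), "grids differ")
})

test_that("the ODE fit recovers a linear self-dynamic exactly", {
  # dP/dt = alpha * P with alpha = 0.3: closed-form exponential oracle
  alpha <- 0.3
  tt <- seq(0, 10, length.out = 30)
  truth <- exp(alpha * tt)
  fit <- fit_qdode(curves_tbl(tt, A = truth), list(), r = 2, smooth = FALSE,
                   ode_steps = 8, polish = TRUE)
  f <- fit$fits$A
  expect_lt(max(abs(f$solution$total - truth)), 1e-4)
  # recovered U(P) is alpha * P on the observed range: check slope
  ps <- seq(min(truth), max(truth), length.out = 50)
  u <- vapply(ps, function(p)
    allonet:::legendre_eval(p, f$phi_self, f$self_range, TRUE), 1)
  slope <- coef(lm(u ~ ps))[2]
  expect_equal(unname(slope), alpha, tolerance = 0.01)
})

test_that("all-zero curves give zero coefficients and zero objective", {
  tt <- seq(0, 10, length.out = 12)
  fit <- fit_qdode(curves_tbl(tt, A = rep(0, 12), B = rep(0, 12)),
                   list(A = "B"), r = 3, smooth = FALSE)
  expect_equal(fit$fits$A$sse, 0)
  expect_equal(unname(fit$fits$A$phi_self), rep(0, 4))
  expect_equal(unname(fit$fits$A$phi_dep$B), rep(0, 3))
})

test_that("decomposition additivity holds exactly and dependents track truth", {
  # two planted regulators with opposite signs
  tt <- seq(0, 10, length.out = 30)
  q1 <- 3 / (1 + exp(-(tt - 3)))
  q2 <- 2 / (1 + exp(-1.5 * (tt - 7)))
  dep_true1 <- 0.4 * allonet:::cumtrapz0(tt, q1)
  dep_true2 <- -0.3 * allonet:::cumtrapz0(tt, q2)
  pf <- 0.5 + dep_true1 + dep_true2
  curves <- curves_tbl(tt, f = pf, q1 = q1, q2 = q2)
  fit <- fit_qdode(curves, list(f = c("q1", "q2")), r = 2, smooth = FALSE,
                   ode_steps = 8)
  dec <- decompose_effects(fit, "f")
  tot <- dec$value[dec$component == "total"]
  ind <- dec$value[dec$component == "independent"]
  d1 <- dec$value[dec$component == "dependent" & dec$regulator == "q1"]
  d2 <- dec$value[dec$component == "dependent" & dec$regulator == "q2"]
  # additivity identity, by construction of the shared integrator
  expect_lt(max(abs(pf[1] + ind + d1 + d2 - tot)), 1e-8)
  # recovered dependent curves track their true counterparts
  expect_gt(cor(d1, dep_true1), 0.9)
  expect_gt(cor(d2, dep_true2), 0.9)
  # no regulators: dependent map empty, independent = total - initial value
  fit0 <- fit_qdode(curves_tbl(tt, g = pf), list(), r = 3, smooth = FALSE)
  dec0 <- decompose_effects(fit0, "g")
  expect_equal(sum(dec0$component == "dependent"), 0)
  tot0 <- dec0$value[dec0$component == "total"]
  ind0 <- dec0$value[dec0$component == "independent"]
  expect_equal(ind0, tot0 - pf[1], tolerance = 1e-12)
})

test_that("halving the integrator step barely changes fitted trajectories", {
  tt <- seq(0, 10, length.out = 20)
  pf <- 1 + 2 / (1 + exp(-(tt - 5)))
  f4 <- fit_qdode(curves_tbl(tt, A = pf), list(), r = 3, smooth = FALSE,
                  polish = FALSE)
  sc <- list(self = f4$fits$A$phi_self)
  s4 <- allonet:::rk4_components(tt, pf[1], sc$self, f4$fits$A$self_range,
                                 list(), steps = 8)
  s8 <- allonet:::rk4_components(tt, pf[1], sc$self, f4$fits$A$self_range,
                                 list(), steps = 16)
  expect_lt(max(abs(s4$total - s8$total)), 1e-6)
})

test_that("interaction classification covers the six epistasis types", {
  nodes <- tibble::tibble(qtl = c("A", "B", "C", "D"),
                          class = NA_character_, hub = FALSE)
  edges <- tibble::tibble(
    from = c("A", "B", "A", "C"), to = c("B", "A", "C", "D"),
    sign = c("+", "-", "+", "-"), weight = c(0.3, 0.2, 0.1, 0.4),
    dep_curve = rep(list(NULL), 4))
  net <- list(nodes = nodes, edges = edges)
  pt <- classify_interactions(net)
  get_type <- function(a, b)
    pt$type[(pt$qtl1 == a & pt$qtl2 == b) | (pt$qtl1 == b & pt$qtl2 == a)]
  expect_equal(get_type("A", "B"), "altruistic/repressive epistasis")
  expect_equal(get_type("A", "C"), "directional positive epistasis")
  expect_equal(get_type("C", "D"), "directional negative epistasis")
  expect_equal(get_type("B", "D"), "symbiosis")
  # mutual activation and mutual repression
  ee <- tibble::tibble(from = c("A", "B", "C", "D"), to = c("B", "A", "D", "C"),
                       sign = c("+", "+", "-", "-"), weight = rep(1, 4),
                       dep_curve = rep(list(NULL), 4))
  pt2 <- classify_interactions(list(nodes = nodes, edges = ee))
  expect_equal(pt2$type[pt2$qtl1 == "A" & pt2$qtl2 == "B"],
               "symmetric positive epistasis")
  expect_equal(pt2$type[pt2$qtl1 == "C" & pt2$qtl2 == "D"],
               "negative epistasis")
})

test_that("hubs are nodes linking more than the average", {
  star <- list(
    nodes = tibble::tibble(qtl = c("hub", paste0("n", 1:4)),
                           class = NA, hub = FALSE),
    edges = tibble::tibble(from = "hub", to = paste0("n", 1:4),
                           sign = "+", weight = 1,
                           dep_curve = rep(list(NULL), 4)))
  expect_equal(detect_hubs(star), "hub")
  empty <- list(nodes = star$nodes,
                edges = star$edges[0, ])
  expect_equal(detect_hubs(empty), character())
})

test_that("edge sign follows the time-averaged dependent curve with + ties", {
  expect_equal(allonet:::edge_sign(c(1, 2, 3)), "+")
  expect_equal(allonet:::edge_sign(c(-1, -2)), "-")
  expect_equal(allonet:::edge_sign(c(-1, 1)), "+")     # exact zero mean
  expect_equal(allonet:::edge_sign(c(-2, 1, 1)), "+")  # zero mean, equal area
})

test_that("network export round-trips and rejects unknown formats", {
  tt <- seq(0, 10, length.out = 12)
  q1 <- 3 / (1 + exp(-(tt - 3)))
  pf <- 0.5 + 0.4 * allonet:::cumtrapz0(tt, q1)
  curves <- curves_tbl(tt, f = pf, g = q1, h = 0.3 * sin(tt) + 2)
  net <- build_network(curves, r = 2, smooth = FALSE, fit_ode = TRUE)
  f <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, f, "tsv", seed = 3)
  back <- read_network(f)
  expect_equal(back$edges$from, net$edges$from)
  expect_equal(back$edges$to, net$edges$to)
  expect_equal(back$edges$sign, net$edges$sign)
  expect_equal(back$edges$weight, net$edges$weight, tolerance = 1e-12)
  expect_setequal(back$nodes$qtl, net$nodes$qtl)
  expect_error(export_network(net, f, "xlsx"), "supported formats")

  # graphml and dot writers produce parseable non-empty files
  g1 <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, g1, "graphml")
  expect_gt(file.size(g1), 0)
  expect_s3_class(igraph::read_graph(g1, format = "graphml"), "igraph")

  # empty network: header-only edge list round-trips
  empty <- net
  empty$edges <- net$edges[0, ]
  f2 <- withr::local_tempfile(fileext = ".tsv")
  export_network(empty, f2, "tsv")
  expect_equal(nrow(read_network(f2)$edges), 0)
})
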