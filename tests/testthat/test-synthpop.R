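test_that("simulated populations have the declared shape and are seeded", {
  pop <- simulate_population(n = 60, T_ = 8, n_markers = 7,
                             causal = default_causal_piqtl(2), seed = 11)
  expect_equal(dim(pop$heights), c(60, 8))
  expect_equal(dim(pop$diameters), c(60, 8))
  expect_equal(nrow(pop$markers), 7)
  pop2 <- simulate_population(n = 60, T_ = 8, n_markers = 7,
                              causal = default_causal_piqtl(2), seed = 11)
  expect_identical(pop$heights, pop2$heights)
  expect_identical(pop$markers$codes, pop2$markers$codes)
})

test_that("segregation ratios match the cross design", {
  pop <- simulate_population(n = 200, T_ = 6, n_markers = 30, seed = 21)
  for (i in seq_len(30)) {
    codes <- pop$markers$codes[[i]]
    if (pop$markers$cross_type[i] == "TESTCROSS") {
      tab <- table(factor(codes, levels = c("nn", "np")))
      p <- chisq.test(tab, p = c(0.5, 0.5))$p.value
    } else {
      tab <- table(factor(codes, levels = c("aa", "ab", "bb")))
      p <- chisq.test(tab, p = c(0.25, 0.5, 0.25))$p.value
    }
    expect_gt(p, 0.001)
  }
})

test_that("simulated residual autocorrelation tracks the design rho", {
  # the noise generator itself: stationary AR(1) with the requested rho
  set.seed(31)
  E <- replicate(250, allonet:::ar1_noise(10, 0.5, 4))
  r1 <- cor(as.vector(E[-10, ]), as.vector(E[-1, ]))
  expect_equal(r1, 0.5, tolerance = 0.1)
  expect_equal(var(as.vector(E)), 4, tolerance = 0.4)

  # and the population's height residuals carry that serial correlation
  # (row-centering to remove the per-individual baseline biases the lag-1
  # correlation downward, so only positivity and rough size are asserted)
  pop <- simulate_population(n = 250, T_ = 10, n_markers = 1,
                             causal = list(),
                             noise = ar1_params(0.5, 4), seed = 31)
  p <- allometry_params("H_FROM_D", h0 = 0, a = 4.2, b = 1, d = -21)
  mu <- exp(p$a + p$d / (p$b + pop$diameters))
  resid <- pop$heights - mu
  resid <- resid - rowMeans(resid)
  r1_pop <- cor(as.vector(resid[, -10]), as.vector(resid[, -1]))
  expect_gt(r1_pop, 0.15)
})

test_that("causal spec validation catches bad inputs before generation", {
  expect_error(causal_qtl_spec(1, "TESTCROSS",
                               list(nn = allometry_params("H_FROM_D"))),
               "must be named")
  same <- allometry_params("H_FROM_D", h0 = 0, a = 4, b = 1, d = -20)
  expect_error(causal_qtl_spec(1, "TESTCROSS", list(nn = same, np = same)),
               "must differ")
  mixed <- list(nn = allometry_params("H_FROM_D", a = 4, b = 1, d = -20),
                np = allometry_params("D_FROM_H", a = 5, b = 1, d = 10))
  expect_error(causal_qtl_spec(1, "TESTCROSS", mixed), "one direction")

  # out-of-domain causal parameters fail before generation
  bad <- causal_qtl_spec(1, "TESTCROSS", list(
    nn = allometry_params("H_FROM_D", h0 = 0, a = 4, b = -40, d = -20),
    np = allometry_params("H_FROM_D", h0 = 0, a = 4.3, b = -40, d = -20)))
  expect_error(simulate_population(n = 50, T_ = 6, n_markers = 2,
                                   causal = bad, seed = 1),
               "out of domain")
  # causal index outside the marker range
  expect_error(simulate_population(n = 50, T_ = 6, n_markers = 2,
                                   causal = default_causal_piqtl(5)),
               "1..n_markers")
})

test_that("a noiseless planted piQTL is always the top scan hit", {
  hits <- vapply(1:5, function(i) {
    pop <- simulate_population(n = 80, T_ = 8, n_markers = 5,
                               causal = default_causal_piqtl(3),
                               noise = ar1_params(0.5, 1e-12),
                               seed = 100 + i)
    sc <- lr_scan(pop, "PI", seed = 1)
    sc$marker[which.min(sc$p)] == "m003"
  }, TRUE)
  expect_true(all(hits))
})

test_that("a miQTL-direction population supports the MI scan", {
  mi_causal <- causal_qtl_spec(1, "TESTCROSS", list(
    nn = allometry_params("D_FROM_H", h0 = 0, a = 4.6, b = 2, d = 10),
    np = allometry_params("D_FROM_H", h0 = 0, a = 4.6, b = 2, d = 11.5)))
  pop <- simulate_population(n = 100, T_ = 8, n_markers = 3,
                             causal = mi_causal,
                             noise = ar1_params(0.5, 0.09), seed = 41)
  expect_true(all(pop$diameters > 0))
  sc <- lr_scan(pop, "MI", seed = 1)
  expect_equal(sc$marker[which.min(sc$p)], "m001")
})

test_that("mixed-direction causal lists are rejected", {
  pi_spec <- default_causal_piqtl(1)
  mi_spec <- causal_qtl_spec(2, "TESTCROSS", list(
    nn = allometry_params("D_FROM_H", h0 = 0, a = 4.6, b = 2, d = 10),
    np = allometry_params("D_FROM_H", h0 = 0, a = 4.6, b = 2, d = 12)))
  expect_error(simulate_population(n = 50, T_ = 6, n_markers = 3,
                                   causal = list(pi_spec, mi_spec)),
               "one allometric direction")
})
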