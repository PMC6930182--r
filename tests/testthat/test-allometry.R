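test_that("height prediction reproduces closed-form values and asymptote", {
  # d = 0 kills the diameter dependence: constant h0 + e^a
  p <- allometry_params("H_FROM_D", h0 = 20, a = 3, b = 1, d = 0)
  expect_equal(predict_h_from_d(p, c(1, 5, 50)), rep(20 + exp(3), 3))

  # late-stage asymptote h0 + e^a as D grows
  p2 <- allometry_params("H_FROM_D", h0 = 20, a = 3, b = 1, d = -4)
  expect_equal(predict_h_from_d(p2, 1e6), 20 + exp(3), tolerance = 1e-3)

  # domain errors carry the offending index
  expect_error(predict_h_from_d(allometry_params("H_FROM_D", b = -2),
                                c(1, 1.5)),
               "index 1")
  expect_error(predict_h_from_d(p, c(1, NaN)), "non-finite")
})

test_that("diameter prediction matches direct substitution and flags domain", {
  p <- allometry_params("D_FROM_H", h0 = 0, a = 2, b = 1, d = 4)
  # ln(e) = 1: D = 4/(2-1) - 1 = 3
  expect_equal(predict_d_from_h(p, exp(1)), 3)
  # H -> 0+ drives the prediction to -b; must be flagged, not returned
  expect_error(predict_d_from_h(p, 1e-8), "negative predicted diameter")
  expect_error(predict_d_from_h(p, -1), "H <= h0")
  # a - ln(H - h0) <= 0
  expect_error(predict_d_from_h(p, exp(3)), "a - ln")
  # monotone nondecreasing in H for d > 0 over the valid domain
  hs <- seq(1.1, exp(1.8), length.out = 40)
  expect_true(all(diff(predict_d_from_h(p, hs)) >= 0))
})

test_that("the two directions are mutual inverses under matched parameters", {
  # d_H<-D = -d_D<-H is the matching sign convention
  for (prm in list(c(0, 2, 1, 4), c(5, 1.5, 2, 3), c(2, 3, 0.5, 6))) {
    pd <- allometry_params("D_FROM_H", h0 = prm[1], a = prm[2], b = prm[3],
                           d = prm[4])
    ph <- allometry_params("H_FROM_D", h0 = prm[1], a = prm[2], b = prm[3],
                           d = -prm[4])
    hmax <- prm[1] + exp(prm[2]) * 0.9
    H <- seq(prm[1] + 0.05, hmax, length.out = 25)
    D <- predict_d_from_h(pd, H, allow_negative = TRUE)
    ok <- pd$a - log(H - pd$h0) > 0 & ph$b + D > 0
    expect_true(all(abs(predict_h_from_d(ph, D[ok]) - H[ok]) <=
                      1e-9 * pmax(abs(H[ok]), 1)))
  }
})

test_that("least-squares fit recovers noise-free truth and honours inits", {
  d <- seq(1, 15)
  h <- 20 + exp(3 - 5 / (2 + d))
  fit <- fit_allometry(d, h, "H_FROM_D", h0 = 20)
  expect_lt(fit$rss, 1e-8)
  est <- c(fit$params$a, fit$params$b, fit$params$d)
  expect_equal(est, c(3, 2, -5), tolerance = 1e-3)

  # constant response: d ~ 0 and h0 + e^a ~ c
  cst <- fit_allometry(d, rep(27, 15), "H_FROM_D", h0 = 20)
  expect_equal(cst$params$d, 0)
  expect_equal(20 + exp(cst$params$a), 27, tolerance = 1e-6)

  # a supplied init can only improve the fit
  init <- allometry_params("H_FROM_D", h0 = 20, a = 3, b = 2, d = -5)
  fit2 <- fit_allometry(d, h, "H_FROM_D", h0 = 20, init = init)
  expect_lte(fit2$rss, 1e-12)
})

test_that("noisy fits stay close to truth across replicates", {
  d <- seq(1, 15)
  mu <- 20 + exp(3 - 5 / (2 + d))
  set.seed(7)
  errs <- replicate(20, {
    h <- mu + rnorm(15, 0, 0.1)
    f <- fit_allometry(d, h, "H_FROM_D", h0 = 20)
    abs(c(f$params$a - 3, f$params$b - 2, f$params$d + 5)) /
      c(3, 2, 5)
  })
  expect_gt(min(colSums(errs >= 0) > 0), 0) # shape sanity
  expect_lt(stats::median(errs), 0.15)
})

test_that("AIC ranking prefers the generating model and breaks ties by k", {
  d <- seq(1, 15)
  # data from the allometry equation: it must rank first
  set.seed(42)
  wins <- 0
  for (i in 1:20) {
    h <- 20 + exp(3 - 5 / (2 + d)) + rnorm(15, 0, 0.05)
    tab <- compare_models_aic(d, h, "H_FROM_D", h0 = 20)
    wins <- wins + (tab$model[1] == "allometry")
  }
  expect_gte(wins, 19)

  # exact line: the 2-parameter linear model wins
  y <- 2 + 3 * d
  tab2 <- compare_models_aic(d, y, "H_FROM_D", h0 = 0)
  expect_equal(tab2$model[1], "linear")

  # ties break towards fewer parameters
  tab3 <- tibble::tibble(model = c("m3", "m2"), k = c(3L, 2L),
                         rss = c(1, 1), aic = c(5, 5))
  expect_equal(dplyr::arrange(tab3, aic, k)$model[1], "m2")
})
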