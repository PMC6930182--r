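test_that("genotype grouping splits, filters, and skips degenerate markers", {
  codes <- c(rep(c("nn", "np"), 12), NA)
  g <- genotype_groups(codes, "TESTCROSS", min_count = 10)
  expect_length(g, 2)
  expect_setequal(unlist(g), which(!is.na(codes)))
  expect_equal(vapply(g, length, 1L), c(nn = 12L, np = 12L))

  g3 <- genotype_groups(rep(c("aa", "ab", "bb"), each = 12), "INTERCROSS")
  expect_length(g3, 3)

  mono <- genotype_groups(rep("nn", 30), "TESTCROSS")
  expect_length(mono, 0)
  expect_equal(attr(mono, "reason"), "monomorphic")

  small <- genotype_groups(c(rep("nn", 25), rep("np", 5)), "TESTCROSS")
  expect_length(small, 0)
  expect_match(attr(small, "reason"), "below min count")

  expect_error(genotype_groups(c("nn", "zz"), "TESTCROSS"), "\"zz\"")
})

test_that("single-group fit matches pooled allometry up to covariance weight", {
  pop <- fixture_pop(n = 60, T_ = 8, n_markers = 2, noise_sd = 0.5)
  f <- fit_funmap(pop, list(all = seq_len(pop$n)), "PI")
  expect_true(f$converged)
  # pooled LS on the stacked baseline-corrected data should land close
  x <- as.vector(pop$diameters)
  y <- as.vector(pop$heights - pop$h0)
  ls <- fit_allometry(x, y, "H_FROM_D", h0 = 0)
  expect_equal(f$params$all$a, ls$params$a, tolerance = 0.05)
  expect_equal(f$params$all$d, ls$params$d, tolerance = 0.15)
})

test_that("genotype-specific parameters are recovered at vanishing noise", {
  pop <- simulate_population(n = 120, T_ = 12, n_markers = 3,
                             causal = default_causal_piqtl(2),
                             noise = ar1_params(0.3, 1e-12), seed = 3)
  g <- genotype_groups(pop$markers$codes[[2]], "TESTCROSS")
  f <- fit_funmap(pop, g, "PI")
  expect_equal(f$params$nn$a, 4.2, tolerance = 0.05 * 4.2)
  expect_equal(f$params$np$a, 4.45, tolerance = 0.05 * 4.45)
  expect_equal(f$params$nn$b, 1, tolerance = 0.05)
  expect_equal(f$params$nn$d, -21, tolerance = 0.05 * 21)
  expect_equal(f$params$np$d, -21, tolerance = 0.05 * 21)
})

test_that("the scan is nested, calibrated-ish, and finds the planted QTL", {
  pop <- fixture_pop(n = 120, T_ = 10, n_markers = 6, causal_idx = 3)
  sc <- lr_scan(pop, "PI", seed = 1)
  # nesting: LR >= 0 within numerical slack, p in [0, 1]
  expect_true(all(sc$LR >= -1e-6))
  expect_true(all(sc$p >= 0 & sc$p <= 1))
  expect_equal(sc$df, 3L * (sc$J - 1L))
  # the planted marker has the smallest p
  expect_equal(sc$marker[which.min(sc$p)], "m003")
  expect_true(sc$significant[sc$marker == "m003"])
})

test_that("identical genotype groups give a vanishing likelihood ratio", {
  pop <- fixture_pop(n = 60, T_ = 8, n_markers = 2, causal_idx = 1)
  idx <- seq_len(pop$n)
  f0 <- fit_funmap(pop, list(all = idx), "PI")
  # two "genotypes" that are copies of the same mean structure: split at random
  set.seed(9)
  half <- sample(idx, 30)
  f1 <- fit_funmap(pop, list(g1 = half, g2 = setdiff(idx, half)), "PI",
                   extra_starts = list(rep(f0$theta, 2)))
  LR <- 2 * (f1$loglik - f0$loglik)
  expect_gte(LR, -1e-6)
  expect_lt(LR, qchisq(0.999, df = 3))
})

test_that("scan is deterministic and the MI direction runs end to end", {
  pop <- fixture_pop(n = 60, T_ = 8, n_markers = 3)
  s1 <- lr_scan(pop, "MI", seed = 5)
  s2 <- lr_scan(pop, "MI", seed = 5)
  expect_identical(s1$LR, s2$LR)
  expect_true(all(s1$LR >= -1e-6))
})

test_that("Bonferroni thresholds follow the per-cross-type arithmetic", {
  res <- tibble::tibble(cross_type = rep(c("TESTCROSS", "INTERCROSS"),
                                         c(261, 1223)),
                        p = runif(1484))
  thr <- bonferroni_thresholds(res, 0.05)
  expect_equal(thr$per_test_alpha[thr$cross_type == "TESTCROSS"], 0.05 / 261)
  expect_equal(thr$per_test_alpha[thr$cross_type == "INTERCROSS"],
               0.05 / 1223)

  # the reference total marker count: 0.05 / 1484 under a combined correction
  thr_c <- bonferroni_thresholds(res, 0.05, "combined")
  expect_equal(unique(thr_c$per_test_alpha), 0.05 / 1484, tolerance = 1e-12)
  expect_equal(unique(thr_c$per_test_alpha), 3.37e-5, tolerance = 1e-2)

  one <- bonferroni_thresholds(tibble::tibble(cross_type = "TESTCROSS",
                                              p = 0.5), 0.05)
  expect_equal(one$per_test_alpha[one$cross_type == "TESTCROSS"], 0.05)
  expect_true(is.na(one$per_test_alpha[one$cross_type == "INTERCROSS"]))
  expect_error(bonferroni_thresholds(res, 1.5), "alpha")
})

test_that("effect curves apply the additive/dominant definitions", {
  pop <- fixture_pop(n = 120, T_ = 8, n_markers = 4, causal_idx = 2)
  sc <- lr_scan(pop, "PI", seed = 1)
  ec <- effect_curves(pop, sc, "m002")
  expect_s3_class(ec, "effect_curve")
  means <- tidyr::pivot_wider(
    dplyr::filter(ec, startsWith(component, "mean_")),
    id_cols = "occasion", names_from = "component", values_from = "value")
  eff <- dplyr::filter(ec, component == "effect")
  expect_equal(eff$value, means$mean_nn - means$mean_np, tolerance = 1e-12)
  expect_equal(unique(ec$qtl_class), "piQTL")
  # curves carry the population-mean predictor value on the grid
  expect_equal(dplyr::filter(ec, component == "effect")$predictor_mean,
               unname(colMeans(pop$diameters)))
  expect_error(effect_curves(pop, sc, "nope"), "not present")
})

test_that("toy genotypic means give Add = 2 and Dom = 1", {
  # mu_AA = 10, mu_Aa = 8, mu_aa = 4 at one occasion:
  # Add = homozygote - heterozygote = 2; Dom = het - (hom1 + hom2)/2 = 1
  mus <- c(aa = 10, ab = 8, bb = 4)
  add <- mus[["aa"]] - mus[["ab"]]
  dom <- mus[["ab"]] - (mus[["aa"]] + mus[["bb"]]) / 2
  expect_equal(add, 2)
  expect_equal(dom, 1)
})

test_that("manhattan export carries thresholds and flags", {
  pop <- fixture_pop(n = 60, T_ = 8, n_markers = 4, causal_idx = 1)
  sc <- lr_scan(pop, "PI", seed = 2)
  md <- manhattan_data(sc)
  thr <- attr(sc, "thresholds")
  expect_equal(nrow(md), nrow(sc))
  expect_true(all(md$threshold %in% thr$neg_log10_threshold))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_scan(sc, f)
  reread <- readr::read_tsv(f, comment = "#", show_col_types = FALSE)
  expect_equal(nrow(reread), nrow(sc))
  expect_true(all(c("a_nn", "b_nn", "d_nn") %in% names(reread)) ||
                all(c("a_aa", "b_aa", "d_aa") %in% names(reread)))
})
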