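## Shared fixtures, built in code at test time.

## small deterministic mapping population with one planted testcross piQTL
fixture_pop <- function(n = 120, T_ = 10, n_markers = 5, causal_idx = 2,
                        noise_sd = 1.5, seed = 101) {
  simulate_population(
    n = n, T_ = T_, n_markers = n_markers,
    causal = default_causal_piqtl(causal_idx),
    noise = ar1_params(0.5, noise_sd^2), seed = seed
  )
}

## long curve table from a named list of curves on a common grid
curves_tbl <- function(.times, ...) {
  vals <- list(...)
  purrr::imap_dfr(vals, function(v, id) {
    tibble::tibble(qtl = id, t = .times, value = v)
  })
}

## dense multivariate-normal log-density oracle (generic O(T^3) route)
dense_mvn_logpdf <- function(r, Sigma) {
  T_ <- length(r)
  L <- chol(Sigma)
  z <- backsolve(L, r, transpose = TRUE)
  -0.5 * (T_ * log(2 * pi) + 2 * sum(log(diag(L))) + sum(z^2))
}
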