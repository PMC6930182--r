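#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.allometry_params <- function(x, ...) {
  tibble::tibble(term = c("h0", "a", "b", "d"),
                 estimate = c(x$h0, x$a, x$b, x$d),
                 direction = x$direction)
}

#' @exportS3Method generics::tidy
tidy.allometry_fit <- function(x, ...) tidy(x$params)

#' @exportS3Method generics::glance
glance.allometry_fit <- function(x, ...) {
  tibble::tibble(n = x$n, k = x$k, rss = x$rss,
                 aic = x$n * log(max(x$rss, 1e-300) / x$n) + 2 * x$k,
                 converged = x$converged)
}

#' @exportS3Method generics::tidy
tidy.ar1_params <- function(x, ...) {
  tibble::tibble(term = c("rho", "sigma2"), estimate = c(x$rho, x$sigma2))
}

#' @exportS3Method generics::tidy
tidy.funmap_fit <- function(x, ...) {
  purrr::imap_dfr(x$params, function(p, nm) {
    dplyr::mutate(tidy(p), genotype = nm, .before = 1)
  })
}

#' @exportS3Method generics::glance
glance.funmap_fit <- function(x, ...) {
  tibble::tibble(J = length(x$groups), loglik = x$loglik,
                 rho = x$ar1$rho, sigma2 = x$ar1$sigma2,
                 converged = x$converged, direction = x$direction)
}

#' @exportS3Method generics::tidy
tidy.qdode_fit <- function(x, ...) {
  purrr::map_dfr(x$fits, function(f) {
    self <- tibble::tibble(qtl = f$qtl, component = "independent",
                           regulator = NA_character_,
                           degree = seq_along(f$phi_self) - 1L,
                           coefficient = f$phi_self)
    deps <- purrr::imap_dfr(f$phi_dep, function(phi, reg) {
      tibble::tibble(qtl = f$qtl, component = "dependent", regulator = reg,
                     degree = seq_along(phi), coefficient = phi)
    })
    dplyr::bind_rows(self, deps)
  })
}

#' @exportS3Method generics::glance
glance.qdode_fit <- function(x, ...) {
  tibble::tibble(
    n_qtls = length(x$fits),
    n_edges = sum(vapply(x$fits, function(f) length(f$regulators), 1L)),
    total_sse = sum(vapply(x$fits, function(f) f$sse, 1)),
    basis_order = x$r,
    converged = all(vapply(x$fits, function(f) f$converged, TRUE))
  )
}

#' @exportS3Method generics::tidy
tidy.qtl_network <- function(x, ...) {
  dplyr::select(x$edges, "from", "to", "sign", "weight")
}

#' @exportS3Method generics::glance
glance.qtl_network <- function(x, ...) {
  tibble::tibble(n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
                 n_hubs = sum(x$nodes$hub),
                 n_positive = sum(x$edges$sign == "+"),
                 n_negative = sum(x$edges$sign == "-"))
}

#' @exportS3Method generics::tidy
tidy.true_network_spec <- function(x, ...) {
  dplyr::mutate(x$edges, sign = ifelse(.data$beta >= 0, "+", "-"))
}
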