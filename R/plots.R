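#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Manhattan plot of a QTL scan
#'
#' One point per marker (`-log10 p` against position, faceted by
#' chromosome), shaped by cross type, with the genome-wide Bonferroni
#' threshold line(s).
#'
#' @param object A [lr_scan()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.scan_result <- function(object, ...) {
  md <- manhattan_data(object)
  thr <- attr(object, "thresholds")
  thr <- thr[!is.na(thr$neg_log10_threshold), , drop = FALSE]
  ggplot2::ggplot(md, ggplot2::aes(x = .data$pos / 1e6,
                                   y = .data$neg_log10_p,
                                   shape = .data$cross_type,
                                   colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(data = thr,
                        ggplot2::aes(yintercept = .data$neg_log10_threshold,
                                     linetype = .data$cross_type)) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom),
                        scales = "free_x", space = "free_x") +
    ggplot2::scale_colour_manual(values = c("FALSE" = "grey40",
                                            "TRUE" = "firebrick")) +
    ggplot2::labs(x = "position (Mb)", y = expression(-log[10](p)),
                  title = paste0(unique(object$direction), " scan")) +
    ggplot2::theme_minimal()
}

#' Plot genetic-effect and genotype mean curves of a QTL
#'
#' @param object An [effect_curves()] result.
#' @param x_axis `"occasion"` or `"predictor"` (the population-mean
#'   predictor value, i.e. diameter for piQTLs and height for miQTLs).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.effect_curve <- function(object, x_axis = c("occasion", "predictor"),
                                  ...) {
  x_axis <- match.arg(x_axis)
  xcol <- if (x_axis == "occasion") "occasion" else "predictor_mean"
  ggplot2::ggplot(object, ggplot2::aes(x = .data[[xcol]], y = .data$value,
                                       colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$qtl)) +
    ggplot2::labs(x = x_axis, y = "effect / genotype mean",
                  title = unique(object$qtl_class)) +
    ggplot2::theme_minimal()
}

#' Plot the ODE decomposition of fitted effect trajectories
#'
#' Overall fitted curve, its independent component and the
#' regulator-dependent components, one panel per focal QTL.
#'
#' @param object A [fit_qdode()] result.
#' @param qtls Optional subset of focal QTL ids.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.qdode_fit <- function(object, qtls = NULL, ...) {
  ids <- if (is.null(qtls)) names(object$fits) else qtls
  dat <- purrr::map_dfr(ids, function(id) decompose_effects(object, id))
  dat$label <- ifelse(dat$component == "dependent",
                      paste0("dep:", dat$regulator), dat$component)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$t, y = .data$value,
                                    colour = .data$label)) +
    ggplot2::geom_line(data = ~dplyr::filter(.x, .data$component != "observed")) +
    ggplot2::geom_point(data = ~dplyr::filter(.x, .data$component == "observed"),
                        colour = "grey30", size = 0.7) +
    ggplot2::scale_colour_manual(values = c(total = "blue",
                                            independent = "red"),
                                 na.value = "darkgreen") +
    ggplot2::facet_wrap(ggplot2::vars(.data$qtl), scales = "free_y") +
    ggplot2::labs(x = "t", y = "genetic effect") +
    ggplot2::theme_minimal()
}

#' Plot a QTL control network
#'
#' Signed, weighted, directed graph with hub nodes emphasised; promotion
#' edges in red, inhibition in blue.
#'
#' @param object A [build_network()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.qtl_network <- function(object, ...) {
  nodes <- object$nodes
  edges <- object$edges
  g <- igraph::graph_from_data_frame(
    if (nrow(edges)) as.data.frame(edges[, c("from", "to")]) else
      data.frame(from = character(), to = character()),
    directed = TRUE, vertices = data.frame(name = nodes$qtl))
  set.seed(1)
  lay <- igraph::layout_in_circle(g)
  pos <- tibble::tibble(qtl = nodes$qtl, x = lay[, 1], y = lay[, 2],
                        hub = nodes$hub)
  p <- ggplot2::ggplot(pos, ggplot2::aes(x = .data$x, y = .data$y))
  if (nrow(edges)) {
    ed <- dplyr::left_join(edges, pos, by = c("from" = "qtl")) |>
      dplyr::rename(x0 = "x", y0 = "y") |>
      dplyr::left_join(pos, by = c("to" = "qtl")) |>
      dplyr::rename(x1 = "x", y1 = "y")
    p <- p + ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                   yend = .data$y1, colour = .data$sign,
                   linewidth = .data$weight),
      arrow = ggplot2::arrow(length = ggplot2::unit(6, "pt")),
      alpha = 0.7) +
      ggplot2::scale_colour_manual(values = c("+" = "firebrick",
                                              "-" = "steelblue")) +
      ggplot2::scale_linewidth(range = c(0.2, 1.5))
  }
  p + ggplot2::geom_point(ggplot2::aes(size = .data$hub), colour = "black") +
    ggplot2::geom_text(ggplot2::aes(label = .data$qtl), vjust = -1) +
    ggplot2::scale_size_manual(values = c("FALSE" = 2, "TRUE" = 5)) +
    ggplot2::theme_void()
}

#' Plot simulation-study recovery metrics by scenario
#'
#' @param object A [run_scenarios()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.simstudy_result <- function(object, ...) {
  dat <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), "nu2", "T",
                  dplyr::ends_with("_mean")),
    dplyr::ends_with("_mean"), names_to = "metric", values_to = "value")
  dat$metric <- sub("_mean$", "", dat$metric)
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data$T), y = .data$value,
                                    fill = factor(.data$nu2))) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = "occasions T", y = "mean over replicates",
                  fill = expression(nu^2)) +
    ggplot2::theme_minimal()
}
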