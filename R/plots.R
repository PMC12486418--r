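# ggplot2 views of the main result objects.

#' @describeIn fit_ncm Occurrence-frequency vs abundance plot with the
#'   fitted neutral curve, 95% Wilson band and taxon partition.
#' @param object A `halo_ncm` fit.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.halo_ncm <- function(object, ...) {
  ggplot2::ggplot(object$fits, ggplot2::aes(x = log10(.data$p))) +
    ggplot2::geom_ribbon(data = object$curve,
                         ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "grey80", alpha = 0.6) +
    ggplot2::geom_line(data = object$curve, ggplot2::aes(y = .data$f_pred),
                       linewidth = 0.8, colour = "black") +
    ggplot2::geom_point(ggplot2::aes(y = .data$f, colour = .data$partition),
                        size = 1, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(above = "#2166ac", within = "grey40",
                                            below = "#b2182b")) +
    ggplot2::labs(x = "log10 mean relative abundance",
                  y = "occurrence frequency",
                  title = sprintf("Sloan NCM fit: Nm = %.0f, R² = %.3f",
                                  object$Nm, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' @describeIn pcoa Ordination scatter of the first two axes; pass a
#'   metadata tibble via `metadata` to colour by group.
#' @param object A `halo_pcoa`.
#' @param metadata Optional tibble with `sample_id` and `group`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.halo_pcoa <- function(object, metadata = NULL, ...) {
  df <- object$coordinates
  pe <- 100 * object$proportion_explained
  if (!is.null(metadata)) {
    df <- dplyr::left_join(df, metadata, by = "sample_id")
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$Axis.1, y = .data$Axis.2))
  p <- if (!is.null(metadata)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group), size = 2)
  } else {
    p + ggplot2::geom_point(size = 2)
  }
  p + ggplot2::labs(x = sprintf("PCo1 (%.2f%%)", pe[1]),
                    y = sprintf("PCo2 (%.2f%%)", if (length(pe) > 1) pe[2] else 0)) +
    ggplot2::theme_minimal()
}

#' @describeIn build_network Force-directed layout of the accepted edges,
#'   coloured by sign.
#' @param object A `halo_network`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.halo_network <- function(object, ...) {
  g <- network_igraph(object)
  lay <- igraph::layout_with_fr(g)
  nodes <- tibble::tibble(taxon_id = igraph::V(g)$name, x = lay[, 1], y = lay[, 2],
                          degree = igraph::degree(g))
  edges <- object$edges
  if (nrow(edges)) {
    edges <- dplyr::mutate(edges,
      x = nodes$x[match(.data$taxon_1, nodes$taxon_id)],
      y = nodes$y[match(.data$taxon_1, nodes$taxon_id)],
      xend = nodes$x[match(.data$taxon_2, nodes$taxon_id)],
      yend = nodes$y[match(.data$taxon_2, nodes$taxon_id)])
  }
  p <- ggplot2::ggplot()
  if (nrow(edges)) {
    p <- p + ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, colour = .data$sign),
      alpha = 0.5, linewidth = 0.3) +
      ggplot2::scale_colour_manual(values = c(positive = "#1b7837", negative = "#b2182b"))
  }
  p + ggplot2::geom_point(data = nodes,
                          ggplot2::aes(x = .data$x, y = .data$y, size = .data$degree),
                          colour = "grey30", alpha = 0.8) +
    ggplot2::scale_size_continuous(range = c(0.5, 3)) +
    ggplot2::theme_void() +
    ggplot2::labs(title = sprintf("%d nodes, %d edges", nrow(object$nodes), nrow(object$edges)))
}

#' Plot rarefaction curves
#'
#' @param curve_tbl Output of [rarefaction_curve()].
#' @param metric `"observed_richness"` or `"shannon"`.
#' @return A ggplot object, one line per sample.
#' @export
plot_rarefaction_curve <- function(curve_tbl, metric = c("observed_richness", "shannon")) {
  metric <- match.arg(metric)
  ggplot2::ggplot(curve_tbl,
                  ggplot2::aes(x = .data$depth, y = .data[[metric]],
                               group = .data$sample_id, colour = .data$sample_id)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "reads subsampled", y = gsub("_", " ", metric)) +
    ggplot2::theme_minimal()
}

#' Plot group NST values against the 50% rule
#'
#' @param nst_tbl Output of [nst()].
#' @return A ggplot bar chart with the 0.5 threshold line.
#' @export
plot_nst <- function(nst_tbl) {
  ggplot2::ggplot(nst_tbl, ggplot2::aes(x = .data$group, y = .data$nst,
                                        fill = .data$classification)) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::scale_fill_manual(values = c("stochastic-dominated" = "#4393c3",
                                          "deterministic-dominated" = "#d6604d")) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(y = "normalized stochasticity ratio") +
    ggplot2::theme_minimal()
}
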