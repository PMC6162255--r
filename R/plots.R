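#' Plot an AMT database in mass/NET space
#'
#' Scatter of every AMT entry's median NET against its average
#' monoisotopic mass, the standard two-dimensional view of an AMT
#' database.
#'
#' @param object An `amt_db`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.amt_db <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$median_net,
                                   y = .data$avg_mass)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.4, colour = "magenta4") +
    ggplot2::labs(x = "median NET", y = "average monoisotopic mass (Da)",
                  title = sprintf("AMT database (%d entries)", nrow(df))) +
    ggplot2::theme_minimal()
}

#' Volcano plot of a differential-expression fit
#'
#' Peptide log2-median ratios against -log10 Storey q-values, with the
#' fold-change and FDR thresholds drawn and significant peptides
#' highlighted.
#'
#' @param object A [dep_test()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dep_fit <- function(object, ...) {
  cfg <- object$config$test
  df <- object$peptides
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_median_ratio,
                                   y = -log10(.data$q_value),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.7) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * log2(cfg$fold_threshold),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_hline(yintercept = -log10(cfg$fdr_threshold),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 median ratio", y = "-log10 q-value",
                  colour = "significant") +
    ggplot2::theme_minimal()
}

#' Bar plot of enriched terms
#'
#' @param object An [enrich_terms()] result.
#' @param top Number of best terms to show (default 15).
#' @param ... Unused.
#' @return A ggplot of -log10 p by term.
#' @export
autoplot.enrichment_tbl <- function(object, top = 15, ...) {
  df <- head(dplyr::arrange(tibble::as_tibble(object), .data$p_value), top)
  df$term_name <- factor(df$term_name, levels = rev(df$term_name))
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$p_value),
                                   y = .data$term_name,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "steelblue4")) +
    ggplot2::labs(x = "-log10 P", y = NULL, fill = "P <= cutoff") +
    ggplot2::theme_minimal()
}

#' Plot a DEP interaction network
#'
#' Force-directed layout (seeded, reproducible) with nodes coloured by
#' log2 fold change and DEPs outlined.
#'
#' @param object A [build_network()] result.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ppi_network <- function(object, seed = 1L, ...) {
  g <- as_igraph(object)
  xy <- with_seed(seed, igraph::layout_with_fr(g))
  nodes <- object$nodes
  nodes$x <- xy[, 1]
  nodes$y <- xy[, 2]
  edges <- object$edges |>
    dplyr::left_join(dplyr::select(nodes, "id", xa = "x", ya = "y"),
                     by = c("a" = "id")) |>
    dplyr::left_join(dplyr::select(nodes, "id", xb = "x", yb = "y"),
                     by = c("b" = "id"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$xa, y = .data$ya,
                                       xend = .data$xb, yend = .data$yb),
                          colour = "grey75", linewidth = 0.3) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     fill = .data$log2fc,
                                     shape = .data$is_dep),
                        size = 3, colour = "grey20") +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 21, `TRUE` = 22)) +
    ggplot2::scale_fill_gradient2(low = "darkgreen", mid = "white",
                                  high = "firebrick", midpoint = 0,
                                  na.value = "grey90") +
    ggplot2::labs(fill = "log2 FC", shape = "DEP") +
    ggplot2::theme_void()
}
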