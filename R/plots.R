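# ggplot2 views of the main result types.

#' Plot cluster mean profiles across fractions
#'
#' @param norm normalized tibble (`gene` + fraction columns).
#' @param assignment tibble (`gene`, `cluster`).
#' @return a ggplot: one facet per cluster, member genes in grey, the
#'   cluster mean in colour.
#' @export
plot_cluster_profiles <- function(norm, assignment) {
  long <- norm %>%
    inner_join(assignment %>% filter(!is.na(.data$cluster)), by = "gene") %>%
    tidyr::pivot_longer(cols = -c("gene", "cluster"),
                        names_to = "fraction", values_to = "value") %>%
    mutate(fraction = factor(.data$fraction,
                             levels = setdiff(names(norm), "gene")))
  means <- long %>%
    group_by(.data$cluster, .data$fraction) %>%
    summarise(value = mean(.data$value), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(.data$fraction, .data$value)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$gene),
                       colour = "grey70", linewidth = 0.2, alpha = 0.5) +
    ggplot2::geom_line(data = means,
                       ggplot2::aes(group = .data$cluster),
                       colour = "#1b7837", linewidth = 1) +
    ggplot2::facet_wrap(~cluster) +
    ggplot2::labs(x = "tissue fraction", y = "normalized expression") +
    ggplot2::theme_minimal()
}

#' @method autoplot woodnet_ks_spectrum
#' @export
autoplot.woodnet_ks_spectrum <- function(object, ...) {
  ggplot2::ggplot(object$grid,
                  ggplot2::aes(.data$log10_ks, .data$density)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(data = object$peaks,
                        ggplot2::aes(xintercept = .data$position),
                        linetype = "dashed", colour = "#762a83") +
    ggplot2::labs(x = expression(log[10] ~ K[s]), y = "density") +
    ggplot2::theme_minimal()
}

#' @method autoplot woodnet_network
#' @export
autoplot.woodnet_network <- function(object, ...) {
  g <- igraph::graph_from_data_frame(
    object %>% select("tf", "target"), directed = TRUE)
  lay <- igraph::layout_with_fr(g)
  nodes <- tibble(name = igraph::V(g)$name, x = lay[, 1], y = lay[, 2],
                  is_tf = igraph::V(g)$name %in% object$tf)
  edges <- object %>%
    left_join(nodes %>% select(tf = "name", x0 = "x", y0 = "y"), by = "tf") %>%
    left_join(nodes %>% select(target = "name", x1 = "x", y1 = "y"),
              by = "target")
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$x0, y = .data$y0,
                                       xend = .data$x1, yend = .data$y1,
                                       colour = .data$cross_cluster),
                          alpha = 0.6) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(.data$x, .data$y,
                                     shape = .data$is_tf,
                                     size = .data$is_tf)) +
    ggplot2::scale_shape_manual(values = c(16, 17)) +
    ggplot2::scale_size_manual(values = c(1.5, 3)) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "cross-cluster", shape = "regulator",
                  size = "regulator")
}

#' Plot conservation against the correlation threshold
#'
#' @param sensitivity tibble from [threshold_sensitivity()].
#' @return a ggplot of the conserved fraction per threshold.
#' @export
plot_threshold_sensitivity <- function(sensitivity) {
  ggplot2::ggplot(sensitivity,
                  ggplot2::aes(.data$r_threshold,
                               100 * .data$fraction_conserved)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "correlation threshold |r|",
                  y = "conserved interactions (%)") +
    ggplot2::theme_minimal()
}
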