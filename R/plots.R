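#' Plot an observed vs fitted mismatch distribution
#'
#' @param fit A [fit_sudden_expansion()] result.
#' @return A ggplot.
#' @export
plot_mismatch <- function(fit) {
  obs <- fit$observed %>%
    mutate(freq = .data$count / sum(.data$count))
  exp_tb <- tibble(differences = seq_along(fit$expected) - 1,
                   freq = fit$expected)
  ggplot2::ggplot(obs, ggplot2::aes(.data$differences, .data$freq)) +
    ggplot2::geom_line(ggplot2::aes(linetype = "observed")) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = exp_tb,
                       ggplot2::aes(linetype = "expected (sudden expansion)")) +
    ggplot2::labs(x = "Pairwise differences", y = "Relative frequency",
                  linetype = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mismatch_fit <- function(object, ...) plot_mismatch(object)

#' Plot a median-joining haplotype network
#'
#' Node area is proportional to haplotype frequency; median vectors are
#' drawn as small open points. Uses an igraph force-directed layout when
#' igraph is installed, otherwise a circular layout.
#'
#' @param network A [median_joining()] result.
#' @param seed Layout seed.
#' @return A ggplot.
#' @export
plot_network <- function(network, seed = 1) {
  nodes <- network$nodes
  edges <- network$edges
  if (requireNamespace("igraph", quietly = TRUE) && nrow(edges)) {
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = nodes$node)
    xy <- with_seed(seed, igraph::layout_with_fr(g,
      weights = 1 / edges$weight))
    layout <- tibble(node = igraph::V(g)$name, x = xy[, 1], y = xy[, 2])
  } else {
    k <- nrow(nodes)
    layout <- tibble(node = nodes$node,
                     x = cos(2 * pi * seq_len(k) / k),
                     y = sin(2 * pi * seq_len(k) / k))
  }
  nodes <- left_join(nodes, layout, by = "node")
  seg <- edges %>%
    left_join(layout, by = c(from = "node")) %>%
    left_join(layout, by = c(to = "node"), suffix = c("", "_to"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$x_to, yend = .data$y_to)) +
    ggplot2::geom_point(data = filter(nodes, !.data$is_median),
                        ggplot2::aes(.data$x, .data$y,
                                     size = .data$frequency),
                        shape = 21, fill = "grey70") +
    ggplot2::geom_point(data = filter(nodes, .data$is_median),
                        ggplot2::aes(.data$x, .data$y), shape = 1, size = 2) +
    ggplot2::geom_text(data = filter(nodes, !.data$is_median),
                       ggplot2::aes(.data$x, .data$y, label = .data$node),
                       vjust = -1.2, size = 3) +
    ggplot2::scale_size_area(max_size = 12) +
    ggplot2::theme_void() +
    ggplot2::labs(size = "Frequency")
}

#' @export
autoplot.haplotype_network <- function(object, ...) plot_network(object, ...)

#' Stacked ancestry bar plot for an admixture fit
#'
#' @param fit An [admixture_mcmc()] result.
#' @param pop_map Optional population map used to order individuals by
#'   population and group.
#' @return A ggplot.
#' @export
plot_structure_bars <- function(fit, pop_map = NULL) {
  qt <- tidy(fit) %>%
    tidyr::pivot_longer(dplyr::starts_with("Q"), names_to = "cluster",
                        values_to = "ancestry")
  if (!is.null(pop_map)) {
    qt <- left_join(qt, pop_map, by = "individual") %>%
      arrange(.data$group, .data$population)
    qt$individual <- factor(qt$individual, unique(qt$individual))
  }
  ggplot2::ggplot(qt, ggplot2::aes(.data$individual, .data$ancestry,
                                   fill = .data$cluster)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank()) +
    ggplot2::labs(x = NULL, y = "Ancestry proportion", fill = NULL)
}

#' @export
autoplot.admixture_fit <- function(object, ...) plot_structure_bars(object, ...)

#' Plot the Evanno delta-K profile
#'
#' @param delta_k An [evanno_delta_k()] table.
#' @return A ggplot.
#' @export
plot_delta_k <- function(delta_k) {
  ggplot2::ggplot(filter(delta_k, is.finite(.data$delta_K)),
                  ggplot2::aes(.data$K, .data$delta_K)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(y = expression(Delta * K)) +
    ggplot2::theme_minimal()
}

#' Plot ABC scenario posterior probabilities
#'
#' @param result An [run_abc()] result.
#' @return A ggplot.
#' @export
plot_abc_probs <- function(result) {
  ggplot2::ggplot(result$model_probs,
                  ggplot2::aes(factor(.data$scenario), .data$probability,
                               fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lower,
                                        ymax = .data$upper),
                           position = ggplot2::position_dodge(0.9),
                           width = 0.25) +
    ggplot2::labs(x = "Scenario", y = "Posterior probability", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.abc_result <- function(object, ...) plot_abc_probs(object)

#' Plot the PCA model check
#'
#' @param check A [model_check_pca()] result.
#' @return A ggplot.
#' @export
plot_model_check <- function(check) {
  ggplot2::ggplot(check$coords, ggplot2::aes(.data$PC1, .data$PC2,
                                             colour = .data$what)) +
    ggplot2::geom_point(data = filter(check$coords,
                                      .data$what != "observed"),
                        alpha = 0.3, size = 0.8) +
    ggplot2::geom_point(data = filter(check$coords,
                                      .data$what == "observed"),
                        size = 4, shape = 8) +
    ggplot2::theme_minimal() +
    ggplot2::labs(colour = NULL)
}
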