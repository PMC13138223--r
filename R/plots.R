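#' Plot a vessel network on its geographic layout
#'
#' Edges are drawn between island coordinates with width proportional to
#' weight; nodes are coloured by Harris SST zone when available.
#'
#' @param net A `vessel_network` whose node table carries `lat`/`lon`.
#' @param label Label islands by name (default TRUE).
#' @return A ggplot object.
#' @export
plot_network <- function(net, label = TRUE) {
  stopifnot(inherits(net, "vessel_network"))
  nodes <- net$nodes
  if (!all(c("lat", "lon") %in% names(nodes))) {
    stop("node table needs lat/lon for the geographic layout")
  }
  e <- net$edges |>
    dplyr::left_join(nodes, by = c(origin = "island")) |>
    dplyr::rename(x = "lon", y = "lat") |>
    dplyr::left_join(nodes, by = c(destination = "island")) |>
    dplyr::rename(xend = "lon", yend = "lat")
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = e,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linewidth = .data$weight),
      alpha = 0.4, colour = "grey40"
    ) +
    ggplot2::scale_linewidth(range = c(0.2, 2), guide = "none")
  if ("harris_zone" %in% names(nodes)) {
    p <- p + ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$lon, y = .data$lat,
                   colour = factor(.data$harris_zone)), size = 3) +
      ggplot2::labs(colour = "SST zone")
  } else {
    p <- p + ggplot2::geom_point(
      data = nodes, ggplot2::aes(x = .data$lon, y = .data$lat), size = 3)
  }
  if (label) {
    p <- p + ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$lon, y = .data$lat, label = .data$island),
      vjust = -1, size = 2.5)
  }
  p + ggplot2::labs(x = "Longitude", y = "Latitude") + ggplot2::theme_minimal()
}

#' Plot the small-world null ensemble
#'
#' Histograms of the null clustering coefficient and average path length
#' with the observed values marked.
#'
#' @param object A `smallworld_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.smallworld_result <- function(object, ...) {
  df <- tidyr::pivot_longer(object$ensemble, c("C", "L"),
                            names_to = "metric", values_to = "value")
  obs <- tibble::tibble(metric = c("C", "L"),
                        value = c(object$C_g, object$L_g))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(data = obs,
                        ggplot2::aes(xintercept = .data$value),
                        colour = "red", linewidth = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(
      title = sprintf("Small-world null ensemble (S = %.2f)", object$S),
      x = "null value", y = "replicates") +
    ggplot2::theme_minimal()
}

#' Plot monthly SST-similarity distributions
#'
#' Boxplots of pairwise similarity per month, the data behind the seasonal
#' Kruskal-Wallis comparison.
#'
#' @param object A `seasonal_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.seasonal_comparison <- function(object, ...) {
  ggplot2::ggplot(object$groups,
                  ggplot2::aes(x = .data$month, y = .data$s_sst)) +
    ggplot2::geom_boxplot(fill = "steelblue", alpha = 0.6,
                          outlier.size = 0.5) +
    ggplot2::labs(
      title = sprintf(
        "SST similarity by month (Kruskal-Wallis chi-squared = %.1f, p = %.2g)",
        object$kw$statistic, object$kw$p_value),
      x = NULL, y = expression(S[SST])) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot the modularity permutation null
#'
#' @param object A `modularity_null`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.modularity_null <- function(object, ...) {
  ggplot2::ggplot(tibble::tibble(Q = object$Q_null),
                  ggplot2::aes(x = .data$Q)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$Q_obs, colour = "red",
                        linewidth = 0.8) +
    ggplot2::labs(
      title = sprintf("Degree-preserving modularity null (z = %.2f, p = %.3f)",
                      object$z, object$p_normal),
      x = "null modularity Q", y = "permutations") +
    ggplot2::theme_minimal()
}
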