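#' Node-level invasion-risk metrics
#'
#' Computes, for every island, out/in degree, out/in strength (summed trip
#' weights), weighted betweenness, and out/in closeness. Shortest paths use
#' the inverted-weight distance d = 1/weight, so heavily trafficked routes
#' are "short". Closeness of a node is the number of nodes reachable from it
#' divided by the sum of shortest distances to them (reachable nodes only);
#' nodes that reach no others get `NA`. Isolated islands carry zero degrees,
#' strengths and betweenness and `NA` closeness.
#'
#' @param net A directed `vessel_network`.
#' @return A tibble, one row per island, columns `island`, `out_degree`,
#'   `in_degree`, `out_strength`, `in_strength`, `betweenness`,
#'   `out_closeness`, `in_closeness`.
#' @export
node_metrics <- function(net) {
  stopifnot(inherits(net, "vessel_network"), net$directed)
  g <- as_igraph(net)
  w <- igraph::E(g)$weight
  d_out <- igraph::degree(g, mode = "out")
  d_in <- igraph::degree(g, mode = "in")
  s_out <- igraph::strength(g, mode = "out", weights = w)
  s_in <- igraph::strength(g, mode = "in", weights = w)
  btw <- igraph::betweenness(g, directed = TRUE, weights = 1 / w)
  D <- igraph::distances(g, mode = "out", weights = 1 / w)
  diag(D) <- Inf
  closeness_from <- function(dmat) {
    apply(dmat, 1, function(row) {
      reach <- is.finite(row)
      if (!any(reach)) return(NA_real_)
      sum(reach) / sum(row[reach])
    })
  }
  clo_out <- closeness_from(D)
  clo_in <- closeness_from(t(D))
  tibble::tibble(
    island = igraph::V(g)$name,
    out_degree = as.integer(d_out),
    in_degree = as.integer(d_in),
    out_strength = as.numeric(s_out),
    in_strength = as.numeric(s_in),
    betweenness = as.numeric(btw),
    out_closeness = as.numeric(clo_out),
    in_closeness = as.numeric(clo_in)
  ) |>
    dplyr::arrange(.data$island)
}

#' Rank connected islands by an invasion-risk index
#'
#' Descending order on the chosen index; ties broken by ascending island
#' name so output is deterministic. Islands with no incident edges are
#' excluded; `NA` index values sort last.
#'
#' @param metrics A node-metrics tibble from [node_metrics()].
#' @param index One of `"out_degree"`, `"out_strength"`, `"betweenness"`,
#'   `"out_closeness"`.
#' @return A tibble `rank`, `island`, `value`.
#' @export
rank_nodes <- function(metrics, index = c("out_degree", "out_strength",
                                          "betweenness", "out_closeness")) {
  valid <- c("out_degree", "out_strength", "betweenness", "out_closeness")
  if (!is.character(index) || !(index[1] %in% valid)) {
    stop("unknown ranking index; valid indices: ", paste(valid, collapse = ", "))
  }
  index <- index[1]
  connected <- metrics$out_degree + metrics$in_degree > 0
  m <- metrics[connected, , drop = FALSE]
  v <- m[[index]]
  ord <- order(-ifelse(is.na(v), -Inf, v), m$island)
  tibble::tibble(
    rank = seq_len(nrow(m)),
    island = m$island[ord],
    value = v[ord]
  )
}

#' Trip-weighted reciprocity of a directed network
#'
#' A trip is reciprocal when its ordered island pair has a positive-weight
#' reverse edge anywhere in the window. The default fraction is
#' trip-weighted (reciprocal trip count over total trips); `method =
#' "edge"` gives the unweighted fraction of directed edges whose reverse
#' exists.
#'
#' @param net A directed `vessel_network`.
#' @param method `"trip"` (weighted, default) or `"edge"`.
#' @return Fraction in \[0, 1\].
#' @export
reciprocity_fraction <- function(net, method = c("trip", "edge")) {
  stopifnot(inherits(net, "vessel_network"), net$directed)
  method <- match.arg(method)
  e <- net$edges
  if (nrow(e) == 0) stop("empty network")
  key <- paste(e$origin, e$destination, sep = "\r")
  rev_key <- paste(e$destination, e$origin, sep = "\r")
  has_rev <- rev_key %in% key
  if (method == "trip") sum(e$weight[has_rev]) / sum(e$weight) else mean(has_rev)
}

#' Within- vs between-zone connection summary
#'
#' Treats each linked unordered island pair as one connection. For every
#' Harris SST zone with at least one incident connection, computes the
#' proportion of its incident connections staying within the zone and
#' crossing to other zones, then summarises across zones (mean and standard
#' error; SE is 0 when a single zone carries all connections).
#'
#' @param net A `vessel_network`.
#' @param islands Island metadata with `island` and `harris_zone`; defaults
#'   to the network's node table.
#' @return A `zone_stats` object; [generics::tidy()] returns the per-zone
#'   table, [generics::glance()] the mean/SE summary.
#' @export
zone_connection_stats <- function(net, islands = NULL) {
  stopifnot(inherits(net, "vessel_network"))
  if (is.null(islands)) islands <- net$nodes
  if (!"harris_zone" %in% names(islands)) stop("island metadata lacks harris_zone")
  und <- if (net$directed) collapse_undirected(net) else net
  e <- und$edges
  zone <- stats::setNames(islands$harris_zone, islands$island)
  connected <- union(e$origin, e$destination)
  nz <- connected[is.na(zone[connected])]
  if (length(nz) > 0) {
    stop("connected island(s) without a zone assignment: ",
         paste(nz, collapse = ", "))
  }
  za <- zone[e$origin]
  zb <- zone[e$destination]
  per_zone <- purrr::map_dfr(sort(unique(c(za, zb))), function(z) {
    inc <- za == z | zb == z
    tibble::tibble(
      zone = z,
      n_connections = sum(inc),
      prop_within = mean(za[inc] == zb[inc]),
      prop_between = mean(za[inc] != zb[inc])
    )
  })
  se <- function(x) if (length(x) < 2) 0 else stats::sd(x) / sqrt(length(x))
  summary <- tibble::tibble(
    n_zones = nrow(per_zone),
    within_mean = mean(per_zone$prop_within),
    within_se = se(per_zone$prop_within),
    between_mean = mean(per_zone$prop_between),
    between_se = se(per_zone$prop_between)
  )
  structure(list(per_zone = per_zone, summary = summary), class = "zone_stats")
}

#' @export
print.zone_stats <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "Zone connections: within %.1f%% +/- %.1f%% (SE), between %.1f%% +/- %.1f%% (SE), %d zones\n",
    100 * s$within_mean, 100 * s$within_se,
    100 * s$between_mean, 100 * s$between_se, s$n_zones
  ))
  invisible(x)
}

#' @rdname zone_connection_stats
#' @param x A `zone_stats` object.
#' @param ... Unused.
#' @export
tidy.zone_stats <- function(x, ...) x$per_zone

#' @rdname zone_connection_stats
#' @export
glance.zone_stats <- function(x, ...) x$summary

#' Export node metrics and rankings as TSV
#'
#' One row per island: the eight metric columns plus a rank column for each
#' of the four ranking indices (`NA` for disconnected islands).
#'
#' @param metrics A node-metrics tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_metrics_tsv <- function(metrics, path) {
  out <- metrics
  for (idx in c("out_degree", "out_strength", "betweenness", "out_closeness")) {
    r <- rank_nodes(metrics, idx)
    out[[paste0("rank_", idx)]] <- r$rank[match(out$island, r$island)]
  }
  readr::write_tsv(out, path)
  invisible(path)
}
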