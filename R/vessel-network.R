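#' Construct a vessel-traffic network
#'
#' A `vessel_network` is a light container for an inter-island traffic
#' network: a node table (one row per island, connected or isolated) and an
#' edge table whose `weight` column holds aggregated trip frequencies.
#' Directed by default; [collapse_undirected()] produces the undirected
#' collapse used by the small-world test.
#'
#' @param edges A data frame with columns `origin`, `destination`, `weight`
#'   (positive). Duplicate ordered pairs are summed; self-loops are an error
#'   here (they are dropped upstream by [read_trip_records()]).
#' @param islands Optional island metadata (columns `island`, and optionally
#'   `lat`, `lon`, `harris_zone`). Islands with no incident edges are kept as
#'   isolated nodes. When `NULL` the node set is the set of edge endpoints.
#' @param directed Logical; trip networks are directed.
#'
#' @return An object of class `vessel_network`: a list with tibbles `nodes`
#'   and `edges` and the `directed` flag.
#' @export
vessel_network <- function(edges, islands = NULL, directed = TRUE) {
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("origin", "destination", "weight") %in% names(edges)))
  if (any(edges$origin == edges$destination)) {
    stop("self-loops are not allowed in a vessel_network")
  }
  if (any(edges$weight <= 0)) stop("edge weights must be positive")
  edges <- edges |>
    dplyr::group_by(.data$origin, .data$destination) |>
    dplyr::summarise(weight = sum(.data$weight), .groups = "drop")
  if (!directed) {
    # canonicalise unordered pairs
    swap <- edges$origin > edges$destination
    tmp <- edges$origin[swap]
    edges$origin[swap] <- edges$destination[swap]
    edges$destination[swap] <- tmp
    edges <- edges |>
      dplyr::group_by(.data$origin, .data$destination) |>
      dplyr::summarise(weight = sum(.data$weight), .groups = "drop")
  }
  endpoint <- union(edges$origin, edges$destination)
  if (is.null(islands)) {
    nodes <- tibble::tibble(island = sort(endpoint))
  } else {
    nodes <- tibble::as_tibble(islands)
    stopifnot("island" %in% names(nodes))
    missing <- setdiff(endpoint, nodes$island)
    if (length(missing) > 0) {
      stop("edges reference islands absent from metadata: ",
           paste(missing, collapse = ", "))
    }
  }
  structure(
    list(nodes = nodes, edges = dplyr::arrange(edges, .data$origin, .data$destination),
         directed = directed),
    class = "vessel_network"
  )
}

#' @export
print.vessel_network <- function(x, ...) {
  cat(sprintf(
    "<vessel_network: %s, %d islands (%d connected), %d edges, total weight %s>\n",
    if (x$directed) "directed" else "undirected",
    nrow(x$nodes), length(union(x$edges$origin, x$edges$destination)),
    nrow(x$edges), format(sum(x$edges$weight))
  ))
  invisible(x)
}

#' Total trip weight of a network
#' @param net A `vessel_network`.
#' @return Sum of all edge weights.
#' @export
total_weight <- function(net) sum(net$edges$weight)

#' Convert a vessel_network to an igraph graph
#'
#' Nodes keep their island names; edge weights are carried in the `weight`
#' attribute. Isolated islands become isolated vertices.
#'
#' @param net A `vessel_network`.
#' @return An `igraph` graph.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "vessel_network"))
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = net$edges$origin, to = net$edges$destination,
                   weight = net$edges$weight),
    directed = net$directed,
    vertices = data.frame(name = net$nodes$island)
  )
  g
}

#' Build the directed weighted network from trip records
#'
#' Aggregates trip counts per ordered island pair over a month window. Each
#' island is a node; the edge weight is the total number of trips on that
#' ordered pair within the window. Islands in the metadata with no in-window
#' traffic are retained as isolated nodes.
#'
#' @param records Trip records (from [read_trip_records()] or
#'   [simulate_traffic()]): columns `origin`, `destination`, `month`
#'   (`"YYYY-MM"`), `count`.
#' @param islands Optional island metadata tibble.
#' @param window Optional character vector of months to keep (e.g.
#'   `month_window("2015-02", "2016-01")`). `NULL` keeps all records.
#' @return A directed `vessel_network` whose total weight equals the sum of
#'   in-window counts.
#' @export
build_network <- function(records, islands = NULL, window = NULL) {
  records <- tibble::as_tibble(records)
  stopifnot(all(c("origin", "destination", "month", "count") %in% names(records)))
  if (!is.null(window)) {
    records <- dplyr::filter(records, .data$month %in% window)
  }
  if (nrow(records) == 0) stop("no trip records in the selected window")
  edges <- records |>
    dplyr::group_by(origin = .data$origin, destination = .data$destination) |>
    dplyr::summarise(weight = sum(.data$count), .groups = "drop")
  vessel_network(edges, islands = islands, directed = TRUE)
}

#' Enumerate a calendar month window
#'
#' @param from,to First and last months, `"YYYY-MM"`.
#' @return Character vector of consecutive months, inclusive.
#' @export
month_window <- function(from, to) {
  f <- as.Date(paste0(from, "-01"))
  t <- as.Date(paste0(to, "-01"))
  stopifnot(f <= t)
  format(seq(f, t, by = "month"), "%Y-%m")
}

#' Collapse a directed network to its undirected form
#'
#' Direction is disregarded and the undirected weight of a pair is the total
#' number of trips in both directions, the convention under which the
#' small-world index is computed.
#'
#' @param net A directed `vessel_network`.
#' @return An undirected `vessel_network`.
#' @export
collapse_undirected <- function(net) {
  stopifnot(inherits(net, "vessel_network"))
  vessel_network(net$edges, islands = net$nodes, directed = FALSE)
}

#' Export a network as GraphML
#'
#' @param net A `vessel_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}

#' Export a network edge list as TSV
#'
#' Columns `origin`, `destination`, `weight`, tab-separated.
#' @inheritParams write_network_graphml
#' @return `path`, invisibly.
#' @export
write_edgelist_tsv <- function(net, path) {
  readr::write_tsv(net$edges, path)
  invisible(path)
}
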