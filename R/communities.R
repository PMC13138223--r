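#' Detect communities with a Leiden-style optimizer
#'
#' Optimises directed weighted modularity on the trip network using the
#' Leiden scheme (local moves, refinement, aggregation). Isolated islands
#' form singleton communities. Deterministic for a fixed seed.
#'
#' @param net A directed `vessel_network` (a composite network works too).
#' @param resolution Positive resolution parameter of the modularity
#'   objective (default 1).
#' @param seed Integer RNG seed (mandatory; node sweep order is randomised).
#' @return A `community_partition`: membership tibble (`island`,
#'   `community`), `n_communities`, modularity `Q`, `resolution`, `seed`.
#'   Community ids are contiguous from 1 in order of first appearance.
#' @export
detect_communities <- function(net, resolution = 1, seed) {
  stopifnot(inherits(net, "vessel_network"))
  if (missing(seed)) stop("seed is required")
  if (!is.numeric(resolution) || resolution <= 0) {
    stop("resolution must be positive")
  }
  if (nrow(net$nodes) == 0) stop("empty network")
  ids <- stats::setNames(seq_len(nrow(net$nodes)), net$nodes$island)
  memb <- leiden_directed(
    from = unname(ids[net$edges$origin]),
    to = unname(ids[net$edges$destination]),
    w = net$edges$weight,
    n = nrow(net$nodes),
    resolution = resolution,
    seed = seed
  )
  membership <- tibble::tibble(island = net$nodes$island, community = memb)
  Q <- modularity_q(net, membership, resolution = resolution)
  structure(
    list(membership = membership,
         n_communities = length(unique(memb)),
         Q = Q, resolution = resolution, seed = seed),
    class = "community_partition"
  )
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("<community_partition: %d communities, Q = %.4f, resolution = %g>\n",
              x$n_communities, x$Q, x$resolution))
  invisible(x)
}

#' @rdname detect_communities
#' @param x A `community_partition`.
#' @param ... Unused.
#' @export
tidy.community_partition <- function(x, ...) x$membership

#' @rdname detect_communities
#' @export
glance.community_partition <- function(x, ...) {
  tibble::tibble(n_communities = x$n_communities, Q = x$Q,
                 resolution = x$resolution, seed = x$seed)
}

#' Directed weighted modularity of a partition
#'
#' \deqn{Q = \sum_{ij\,:\,c_i = c_j} \left[ \frac{w_{ij}}{W} -
#'   \gamma\,\frac{s^{out}_i s^{in}_j}{W^2} \right]}
#' with `W` the total edge weight.
#'
#' @param net A directed `vessel_network`.
#' @param membership A data frame (`island`, `community`) or a named vector.
#' @param resolution Resolution parameter gamma (default 1).
#' @return Modularity Q.
#' @export
modularity_q <- function(net, membership, resolution = 1) {
  stopifnot(inherits(net, "vessel_network"))
  if (is.data.frame(membership)) {
    membership <- stats::setNames(membership$community, membership$island)
  }
  missing_nodes <- setdiff(net$nodes$island, names(membership))
  if (length(missing_nodes) > 0) {
    stop("membership missing node(s): ", paste(missing_nodes, collapse = ", "))
  }
  ids <- stats::setNames(seq_len(nrow(net$nodes)), net$nodes$island)
  modularity_directed(
    from = unname(ids[net$edges$origin]),
    to = unname(ids[net$edges$destination]),
    w = net$edges$weight,
    n = nrow(net$nodes),
    memb = as.integer(factor(membership[net$nodes$island])),
    gamma = resolution
  )
}

#' Two-sided normal-approximation p-value for a z-score
#'
#' `p = 2 * (1 - pnorm(|z|))`, the convention used to convert the
#' permutation-test z-scores of the modularity null test to p-values.
#'
#' @param z Finite numeric z-score(s).
#' @return Two-sided p-value(s) in (0, 1\].
#' @export
z_to_p <- function(z) {
  stopifnot(all(is.finite(z)))
  2 * stats::pnorm(-abs(z))
}

# one weighted degree-preserving rewire: double-edge swaps on the directed
# edge list; weights travel with their source endpoint. Attempts
# swaps_per_edge * |E| swaps, rejecting self-loops and multi-edges.
rewire_degree_preserving <- function(edges, swaps_per_edge = 10) {
  m <- nrow(edges)
  from <- edges$origin; to <- edges$destination
  key <- paste(from, to, sep = "\r")
  have <- new.env(hash = TRUE, parent = emptyenv())
  for (k in key) assign(k, TRUE, envir = have)
  n_attempts <- swaps_per_edge * m
  picks <- matrix(sample.int(m, 2 * n_attempts, replace = TRUE), ncol = 2)
  for (t in seq_len(n_attempts)) {
    i <- picks[t, 1]; j <- picks[t, 2]
    if (i == j) next
    a <- from[i]; b <- to[i]; c <- from[j]; d <- to[j]
    if (a == d || c == b) next                 # would create self-loops
    k1 <- paste(a, d, sep = "\r"); k2 <- paste(c, b, sep = "\r")
    if (exists(k1, envir = have, inherits = FALSE) ||
        exists(k2, envir = have, inherits = FALSE)) next  # multi-edge
    rm(list = c(paste(a, b, sep = "\r"), paste(c, d, sep = "\r")), envir = have)
    assign(k1, TRUE, envir = have)
    assign(k2, TRUE, envir = have)
    to[i] <- d; to[j] <- b
  }
  tibble::tibble(origin = from, destination = to, weight = edges$weight)
}

#' Degree-preserving permutation test of modularity
#'
#' Each permutation rewires the directed network by weighted double-edge
#' swaps that preserve every node's in- and out-degree (weights travel with
#' edges; `10 |E|` attempted swaps), re-optimises communities on the rewired
#' network, and records the optimised modularity. The z-score standardises
#' the observed Q against the null ensemble; the reported p is the two-sided
#' normal tail of z ([z_to_p()]); an add-one empirical two-sided p is also
#' returned.
#'
#' @param net A directed `vessel_network`.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer RNG seed (mandatory).
#' @param resolution Modularity resolution (default 1).
#' @param swaps_per_edge Attempted swaps per edge per replicate (default 10).
#' @return A `modularity_null` with `Q_obs`, `Q_null_mean`, `Q_null_sd`,
#'   `z`, `p_normal`, `p_empirical`, `n_perm`, `seed`, and the replicate
#'   vector `Q_null`.
#' @export
modularity_null_test <- function(net, n_perm = 1000, seed, resolution = 1,
                                 swaps_per_edge = 10) {
  stopifnot(inherits(net, "vessel_network"), net$directed)
  if (missing(seed)) stop("seed is required")
  if (nrow(net$edges) < 2) stop("need at least 2 edges to rewire")
  obs <- detect_communities(net, resolution = resolution, seed = seed)
  Q_obs <- obs$Q
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_perm)
  Q_null <- numeric(n_perm)
  for (r in seq_len(n_perm)) {
    set.seed(rep_seeds[r])
    re <- rewire_degree_preserving(net$edges, swaps_per_edge)
    rnet <- vessel_network(re, islands = net$nodes, directed = TRUE)
    Q_null[r] <- detect_communities(rnet, resolution = resolution,
                                    seed = rep_seeds[r])$Q
  }
  sd0 <- stats::sd(Q_null)
  if (!is.finite(sd0) || sd0 == 0) {
    stop("null modularity has zero spread; z undefined ",
         "(all rewired replicates gave Q = ", Q_null[1], ")")
  }
  z <- (Q_obs - mean(Q_null)) / sd0
  dev <- abs(Q_null - mean(Q_null))
  p_emp <- min(1, (1 + sum(dev >= abs(Q_obs - mean(Q_null)))) / (n_perm + 1))
  structure(
    list(Q_obs = Q_obs, Q_null_mean = mean(Q_null), Q_null_sd = sd0,
         z = z, p_normal = z_to_p(z), p_empirical = p_emp,
         n_perm = n_perm, seed = seed, Q_null = Q_null),
    class = "modularity_null"
  )
}

#' @export
print.modularity_null <- function(x, ...) {
  cat(sprintf(
    "Degree-preserving modularity test: Q = %.4f vs null %.4f +/- %.4f\n  z = %.3f, two-sided p = %.3f (empirical %.3f), %d permutations\n",
    x$Q_obs, x$Q_null_mean, x$Q_null_sd, x$z, x$p_normal, x$p_empirical,
    x$n_perm
  ))
  invisible(x)
}

#' @rdname modularity_null_test
#' @param x A `modularity_null` object.
#' @param ... Unused.
#' @export
glance.modularity_null <- function(x, ...) {
  tibble::tibble(Q_obs = x$Q_obs, Q_null_mean = x$Q_null_mean,
                 Q_null_sd = x$Q_null_sd, z = x$z, p_normal = x$p_normal,
                 p_empirical = x$p_empirical, n_perm = x$n_perm, seed = x$seed)
}

#' Serialise a modularity null test to JSON
#' @param x A `modularity_null`.
#' @param path Optional file; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
modularity_null_json <- function(x, path = NULL) {
  blk <- x[c("Q_obs", "Q_null_mean", "Q_null_sd", "z", "p_normal",
             "p_empirical", "n_perm", "seed")]
  js <- jsonlite::toJSON(blk, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Per-community vulnerability metrics
#'
#' For each community: size, number of bridges (directed inter-community
#' edges incident to the community — an edge counts for both its endpoint
#' communities), internal flow (total weight within), total inflow and
#' outflow (weight entering/leaving), mean member in-/out-closeness and mean
#' member betweenness (averages over members with defined values).
#'
#' @param net A directed `vessel_network`.
#' @param partition A `community_partition` or a membership data frame.
#' @return A tibble, one row per community.
#' @export
community_vulnerability <- function(net, partition) {
  stopifnot(inherits(net, "vessel_network"), net$directed)
  membership <- if (inherits(partition, "community_partition")) {
    partition$membership
  } else {
    tibble::as_tibble(partition)
  }
  comm <- stats::setNames(membership$community, membership$island)
  missing_nodes <- setdiff(net$nodes$island, names(comm))
  if (length(missing_nodes) > 0) {
    stop("partition missing node(s): ", paste(missing_nodes, collapse = ", "))
  }
  metrics <- node_metrics(net)
  mcomm <- comm[metrics$island]
  e <- net$edges
  co <- comm[e$origin]
  cd <- comm[e$destination]
  purrr::map_dfr(sort(unique(comm)), function(cc) {
    members <- names(comm)[comm == cc]
    inter_out <- co == cc & cd != cc
    inter_in <- co != cc & cd == cc
    within <- co == cc & cd == cc
    mm <- metrics[mcomm == cc, , drop = FALSE]
    tibble::tibble(
      community = cc,
      size = length(members),
      n_bridges = sum(inter_out) + sum(inter_in),
      internal_flow = sum(e$weight[within]),
      total_inflow = sum(e$weight[inter_in]),
      total_outflow = sum(e$weight[inter_out]),
      in_closeness = mean(mm$in_closeness, na.rm = TRUE),
      out_closeness = mean(mm$out_closeness, na.rm = TRUE),
      avg_betweenness = mean(mm$betweenness, na.rm = TRUE)
    )
  })
}

#' Export a community membership table as TSV
#' @param partition A `community_partition` or membership data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_membership_tsv <- function(partition, path) {
  membership <- if (inherits(partition, "community_partition")) {
    partition$membership
  } else {
    tibble::as_tibble(partition)
  }
  readr::write_tsv(membership, path)
  invisible(path)
}
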