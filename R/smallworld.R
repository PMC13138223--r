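#' Weighted global clustering coefficient
#'
#' Mean over nodes of degree >= 2 of the local weighted clustering
#' coefficient. The default variant is the geometric-mean (Onnela) form with
#' weights normalised by the maximum weight, which keeps the coefficient in
#' \[0, 1\] and comparable between the observed network and randomly
#' re-weighted null graphs:
#' \deqn{C_i = \frac{1}{k_i (k_i - 1)} \sum_{j,h} (\hat w_{ij} \hat w_{ih} \hat w_{jh})^{1/3}}
#' with \eqn{\hat w = w / \max(w)}. `"barrat"` (strength-weighted triangle
#' intensity) and `"binary"` (unweighted local clustering) are also
#' available.
#'
#' @param unet An undirected `vessel_network`.
#' @param variant `"onnela"` (default), `"barrat"` or `"binary"`.
#' @return The global coefficient, or `NA` when no node has degree >= 2.
#' @export
weighted_clustering <- function(unet, variant = c("onnela", "barrat", "binary")) {
  stopifnot(inherits(unet, "vessel_network"), !unet$directed)
  variant <- match.arg(variant)
  g <- as_igraph(unet)
  n <- igraph::vcount(g)
  if (igraph::ecount(g) == 0) return(NA_real_)
  W <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
  A <- (W > 0) * 1
  k <- rowSums(A)
  eligible <- k >= 2
  if (!any(eligible)) return(NA_real_)
  local <- switch(variant,
    onnela = {
      Wh <- (W / max(W))^(1 / 3)
      diag(Wh %*% Wh %*% Wh) / (k * (k - 1))
    },
    barrat = {
      s <- rowSums(W)
      # ordered neighbour pairs (j,h) closing a triangle contribute
      # (w_ij + w_ih)/2, which sums to diag(W A A) by symmetry
      diag(W %*% A %*% A) / (s * (k - 1))
    },
    binary = diag(A %*% A %*% A) / (k * (k - 1))
  )
  mean(local[eligible])
}

#' Weighted average shortest-path length
#'
#' Mean shortest-path distance over all reachable unordered node pairs of an
#' undirected network, with distances d = 1/weight. Unreachable pairs are
#' excluded; returns `NA` when no pair is reachable.
#'
#' @param unet An undirected `vessel_network`.
#' @return Mean shortest-path length, or `NA`.
#' @export
average_path_length <- function(unet) {
  stopifnot(inherits(unet, "vessel_network"), !unet$directed)
  g <- as_igraph(unet)
  if (igraph::ecount(g) == 0) return(NA_real_)
  D <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  vals <- D[upper.tri(D)]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0) return(NA_real_)
  mean(vals)
}

#' Random-network null ensemble for the small-world test
#'
#' Each replicate is a uniform random simple undirected graph with exactly
#' `n_edges` edges on `n_nodes` nodes (Erdos-Renyi G(n, m)); edge weights are
#' drawn with replacement from the observed weight pool. Replicates on which
#' clustering or path length is undefined are resampled (count recorded).
#'
#' @param n_nodes,n_edges Node and edge counts matching the observed network.
#' @param weight_pool Numeric vector of observed undirected edge weights.
#' @param n_sims Number of replicates.
#' @param seed Integer RNG seed (mandatory).
#' @param variant Clustering variant, see [weighted_clustering()].
#' @return A `random_ensemble`: tibble of per-replicate `C` and `L` plus
#'   summary attributes (`C_mean`, `C_sd`, `L_mean`, `L_sd`, `n_resampled`).
#' @export
random_ensemble <- function(n_nodes, n_edges, weight_pool, n_sims, seed,
                            variant = "onnela") {
  stopifnot(length(weight_pool) > 0, n_sims >= 1)
  if (n_edges > n_nodes * (n_nodes - 1) / 2) {
    stop("n_edges exceeds the maximum for a simple graph on n_nodes nodes")
  }
  set.seed(seed)
  # sort so replicates depend on the weight multiset, not the edge order
  weight_pool <- sort(as.numeric(weight_pool))
  C <- numeric(n_sims)
  L <- numeric(n_sims)
  n_resampled <- 0L
  for (i in seq_len(n_sims)) {
    repeat {
      g <- igraph::sample_gnm(n_nodes, n_edges, directed = FALSE)
      el <- igraph::as_edgelist(g, names = FALSE)
      w <- weight_pool[sample.int(length(weight_pool), n_edges,
                                  replace = TRUE)]
      unet <- vessel_network(
        tibble::tibble(origin = sprintf("n%03d", el[, 1]),
                       destination = sprintf("n%03d", el[, 2]),
                       weight = w),
        islands = tibble::tibble(island = sprintf("n%03d", seq_len(n_nodes))),
        directed = FALSE
      )
      Ci <- weighted_clustering(unet, variant)
      Li <- average_path_length(unet)
      if (is.finite(Ci) && is.finite(Li)) break
      n_resampled <- n_resampled + 1L
    }
    C[i] <- Ci
    L[i] <- Li
  }
  if (n_resampled > 0) {
    message(n_resampled, " degenerate null replicate(s) resampled")
  }
  structure(
    tibble::tibble(replicate = seq_len(n_sims), C = C, L = L),
    C_mean = mean(C), C_sd = stats::sd(C),
    L_mean = mean(L), L_sd = stats::sd(L),
    n_resampled = n_resampled,
    class = c("random_ensemble", class(tibble::tibble()))
  )
}

#' Weighted small-world-ness test
#'
#' Computes the small-world-ness index
#' \deqn{S = (C_g / \bar C_{rand}) / (L_g / \bar L_{rand})}
#' where \eqn{C_g} and \eqn{L_g} are the weighted global clustering
#' coefficient and average shortest-path length of the undirected collapse of
#' the trip network, and the null quantities are ensemble means over random
#' graphs matched in node and edge counts with weights resampled from the
#' observed weight pool. A network with S > 1 is classified small-world.
#' Also reports empirical add-one p-values: one-sided for clustering
#' (fraction of replicates with C >= C_g) and two-sided for path length.
#'
#' @param net A directed `vessel_network` (collapsed internally) or an
#'   undirected one.
#' @param n_sims Ensemble size (default 1000).
#' @param seed Integer RNG seed (mandatory).
#' @param variant Clustering variant, see [weighted_clustering()].
#' @return A `smallworld_result` with elements `C_g`, `L_g`, `C_rand_mean`,
#'   `C_rand_sd`, `L_rand_mean`, `L_rand_sd`, `S`, `p_C`, `p_L`,
#'   `small_world`, `n_sims`, `seed`, and the replicate tibble `ensemble`.
#' @export
smallworldness <- function(net, n_sims = 1000, seed, variant = "onnela") {
  stopifnot(inherits(net, "vessel_network"))
  if (missing(seed)) stop("seed is required for the null ensemble")
  unet <- if (net$directed) collapse_undirected(net) else net
  C_g <- weighted_clustering(unet, variant)
  L_g <- average_path_length(unet)
  if (!is.finite(C_g) || !is.finite(L_g)) {
    stop("clustering or path length undefined: the network is too sparse ",
         "(needs a node of degree >= 2 and at least one reachable pair)")
  }
  ens <- random_ensemble(
    n_nodes = nrow(unet$nodes), n_edges = nrow(unet$edges),
    weight_pool = unet$edges$weight, n_sims = n_sims, seed = seed,
    variant = variant
  )
  C_rand_mean <- attr(ens, "C_mean")
  L_rand_mean <- attr(ens, "L_mean")
  S <- (C_g / C_rand_mean) / (L_g / L_rand_mean)
  p_C <- (1 + sum(ens$C >= C_g)) / (n_sims + 1)
  p_lo <- (1 + sum(ens$L <= L_g)) / (n_sims + 1)
  p_hi <- (1 + sum(ens$L >= L_g)) / (n_sims + 1)
  p_L <- min(1, 2 * min(p_lo, p_hi))
  structure(
    list(
      C_g = C_g, L_g = L_g,
      C_rand_mean = C_rand_mean, C_rand_sd = attr(ens, "C_sd"),
      L_rand_mean = L_rand_mean, L_rand_sd = attr(ens, "L_sd"),
      S = S, p_C = p_C, p_L = p_L,
      small_world = S > 1,
      n_sims = n_sims, seed = seed, variant = variant,
      ensemble = tibble::as_tibble(ens)
    ),
    class = "smallworld_result"
  )
}

#' @export
print.smallworld_result <- function(x, ...) {
  cat(sprintf(
    paste0("Weighted small-world test (%d null simulations)\n",
           "  C_g = %.4f  (null %.4f +/- %.4f, p = %.4g)\n",
           "  L_g = %.4g  (null %.4g +/- %.4g, p = %.4g)\n",
           "  S = %.3f  -> %ssmall-world\n"),
    x$n_sims, x$C_g, x$C_rand_mean, x$C_rand_sd, x$p_C,
    x$L_g, x$L_rand_mean, x$L_rand_sd, x$p_L,
    x$S, if (x$small_world) "" else "not "
  ))
  invisible(x)
}

#' Tidy a small-world result
#' @param x A `smallworld_result`.
#' @param ... Unused.
#' @return Component-wise tibble (`tidy`) or one-row summary (`glance`).
#' @export
tidy.smallworld_result <- function(x, ...) {
  tibble::tibble(
    statistic = c("C_g", "L_g", "C_rand_mean", "C_rand_sd",
                  "L_rand_mean", "L_rand_sd", "S", "p_C", "p_L"),
    value = c(x$C_g, x$L_g, x$C_rand_mean, x$C_rand_sd,
              x$L_rand_mean, x$L_rand_sd, x$S, x$p_C, x$p_L)
  )
}

#' @rdname tidy.smallworld_result
#' @export
glance.smallworld_result <- function(x, ...) {
  tibble::tibble(
    C_g = x$C_g, L_g = x$L_g, S = x$S, p_C = x$p_C, p_L = x$p_L,
    small_world = x$small_world, n_sims = x$n_sims, seed = x$seed
  )
}

#' Serialise a small-world result to JSON
#' @param x A `smallworld_result`.
#' @param path Optional file; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
smallworld_json <- function(x, path = NULL) {
  blk <- x[c("C_g", "L_g", "C_rand_mean", "C_rand_sd", "L_rand_mean",
             "L_rand_sd", "S", "p_C", "p_L", "n_sims", "seed")]
  js <- jsonlite::toJSON(blk, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
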