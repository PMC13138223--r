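# Independent brute-force oracles, deliberately naive: exhaustive simple-path
# enumeration for shortest paths and betweenness, double-loop sums for
# modularity, closed-form rank statistics. Used to validate the package's
# igraph-backed and hand-written implementations on tiny graphs.

# Enumerate all simple paths between every ordered node pair and return the
# shortest-path distance matrix (d = 1/weight) and betweenness counts.
# el: data frame with integer columns from, to and numeric w.
brute_shortest_paths <- function(el, n, directed = TRUE) {
  adj <- vector("list", n)
  add <- function(a, b, w) adj[[a]] <<- rbind(adj[[a]], c(b, w))
  for (r in seq_len(nrow(el))) {
    add(el$from[r], el$to[r], el$w[r])
    if (!directed) add(el$to[r], el$from[r], el$w[r])
  }
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  btw <- numeric(n)
  tol <- 1e-12
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      if (s == t) next
      best <- Inf
      paths <- list()
      dfs <- function(v, dist, path) {
        if (dist > best + tol) return()
        if (v == t) {
          if (dist < best - tol) {
            best <<- dist
            paths <<- list(path)
          } else {
            paths[[length(paths) + 1]] <<- path
          }
          return()
        }
        if (is.null(adj[[v]])) return()
        for (r in seq_len(nrow(adj[[v]]))) {
          u <- adj[[v]][r, 1]
          if (u %in% path) next
          dfs(u, dist + 1 / adj[[v]][r, 2], c(path, u))
        }
      }
      dfs(s, 0, s)
      D[s, t] <- best
      if (is.finite(best) && length(paths) > 0) {
        nsp <- length(paths)
        for (p in paths) {
          interior <- p[-c(1, length(p))]
          for (v in interior) btw[v] <- btw[v] + 1 / nsp
        }
      }
    }
  }
  if (!directed) btw <- btw / 2
  list(D = D, betweenness = btw)
}

# closeness from a distance matrix, reachable-only convention
brute_closeness <- function(D) {
  n <- nrow(D)
  diag(D) <- Inf
  out <- numeric(n)
  for (v in seq_len(n)) {
    reach <- is.finite(D[v, ])
    out[v] <- if (!any(reach)) NA_real_ else sum(reach) / sum(D[v, reach])
  }
  out
}

# directed weighted modularity by the literal double sum over node pairs
brute_modularity <- function(el, n, memb, gamma = 1) {
  Wm <- matrix(0, n, n)
  for (r in seq_len(nrow(el))) {
    Wm[el$from[r], el$to[r]] <- Wm[el$from[r], el$to[r]] + el$w[r]
  }
  W <- sum(Wm)
  s_out <- rowSums(Wm)
  s_in <- colSums(Wm)
  Q <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (memb[i] == memb[j]) {
        Q <- Q + Wm[i, j] / W - gamma * s_out[i] * s_in[j] / W^2
      }
    }
  }
  Q
}

# tie-corrected Kruskal-Wallis H from first principles
brute_kruskal_H <- function(values, groups) {
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  n_g <- tapply(r, groups, length)
  H <- 12 / (N * (N + 1)) * sum(n_g * rbar^2) - 3 * (N + 1)
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# random simple directed graph as integer edge list with continuous weights
# (continuous weights make shortest-path ties measure-zero)
random_digraph <- function(n, m) {
  all_pairs <- expand.grid(from = seq_len(n), to = seq_len(n))
  all_pairs <- all_pairs[all_pairs$from != all_pairs$to, ]
  pick <- all_pairs[sample(nrow(all_pairs), min(m, nrow(all_pairs))), ]
  pick$w <- stats::runif(nrow(pick), 0.5, 10)
  pick
}

# vessel_network from an integer edge list
net_from_el <- function(el, n, directed = TRUE) {
  nm <- sprintf("v%02d", seq_len(n))
  vessel_network(
    tibble::tibble(origin = nm[el$from], destination = nm[el$to],
                   weight = el$w),
    islands = tibble::tibble(island = nm),
    directed = directed
  )
}

# vessel_network straight from character edges
net_from_edges <- function(origin, destination, weight, islands = NULL,
                           directed = TRUE) {
  vessel_network(
    tibble::tibble(origin = origin, destination = destination,
                   weight = weight),
    islands = islands, directed = directed
  )
}
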