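# Leiden-style optimisation of directed weighted modularity.
#
# The quality function is directed Newman modularity
#   Q = sum_c [ w_in(c)/W - gamma * S_out(c) * S_in(c) / W^2 ]
# with W the total edge weight, w_in(c) the weight inside community c, and
# S_out/S_in the summed out-/in-strengths of its members. Optimisation
# follows the Leiden scheme: queue-driven local moves (including split-off
# to a fresh singleton), a refinement pass that re-partitions each community
# from singletons before aggregation, then aggregation and repetition while
# modularity improves. Networks in this domain are tens of nodes, so a plain
# R implementation is ample.

# One pass of queue-driven local moves. from/to: integer endpoints, w:
# weights (self-loops allowed; they are neutral to move gains), memb:
# initial membership with ids in 1..n. restrict: optional vector; moves may
# only join communities inside the same restrict block (refinement phase).
local_move_phase <- function(from, to, w, n, memb, gamma, W, restrict = NULL) {
  s_out <- numeric(n); s_in <- numeric(n)
  for (i in seq_along(w)) {
    s_out[from[i]] <- s_out[from[i]] + w[i]
    s_in[to[i]] <- s_in[to[i]] + w[i]
  }
  nb <- vector("list", n)
  for (i in seq_along(w)) {
    a <- from[i]; b <- to[i]
    if (a == b) next  # self-loop weight moves with the node: constant in Q
    nb[[a]] <- rbind(nb[[a]], c(b, w[i]))
    nb[[b]] <- rbind(nb[[b]], c(a, w[i]))
  }
  memb <- match(memb, unique(memb))
  cS_out <- numeric(n); cS_in <- numeric(n); csize <- integer(n)
  for (v in seq_len(n)) {
    cS_out[memb[v]] <- cS_out[memb[v]] + s_out[v]
    cS_in[memb[v]] <- cS_in[memb[v]] + s_in[v]
    csize[memb[v]] <- csize[memb[v]] + 1L
  }
  queue <- sample.int(n)
  in_queue <- rep(TRUE, n)
  head <- 1L
  while (head <= length(queue)) {
    v <- queue[head]; head <- head + 1L
    in_queue[v] <- FALSE
    if (is.null(nb[[v]])) next
    cur <- memb[v]
    nbm <- nb[[v]]
    if (!is.null(restrict)) {
      keep <- restrict[nbm[, 1]] == restrict[v]
      nbm <- nbm[keep, , drop = FALSE]
      if (nrow(nbm) == 0) next
    }
    comms <- memb[nbm[, 1]]
    k_vc <- tapply(nbm[, 2], comms, sum)
    cand <- as.integer(names(k_vc))
    # book v out of its community
    cS_out[cur] <- cS_out[cur] - s_out[v]
    cS_in[cur] <- cS_in[cur] - s_in[v]
    csize[cur] <- csize[cur] - 1L
    gain_of <- function(cc, k) {
      k / W - gamma * (s_out[v] * cS_in[cc] + s_in[v] * cS_out[cc]) / W^2
    }
    gains <- gain_of(cand, as.numeric(k_vc))
    stay <- gain_of(cur, if (cur %in% cand) k_vc[[match(cur, cand)]] else 0)
    best <- which.max(gains)
    new <- cur
    if (gains[best] > stay + 1e-12 && gains[best] >= -1e-12) {
      new <- cand[best]
    } else if (0 > stay + 1e-12 && max(gains) <= 1e-12) {
      # better off alone: move to an empty community id
      new <- which(csize == 0L)[1]
    }
    cS_out[new] <- cS_out[new] + s_out[v]
    cS_in[new] <- cS_in[new] + s_in[v]
    csize[new] <- csize[new] + 1L
    if (new != cur) {
      memb[v] <- new
      for (u in nbm[, 1]) {
        if (memb[u] != new && !in_queue[u]) {
          queue <- c(queue, u)
          in_queue[u] <- TRUE
        }
      }
    }
  }
  match(memb, unique(memb))
}

# Directed weighted modularity of a membership vector (integer edge lists).
modularity_directed <- function(from, to, w, n, memb, gamma = 1) {
  W <- sum(w)
  if (W == 0) return(0)
  s_out <- numeric(n); s_in <- numeric(n)
  for (i in seq_along(w)) {
    s_out[from[i]] <- s_out[from[i]] + w[i]
    s_in[to[i]] <- s_in[to[i]] + w[i]
  }
  within <- sum(w[memb[from] == memb[to]]) / W
  exp_term <- 0
  for (c in unique(memb)) {
    m <- memb == c
    exp_term <- exp_term + sum(s_out[m]) * sum(s_in[m])
  }
  within - gamma * exp_term / W^2
}

# Full Leiden loop; returns a membership vector for the original nodes,
# relabelled contiguously (1..K) by first appearance in node order.
leiden_directed <- function(from, to, w, n, resolution = 1, seed = 1L,
                            max_levels = 50L) {
  set.seed(seed)
  W <- sum(w)
  memb <- seq_len(n)
  if (length(w) == 0 || W == 0) return(memb)
  af <- from; at <- to; aw <- w; an <- n
  agg_of_node <- seq_len(n)
  init <- seq_len(an)
  Q_best <- modularity_directed(from, to, w, n, memb, resolution)
  for (level in seq_len(max_levels)) {
    coarse <- local_move_phase(af, at, aw, an, init, resolution, W)
    cand_memb <- coarse[agg_of_node]
    Q_new <- modularity_directed(from, to, w, n, cand_memb, resolution)
    if (Q_new > Q_best + 1e-12) {
      memb <- cand_memb
      Q_best <- Q_new
    } else {
      break
    }
    # refinement: split each coarse community back into well-connected parts
    refined <- local_move_phase(af, at, aw, an, seq_len(an), resolution, W,
                                restrict = coarse)
    r_ids <- match(refined, unique(refined))
    n_ref <- length(unique(r_ids))
    if (n_ref == an) {
      # refinement kept singletons; aggregate directly on the coarse partition
      r_ids <- match(coarse, unique(coarse))
      n_ref <- length(unique(r_ids))
      if (n_ref == an) break
    }
    # aggregate edges on the refined partition
    nf <- r_ids[af]; nt <- r_ids[at]
    key <- (nf - 1) * n_ref + nt
    agg <- rowsum(aw, key)
    k <- as.numeric(rownames(agg))
    af <- as.integer((k - 1) %/% n_ref) + 1L
    at <- as.integer((k - 1) %% n_ref) + 1L
    aw <- as.numeric(agg)
    # next level starts from the coarse community of each refined aggregate
    init <- integer(n_ref)
    init[r_ids] <- match(coarse, unique(coarse))
    agg_of_node <- r_ids[agg_of_node]
    an <- n_ref
  }
  match(memb, unique(memb))
}
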