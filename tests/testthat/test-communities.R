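two_triangles <- function(bridge_weight = 0.5) {
  # two reciprocal unit-weight triangles joined by one weak edge
  tri <- function(v) {
    tibble::tibble(origin = c(v[1], v[2], v[2], v[3], v[1], v[3]),
                   destination = c(v[2], v[1], v[3], v[2], v[3], v[1]),
                   weight = 1)
  }
  edges <- dplyr::bind_rows(tri(c("A", "B", "C")), tri(c("X", "Y", "Z")),
                            tibble::tibble(origin = "C", destination = "X",
                                           weight = bridge_weight))
  vessel_network(edges, directed = TRUE)
}

test_that("planted two-triangle partition is recovered", {
  net <- two_triangles()
  p <- detect_communities(net, seed = 13)
  expect_equal(p$n_communities, 2)
  memb <- tibble::deframe(p$membership)
  expect_equal(length(unique(memb[c("A", "B", "C")])), 1)
  expect_equal(length(unique(memb[c("X", "Y", "Z")])), 1)
  expect_true(memb[["A"]] != memb[["X"]])
  expect_gte(p$Q, 0)
})

test_that("isolated islands form singleton communities", {
  scn <- synthetic_scenario(seed = 31)
  islands <- simulate_islands(scn)
  net <- build_network(simulate_traffic(scn, islands), islands)
  p <- detect_communities(net, seed = 2)
  sizes <- table(p$membership$community)
  expect_equal(sum(sizes == 1), 4)
  iso <- setdiff(islands$island, union(net$edges$origin, net$edges$destination))
  iso_comms <- p$membership$community[p$membership$island %in% iso]
  expect_true(all(table(iso_comms) == 1))
  expect_true(all(iso_comms %in% as.integer(names(sizes)[sizes == 1])))
})

test_that("a single reciprocal clique is one community", {
  v <- c("A", "B", "C", "D")
  prs <- t(utils::combn(v, 2))
  net <- net_from_edges(c(prs[, 1], prs[, 2]), c(prs[, 2], prs[, 1]),
                        rep(1, 2 * nrow(prs)))
  p <- detect_communities(net, seed = 1)
  expect_equal(p$n_communities, 1)
  expect_error(detect_communities(net, resolution = -1, seed = 1), "positive")
})

test_that("detection is bit-stable under a fixed seed", {
  scn <- synthetic_scenario(seed = 17)
  islands <- simulate_islands(scn)
  net <- build_network(simulate_traffic(scn, islands), islands)
  p1 <- detect_communities(net, seed = 99)
  p2 <- detect_communities(net, seed = 99)
  expect_identical(p1$membership, p2$membership)
  expect_identical(p1$Q, p2$Q)
})

test_that("modularity matches the brute-force double sum", {
  # all nodes in one community
  net <- two_triangles()
  memb_all <- tibble::tibble(island = net$nodes$island, community = 1L)
  expect_equal(modularity_q(net, memb_all), 0)

  # single edge, endpoints split
  net1 <- net_from_edges("A", "B", 3)
  split <- tibble::tibble(island = c("A", "B"), community = c(1L, 2L))
  expect_equal(modularity_q(net1, split), 0)

  # two disconnected reciprocal triangles, correct split, vs brute force
  net2 <- two_triangles(bridge_weight = 1e-9)
  el <- data.frame(from = match(net2$edges$origin, net2$nodes$island),
                   to = match(net2$edges$destination, net2$nodes$island),
                   w = net2$edges$weight)
  memb <- ifelse(net2$nodes$island %in% c("A", "B", "C"), 1L, 2L)
  expect_equal(
    modularity_q(net2, tibble::tibble(island = net2$nodes$island,
                                      community = memb)),
    brute_modularity(el, nrow(net2$nodes), memb),
    tolerance = 1e-12
  )
  expect_error(modularity_q(net2, tibble::tibble(island = "A", community = 1L)),
               "missing")
})

test_that("Leiden Q dominates the trivial partitions on random graphs", {
  for (s in 1:10) {
    set.seed(s)
    el <- random_digraph(8, 16)
    net <- net_from_el(el, 8)
    p <- detect_communities(net, seed = s)
    n <- nrow(net$nodes)
    q_all <- modularity_q(net, tibble::tibble(island = net$nodes$island,
                                              community = 1L))
    q_single <- modularity_q(net, tibble::tibble(island = net$nodes$island,
                                                 community = seq_len(n)))
    expect_gte(p$Q, q_all - 1e-12)
    expect_gte(p$Q, q_single - 1e-12)
    expect_equal(p$Q, modularity_q(net, p$membership), tolerance = 1e-12)
  }
})

test_that("z_to_p is the two-sided standard-normal tail", {
  expect_equal(z_to_p(0), 1)
  expect_equal(z_to_p(1.96), 0.05, tolerance = 1e-3)
  expect_equal(z_to_p(-1.5), z_to_p(1.5))
})

test_that("rewiring preserves in/out degrees and the weight multiset", {
  scn <- synthetic_scenario(seed = 53)
  islands <- simulate_islands(scn)
  net <- build_network(simulate_traffic(scn, islands), islands)
  deg_sig <- function(edges) {
    list(out = sort(table(edges$origin)), in_ = sort(table(edges$destination)),
         w = sort(edges$weight))
  }
  before <- deg_sig(net$edges)
  for (s in 1:5) {
    set.seed(s)
    re <- vesselnet:::rewire_degree_preserving(net$edges)
    after <- deg_sig(re)
    expect_identical(after$out, before$out)
    expect_identical(after$in_, before$in_)
    expect_identical(after$w, before$w)
    expect_false(any(re$origin == re$destination))
    expect_equal(anyDuplicated(paste(re$origin, re$destination)), 0)
  }
})

test_that("modularity null test is calibrated on networks drawn by rewiring", {
  # observed network generated by rewiring a scaffold: it IS a null draw
  scn <- synthetic_scenario(seed = 61)
  islands <- simulate_islands(scn)
  scaffold <- build_network(simulate_traffic(scn, islands), islands)
  set.seed(77)
  obs_edges <- vesselnet:::rewire_degree_preserving(scaffold$edges)
  obs <- vessel_network(obs_edges, islands = scaffold$nodes, directed = TRUE)
  mt <- modularity_null_test(obs, n_perm = 60, seed = 15)
  expect_lt(abs(mt$z), 3)
  expect_equal(mt$z, (mt$Q_obs - mt$Q_null_mean) / mt$Q_null_sd)
  expect_equal(mt$p_normal, z_to_p(mt$z))
  js <- jsonlite::fromJSON(modularity_null_json(mt))
  expect_equal(js$z, mt$z)
})

test_that("community vulnerability metrics follow their definitions", {
  # single community: everything internal
  net <- two_triangles()
  one <- tibble::tibble(island = net$nodes$island, community = 1L)
  v1 <- community_vulnerability(net, one)
  expect_equal(v1$internal_flow, total_weight(net))
  expect_equal(v1$total_inflow, 0)
  expect_equal(v1$total_outflow, 0)
  expect_equal(v1$n_bridges, 0L)

  # two singleton communities with one directed edge
  net2 <- net_from_edges("a", "b", 7)
  two <- tibble::tibble(island = c("a", "b"), community = c(1L, 2L))
  v2 <- community_vulnerability(net2, two)
  expect_equal(v2$total_outflow, c(7, 0))
  expect_equal(v2$total_inflow, c(0, 7))
  expect_equal(v2$n_bridges, c(1L, 1L))

  # conservation on an arbitrary partition of a random graph
  set.seed(8)
  el <- random_digraph(9, 20)
  net3 <- net_from_el(el, 9)
  part <- tibble::tibble(island = net3$nodes$island,
                         community = sample(1:3, 9, replace = TRUE))
  v3 <- community_vulnerability(net3, part)
  expect_equal(sum(v3$total_inflow), sum(v3$total_outflow))
  expect_equal(sum(v3$internal_flow) + sum(v3$total_outflow),
               total_weight(net3))
})
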