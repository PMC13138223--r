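test_that("trip records parse, clean self-loops and reject bad counts", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("origin,destination,month,count",
               "A,B,2015-02,3",
               "B,A,2015-03,2",
               "A,C,2015-02,5"), tmp)
  rec <- read_trip_records(tmp)
  expect_equal(nrow(rec), 3)
  expect_named(rec, c("origin", "destination", "month", "count"))

  writeLines(c("origin,destination,month,count",
               "A,A,2015-02,3",
               "A,B,2015-02,1"), tmp)
  expect_warning(rec <- read_trip_records(tmp), "self-loop")
  expect_equal(nrow(rec), 1)

  writeLines(c("origin,destination,month,count", "A,B,2015-02,-2"), tmp)
  expect_error(read_trip_records(tmp), "count")

  writeLines(c("origin,destination,count", "A,B,3"), tmp)
  expect_error(read_trip_records(tmp), "month")
})

test_that("build_network aggregates duplicates, keeps isolates, windows months", {
  rec <- tibble::tibble(
    origin = c("A", "A", "B"), destination = c("B", "B", "C"),
    month = c("2015-02", "2015-03", "2016-02"), count = c(3, 2, 7)
  )
  islands <- tibble::tibble(island = c("A", "B", "C", "D"))
  net <- build_network(rec, islands)
  eAB <- net$edges[net$edges$origin == "A" & net$edges$destination == "B", ]
  expect_equal(eAB$weight, 5)

  win <- month_window("2015-02", "2016-01")
  netw <- build_network(rec, islands, window = win)
  expect_equal(total_weight(netw), 5)            # out-of-window record dropped
  expect_equal(nrow(netw$nodes), 4)              # D retained, isolated
  expect_error(build_network(rec, islands, window = "2020-01"), "window")
})

test_that("node metrics match forced conventions on tiny graphs", {
  # directed path A -> B -> C, unit weights
  net <- net_from_edges(c("A", "B"), c("B", "C"), c(1, 1),
                        islands = tibble::tibble(island = c("A", "B", "C")))
  m <- node_metrics(net)
  expect_equal(m$betweenness[m$island == "B"], 1)
  expect_equal(m$betweenness[m$island %in% c("A", "C")], c(0, 0))

  # single edge A -> B weight 4: out-closeness(A) = 1 / (1/4) = 4
  net2 <- net_from_edges("A", "B", 4)
  m2 <- node_metrics(net2)
  expect_equal(m2$out_closeness[m2$island == "A"], 4)
  expect_true(is.na(m2$out_closeness[m2$island == "B"]))
  expect_true(is.na(m2$in_closeness[m2$island == "A"]))

  # reciprocal star: hub on 12 ordered leaf-pair shortest paths
  leaves <- c("L1", "L2", "L3", "L4")
  net3 <- net_from_edges(c(rep("H", 4), leaves),
                         c(leaves, rep("H", 4)), rep(1, 8))
  m3 <- node_metrics(net3)
  expect_equal(m3$betweenness[m3$island == "H"], 12)
})

test_that("strength sums conserve total network weight", {
  set.seed(41)
  el <- random_digraph(7, 14)
  net <- net_from_el(el, 7)
  m <- node_metrics(net)
  expect_equal(sum(m$out_strength), total_weight(net))
  expect_equal(sum(m$in_strength), total_weight(net))
})

test_that("rank_nodes orders descending, breaks ties by name, drops isolates", {
  net <- net_from_edges(c("A", "C"), c("B", "B"), c(5, 5),
                        islands = tibble::tibble(island = c("A", "B", "C", "Z")))
  m <- node_metrics(net)
  r <- rank_nodes(m, "out_strength")
  expect_equal(nrow(r), 3)                       # Z isolated, excluded
  expect_equal(r$island, c("A", "C", "B"))       # 5, 5 tie -> A before C
  expect_error(rank_nodes(m, "in_degree"), "valid indices")
})

test_that("reciprocity fraction follows the trip-weighted definition", {
  net <- net_from_edges(c("A", "B", "A"), c("B", "A", "C"), c(3, 2, 5))
  expect_equal(reciprocity_fraction(net), 0.5)
  expect_equal(reciprocity_fraction(net, "edge"), 2 / 3)

  full <- net_from_edges(c("A", "B"), c("B", "A"), c(7, 1))
  expect_equal(reciprocity_fraction(full), 1)

  star <- net_from_edges(rep("H", 3), c("A", "B", "C"), c(1, 2, 3))
  expect_equal(reciprocity_fraction(star), 0)
})

test_that("reciprocity is invariant to relabeling and record splitting", {
  rec <- tibble::tibble(origin = c("A", "B", "A"),
                        destination = c("B", "A", "C"),
                        month = "2015-02", count = c(3, 2, 5))
  f1 <- reciprocity_fraction(build_network(rec))
  relab <- rec
  relab$origin <- chartr("ABC", "XYZ", relab$origin)
  relab$destination <- chartr("ABC", "XYZ", relab$destination)
  expect_equal(reciprocity_fraction(build_network(relab)), f1)
  split <- rbind(rec, rec[1, ])
  split$count[c(1, 4)] <- c(1, 2)
  expect_equal(reciprocity_fraction(build_network(split)), f1)
})

test_that("scaling all weights preserves orderings of the risk indices", {
  set.seed(99)
  el <- random_digraph(8, 18)
  net1 <- net_from_el(el, 8)
  el$w <- el$w * 7.3
  net2 <- net_from_el(el, 8)
  m1 <- node_metrics(net1)
  m2 <- node_metrics(net2)
  for (idx in c("out_degree", "out_strength", "betweenness", "out_closeness")) {
    expect_equal(rank_nodes(m1, idx)$island, rank_nodes(m2, idx)$island)
  }
  expect_equal(m1$betweenness, m2$betweenness)   # counts, not distances
})

test_that("zone connection stats handle degenerate and mixed cases", {
  one_zone <- net_from_edges(
    c("A", "B"), c("B", "C"), c(1, 1),
    islands = tibble::tibble(island = c("A", "B", "C"),
                             harris_zone = c(1L, 1L, 1L)))
  s1 <- glance(zone_connection_stats(one_zone))
  expect_equal(s1$within_mean, 1)
  expect_equal(s1$within_se, 0)

  crossing <- net_from_edges(
    c("A", "B"), c("C", "D"), c(1, 1),
    islands = tibble::tibble(island = c("A", "B", "C", "D"),
                             harris_zone = c(1L, 1L, 2L, 2L)))
  s2 <- glance(zone_connection_stats(crossing))
  expect_equal(s2$between_mean, 1)
  expect_equal(s2$within_mean, 0)

  # 3 zones, hand-enumerated: zone1 {A,B}: A-B within, B-C cross;
  # zone2 {C}: B-C, C-D cross; zone3 {D}: C-D cross
  three <- net_from_edges(
    c("A", "B", "C"), c("B", "C", "D"), c(2, 3, 4),
    islands = tibble::tibble(island = c("A", "B", "C", "D"),
                             harris_zone = c(1L, 1L, 2L, 3L)))
  tz <- tidy(zone_connection_stats(three))
  expect_equal(tz$prop_within, c(1 / 2, 0, 0))
  expect_equal(tz$n_connections, c(2L, 2L, 1L))

  no_zone <- net_from_edges("A", "B", 1,
                            islands = tibble::tibble(island = c("A", "B"),
                                                     harris_zone = c(1L, NA)))
  expect_error(zone_connection_stats(no_zone), "B")
})

test_that("network exports round-trip", {
  net <- net_from_edges(c("A", "B"), c("B", "C"), c(3, 4))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_edgelist_tsv(net, tsv)
  back <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(back$weight, c(3, 4))
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(net, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(sort(igraph::E(g)$weight), c(3, 4))
  expect_true(igraph::is_directed(g))
})
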