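sst_grid <- function(islands, months, values) {
  tidyr::expand_grid(island = islands, month = months) |>
    dplyr::mutate(sst_c = values)
}

test_that("SST reader validates shape, duplicates and missing months", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("island,month,sst_c",
               "A,2015-02,25", "A,2015-03,24",
               "B,2015-02,23", "B,2015-03,22",
               "C,2015-02,20", "C,2015-03,21"), tmp)
  sst <- read_sst(tmp)
  expect_equal(dim(sst), c(6L, 3L))

  writeLines(c("island,month,sst_c", "A,2015-02,25", "A,2015-02,24"), tmp)
  expect_error(read_sst(tmp), "duplicate")

  writeLines(c("island,month,sst_c", "A,2015-02,warm"), tmp)
  expect_error(read_sst(tmp), "SST")

  # island missing a month: pairs excluded with a warning downstream
  sst2 <- tibble::tibble(island = c("A", "B", "C", "A", "B"),
                         month = c(rep("2015-02", 3), rep("2015-03", 2)),
                         sst_c = c(25, 23, 20, 24, 22))
  expect_warning(d <- pairwise_delta(sst2, "2015-03"), "C")
  expect_equal(nrow(d), 1)
})

test_that("pairwise deltas enumerate unordered pairs", {
  sst <- tibble::tibble(island = c("A", "B", "C"), month = "2015-02",
                        sst_c = c(25.0, 23.5, 25.0))
  d <- pairwise_delta(sst, "2015-02")
  expect_equal(nrow(d), 3)
  expect_equal(d$delta_t[d$island_a == "A" & d$island_b == "B"], 1.5)
  expect_equal(d$delta_t[d$island_a == "A" & d$island_b == "C"], 0)
  expect_error(pairwise_delta(sst, "1999-01"), "unknown month")
})

test_that("Gaussian kernel hits its closed-form values and bounds", {
  expect_equal(sst_sim(0), 1)
  expect_equal(round(sst_sim(2, 2), 1), 0.6)
  expect_equal(sst_sim(2, 2), exp(-0.5))
  expect_equal(sst_sim(4, 2), exp(-2))
  expect_error(sst_sim(-1), "non-negative")
  expect_error(sst_sim(1, 0), "positive")
})

test_that("kernel is monotone in delta_t and sigma_t", {
  set.seed(12)
  dt <- sort(runif(50, 0, 10))
  s <- sst_sim(dt, 2)
  expect_true(all(s > 0 & s <= 1))
  expect_true(all(diff(s) < 0))
  sig <- sort(runif(20, 0.5, 5))
  expect_true(all(diff(sst_sim(3, sig)) > 0))
})

test_that("monthly groups have combinatorial sizes", {
  months <- month_window("2015-02", "2016-01")
  set.seed(3)
  full <- tidyr::expand_grid(island = sprintf("I%02d", 1:23), month = months) |>
    dplyr::mutate(sst_c = rnorm(dplyr::n(), 24, 1))
  g <- monthly_similarity_groups(full)
  expect_equal(unname(table(g$month)), rep(choose(23, 2), 12),
               ignore_attr = TRUE)

  # one island missing one month -> C(22,2) pairs that month
  drop1 <- full[!(full$island == "I01" & full$month == months[5]), ]
  expect_warning(g2 <- monthly_similarity_groups(drop1), "I01")
  expect_equal(sum(g2$month == months[5]), choose(22, 2))

  const <- tidyr::expand_grid(island = c("A", "B", "C"), month = months[1:2]) |>
    dplyr::mutate(sst_c = 24)
  expect_true(all(monthly_similarity_groups(const)$s_sst == 1))
})

test_that("Kruskal-Wallis matches the hand-worked example and an oracle", {
  df <- tibble::tibble(value = c(1, 2, 3, 4), group = c("a", "a", "b", "b"))
  kw <- kruskal_wallis(df, value, group)
  expect_equal(kw$statistic, 2.4)
  expect_equal(kw$df, 1)

  ident <- tibble::tibble(value = rep(5, 6), group = rep(c("a", "b"), 3))
  expect_equal(kruskal_wallis(ident, value, group)$statistic, 0)

  # random small samples vs first-principles tie-corrected H
  for (s in 1:25) {
    set.seed(s)
    k <- sample(2:5, 1)
    n <- sample(3:10, k, replace = TRUE)
    df <- tibble::tibble(
      value = round(rnorm(sum(n)), 1),       # rounding forces ties
      group = rep(letters[1:k], n)
    )
    expect_equal(kruskal_wallis(df, value, group)$statistic,
                 brute_kruskal_H(df$value, df$group), tolerance = 1e-9)
  }
})

test_that("Dunn post hoc adjusts p-values by BH step-up", {
  # two groups: single comparison, adjusted = raw
  df <- tibble::tibble(value = c(1, 2, 3, 10, 11, 12),
                       group = rep(c("a", "b"), each = 3))
  d <- dunn_posthoc(df, value, group)
  expect_equal(nrow(d), 1)
  expect_equal(d$p_adjusted, d$p_value)

  # BH on (0.01, 0.02, 0.03) -> (0.03, 0.03, 0.03)
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))

  # 12 groups -> 66 pairwise rows; adjusted >= raw, monotone step-up
  set.seed(4)
  df12 <- tibble::tibble(value = rnorm(120, rep(1:12, each = 10) / 4),
                         group = rep(sprintf("m%02d", 1:12), each = 10))
  d12 <- dunn_posthoc(df12, value, group)
  expect_equal(nrow(d12), 66)
  expect_true(all(d12$p_adjusted >= d12$p_value - 1e-15))
  ord <- order(d12$p_value)
  expect_true(all(diff(d12$p_adjusted[ord]) >= -1e-15))
  expect_error(dunn_posthoc(df12[0, ], value, group))
})

test_that("seasonal comparison on a seasonal synthetic field is significant", {
  scn <- synthetic_scenario(seed = 27)
  islands <- simulate_islands(scn)
  sst <- simulate_sst(scn, islands)
  sc <- seasonal_comparison(sst)
  expect_equal(sc$kw$df, 11)
  expect_lt(sc$kw$p_value, 0.001)
  expect_true(all(sc$medians$median_s_sst > 0 & sc$medians$median_s_sst <= 1))
  expect_equal(nrow(sc$pairwise), choose(12, 2))
  expect_true(best_similarity_month(sc) %in% sc$medians$month)
  expect_equal(glance(sc)$statistic, sc$kw$statistic)
})

test_that("composite network multiplies weights and preserves structure", {
  net <- net_from_edges(c("A", "B", "A"), c("B", "A", "C"), c(10, 4, 6))
  sim <- tibble::tibble(island_a = c("A", "A", "B"),
                        island_b = c("B", "C", "C"),
                        month = "2015-04",
                        delta_t = c(0, 2, 1),
                        s_sst = c(1, exp(-0.5), exp(-0.125)))
  comp <- composite_network(net, sim, "2015-04")
  eAB <- comp$edges[comp$edges$origin == "A" & comp$edges$destination == "B", ]
  expect_equal(eAB$weight, 10)                       # similarity 1: identity
  eAC <- comp$edges[comp$edges$origin == "A" & comp$edges$destination == "C", ]
  expect_equal(eAC$weight, 6 * exp(-0.5))
  expect_equal(nrow(comp$edges), nrow(net$edges))    # edge set unchanged
  expect_true(all(comp$edges$weight <= comp$edges$frequency + 1e-12))
  mf <- node_metrics(net)
  mc <- node_metrics(comp)
  expect_equal(mc$out_degree, mf$out_degree)
  expect_equal(mc$in_degree, mf$in_degree)

  expect_error(composite_network(net, sim[-1, ], "2015-04"), "A-B")
})
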