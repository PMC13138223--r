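# vesselnet

Network analysis of inter-island tourist-vessel traffic for marine
biosecurity planning. Small vessels moving between the islands of an
archipelago are a dominant human-mediated pathway for non-indigenous marine
species (NIMS): trip frequency proxies propagule pressure, and the
similarity of sea-surface temperature (SST) between a donor and a recipient
island proxies how likely a transported species is to establish. `vesselnet`
turns timetable-style trip records into a directed weighted network and asks
the questions a biosecurity planner needs answered: is the traffic
small-world (so an introduction anywhere spreads fast)? Which islands rank
highest as spreaders? Does the network partition into communities that could
be managed as units, and how vulnerable is each? And how do the answers
change when edges are re-weighted by environmental matching?

## The model

* **Network.** Each island is a node; the edge weight `w(i→j)` is the number
  of trips from `i` to `j` over the study window. Shortest-path metrics use
  inverted weights `d = 1/w`, so busy routes are short. Node-level
  invasion-risk indices: out-degree, out-strength, betweenness, and
  out-closeness (reachable-count over summed distances, reachable nodes
  only).
* **Weighted small-world-ness.** On the undirected collapse (pair weight =
  trips in both directions),

  `S = (C_g / C_rand) / (L_g / L_rand)`

  where `C_g` is the mean Onnela (geometric-mean, max-normalised) local
  clustering over nodes of degree ≥ 2, `L_g` the mean shortest-path length
  over reachable pairs, and the null terms are means over random G(n, m)
  graphs matched in node and edge counts with weights resampled from the
  observed pool. `S > 1` is small-world; empirical add-one p-values
  accompany both components.
* **Communities.** A Leiden-style optimizer (local move, refinement,
  aggregation) maximises directed weighted modularity
  `Q = Σ_within [w_ij/W − s_i^out s_j^in / W²]`. Significance is assessed by
  a degree-preserving permutation test: weighted double-edge swaps, Leiden
  re-run per replicate, `z = (Q_obs − mean Q_null)/sd Q_null`, two-sided
  normal p. Per-community vulnerability metrics: size, bridges, internal
  flow, in/out flow, mean member in/out-closeness and betweenness.
* **Environmental matching.** Pairwise SST similarity is a Gaussian kernel
  `S_SST = exp(−ΔT²/(2σ_T²))` with scale `σ_T = 2 °C` (≈ 0.6 at a 2 °C
  difference). Months are compared by Kruskal–Wallis plus Dunn's post hoc
  with Benjamini–Hochberg adjustment; composite edge weights are
  `trip frequency × S_SST` for a chosen month (by default the month with
  the highest median similarity).

Because real trip records of this kind are rarely shareable, the package
ships a synthetic archipelago generator (`synthetic_scenario()`) that
reproduces the structure the analysis assumes — a dominant hub, a clustered
partially rewired backbone, ~55 % reciprocal trips, isolated islands, and
seasonal latitudinally structured SST fields — so the whole pipeline is
testable end to end.

## Worked example

```r
library(vesselnet)

scn <- synthetic_scenario(seed = 42)   # 23 islands, 19 connected, 12000 trips
sim <- simulate_scenario(scn)
net <- build_network(sim$trips, sim$islands)
net
#> <vessel_network: directed, 23 islands (19 connected), 81 edges, total weight 12000>
reciprocity_fraction(net)
#> [1] 0.549

m <- node_metrics(net)
head(rank_nodes(m, "out_strength"), 3)
#>    rank island   value
#> 1     1 Island01  2675
#> 2     2 Island02   919
#> 3     3 Island09   746

smallworldness(net, n_sims = 1000, seed = 1)
#> Weighted small-world test (1000 null simulations)
#>   C_g = 0.4877  (null 0.1615 +/- 0.0436, p = 0.000999)
#>   L_g = 0.006528  (null 0.009113 +/- 0.000294, p = 0.001998)
#>   S = 4.214  -> small-world

p <- detect_communities(net, seed = 2)
p
#> <community_partition: 8 communities, Q = 0.2255, resolution = 1>
modularity_null_test(net, n_perm = 200, seed = 3)
#> Degree-preserving modularity test: Q = 0.2210 vs null 0.1875 +/- 0.0192
#>   z = 1.744, two-sided p = 0.081 (empirical 0.075), 200 permutations

sc <- seasonal_comparison(sim$sst)
sc
#> Seasonal SST-similarity comparison: Kruskal-Wallis chi-squared = 340.97, df = 11, p = 1.97e-66
#>   highest-median month: 2015-02 (median 0.919)

mo <- best_similarity_month(sc)
comp <- composite_network(net, sst_similarity(sim$sst, mo), mo)
detect_communities(comp, seed = 2)$Q
#> [1] 0.268   # up from 0.225: SST matching sharpens community structure
```

The hub (`Island01`) tops every risk index; the 4 islands without traffic
appear as singleton communities; the weighted small-world index is far above
1 because the backbone is clustered while hub spokes keep paths short; and
re-weighting by SST similarity raises modularity, concentrating risk within
environmentally matched clusters. `run_full_analysis()` chains all stages
from a config (or YAML file) and `write_report()` emits the TSV/GraphML/JSON
report; `scripts/vesselnet.R` exposes the same stages as subcommands
(`simulate`, `build`, `smallworld`, `communities`, `sst`, `rank`, `report`,
`run`).

Result objects follow broom conventions (`tidy()`, `glance()`) and have
`autoplot()` methods (`plot_network()` for the geographic layout).

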