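---
title: "Methods: vessel-traffic networks for marine biosecurity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vessel-traffic networks for marine biosecurity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselnet)
```

## The problem

Small tourist vessels shuttling between the islands of an archipelago are an
efficient vector for non-indigenous marine species (NIMS): hull fouling and
entrained water move organisms along whatever routes the fleet serves, at
whatever frequency it serves them. `vesselnet` treats the fleet's timetable
as a directed weighted network — islands as nodes, trip counts as edge
weights — and derives the quantities a biosecurity planner acts on: how fast
an introduction can percolate (small-world structure), which islands are the
strongest spreaders (node risk indices), whether the system decomposes into
communities that can be ring-fenced (modularity and its significance), and
how environmental matching between islands reshapes all of the above
(SST-composite weights).

## Network conventions

Edge weights are trip frequencies, so connection strength and distance are
inverse: all shortest-path computations use `d = 1/w` exactly, with no
tuning exponent. Closeness of a node is the number of nodes it can reach
divided by the summed shortest distances to them, computed over reachable
nodes only; a node that reaches nothing gets `NA` rather than zero, which
keeps means over community members honest. Because typical weights are in
the tens to hundreds of trips, distances are hundredths — closeness values
well above 1 are expected and meaningful only relative to one another.
Rankings sort descending with ties broken by island name so output is
deterministic; islands with no traffic are excluded from rankings but kept
in the network (they matter for community counts and for the null model's
node count).

Reciprocity is trip-weighted by default: the fraction of all trips whose
ordered pair is also served in the reverse direction anywhere in the window.
An edge-count variant is available (`method = "edge"`); the two differ
whenever heavy routes are more (or less) likely to be two-way than light
ones.

Zone connection statistics treat each linked unordered pair as one
connection and compute, per SST zone with at least one incident connection,
the share of its connections staying inside the zone. The mean and standard
error are taken across zones — the zone is the replication unit — and the SE
is defined as 0 when a single zone carries everything.

## Weighted small-world-ness

The index is `S = (C_g / C_rand) / (L_g / L_rand)` on the undirected
collapse of the network (pair weight = trips in both directions). Choices
that the definition leaves open, and what this package does:

* **Clustering variant.** `C_g` is the mean over nodes of degree ≥ 2 of the
  Onnela local coefficient — geometric mean of the three triangle weights,
  each normalised by the network's maximum weight. This keeps `C` in [0, 1]
  and, crucially, makes observed and null values comparable: the null graphs
  carry weights resampled from the observed pool, so the same normalisation
  applies on both sides. Barrat and binary variants are exposed
  (`variant =` in `weighted_clustering()`) for sensitivity checks.
  Degree-0/1 nodes carry no closure information and are excluded from the
  mean rather than entered as zeros.
* **Path length.** Mean of `d = 1/w` shortest paths over reachable unordered
  pairs; unreachable pairs are excluded rather than imputed, so isolated
  islands do not inflate `L_g`.
* **Null model.** Uniform simple G(n, m) graphs matched to the observed node
  and edge counts (including isolated nodes in `n`), with weights drawn with
  replacement from the observed weight multiset. Replicates on which `C` or
  `L` is undefined (no degree-2 node) are resampled and counted. The weight
  pool is sorted before sampling so results depend on the multiset, not on
  edge order — node relabelling cannot change any p-value.
* **p-values.** Add-one empirical estimators: one-sided for clustering
  (`P(C_rand ≥ C_g)`, the direction of interest), two-sided for path length
  (`2·min` of the two tails, capped at 1), since path length can credibly
  deviate either way.

Scaling every weight by `k > 0` leaves `C_g` unchanged and scales both `L_g`
and `L_rand` by `1/k`, so `S` is scale-invariant — a property the test suite
asserts.

## Communities and the permutation test

The installed graph library's Leiden implementation handles undirected
graphs only, so the package carries its own Leiden-style optimizer for
directed weighted modularity (`Q = Σ_within [w_ij/W − s_i^out s_j^in/W²]`):
queue-driven local moves (with the option of splitting off to a singleton),
a refinement pass that re-partitions each community from singletons before
aggregation, and repetition while `Q` improves. The sweep order is
randomised under the caller's seed; a fixed seed gives bit-identical
partitions. On the tens-of-nodes networks this package targets, the
optimizer's `Q` dominates both trivial partitions and matches brute-force
modularity evaluation (tested to 1e-9).

Significance uses a degree-preserving null: weighted double-edge swaps
(`a→b, c→d` becomes `a→d, c→b`; weights travel with edges; self-loops and
multi-edges rejected; `10·|E|` attempts per replicate), Leiden re-optimised
on every replicate — comparing optimised observed `Q` against optimised null
`Q` is the conservative choice when the alternative (holding the observed
membership fixed on replicates) is not specified. The reported p is the
two-sided standard-normal tail of `z`; the add-one empirical p is reported
alongside because the normal approximation can be optimistic at small
permutation counts.

Vulnerability metrics count a bridge once for each of its two endpoint
communities (an inter-community edge is a risk to both sides); flow columns
satisfy `Σ inflow = Σ outflow` and `Σ internal + Σ outflow = W` exactly, and
the tests assert this without tolerance. Closeness averages skip `NA`
members (isolated islands).

## SST similarity and composite weights

Similarity is `exp(−ΔT²/(2σ_T²))` with `σ_T = 2 °C` by default — at a 2 °C
difference the similarity is ≈ 0.6, a natural midpoint for interpreting
maps. The kernel is applied to the continuous difference; any 1 °C binning
is a reporting convenience, not part of the computation. Monthly groups
include every island pair with SST data that month (not just connected
pairs); an island missing a month drops its pairs from that month with a
warning rather than failing the run. The omnibus month comparison is
Kruskal–Wallis (tie-corrected, via `stats::kruskal.test`); the post hoc is
Dunn's pooled-rank z with tie correction — implemented here because no
installed package provides it — with Benjamini–Hochberg adjustment through
`stats::p.adjust`. When every similarity is identical (a constant SST
field), H is defined as 0 with p = 1 and all Dunn z as 0.

The composite network multiplies each directed edge's trip frequency by the
endpoint pair's similarity for one month — by default the month with the
highest median similarity, earliest month on ties, configurable to a fixed
month. The composite keeps the annual trip network's edge set and degrees
(similarity is positive), and can only shrink weights; every downstream
operation (metrics, rankings, communities, vulnerability) accepts it
unchanged.

## The synthetic generator

No trip data of this kind are public, so the generator is a first-class
module, not a fixture. Its defaults encode the study conditions the
analysis expects: 23 islands, 19 connected, 12 000 annual trips, a
reciprocity target of 0.55, one dominant hub, five latitude-banded SST
zones, and a 12-month window (Feb 2015–Jan 2016).

* **Backbone.** Connected islands are placed on a ring lattice ordered by
  latitude with links to the two nearest neighbours on each side — the
  minimal construction giving local clustering and geographic assortativity
  — rewired with probability 0.1 per edge (short global paths), plus spokes
  from the hub to every connected island. This is the smallest structure
  that simultaneously produces the observed features: a hub topping every
  risk index, clustering far above random, short paths, and isolated
  islands.
* **Traffic.** Hub-incident pairs share `hub_bias = 0.4` of the 12 000
  trips; each backbone pair is guaranteed 2 trips and the rest are
  multinomial. A randomised greedy subset of pairs whose expected traffic
  share is closest to 0.55 is served in both directions, so realised
  reciprocity fluctuates around the target rather than being enforced (the
  tests check recovery to ±0.05 over seeds). Trips spread uniformly over
  months; monthly traffic structure is not modelled.
* **SST.** `SST(i, m) = μ + A·cos(2π(m − peak)/12) + g_m·lat_i + ε` with
  `g_m = g·(1 + κ·cos(2π(m − peak − 6)/12))`. The seasonally modulated
  gradient (κ = 0.5, strongest in the cool season) is what makes monthly
  similarity distributions differ — a static gradient plus an
  island-independent seasonal term would give identical pairwise ΔT every
  month and an undetectable seasonal signal. Defaults: mean 24 °C, amplitude
  2 °C, gradient 2 °C per degree latitude, noise SD 0.4 °C.

What the generator does **not** emulate: vessel itineraries (edges are
independent pairs, not tours), monthly traffic seasonality, distance-decay
in route choice, and spatial autocorrelation of SST beyond the latitude
gradient. Passing tests therefore demonstrate that the pipeline recovers
planted structure of these kinds — not that real archipelago traffic has
that structure.

## Numerical and design notes

* Seeds are mandatory wherever randomness enters (generator, null
  ensembles, Leiden sweeps, permutation test); the pipeline derives
  independent stage seeds from one master seed so stages can be re-run in
  isolation and a full run is byte-reproducible.
* Problem sizes used by the shipped checks — 100 brute-force oracle graphs
  of ≤ 8 nodes, 50-seed recovery ensembles at 200 null simulations, 20-seed
  reciprocity recovery, 500–1000 permutations — were chosen to keep
  Monte-Carlo error well inside the asserted bounds while the whole suite
  runs in minutes.
* Degenerate inputs: empty month windows, networks without a degree-2 node,
  all-tied rank statistics, missing similarities for connected pairs, and
  zero-spread permutation nulls all raise informative errors or defined
  degenerate values rather than NaN.
* Known limitations: the modularity z-test's normal approximation is rough
  for skewed nulls (the empirical p is reported for that reason); Onnela
  max-normalisation ties `C_g` to the single largest weight, so one extreme
  route depresses clustering globally; and the generator's reciprocity is a
  target, not a constraint.
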