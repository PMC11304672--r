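---
title: "Assessing bias and robustness of telemetry-based social network metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing bias and robustness of telemetry-based social network metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telesna)
```

## Why a protocol

Social network analysis of wild animals almost always works from a partial
sample: GPS collars are expensive, captures are hard, and the monitored
animals are an unknown fraction of the population. Metrics computed on the
resulting *partial network* inherit two distinct problems — **bias** (the
expected value of the metric changes systematically with the number of
nodes) and **uncertainty** (a different draw of tagged animals would have
given a different value). Neither is visible from a single point estimate.
`telesna` packages a five-step resampling protocol that makes both visible
for any weighted association network, together with the machinery to build
such networks from raw relocations.

## From relocations to a network

Two fixes from two animals form a **joint observation** when their
timestamps differ by at most the temporal threshold `t` (minutes). Within
each dyad, fixes are matched **one-to-one**, greedily by ascending time
difference (ties broken by the earlier fix), so a single fix never counts
twice when the fix schedule is denser than `t`. The window is symmetric in
the two animals; for candidate generation a symmetric window and a
forward-scan window select the same pairs, so only the matching rule
(`greedy_one_to_one` vs `all_pairs`) is exposed.

With `x_AB` the joint observations at distance ≤ `s` metres and `y_AB` the
rest, the edge weight is the modified Simple Ratio Index
`x_AB / (x_AB + y_AB)`. The denominator deliberately counts only occasions
when *both* animals produced a fix: in telemetry, seeing A without B
usually means B's collar did not report, not that B was absent. Dyads never
co-observed contribute no edge; animals with no edges remain in the network
as isolates, so the network order always equals the number of animals
monitored.

Defaults `s = 15` m, `t = 7` min fit multi-hour ungulate collar schedules
whose fixes arrive with up to a few minutes of reception delay; a tighter
`s = 10` m suits denser deployments. `suggest_spatial_threshold()`
implements the usual data-driven alternative: the first mode of the
inter-individual distance histogram, on the argument that genuinely
associating pairs produce an excess of short distances. `sweep_thresholds()`
reports edge count, density and mean strength over an `(s, t)` grid for
sensitivity analysis.

Timestamps are stored UTC; the timezone used to *segment days* (below) is a
separate, explicit parameter, because "the tracks walked each day" is a
local-time notion. Geographic coordinates use haversine distances on a
6,371 km sphere rather than being projected: at the sub-100 m scales that
matter here, sphere error is negligible and no CRS choice is forced on the
user.

## The metrics

Node metrics: degree, strength (summed SRI weights), betweenness, local
clustering, eigenvector centrality. Global metrics: edge density,
transitivity, diameter, mean degree, mean strength, and `N`-scaled versions
of mean strength and diameter. Path-based and triangle-based metrics
(degree, betweenness, clustering, density, transitivity, diameter) use the
binary topology: treating a *low* association index as a *long* path length
would invert the index's meaning, so weights enter only strength and
eigenvector centrality. Diameter of a disconnected network is the largest
component diameter, so partitioned populations still yield a finite value.

Eigenvector centrality is the principal eigenvector of the weighted
adjacency (deterministic power iteration, uniform start, tolerance 1e-10,
≤ 10,000 iterations), scaled to max 1. On a disconnected network the
principal eigenvector is supported only on the component(s) of maximal
spectral radius; all other nodes get 0 (ties keep every dominant
component). This is the standard convention and, importantly, it is *why*
the metric is fragile under subsampling: removing nodes can change which
component dominates, flipping values between ~0 and ~1. An earlier design
that rescaled every component to max 1 was rejected precisely because it
suppressed this real instability.

## Step 1 — datastream permutations

Post-hoc edge shuffles destroy the autocorrelation that telemetry data
carry, so the null model permutes the *datastream*: each individual's track
is cut into calendar days, and the dates of those daily tracks are shuffled
uniformly *within that individual's own observed dates*. Every animal keeps
its exact home range, fix count, monitoring window and within-day movement;
only the alignment between individuals — who could have met whom — is
randomised. Dates are shuffled over the whole study period (no seasonal
blocking; a stratified variant would be a straightforward extension but is
not implemented).

`null_distribution()` repeats permute → build network → global metrics
`n_perm` times (1000 by default) and positions the observed value in the
null. Empirical p-values use the add-one correction,
`p_upper = (1 + #[null ≥ obs]) / (n_valid + 1)`, which guarantees p > 0;
permutations where a metric is undefined are excluded and tallied. A metric
whose observed value sits inside its null distribution does not capture
non-random association in this sample and should not carry ecological
inference.

## Step 2 — node subsampling

`subsample_distribution()` draws induced subgraphs of
`m = max(1, round(level · N))` nodes (associations among sampled nodes
kept, everything else dropped — exactly the network that tagging only those
animals would have produced) at levels 0.1–0.9, 100 replicates per level.
Two exact facts anchor the interpretation, and are verified by exhaustive
subset enumeration in the test suite:

* the expected induced-subgraph **density equals the full density** for
  every m ≥ 2 (each node pair survives with equal probability), which is
  why density is the protocol's most bias-resistant metric; and
* the expected induced-subgraph **mean strength is `(m−1)/(N−1)` times the
  full mean strength** (each retained node keeps that fraction of its
  neighbours in expectation) — the linear bias pattern, correctable when
  the sampling fraction is known.

`permuted_subsample_comparison()` pairs the observed-network subsample
distributions with one subsample per permuted network per level,
identifying the sampling fraction below which the observed network is no
longer distinguishable from a random one.

## Step 3 — bootstrap confidence intervals

`bootstrap_network()` samples the N nodes **with replacement**; each
replicate has exactly N node-copies. Copies of different originals are
adjacent iff the originals were, with the original weight. For a pair of
copies of the *same* original there is no observed edge to copy, so the
pair is always connected by an edge drawn uniformly from the original edge
list, carrying that edge's weight (`dup_edge_rule = "always_draw"`); an
alternative that connects such pairs only with probability equal to the
observed density is available (`"density_bernoulli"`), since the right
behaviour is genuinely ambiguous. Zero edges are resampled as zeros in
every replicate, so for very sparse networks (density < 0.05) a warning
notes that intervals may be optimistic; no correction is attempted.

CIs are equal-tailed percentile intervals with type-7 (linear
interpolation) quantiles — matching the bootstrap lineage of classical
social-network software and keeping the computation deterministic given the
replicate values. `ci_width_vs_samplesize()` traces mean CI width against
the number of nodes (10 outer subsample draws per size by default). Mean
strength and diameter are automatically replaced by their `N`-scaled
versions there: the raw metrics' attainable ranges shrink mechanically with
the node count, which would otherwise make widths *fall* as samples shrink
and mask the real growth of uncertainty.

`split_half_calibration()` guards against the opposite failure — intervals
so wide or so misplaced that equal things look different: nodes are split
into two disjoint halves, each half's induced network is bootstrapped, and
the proportion of trials with overlapping CIs is reported. On homogeneous
networks the two halves share a true value, so overlap should be nearly
universal.

## Steps 4 and 5 — node-level stability and uncertainty

`node_metric_correlation()` subsamples at levels 0.1/0.3/0.5/0.7/0.9 (10
repeats each), computes node metrics on the partial network and correlates
them against the *same nodes'* full-network values. Pearson is the default
(the conventional choice; Spearman is available), constant-vector repeats
are recorded as NA and tallied, and NA metric values (clustering below
degree 2) are dropped pairwise. A mean correlation above 0.7 is flagged as
"stable" — a reporting aid, not a filter. `node_metric_regression()` adds
the OLS slope of partial on full values; for degree and strength the
expected slope is `(m−1)/(N−1)`, the same geometry as the mean-strength
bias above.

`bootstrap_node_ci()` computes node metrics on each bootstrap replicate
(copies are distinct nodes), averages a node's copies within a replicate,
and builds percentile intervals over the replicates containing the node
(the expected share is `1 − (1 − 1/N)^N` ≈ 63%; `n_effective` reports the
realised count, and nodes absent from every replicate — possible at tiny B
— are flagged). Output is sorted by decreasing observed value per metric,
the caterpillar-plot convention.

Steps 4–5 depend only on the network, not on Steps 1–3, and can be run
independently — as `run_protocol()` does automatically for prebuilt-network
input (observational association data), where the permutation null model
has no raw datastream to permute.

## The simulator

`simulate_population()` generates the data the protocol expects: per-group
centroids follow correlated random walks that *continue across days* (so
different days occupy genuinely different places — a datastream permutation
then decouples contacts, which is what makes the null model informative on
simulated data); each member either attends its group on a given day
(probability `sociality`, default 0.9), walking with a pull of strength
`cohesion` (default 0.9) toward the centroid, or walks independently around
its own home-range centre. Fixes arrive every `fix_interval_minutes`
(default 120, a typical collar schedule) over `duration_days` (default 30)
with 20 s Gaussian schedule jitter and 10 m GPS noise; `step_sd` defaults
to 25 m, giving within-attending-group spreads of a few tens of metres and
hence informative — not saturated — SRI weights at the 15 m threshold.
Groups are spaced 10 km apart, so between-group edges are essentially
impossible and network components should recover the planted groups.

What the simulator does *not* emulate: habitat structure, behavioural state
switching, fix loss, and irregular sampling. Passing tests therefore
demonstrate the statistical machinery on data with planted truth and
telemetry-like schedule/autocorrelation structure, not performance on every
pathology of field data.

Two simulator regimes matter in the tests. With the defaults, every
within-group dyad associates and the network is a union of cliques — ideal
for detecting planted structure, but degenerate for node-level comparisons
(eigenvector centrality is constant on a clique). The 60-animal herd used
for the stability analyses therefore sets `sociality = 0.5`, the minimal
change that gives within-group degree heterogeneity and makes the
node-level correlations well defined.

## Numerical choices and problem sizes

Seeds: every stochastic function takes an optional `seed`; compound
procedures draw per-stage/per-permutation child seeds from one master seed,
so identical inputs and seed reproduce every output byte for byte
(`run_protocol()` writes the seed into its manifest). Tests and the
acceptance script run the protocol at reduced sizes chosen to keep the full
validation suite in the tens of minutes on one core: 100–200 permutations,
50–100 subsample replicates, B = 200–500 bootstrap replicates, networks of
6–60 nodes, with exhaustive enumeration (all 32,768 six-node edge sets; all
induced subsets of six-node fixtures) wherever a property can be checked
exactly.

## Known limitations

* The SRI treats all within-threshold contacts equally; duration- or
  distance-weighted indices are out of scope.
* The permutation null randomises contacts but cannot separate social
  preference from shared habitat use at fine scales.
* Bootstrap intervals understate uncertainty for very sparse networks
  (zero edges stay zero); the package warns rather than corrects.
* Subsampling is uniform; biased missingness (e.g. central animals easier
  to collar) is not modelled.
* No movement-model-based interaction recovery; the unit of evidence is
  the fix pair, not the continuous trajectory.
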