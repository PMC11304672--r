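# telesna

Bias and robustness assessment for animal social networks built from GPS
radio-telemetry.

## The problem

GPS collars monitor only a subset of a wild population, and social network
metrics computed from such a partial sample can be badly biased or wildly
uncertain — with the damage depending on the metric, the network structure,
and the fraction of animals tagged. `telesna` builds proximity-based
association networks from relocation streams and implements a five-step
protocol to decide which network metrics can be trusted for a given sample:

1. **Datastream permutation null models** — shuffle each animal's daily
   tracks across its own observed dates (preserving home ranges and
   within-day autocorrelation, randomising contacts) and test whether each
   global metric captures non-random association.
2. **Node subsampling** — induced subnetworks at 10%–90% of the nodes
   quantify the bias and spread of each global metric as the tagged
   fraction falls, side by side with subsamples of the permuted networks.
3. **Bootstrap confidence intervals for global metrics** — node bootstrap
   with replacement (same-node copy pairs get an edge redrawn from the
   original edge list), plus CI-width-vs-sample-size curves and a
   split-half calibration check.
4. **Node-metric stability** — correlation and regression of node-level
   metrics between partial and full networks at each sampling level.
5. **Bootstrap confidence intervals for node-level metrics** — per-animal
   uncertainty, sorted caterpillar-style.

Edges are weighted by a modified Simple Ratio Index. A pair of fixes from
two animals within *t* minutes of each other is one joint observation
(matched one-to-one per dyad); with `x_AB` the joint observations within
*s* metres and `y_AB` those farther apart,

```
SRI(A, B) = x_AB / (x_AB + y_AB)
```

so the denominator counts only occasions where **both** animals were
actually observed — the appropriate form for telemetry, where an absence is
usually a missing fix, not a missing animal. Defaults are `s = 15` m and
`t = 7` min, matching coarse ungulate telemetry with minute-scale
fix-schedule jitter.

A correlated-random-walk simulator with planted social groups
(`simulate_population()`) provides data with known structure, so every step
of the protocol is validated against planted truth.

## Worked example

```r
library(telesna)

sim <- simulate_population(n_individuals = 10, duration_days = 10, seed = 42)
g   <- build_network(sim$telemetry, s = 15, t = 7)
global_metrics(g)
#> # A tibble: 7 × 2
#>   metric               value
#>   <chr>                <dbl>
#> 1 density              0.267
#> 2 transitivity         1
#> 3 diameter             1
#> 4 mean_degree          2.4
#> 5 mean_strength        0.13
#> 6 scaled_mean_strength 0.013
#> 7 scaled_diameter      0.1
```

Ten animals in three planted groups yield three cliques: density 0.267
(12 of 45 possible edges), transitivity 1, diameter 1. Mean strength 0.13
is the average summed SRI per animal — each animal spends a modest fraction
of its joint observations within 15 m of each group-mate.

Is that association structure non-random?

```r
nd <- null_distribution(sim$telemetry, n_perm = 20, seed = 7)
glance(nd)[, c("metric", "observed", "null_mean", "p_upper")]
#> # A tibble: 4 × 4
#>   metric        observed null_mean p_upper
#> 1 density          0.267    0.148   0.0476
#> 2 mean_strength    0.13     0.0108  0.0476
#> 3 transitivity     1        0.461   0.0476
#> 4 diameter         1        3.15    1
```

Observed mean strength (0.13) is an order of magnitude above the permuted
datastreams' (0.011) and beats all 20 permutations (`p_upper = 1/21`):
the planted groups are detected. Each result object has `tidy()`,
`glance()` and `autoplot()` methods; `run_protocol()` executes all five
steps and writes tidy CSVs, figures and a JSON manifest:

```r
run_protocol(sim$telemetry, protocol_config(n_perm = 200, B = 500),
             output_dir = "report", seed = 1)
```

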