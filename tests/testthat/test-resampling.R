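test_that("induced subsampling preserves associations among sampled nodes", {
  g <- random_weighted_network(8, 0.5, seed = 2)
  expect_equal(igraph::vcount(subsample_network(g, 8)), 8)
  set.seed(1)
  s8 <- subsample_network(g, 8)
  expect_equal(igraph::ecount(s8), igraph::ecount(g))  # m = N keeps everything
  s1 <- subsample_network(g, 1)
  expect_equal(igraph::vcount(s1), 1)
  expect_equal(igraph::ecount(s1), 0)
  k4 <- igraph::make_full_graph(4)
  for (i in 1:5) expect_equal(igraph::ecount(subsample_network(k4, 2)), 1)
  expect_error(subsample_network(g, 0))
  expect_error(subsample_network(g, 9))
})

test_that("subsample distributions at level 1 reproduce the observed values", {
  g <- random_weighted_network(10, 0.4, seed = 5)
  sd1 <- subsample_distribution(g, levels = 1, n_rep = 5, seed = 3)
  obs <- sd1$observed
  for (m in names(obs)) {
    expect_true(all(sd1$values$value[sd1$values$metric == m] == obs[[m]]))
  }
})

test_that("induced-subgraph density is unbiased and mean strength scales by (m-1)/(N-1)", {
  # exhaustive enumeration over all C(6, m) subsets of one weighted fixture
  g <- random_weighted_network(6, 0.6, seed = 9)
  full <- global_metrics(g, c("density", "mean_strength"))
  full_d <- full$value[full$metric == "density"]
  full_ms <- full$value[full$metric == "mean_strength"]
  for (m in 2:6) {
    subs <- combn(6, m)
    vals <- apply(subs, 2, function(idx) {
      sg <- igraph::induced_subgraph(g, idx)
      gm <- global_metrics(sg, c("density", "mean_strength"))
      gm$value
    })
    expect_equal(mean(vals[1, ]), full_d, tolerance = 1e-12)
    expect_equal(mean(vals[2, ]), (m - 1) / 5 * full_ms, tolerance = 1e-12)
  }
})

test_that("bootstrap replicates have N nodes and honour the duplicate-copy edge rule", {
  g <- random_weighted_network(12, 0.3, seed = 7)
  set.seed(4)
  for (i in 1:5) {
    rg <- bootstrap_network(g)
    expect_equal(igraph::vcount(rg), 12)
    expect_false(igraph::any_loop(rg))
  }

  # forced all-distinct draw (a permutation) reconstructs the original
  perm <- sample(12)
  rg <- bootstrap_network(g, ids = perm)
  A <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
  R <- igraph::as_adjacency_matrix(rg, attr = "weight", sparse = FALSE)
  expect_equal(unname(R), unname(A[perm, perm]))

  # 2-node single-edge network: both copies of A get the only edge's weight
  g2 <- igraph::graph_from_literal(A - B)
  igraph::E(g2)$weight <- 0.42
  rg2 <- bootstrap_network(g2, ids = c(1, 1))
  expect_equal(igraph::ecount(rg2), 1)
  expect_equal(igraph::E(rg2)$weight, 0.42)

  # edgeless original: replicates stay edgeless, with a warning for dup pairs
  g0 <- igraph::make_empty_graph(4, directed = FALSE)
  igraph::V(g0)$name <- letters[1:4]
  expect_warning(rg0 <- bootstrap_network(g0, ids = c(1, 1, 2, 3)), "no edges")
  expect_equal(igraph::ecount(rg0), 0)
})

test_that("global bootstrap CIs are percentile intervals around the observed value", {
  # complete graph with constant weights: density replicates are constant
  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- letters[1:5]
  igraph::E(k5)$weight <- 1
  ci <- bootstrap_global_ci(k5, B = 30, metrics = "density", seed = 1)
  expect_equal(ci$ci$lower, 1)
  expect_equal(ci$ci$upper, 1)

  g <- random_weighted_network(20, 0.3, seed = 3)
  ci2 <- bootstrap_global_ci(g, B = 100, metrics = c("density", "mean_strength"),
                             seed = 2)
  reps <- tidy(ci2)
  for (m in c("density", "mean_strength")) {
    v <- reps$value[reps$metric == m]
    row <- ci2$ci[ci2$ci$metric == m, ]
    expect_lte(row$lower, row$upper)
    expect_equal(row$lower, quantile(v, 0.025, names = FALSE))
    expect_equal(row$upper, quantile(v, 0.975, names = FALSE))
    expect_equal(row$n_effective, 100)
  }
})

test_that("the observed density falls inside its own bootstrap CI in most runs", {
  g <- random_weighted_network(40, 0.2, seed = 11)
  obs <- global_metrics(g, "density")$value
  inside <- vapply(1:10, function(s) {
    ci <- suppressWarnings(
      bootstrap_global_ci(g, B = 100, metrics = "density", seed = 200 + s))$ci
    ci$lower <= obs && obs <= ci$upper
  }, logical(1))
  expect_gte(mean(inside), 0.8)
})

test_that("CI-width table has the contracted shape and maps raw metrics to scaled", {
  g <- random_weighted_network(30, 0.25, seed = 6)
  expect_message(
    w <- ci_width_vs_samplesize(g, sizes = c(10, 30), B = 40,
                                metrics = c("density", "mean_strength"),
                                n_outer = 2, seed = 1),
    "scaled")
  expect_equal(nrow(w), 4)
  expect_setequal(unique(w$metric), c("density", "scaled_mean_strength"))
})

test_that("split-half calibration returns a proportion with degenerate range at 1 trial", {
  g <- random_weighted_network(20, 0.4, seed = 8)
  r1 <- split_half_calibration(g, B = 30, n_trials = 1, seed = 2)
  expect_true(r1$overlap_proportion %in% c(0, 1))
  expect_equal(nrow(r1$results), 1)
})

test_that("node-level bootstrap CIs aggregate copies and track replicate membership", {
  # 2-node 1-edge network: every replicate containing A gives degree 1
  g2 <- igraph::graph_from_literal(A - B)
  igraph::E(g2)$weight <- 0.5
  nc <- bootstrap_node_ci(g2, B = 60, metrics = "degree", seed = 3)
  rowA <- nc$ci[nc$ci$node == "A", ]
  expect_equal(rowA$lower, 1)
  expect_equal(rowA$upper, 1)
  expect_lt(rowA$n_effective, 60)   # A absent from ~1/4 of replicates

  # edgeless network: strength CI is [0, 0]
  g0 <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(g0)$name <- c("a", "b", "c")
  nc0 <- suppressWarnings(bootstrap_node_ci(g0, B = 30, metrics = "strength", seed = 1))
  got <- nc0$ci[nc0$ci$n_effective > 0, ]
  expect_true(all(got$lower == 0 & got$upper == 0))

  # output sorted by decreasing observed value within metric
  g <- random_weighted_network(15, 0.3, seed = 5)
  nc2 <- suppressWarnings(bootstrap_node_ci(g, B = 50, metrics = c("degree", "strength"),
                                            seed = 7))
  for (m in c("degree", "strength")) {
    ov <- nc2$ci$observed[nc2$ci$metric == m]
    expect_true(all(diff(ov) <= 0))
  }
})

test_that("node-copy multiplicities look multinomial over replicates", {
  g <- random_weighted_network(10, 0.4, seed = 1)
  set.seed(12)
  counts <- integer(10)
  for (i in 1:200) {
    rg <- bootstrap_network(g)
    tab <- table(factor(igraph::V(rg)$original_id,
                        levels = igraph::V(g)$name))
    counts <- counts + as.integer(tab)
  }
  expect_equal(sum(counts), 2000)
  expect_gt(stats::chisq.test(counts, p = rep(0.1, 10))$p.value, 0.001)
})
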