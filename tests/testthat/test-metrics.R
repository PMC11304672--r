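triangle <- function(w = 1) {
  g <- igraph::graph_from_literal(A - B, B - C, A - C)
  igraph::E(g)$weight <- w
  g
}

nm_value <- function(tbl, node, metric) tbl$value[tbl$node == node & tbl$metric == metric]
gm_value <- function(g, metric) global_metrics(g, metric)$value

test_that("node metrics on canonical small graphs", {
  nm <- node_metrics(triangle())
  for (v in c("A", "B", "C")) {
    expect_equal(nm_value(nm, v, "degree"), 2)
    expect_equal(nm_value(nm, v, "strength"), 2)
    expect_equal(nm_value(nm, v, "clustering"), 1)
    expect_equal(nm_value(nm, v, "betweenness"), 0)
  }

  path <- igraph::graph_from_literal(A - B, B - C)
  igraph::E(path)$weight <- 1
  nmp <- node_metrics(path, c("betweenness", "clustering"))
  expect_equal(nm_value(nmp, "B", "betweenness"), 1)
  expect_equal(nm_value(nmp, "A", "betweenness"), 0)
  expect_true(is.na(nm_value(nmp, "A", "clustering")))  # degree < 2

  star <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("hub", paste0("L", 1:4))
  igraph::E(star)$weight <- 0.5
  nms <- node_metrics(star, "strength")
  expect_equal(nm_value(nms, "hub", "strength"), 2)
  expect_equal(nm_value(nms, "L1", "strength"), 0.5)
})

test_that("global metrics on canonical small graphs", {
  k4 <- igraph::make_full_graph(4)
  igraph::E(k4)$weight <- 1
  expect_equal(gm_value(k4, "density"), 1)
  expect_equal(gm_value(k4, "transitivity"), 1)
  expect_equal(gm_value(k4, "diameter"), 1)
  expect_equal(gm_value(k4, "mean_degree"), 3)

  p4 <- igraph::graph_from_literal(A - B, B - C, C - D)
  expect_equal(gm_value(p4, "density"), 0.5)
  expect_equal(gm_value(p4, "diameter"), 3)
  expect_equal(gm_value(p4, "transitivity"), 0)

  # two disjoint triangles: diameter is the max over components
  tt <- igraph::disjoint_union(igraph::make_full_graph(3), igraph::make_full_graph(3))
  expect_equal(gm_value(tt, "diameter"), 1)
  expect_equal(gm_value(tt, "density"), 6 / 15)

  # degenerate cases
  one <- igraph::make_empty_graph(1, directed = FALSE)
  expect_equal(gm_value(one, "density"), 0)
  expect_true(is.na(gm_value(one, "transitivity")))
  expect_equal(gm_value(one, "diameter"), 0)
})

test_that("degree/strength sums and the density identity hold on random graphs", {
  for (seed in 1:5) {
    g <- random_weighted_network(15, 0.3, seed = seed)
    nm <- node_metrics(g, c("degree", "strength"))
    expect_equal(sum(nm$value[nm$metric == "degree"]), 2 * igraph::ecount(g))
    expect_equal(sum(nm$value[nm$metric == "strength"]),
                 2 * sum(igraph::E(g)$weight))
    expect_equal(gm_value(g, "mean_degree") / (igraph::vcount(g) - 1),
                 gm_value(g, "density"))
    expect_equal(gm_value(g, "scaled_mean_strength"),
                 gm_value(g, "mean_strength") / igraph::vcount(g))
  }
})

test_that("eigenvector centrality matches igraph on connected graphs and zeroes isolates", {
  set.seed(3)
  g <- random_weighted_network(12, 0.5, seed = 8)
  stopifnot(igraph::is_connected(g))
  ours <- node_metrics(g, "eigenvector")$value
  ref <- igraph::eigen_centrality(g, weights = igraph::E(g)$weight)$vector
  expect_equal(ours, unname(ref), tolerance = 1e-6)

  # isolates get 0; only the dominant component carries non-zero values
  gi <- igraph::disjoint_union(igraph::make_full_graph(3),
                               igraph::make_empty_graph(2, directed = FALSE))
  igraph::E(gi)$weight <- 1
  ev <- node_metrics(gi, "eigenvector")$value
  expect_equal(ev, c(1, 1, 1, 0, 0))

  gk <- igraph::disjoint_union(igraph::make_full_graph(4),
                               igraph::make_full_graph(3))
  igraph::E(gk)$weight <- 1
  evk <- node_metrics(gk, "eigenvector")$value
  expect_equal(evk, c(1, 1, 1, 1, 0, 0, 0))
  expect_equal(evk, unname(igraph::eigen_centrality(gk)$vector), tolerance = 1e-6)

  expect_warning(ev0 <- node_metrics(igraph::make_empty_graph(3, directed = FALSE),
                                     "eigenvector")$value,
                 "edgeless")
  expect_equal(ev0, c(0, 0, 0))
})

test_that("metrics agree with the matrix-power oracle on random 6-node graphs", {
  pairs <- t(combn(6, 2))
  set.seed(11)
  for (code in sample(0:32767, 40)) {
    gc <- graph_from_code(code, pairs)
    o <- oracle_graph_stats(gc$A)
    expect_equal(gm_value(gc$g, "density"), o$density)
    expect_equal(gm_value(gc$g, "diameter"), o$diameter)
    tr <- gm_value(gc$g, "transitivity")
    if (is.na(o$transitivity)) expect_true(is.na(tr)) else expect_equal(tr, o$transitivity)
    btw <- node_metrics(gc$g, "betweenness")$value
    expect_equal(btw, o$betweenness, tolerance = 1e-9)
  }
})

test_that("metrics are invariant to node relabelling", {
  g <- random_weighted_network(10, 0.4, seed = 4)
  perm <- sample(10)
  g2 <- igraph::permute(g, perm)
  nm1 <- node_metrics(g)
  nm2 <- node_metrics(g2)
  for (m in unique(nm1$metric)) {
    v1 <- nm1$value[nm1$metric == m][order(nm1$node[nm1$metric == m])]
    v2 <- nm2$value[nm2$metric == m][order(nm2$node[nm2$metric == m])]
    expect_equal(v1, v2, tolerance = 1e-9)
  }
  expect_equal(global_metrics(g), global_metrics(g2), tolerance = 1e-9)
})

test_that("unknown metric names are configuration errors", {
  g <- triangle()
  expect_error(node_metrics(g, "pagerank"), class = "telesna_config_error")
  expect_error(global_metrics(g, "modularity"), class = "telesna_config_error")
})
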