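test_that("temporal window includes fixes up to t minutes apart and excludes beyond", {
  # a fix at 09:57 is evaluated against the other animal's fixes until 10:04
  ds <- make_ds(c("A", "B"), c(57, 64), x = c(0, 0), y = c(0, 0))
  jo <- find_joint_observations(ds, t = 7)
  expect_equal(nrow(jo), 1)
  expect_equal(jo$dt_mins, 7)

  ds2 <- make_ds(c("A", "B"), c(57, 65), x = c(0, 0), y = c(0, 0))
  expect_equal(nrow(find_joint_observations(ds2, t = 7)), 0)
})

test_that("greedy one-to-one matching uses each fix once and picks minimal dt", {
  # A at 10:00 and 10:10, B at 10:03: B's single fix matches the 10:00 fix
  ds <- make_ds(c("A", "A", "B"), c(60, 70, 63), x = c(0, 0, 0), y = c(0, 0, 0))
  jo <- find_joint_observations(ds, t = 7)
  expect_equal(nrow(jo), 1)
  expect_equal(jo$dt_mins, 3)

  # all_pairs keeps both candidates
  expect_equal(nrow(find_joint_observations(ds, t = 7, matching = "all_pairs")), 2)
})

test_that("association counts and SRI follow the modified index definition", {
  jo <- tibble::tibble(animal_a = "A", animal_b = "B",
                       time_a = Sys.time() + 1:3, time_b = Sys.time() + 1:3,
                       dt_mins = 0, distance_m = c(5, 20, 400))
  tab <- compute_associations(jo, s = 15)
  expect_equal(tab$x_ab, 1)
  expect_equal(tab$y_ab, 2)
  expect_equal(tab$sri, 1 / 3)

  # never within s -> sri 0; always within s -> sri 1
  tab0 <- compute_associations(dplyr::mutate(jo, distance_m = 100), s = 15)
  expect_equal(tab0$sri, 0)
  tab1 <- compute_associations(dplyr::mutate(jo, distance_m = 3), s = 15)
  expect_equal(tab1$sri, 1)
})

test_that("networks keep all animals as nodes and only positive-SRI edges", {
  ds <- make_ds(c("A", "B", "C"), c(0, 1, 200), x = c(0, 5, 0), y = c(0, 0, 0))
  g <- build_network(ds, s = 15, t = 7)
  expect_equal(igraph::vcount(g), 3)       # C isolated but present
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$weight, 1)

  # sri = 0 dyads produce no edge
  ds2 <- make_ds(c("A", "B"), c(0, 1), x = c(0, 500), y = c(0, 0))
  g2 <- build_network(ds2, s = 15, t = 7)
  expect_equal(igraph::ecount(g2), 0)
  expect_equal(igraph::vcount(g2), 2)

  expect_warning(build_network(make_ds("A", 0, 1, 1)), "fewer than 2")
})

test_that("one-to-one matching bounds the dyadic denominator", {
  for (seed in 1:10) {
    ds <- random_grid_ds(3, 8, seed)
    jo <- find_joint_observations(ds, t = 10)
    if (nrow(jo) == 0) next
    counts <- table(ds$animal_id)
    per_dyad <- dplyr::count(jo, animal_a, animal_b)
    for (r in seq_len(nrow(per_dyad))) {
      expect_lte(per_dyad$n[r],
                 min(counts[[per_dyad$animal_a[r]]], counts[[per_dyad$animal_b[r]]]))
    }
  }
})

test_that("association counts match the brute-force matcher on small datasets", {
  for (seed in 1:15) {
    ds <- random_grid_ds(sample(2:4, 1), 12, seed)
    got <- compute_associations(find_joint_observations(ds, t = 10), s = 15)
    want <- oracle_associations(ds, s = 15, t = 10)
    got <- as.data.frame(got[order(got$animal_a, got$animal_b), c("animal_a", "animal_b", "x_ab", "y_ab")])
    want <- want[order(want$animal_a, want$animal_b), ]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("relabelling animals yields an isomorphic network with identical weights", {
  ds <- random_grid_ds(4, 10, 99)
  g1 <- build_network(ds, s = 25, t = 10)
  relab <- setNames(paste0("Z", rev(sort(unique(ds$animal_id)))),
                    sort(unique(ds$animal_id)))
  ds2 <- ds
  ds2$animal_id <- unname(relab[ds$animal_id])
  ds2 <- as_telemetry(as.data.frame(ds2))
  g2 <- build_network(ds2, s = 25, t = 10)
  el1 <- igraph::as_data_frame(g1)
  el2 <- igraph::as_data_frame(g2)
  el1$from <- unname(relab[el1$from]); el1$to <- unname(relab[el1$to])
  key <- function(e) paste(pmin(e$from, e$to), pmax(e$from, e$to))
  expect_setequal(paste(key(el1), el1$weight), paste(key(el2), el2$weight))
})

test_that("suggest_spatial_threshold finds the first distance mode", {
  set.seed(42)
  n <- 400
  d <- c(abs(rnorm(0.8 * n, 10, 2)), runif(0.2 * n, 0, 500))
  # two animals alternating fixes a known distance apart, 1 min gaps
  ds <- make_ds(rep(c("A", "B"), each = n), rep(seq_len(n) * 10, 2),
                x = c(rep(0, n), d), y = 0)
  s_hat <- suggest_spatial_threshold(ds, t = 1, max_distance = 500, bin_width = 5)
  expect_gte(s_hat, 5); expect_lte(s_hat, 15)

  # degenerate unimodal: all joint distances 12 m -> bin containing 12
  ds2 <- make_ds(c("A", "B", "A", "B"), c(0, 0, 60, 60),
                 x = c(0, 12, 0, 12), y = 0)
  s2 <- suggest_spatial_threshold(ds2, t = 1, max_distance = 100, bin_width = 5)
  expect_lt(abs(s2 - 12), 5)

  # nothing within max_distance -> undefined-threshold error
  ds3 <- make_ds(c("A", "B"), c(0, 0), x = c(0, 5000), y = 0)
  expect_error(suggest_spatial_threshold(ds3, t = 1, max_distance = 100),
               class = "telesna_threshold_error")
})

test_that("threshold sweep is monotone in s and consistent with direct builds", {
  ds <- random_grid_ds(4, 10, 5)
  sw <- sweep_thresholds(ds, s_values = c(5, 15, 50), t_values = c(5, 10))
  expect_equal(nrow(sw), 6)
  for (tv in c(5, 10)) {
    ne <- sw$n_edges[sw$t == tv][order(sw$s[sw$t == tv])]
    expect_true(all(diff(ne) >= 0))
  }
  # joint-observation totals are non-decreasing in t
  for (seed in 1:5) {
    dsx <- random_grid_ds(3, 10, seed + 50)
    n5 <- nrow(find_joint_observations(dsx, t = 5))
    n10 <- nrow(find_joint_observations(dsx, t = 10))
    expect_lte(n5, n10)
  }
  # single combination equals the direct build
  g <- build_network(ds, s = 15, t = 5)
  one <- sweep_thresholds(ds, 15, 5)
  expect_equal(one$n_edges, igraph::ecount(g))
  expect_equal(one$density, global_metrics(g, "density")$value)
})

test_that("network writers round-trip nodes, edges and weights", {
  g <- build_network(make_ds(c("A", "B", "C"), c(0, 1, 500),
                             x = c(0, 5, 0), y = c(0, 0, 0)), s = 15, t = 7)
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(g, gml)
  g2 <- read_network_graphml(gml)
  expect_equal(igraph::vcount(g2), 3)
  expect_equal(igraph::E(g2)$weight, igraph::E(g)$weight)

  csv <- withr::local_tempfile(fileext = ".csv")
  write_network_edgelist(g, csv)
  g3 <- read_network_edgelist(csv)
  expect_equal(igraph::vcount(g3), 3)   # isolate C preserved
  expect_equal(sort(igraph::E(g3)$weight), sort(igraph::E(g)$weight))
})
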