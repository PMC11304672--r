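#' Induced subsample of a network
#'
#' Uniformly samples `m` nodes without replacement and returns the induced
#' subgraph: associations among sampled nodes are preserved, all others
#' dropped — the network one would have observed had only those `m`
#' animals been tagged.
#'
#' @param g An `igraph` network of `N` nodes.
#' @param m Subsample size, `1 <= m <= N`.
#' @return An `igraph` network of `m` nodes.
#' @export
subsample_network <- function(g, m) {
  n <- igraph::vcount(g)
  stopifnot(m >= 1, m <= n)
  igraph::induced_subgraph(g, sample.int(n, m))
}

#' Subsampling distributions of global metrics
#'
#' Step 2 of the protocol: at each sampling level, draws `n_rep` induced
#' subsamples of `m = max(1, round(level * N))` nodes and records the
#' requested global metrics, revealing which metrics stay unbiased as the
#' proportion of tagged individuals falls.
#'
#' @param g An `igraph` network.
#' @param levels Sampling proportions in `(0, 1]` (default 10%–90%).
#' @param n_rep Replicates per level (default 100).
#' @param metrics Global metrics (see [global_metrics()]).
#' @param seed Optional integer seed.
#' @return An `sna_subsample` object: tibble of `(level, m, rep, metric,
#'   value)` plus observed values; see [autoplot.sna_subsample()].
#' @export
subsample_distribution <- function(g, levels = seq(0.1, 0.9, by = 0.1),
                                   n_rep = 100,
                                   metrics = c("density", "mean_strength",
                                               "transitivity", "diameter"),
                                   seed = NULL) {
  stopifnot(all(levels > 0), all(levels <= 1), n_rep >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- igraph::vcount(g)
  values <- purrr::map_dfr(levels, function(lv) {
    m <- max(1L, round(lv * n))
    purrr::map_dfr(seq_len(n_rep), function(r) {
      sub <- subsample_network(g, m)
      tibble(level = lv, m = m, rep = r, metric = metrics,
             value = unname(global_metric_values(sub, metrics)))
    })
  })
  structure(list(values = values,
                 observed = global_metric_values(g, metrics),
                 n = n, n_rep = n_rep),
            class = "sna_subsample")
}

#' @export
print.sna_subsample <- function(x, ...) {
  cat("Subsampling distributions (", x$n_rep, " replicates/level, N = ",
      x$n, ")\n\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' @rdname tidy.sna_permtest
#' @method tidy sna_subsample
#' @export
tidy.sna_subsample <- function(x, ...) x$values

#' @rdname tidy.sna_permtest
#' @method glance sna_subsample
#' @export
glance.sna_subsample <- function(x, ...) {
  x$values |>
    group_by(.data$level, .data$m, .data$metric) |>
    summarise(mean = mean(.data$value, na.rm = TRUE),
              sd = sd(.data$value, na.rm = TRUE),
              n_na = sum(is.na(.data$value)), .groups = "drop") |>
    left_join(tibble(metric = names(x$observed), observed = unname(x$observed)),
              by = "metric")
}

#' Boxplots of subsampling distributions
#'
#' One facet per metric; boxes per sampling level; the observed full-network
#' value as a red horizontal line. Box positions relative to the red line
#' show bias, box sizes show uncertainty.
#'
#' @param object An `sna_subsample` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sna_subsample
#' @export
autoplot.sna_subsample <- function(object, ...) {
  obs <- tibble(metric = names(object$observed),
                observed = unname(object$observed))
  ggplot2::ggplot(object$values,
                  ggplot2::aes(x = factor(.data$level), y = .data$value)) +
    ggplot2::geom_boxplot(fill = "grey80", outlier.size = 0.5) +
    ggplot2::geom_hline(data = obs, ggplot2::aes(yintercept = .data$observed),
                        colour = "red") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "sampling level (proportion of nodes)", y = "metric value",
                  title = "Effect of node subsampling on global metrics")
}

#' Subsampling of permuted networks alongside the observed network
#'
#' Builds permuted datastream networks, draws one induced subsample per
#' permutation at each level, and pairs those with subsampling
#' distributions of the observed network — identifying the sampling level
#' at which the observed network starts resembling a random one.
#'
#' @param ds A `telemetry` tibble.
#' @param s,t Thresholds (see [build_network()]).
#' @param levels,n_rep,metrics As in [subsample_distribution()].
#' @param n_perm Number of permuted networks (1000 in routine use).
#' @param seed Optional integer seed.
#' @return A tibble `(source, level, m, rep, metric, value)` with `source`
#'   in `{"observed", "permuted"}`, of class `sna_subsample_comparison`.
#' @export
permuted_subsample_comparison <- function(ds, s = 15, t = 7,
                                          levels = seq(0.1, 0.9, by = 0.1),
                                          n_perm = 1000, n_rep = 100,
                                          metrics = c("density", "mean_strength",
                                                      "transitivity", "diameter"),
                                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g_obs <- build_network(ds, s = s, t = t)
  n <- igraph::vcount(g_obs)
  obs <- subsample_distribution(g_obs, levels, n_rep, metrics)$values
  obs$source <- "observed"
  perm <- purrr::map_dfr(seq_len(n_perm), function(i) {
    gp <- build_network(permute_datastream(ds), s = s, t = t)
    purrr::map_dfr(levels, function(lv) {
      m <- max(1L, round(lv * n))
      sub <- subsample_network(gp, m)
      tibble(level = lv, m = m, rep = i, metric = metrics,
             value = unname(global_metric_values(sub, metrics)))
    })
  })
  perm$source <- "permuted"
  out <- bind_rows(obs, perm) |>
    select("source", dplyr::everything())
  class(out) <- c("sna_subsample_comparison", class(out))
  attr(out, "observed") <- global_metric_values(g_obs, metrics)
  out
}

#' @rdname autoplot.sna_subsample
#' @param object An `sna_subsample_comparison` tibble.
#' @method autoplot sna_subsample_comparison
#' @export
autoplot.sna_subsample_comparison <- function(object, ...) {
  obs <- attr(object, "observed")
  obs_tbl <- tibble(metric = names(obs), observed = unname(obs))
  ggplot2::ggplot(object,
                  ggplot2::aes(x = factor(.data$level), y = .data$value,
                               fill = .data$source)) +
    ggplot2::geom_boxplot(outlier.size = 0.4, position = "dodge") +
    ggplot2::geom_hline(data = obs_tbl,
                        ggplot2::aes(yintercept = .data$observed), colour = "red") +
    ggplot2::scale_fill_manual(values = c(observed = "steelblue", permuted = "grey70")) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "sampling level", y = "metric value",
                  title = "Observed vs permuted subsampling distributions")
}

#' Node bootstrap replicate of a network
#'
#' Samples the `N` nodes with replacement and builds a replicate network of
#' exactly `N` node-copies: a pair of copies of *different* originals is
#' joined iff the originals were adjacent (with the original weight); a
#' pair of copies of the *same* original is joined by an edge drawn
#' uniformly from the original edge list, taking that edge's weight. If the
#' original network has no edges, same-original pairs stay unconnected
#' (with a warning).
#'
#' With `dup_edge_rule = "density_bernoulli"` a same-original copy pair is
#' instead connected with probability equal to the original edge density,
#' with a weight drawn uniformly from the original edge weights.
#'
#' @param g An `igraph` network with `N >= 2` nodes.
#' @param ids Optional integer vector of length `N` of original node
#'   indices (a forced draw, e.g. a permutation); sampled uniformly with
#'   replacement when `NULL`.
#' @param dup_edge_rule `"always_draw"` (default) or `"density_bernoulli"`.
#' @return An `igraph` network of `N` copies; vertex attribute
#'   `original_id` maps copies back to original node names.
#' @export
bootstrap_network <- function(g, ids = NULL,
                              dup_edge_rule = c("always_draw", "density_bernoulli")) {
  dup_edge_rule <- match.arg(dup_edge_rule)
  n <- igraph::vcount(g)
  stopifnot(n >= 2)
  if (is.null(ids)) ids <- sample.int(n, n, replace = TRUE)
  stopifnot(length(ids) == n)
  has_w <- "weight" %in% igraph::edge_attr_names(g)
  A <- igraph::as_adjacency_matrix(g, attr = if (has_w) "weight" else NULL,
                                   sparse = FALSE)
  R <- A[ids, ids, drop = FALSE]
  diag(R) <- 0
  ew <- edge_weights_of(g)
  dup_pairs <- which(outer(ids, ids, "==") & upper.tri(diag(n)), arr.ind = TRUE)
  if (nrow(dup_pairs) > 0) {
    if (length(ew) == 0) {
      warn("Original network has no edges; same-original copy pairs left unconnected.")
    } else {
      dens <- 2 * length(ew) / (n * (n - 1))
      for (r in seq_len(nrow(dup_pairs))) {
        i <- dup_pairs[r, 1]; j <- dup_pairs[r, 2]
        w <- if (dup_edge_rule == "always_draw") {
          ew[sample.int(length(ew), 1L)]
        } else if (runif(1) < dens) {
          ew[sample.int(length(ew), 1L)]
        } else 0
        R[i, j] <- w; R[j, i] <- w
      }
    }
  }
  orig_names <- igraph::V(g)$name %||% as.character(seq_len(n))
  rownames(R) <- colnames(R) <- make.unique(orig_names[ids], sep = "#")
  rep_g <- igraph::graph_from_adjacency_matrix(R, mode = "undirected",
                                               weighted = TRUE)
  igraph::V(rep_g)$original_id <- orig_names[ids]
  rep_g
}

#' Bootstrap percentile confidence intervals for global metrics
#'
#' Step 3 of the protocol: `B` node-bootstrap replicates of the network,
#' the requested global metrics on each, and equal-tailed percentile
#' intervals (linear interpolation between order statistics).
#'
#' A warning is issued for very sparse networks (density < 0.05): edges
#' absent from the observed network are resampled as absent in every
#' replicate, so bootstrap intervals can understate uncertainty there.
#'
#' @param g An `igraph` network.
#' @param B Bootstrap replicates (>= 2; 1000 in routine use).
#' @param metrics Global metrics.
#' @param conf Confidence level (default 0.95).
#' @param dup_edge_rule Passed to [bootstrap_network()].
#' @param seed Optional integer seed.
#' @return An `sna_global_ci` object: per-metric observed value, interval
#'   bounds and number of non-`NA` replicates; replicate values retained
#'   for [tidy.sna_global_ci()].
#' @export
bootstrap_global_ci <- function(g, B = 1000,
                                metrics = c("density", "mean_strength",
                                            "transitivity", "diameter"),
                                conf = 0.95,
                                dup_edge_rule = "always_draw", seed = NULL) {
  stopifnot(B >= 2)
  if (!is.null(seed)) set.seed(seed)
  dens <- 2 * igraph::ecount(g) / max(1, igraph::vcount(g) * (igraph::vcount(g) - 1))
  if (dens < 0.05 && igraph::vcount(g) > 1) {
    warn("Network density < 0.05: unobserved (zero) edges are resampled as zeros in every bootstrap replicate; intervals may be optimistic.")
  }
  reps <- purrr::map_dfr(seq_len(B), function(b) {
    rg <- bootstrap_network(g, dup_edge_rule = dup_edge_rule)
    tibble(replicate = b, metric = metrics,
           value = unname(global_metric_values(rg, metrics)))
  })
  observed <- global_metric_values(g, metrics)
  alpha <- (1 - conf) / 2
  ci <- reps |>
    group_by(.data$metric) |>
    summarise(
      lower = quantile(.data$value, alpha, na.rm = TRUE, names = FALSE, type = 7),
      upper = quantile(.data$value, 1 - alpha, na.rm = TRUE, names = FALSE, type = 7),
      n_effective = sum(!is.na(.data$value)),
      .groups = "drop"
    ) |>
    left_join(tibble(metric = names(observed), observed = unname(observed)),
              by = "metric") |>
    select("metric", "observed", "lower", "upper", "n_effective")
  structure(list(ci = ci, replicates = reps, B = B, conf = conf),
            class = "sna_global_ci")
}

#' @export
print.sna_global_ci <- function(x, ...) {
  cat("Bootstrap percentile CIs (B = ", x$B, ", conf = ", x$conf, ")\n\n", sep = "")
  print(x$ci)
  invisible(x)
}

#' @rdname tidy.sna_permtest
#' @method tidy sna_global_ci
#' @export
tidy.sna_global_ci <- function(x, ...) x$replicates

#' @rdname tidy.sna_permtest
#' @method glance sna_global_ci
#' @export
glance.sna_global_ci <- function(x, ...) x$ci

#' Mean confidence-interval width against sample size
#'
#' For each sample size, draws an induced subsample of that many nodes,
#' bootstraps it, and records the width of the percentile interval;
#' repeated `n_outer` times and averaged. For mean strength and diameter,
#' the node-count-scaled versions are substituted automatically, since the
#' raw metrics' ranges shrink mechanically with the node count, which would
#' reverse the width-vs-size trend.
#'
#' @param g An `igraph` network.
#' @param sizes Node counts to examine (each `<= N`).
#' @param B Bootstrap replicates per interval.
#' @param metrics Global metrics (raw mean strength/diameter are mapped to
#'   their scaled variants).
#' @param n_outer Outer repetitions (default 10).
#' @param conf Confidence level.
#' @param seed Optional integer seed.
#' @return A tibble `(size, metric, mean_width, sd_width)` of class
#'   `sna_ci_width`.
#' @export
ci_width_vs_samplesize <- function(g, sizes, B = 1000,
                                   metrics = c("density", "transitivity",
                                               "scaled_mean_strength",
                                               "scaled_diameter"),
                                   n_outer = 10, conf = 0.95, seed = NULL) {
  stopifnot(all(sizes <= igraph::vcount(g)), all(sizes >= 2), n_outer >= 1)
  if (!is.null(seed)) set.seed(seed)
  mapped <- dplyr::recode(metrics,
                          mean_strength = "scaled_mean_strength",
                          diameter = "scaled_diameter")
  if (!identical(mapped, metrics)) {
    inform("Using scaled versions of mean strength / diameter for CI-width comparison.")
  }
  out <- purrr::map_dfr(sizes, function(sz) {
    widths <- purrr::map_dfr(seq_len(n_outer), function(o) {
      sub <- subsample_network(g, sz)
      ci <- suppressWarnings(
        bootstrap_global_ci(sub, B = B, metrics = mapped, conf = conf)
      )$ci
      tibble(outer = o, metric = ci$metric, width = ci$upper - ci$lower)
    })
    widths |>
      group_by(.data$metric) |>
      summarise(mean_width = mean(.data$width, na.rm = TRUE),
                sd_width = sd(.data$width, na.rm = TRUE), .groups = "drop") |>
      mutate(size = sz, .before = 1)
  })
  class(out) <- c("sna_ci_width", class(out))
  out
}

#' @rdname autoplot.sna_subsample
#' @param object An `sna_ci_width` tibble.
#' @method autoplot sna_ci_width
#' @export
autoplot.sna_ci_width <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$size, y = .data$mean_width)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "number of nodes", y = "mean 95% CI width",
                  title = "Bootstrap CI width vs sample size")
}

#' Split-half calibration of the bootstrap
#'
#' Checks that the bootstrap does not manufacture spurious significance:
#' nodes are partitioned uniformly into two disjoint halves, each half's
#' induced network is bootstrapped, and the proportion of trials in which
#' the two confidence intervals overlap is reported. For a homogeneous
#' network the two halves share the same true metric value, so overlap
#' should be frequent.
#'
#' @param g An `igraph` network with `N >= 4`.
#' @param B Bootstrap replicates per half.
#' @param metric A single global metric (default `"density"`).
#' @param n_trials Number of random partitions (default 50).
#' @param conf Confidence level.
#' @param seed Optional integer seed.
#' @return A list: `overlap_proportion`, `n_trials`, `n_skipped` (trials
#'   where the metric was undefined in a half), and per-trial `results`.
#' @export
split_half_calibration <- function(g, B = 1000, metric = "density",
                                   n_trials = 50, conf = 0.95, seed = NULL) {
  n <- igraph::vcount(g)
  stopifnot(n >= 4, length(metric) == 1)
  if (!is.null(seed)) set.seed(seed)
  res <- purrr::map_dfr(seq_len(n_trials), function(tr) {
    perm <- sample.int(n)
    h1 <- perm[seq_len(n %/% 2)]
    h2 <- perm[(n %/% 2 + 1):n]
    ci1 <- suppressWarnings(bootstrap_global_ci(
      igraph::induced_subgraph(g, h1), B = B, metrics = metric, conf = conf))$ci
    ci2 <- suppressWarnings(bootstrap_global_ci(
      igraph::induced_subgraph(g, h2), B = B, metrics = metric, conf = conf))$ci
    ok <- !any(is.na(c(ci1$lower, ci1$upper, ci2$lower, ci2$upper)))
    tibble(trial = tr,
           lower1 = ci1$lower, upper1 = ci1$upper,
           lower2 = ci2$lower, upper2 = ci2$upper,
           valid = ok,
           overlap = if (ok) ci1$lower <= ci2$upper && ci2$lower <= ci1$upper else NA)
  })
  valid <- res[res$valid, , drop = FALSE]
  list(overlap_proportion = mean(valid$overlap),
       n_trials = n_trials,
       n_skipped = sum(!res$valid),
       results = res)
}

#' Bootstrap percentile confidence intervals for node-level metrics
#'
#' Step 5 of the protocol: `B` node-bootstrap replicates; in each, node
#' metrics are computed on the replicate graph (copies are distinct nodes)
#' and a node's value is the mean over its copies. Replicates not
#' containing a node contribute nothing to that node's interval (the
#' expected share of contributing replicates is `1 - (1 - 1/N)^N`, about
#' 63%); `n_effective` reports the count. Output is sorted within metric by
#' decreasing observed value (caterpillar-plot convention).
#'
#' @param g An `igraph` network.
#' @param B Bootstrap replicates (1000 in routine use).
#' @param metrics Node metrics (see [node_metrics()]).
#' @param conf Confidence level.
#' @param dup_edge_rule Passed to [bootstrap_network()].
#' @param seed Optional integer seed.
#' @return An `sna_node_ci` object: tibble `(metric, node, observed, lower,
#'   upper, n_effective)`; nodes never sampled across all `B` replicates
#'   get `NA` bounds.
#' @export
bootstrap_node_ci <- function(g, B = 1000, metrics = NODE_METRICS, conf = 0.95,
                              dup_edge_rule = "always_draw", seed = NULL) {
  stopifnot(B >= 2)
  if (!is.null(seed)) set.seed(seed)
  nodes <- igraph::V(g)$name %||% as.character(seq_len(igraph::vcount(g)))
  reps <- purrr::map_dfr(seq_len(B), function(b) {
    rg <- suppressWarnings(bootstrap_network(g, dup_edge_rule = dup_edge_rule))
    nm <- node_metrics(rg, metrics)
    nm$node <- igraph::V(rg)$original_id[match(nm$node, igraph::V(rg)$name)]
    nm |>
      group_by(.data$node, .data$metric) |>
      summarise(value = mean(.data$value), .groups = "drop") |>
      mutate(replicate = b)
  })
  obs <- node_metrics(g, metrics) |> rename(observed = "value")
  alpha <- (1 - conf) / 2
  ci <- reps |>
    group_by(.data$metric, .data$node) |>
    summarise(
      lower = quantile(.data$value, alpha, na.rm = TRUE, names = FALSE, type = 7),
      upper = quantile(.data$value, 1 - alpha, na.rm = TRUE, names = FALSE, type = 7),
      n_effective = sum(!is.na(.data$value)),
      .groups = "drop"
    ) |>
    right_join(obs, by = c("metric", "node")) |>
    mutate(n_effective = dplyr::coalesce(.data$n_effective, 0L)) |>
    select("metric", "node", "observed", "lower", "upper", "n_effective") |>
    arrange(.data$metric, dplyr::desc(.data$observed))
  if (any(ci$n_effective == 0)) {
    warn(sprintf("%d node(s) were absent from every replicate; their CIs are undefined.",
                 sum(ci$n_effective == 0)))
  }
  structure(list(ci = ci, B = B, conf = conf), class = "sna_node_ci")
}

#' @export
print.sna_node_ci <- function(x, ...) {
  cat("Node-level bootstrap CIs (B = ", x$B, ", conf = ", x$conf, ")\n\n", sep = "")
  print(x$ci)
  invisible(x)
}

#' @rdname tidy.sna_permtest
#' @method tidy sna_node_ci
#' @export
tidy.sna_node_ci <- function(x, ...) x$ci

#' Caterpillar plot of node-level bootstrap intervals
#'
#' Nodes sorted by decreasing observed value within each metric facet;
#' points are observed values, bars the bootstrap percentile intervals.
#'
#' @param object An `sna_node_ci` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sna_node_ci
#' @export
autoplot.sna_node_ci <- function(object, ...) {
  df <- object$ci |>
    group_by(.data$metric) |>
    mutate(rank = dplyr::row_number()) |>
    ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$observed)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                           width = 0, colour = "grey50") +
    ggplot2::geom_point(size = 0.8, colour = "red") +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = "node (decreasing observed value)", y = "metric value",
                  title = "Node-level metrics with bootstrap CIs")
}
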