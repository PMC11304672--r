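NODE_METRICS <- c("degree", "strength", "betweenness", "eigenvector", "clustering")
GLOBAL_METRICS <- c("density", "transitivity", "diameter", "mean_degree",
                    "mean_strength", "scaled_mean_strength", "scaled_diameter")

edge_weights_of <- function(g) {
  if ("weight" %in% igraph::edge_attr_names(g)) igraph::E(g)$weight
  else rep(1, igraph::ecount(g))
}

#' Node-level network metrics
#'
#' Computes the standard node-level metrics of animal social network
#' analysis. Degree, betweenness and the local clustering coefficient use
#' the binary topology; strength sums the incident association-index
#' weights; eigenvector centrality uses the weighted adjacency. Topological
#' path metrics are kept unweighted because a low association index would
#' otherwise read as a long distance, which is not what the index measures.
#'
#' Eigenvector centrality is the principal eigenvector of the weighted
#' adjacency, obtained by deterministic power iteration (uniform start
#' vector, tolerance 1e-10, at most 10,000 iterations), scaled to a
#' maximum of 1. On a disconnected network only the component(s) with the
#' largest spectral radius carry non-zero values and all other nodes get 0
#' — the standard convention, and the root of this metric's fragility when
#' nodes are subsampled.
#'
#' @param g An `igraph` network (undirected; edge attribute `weight`).
#' @param which Subset of
#'   `c("degree", "strength", "betweenness", "eigenvector", "clustering")`.
#' @return A tidy tibble `(node, metric, value)`. Clustering is `NA` for
#'   nodes of degree < 2; betweenness is unnormalised.
#' @export
node_metrics <- function(g, which = NODE_METRICS) {
  bad <- setdiff(which, NODE_METRICS)
  if (length(bad) > 0) {
    abort(paste0("Unknown node metric(s): ", paste(bad, collapse = ", ")),
          class = "telesna_config_error")
  }
  nodes <- igraph::V(g)$name %||% as.character(seq_len(igraph::vcount(g)))
  vals <- list()
  if ("degree" %in% which) {
    vals$degree <- as.numeric(igraph::degree(g))
  }
  if ("strength" %in% which) {
    vals$strength <- as.numeric(igraph::strength(g, weights = edge_weights_of(g)))
  }
  if ("betweenness" %in% which) {
    vals$betweenness <- as.numeric(igraph::betweenness(g, weights = NA, normalized = FALSE))
  }
  if ("eigenvector" %in% which) {
    vals$eigenvector <- eigenvector_centrality(g)
  }
  if ("clustering" %in% which) {
    cl <- suppressWarnings(igraph::transitivity(g, type = "local", isolates = "NaN"))
    cl[is.nan(cl)] <- NA_real_
    vals$clustering <- cl
  }
  purrr::imap_dfr(vals[which[which %in% names(vals)]], function(v, m) {
    tibble(node = nodes, metric = m, value = unname(v))
  })
}

# Principal-eigenvector centrality of the weighted adjacency, by
# deterministic power iteration (uniform start, tolerance 1e-10, at most
# 10,000 iterations). Iteration runs per connected component for numerical
# control, but only components attaining the graph's maximal spectral
# radius carry non-zero values — the global principal eigenvector of the
# block-diagonal adjacency is supported there, which is what makes the
# metric fragile under subsampling (the dominant component can change
# identity). Isolates and sub-dominant components get 0; the result is
# scaled to max = 1.
eigenvector_centrality <- function(g, tol = 1e-10, max_iter = 10000L) {
  n <- igraph::vcount(g)
  if (n == 0) return(numeric(0))
  if (igraph::ecount(g) == 0) {
    warn("Eigenvector centrality on an edgeless network: all values 0.")
    return(rep(0, n))
  }
  A <- igraph::as_adjacency_matrix(g, attr = if ("weight" %in% igraph::edge_attr_names(g)) "weight" else NULL,
                                   sparse = FALSE)
  comp <- igraph::components(g)$membership
  vecs <- list(); lams <- numeric(0); idxs <- list()
  for (cmp in unique(comp)) {
    idx <- which(comp == cmp)
    if (length(idx) == 1) next  # isolate
    Ac <- A[idx, idx, drop = FALSE]
    v <- rep(1 / sqrt(length(idx)), length(idx))
    lam <- 0
    for (it in seq_len(max_iter)) {
      w <- as.numeric(Ac %*% v)
      nw <- sqrt(sum(w^2))
      if (nw == 0) break
      lam <- nw
      w <- w / nw
      if (max(abs(w - v)) < tol) { v <- w; break }
      v <- w
    }
    k <- length(vecs) + 1L
    vecs[[k]] <- abs(v); lams[k] <- lam; idxs[[k]] <- idx
  }
  out <- rep(0, n)
  if (length(lams) > 0) {
    lam_max <- max(lams)
    for (k in seq_along(lams)) {
      # ties (equal spectral radii) keep every dominant component
      if (lams[k] >= lam_max * (1 - 1e-9)) out[idxs[[k]]] <- vecs[[k]]
    }
    out <- out / max(out)
  }
  out
}

#' Global network metrics
#'
#' Density, transitivity, diameter, mean degree and mean strength, plus the
#' node-count-scaled variants of mean strength and diameter used when
#' comparing uncertainty across sample sizes (the raw versions shrink
#' mechanically with fewer nodes, so their confidence-interval widths are
#' not comparable across network orders).
#'
#' @param g An `igraph` network.
#' @param which Subset of `c("density", "transitivity", "diameter",
#'   "mean_degree", "mean_strength", "scaled_mean_strength",
#'   "scaled_diameter")`.
#' @return A tibble `(metric, value)`. Density is `2|E| / (N(N-1))` (0 for
#'   a single node); transitivity is `NA` when the network has no connected
#'   triples; diameter is the maximum unweighted component diameter, so
#'   disconnected networks still yield a finite value; means are over all
#'   `N` nodes, isolates included; scaled variants divide by `N`.
#' @export
global_metrics <- function(g, which = GLOBAL_METRICS) {
  bad <- setdiff(which, GLOBAL_METRICS)
  if (length(bad) > 0) {
    abort(paste0("Unknown global metric(s): ", paste(bad, collapse = ", ")),
          class = "telesna_config_error")
  }
  n <- igraph::vcount(g)
  w <- edge_weights_of(g)
  need_diam <- any(c("diameter", "scaled_diameter") %in% which)
  diam <- if (need_diam) {
    if (igraph::ecount(g) == 0) 0
    else as.numeric(igraph::diameter(g, weights = NA, unconnected = TRUE))
  } else NA_real_
  need_ms <- any(c("mean_strength", "scaled_mean_strength") %in% which)
  ms <- if (need_ms && n > 0) 2 * sum(w) / n else NA_real_
  vals <- c(
    density = if (n > 1) 2 * igraph::ecount(g) / (n * (n - 1)) else 0,
    transitivity = {
      tr <- suppressWarnings(igraph::transitivity(g, type = "global"))
      if (is.nan(tr)) NA_real_ else tr
    },
    diameter = diam,
    mean_degree = if (n > 0) 2 * igraph::ecount(g) / n else NA_real_,
    mean_strength = ms,
    scaled_mean_strength = if (n > 0) ms / n else NA_real_,
    scaled_diameter = if (n > 0) diam / n else NA_real_
  )
  tibble(metric = which, value = unname(vals[which]))
}

# Named vector shortcut used by the resampling loops.
global_metric_values <- function(g, which) {
  gm <- global_metrics(g, which)
  setNames(gm$value, gm$metric)
}

# Wide node-metric matrix (nodes x metrics) used by stability analyses.
node_metric_wide <- function(g, which) {
  nm <- node_metrics(g, which)
  tidyr::pivot_wider(nm, names_from = "metric", values_from = "value")
}
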