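#' Find temporally matched joint observations between dyads
#'
#' For every unordered pair of animals, fixes of the two animals are matched
#' one-to-one within the temporal threshold: candidate pairs with
#' `|timestamp difference| <= t` minutes are taken greedily in ascending
#' `|dt|` (ties broken by the earlier fix of the first animal, then of the
#' second), each fix being used at most once per dyad. Each matched pair is
#' one simultaneous sampling event — the unit counted in the modified Simple
#' Ratio Index denominator.
#'
#' With `matching = "all_pairs"` every candidate pair within the window is
#' kept (no one-to-one constraint); this can double-count events when the
#' fix interval is shorter than `t`.
#'
#' @param ds A `telemetry` tibble.
#' @param t Temporal threshold in minutes (> 0).
#' @param matching `"greedy_one_to_one"` (default) or `"all_pairs"`.
#' @return A tibble with columns `animal_a`, `animal_b` (with
#'   `animal_a < animal_b`), `time_a`, `time_b`, `dt_mins`, `distance_m`.
#' @export
find_joint_observations <- function(ds, t, matching = c("greedy_one_to_one", "all_pairs")) {
  matching <- match.arg(matching)
  stopifnot(t > 0)
  mode <- coordinate_mode_of(ds)
  ids <- sort(unique(ds$animal_id))
  if (length(ids) < 2) {
    return(tibble(animal_a = character(), animal_b = character(),
                  time_a = as.POSIXct(character(), tz = "UTC"),
                  time_b = as.POSIXct(character(), tz = "UTC"),
                  dt_mins = double(), distance_m = double()))
  }
  xy <- coord_matrix(ds)
  secs <- as.numeric(ds$timestamp)
  idx_by_animal <- split(seq_len(nrow(ds)), ds$animal_id)
  tol <- t * 60

  res <- vector("list", length(ids) * (length(ids) - 1L) / 2L)
  k <- 0L
  for (i in seq_len(length(ids) - 1L)) {
    ia <- idx_by_animal[[ids[i]]]
    ta <- secs[ia]
    for (j in seq.int(i + 1L, length(ids))) {
      ib <- idx_by_animal[[ids[j]]]
      tb <- secs[ib]
      dt <- abs(outer(ta, tb, "-"))
      cand <- which(dt <= tol, arr.ind = TRUE)
      if (nrow(cand) == 0) next
      if (matching == "greedy_one_to_one") {
        ord <- order(dt[cand], ta[cand[, 1]], tb[cand[, 2]])
        cand <- cand[ord, , drop = FALSE]
        used_a <- logical(length(ta)); used_b <- logical(length(tb))
        keep <- logical(nrow(cand))
        for (r in seq_len(nrow(cand))) {
          ai <- cand[r, 1]; bi <- cand[r, 2]
          if (!used_a[ai] && !used_b[bi]) {
            used_a[ai] <- TRUE; used_b[bi] <- TRUE; keep[r] <- TRUE
          }
        }
        cand <- cand[keep, , drop = FALSE]
      }
      ra <- ia[cand[, 1]]; rb <- ib[cand[, 2]]
      k <- k + 1L
      res[[k]] <- tibble(
        animal_a = ids[i], animal_b = ids[j],
        time_a = ds$timestamp[ra], time_b = ds$timestamp[rb],
        dt_mins = abs(secs[ra] - secs[rb]) / 60,
        distance_m = pairwise_distance(xy[ra, , drop = FALSE],
                                       xy[rb, , drop = FALSE], mode)
      )
    }
  }
  if (k == 0L) {
    return(tibble(animal_a = character(), animal_b = character(),
                  time_a = as.POSIXct(character(), tz = "UTC"),
                  time_b = as.POSIXct(character(), tz = "UTC"),
                  dt_mins = double(), distance_m = double()))
  }
  bind_rows(res[seq_len(k)])
}

#' Dyadic association counts and modified Simple Ratio Index
#'
#' For each dyad, `x_ab` counts joint observations within the spatial
#' threshold `s` (the two animals associating) and `y_ab` those outside it
#' (both observed, not associating). The association index is
#' `sri = x_ab / (x_ab + y_ab)`: 0 when the pair was never observed
#' together, 1 when always. Dyads with no joint observations do not appear.
#'
#' @param joint_obs Output of [find_joint_observations()].
#' @param s Spatial threshold in metres (> 0).
#' @return A tibble `animal_a`, `animal_b`, `x_ab`, `y_ab`, `sri`.
#' @export
compute_associations <- function(joint_obs, s) {
  stopifnot(s > 0)
  joint_obs |>
    group_by(.data$animal_a, .data$animal_b) |>
    summarise(
      x_ab = sum(.data$distance_m <= s),
      y_ab = sum(.data$distance_m > s),
      .groups = "drop"
    ) |>
    mutate(sri = .data$x_ab / (.data$x_ab + .data$y_ab))
}

#' Build a weighted association network
#'
#' Nodes are all animals in the dataset (isolated animals are retained, so
#' the network order equals the number of animals tagged); an edge joins a
#' dyad iff its association index is positive, with edge weight `sri`.
#'
#' @param x A `telemetry` tibble, or an association table as returned by
#'   [compute_associations()] (then `animals` should list all node ids).
#' @param s,t Spatial (metres) and temporal (minutes) thresholds. The
#'   defaults, 15 m and 7 min, suit coarse ungulate telemetry with
#'   minute-scale fix-schedule jitter; a 10 m spatial threshold is a common
#'   alternative for denser sampling. Ignored when `x` is already an
#'   association table (except `s` is unused there too).
#' @param animals Optional character vector of node ids (required to keep
#'   isolates when `x` is an association table).
#' @param matching Passed to [find_joint_observations()].
#' @return An `igraph` undirected weighted graph; edge attributes `weight`
#'   (the SRI), `x_ab`, `y_ab`.
#' @export
build_network <- function(x, s = 15, t = 7, animals = NULL,
                          matching = "greedy_one_to_one") {
  if (inherits(x, "telemetry") ||
      (is.data.frame(x) && all(c("animal_id", "timestamp") %in% names(x)))) {
    animals <- sort(unique(x$animal_id))
    assoc <- compute_associations(find_joint_observations(x, t, matching), s)
  } else {
    assoc <- x
    if (is.null(animals)) animals <- sort(unique(c(assoc$animal_a, assoc$animal_b)))
  }
  if (length(animals) < 2) {
    warn("Network has fewer than 2 nodes.")
  }
  edges <- assoc[assoc$sri > 0, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = edges$animal_a, to = edges$animal_b,
                   weight = edges$sri, x_ab = edges$x_ab, y_ab = edges$y_ab),
    directed = FALSE,
    vertices = data.frame(name = animals)
  )
  g
}

#' Suggest a spatial threshold from the inter-individual distance distribution
#'
#' Histograms the joint-observation distances (up to `max_distance`) and
#' returns the centre of the first local-maximum bin — the first bin whose
#' count exceeds both neighbours (the leading bin qualifies if it exceeds
#' its right neighbour). The first mode of the inter-individual distance
#' distribution is a common heuristic for the distance at which socially
#' associating pairs sit.
#'
#' @param ds A `telemetry` tibble with at least two animals.
#' @param t Temporal threshold in minutes.
#' @param max_distance Histogram range in metres.
#' @param bin_width Histogram bin width in metres.
#' @return Suggested spatial threshold in metres (a bin centre).
#' @export
suggest_spatial_threshold <- function(ds, t = 7, max_distance = 1000, bin_width = 5) {
  jo <- find_joint_observations(ds, t)
  d <- jo$distance_m[jo$distance_m <= max_distance]
  if (length(d) == 0) {
    abort("No joint observations within max_distance; threshold undefined.",
          class = "telesna_threshold_error")
  }
  breaks <- seq(0, max_distance + bin_width, by = bin_width)
  counts <- tabulate(findInterval(d, breaks, rightmost.closed = TRUE),
                     nbins = length(breaks) - 1L)
  centres <- breaks[-length(breaks)] + bin_width / 2
  padded <- c(-Inf, counts, -Inf)
  for (i in seq_along(counts)) {
    if (counts[i] > padded[i] && counts[i] > padded[i + 2L]) return(centres[i])
  }
  # monotone histogram: fall back to the global maximum bin
  centres[which.max(counts)]
}

#' Sensitivity sweep over spatial and temporal thresholds
#'
#' @param ds A `telemetry` tibble.
#' @param s_values,t_values Threshold grids (metres / minutes).
#' @param matching Passed to [find_joint_observations()].
#' @return A tibble `(s, t, n_edges, density, mean_strength)`, one row per
#'   combination. `n_edges` is non-decreasing in `s` at fixed `t`.
#' @export
sweep_thresholds <- function(ds, s_values, t_values, matching = "greedy_one_to_one") {
  stopifnot(length(s_values) > 0, length(t_values) > 0)
  animals <- sort(unique(ds$animal_id))
  purrr::map_dfr(t_values, function(t) {
    jo <- find_joint_observations(ds, t, matching)
    purrr::map_dfr(s_values, function(s) {
      g <- build_network(compute_associations(jo, s), animals = animals)
      gm <- global_metrics(g, c("density", "mean_strength"))
      tibble(s = s, t = t, n_edges = igraph::ecount(g),
             density = gm$value[gm$metric == "density"],
             mean_strength = gm$value[gm$metric == "mean_strength"])
    })
  })
}

#' Write / read association networks
#'
#' GraphML (edge attribute `weight` holding the SRI) and weighted edge-list
#' CSV (`from,to,x_ab,y_ab,weight`) with a companion node-list column for
#' isolates.
#'
#' @param g An `igraph` network.
#' @param path Output path.
#' @return `path` (writers, invisibly) or an `igraph` (readers).
#' @export
write_network_graphml <- function(g, path) {
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
read_network_graphml <- function(path) {
  igraph::read_graph(path, format = "graphml")
}

#' @rdname write_network_graphml
#' @export
write_network_edgelist <- function(g, path) {
  el <- igraph::as_data_frame(g, what = "edges")
  nodes <- igraph::V(g)$name
  out <- tibble(
    from = c(el$from, nodes),
    to = c(el$to, rep(NA_character_, length(nodes))),
    x_ab = c(if ("x_ab" %in% names(el)) el$x_ab else rep(NA, nrow(el)),
             rep(NA, length(nodes))),
    y_ab = c(if ("y_ab" %in% names(el)) el$y_ab else rep(NA, nrow(el)),
             rep(NA, length(nodes))),
    weight = c(el$weight, rep(NA_real_, length(nodes)))
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
read_network_edgelist <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  nodes <- unique(c(df$from[is.na(df$to)], df$from[!is.na(df$to)], df$to[!is.na(df$to)]))
  edges <- df[!is.na(df$to), , drop = FALSE]
  igraph::graph_from_data_frame(
    data.frame(from = edges$from, to = edges$to, weight = edges$weight,
               x_ab = edges$x_ab, y_ab = edges$y_ab),
    directed = FALSE, vertices = data.frame(name = sort(nodes))
  )
}
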