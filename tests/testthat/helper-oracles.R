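# Independent oracles used by unit and acceptance tests. These deliberately
# avoid the package's own code paths (and igraph where they check igraph-backed
# metrics).

# Brute-force greedy one-to-one matcher for one dyad: repeatedly pick, from
# the remaining candidate fix pairs within the window, the one minimising
# (|dt|, time_a, time_b), and remove both fixes. Recomputes the minimum from
# scratch at every step (no sorting shared with the implementation).
oracle_match_dyad <- function(times_a, times_b, tol_secs) {
  cand <- expand.grid(i = seq_along(times_a), j = seq_along(times_b))
  cand$dt <- abs(times_a[cand$i] - times_b[cand$j])
  cand <- cand[cand$dt <= tol_secs, , drop = FALSE]
  out <- list()
  while (nrow(cand) > 0) {
    ord <- order(cand$dt, times_a[cand$i], times_b[cand$j])
    best <- cand[ord[1], ]
    out[[length(out) + 1]] <- best
    cand <- cand[cand$i != best$i & cand$j != best$j, , drop = FALSE]
  }
  if (length(out) == 0) {
    return(data.frame(i = integer(), j = integer(), dt = numeric()))
  }
  do.call(rbind, out)
}

# Brute-force association table from a projected-coordinate telemetry tibble.
oracle_associations <- function(ds, s, t) {
  ids <- sort(unique(ds$animal_id))
  secs <- as.numeric(ds$timestamp)
  rows <- list()
  for (i in seq_len(length(ids) - 1)) {
    for (j in seq.int(i + 1, length(ids))) {
      ia <- which(ds$animal_id == ids[i])
      ib <- which(ds$animal_id == ids[j])
      m <- oracle_match_dyad(secs[ia], secs[ib], t * 60)
      if (nrow(m) == 0) next
      d <- sqrt((ds$x[ia[m$i]] - ds$x[ib[m$j]])^2 +
                  (ds$y[ia[m$i]] - ds$y[ib[m$j]])^2)
      rows[[length(rows) + 1]] <- data.frame(
        animal_a = ids[i], animal_b = ids[j],
        x_ab = sum(d <= s), y_ab = sum(d > s))
    }
  }
  if (length(rows) == 0) {
    return(data.frame(animal_a = character(), animal_b = character(),
                      x_ab = integer(), y_ab = integer()))
  }
  do.call(rbind, rows)
}

# Graph-metric oracle from a binary adjacency matrix, via matrix powers:
# d(s,t) = min k with (A^k)[s,t] > 0; shortest-path counts sigma_st =
# (A^d)[s,t]; betweenness from the path-count factorisation through v.
oracle_graph_stats <- function(A) {
  n <- nrow(A)
  pw <- vector("list", n + 1)
  pw[[1]] <- diag(n); pw[[2]] <- A
  for (k in 2:n) pw[[k + 1]] <- pw[[k]] %*% A
  D <- matrix(Inf, n, n); diag(D) <- 0
  for (k in 1:n) D[pw[[k + 1]] > 0 & is.infinite(D)] <- k
  deg <- rowSums(A)
  tri <- sum(diag(pw[[4]])) / 6
  triples <- sum(deg * (deg - 1) / 2)
  btw <- numeric(n)
  if (n >= 3) {
    for (s in 1:(n - 1)) for (t2 in (s + 1):n) {
      d <- D[s, t2]
      if (!is.finite(d) || d < 2) next
      sig <- pw[[d + 1]][s, t2]
      for (v in seq_len(n)) {
        if (v == s || v == t2) next
        d1 <- D[s, v]; d2 <- D[v, t2]
        if (is.finite(d1) && is.finite(d2) && d1 + d2 == d) {
          btw[v] <- btw[v] + pw[[d1 + 1]][s, v] * pw[[d2 + 1]][v, t2] / sig
        }
      }
    }
  }
  finite_d <- D[is.finite(D)]
  list(
    density = if (n > 1) sum(A) / (n * (n - 1)) else 0,
    transitivity = if (triples > 0) 3 * tri / triples else NA_real_,
    diameter = if (length(finite_d) > 0) max(finite_d) else 0,
    betweenness = btw
  )
}

# Small projected-coordinate telemetry tibble from vectors.
make_ds <- function(animal_id, mins, x, y, day_timezone = "UTC") {
  as_telemetry(
    data.frame(animal_id = animal_id,
               timestamp = as.POSIXct("2022-03-01 00:00:00", tz = "UTC") + mins * 60,
               x = x, y = y),
    coordinate_mode = "projected", day_timezone = day_timezone)
}

# Random small telemetry dataset on a coarse space-time grid.
random_grid_ds <- function(n_animals, max_fixes, seed) {
  set.seed(seed)
  rows <- do.call(rbind, lapply(seq_len(n_animals), function(i) {
    k <- sample.int(max_fixes, 1)
    data.frame(animal_id = LETTERS[i],
               mins = sort(sample(seq(0, 115, by = 5), k)),
               x = sample(seq(0, 100, by = 10), k, replace = TRUE),
               y = sample(seq(0, 100, by = 10), k, replace = TRUE))
  }))
  make_ds(rows$animal_id, rows$mins, rows$x, rows$y)
}

# igraph from a 6-node adjacency code (bit b of `code` switches edge b on).
graph_from_code <- function(code, pairs, n = 6) {
  bits <- as.integer(intToBits(code))[seq_len(nrow(pairs))]
  A <- matrix(0, n, n)
  on <- pairs[bits == 1, , drop = FALSE]
  A[on] <- 1
  A <- A + t(A)
  list(A = A,
       g = igraph::graph_from_adjacency_matrix(A, mode = "undirected"))
}
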