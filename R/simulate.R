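#' Simulate a telemetry stream with planted social groups
#'
#' Generates multi-individual GPS relocation streams with known social
#' structure so every protocol stage can be validated against planted
#' truth. Each group has a daily-continuing centroid random walk; on each
#' day, each group member either attends its group (probability
#' `sociality`) — performing a correlated random walk pulled toward the
#' centroid with strength `cohesion` — or walks independently around its
#' own home-range centre. Fixes are emitted on a regular schedule with
#' small Gaussian schedule jitter (emulating signal-reception delay) and
#' Gaussian GPS positional noise. Projected coordinates (metres).
#'
#' With `cohesion = 0` the centroid pull vanishes and all individuals walk
#' independently from their home-range centres (a null construction).
#' Groups whose centres are separated by much more than `step_sd` produce
#' networks whose components match the planted groups.
#'
#' @param n_individuals Number of animals (default 15).
#' @param n_groups Number of planted groups (default 3); animals are
#'   assigned round-robin unless `group_assignment` is given.
#' @param group_assignment Optional integer vector (length
#'   `n_individuals`) of group ids in `1:n_groups`.
#' @param duration_days Study duration in days (default 30).
#' @param fix_interval_minutes Fix schedule interval (default 120, the
#'   every-2-h schedule typical of ungulate collar deployments).
#' @param start_date First calendar day (default `"2022-01-01"`).
#' @param group_spacing Distance between neighbouring group centres in
#'   metres (default 10000 — far enough that between-group proximity is
#'   essentially impossible).
#' @param home_range_sd Spread of individual home-range centres around the
#'   group centre, metres (default 200).
#' @param step_sd Random-walk step scale per fix, metres (default 25).
#' @param cohesion Pull toward the group centroid per step, in `[0, 1]`
#'   (default 0.9).
#' @param sociality Probability a member attends its group on a given day
#'   (default 0.9).
#' @param gps_noise_sd GPS positional noise, metres (default 10).
#' @param schedule_jitter_sd Fix-time jitter, seconds (default 20).
#' @param day_timezone Timezone for day segmentation (default `"UTC"`).
#' @param seed Integer seed; the simulation is deterministic given it.
#' @return A list: `telemetry` (a `telemetry` tibble) and `truth` (tibble
#'   `animal_id`, `group` — the planted assignment; within-group dyads are
#'   the dyads expected to associate).
#' @export
simulate_population <- function(n_individuals = 15, n_groups = 3,
                                group_assignment = NULL,
                                duration_days = 30,
                                fix_interval_minutes = 120,
                                start_date = "2022-01-01",
                                group_spacing = 10000,
                                home_range_sd = 200,
                                step_sd = 25,
                                cohesion = 0.9,
                                sociality = 0.9,
                                gps_noise_sd = 10,
                                schedule_jitter_sd = 20,
                                day_timezone = "UTC",
                                seed = 1) {
  stopifnot(n_groups <= n_individuals, cohesion >= 0, cohesion <= 1,
            sociality >= 0, sociality <= 1,
            duration_days >= 1, fix_interval_minutes > 0, step_sd > 0)
  set.seed(seed)
  if (is.null(group_assignment)) {
    group_assignment <- rep(seq_len(n_groups), length.out = n_individuals)
  }
  stopifnot(length(group_assignment) == n_individuals)

  ids <- sprintf("A%02d", seq_len(n_individuals))
  fixes_per_day <- floor(24 * 60 / fix_interval_minutes)
  n_fix <- duration_days * fixes_per_day
  t0 <- as.POSIXct(paste(start_date, "00:00:00"), tz = day_timezone)
  sched <- as.numeric(t0) +
    rep((seq_len(duration_days) - 1) * 86400, each = fixes_per_day) +
    rep((seq_len(fixes_per_day) - 1) * fix_interval_minutes * 60, duration_days)

  # group centres on a line; centroid paths continue across days so that
  # different days occupy different places (datastream permutation then
  # genuinely decouples contacts)
  centres <- cbind((seq_len(n_groups) - 1) * group_spacing, 0)
  centroid <- lapply(seq_len(n_groups), function(gp) {
    steps <- matrix(rnorm(2 * n_fix, sd = 2 * step_sd), ncol = 2)
    sweep(apply(steps, 2, cumsum), 2, centres[gp, ], "+")
  })

  home <- centres[group_assignment, , drop = FALSE] +
    matrix(rnorm(2 * n_individuals, sd = home_range_sd), ncol = 2)

  rows <- vector("list", n_individuals)
  for (i in seq_len(n_individuals)) {
    cpath <- centroid[[group_assignment[i]]]
    pos <- matrix(NA_real_, n_fix, 2)
    attend_day <- runif(duration_days) < sociality
    for (d in seq_len(duration_days)) {
      k0 <- (d - 1) * fixes_per_day
      att <- attend_day[d]
      target0 <- if (att) cpath[k0 + 1, ] else home[i, ]
      p <- home[i, ] + cohesion * (target0 - home[i, ]) + rnorm(2, sd = step_sd)
      pos[k0 + 1, ] <- p
      if (fixes_per_day > 1) {
        for (k in seq.int(2, fixes_per_day)) {
          target <- if (att) cpath[k0 + k, ] else home[i, ]
          p <- p + cohesion * (target - p) + rnorm(2, sd = step_sd)
          pos[k0 + k, ] <- p
        }
      }
    }
    obs <- pos + matrix(rnorm(2 * n_fix, sd = gps_noise_sd), ncol = 2)
    ts <- sched + rnorm(n_fix, sd = schedule_jitter_sd)
    rows[[i]] <- tibble(animal_id = ids[i],
                        timestamp = as.POSIXct(ts, origin = "1970-01-01", tz = "UTC"),
                        x = obs[, 1], y = obs[, 2])
  }
  ds <- as_telemetry(bind_rows(rows), coordinate_mode = "projected",
                     day_timezone = day_timezone)
  list(telemetry = ds,
       truth = tibble(animal_id = ids, group = group_assignment))
}

#' Random weighted network fixture
#'
#' An Erdős–Rényi `G(n, p)` graph with i.i.d. edge weights — the plain
#' fixture used by the resampling and bootstrap property checks.
#'
#' @param n Number of nodes.
#' @param p Edge probability in `[0, 1]`.
#' @param weight_dist `"uniform01"` (weights `U(0, 1)`) or `"constant"`.
#' @param w Weight value when `weight_dist = "constant"` (default 1).
#' @param seed Optional integer seed.
#' @return An `igraph` undirected weighted graph with named nodes.
#' @export
random_weighted_network <- function(n, p, weight_dist = c("uniform01", "constant"),
                                    w = 1, seed = NULL) {
  weight_dist <- match.arg(weight_dist)
  stopifnot(n >= 1, p >= 0, p <= 1)
  if (!is.null(seed)) set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("N%03d", seq_len(n))
  m <- igraph::ecount(g)
  igraph::E(g)$weight <- if (weight_dist == "uniform01") runif(m) else rep(w, m)
  g
}
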