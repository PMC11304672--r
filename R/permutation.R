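#' Datastream permutation of daily tracks
#'
#' The pre-network null model for autocorrelated telemetry: each
#' individual's track is segmented into calendar days (in the dataset's
#' `day_timezone`), and the dates on which those daily tracks were walked
#' are shuffled uniformly within that individual's own observed date set.
#' Each fix keeps its time of day and coordinates, so every individual's
#' home range, fix count, and within-day movement autocorrelation are
#' exactly preserved — but whom it could have met is randomised.
#'
#' Uses the current R random number generator state; call [set.seed()]
#' first for reproducibility.
#'
#' @param ds A `telemetry` tibble.
#' @return A `telemetry` tibble with permuted timestamps.
#' @export
permute_datastream <- function(ds) {
  day_tz <- day_timezone_of(ds)
  day <- as.Date(format(ds$timestamp, tz = day_tz, format = "%Y-%m-%d"))
  udays <- sort(unique(day))
  day_start <- as.POSIXct(paste0(as.character(udays), " 00:00:00"), tz = day_tz)
  start_of <- setNames(as.numeric(day_start), as.character(udays))

  day_chr <- as.character(day)
  new_secs <- as.numeric(ds$timestamp)
  for (id in unique(ds$animal_id)) {
    rows <- which(ds$animal_id == id)
    own_days <- unique(day_chr[rows])
    if (length(own_days) < 2) next
    perm <- setNames(sample(own_days), own_days)
    shift <- start_of[perm[day_chr[rows]]] - start_of[day_chr[rows]]
    new_secs[rows] <- new_secs[rows] + shift
  }
  out <- as_tibble(ds)
  out$timestamp <- as.POSIXct(new_secs, origin = "1970-01-01", tz = "UTC")
  out <- arrange(out, .data$animal_id, .data$timestamp)
  structure(out,
            coordinate_mode = coordinate_mode_of(ds),
            day_timezone = day_tz,
            class = c("telemetry", class(as_tibble(out))))
}

#' Null distributions of global metrics from datastream permutations
#'
#' Step 1 of the protocol: builds `n_perm` permuted datastreams with
#' [permute_datastream()], constructs the association network for each, and
#' records the requested global metrics, giving a null distribution against
#' which the observed values are positioned. Empirical p-values use the
#' add-one permutation correction:
#' `p_upper = (1 + #[null >= observed]) / (n_valid + 1)` (and analogously
#' for `p_lower`); `p_two_sided = min(1, 2 min(p_upper, p_lower))`.
#' Permutations where a metric is undefined (`NA`) are excluded from the
#' p-value counts and tallied.
#'
#' @param ds A `telemetry` tibble.
#' @param s,t Spatial / temporal thresholds (see [build_network()]).
#' @param metrics Global metrics to test (default the four the protocol
#'   routinely screens: density, mean strength, transitivity, diameter).
#' @param n_perm Number of permutations (>= 1; 1000 in routine use).
#' @param seed Optional integer master seed; per-permutation child seeds
#'   are derived from it deterministically.
#' @return An object of class `sna_permtest`; see [tidy.sna_permtest()],
#'   [glance.sna_permtest()], [autoplot.sna_permtest()].
#' @export
null_distribution <- function(ds, s = 15, t = 7,
                              metrics = c("density", "mean_strength",
                                          "transitivity", "diameter"),
                              n_perm = 1000, seed = NULL) {
  stopifnot(n_perm >= 1)
  if (!is.null(seed)) set.seed(seed)
  child_seeds <- sample.int(.Machine$integer.max, n_perm)

  g_obs <- build_network(ds, s = s, t = t)
  observed <- global_metric_values(g_obs, metrics)

  null_tbl <- purrr::map_dfr(seq_len(n_perm), function(i) {
    set.seed(child_seeds[i])
    gp <- build_network(permute_datastream(ds), s = s, t = t)
    tibble(perm = i, metric = metrics,
           value = unname(global_metric_values(gp, metrics)))
  })

  pvals <- purrr::map_dfr(metrics, function(m) {
    nv <- null_tbl$value[null_tbl$metric == m]
    n_na <- sum(is.na(nv))
    nv <- nv[!is.na(nv)]
    obs <- observed[[m]]
    if (length(nv) == 0 || is.na(obs)) {
      return(tibble(metric = m, observed = obs, null_mean = NA_real_,
                    null_q025 = NA_real_, null_q975 = NA_real_,
                    p_upper = NA_real_, p_lower = NA_real_,
                    p_two_sided = NA_real_, n_valid = length(nv), n_na = n_na))
    }
    p_up <- (1 + sum(nv >= obs)) / (length(nv) + 1)
    p_lo <- (1 + sum(nv <= obs)) / (length(nv) + 1)
    tibble(metric = m, observed = obs, null_mean = mean(nv),
           null_q025 = quantile(nv, 0.025, names = FALSE),
           null_q975 = quantile(nv, 0.975, names = FALSE),
           p_upper = p_up, p_lower = p_lo,
           p_two_sided = min(1, 2 * min(p_up, p_lo)),
           n_valid = length(nv), n_na = n_na)
  })
  if (sum(pvals$n_na) > 0) {
    inform(sprintf("%d permutation metric value(s) were NA and excluded from p-values.",
                   sum(pvals$n_na)))
  }
  structure(list(observed = observed, null = null_tbl, summary = pvals,
                 n_perm = n_perm, s = s, t = t),
            class = "sna_permtest")
}

#' @export
print.sna_permtest <- function(x, ...) {
  cat("Datastream permutation test (", x$n_perm, " permutations, s = ",
      x$s, " m, t = ", x$t, " min)\n\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Tidiers for datastream permutation tests
#'
#' `tidy()` returns the per-permutation null metric values; `glance()`
#' returns one row per metric with the observed value, null summary and
#' permutation p-values.
#'
#' @param x An `sna_permtest` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy sna_permtest
#' @export
tidy.sna_permtest <- function(x, ...) x$null

#' @rdname tidy.sna_permtest
#' @method glance sna_permtest
#' @export
glance.sna_permtest <- function(x, ...) x$summary

#' Histogram panel of permutation null distributions
#'
#' One facet per metric: the null histogram with the observed value marked
#' as a red vertical line.
#'
#' @param object An `sna_permtest` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sna_permtest
#' @export
autoplot.sna_permtest <- function(object, ...) {
  obs <- tibble(metric = names(object$observed),
                observed = unname(object$observed))
  ggplot2::ggplot(object$null, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey65", colour = "grey30") +
    ggplot2::geom_vline(data = obs,
                        ggplot2::aes(xintercept = .data$observed),
                        colour = "red", linewidth = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = "metric value under the null", y = "permutations",
                  title = "Datastream permutation null distributions")
}
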