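#' Correlation of node metrics between partial and full networks
#'
#' Step 4 of the protocol: at each sampling level, nodes are subsampled
#' without replacement, node metrics are computed on the induced partial
#' network, and correlated against the *same nodes'* values in the full
#' observed network. Repeated `n_rep` times per level; the mean and
#' standard deviation of the correlation coefficients are reported, along
#' with a stability flag (`mean_r > 0.7`), a common rule of thumb for a
#' node metric stable enough to carry into downstream analyses.
#'
#' Repeats with a constant metric vector (zero variance) have an undefined
#' correlation; they are recorded as `NA` and excluded from the mean/sd
#' with a tally. `NA` metric values (e.g. clustering for degree < 2) are
#' handled by pairwise-complete deletion.
#'
#' @param g An `igraph` network.
#' @param levels Sampling proportions (default `c(0.1, 0.3, 0.5, 0.7, 0.9)`).
#'   Each must yield at least 3 nodes.
#' @param metrics Node metrics (see [node_metrics()]).
#' @param n_rep Repeats per level (default 10).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param seed Optional integer seed.
#' @return An `sna_stability` object; `tidy()` gives per-repeat
#'   correlations, `glance()` the per-(metric, level) summary.
#' @export
node_metric_correlation <- function(g, levels = c(0.1, 0.3, 0.5, 0.7, 0.9),
                                    metrics = NODE_METRICS, n_rep = 10,
                                    method = c("pearson", "spearman"),
                                    seed = NULL) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  n <- igraph::vcount(g)
  ms <- sapply(levels, function(lv) max(1L, round(lv * n)))
  if (any(ms < 3)) {
    abort("Every sampling level must yield at least 3 nodes for a defined correlation.",
          class = "telesna_config_error")
  }
  full <- node_metric_wide(g, metrics)
  per_rep <- purrr::map_dfr(seq_along(levels), function(k) {
    purrr::map_dfr(seq_len(n_rep), function(r) {
      sub <- subsample_network(g, ms[k])
      part <- node_metric_wide(sub, metrics)
      shared <- full[match(part$node, full$node), , drop = FALSE]
      purrr::map_dfr(metrics, function(m) {
        x <- part[[m]]; y <- shared[[m]]
        ok <- complete.cases(x, y)
        r_val <- if (sum(ok) >= 3 && sd(x[ok]) > 0 && sd(y[ok]) > 0) {
          cor(x[ok], y[ok], method = method)
        } else NA_real_
        tibble(metric = m, level = levels[k], m_nodes = ms[k], rep = r, r = r_val)
      })
    })
  })
  summary <- per_rep |>
    group_by(.data$metric, .data$level, .data$m_nodes) |>
    summarise(mean_r = mean(.data$r, na.rm = TRUE),
              sd_r = sd(.data$r, na.rm = TRUE),
              n_valid = sum(!is.na(.data$r)),
              n_na = sum(is.na(.data$r)),
              .groups = "drop") |>
    mutate(stable = .data$mean_r > 0.7)
  if (sum(summary$n_na) > 0) {
    inform(sprintf("%d repeat(s) had undefined correlations (constant metric vector) and were excluded.",
                   sum(summary$n_na)))
  }
  structure(list(per_rep = per_rep, summary = summary,
                 method = method, n_rep = n_rep),
            class = "sna_stability")
}

#' @export
print.sna_stability <- function(x, ...) {
  cat("Partial-vs-full node-metric correlation (", x$method, ", ",
      x$n_rep, " repeats/level)\n\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @rdname tidy.sna_permtest
#' @method tidy sna_stability
#' @export
tidy.sna_stability <- function(x, ...) x$per_rep

#' @rdname tidy.sna_permtest
#' @method glance sna_stability
#' @export
glance.sna_stability <- function(x, ...) x$summary

#' Ribbon plot of node-metric stability under subsampling
#'
#' Mean correlation (line) with a one-standard-deviation band per metric,
#' against the sampling level.
#'
#' @param object An `sna_stability` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sna_stability
#' @export
autoplot.sna_stability <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$level, y = .data$mean_r)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_r - .data$sd_r,
                                      ymax = .data$mean_r + .data$sd_r),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0.7, linetype = "dashed", colour = "grey40") +
    ggplot2::facet_wrap(~metric) +
    ggplot2::coord_cartesian(ylim = c(-0.1, 1)) +
    ggplot2::labs(x = "sampling level (proportion of nodes)",
                  y = "correlation with full network",
                  title = "Node-metric stability under subsampling")
}

#' Regression of subsampled node metrics on full-network values
#'
#' Ordinary least squares of the partial-network node metric (response) on
#' the full-network value (predictor) over the nodes present in the
#' subsample, per repeat, plus a pooled fit over all repeats. For degree
#' and strength the expected slope under uniform node removal is
#' `(m - 1) / (N - 1)`: each retained node keeps that fraction of its
#' neighbours in expectation.
#'
#' @param g An `igraph` network.
#' @param level A single sampling proportion (must yield >= 3 nodes).
#' @param metric A single node metric.
#' @param n_rep Repeats (default 10).
#' @param seed Optional integer seed.
#' @return A tibble `(metric, level, rep, slope, intercept, r_squared,
#'   n_points)`; the pooled fit has `rep = NA`.
#' @export
node_metric_regression <- function(g, level = 0.5, metric = "degree",
                                   n_rep = 10, seed = NULL) {
  stopifnot(length(level) == 1, length(metric) == 1)
  if (!is.null(seed)) set.seed(seed)
  n <- igraph::vcount(g)
  m <- max(1L, round(level * n))
  if (m < 3) {
    abort("Sampling level must yield at least 3 nodes.",
          class = "telesna_config_error")
  }
  full <- node_metric_wide(g, metric)
  fit_one <- function(x, y) {
    ok <- complete.cases(x, y)
    if (sum(ok) < 3 || sd(y[ok]) == 0) {
      return(c(slope = NA_real_, intercept = NA_real_,
               r_squared = NA_real_, n_points = sum(ok)))
    }
    fit <- lm(x[ok] ~ y[ok])
    # summary() warns on exact fits (level 1 gives the identity); that case is fine
    r2 <- suppressWarnings(unname(summary(fit)$r.squared))
    c(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
      r_squared = r2, n_points = sum(ok))
  }
  pooled_x <- numeric(0); pooled_y <- numeric(0)
  rows <- purrr::map_dfr(seq_len(n_rep), function(r) {
    sub <- subsample_network(g, m)
    part <- node_metric_wide(sub, metric)
    y <- full[[metric]][match(part$node, full$node)]
    x <- part[[metric]]
    pooled_x <<- c(pooled_x, x); pooled_y <<- c(pooled_y, y)
    est <- fit_one(x, y)
    tibble(metric = metric, level = level, rep = r,
           slope = est[["slope"]], intercept = est[["intercept"]],
           r_squared = est[["r_squared"]], n_points = est[["n_points"]])
  })
  est <- fit_one(pooled_x, pooled_y)
  bind_rows(rows, tibble(metric = metric, level = level, rep = NA_integer_,
                         slope = est[["slope"]], intercept = est[["intercept"]],
                         r_squared = est[["r_squared"]], n_points = est[["n_points"]]))
}
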