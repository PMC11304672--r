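#' Configuration for the five-step protocol
#'
#' Collects the tunable parameters of [run_protocol()] with the routine
#' defaults: 15 m / 7 min association thresholds, 1000 permutations, 100
#' subsamples per level at levels 10%–90%, 1000 bootstrap replicates, 95%
#' confidence, 10 outer repeats for CI-width curves, and 10 correlation
#' repeats at levels 10/30/50/70/90%.
#'
#' @param s,t Spatial (m) / temporal (min) association thresholds.
#' @param global_metrics,node_metrics Metric selections.
#' @param n_perm Datastream permutations (Step 1 and the permuted
#'   subsample comparison).
#' @param levels Subsampling levels for Step 2.
#' @param n_rep Subsamples per level (Step 2).
#' @param B Bootstrap replicates (Steps 3 and 5).
#' @param conf Confidence level.
#' @param ci_sizes Node counts for the CI-width curve (default: 5 sizes
#'   evenly spaced from ~20% of N to N).
#' @param n_outer Outer repeats per size for the CI-width curve.
#' @param split_trials Split-half calibration trials.
#' @param corr_levels,corr_n_rep,corr_method Step 4 settings.
#' @param matching Fix-matching rule (see [find_joint_observations()]).
#' @param dup_edge_rule Bootstrap duplicate-copy edge rule
#'   (see [bootstrap_network()]).
#' @param make_plots Write figure files (PNG) alongside the CSVs.
#' @return A named list of class `protocol_config`.
#' @export
protocol_config <- function(s = 15, t = 7,
                            global_metrics = c("density", "mean_strength",
                                               "transitivity", "diameter"),
                            node_metrics = c("degree", "strength", "betweenness",
                                             "eigenvector", "clustering"),
                            n_perm = 1000,
                            levels = seq(0.1, 0.9, by = 0.1),
                            n_rep = 100,
                            B = 1000,
                            conf = 0.95,
                            ci_sizes = NULL,
                            n_outer = 10,
                            split_trials = 50,
                            corr_levels = c(0.1, 0.3, 0.5, 0.7, 0.9),
                            corr_n_rep = 10,
                            corr_method = "pearson",
                            matching = "greedy_one_to_one",
                            dup_edge_rule = "always_draw",
                            make_plots = FALSE) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_perm >= 1, cfg$n_rep >= 1, cfg$B >= 2, cfg$n_outer >= 1,
            all(cfg$levels > 0), all(cfg$levels <= 1),
            all(cfg$corr_levels > 0), all(cfg$corr_levels <= 1))
  structure(cfg, class = "protocol_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("Protocol stage '", name, "' failed: ", conditionMessage(e)),
          class = "telesna_stage_error")
  })
}

#' Run the five-step robustness protocol end to end
#'
#' Executes, in order: (1) datastream-permutation null models, (2) node
#' subsampling of the observed and permuted networks, (3) bootstrap
#' confidence intervals for global metrics with the CI-width-vs-size curve
#' and split-half calibration, (4) partial-vs-full node-metric correlation
#' and regression, and (5) node-level bootstrap confidence intervals. All
#' results are written as tidy CSVs (plus optional figures) under
#' `output_dir`, with a machine-readable JSON manifest recording the
#' configuration, seed and steps executed.
#'
#' Step 1 (and the permuted half of Step 2) requires raw relocations and is
#' skipped automatically when `input` is a prebuilt network — the path for
#' observational association data, where the spatio-temporal thresholding
#' that the permutation null model probes never happened. Steps 4–5 do not
#' depend on the earlier steps.
#'
#' @param input A `telemetry` tibble or a prebuilt weighted `igraph`
#'   network.
#' @param config A [protocol_config()] list.
#' @param output_dir Output directory (created if needed).
#' @param seed Integer master seed; every stage derives its own child seed
#'   from it, so identical `input` + `config` + `seed` reproduce all CSVs
#'   byte for byte.
#' @return Invisibly, a list with the per-step result objects and the
#'   manifest.
#' @export
run_protocol <- function(input, config = protocol_config(), output_dir,
                         seed = 1) {
  stopifnot(inherits(config, "protocol_config"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  stage_seeds <- sample.int(.Machine$integer.max, 8)
  is_telemetry <- inherits(input, "telemetry") ||
    (is.data.frame(input) && all(c("animal_id", "timestamp") %in% names(input)))
  out <- list()
  steps <- character(0)
  p <- function(f) file.path(output_dir, f)

  g <- run_stage("network", {
    if (is_telemetry) build_network(input, s = config$s, t = config$t,
                                    matching = config$matching)
    else input
  })
  write_network_graphml(g, p("network.graphml"))
  write_network_edgelist(g, p("network_edgelist.csv"))
  readr::write_csv(global_metrics(g, GLOBAL_METRICS), p("global_metrics.csv"),
                   progress = FALSE)
  readr::write_csv(node_metrics(g, config$node_metrics), p("node_metrics.csv"),
                   progress = FALSE)
  out$network <- g
  n <- igraph::vcount(g)

  if (is_telemetry) {
    out$step1 <- run_stage("step1_permutation", {
      null_distribution(input, s = config$s, t = config$t,
                        metrics = config$global_metrics,
                        n_perm = config$n_perm, seed = stage_seeds[1])
    })
    readr::write_csv(tidy(out$step1), p("step1_null_distribution.csv"),
                     progress = FALSE)
    readr::write_csv(glance(out$step1), p("step1_summary.csv"), progress = FALSE)
    steps <- c(steps, "step1:executed")
  } else {
    steps <- c(steps, "step1:skipped (prebuilt network input)")
  }

  out$step2 <- run_stage("step2_subsampling", {
    subsample_distribution(g, levels = config$levels, n_rep = config$n_rep,
                           metrics = config$global_metrics,
                           seed = stage_seeds[2])
  })
  readr::write_csv(tidy(out$step2), p("step2_subsample_values.csv"),
                   progress = FALSE)
  readr::write_csv(glance(out$step2), p("step2_subsample_summary.csv"),
                   progress = FALSE)
  if (is_telemetry) {
    out$step2_permuted <- run_stage("step2_permuted_comparison", {
      permuted_subsample_comparison(input, s = config$s, t = config$t,
                                    levels = config$levels,
                                    n_perm = config$n_perm, n_rep = config$n_rep,
                                    metrics = config$global_metrics,
                                    seed = stage_seeds[3])
    })
    readr::write_csv(as_tibble(out$step2_permuted),
                     p("step2_permuted_comparison.csv"), progress = FALSE)
  }
  steps <- c(steps, "step2:executed")

  out$step3_ci <- run_stage("step3_bootstrap_ci", {
    suppressWarnings(bootstrap_global_ci(g, B = config$B,
                                         metrics = config$global_metrics,
                                         conf = config$conf,
                                         dup_edge_rule = config$dup_edge_rule,
                                         seed = stage_seeds[4]))
  })
  readr::write_csv(glance(out$step3_ci), p("step3_global_ci.csv"), progress = FALSE)
  ci_sizes <- config$ci_sizes %||% unique(pmax(4L, round(seq(0.2, 1, 0.2) * n)))
  out$step3_width <- run_stage("step3_ci_width", {
    suppressMessages(ci_width_vs_samplesize(g, sizes = ci_sizes, B = config$B,
                                            metrics = config$global_metrics,
                                            n_outer = config$n_outer,
                                            conf = config$conf,
                                            seed = stage_seeds[5]))
  })
  readr::write_csv(as_tibble(out$step3_width), p("step3_ci_width.csv"),
                   progress = FALSE)
  out$step3_splithalf <- run_stage("step3_splithalf", {
    split_half_calibration(g, B = config$B, metric = config$global_metrics[1],
                           n_trials = config$split_trials, conf = config$conf,
                           seed = stage_seeds[6])
  })
  readr::write_csv(out$step3_splithalf$results, p("step3_splithalf.csv"),
                   progress = FALSE)
  steps <- c(steps, "step3:executed")

  out$step4 <- run_stage("step4_correlation", {
    node_metric_correlation(g, levels = config$corr_levels,
                            metrics = config$node_metrics,
                            n_rep = config$corr_n_rep,
                            method = config$corr_method,
                            seed = stage_seeds[7])
  })
  readr::write_csv(tidy(out$step4), p("step4_correlation.csv"), progress = FALSE)
  readr::write_csv(glance(out$step4), p("step4_correlation_summary.csv"),
                   progress = FALSE)
  out$step4_regression <- run_stage("step4_regression", {
    purrr::map_dfr(intersect(config$node_metrics, c("degree", "strength")),
                   function(m) {
                     node_metric_regression(g, level = 0.5, metric = m,
                                            n_rep = config$corr_n_rep,
                                            seed = stage_seeds[7])
                   })
  })
  readr::write_csv(out$step4_regression, p("step4_regression.csv"),
                   progress = FALSE)
  steps <- c(steps, "step4:executed")

  out$step5 <- run_stage("step5_node_ci", {
    suppressWarnings(bootstrap_node_ci(g, B = config$B,
                                       metrics = config$node_metrics,
                                       conf = config$conf,
                                       dup_edge_rule = config$dup_edge_rule,
                                       seed = stage_seeds[8]))
  })
  readr::write_csv(tidy(out$step5), p("step5_node_ci.csv"), progress = FALSE)
  steps <- c(steps, "step5:executed")

  if (isTRUE(config$make_plots)) {
    run_stage("figures", {
      figdir <- p("figures")
      dir.create(figdir, showWarnings = FALSE)
      if (!is.null(out$step1)) {
        ggplot2::ggsave(file.path(figdir, "step1_null_distributions.png"),
                        autoplot(out$step1), width = 8, height = 6, dpi = 120)
      }
      ggplot2::ggsave(file.path(figdir, "step2_subsampling.png"),
                      autoplot(out$step2), width = 8, height = 6, dpi = 120)
      if (!is.null(out$step2_permuted)) {
        ggplot2::ggsave(file.path(figdir, "step2_permuted_comparison.png"),
                        autoplot(out$step2_permuted), width = 9, height = 6, dpi = 120)
      }
      ggplot2::ggsave(file.path(figdir, "step3_ci_width.png"),
                      autoplot(out$step3_width), width = 8, height = 6, dpi = 120)
      ggplot2::ggsave(file.path(figdir, "step4_stability.png"),
                      autoplot(out$step4), width = 8, height = 6, dpi = 120)
      ggplot2::ggsave(file.path(figdir, "step5_node_ci.png"),
                      autoplot(out$step5), width = 9, height = 7, dpi = 120)
    })
  }

  manifest <- list(
    package = "telesna",
    version = as.character(utils::packageVersion("telesna")),
    seed = seed,
    input = if (is_telemetry) "telemetry" else "prebuilt_network",
    n_nodes = n,
    n_edges = igraph::ecount(g),
    steps = steps,
    config = unclass(config)
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  out$manifest <- manifest
  invisible(out)
}
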