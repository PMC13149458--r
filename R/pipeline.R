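# End-to-end orchestration: simulate -> edge stats -> graph metrics ->
# node/global stats -> classification -> report tables, with a
# reproducibility manifest (config echo, seed, package version). Each
# stage can be toggled; outputs are plain CSV/JSON under the output
# directory. The numbered scripts under analysis/ are thin drivers over
# this function and the stage functions it calls.

#' Pipeline run configuration
#'
#' @param sim a [simulation_config()] describing the cohort to generate
#'   (or an existing [simulate_cohort()] result to reuse).
#' @param metrics connectivity metrics to analyze.
#' @param tfnbs a [tfnbs_config()] for edge-level inference.
#' @param alpha pre-correction significance level for the impact taxonomy.
#' @param models classifiers to run, subset of
#'   `c("SVM", "SVM64", "GCN", "GAT")`.
#' @param folds_k cross-validation folds.
#' @param gnn a [gnn_config()] (variant is overridden per model).
#' @param stages character subset of
#'   `c("edge_stats", "graph_metrics", "classify")`.
#' @param seed master seed, propagated to folds and classifiers.
#' @return list of class `"run_config"`.
#' @export
run_config <- function(sim = simulation_config(),
                       metrics = sim$metrics,
                       tfnbs = tfnbs_config(),
                       alpha = 0.05,
                       models = c("SVM", "SVM64", "GCN", "GAT"),
                       folds_k = 5,
                       gnn = gnn_config(),
                       stages = c("edge_stats", "graph_metrics", "classify"),
                       seed = 1L) {
  models <- match.arg(models, CLASSIFIER_MODELS, several.ok = TRUE)
  stages <- match.arg(stages, c("edge_stats", "graph_metrics", "classify"),
                      several.ok = TRUE)
  structure(list(sim = sim, metrics = metrics, tfnbs = tfnbs, alpha = alpha,
                 models = models, folds_k = folds_k, gnn = gnn,
                 stages = stages, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Generates (or reuses) a simulated cohort, then runs the enabled stages
#' over every (metric, filtering) slice: TFNBS edge inference with top
#' connection tables, node/global graph metrics with BY-corrected group
#' tests, the filtering-impact taxonomy, the effect-size (d / delta d)
#' summary, SIFT2-multiplier histograms, and cross-validated
#' classification. All tables are returned and, when `out_dir` is given,
#' written as CSV along with a JSON run manifest.
#'
#' @param cfg a [run_config()].
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @return list of result tables (invisible when writing to `out_dir`).
#' @export
run_pipeline <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  sim <- if (inherits(cfg$sim, "sim_cohort")) cfg$sim else {
    message("stage: simulate")
    simulate_cohort(cfg$sim)
  }
  co <- sim$cohort
  res <- list(manifest = co$manifest)

  if ("edge_stats" %in% cfg$stages) {
    message("stage: edge_stats")
    res$edge <- list(); res$top_connections <- list()
    for (metric in cfg$metrics) for (state in FILTER_STATES) {
      key <- paste(metric, state, sep = "_")
      inf <- tfnbs_fwe(co, metric, state, cfg$tfnbs)
      res$edge[[key]] <- inf
      for (hyp in HYPOTHESES) {
        res$top_connections[[paste(key, hyp, sep = "_")]] <-
          cbind(metric = metric, filtering = state, hypothesis = hyp,
                top_connections_table(inf, k = 10, hypothesis = hyp))
      }
    }
    res$top_connections <- do.call(rbind, res$top_connections)
    rownames(res$top_connections) <- NULL
  }

  if ("graph_metrics" %in% cfg$stages) {
    message("stage: graph_metrics")
    nodes <- list(); globals <- list()
    for (metric in cfg$metrics) for (state in FILTER_STATES) {
      gm <- compute_cohort_metrics(co, metric, state)
      nodes[[paste(metric, state)]] <- gm$nodes
      globals[[paste(metric, state)]] <- gm$globals
    }
    res$node_metrics <- do.call(rbind, nodes)
    res$global_metrics <- do.call(rbind, globals)
    rownames(res$node_metrics) <- rownames(res$global_metrics) <- NULL
    res$node_tests <- node_group_tests(res$node_metrics, co$manifest)
    glob <- global_group_tests(res$global_metrics, co$manifest)
    res$global_tests <- glob$tests
    res$effect_sizes <- glob$effect_sizes
    res$impact <- filtering_impact(
      res$node_tests[res$node_tests$filtering == "unfiltered", ],
      res$node_tests[res$node_tests$filtering == "filtered", ],
      alpha = cfg$alpha)
    res$significance <- lapply(stats::setNames(GRAPH_NODE_MEASURES,
                                               GRAPH_NODE_MEASURES),
                               function(m) significance_report(res$node_tests, m))
    res$sift2 <- sift2_weight_histograms(
      sim, n_subjects = min(20, 2 * min(table(co$manifest$group))),
      seed = cfg$seed)
  }

  if ("classify" %in% cfg$stages) {
    message("stage: classify")
    folds <- make_folds(co$manifest, k = cfg$folds_k, seed = cfg$seed)
    rows <- list()
    for (metric in cfg$metrics) for (state in FILTER_STATES) {
      for (model in cfg$models) {
        rows[[paste(metric, state, model)]] <- switch(
          model,
          SVM = train_eval_svm(co, metric, state, folds, use_pca64 = FALSE),
          SVM64 = train_eval_svm(co, metric, state, folds, use_pca64 = TRUE),
          GCN = {
            g <- cfg$gnn; g$variant <- "GCN"; g$seed <- cfg$seed
            train_eval_gnn(co, metric, state, folds, g)
          },
          GAT = {
            g <- cfg$gnn; g$variant <- "GAT"; g$seed <- cfg$seed
            train_eval_gnn(co, metric, state, folds, g)
          })
      }
    }
    res$classification_folds <- do.call(rbind, rows)
    rownames(res$classification_folds) <- NULL
    res$classification <- report_table(res$classification_folds)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wcsv <- function(df, name) {
      if (!is.null(df)) write.table(df, file.path(out_dir, name), sep = ",",
                                    row.names = FALSE, quote = TRUE)
    }
    wcsv(res$top_connections, "top_connections.csv")
    wcsv(res$node_tests, "node_tests.csv")
    wcsv(res$global_tests, "global_tests.csv")
    wcsv(res$effect_sizes, "effect_sizes.csv")
    wcsv(res$impact, "filtering_impact.csv")
    if (!is.null(res$significance)) {
      for (m in names(res$significance)) {
        wcsv(res$significance[[m]], sprintf("significance_%s.csv", m))
      }
    }
    if (!is.null(res$sift2)) wcsv(res$sift2$histogram, "sift2_histogram.csv")
    wcsv(res$classification_folds, "classification_folds.csv")
    wcsv(res$classification, "classification_summary.csv")
    manifest <- list(
      package_version = as.character(utils::packageVersion("filtconn")),
      r_version = R.version.string,
      seed = cfg$seed,
      stages = cfg$stages,
      metrics = cfg$metrics,
      n_hc = if (inherits(cfg$sim, "simulation_config")) cfg$sim$n_hc else NA,
      n_pd = if (inherits(cfg$sim, "simulation_config")) cfg$sim$n_pd else NA,
      tfnbs = unclass(cfg$tfnbs),
      timestamp = format(Sys.time(), tz = "UTC")
    )
    jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    return(invisible(res))
  }
  res
}
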