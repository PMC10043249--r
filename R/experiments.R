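#' Experiment settings for the sweep and comparison harness
#'
#' @param gen a [gen_config()] used when no explicit dataset is given.
#' @param dataset optional [plan_table()] or path to a plan CSV/JSON.
#' @param depths encoder depths for [run_depth_sweep()] (subset of 1..9).
#' @param lambdas composite-loss weights for [run_lambda_sweep()].
#' @param depth fixed depth used by the lambda sweep and the baseline
#'   comparison (6, the depth winning the depth sweep on this problem
#'   class).
#' @param repeats number of repeated trainings per configuration.
#' @param seeds explicit training seeds; when given, must have length
#'   `repeats`; defaults to `0:(repeats - 1)`.
#' @param ae named list of [ae_config()] overrides shared by all runs
#'   (e.g. `epochs`, `latent_dim`).
#' @param scale continuous-column scaling passed to [encode_table()].
#' @param objective grid-search objective for the baselines.
#' @param baseline_kinds which baseline detectors to compare.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(gen = gen_config(), dataset = NULL,
                              depths = 1:9,
                              lambdas = c(0.1, 0.5, 0.9, 0.99),
                              depth = 6L, repeats = 10L, seeds = NULL,
                              ae = list(), scale = "minmax",
                              objective = c("auc", "precision_at_tpr1"),
                              baseline_kinds = c("lof", "hdbscan",
                                                 "ocsvm", "pca")) {
  objective <- match.arg(objective)
  stopifnot(all(depths %in% 1:9), all(lambdas >= 0), depth %in% 1:9,
            repeats >= 1L)
  if (is.null(seeds)) {
    seeds <- seq_len(repeats) - 1L
  } else if (length(seeds) != repeats) {
    stop("when seeds are explicit, repeats must equal length(seeds)")
  }
  structure(
    list(gen = gen, dataset = dataset, depths = as.integer(depths),
         lambdas = lambdas, depth = as.integer(depth),
         repeats = as.integer(repeats), seeds = as.integer(seeds),
         ae = ae, scale = scale, objective = objective,
         baseline_kinds = baseline_kinds),
    class = "experiment_config")
}

resolve_dataset <- function(config) {
  ds <- config$dataset
  if (is.null(ds)) return(generate_dataset(config$gen)$table)
  if (inherits(ds, "plan_table")) return(ds)
  if (is_string(ds)) {
    return(load_plan_table(ds, protocol_schema(config$gen$protocol)))
  }
  stop("dataset must be NULL, a plan_table, or a file path")
}

run_single_ae <- function(encoded, depth, lambda, seed, ae_overrides) {
  args <- utils::modifyList(
    list(depth = depth, lambda_weight = lambda, seed = seed), ae_overrides)
  cfg <- do.call(ae_config, args)
  model <- build_autoencoder(cfg, encoded)
  fit <- ae_train(model, encoded, cfg)
  scores <- sample_errors(fit$model, encoded)
  ev <- evaluate_scores(scores, encoded$labels)
  list(scores = scores, ev = ev, fit = fit)
}

run_block <- function(encoded, grid, grid_name, fixed, config) {
  rows <- list()
  for (g in grid) {
    for (seed in config$seeds) {
      row <- tryCatch({
        depth <- if (grid_name == "depth") g else fixed$depth
        lambda <- if (grid_name == "lambda") g else fixed$lambda
        r <- run_single_ae(encoded, depth, lambda, seed, config$ae)
        m <- r$ev$metrics
        data.frame(value = g, seed = seed, auc = r$ev$auc,
                   accuracy = m$accuracy, precision = m$precision,
                   recall = m$recall, fpr = m$fpr, f1 = m$f1,
                   anomalies = m$anomalies, threshold = r$ev$threshold,
                   failed = FALSE)
      }, error = function(e) {
        warning(sprintf("run (%s=%s, seed=%d) failed: %s", grid_name,
                        format(g), seed, conditionMessage(e)))
        data.frame(value = g, seed = seed, auc = NA_real_,
                   accuracy = NA_real_, precision = NA_real_,
                   recall = NA_real_, fpr = NA_real_, f1 = NA_real_,
                   anomalies = NA_integer_, threshold = NA_real_,
                   failed = TRUE)
      })
      rows[[length(rows) + 1L]] <- row
    }
  }
  runs <- do.call(rbind, rows)
  names(runs)[1] <- grid_name
  runs
}

# Table 2 / Fig 4 style aggregation: mean and max of the benefit metrics,
# mean and min of FPR and flagged count; medians logged alongside.
aggregate_sweep <- function(runs, by) {
  agg <- lapply(split(runs, runs[[by]]), function(d) {
    ok <- d[!d$failed, , drop = FALSE]
    stat <- function(col, f) if (nrow(ok)) f(ok[[col]]) else NA_real_
    data.frame(
      value = d[[by]][1], runs = nrow(d), failed = sum(d$failed),
      auc_mean = stat("auc", mean), auc_max = stat("auc", max),
      auc_median = stat("auc", stats::median),
      accuracy_mean = stat("accuracy", mean),
      accuracy_max = stat("accuracy", max),
      precision_mean = stat("precision", mean),
      precision_max = stat("precision", max),
      precision_median = stat("precision", stats::median),
      precision_sd = if (nrow(ok) > 1) stats::sd(ok$precision) else NA_real_,
      f1_mean = stat("f1", mean), f1_max = stat("f1", max),
      fpr_mean = stat("fpr", mean), fpr_min = stat("fpr", min),
      anomalies_mean = stat("anomalies", mean),
      anomalies_min = stat("anomalies", min))
  })
  out <- do.call(rbind, agg)
  names(out)[1] <- by
  out <- out[order(match(out[[by]], unique(runs[[by]]))), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, runs = runs, class = c("sweep_table", "data.frame"))
}

#' Depth sweep
#'
#' Trains autoencoders at each encoder depth, `repeats` times each with
#' the configured seeds, on one fixed dataset, and aggregates the metric
#' suite per depth (mean and max; mean and min for FPR and flagged
#' count). The per-run log is attached as `attr(, "runs")`.
#'
#' @param config an [experiment_config()].
#' @return a `sweep_table` data.frame, one row per depth.
#' @export
run_depth_sweep <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  encoded <- encode_table(resolve_dataset(config), scale = config$scale)
  if (is.null(encoded$labels)) stop("the sweep harness needs labelled data")
  lambda <- config$ae$lambda_weight %||% 0.99
  runs <- run_block(encoded, config$depths, "depth",
                    list(lambda = lambda), config)
  aggregate_sweep(runs, "depth")
}

#' Lambda sweep
#'
#' Identical pipeline to [run_depth_sweep()] but varying only the
#' composite-loss weight at the fixed depth; the default grid is
#' `{0.1, 0.5, 0.9, 0.99}`. Per-lambda precision dispersion across the
#' repeated seeds is reported (`precision_sd`, `precision_median`).
#'
#' @param config an [experiment_config()].
#' @return a `sweep_table` data.frame, one row per lambda.
#' @export
run_lambda_sweep <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  encoded <- encode_table(resolve_dataset(config), scale = config$scale)
  if (is.null(encoded$labels)) stop("the sweep harness needs labelled data")
  runs <- run_block(encoded, config$lambdas, "lambda",
                    list(depth = config$depth), config)
  aggregate_sweep(runs, "lambda")
}

#' Baseline comparison
#'
#' Evaluates the autoencoder (fixed depth, averaged over the configured
#' seeds) against each baseline detector (grid-searched with
#' [default_grids()]) under the shared TPR==1 policy, one row per
#' detector. ROC overlay data for every detector is attached as
#' `attr(, "roc")`; a failed baseline is marked in its row without
#' affecting the others.
#'
#' @param config an [experiment_config()].
#' @return a `comparison_table` data.frame with columns detector, params,
#'   auc, accuracy, precision, recall, fpr, f1, anomalies, failed.
#' @export
run_baseline_comparison <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  encoded <- encode_table(resolve_dataset(config), scale = config$scale)
  if (is.null(encoded$labels)) stop("the comparison harness needs labelled data")
  labels <- encoded$labels
  lambda <- config$ae$lambda_weight %||% 0.99
  roc_data <- list()

  ae_runs <- run_block(encoded, config$depth, "depth",
                       list(lambda = lambda), config)
  ok <- ae_runs[!ae_runs$failed, , drop = FALSE]
  ae_row <- data.frame(
    detector = sprintf("autoencoder (depth = %d)", config$depth),
    params = sprintf("{\"depth\":%d,\"lambda\":%g,\"seeds\":%d}",
                     config$depth, lambda, nrow(ae_runs)),
    auc = mean(ok$auc), accuracy = mean(ok$accuracy),
    precision = mean(ok$precision), recall = mean(ok$recall),
    fpr = mean(ok$fpr), f1 = mean(ok$f1),
    anomalies = mean(ok$anomalies), failed = nrow(ok) == 0L,
    stringsAsFactors = FALSE)
  ae_scores <- run_single_ae(encoded, config$depth, lambda,
                             config$seeds[1], config$ae)$scores
  roc_data[["autoencoder"]] <- roc_and_auc(ae_scores, labels)$roc

  rows <- list(ae_row)
  for (kind in config$baseline_kinds) {
    row <- tryCatch({
      gr <- grid_search(default_grids(ncol(encoded$values), kinds = kind),
                        encoded, labels, objective = config$objective)
      best <- gr$results[gr$best_index, ]
      scores <- detector_scores(gr$best, encoded)
      roc_data[[kind]] <- roc_and_auc(scores, labels)$roc
      data.frame(detector = kind, params = best$params, auc = best$auc,
                 accuracy = best$accuracy, precision = best$precision,
                 recall = best$recall, fpr = best$fpr, f1 = best$f1,
                 anomalies = best$anomalies, failed = FALSE,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      warning(sprintf("baseline '%s' failed: %s", kind,
                      conditionMessage(e)))
      data.frame(detector = kind, params = NA_character_, auc = NA_real_,
                 accuracy = NA_real_, precision = NA_real_,
                 recall = NA_real_, fpr = NA_real_, f1 = NA_real_,
                 anomalies = NA_real_, failed = TRUE,
                 stringsAsFactors = FALSE)
    })
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, roc = roc_data, ae_runs = ae_runs,
            class = c("comparison_table", "data.frame"))
}

#' Write a sweep or comparison table as CSV + JSON
#'
#' @param table a `sweep_table` or `comparison_table`.
#' @param prefix output path prefix (writes `<prefix>.csv`,
#'   `<prefix>.json`, and per-run/ROC side files when present).
#' @return invisibly, the paths written.
#' @export
write_result_table <- function(table, prefix) {
  csv <- paste0(prefix, ".csv")
  json <- paste0(prefix, ".json")
  df <- as.data.frame(table)
  utils::write.csv(df, csv, row.names = FALSE)
  jsonlite::write_json(df, json, dataframe = "rows", digits = NA,
                       na = "null")
  paths <- c(csv, json)
  runs <- attr(table, "runs")
  if (!is.null(runs)) {
    p <- paste0(prefix, "_runs.csv")
    utils::write.csv(runs, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  roc <- attr(table, "roc")
  if (!is.null(roc)) {
    for (nm in names(roc)) {
      p <- paste0(prefix, "_roc_", nm, ".csv")
      utils::write.csv(roc[[nm]][, c("fpr", "tpr")], p, row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
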