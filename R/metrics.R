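#' TPR==1 threshold selection
#'
#' Radiation incidents are irreversible, so plan review requires that
#' every known abnormal plan is flagged. The policy threshold is the
#' largest value that still flags all labelled-abnormal plans, i.e. the
#' minimum abnormal score; under the `score >= threshold` convention this
#' guarantees recall 1 with the minimum achievable false-positive rate.
#'
#' @param scores numeric anomaly scores (higher = more anomalous).
#' @param labels ground-truth labels (see [plan_table()] encodings); at
#'   least one abnormal label is required.
#' @return the threshold (a single numeric).
#' @export
select_threshold_tpr1 <- function(scores, labels) {
  stopifnot(is.numeric(scores), length(scores) == length(labels))
  abn <- label_is_abnormal(labels)
  if (!any(abn)) {
    stop_planomaly("TPR==1 policy is undefined without abnormal labels",
                   "planomaly_policy_error")
  }
  min(scores[abn])
}

#' Quantile threshold selection
#'
#' Unsupervised deployment mode: flag the upper `1 - q` tail of the score
#' distribution. The threshold is the empirical `q`-quantile computed
#' with R's default linear interpolation (type 7).
#'
#' @param scores numeric anomaly scores.
#' @param q probability in (0, 1).
#' @return the threshold.
#' @export
select_threshold_quantile <- function(scores, q) {
  stopifnot(length(scores) >= 1L, is.numeric(scores))
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 1) {
    stop("q must be a single probability strictly between 0 and 1")
  }
  unname(stats::quantile(scores, probs = q, type = 7, names = FALSE))
}

#' Classify scores against a threshold
#'
#' A plan is called abnormal when its score is greater than or equal to
#' the threshold (the inclusive convention lets the TPR==1 threshold sit
#' exactly on the minimum abnormal score).
#'
#' @param scores numeric anomaly scores.
#' @param threshold finite numeric threshold.
#' @return logical vector of abnormal flags.
#' @export
classify_scores <- function(scores, threshold) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            is.finite(threshold))
  scores >= threshold
}

#' Confusion counts and derived detection metrics
#'
#' Computes the confusion table of flags against labels and the derived
#' statistics: accuracy, precision, recall (TPR), FPR, F1 and the number
#' of plans flagged abnormal (`anomalies = TP + FP`). Precision is
#' defined as 0 (with a warning) when nothing is flagged, and F1 as 0
#' when precision + recall is 0, keeping the suite total.
#'
#' @param flags logical abnormal calls (or 0/1).
#' @param labels ground-truth labels.
#' @return an object of class `plan_metrics` (a list with the confusion
#'   counts and metric values).
#' @export
compute_metrics <- function(flags, labels) {
  if (length(flags) != length(labels)) {
    stop("flags and labels must have equal length")
  }
  flags <- as.logical(flags)
  abn <- label_is_abnormal(labels)
  tp <- sum(flags & abn)
  fp <- sum(flags & !abn)
  tn <- sum(!flags & !abn)
  fn <- sum(!flags & abn)
  n <- tp + fp + tn + fn
  precision <- if (tp + fp == 0L) {
    warning("no plans flagged; precision defined as 0")
    0
  } else tp / (tp + fp)
  recall <- if (tp + fn == 0L) NA_real_ else tp / (tp + fn)
  fpr <- if (fp + tn == 0L) NA_real_ else fp / (fp + tn)
  f1 <- if (is.na(recall) || precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  structure(
    list(TP = tp, FP = fp, TN = tn, FN = fn,
         accuracy = (tp + tn) / n, precision = precision, recall = recall,
         fpr = fpr, f1 = f1, anomalies = tp + fp),
    class = "plan_metrics")
}

#' @export
print.plan_metrics <- function(x, ...) {
  cat(sprintf(
    "<plan_metrics> TP=%d FP=%d TN=%d FN=%d | acc=%.4f prec=%.4f rec=%.4f fpr=%.4f f1=%.4f anomalies=%d\n",
    x$TP, x$FP, x$TN, x$FN, x$accuracy, x$precision, x$recall, x$fpr,
    x$f1, x$anomalies))
  invisible(x)
}

#' ROC curve and AUC
#'
#' Sweeps every distinct score (plus an above-maximum sentinel) as a
#' threshold under the `score >= t` convention, producing a monotone
#' (FPR, TPR) staircase from (0, 0) to (1, 1). The trapezoidal area under
#' the curve equals the Mann-Whitney statistic
#' `P(score_abn > score_norm) + 0.5 * P(tie)`.
#'
#' @param scores numeric anomaly scores.
#' @param labels ground-truth labels; both classes must be present.
#' @return list with `roc` (data.frame threshold/fpr/tpr) and `auc`.
#' @export
roc_and_auc <- function(scores, labels) {
  stopifnot(is.numeric(scores), length(scores) == length(labels))
  abn <- label_is_abnormal(labels)
  n_pos <- sum(abn)
  n_neg <- sum(!abn)
  if (n_pos == 0L || n_neg == 0L) {
    stop_planomaly("ROC requires both normal and abnormal labels",
                   "planomaly_policy_error")
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  thr <- c(Inf, thr)                 # (0, 0) endpoint: nothing flagged
  tpr <- vapply(thr, function(t) sum(scores >= t & abn) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !abn) / n_neg, numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc = data.frame(threshold = thr, fpr = fpr, tpr = tpr), auc = auc)
}

#' Write a metrics report
#'
#' Emits the metric suite as machine-readable JSON plus a flat
#' `key<TAB>value` text file, and optionally the ROC as a two-column CSV.
#'
#' @param metrics a `plan_metrics` object.
#' @param prefix path prefix; writes `<prefix>.json` and `<prefix>.txt`.
#' @param roc optional ROC data.frame from [roc_and_auc()]; written to
#'   `<prefix>_roc.csv` with columns fpr, tpr.
#' @param extra named list of extra scalars to include (e.g. auc,
#'   threshold).
#' @return invisibly, the paths written.
#' @export
write_metrics_report <- function(metrics, prefix, roc = NULL, extra = list()) {
  stopifnot(inherits(metrics, "plan_metrics"))
  vals <- c(unclass(metrics), extra)
  json_path <- paste0(prefix, ".json")
  txt_path <- paste0(prefix, ".txt")
  jsonlite::write_json(vals, json_path, auto_unbox = TRUE, digits = NA)
  writeLines(paste(names(vals), vapply(vals, format, character(1)),
                   sep = "\t"), txt_path)
  paths <- c(json_path, txt_path)
  if (!is.null(roc)) {
    roc_path <- paste0(prefix, "_roc.csv")
    utils::write.csv(roc[, c("fpr", "tpr")], roc_path, row.names = FALSE)
    paths <- c(paths, roc_path)
  }
  invisible(paths)
}

#' One-call evaluation of a score vector
#'
#' Applies the TPR==1 policy, classifies, and assembles the full metric
#' suite including AUC — the shared downstream pipeline used for the
#' autoencoder and every baseline detector.
#'
#' @param scores numeric anomaly scores.
#' @param labels ground-truth labels with both classes present.
#' @return list with `threshold`, `flags`, `metrics` (`plan_metrics`),
#'   `auc` and `roc`.
#' @export
evaluate_scores <- function(scores, labels) {
  threshold <- select_threshold_tpr1(scores, labels)
  flags <- classify_scores(scores, threshold)
  metrics <- compute_metrics(flags, labels)
  ra <- roc_and_auc(scores, labels)
  list(threshold = threshold, flags = flags, metrics = metrics,
       auc = ra$auc, roc = ra$roc)
}
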