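# Assessment metrics: confusion matrix, accuracy/precision/recall/F1,
# trapezoidal ROC-AUC, calibration (reliability) curves, and stratified
# cross-validation with bootstrap confidence intervals. The positive class
# is malignant throughout.

#' Confusion counts for binary predictions
#' @param labels True labels (0/1 or benign/malignant).
#' @param predictions Predicted labels, same coding.
#' @return A `confusion_counts`: list with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(labels, predictions) {
  y <- labels_to_binary(labels)
  p <- labels_to_binary(predictions)
  if (length(y) == 0) stop("empty input", call. = FALSE)
  if (length(y) != length(p)) stop("length mismatch", call. = FALSE)
  structure(list(tp = sum(y == 1 & p == 1), fp = sum(y == 0 & p == 1),
                 tn = sum(y == 0 & p == 0), fn = sum(y == 1 & p == 0)),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' accuracy = (TP+TN)/total, precision = TP/(TP+FP), recall = TP/(TP+FN),
#' F1 = 2PR/(P+R). A metric whose denominator is zero is reported as `NA`
#' with a warning, never silently zeroed.
#'
#' @param counts A `confusion_counts`.
#' @return Named list: accuracy, precision, recall, f1.
#' @export
classification_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  total <- tp + fp + tn + fn
  undef <- function(what) {
    warning(what, " undefined (zero denominator)", call. = FALSE)
    NA_real_
  }
  precision <- if (tp + fp == 0) undef("precision") else tp / (tp + fp)
  recall <- if (tp + fn == 0) undef("recall") else tp / (tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    undef("F1")
  } else {
    2 * precision * recall / (precision + recall)
  }
  list(accuracy = (tp + tn) / total, precision = precision,
       recall = recall, f1 = f1)
}

#' Area under the ROC curve
#'
#' Trapezoidal area under the ROC built from every score threshold, with
#' tied scores grouped — equivalent to the pairwise concordance statistic
#' P(score+ > score-) + 0.5 P(tie).
#'
#' @param labels Binary labels; both classes must be present.
#' @param scores Finite numeric scores (higher = more malignant).
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(labels, scores) {
  y <- labels_to_binary(labels)
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  if (length(unique(y)) < 2) {
    stop("both classes must be present", call. = FALSE)
  }
  np <- sum(y == 1); nn <- sum(y == 0)
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  grp_last <- c(ss[-1] != ss[-length(ss)], TRUE)  # last index of each tie group
  ctp <- cumsum(ys == 1)[grp_last]
  cfp <- cumsum(ys == 0)[grp_last]
  tpr <- c(0, ctp / np)
  fpr <- c(0, cfp / nn)
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

#' Calibration (reliability) curve
#'
#' Predicted probabilities are cut into `n_bins` equal-width bins on
#' [0, 1]; each non-empty bin contributes one point (mean predicted
#' probability, observed positive fraction). Empty bins are omitted.
#'
#' @param labels Binary labels.
#' @param probabilities Predicted probabilities in [0, 1].
#' @param n_bins Number of bins (>= 2, default 10).
#' @return data.frame: bin, mean_predicted, observed_fraction, n.
#' @export
calibration_curve <- function(labels, probabilities, n_bins = 10) {
  y <- labels_to_binary(labels)
  if (any(probabilities < 0 | probabilities > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (n_bins < 2) stop("n_bins must be >= 2", call. = FALSE)
  bin <- pmin(floor(probabilities * n_bins) + 1L, n_bins)
  keep <- sort(unique(bin))
  data.frame(
    bin = keep,
    mean_predicted = vapply(keep, function(b) mean(probabilities[bin == b]),
                            numeric(1)),
    observed_fraction = vapply(keep, function(b) mean(y[bin == b]),
                               numeric(1)),
    n = vapply(keep, function(b) sum(bin == b), numeric(1)))
}

#' Full metric report for scored predictions
#'
#' Thresholds the scores at `threshold`, computes the confusion counts,
#' headline metrics, AUC, the row-normalized confusion percentages (each
#' true-class row sums to 100) and the calibration points.
#'
#' @param labels Binary labels.
#' @param scores Predicted malignancy probabilities.
#' @param threshold Decision threshold (default 0.5).
#' @param n_bins Calibration bins.
#' @return A `metric_report`.
#' @export
metric_report <- function(labels, scores, threshold = 0.5, n_bins = 10) {
  y <- labels_to_binary(labels)
  pred <- as.numeric(scores >= threshold)
  counts <- confusion_counts(y, pred)
  mets <- classification_metrics(counts)
  conf_pct <- rbind(
    benign = c(benign = counts$tn, malignant = counts$fp) /
      max(1, counts$tn + counts$fp) * 100,
    malignant = c(benign = counts$fn, malignant = counts$tp) /
      max(1, counts$fn + counts$tp) * 100)
  structure(list(
    counts = counts, accuracy = mets$accuracy, precision = mets$precision,
    recall = mets$recall, f1 = mets$f1,
    auc = if (length(unique(y)) == 2) roc_auc(y, scores) else NA_real_,
    confusion_percent = conf_pct,
    calibration = calibration_curve(y, clip(scores, 0, 1), n_bins),
    n = length(y), threshold = threshold),
    class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<metric_report n=%d>\n  accuracy %.4f  precision %s  recall %s",
    "  f1 %s  auc %s\n"),
    x$n, x$accuracy, fmt_na(x$precision), fmt_na(x$recall),
    fmt_na(x$f1), fmt_na(x$auc)))
  invisible(x)
}

fmt_na <- function(v) if (is.na(v)) "NA" else sprintf("%.4f", v)

report_to_list <- function(report) {
  list(n = report$n, threshold = report$threshold,
       accuracy = report$accuracy, precision = report$precision,
       recall = report$recall, f1 = report$f1, auc = report$auc,
       confusion = list(tp = report$counts$tp, fp = report$counts$fp,
                        tn = report$counts$tn, fn = report$counts$fn),
       confusion_percent = list(
         benign = as.list(report$confusion_percent["benign", ]),
         malignant = as.list(report$confusion_percent["malignant", ])),
       calibration = report$calibration)
}

#' Write a metric report as JSON
#' @param report A `metric_report`.
#' @param path Output path.
#' @export
write_metric_report <- function(report, path) {
  jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns", na = "null")
  invisible(path)
}

#' Image-level aggregation of patch scores
#'
#' Secondary report: an image's score is the maximum malignancy
#' probability over its patches (an image is called malignant when any
#' patch is sufficiently suspicious), scored against the image labels.
#'
#' @param source_ids Image identifier per patch.
#' @param image_labels Named or id-indexed binary labels per image
#'   (data.frame with `id` and `label` columns).
#' @param scores Patch-level malignancy probabilities.
#' @param threshold Decision threshold on the aggregated score.
#' @return A `metric_report` at image level.
#' @export
image_level_report <- function(source_ids, image_labels, scores,
                               threshold = 0.5) {
  agg <- tapply(scores, source_ids, max)
  ids <- as.numeric(names(agg))
  lab <- image_labels$label[match(ids, image_labels$id)]
  metric_report(lab, as.numeric(agg), threshold = threshold)
}

#' Stratified repeated cross-validation with bootstrap CIs
#'
#' Stratified seeded folds; per fold the standardizer is fitted on the
#' training portion only, the model is refit, and the held-out fold is
#' scored. Metric means and sds are reported over all fold-by-repeat runs,
#' with 95% percentile bootstrap confidence intervals (default 2000
#' resamples) for the mean of each metric.
#'
#' @param x Feature matrix.
#' @param y Binary labels.
#' @param fit_fun Function `(x_train, y_train, seed)` returning a fitted
#'   model; defaults to a compact [train_classifier()] run.
#' @param predict_fun Function `(model, x)` returning scores; defaults to
#'   [predict_proba()].
#' @param n_folds Folds (>= 2; every class must reach every fold).
#' @param n_repeats Independent repetitions with reshuffled folds.
#' @param seed Master seed.
#' @param n_boot Bootstrap resamples.
#' @return A `cv_summary`: per-run metrics, `mean`, `sd`, and `ci` (2.5/97.5
#'   percentiles) per metric.
#' @export
cross_validate <- function(x, y, fit_fun = NULL, predict_fun = NULL,
                           n_folds = 5, n_repeats = 1, seed = 0,
                           n_boot = 2000) {
  x <- as.matrix(x)
  y <- labels_to_binary(y)
  if (is.null(fit_fun)) {
    # compact default: few epochs, step sizes sized to small folds
    fit_fun <- function(xtr, ytr, seed) {
      train_classifier(xtr, ytr,
                       plan = train_plan(total_epochs = 20,
                                         dropout_rate = 0.1,
                                         lr_spec = cyclical_lr_spec(1e-4,
                                                                    1e-2)),
                       model = mlp_model(ncol(xtr), hidden = 16,
                                         seed = seed),
                       seed = seed)$model
    }
  }
  if (is.null(predict_fun)) predict_fun <- predict_proba
  run_seeds <- derive_seeds(seed, n_repeats * n_folds + 1)
  rows <- list()
  k <- 0
  for (r in seq_len(n_repeats)) {
    folds <- make_cv_folds(y, n_folds, seed = run_seeds[1] + r)
    for (f in seq_len(n_folds)) {
      k <- k + 1
      tr <- folds != f
      std <- fit_standardizer(x[tr, , drop = FALSE])
      xtr <- apply_standardizer(x[tr, , drop = FALSE], std)
      xte <- apply_standardizer(x[!tr, , drop = FALSE], std)
      model <- fit_fun(xtr, y[tr], seed = run_seeds[k + 1])
      scores <- predict_fun(model, xte)
      rep_f <- metric_report(y[!tr], scores)
      rows[[k]] <- data.frame(repeat_index = r, fold = f,
                              accuracy = rep_f$accuracy,
                              precision = rep_f$precision,
                              recall = rep_f$recall, f1 = rep_f$f1,
                              auc = rep_f$auc)
    }
  }
  per_run <- do.call(rbind, rows)
  metrics <- c("accuracy", "precision", "recall", "f1", "auc")
  summ <- lapply(stats::setNames(metrics, metrics), function(m) {
    v <- per_run[[m]]
    v_ok <- v[!is.na(v)]
    ci <- withr::with_seed(run_seeds[1], {
      boots <- vapply(seq_len(n_boot), function(b) {
        mean(sample(v_ok, replace = TRUE))
      }, numeric(1))
      stats::quantile(boots, c(0.025, 0.975), names = FALSE)
    })
    list(mean = mean(v_ok), sd = stats::sd(v_ok), ci_low = ci[1],
         ci_high = ci[2])
  })
  structure(list(per_run = per_run, summary = summ, n_folds = n_folds,
                 n_repeats = n_repeats),
            class = "cv_summary")
}

#' @export
print.cv_summary <- function(x, ...) {
  cat(sprintf("<cv_summary %d-fold x %d repeats>\n", x$n_folds,
              x$n_repeats))
  for (m in names(x$summary)) {
    s <- x$summary[[m]]
    cat(sprintf("  %-9s %.4f +/- %.4f  [%.4f, %.4f]\n", m, s$mean,
                s$sd, s$ci_low, s$ci_high))
  }
  invisible(x)
}
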