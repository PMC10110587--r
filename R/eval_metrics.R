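#' ROC AUC as the rank statistic
#'
#' Equals the probability that a random positive outscores a random
#' negative, counting ties as one half — computed via the Wilcoxon rank-sum
#' identity.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (0/1, logical, or "DI"/"NDI"); both classes
#'   must be present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  y <- .lab01(labels)
  np <- sum(y == 1); nn <- sum(y == 0)
  if (np == 0 || nn == 0)
    stop("roc_auc requires both classes", call. = FALSE)
  r <- rank(scores)          # average ranks implement the tie = 1/2 rule
  (sum(r[y == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Operating-point threshold at a fixed false-positive rate
#'
#' Returns the smallest threshold whose realized FPR (with the decision
#' rule `score >= threshold` => predicted DI) does not exceed `max_fpr` —
#' the threshold admitting the most positives while respecting the FPR cap.
#' When even the largest score cannot (all-tied degenerate case), `Inf` is
#' returned so that nothing is flagged.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels; both classes must be present.
#' @param max_fpr FPR cap (default 0.05).
#' @return Threshold value.
#' @export
operating_point <- function(scores, labels, max_fpr = 0.05) {
  y <- .lab01(labels)
  if (length(unique(y)) < 2)
    stop("operating_point requires both classes", call. = FALSE)
  neg <- scores[y == 0]
  for (t in sort(unique(scores))) {
    if (mean(neg >= t) <= max_fpr) return(t)
  }
  Inf
}

#' Confusion metrics at a threshold
#'
#' Standard confusion-count metrics with the rule `score >= threshold` =>
#' predicted DI. Zero-denominator cases return 0 with a logged message
#' (Precision when nothing is predicted positive; Recall when there are no
#' positives; FPR when there are no negatives, with TNR then 1) so sweeps
#' never crash.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels.
#' @param threshold Decision threshold.
#' @return Named numeric vector: Recall, Precision, F1, Accuracy, TNR, FPR.
#' @export
confusion_metrics <- function(scores, labels, threshold) {
  y <- .lab01(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1); tn <- sum(pred == 0 & y == 0)

  recall <- if (tp + fn == 0) {
    message("confusion_metrics: no positive labels; Recall set to 0"); 0
  } else tp / (tp + fn)
  precision <- if (tp + fp == 0) {
    message("confusion_metrics: no predicted positives; Precision set to 0"); 0
  } else tp / (tp + fp)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  if (tn + fp == 0) {
    message("confusion_metrics: no negative labels; FPR set to 0, TNR to 1")
    fpr <- 0; tnr <- 1
  } else {
    fpr <- fp / (tn + fp); tnr <- tn / (tn + fp)
  }
  c(Recall = recall, Precision = precision, F1 = f1,
    Accuracy = (tp + tn) / length(y), TNR = tnr, FPR = fpr)
}

METRIC_NAMES <- c("ROC_AUC", "Recall", "Precision", "F1", "Accuracy",
                  "TNR", "FPR")

#' Per-topic metric report over folds
#'
#' For each fold and each topic, the operating-point threshold is chosen on
#' that fold's out-of-fold scores for the topic at `max_fpr` (so every
#' topic row respects the FPR cap); the pooled "all_topics" row uses the
#' fold's pooled threshold. AUC and the confusion metrics are reported as
#' mean (sd) across folds. A topic with a single class in some fold has its
#' metrics marked unavailable for that fold (logged) and excluded from the
#' mean/sd. DI counts per topic are appended.
#'
#' @param oof OOF score table (columns `screening_id`, `topic`, `fold`,
#'   `label`, `score`) from a fitted bundle.
#' @param max_fpr Operating-point FPR cap (default 0.05).
#' @return An object of class `"poly_metrics"`: list with `table` (long
#'   data frame: topic, metric, mean, sd), `di_counts`, `thresholds`
#'   (pooled, per fold), `topic_thresholds` (topic x fold matrix), and
#'   `fold_fpr` (realized all-topics FPR per fold).
#' @export
per_topic_report <- function(oof, max_fpr = 0.05) {
  stopifnot(all(c("topic", "fold", "label", "score") %in% names(oof)))
  folds <- sort(unique(oof$fold))
  topics <- c(sort(unique(oof$topic)), "all_topics")

  thresholds <- setNames(numeric(length(folds)), folds)
  topic_thresholds <- matrix(NA_real_, length(topics), length(folds),
                             dimnames = list(topics, folds))
  vals <- array(NA_real_, c(length(topics), length(METRIC_NAMES),
                            length(folds)),
                dimnames = list(topics, METRIC_NAMES, folds))
  for (fi in seq_along(folds)) {
    f <- folds[fi]
    sub <- oof[oof$fold == f, ]
    thresholds[fi] <- tryCatch(
      operating_point(sub$score, sub$label, max_fpr),
      error = function(e) {
        message(sprintf("per_topic_report: fold %s pooled labels are single-class; threshold set to Inf", f))
        Inf
      })
    for (tp in topics) {
      rows <- if (tp == "all_topics") sub else sub[sub$topic == tp, ]
      if (nrow(rows) == 0) next
      if (length(unique(rows$label)) < 2) {
        message(sprintf("per_topic_report: topic '%s' single-class in fold %s; skipped",
                        tp, f))
        next
      }
      thr <- if (tp == "all_topics") thresholds[fi]
             else operating_point(rows$score, rows$label, max_fpr)
      topic_thresholds[tp, fi] <- thr
      vals[tp, "ROC_AUC", fi] <- roc_auc(rows$score, rows$label)
      cm <- suppressMessages(confusion_metrics(rows$score, rows$label, thr))
      vals[tp, names(cm), fi] <- cm
    }
  }

  tab <- expand.grid(topic = topics, metric = METRIC_NAMES,
                     stringsAsFactors = FALSE)
  tab$mean <- NA_real_; tab$sd <- NA_real_
  for (i in seq_len(nrow(tab))) {
    v <- vals[tab$topic[i], tab$metric[i], ]
    if (any(!is.na(v))) {
      tab$mean[i] <- mean(v, na.rm = TRUE)
      tab$sd[i] <- if (sum(!is.na(v)) > 1) sd(v, na.rm = TRUE) else 0
    }
  }
  di <- tapply(oof$label, oof$topic, sum)
  di_counts <- c(di, all_topics = sum(oof$label))

  fold_fpr <- vals["all_topics", "FPR", ]
  structure(list(table = tab, di_counts = di_counts,
                 thresholds = thresholds,
                 topic_thresholds = topic_thresholds, fold_fpr = fold_fpr,
                 max_fpr = max_fpr, per_fold = vals),
            class = "poly_metrics")
}

#' @export
print.poly_metrics <- function(x, ...) {
  wide <- stats::reshape(x$table, idvar = "metric", timevar = "topic",
                  direction = "wide", drop = "sd")
  names(wide) <- sub("^mean\\.", "", names(wide))
  cat(sprintf("Per-topic metrics (mean over %d folds, operating point FPR <= %.2f)\n",
              length(x$thresholds), x$max_fpr))
  print(format(wide, digits = 3), row.names = FALSE)
  cat("Number of DI:",
      paste(sprintf("%s=%d", names(x$di_counts), x$di_counts), collapse = " "),
      "\n")
  invisible(x)
}

#' Write a metric report as CSV and JSON
#'
#' @param report A `"poly_metrics"` object.
#' @param csv_path,json_path Output paths (either may be NULL).
#' @return Invisibly, the report.
#' @export
write_metrics_report <- function(report, csv_path = NULL, json_path = NULL) {
  tab <- report$table
  tab$di_count <- as.integer(report$di_counts[tab$topic])
  if (!is.null(csv_path)) data.table::fwrite(tab, csv_path)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(metrics = tab,
           di_counts = as.list(report$di_counts),
           thresholds = unname(report$thresholds),
           max_fpr = report$max_fpr),
      json_path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(report)
}
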