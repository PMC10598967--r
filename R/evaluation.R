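# Threshold metrics (Sn, Sp, ACC, MCC), ranking metrics (AUROC, AUPR) and
# repeated stratified cross-validation with per-fold dispersion.

#' Confusion counts at a score threshold
#'
#' A sample is predicted positive iff its score is greater than or equal to
#' the threshold (ties go to positive).
#'
#' @param y_true Binary labels (0/1 numeric, or "positive"/"negative").
#' @param scores Numeric scores, same length.
#' @param threshold Decision threshold (default 0.5).
#' @return A `confusion_counts` list with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(y_true, scores, threshold = 0.5) {
  y <- as_binary_labels(y_true)
  if (length(y) == 0L) stop("empty input")
  if (length(y) != length(scores)) stop("label/score length mismatch")
  pred <- as.numeric(scores >= threshold)
  structure(list(TP = sum(pred == 1 & y == 1), FP = sum(pred == 1 & y == 0),
                 TN = sum(pred == 0 & y == 0), FN = sum(pred == 0 & y == 1)),
            class = "confusion_counts")
}

as_binary_labels <- function(y) {
  if (is.character(y) || is.factor(y)) {
    y <- as.character(y)
    ok <- y %in% c("positive", "negative")
    if (!all(ok)) stop("labels must be 0/1 or 'positive'/'negative'")
    as.numeric(y == "positive")
  } else {
    y <- as.numeric(y)
    if (!all(y %in% c(0, 1))) stop("numeric labels must be 0/1")
    y
  }
}

#' Threshold classification metrics from confusion counts
#'
#' Sn = TP/(TP+FN), Sp = TN/(TN+FP), ACC = (TP+TN)/total and
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FN)(TN+FN)(TP+FP)(TN+FP)). A ratio with
#' zero denominator is reported as 0 and flagged as degenerate instead of
#' raising, so cross-validation summaries never crash on an unlucky fold.
#'
#' @param counts A `confusion_counts` object (or list with TP/FP/TN/FN).
#' @return A list with `Sn`, `Sp`, `ACC`, `MCC` and a `degenerate` character
#'   vector naming any zero-denominator metrics.
#' @export
classification_metrics <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  total <- TP + FP + TN + FN
  degenerate <- character(0)
  safe_div <- function(num, den, name) {
    if (den == 0) {
      degenerate <<- c(degenerate, name)
      0
    } else num / den
  }
  Sn <- safe_div(TP, TP + FN, "Sn")
  Sp <- safe_div(TN, TN + FP, "Sp")
  ACC <- safe_div(TP + TN, total, "ACC")
  mcc_den <- sqrt(prod(c(TP + FN, TN + FN, TP + FP, TN + FP)))
  MCC <- if (mcc_den == 0) {
    degenerate <- c(degenerate, "MCC")
    0
  } else (TP * TN - FP * FN) / mcc_den
  list(Sn = Sn, Sp = Sp, ACC = ACC, MCC = MCC, degenerate = degenerate)
}

#' Area under the ROC curve (rank statistic)
#'
#' Equals the probability that a uniformly drawn positive outranks a
#' uniformly drawn negative, with ties counted one half (Mann-Whitney
#' formulation with mid-ranks).
#'
#' @param y_true Binary labels.
#' @param scores Numeric scores.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(y_true, scores) {
  y <- as_binary_labels(y_true)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L) stop("AUROC requires both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (step-wise)
#'
#' Non-interpolated step integration over the unique score thresholds,
#' sweeping from the highest score down: AUPR = sum over threshold steps of
#' (R_t - R_{t-1}) * P_t.
#'
#' @param y_true Binary labels.
#' @param scores Numeric scores.
#' @return AUPR in \[0, 1\].
#' @export
aupr <- function(y_true, scores) {
  y <- as_binary_labels(y_true)
  n1 <- sum(y == 1)
  if (n1 == 0L || n1 == length(y)) stop("AUPR requires both classes present")
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  tp <- cumsum(ys)
  fp <- cumsum(1 - ys)
  # evaluate only at the last index of each tied score block
  keep <- c(ss[-1] != ss[-length(ss)], TRUE)
  tp <- tp[keep]; fp <- fp[keep]
  prec <- tp / (tp + fp)
  rec <- tp / n1
  sum(diff(c(0, rec)) * prec)
}

#' Full metric report for scored predictions
#'
#' @param y_true Binary labels.
#' @param scores Numeric scores in \[0, 1\].
#' @param threshold Decision threshold (default 0.5).
#' @return A `metric_report`: Sn, Sp, ACC, MCC, AUROC, AUPR, n_pos, n_neg,
#'   and any degenerate flags.
#' @export
metric_report <- function(y_true, scores, threshold = 0.5) {
  y <- as_binary_labels(y_true)
  cm <- classification_metrics(confusion_counts(y, scores, threshold))
  both <- length(unique(y)) == 2L
  out <- list(Sn = cm$Sn, Sp = cm$Sp, ACC = cm$ACC, MCC = cm$MCC,
              AUROC = if (both) auroc(y, scores) else NA_real_,
              AUPR = if (both) aupr(y, scores) else NA_real_,
              n_pos = sum(y == 1), n_neg = sum(y == 0),
              degenerate = cm$degenerate)
  class(out) <- "metric_report"
  out
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "Sn %.4f  Sp %.4f  ACC %.4f  MCC %.4f  AUROC %s  AUPR %s  (n=%d+/%d-)\n",
    x$Sn, x$Sp, x$ACC, x$MCC,
    ifelse(is.na(x$AUROC), "NA", sprintf("%.4f", x$AUROC)),
    ifelse(is.na(x$AUPR), "NA", sprintf("%.4f", x$AUPR)),
    x$n_pos, x$n_neg))
  invisible(x)
}

metric_names <- c("Sn", "Sp", "ACC", "MCC", "AUROC", "AUPR")

#' Repeated stratified cross-validation
#'
#' Splits the dataset into k stratified folds, fits the pipeline on the
#' training folds and scores the held-out fold; each repeat reshuffles with a
#' seed derived from `seed`. Summaries report the per-fold mean and the
#' population standard deviation across folds.
#'
#' @param pipeline_factory Function `(train_windows, train_y) ->
#'   function(windows) -> scores`.
#' @param dataset A `site_dataset` (or character windows with `y` given).
#' @param y Binary labels (taken from the dataset if omitted).
#' @param k Folds per repeat (>= 2).
#' @param repeats Number of shuffled repeats.
#' @param seed Base seed.
#' @param threshold Decision threshold for the fold metric reports.
#' @return A `cv_summary`: `folds` (data frame, one row per fold x repeat),
#'   `mean`, `sd`, plus `k`, `repeats`, `seed`. Each fold is audited to
#'   never score a training sample (`leakage_audit` is TRUE when clean).
#' @export
cross_validate <- function(pipeline_factory, dataset, y = NULL, k = 5L,
                           repeats = 1L, seed = 1L, threshold = 0.5) {
  if (inherits(dataset, "site_dataset")) {
    if (is.null(y)) y <- dataset_labels(dataset)
    windows <- dataset$window
  } else windows <- as.character(dataset)
  y <- as.numeric(y)
  rows <- list()
  audit_ok <- TRUE
  for (r in seq_len(repeats)) {
    fold <- stratified_folds(y, k, seed = as.integer(seed + 1000L * (r - 1L)))
    for (f in seq_len(k)) {
      tr <- which(fold != f)
      te <- which(fold == f)
      if (length(intersect(tr, te)) > 0) audit_ok <- FALSE
      predictor <- pipeline_factory(windows[tr], y[tr])
      rep_m <- metric_report(y[te], predictor(windows[te]), threshold)
      rows[[length(rows) + 1L]] <- data.frame(
        repeat_id = r, fold = f, n_test = length(te),
        Sn = rep_m$Sn, Sp = rep_m$Sp, ACC = rep_m$ACC, MCC = rep_m$MCC,
        AUROC = rep_m$AUROC, AUPR = rep_m$AUPR)
    }
  }
  folds <- do.call(rbind, rows)
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  structure(list(folds = folds,
                 mean = vapply(metric_names, function(m) mean(folds[[m]]),
                               numeric(1)),
                 sd = vapply(metric_names, function(m) pop_sd(folds[[m]]),
                             numeric(1)),
                 k = k, repeats = repeats, seed = seed,
                 leakage_audit = audit_ok),
            class = "cv_summary")
}

#' @export
print.cv_summary <- function(x, ...) {
  cat(sprintf("<cv_summary> %d-fold x %d repeat(s), seed %d\n", x$k,
              x$repeats, x$seed))
  for (m in metric_names) {
    cat(sprintf("  %-5s %.4f +/- %.4f\n", m, x$mean[[m]], x$sd[[m]]))
  }
  invisible(x)
}

#' Negative-resampling stability experiment
#'
#' Repeatedly draws a fresh negative sample from a pool at `ratio` negatives
#' per positive, then runs repeated stratified cross-validation on each
#' draw — the design used to check that results are stable across negative
#' sets (and, at ratio 4, the 1:4 imbalanced design).
#'
#' @param pos_windows Character vector of positive windows.
#' @param neg_pool Character vector of candidate negative windows (must hold
#'   at least `ratio * length(pos_windows)` sequences).
#' @param pipeline_factory As in [cross_validate()].
#' @param n_repeats Number of independent negative draws.
#' @param ratio Negatives per positive.
#' @param k,cv_repeats,seed Cross-validation controls.
#' @return List of `cv_summary`, one per draw.
#' @export
negative_resampling_experiment <- function(pos_windows, neg_pool,
                                           pipeline_factory, n_repeats = 5L,
                                           ratio = 1, k = 10L,
                                           cv_repeats = 1L, seed = 1L) {
  n_neg <- as.integer(round(ratio * length(pos_windows)))
  if (length(neg_pool) < n_neg) {
    stop("negative pool (", length(neg_pool), ") smaller than required ",
         n_neg, " draws")
  }
  lapply(seq_len(n_repeats), function(r) {
    set.seed(as.integer(seed + 7919L * (r - 1L)))
    negs <- sample(neg_pool, n_neg)
    windows <- c(pos_windows, negs)
    y <- c(rep(1, length(pos_windows)), rep(0, n_neg))
    cross_validate(pipeline_factory, windows, y, k = k, repeats = cv_repeats,
                   seed = as.integer(seed + 104729L * (r - 1L)))
  })
}
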