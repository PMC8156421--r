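## Confusion-matrix metrics, AUROC, repeated stratified cross-validation,
## bootstrap-CI predictor comparison and window-size significance tests.
## Driver is the positive class throughout.

#' Build a confusion matrix
#'
#' Either from the four counts directly, or from parallel vectors of calls
#' and truths (values \code{"driver"}/\code{"passenger"}).
#'
#' @param tp,fp,fn,tn non-negative integer counts.
#' @param calls,truth optional label vectors used instead of counts.
#' @return object of class \code{"confusion_matrix"}.
#' @export
confusion_matrix <- function(tp = NULL, fp = NULL, fn = NULL, tn = NULL,
                             calls = NULL, truth = NULL) {
  if (!is.null(calls)) {
    stopifnot(length(calls) == length(truth))
    tp <- sum(calls == "driver" & truth == "driver")
    fp <- sum(calls == "driver" & truth == "passenger")
    fn <- sum(calls == "passenger" & truth == "driver")
    tn <- sum(calls == "passenger" & truth == "passenger")
  }
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(is.na(counts)) || any(counts < 0))
    stop2("confusion counts must be non-negative")
  if (sum(counts) == 0) stop2("empty confusion matrix")
  structure(as.list(counts), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2,
              dimnames = list(truth = c("driver", "passenger"),
                              call = c("driver", "passenger")))
  print(m)
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), PPV TP/(TP+FP),
#' NPV TN/(TN+FN), accuracy, the Matthews correlation coefficient
#' \deqn{MCC = (TP \cdot TN - FP \cdot FN) /
#'   \sqrt{(TP+FP)(TP+FN)(TN+FN)(TN+FP)}}
#' (0 when any denominator factor is 0), and the composite score
#' = sensitivity + specificity + PPV + NPV (range [0, 4]).
#' Rates with a zero denominator are reported as NA, except that they count
#' as 0 in the composite sum.
#'
#' @param cm a \code{"confusion_matrix"}.
#' @return object of class \code{"metrics_report"}: list with
#'   \code{sensitivity}, \code{specificity}, \code{ppv}, \code{npv},
#'   \code{accuracy}, \code{mcc}, \code{composite}.
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tp <- cm$tp; fp <- cm$fp; fn <- cm$fn; tn <- cm$tn
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- rate(tp, tp + fn)
  spec <- rate(tn, tn + fp)
  ppv <- rate(tp, tp + fp)
  npv <- rate(tn, tn + fn)
  acc <- (tp + tn) / (tp + fp + fn + tn)
  denom <- as.numeric(tp + fp) * (tp + fn) * (tn + fn) * (tn + fp)
  mcc <- if (denom == 0) 0 else
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(denom)
  zero_na <- function(v) if (is.na(v)) 0 else v
  composite <- zero_na(sens) + zero_na(spec) + zero_na(ppv) + zero_na(npv)
  structure(list(sensitivity = sens, specificity = spec, ppv = ppv,
                 npv = npv, accuracy = acc, mcc = mcc,
                 composite = composite),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  v <- unlist(x)
  cat(paste(sprintf("  %-12s %.4f", names(v), v), collapse = "\n"), "\n")
  invisible(x)
}

#' Area under the ROC curve
#'
#' Rank-based AUROC: the probability that a randomly chosen driver receives
#' a higher score than a randomly chosen passenger, ties counted half.
#'
#' @param scores numeric vector.
#' @param labels \code{"driver"}/\code{"passenger"} vector; both classes
#'   must be present.
#' @return scalar in [0, 1].
#' @export
auroc <- function(scores, labels) {
  is_d <- labels == "driver"
  n1 <- sum(is_d); n0 <- sum(!is_d)
  if (n1 == 0 || n0 == 0) stop2("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[is_d]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified fold assignment: each class is split as evenly as possible.
stratified_folds <- function(labels, n_folds, seed = NULL) {
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
  })
  fold
}

#' Repeated stratified cross-validation of a pipeline
#'
#' Runs \code{n_repeats} rounds of stratified \code{n_folds}-fold
#' cross-validation, yielding \code{n_folds * n_repeats} values per metric.
#' All fitting (vocabulary learning, imputation, rebalancing, feature
#' selection, tuning) must happen inside \code{pipeline$fit}, which only
#' ever sees the training fold, so nothing leaks from held-out data.
#'
#' @param data any object subsettable by \code{pipeline$subset(data, idx)}
#'   (default subset works for matrices/data.frames by row).
#' @param labels \code{"driver"}/\code{"passenger"} vector.
#' @param pipeline list with \code{fit(data_train, labels_train, seed)}
#'   returning a fitted object and \code{score(fit, data_test)} returning
#'   driver scores in [0, 1]; optional \code{subset(data, idx)}.
#' @param n_folds folds per round (default 10).
#' @param n_repeats rounds (default 3).
#' @param score_threshold threshold for confusion-based metrics
#'   (default 0.5).
#' @param seed integer seed.
#' @return object of class \code{"cv_result"}: list with \code{values}
#'   (data.frame, one row per fold x repeat with all metrics),
#'   \code{median} and \code{ci} (95\% Student-t interval on the mean) per
#'   metric.
#' @export
repeated_cv <- function(data, labels, pipeline, n_folds = 10L,
                        n_repeats = 3L, score_threshold = 0.5, seed = 1L) {
  labels <- as.character(labels)
  subset_fun <- pipeline$subset %||%
    function(d, idx) if (is.matrix(d) || is.data.frame(d))
      d[idx, , drop = FALSE] else d[idx]
  counts <- table(labels)
  if (min(counts) < n_folds)
    stop2("cannot stratify: smallest class (", min(counts),
          ") has fewer rows than n_folds (", n_folds, ")")
  rows <- list()
  for (r in seq_len(n_repeats)) {
    fold <- stratified_folds(labels, n_folds, seed = derive_seed(seed, r))
    for (f in seq_len(n_folds)) {
      tr <- which(fold != f); te <- which(fold == f)
      if (length(unique(labels[te])) < 2L)
        stop2("fold with a single class; not stratifiable")
      fit <- pipeline$fit(subset_fun(data, tr), labels[tr],
                          seed = derive_seed(seed, 100L * r + f))
      scores <- pipeline$score(fit, subset_fun(data, te))
      calls <- apply_threshold(scores, score_threshold)
      m <- compute_metrics(confusion_matrix(calls = calls,
                                            truth = labels[te]))
      rows[[length(rows) + 1L]] <- data.frame(
        repeat_ = r, fold = f,
        sensitivity = m$sensitivity, specificity = m$specificity,
        ppv = m$ppv, npv = m$npv, accuracy = m$accuracy, mcc = m$mcc,
        composite = m$composite,
        auroc = auroc(scores, labels[te]))
    }
  }
  values <- do.call(rbind, rows)
  metric_cols <- setdiff(names(values), c("repeat_", "fold"))
  med <- vapply(values[metric_cols], median, numeric(1), na.rm = TRUE)
  ci <- t(vapply(values[metric_cols], function(v) {
    v <- v[!is.na(v)]
    m <- mean(v); s <- sd(v) / sqrt(length(v))
    m + c(-1, 1) * qt(0.975, length(v) - 1L) * s
  }, numeric(2)))
  colnames(ci) <- c("lower", "upper")
  structure(list(values = values, median = med, ci = ci,
                 n_folds = n_folds, n_repeats = n_repeats),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("Repeated stratified cross-validation: ", x$n_folds, " folds x ",
      x$n_repeats, " repeats = ", nrow(x$values), " values per metric\n",
      sep = "")
  tab <- cbind(median = x$median, x$ci)
  print(round(tab, 4))
  invisible(x)
}

#' Bootstrap-CI comparison of two predictors
#'
#' Percentile 95\% confidence intervals for a metric of each predictor,
#' from \code{n_boot} resamples (with replacement) of the shared test set.
#' The difference is called significant when the two intervals are disjoint
#' or touch at an endpoint.  Resamples on which the metric is undefined
#' (e.g. a single-class draw) are redrawn and counted.
#'
#' @param scores_a,scores_b driver scores of the two predictors on the same
#'   test set.
#' @param labels true labels.
#' @param metric function \code{(scores, labels) -> scalar}; defaults to
#'   [auroc()].
#' @param n_boot bootstrap iterations (default 1000).
#' @param seed integer seed.
#' @return list with \code{ci_a}, \code{ci_b} (length-2 vectors),
#'   \code{significant} (logical), \code{n_redrawn}.
#' @export
bootstrap_ci_compare <- function(scores_a, scores_b, labels,
                                 metric = auroc, n_boot = 1000L, seed = 1L) {
  stopifnot(length(scores_a) == length(labels),
            length(scores_b) == length(labels))
  n <- length(labels)
  vals_a <- numeric(n_boot); vals_b <- numeric(n_boot)
  n_redrawn <- 0L
  set.seed(as.integer(seed))
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      va <- tryCatch(metric(scores_a[idx], labels[idx]), error = function(e) NA)
      vb <- tryCatch(metric(scores_b[idx], labels[idx]), error = function(e) NA)
      if (!is.na(va) && !is.na(vb)) break
      n_redrawn <- n_redrawn + 1L
    }
    vals_a[b] <- va; vals_b[b] <- vb
  }
  ci_a <- unname(quantile(vals_a, c(0.025, 0.975)))
  ci_b <- unname(quantile(vals_b, c(0.025, 0.975)))
  tol <- 1e-12
  significant <- (ci_a[1] >= ci_b[2] - tol) || (ci_b[1] >= ci_a[2] - tol)
  if (n_redrawn > 0L)
    message(n_redrawn, " degenerate resample(s) redrawn")
  list(ci_a = ci_a, ci_b = ci_b, significant = significant,
       n_redrawn = n_redrawn)
}

#' Pairwise significance tests across window sizes
#'
#' For every ordered pair of window sizes (x, y), x < y, tests whether the
#' per-run metric values differ, with the Wilcoxon signed-rank test
#' (paired; equal lengths required) or the Mann-Whitney U test (unpaired).
#' Ten windows give 45 pairs.
#'
#' @param metric_values_by_window named list: window -> numeric vector of
#'   metric values (e.g. 30 CV values).
#' @param test \code{"wilcoxon_signed_rank"} (default) or
#'   \code{"mann_whitney_u"}.
#' @return \code{data.frame} with columns \code{window_x}, \code{window_y},
#'   \code{p_value}.
#' @export
compare_windows <- function(metric_values_by_window,
                            test = c("wilcoxon_signed_rank",
                                     "mann_whitney_u")) {
  test <- match.arg(test)
  wins <- names(metric_values_by_window)
  if (is.null(wins)) wins <- as.character(seq_along(metric_values_by_window))
  nw <- length(wins)
  rows <- list()
  for (i in seq_len(nw - 1L)) {
    for (j in seq((i + 1L), nw)) {
      a <- metric_values_by_window[[i]]
      b <- metric_values_by_window[[j]]
      if (test == "wilcoxon_signed_rank") {
        if (length(a) != length(b))
          stop2("paired test needs equal-length vectors for windows ",
                wins[i], " and ", wins[j])
        p <- if (all(a == b)) 1 else
          suppressWarnings(stats::wilcox.test(a, b, paired = TRUE)$p.value)
      } else {
        p <- suppressWarnings(stats::wilcox.test(a, b)$p.value)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        window_x = wins[i], window_y = wins[j], p_value = p,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
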