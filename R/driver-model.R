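## The central fitting front-end: encode -> merge descriptive features ->
## impute -> rebalance -> select -> fit estimator(s) -> tune threshold.
## Everything fitted here is captured so new data can be transformed
## without re-fitting (vocabulary, scaling, selected features, threshold).

#' Train a neighborhood-based driver/passenger classifier
#'
#' Fits the full classification pipeline on labeled mutations:
#' \enumerate{
#'   \item extract neighborhood sequences of \code{window_size} around each
#'     mutation and encode them (default: TF-IDF of overlapping 4-mers,
#'     window 10, plus chromosome and substitution-type codes);
#'   \item optionally merge a descriptive genomic feature table and fill
#'     missing entries by gene-aware k-nearest-neighbor imputation;
#'   \item standardize columns, rebalance classes with repeated edited
#'     nearest neighbors (RENN) undersampling;
#'   \item keep the \code{top_n} features by impurity importance;
#'   \item fit the estimator: a soft-average ensemble of a linear-kernel
#'     SVM and a generative KDE classifier (default), or either alone, or
#'     a random-forest / extra-trees model;
#'   \item search the decision threshold on a 0..1 grid of step 0.001,
#'     maximizing the composite score (sens + spec + PPV + NPV) on the
#'     training scores.
#' }
#'
#' @param mutations labeled mutation \code{data.frame}
#'   (see [read_mutations()]); labels must contain both classes.
#' @param genome reference genome accepted by [load_genome()].
#' @param descriptive optional descriptive feature table with a \code{key}
#'   column (see [assemble_features()]); \code{NULL} gives the
#'   neighborhood-only model.
#' @param window_size flank length n (default 10).
#' @param representation \code{"tf"}, \code{"cv"} or \code{"ohe"}.
#' @param k k-mer length for k-mer representations (default 4).
#' @param tfidf_variant passed to [tfidf_vectorize()].
#' @param top_n features kept by impurity selection (default 50; clipped to
#'   the number of available features).
#' @param estimator \code{"svm_kde"} (default), \code{"svm"}, \code{"kde"},
#'   \code{"rf"} or \code{"et"}.
#' @param rebalance apply RENN undersampling (default TRUE).
#' @param renn_k,renn_max_iter RENN parameters.
#' @param impute_k neighbors for descriptive-feature imputation.
#' @param svm_cost linear-SVM cost parameter (default 1).
#' @param num_trees trees for forest estimators and for impurity selection.
#' @param bandwidth_grid KDE bandwidths (default 20 log-spaced values in
#'   [1e-2, 10]).
#' @param threshold fixed decision threshold in [0, 1], or \code{NULL} to
#'   search (default).
#' @param threshold_objective \code{"composite"} (default) or \code{"mcc"}.
#' @param seed integer seed driving all stochastic stages.
#' @return object of class \code{"driver_model"}.
#' @seealso [predict.driver_model()], [compute_metrics()]
#' @export
driver_model <- function(mutations, genome, descriptive = NULL,
                         window_size = 10L,
                         representation = c("tf", "cv", "ohe"), k = 4L,
                         tfidf_variant = c("smoothed_l2", "paper_formula"),
                         top_n = 50L,
                         estimator = c("svm_kde", "svm", "kde", "rf", "et"),
                         rebalance = TRUE, renn_k = 3L, renn_max_iter = 100L,
                         impute_k = 5L, svm_cost = 1,
                         num_trees = 500L,
                         bandwidth_grid = default_bandwidth_grid(),
                         threshold = NULL,
                         threshold_objective = c("composite", "mcc"),
                         seed = 1L) {
  representation <- match.arg(representation)
  tfidf_variant <- match.arg(tfidf_variant)
  estimator <- match.arg(estimator)
  threshold_objective <- match.arg(threshold_objective)
  genome <- load_genome(genome)

  labels <- tolower(as.character(mutations$label))
  if (!all(c("driver", "passenger") %in% labels))
    stop2("training mutations must contain both driver and passenger labels")

  nb <- extract_neighborhoods(mutations, genome, window_size)
  labels <- nb$label
  enc <- encode_neighborhoods(nb, representation, k = k,
                              tfidf_variant = tfidf_variant)
  feats <- assemble_features(enc$features, descriptive)
  if (anyNA(feats)) feats <- knn_impute(feats, gene_keys = nb$gene,
                                        k = impute_k)

  centers <- colMeans(feats)
  scales <- apply(feats, 2L, sd)
  scales[scales == 0 | !is.finite(scales)] <- 1
  x <- sweep(sweep(feats, 2L, centers), 2L, scales, "/")

  if (rebalance) {
    bal <- renn_undersample(x, labels, k = renn_k, max_iter = renn_max_iter)
    x_fit <- bal$features; y_fit <- bal$labels
  } else {
    x_fit <- x; y_fit <- labels
  }

  n_keep <- min(as.integer(top_n), ncol(x_fit))
  selected <- impurity_select(x_fit, y_fit, mode = "top_n", value = n_keep,
                              num_trees = num_trees,
                              seed = derive_seed(seed, 11L))
  x_sel <- x_fit[, selected, drop = FALSE]

  fits <- fit_estimators(x_sel, y_fit, estimator, svm_cost, num_trees,
                         bandwidth_grid, seed)

  train_scores <- score_estimators(fits, x[, selected, drop = FALSE])
  if (is.null(threshold)) {
    threshold <- search_threshold(train_scores, labels,
                                  objective = threshold_objective)
  }

  structure(list(
    window_size = as.integer(window_size),
    representation = representation, k = as.integer(k),
    tfidf_variant = tfidf_variant,
    vocab = enc$vocab,
    uses_descriptive = !is.null(descriptive),
    centers = centers, scales = scales,
    selected_features = selected,
    estimator = estimator, fits = fits,
    threshold = threshold,
    threshold_objective = threshold_objective,
    train_scores = train_scores, train_labels = labels,
    train_keys = nb$key,
    n_train = nrow(x), n_after_rebalance = nrow(x_fit),
    seed = as.integer(seed)
  ), class = "driver_model")
}

fit_estimators <- function(x, y, estimator, svm_cost, num_trees,
                           bandwidth_grid, seed) {
  yf <- factor(y, levels = c("driver", "passenger"))
  fits <- list()
  if (estimator %in% c("svm", "svm_kde")) {
    set.seed(derive_seed(seed, 21L))
    fits$svm <- e1071::svm(x, yf, kernel = "linear", cost = svm_cost,
                           probability = TRUE, scale = FALSE)
  }
  if (estimator %in% c("kde", "svm_kde")) {
    fits$kde <- kde_classifier_fit(x, y, bandwidth_grid,
                                   seed = derive_seed(seed, 22L))
  }
  if (estimator %in% c("rf", "et")) {
    df <- as.data.frame(x); names(df) <- make.names(names(df), unique = TRUE)
    df$.label <- yf
    fits$forest <- ranger::ranger(
      dependent.variable.name = ".label", data = df,
      num.trees = num_trees, probability = TRUE,
      splitrule = if (estimator == "et") "extratrees" else "gini",
      num.random.splits = 1L,
      seed = derive_seed(seed, 23L), num.threads = 1L)
  }
  fits
}

# Soft-averaged driver score across the fitted estimators.
score_estimators <- function(fits, x) {
  scores <- list()
  if (!is.null(fits$svm)) {
    pr <- attr(predict(fits$svm, x, probability = TRUE), "probabilities")
    scores$svm <- pr[, "driver"]
  }
  if (!is.null(fits$kde))
    scores$kde <- kde_classifier_posterior(fits$kde, x)
  if (!is.null(fits$forest)) {
    df <- as.data.frame(x); names(df) <- make.names(names(df), unique = TRUE)
    scores$forest <- predict(fits$forest, df)$predictions[, "driver"]
  }
  Reduce(`+`, scores) / length(scores)
}

#' Search the decision threshold maximizing a metric
#'
#' Scans thresholds from 0 to 1 in steps of \code{step} and returns the one
#' maximizing the objective computed from the thresholded calls (smallest
#' threshold wins ties).
#'
#' @param scores driver scores in [0, 1].
#' @param labels true labels (\code{"driver"}/\code{"passenger"}).
#' @param step grid step (default 0.001).
#' @param objective \code{"composite"} or \code{"mcc"}.
#' @return the selected threshold (scalar).
#' @export
search_threshold <- function(scores, labels, step = 0.001,
                             objective = c("composite", "mcc")) {
  objective <- match.arg(objective)
  grid <- seq(0, 1, by = step)
  is_driver <- labels == "driver"
  n_d <- sum(is_driver); n_p <- sum(!is_driver)
  best_val <- -Inf; best_thr <- grid[1]
  for (thr in grid) {
    call_driver <- scores > thr
    tp <- sum(call_driver & is_driver)
    fp <- sum(call_driver & !is_driver)
    m <- compute_metrics(confusion_matrix(tp = tp, fp = fp,
                                          fn = n_d - tp, tn = n_p - fp))
    val <- if (objective == "composite") m$composite else m$mcc
    if (val > best_val + 1e-12) { best_val <- val; best_thr <- thr }
  }
  best_thr
}

#' Predict driver scores or labels for new mutations
#'
#' Applies the fitted pipeline transform-only: the training vocabulary,
#' scaling, selected features and threshold are reused; unseen k-mers
#' contribute nothing.  Missing descriptive entries are filled with the
#' training column means.
#'
#' @param object a \code{"driver_model"}.
#' @param mutations mutation \code{data.frame}.
#' @param genome reference genome accepted by [load_genome()].
#' @param descriptive optional descriptive feature table (required when the
#'   model was trained with one).
#' @param type \code{"score"} (driver probability), \code{"label"}
#'   (thresholded call) or \code{"both"} (data.frame with key, score,
#'   label).
#' @param ... unused.
#' @return per-mutation scores, labels, or a data.frame.
#' @export
predict.driver_model <- function(object, mutations, genome,
                                 descriptive = NULL,
                                 type = c("score", "label", "both"), ...) {
  type <- match.arg(type)
  if (object$uses_descriptive && is.null(descriptive))
    stop2("model was trained with descriptive features; supply them")
  nb <- extract_neighborhoods(mutations, load_genome(genome),
                              object$window_size)
  enc <- encode_neighborhoods(nb, object$representation, k = object$k,
                              vocab = object$vocab,
                              tfidf_variant = object$tfidf_variant)
  feats <- assemble_features(enc$features, descriptive)
  if (anyNA(feats)) {   # fill with training means (transform discipline)
    for (j in colnames(feats)) {
      mis <- is.na(feats[, j])
      if (any(mis)) feats[mis, j] <- object$centers[[j]]
    }
  }
  x <- sweep(sweep(feats, 2L, object$centers[colnames(feats)]),
             2L, object$scales[colnames(feats)], "/")
  scores <- score_estimators(object$fits,
                             x[, object$selected_features, drop = FALSE])
  if (type == "score") return(scores)
  labs <- apply_threshold(scores, object$threshold)
  if (type == "label") return(labs)
  data.frame(key = nb$key, score = scores, label = labs,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @export
print.driver_model <- function(x, ...) {
  cat("Neighborhood-based driver/passenger classifier\n")
  cat("  encoding: ", toupper(x$representation),
      if (x$representation != "ohe") paste0(" (k = ", x$k, ")"),
      ", window size ", x$window_size, "\n", sep = "")
  cat("  features: ", if (x$uses_descriptive)
    "neighborhood + descriptive" else "neighborhood-only",
    "; ", length(x$selected_features), " selected\n", sep = "")
  cat("  estimator: ", x$estimator, "   threshold: ",
      format(x$threshold), "\n", sep = "")
  cat("  training: ", x$n_train, " mutations (",
      sum(x$train_labels == "driver"), " drivers), ",
      x$n_after_rebalance, " after rebalancing\n", sep = "")
  invisible(x)
}

#' @export
summary.driver_model <- function(object, ...) {
  calls <- apply_threshold(object$train_scores, object$threshold)
  cm <- confusion_matrix(calls = calls, truth = object$train_labels)
  metrics <- compute_metrics(cm)
  out <- list(model = object, confusion = cm, metrics = metrics)
  class(out) <- "summary.driver_model"
  out
}

#' @export
print.summary.driver_model <- function(x, ...) {
  print(x$model)
  cat("\nTraining-set (resubstitution) performance at threshold ",
      format(x$model$threshold), ":\n", sep = "")
  print(x$metrics)
  invisible(x)
}

#' @export
coef.driver_model <- function(object, ...) {
  imp <- attr(object$selected_features, "importance")
  imp[object$selected_features]
}

#' @export
plot.driver_model <- function(x, ...) {
  d <- x$train_scores[x$train_labels == "driver"]
  p <- x$train_scores[x$train_labels == "passenger"]
  graphics::hist(p, breaks = 30, col = grDevices::rgb(0, 0, 1, 0.4),
                 xlim = c(0, 1), main = "Training driver scores by class",
                 xlab = "driver score", freq = FALSE)
  graphics::hist(d, breaks = 30, col = grDevices::rgb(1, 0, 0, 0.4),
                 add = TRUE, freq = FALSE)
  graphics::abline(v = x$threshold, lty = 2)
  graphics::legend("topright", fill = grDevices::rgb(c(1, 0), 0, c(0, 1),
                                                     0.4),
                   legend = c("driver", "passenger"), bty = "n")
  invisible(x)
}
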