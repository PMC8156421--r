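## Generative KDE classifier, class rebalancing, imputation, feature
## selection, thresholding and vote combination.

#' Fit a generative KDE classifier
#'
#' Fits one bandwidth-tuned Gaussian KDE per class (driver, passenger) as
#' the class-conditional likelihood, with class priors equal to the
#' training class fractions.
#'
#' @param features numeric matrix.
#' @param labels character/factor vector with values \code{"driver"} and
#'   \code{"passenger"}; both classes must be present.
#' @param bandwidth_grid bandwidths for [fit_kde()].
#' @param folds CV folds for bandwidth selection.
#' @param seed integer seed.
#' @return object of class \code{"kde_classifier"}.
#' @export
kde_classifier_fit <- function(features, labels,
                               bandwidth_grid = default_bandwidth_grid(),
                               folds = 5L, seed = NULL) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  classes <- c("driver", "passenger")
  if (!all(classes %in% labels))
    stop2("both classes (driver, passenger) must be present")
  models <- list(); log_priors <- numeric(0)
  for (cl in classes) {
    rows <- features[labels == cl, , drop = FALSE]
    models[[cl]] <- fit_kde(rows, bandwidth_grid, folds,
                            seed = derive_seed(seed %||% 0L, match(cl, classes)))
    log_priors[cl] <- log(nrow(rows) / nrow(features))
  }
  structure(list(class_models = models, log_priors = log_priors,
                 labels = classes, dim = ncol(features)),
            class = "kde_classifier")
}

#' Posterior driver probability under a KDE classifier
#'
#' Computes \eqn{P(driver | x) = P(x | driver) P(driver) / \sum_c P(x | c)
#' P(c)} in log space.  The hard label maximizes the posterior; exact ties
#' go to passenger (the conservative call).
#'
#' @param model a \code{"kde_classifier"}.
#' @param x numeric matrix (or vector) of feature rows.
#' @return numeric vector of driver posterior probabilities.
#' @export
kde_classifier_posterior <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) == 1L && model$dim > 1L) x <- t(x)
  if (ncol(x) != model$dim)
    stop2("feature dimension ", ncol(x), " does not match model (",
          model$dim, ")")
  ld <- kde_log_density(model$class_models$driver, x) +
    model$log_priors["driver"]
  lp <- kde_log_density(model$class_models$passenger, x) +
    model$log_priors["passenger"]
  # 1 / (1 + exp(lp - ld)), stable in log space
  1 / (1 + exp(pmin(700, pmax(-700, lp - ld))))
}

#' @export
predict.kde_classifier <- function(object, newdata, type = c("prob", "label"),
                                   ...) {
  type <- match.arg(type)
  post <- kde_classifier_posterior(object, newdata)
  if (type == "prob") return(post)
  ifelse(post > 0.5, "driver", "passenger")   # ties -> passenger
}

#' @export
print.kde_classifier <- function(x, ...) {
  cat("Generative KDE classifier (", x$dim, " features)\n", sep = "")
  for (cl in x$labels)
    cat(sprintf("  %-9s n = %d, bandwidth = %.4g, prior = %.3f\n", cl,
                nrow(x$class_models[[cl]]$points),
                x$class_models[[cl]]$bandwidth, exp(x$log_priors[cl])))
  invisible(x)
}

#' Repeated edited nearest neighbors undersampling
#'
#' Iteratively removes majority-class points that are misclassified by a
#' majority vote of their k nearest neighbors (Euclidean distance, among
#' all remaining points), until a pass removes nothing or \code{max_iter}
#' passes have run.  The minority class is never edited, so its count is
#' preserved and the output rows are always a subset of the input rows.
#'
#' @param features numeric matrix.
#' @param labels vector with two classes.
#' @param k neighbors to consult (default 3).
#' @param max_iter maximum editing passes (default 100).
#' @return list with \code{features}, \code{labels} and \code{kept}
#'   (indices into the input rows).
#' @export
renn_undersample <- function(features, labels, k = 3L, max_iter = 100L) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L) stop2("both classes must be present")
  if (k >= nrow(features)) stop2("k must be smaller than the dataset size")
  counts <- table(labels)
  majority <- names(counts)[which.max(counts)]
  kept <- seq_len(nrow(features))
  for (iter in seq_len(max_iter)) {
    f <- features[kept, , drop = FALSE]
    l <- labels[kept]
    maj_idx <- which(l == majority)
    if (length(maj_idx) <= k) break
    d2 <- pairwise_sqdist(f[maj_idx, , drop = FALSE], f)
    d2[cbind(seq_along(maj_idx), maj_idx)] <- Inf   # exclude self
    remove <- logical(length(maj_idx))
    for (j in seq_along(maj_idx)) {
      nn <- order(d2[j, ])[seq_len(k)]
      votes <- sum(l[nn] == majority)
      remove[j] <- votes < (k - votes + 1L)  # strict majority against
    }
    if (!any(remove)) break
    kept <- kept[-maj_idx[remove]]
  }
  list(features = features[kept, , drop = FALSE],
       labels = labels[kept], kept = kept)
}

#' Gene-aware k-nearest-neighbor imputation
#'
#' Replaces each missing cell with the mean of that column over the k
#' nearest complete rows (Euclidean distance on the columns observed in the
#' target row).  When at least k complete rows share the target row's gene,
#' neighbors are restricted to that gene; otherwise all complete rows are
#' candidates.
#'
#' @param features numeric matrix possibly containing \code{NA}.
#' @param gene_keys optional character vector of per-row gene symbols.
#' @param k neighbors to average (default 5).
#' @return complete numeric matrix.
#' @export
knn_impute <- function(features, gene_keys = NULL, k = 5L) {
  features <- as.matrix(features)
  if (!anyNA(features)) return(features)
  if (any(colSums(!is.na(features)) == 0L))
    stop2("cannot impute a column with no observed values")
  complete <- which(complete.cases(features))
  if (!length(complete)) stop2("no complete rows available for imputation")
  out <- features
  for (i in which(!complete.cases(features))) {
    cand <- complete
    if (!is.null(gene_keys) && !is.na(gene_keys[i])) {
      same_gene <- complete[gene_keys[complete] == gene_keys[i] &
                              !is.na(gene_keys[complete])]
      if (length(same_gene) >= k) cand <- same_gene
    }
    obs <- which(!is.na(features[i, ]))
    d2 <- pairwise_sqdist(features[i, obs, drop = FALSE],
                          features[cand, obs, drop = FALSE])[1L, ]
    nn <- cand[order(d2)[seq_len(min(k, length(cand)))]]
    mis <- which(is.na(features[i, ]))
    out[i, mis] <- colMeans(features[nn, mis, drop = FALSE])
  }
  out
}

#' Impurity-based feature selection
#'
#' Ranks features by mean impurity importance from an extremely randomized
#' trees ensemble and keeps either the top percentile or the top n.
#'
#' @param features numeric matrix with named columns.
#' @param labels two-class vector.
#' @param mode \code{"percentile"} or \code{"top_n"}.
#' @param value percentile to keep (e.g. 30 keeps the top 30\% most
#'   important features) or n for \code{"top_n"}.
#' @param num_trees trees in the ensemble (default 500).
#' @param seed integer seed.
#' @return character vector of selected feature names, most important
#'   first; importances attached as the \code{"importance"} attribute.
#' @export
impurity_select <- function(features, labels, mode = c("percentile", "top_n"),
                            value = 30, num_trees = 500L, seed = 1L) {
  mode <- match.arg(mode)
  features <- as.matrix(features)
  if (is.null(colnames(features)))
    colnames(features) <- paste0("f", seq_len(ncol(features)))
  df <- as.data.frame(features)
  names(df) <- make.names(names(df), unique = TRUE)
  df$.label <- factor(as.character(labels))
  fit <- ranger::ranger(
    dependent.variable.name = ".label", data = df,
    num.trees = num_trees, importance = "impurity",
    splitrule = "extratrees", num.random.splits = 1L,
    seed = as.integer(seed), num.threads = 1L)
  imp <- fit$variable.importance
  ord <- order(imp, decreasing = TRUE)
  if (mode == "percentile") {
    n_keep <- max(1L, ceiling(ncol(features) * value / 100))
  } else {
    n_keep <- as.integer(value)
    if (n_keep > ncol(features)) {
      warning("top_n = ", n_keep, " exceeds feature count (",
              ncol(features), "); clipped")
      n_keep <- ncol(features)
    }
  }
  selected <- colnames(features)[ord[seq_len(n_keep)]]
  attr(selected, "importance") <- imp[ord]
  selected
}

#' Apply a decision threshold to driver scores
#'
#' Scores strictly above the threshold are called driver, all others
#' passenger.
#'
#' @param scores numeric vector in [0, 1].
#' @param threshold scalar in [0, 1].
#' @return character vector of \code{"driver"}/\code{"passenger"} calls.
#' @export
apply_threshold <- function(scores, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 1)
    stop2("threshold must be a scalar in [0, 1]")
  if (any(scores < 0 | scores > 1)) stop2("scores must lie in [0, 1]")
  ifelse(scores > threshold, "driver", "passenger")
}

#' Combine binary calls from several predictors
#'
#' \code{"majority"}: the label with most votes wins, ties go to driver
#' (the sensitivity-favoring convention).  \code{"at_least_p"}: driver iff
#' at least \code{p} members called driver.
#'
#' @param calls matrix or data.frame of 0/1 (or
#'   \code{"driver"}/\code{"passenger"}) calls, one column per member, or a
#'   vector for a single mutation; missing calls are an error.
#' @param mode \code{"majority"} or \code{"at_least_p"}.
#' @param p required driver votes for \code{"at_least_p"}.
#' @return character vector of combined calls.
#' @export
vote <- function(calls, mode = c("majority", "at_least_p"), p = NULL) {
  mode <- match.arg(mode)
  if (is.vector(calls) && !is.list(calls)) calls <- matrix(calls, nrow = 1L)
  calls <- as.matrix(calls)
  if (is.character(calls)) {
    bad <- !(calls %in% c("driver", "passenger"))
    if (any(bad)) stop2("calls must be driver/passenger or 0/1")
    calls <- matrix(as.integer(calls == "driver"), nrow = nrow(calls))
  }
  if (anyNA(calls)) stop2("missing member call (no silent abstention)")
  n_members <- ncol(calls)
  driver_votes <- rowSums(calls)
  if (mode == "majority") {
    return(ifelse(driver_votes >= n_members / 2, "driver", "passenger"))
  }
  if (is.null(p) || !is_count(p) || p < 1 || p > n_members)
    stop2("p must be an integer in 1..", n_members)
  ifelse(driver_votes >= p, "driver", "passenger")
}
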