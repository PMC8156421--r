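## Class-conditional Gaussian kernel density estimation and
## Jensen-Shannon divergence against a label-randomization null.

#' Fit a Gaussian kernel density estimate with cross-validated bandwidth
#'
#' Places one isotropic Gaussian kernel per training point.  The bandwidth
#' is chosen from \code{bandwidth_grid} by k-fold cross-validation,
#' maximizing the mean held-out log-density.
#'
#' @param points numeric matrix (rows = observations) or vector (1-D).
#' @param bandwidth_grid positive scalars to try; a single value skips CV.
#' @param folds CV folds (default 5); \code{nrow(points)} must be >= folds.
#' @param seed integer seed for the fold assignment.
#' @return object of class \code{"kde_model"}: list with \code{bandwidth},
#'   \code{points}, \code{dim}, \code{cv_scores}.
#' @export
fit_kde <- function(points, bandwidth_grid, folds = 5L, seed = NULL) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (any(bandwidth_grid <= 0)) stop2("bandwidths must be positive")
  n <- nrow(points)
  bandwidth_grid <- as.numeric(bandwidth_grid)
  if (length(bandwidth_grid) == 1L) {   # nothing to select; no CV needed
    best <- bandwidth_grid
    scores <- NA_real_
  } else {
    if (n < folds) stop2("need at least ", folds, " rows to run ", folds,
                         "-fold bandwidth selection (got ", n, ")")
    fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
    scores <- vapply(bandwidth_grid, function(h) {
      tot <- 0
      for (f in seq_len(folds)) {
        train <- points[fold_id != f, , drop = FALSE]
        test <- points[fold_id == f, , drop = FALSE]
        tot <- tot + sum(kde_log_density_at(test, train, h))
      }
      tot / n
    }, numeric(1))
    best <- bandwidth_grid[which.max(scores)]
  }
  structure(list(bandwidth = best, points = points, dim = ncol(points),
                 cv_scores = scores, grid = bandwidth_grid),
            class = "kde_model")
}

# log density of rows of x under an isotropic Gaussian KDE on train with
# bandwidth h; pure matrix arithmetic, -Inf-safe via log-sum-exp
kde_log_density_at <- function(x, train, h) {
  x <- as.matrix(x); train <- as.matrix(train)
  d <- ncol(train)
  n <- nrow(train)
  d2 <- pairwise_sqdist(x, train)                     # |x| x n
  expo <- -d2 / (2 * h^2)
  m <- apply(expo, 1L, max)
  lse <- m + log(rowSums(exp(expo - m)))
  lse - log(n) - d * log(h) - d / 2 * log(2 * pi)
}

#' Evaluate the log density of a fitted KDE
#'
#' @param model a \code{"kde_model"} from [fit_kde()].
#' @param x numeric matrix or vector of evaluation points.
#' @return numeric vector of log densities.
#' @export
kde_log_density <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != model$dim)
    stop2("evaluation points have dimension ", ncol(x),
          ", model expects ", model$dim)
  kde_log_density_at(x, model$points, model$bandwidth)
}

#' @export
print.kde_model <- function(x, ...) {
  cat("Gaussian KDE:", nrow(x$points), "points,", x$dim,
      "dimension(s), bandwidth", format(x$bandwidth), "\n")
  invisible(x)
}

#' Jensen-Shannon distance between two probability vectors
#'
#' Square root of the Jensen-Shannon divergence with base-2 logarithms, so
#' the value lies in [0, 1]: 0 for identical distributions, 1 for disjoint
#' support.  Inputs are renormalized to sum to one (tolerance 1e-9).
#'
#' @param p,q non-negative vectors of equal length.
#' @return scalar in [0, 1].
#' @export
js_distance <- function(p, q) {
  if (length(p) != length(q)) stop2("p and q must have equal length")
  if (any(p < 0) || any(q < 0)) stop2("probability vectors must be >= 0")
  sp <- sum(p); sq <- sum(q)
  if (sp <= 0 || sq <= 0) stop2("zero-sum probability vector")
  p <- p / sp; q <- q / sq
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / b[nz]))
  }
  div <- 0.5 * kl(p, m) + 0.5 * kl(q, m)
  sqrt(max(0, min(1, div)))
}

default_bandwidth_grid <- function() 10^seq(-2, 1, length.out = 20L)

# Fit per-class KDEs on the two sample matrices and return the JS distance
# between the densities evaluated on the union of both samples.
js_between_kdes <- function(a, b, bandwidth_grid, folds, seed) {
  fit_a <- fit_kde(a, bandwidth_grid, folds, seed = derive_seed(seed, 1L))
  fit_b <- fit_kde(b, bandwidth_grid, folds, seed = derive_seed(seed, 2L))
  eval_pts <- rbind(a, b)
  da <- exp(kde_log_density(fit_a, eval_pts))
  db <- exp(kde_log_density(fit_b, eval_pts))
  da <- pmax(da, 1e-300)
  db <- pmax(db, 1e-300)
  js_distance(da / sum(da), db / sum(db))
}

#' One run of the class-divergence KDE experiment
#'
#' Samples \code{n_per_class} rows with replacement from each class, fits a
#' bandwidth-tuned Gaussian KDE per class, evaluates both densities on the
#' union of the two samples, normalizes to probability vectors and returns
#' the Jensen-Shannon distance.
#'
#' @param drivers,passengers numeric matrices of encoded neighborhoods.
#' @param n_per_class sample size per class (default: smaller class size).
#' @param bandwidth_grid bandwidths for [fit_kde()].
#' @param folds CV folds for bandwidth selection.
#' @param seed integer seed.
#' @return scalar JS distance in [0, 1].
#' @export
kde_js_run <- function(drivers, passengers, n_per_class = NULL,
                       bandwidth_grid = default_bandwidth_grid(),
                       folds = 5L, seed = NULL) {
  drivers <- as.matrix(drivers); passengers <- as.matrix(passengers)
  if (!nrow(drivers) || !nrow(passengers))
    stop2("both classes must be non-empty")
  n_per_class <- n_per_class %||% min(nrow(drivers), nrow(passengers))
  if (n_per_class < folds)
    stop2("n_per_class (", n_per_class, ") must be >= folds (", folds, ")")
  idx <- with_seed(seed, list(
    d = sample.int(nrow(drivers), n_per_class, replace = TRUE),
    p = sample.int(nrow(passengers), n_per_class, replace = TRUE)))
  js_between_kdes(drivers[idx$d, , drop = FALSE],
                  passengers[idx$p, , drop = FALSE],
                  bandwidth_grid, folds, seed = derive_seed(seed %||% 0L, 3L))
}

#' One run of the label-randomization null
#'
#' Samples \code{2 * n_per_class} rows with replacement from the pooled data
#' irrespective of labels, splits them randomly in half into two pseudo
#' classes, and proceeds exactly as [kde_js_run()].
#'
#' @param pool numeric matrix pooling both classes.
#' @inheritParams kde_js_run
#' @return scalar JS distance in [0, 1].
#' @export
randomized_null_run <- function(pool, n_per_class,
                                bandwidth_grid = default_bandwidth_grid(),
                                folds = 5L, seed = NULL) {
  pool <- as.matrix(pool)
  if (n_per_class < folds)
    stop2("n_per_class (", n_per_class, ") must be >= folds (", folds, ")")
  idx <- with_seed(seed, sample.int(nrow(pool), 2L * n_per_class,
                                    replace = TRUE))
  a <- pool[idx[seq_len(n_per_class)], , drop = FALSE]
  b <- pool[idx[n_per_class + seq_len(n_per_class)], , drop = FALSE]
  js_between_kdes(a, b, bandwidth_grid, folds,
                  seed = derive_seed(seed %||% 0L, 4L))
}

#' Run the full density-divergence experiment for one representation
#'
#' Repeats the original (labeled) and randomized (label-free) KDE
#' Jensen-Shannon runs \code{n_runs} times and reports the per-run
#' distances, their medians, and the empirical p-value: the fraction of
#' randomized runs whose distance exceeds the median original distance.
#'
#' @param drivers,passengers numeric matrices of encoded neighborhoods.
#' @param n_runs number of repetitions per arm (default 30).
#' @param n_per_class per-class sample size (default: smaller class size).
#' @param bandwidth_grid bandwidths for [fit_kde()].
#' @param folds CV folds for bandwidth selection.
#' @param seed integer seed driving all runs.
#' @param window_size,encoding optional bookkeeping fields carried into the
#'   result.
#' @return object of class \code{"density_comparison"}: list with
#'   \code{original}, \code{randomized} (length \code{n_runs} each),
#'   \code{median_original}, \code{median_randomized}, \code{p_value},
#'   \code{n_per_class}, \code{window_size}, \code{encoding}.
#' @export
run_density_experiment <- function(drivers, passengers, n_runs = 30L,
                                   n_per_class = NULL,
                                   bandwidth_grid = default_bandwidth_grid(),
                                   folds = 5L, seed = 1L,
                                   window_size = NA, encoding = NA) {
  if (!is_count(n_runs) || n_runs < 1) stop2("n_runs must be a positive integer")
  drivers <- as.matrix(drivers); passengers <- as.matrix(passengers)
  n_per_class <- n_per_class %||% min(nrow(drivers), nrow(passengers))
  pool <- rbind(drivers, passengers)
  original <- vapply(seq_len(n_runs), function(i)
    kde_js_run(drivers, passengers, n_per_class, bandwidth_grid, folds,
               seed = derive_seed(seed, 2L * i)), numeric(1))
  randomized <- vapply(seq_len(n_runs), function(i)
    randomized_null_run(pool, n_per_class, bandwidth_grid, folds,
                        seed = derive_seed(seed, 2L * i + 1L)), numeric(1))
  med_o <- median(original)
  structure(list(
    original = original,
    randomized = randomized,
    median_original = med_o,
    median_randomized = median(randomized),
    p_value = sum(randomized > med_o) / n_runs,
    n_per_class = n_per_class,
    window_size = window_size,
    encoding = encoding
  ), class = "density_comparison")
}

#' @export
print.density_comparison <- function(x, ...) {
  cat("Density divergence experiment (", length(x$original),
      " runs, n = ", x$n_per_class, " per class)\n", sep = "")
  if (!is.na(x$window_size))
    cat("  window size: ", x$window_size, "   encoding: ", x$encoding,
        "\n", sep = "")
  cat(sprintf("  median JS distance: original %.3f, randomized %.3f\n",
              x$median_original, x$median_randomized))
  cat(sprintf("  empirical p-value: %.3f%s\n", x$p_value,
              if (x$p_value < 0.05) " (significant)" else " (not significant)"))
  invisible(x)
}

#' Tidy per-run table of a density experiment
#'
#' @param x a \code{"density_comparison"} object.
#' @param ... unused.
#' @return \code{data.frame} with columns \code{window}, \code{encoding},
#'   \code{run}, \code{arm}, \code{distance}.
#' @export
as.data.frame.density_comparison <- function(x, ...) {
  n <- length(x$original)
  data.frame(
    window = rep(x$window_size, 2L * n),
    encoding = rep(x$encoding, 2L * n),
    run = rep(seq_len(n), 2L),
    arm = rep(c("original", "randomized"), each = n),
    distance = c(x$original, x$randomized),
    stringsAsFactors = FALSE
  )
}
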