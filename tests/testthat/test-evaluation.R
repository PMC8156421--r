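test_that("metrics agree with independent arithmetic on random matrices", {
  set.seed(1)
  for (i in 1:200) {
    tp <- sample(0:50, 1); fp <- sample(0:50, 1)
    fn <- sample(0:50, 1); tn <- sample(0:50, 1)
    if (tp + fp + fn + tn == 0) next
    m <- compute_metrics(confusion_matrix(tp = tp, fp = fp,
                                          fn = fn, tn = tn))
    if (tp + fn > 0) expect_equal(m$sensitivity, tp / (tp + fn))
    if (tn + fp > 0) expect_equal(m$specificity, tn / (tn + fp))
    if (tp + fp > 0) expect_equal(m$ppv, tp / (tp + fp))
    if (tn + fn > 0) expect_equal(m$npv, tn / (tn + fn))
    expect_equal(m$accuracy, (tp + tn) / (tp + fp + fn + tn))
    den <- as.numeric(tp + fp) * (tp + fn) * (tn + fn) * (tn + fp)
    expect_equal(m$mcc, if (den == 0) 0 else
      (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(den))
    expect_true(m$mcc >= -1 && m$mcc <= 1)
    # composite invariant: sum of the four defined rates
    parts <- c(m$sensitivity, m$specificity, m$ppv, m$npv)
    expect_equal(m$composite, sum(parts, na.rm = TRUE), tolerance = 1e-12)
    expect_true(m$composite >= 0 && m$composite <= 4)
  }
  m <- compute_metrics(confusion_matrix(tp = 5, fp = 0, fn = 0, tn = 5))
  expect_equal(m$mcc, 1); expect_equal(m$composite, 4)
  m <- compute_metrics(confusion_matrix(tp = 0, fp = 5, fn = 5, tn = 0))
  expect_equal(m$mcc, -1)
  expect_error(confusion_matrix(tp = 0, fp = 0, fn = 0, tn = 0), "empty")
})

test_that("confusion_matrix from calls matches counted cells", {
  calls <- c("driver", "driver", "passenger", "passenger", "driver")
  truth <- c("driver", "passenger", "driver", "passenger", "driver")
  cm <- confusion_matrix(calls = calls, truth = truth)
  expect_equal(unlist(cm[c("tp", "fp", "fn", "tn")]),
               c(tp = 2L, fp = 1L, fn = 1L, tn = 1L))
})

test_that("auroc equals brute-force pairwise counting", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1),
                     c("driver", "driver", "passenger", "passenger")), 1)
  expect_equal(auroc(rep(0.5, 6),
                     rep(c("driver", "passenger"), 3)), 0.5)
  expect_equal(auroc(c(0.9, 0.4, 0.6, 0.1),
                     c("driver", "driver", "passenger", "passenger")),
               0.75)
  # random short vectors vs exhaustive pairwise wins (ties count half)
  set.seed(2)
  for (i in 1:100) {
    n <- sample(2:8, 1)
    labels <- c("driver", "passenger",
                sample(c("driver", "passenger"), n - 2, TRUE))
    scores <- sample(seq(0, 1, 0.25), n, TRUE)   # force ties sometimes
    d <- scores[labels == "driver"]; p <- scores[labels == "passenger"]
    wins <- sum(outer(d, p, ">")) + 0.5 * sum(outer(d, p, "=="))
    expect_equal(auroc(scores, labels), wins / (length(d) * length(p)))
  }
  expect_error(auroc(1:3, rep("driver", 3)), "both classes")
})

test_that("auroc agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(3)
  scores <- runif(60)
  labels <- sample(c("driver", "passenger"), 60, TRUE)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores, levels = c("passenger", "driver"),
    direction = "<", quiet = TRUE)))
  expect_equal(auroc(scores, labels), ref, tolerance = 1e-12)
})

simple_pipeline <- function() {
  list(
    fit = function(x, y, seed) {
      # class-mean prototype classifier; no tuning needed
      list(mu_d = colMeans(x[y == "driver", , drop = FALSE]),
           mu_p = colMeans(x[y == "passenger", , drop = FALSE]))
    },
    score = function(fit, x) {
      dd <- rowSums(sweep(x, 2, fit$mu_d)^2)
      dp <- rowSums(sweep(x, 2, fit$mu_p)^2)
      1 / (1 + exp(dd - dp))
    })
}

test_that("repeated CV yields n_folds x n_repeats stratified values", {
  clouds <- two_clouds(n_per_class = 60, d = 2, gap = 4, seed = 4)
  res <- repeated_cv(clouds$x, clouds$labels, simple_pipeline(),
                     n_folds = 10, n_repeats = 3, seed = 1)
  expect_equal(nrow(res$values), 30L)
  expect_true(all(c("sensitivity", "specificity", "mcc", "auroc")
                  %in% names(res$values)))
  expect_gt(res$median["mcc"], 0.5)       # separable recovery
  expect_true(res$ci["auroc", "lower"] <= res$median["auroc"] ||
                res$ci["auroc", "upper"] >= res$median["auroc"])

  # label-independent features: AUROC near 1/2
  set.seed(5)
  x_null <- matrix(rnorm(240), ncol = 2)
  res_null <- repeated_cv(x_null, clouds$labels, simple_pipeline(),
                          n_folds = 10, n_repeats = 3, seed = 2)
  expect_gt(res_null$median["auroc"], 0.35)
  expect_lt(res_null$median["auroc"], 0.65)
  expect_error(repeated_cv(clouds$x[55:70, ], clouds$labels[55:70],
                           simple_pipeline(), n_folds = 10), "stratify")
})

test_that("repeated CV never leaks held-out rows into fitting", {
  clouds <- two_clouds(n_per_class = 30, d = 2, gap = 4, seed = 6)
  n <- nrow(clouds$x)
  seen <- list()
  probe <- simple_pipeline()
  base_fit <- probe$fit
  probe$fit <- function(x, y, seed) {
    fit <- base_fit(x, y, seed)
    fit$train_rows <- rownames(x)
    seen[[length(seen) + 1L]] <<- rownames(x)
    fit
  }
  base_score <- probe$score
  probe$score <- function(fit, x) {
    expect_length(intersect(fit$train_rows, rownames(x)), 0L)
    base_score(fit, x)
  }
  rownames(clouds$x) <- paste0("r", seq_len(n))
  res <- repeated_cv(clouds$x, clouds$labels, probe,
                     n_folds = 5, n_repeats = 2, seed = 3)
  expect_length(seen, 10L)
  expect_true(all(lengths(seen) < n))     # never the full data
})

test_that("bootstrap CI comparison flags real differences only", {
  set.seed(7)
  n <- 500
  labels <- sample(c("driver", "passenger"), n, TRUE)
  perfect <- as.numeric(labels == "driver")
  random <- runif(n)
  cmp <- bootstrap_ci_compare(perfect, random, labels, n_boot = 300,
                              seed = 1)
  expect_true(cmp$significant)
  expect_equal(cmp$ci_a, c(1, 1))
  # identical predictors: identical CIs, not significant
  cmp2 <- bootstrap_ci_compare(random, random, labels, n_boot = 300,
                               seed = 1)
  expect_identical(cmp2$ci_a, cmp2$ci_b)
  expect_false(cmp2$significant)
  # reproducible under the seed
  cmp3 <- bootstrap_ci_compare(perfect, random, labels, n_boot = 300,
                               seed = 1)
  expect_identical(cmp$ci_b, cmp3$ci_b)
})

test_that("window comparison emits one p-value per ordered pair", {
  set.seed(8)
  vals <- lapply(1:10, function(i) rnorm(30, mean = i * 0.01))
  names(vals) <- as.character(1:10)
  tab <- compare_windows(vals)
  expect_equal(nrow(tab), 45L)
  # identical vectors -> p = 1
  same <- list(a = rnorm(30), b = NULL); same$b <- same$a
  expect_equal(compare_windows(same)$p_value, 1)
  # constant shift -> significant for n = 30
  v <- rnorm(30)
  shifted <- list(a = v, b = v + 1)
  expect_lt(compare_windows(shifted)$p_value, 0.05)
  expect_lt(compare_windows(shifted, test = "mann_whitney_u")$p_value,
            0.05)
  uneq <- list(a = rnorm(10), b = rnorm(12))
  expect_error(compare_windows(uneq), "equal-length")
  expect_equal(nrow(compare_windows(uneq, test = "mann_whitney_u")), 1L)
})
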