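test_that("KDE classifier priors are the training class fractions", {
  clouds <- two_clouds(n_per_class = 20, d = 1, gap = 6, seed = 1)
  fit <- kde_classifier_fit(clouds$x, clouds$labels,
                            bandwidth_grid = 0.5)
  expect_equal(unname(exp(fit$log_priors)), c(0.5, 0.5))
  # the imbalanced pre-rebalancing shape: 544 drivers / 4005 passengers
  set.seed(2)
  labels <- rep(c("driver", "passenger"), c(544, 4005))
  x <- matrix(rnorm(4549), ncol = 1)
  fit2 <- kde_classifier_fit(x, labels, bandwidth_grid = 1)
  expect_equal(unname(exp(fit2$log_priors["driver"])), 544 / 4549,
               tolerance = 1e-12)
  expect_error(kde_classifier_fit(x, rep("driver", 4549),
                                  bandwidth_grid = 1), "both classes")
})

test_that("posteriors equal an explicit Bayes-rule oracle", {
  # tiny discrete fixture, exhaustive likelihood x prior normalization
  xd <- matrix(c(0, 0.5, 1), ncol = 1)
  xp <- matrix(c(4, 5), ncol = 1)
  x <- rbind(xd, xp)
  labels <- rep(c("driver", "passenger"), c(3, 2))
  h <- 0.7
  fit <- kde_classifier_fit(x, labels, bandwidth_grid = h)
  test_pts <- matrix(c(-1, 0.3, 2, 4.5, 7), ncol = 1)
  lik <- function(pt, train) mean(exp(-(pt - train)^2 / (2 * h^2)) /
                                    (sqrt(2 * pi) * h))
  oracle <- sapply(test_pts, function(pt) {
    pd <- lik(pt, xd) * (3 / 5)
    pp <- lik(pt, xp) * (2 / 5)
    pd / (pd + pp)
  })
  post <- kde_classifier_posterior(fit, test_pts)
  expect_equal(unname(post), oracle, tolerance = 1e-10)
  # complements sum to one by construction; bounds hold
  expect_true(all(post >= 0 & post <= 1))
})

test_that("posterior symmetry and confidence behave as Bayes predicts", {
  # mirror-symmetric fixture: passengers are the reflection of drivers
  # about x = 5, so the posterior at the midpoint is exactly 1/2
  set.seed(3)
  xd <- matrix(rnorm(40), ncol = 1)
  xp <- 10 - xd
  fit <- kde_classifier_fit(rbind(xd, xp),
                            rep(c("driver", "passenger"), each = 40),
                            bandwidth_grid = 0.8)
  expect_equal(unname(kde_classifier_posterior(fit, matrix(5))), 0.5,
               tolerance = 1e-10)
  deep <- matrix(mean(xd), ncol = 1)
  expect_gt(kde_classifier_posterior(fit, deep), 0.99)
  expect_error(kde_classifier_posterior(fit, matrix(1, 1, 3)), "dimension")
  # refit with the same seed reproduces the bandwidths
  clouds <- two_clouds(n_per_class = 40, d = 1, gap = 10, seed = 3)
  fit2 <- kde_classifier_fit(clouds$x, clouds$labels,
                             bandwidth_grid = c(0.3, 1), seed = 4)
  fit3 <- kde_classifier_fit(clouds$x, clouds$labels,
                             bandwidth_grid = c(0.3, 1), seed = 4)
  expect_identical(fit2$class_models$driver$bandwidth,
                   fit3$class_models$driver$bandwidth)
})

test_that("RENN leaves separated clusters alone and removes intruders", {
  clouds <- two_clouds(n_per_class = 25, d = 2, gap = 12, seed = 5)
  out <- renn_undersample(clouds$x, clouds$labels, k = 3)
  expect_identical(out$kept, seq_len(50L))

  # one majority point planted inside the minority cluster is removed
  labels <- rep(c("passenger", "driver"), c(26, 25))   # passenger majority
  x <- rbind(clouds$x[clouds$labels == "passenger", ],
             matrix(c(0.1, 0.1), 1, 2),                # intruder at minority
             clouds$x[clouds$labels == "driver", ])
  out2 <- renn_undersample(x, labels, k = 3)
  expect_false(26L %in% out2$kept)
  expect_equal(sum(out2$labels == "driver"), 25L)      # minority preserved
  expect_true(all(out2$kept %in% seq_len(nrow(x))))    # subset of input

  # idempotence: a second application is a fixed point
  out3 <- renn_undersample(out2$features, out2$labels, k = 3)
  expect_identical(out3$kept, seq_len(nrow(out2$features)))

  expect_error(renn_undersample(x, labels, k = 60), "smaller")
  expect_error(renn_undersample(x, rep("driver", nrow(x)), k = 3),
               "both classes")
})

test_that("kNN imputation honors gene restriction and brute-force means", {
  x <- matrix(c(1, 2, 3, 4,
                1, 2, 3, NA), ncol = 2)
  expect_identical(knn_impute(matrix(1:4, 2)), matrix(1:4, 2))
  # k = 1 with one same-gene neighbor copies its value
  genes <- c("g1", "g2", "g2", "g2")
  x1 <- matrix(c(0, 5, 5.1, 5.2,
                 9, 7, NA, 8), ncol = 2)
  out <- knn_impute(x1, gene_keys = genes, k = 1)
  expect_equal(out[3, 2], 7)   # nearest same-gene complete row is row 2
  # k = 2 averaging two equidistant neighbors valued 1 and 3 -> 2
  x2 <- matrix(c(0, 2, 1,
                 1, 3, NA), ncol = 2)
  out2 <- knn_impute(x2, k = 2)
  expect_equal(out2[3, 2], 2)
  expect_error(knn_impute(matrix(c(1, 2, NA, NA), 2)), "no observed")
})

test_that("impurity selection ranks a label-copy feature first", {
  set.seed(6)
  n <- 200
  labels <- rep(c("driver", "passenger"), each = n / 2)
  x <- cbind(copy = as.numeric(labels == "driver"),
             matrix(rnorm(n * 9), ncol = 9,
                    dimnames = list(NULL, paste0("noise", 1:9))))
  sel <- impurity_select(x, labels, mode = "top_n", value = 3, seed = 1)
  expect_equal(sel[1], "copy")
  expect_length(sel, 3L)
  # percentile mode keeps the stated fraction
  sel30 <- impurity_select(x, labels, mode = "percentile", value = 30,
                           seed = 1)
  expect_length(sel30, 3L)   # ceiling(10 * 0.30)
  expect_warning(selc <- impurity_select(x, labels, mode = "top_n",
                                         value = 50, seed = 1), "clipped")
  expect_length(selc, 10L)
  # deterministic given the seed
  expect_identical(sel, impurity_select(x, labels, mode = "top_n",
                                        value = 3, seed = 1))
})

test_that("threshold application follows the strict-greater rule", {
  expect_equal(apply_threshold(c(0.2), 0.119), "driver")
  expect_equal(apply_threshold(c(0.119), 0.119), "passenger")
  expect_true(all(apply_threshold(runif(20), 1.0) == "passenger"))
  scores <- c(0, 0.01, 0.5)
  expect_equal(apply_threshold(scores, 0),
               c("passenger", "driver", "driver"))
  expect_error(apply_threshold(0.5, 1.5), "\\[0, 1\\]")
  expect_error(apply_threshold(c(-0.1), 0.5), "\\[0, 1\\]")
})

test_that("vote combination implements at-least-p and majority rules", {
  expect_equal(vote(c(0, 0, 0, 1), mode = "at_least_p", p = 1), "driver")
  expect_equal(vote(c(1, 1, 1, 0), mode = "at_least_p", p = 4), "passenger")
  expect_equal(vote(c(1, 1, 0), mode = "majority"), "driver")
  expect_equal(vote(c(1, 0, 0), mode = "majority"), "passenger")
  expect_equal(vote(c(1, 1, 0, 0), mode = "majority"), "driver")  # tie
  calls <- rbind(c(1, 0, 1), c(0, 0, 1))
  expect_equal(vote(calls, mode = "majority"), c("driver", "passenger"))
  expect_equal(vote(matrix(c("driver", "passenger"), 1),
                    mode = "at_least_p", p = 1), "driver")
  expect_error(vote(c(1, NA, 0), mode = "majority"), "missing")
  expect_error(vote(c(1, 0), mode = "at_least_p", p = 3), "p must be")
  # at_least_p with p = ceil((n+1)/2) coincides with majority on odd panels
  set.seed(7)
  for (i in 1:20) {
    calls <- matrix(rbinom(15, 1, 0.5), ncol = 5)
    expect_equal(vote(calls, "at_least_p", p = 3), vote(calls, "majority"))
  }
})

test_that("threshold search maximizes the requested objective", {
  scores <- c(0.05, 0.2, 0.6, 0.9, 0.15, 0.3)
  labels <- c("passenger", "passenger", "driver", "driver", "passenger",
              "driver")
  thr <- search_threshold(scores, labels, step = 0.05)
  # brute-force oracle over the same grid
  grid <- seq(0, 1, by = 0.05)
  comp <- sapply(grid, function(t) {
    m <- compute_metrics(confusion_matrix(
      calls = apply_threshold(scores, t), truth = labels))
    m$composite
  })
  expect_equal(thr, grid[which.max(comp)])
})
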