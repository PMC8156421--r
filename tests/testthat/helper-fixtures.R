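# Shared fixtures, all built in code at test time.

toy_genome <- function() c(chr1 = "ACGTACGTACG")

# Two well-separated Gaussian clouds in d dimensions.
two_clouds <- function(n_per_class = 30, d = 2, gap = 10, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * d, 0), ncol = d),
             matrix(rnorm(n_per_class * d, gap), ncol = d))
  list(x = x,
       labels = rep(c("driver", "passenger"), each = n_per_class))
}

# Small synthetic benchmark; divergent = TRUE separates the class context
# models (GC-rich driver flanks vs AT-rich passenger flanks).
small_bench <- function(n_drivers = 60, n_passengers = 120,
                        divergent = FALSE, seed = 7,
                        contig_length = 10000, n_contigs = 1,
                        strength = 0.85) {
  ctx <- if (divergent) drivernb:::divergent_context_models(strength)
         else list(driver = NULL, passenger = NULL)
  spec <- synthetic_spec(
    n_contigs = n_contigs, contig_length = contig_length,
    n_drivers = n_drivers, n_passengers = n_passengers,
    driver_context = ctx$driver, passenger_context = ctx$passenger,
    seed = seed)
  generate_benchmark(spec)
}

# Independent KL-based Jensen-Shannon oracle (base-2, distance form).
js_oracle <- function(p, q) {
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / b[nz]))
  }
  sqrt(0.5 * kl(p, m) + 0.5 * kl(q, m))
}

# Brute-force Gaussian-KDE log density at points x.
kde_oracle <- function(x, train, h) {
  x <- as.matrix(x); train <- as.matrix(train)
  d <- ncol(train)
  sapply(seq_len(nrow(x)), function(i) {
    dens <- mean(sapply(seq_len(nrow(train)), function(j) {
      exp(-sum((x[i, ] - train[j, ])^2) / (2 * h^2)) /
        ((2 * pi)^(d / 2) * h^d)
    }))
    log(dens)
  })
}
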