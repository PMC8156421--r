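## Synthetic genomes, class-labeled mutations with controllable
## neighborhood-context divergence, and descriptive feature tables.
## Everything is bit-reproducible under a fixed seed, so the whole
## pipeline is testable without external downloads.

#' Specification for synthetic data generation
#'
#' Bundles the knobs of the generator.  Context models are first-order
#' Markov transition matrices over A, C, G, T (rows sum to 1); a mutation's
#' flanks are sampled from its class's chain, so driver and passenger
#' neighborhoods can be made arbitrarily similar or divergent.
#'
#' Descriptive-feature defaults emulate class-shifted annotation features:
#' a binary PTM-site-like indicator with class rates 0.31 (drivers) versus
#' 0.004 (passengers), a binary region-of-interest-like indicator (0.37 vs
#' 0.11), and Gaussian conservation-like scores with a configurable class
#' mean shift; a small fraction of entries (default 0.001) is masked as
#' missing.
#'
#' @param n_contigs,contig_length genome shape (defaults 2 x 50000).
#' @param gc background GC content (default 0.5).
#' @param n_drivers,n_passengers class counts (defaults 150 / 600, roughly
#'   the 1:4 imbalance of curated driver/passenger compilations).
#' @param driver_context,passenger_context 4x4 Markov transition matrices
#'   (rows/cols A, C, G, T); \code{NULL} means uniform.
#' @param ptm_rates,region_rates length-2 vectors (driver, passenger) of
#'   Bernoulli rates.
#' @param conservation_shift mean shift of drivers on the two Gaussian
#'   conservation-like features (default 1).
#' @param missing_rate fraction of descriptive cells masked NA
#'   (default 0.001).
#' @param seed integer seed.
#' @return list of class \code{"synthetic_spec"}.
#' @export
synthetic_spec <- function(n_contigs = 2L, contig_length = 50000L,
                           gc = 0.5,
                           n_drivers = 150L, n_passengers = 600L,
                           driver_context = NULL, passenger_context = NULL,
                           ptm_rates = c(0.31, 0.004),
                           region_rates = c(0.37, 0.11),
                           conservation_shift = 1,
                           missing_rate = 0.001,
                           seed = 1L) {
  check_context <- function(m, what) {
    if (is.null(m)) return(matrix(0.25, 4, 4,
                                  dimnames = list(BASES, BASES)))
    m <- as.matrix(m)
    if (!all(dim(m) == c(4L, 4L)) || any(m < 0) ||
        any(abs(rowSums(m) - 1) > 1e-8))
      stop2(what, " must be a 4x4 transition matrix with rows summing to 1")
    dimnames(m) <- list(BASES, BASES)
    m
  }
  if (any(c(ptm_rates, region_rates) < 0) ||
      any(c(ptm_rates, region_rates) > 1))
    stop2("class rates must lie in [0, 1]")
  if (missing_rate < 0 || missing_rate > 1)
    stop2("missing_rate must lie in [0, 1]")
  if (n_drivers < 1L || n_passengers < 1L)
    stop2("both classes need at least one mutation")
  structure(list(
    n_contigs = as.integer(n_contigs),
    contig_length = as.integer(contig_length),
    gc = gc,
    n_drivers = as.integer(n_drivers),
    n_passengers = as.integer(n_passengers),
    driver_context = check_context(driver_context, "driver_context"),
    passenger_context = check_context(passenger_context,
                                      "passenger_context"),
    ptm_rates = ptm_rates, region_rates = region_rates,
    conservation_shift = conservation_shift,
    missing_rate = missing_rate,
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

# A GC-rich-flank vs AT-rich-flank pair of strongly divergent chains.
divergent_context_models <- function(strength = 0.9) {
  gc_rich <- matrix(rep(c((1 - strength) / 2, strength / 2,
                          strength / 2, (1 - strength) / 2), each = 4),
                    4, 4, dimnames = list(BASES, BASES))
  at_rich <- matrix(rep(c(strength / 2, (1 - strength) / 2,
                          (1 - strength) / 2, strength / 2), each = 4),
                    4, 4, dimnames = list(BASES, BASES))
  list(driver = gc_rich, passenger = at_rich)
}

#' Generate a random toy genome
#'
#' Uniform-random (optionally GC-biased) background sequence; deterministic
#' under the spec's seed.
#'
#' @param spec a [synthetic_spec()].
#' @param path optional FASTA path to write.
#' @return named character vector of contigs (attribute \code{"path"} set
#'   when written).
#' @export
generate_genome <- function(spec, path = NULL) {
  if (spec$contig_length < 21L)
    stop2("contig_length must cover at least one full window (>= 21)")
  probs <- c(A = (1 - spec$gc) / 2, C = spec$gc / 2,
             G = spec$gc / 2, T = (1 - spec$gc) / 2)
  contigs <- with_seed(spec$seed, {
    vapply(seq_len(spec$n_contigs), function(i)
      paste(sample(BASES, spec$contig_length, replace = TRUE,
                   prob = probs), collapse = ""), character(1))
  })
  # numeric contig names map directly onto the standard chromosome codes
  names(contigs) <- as.character(seq_len(spec$n_contigs))
  if (!is.null(path)) {
    set <- Biostrings::DNAStringSet(contigs)
    Biostrings::writeXStringSet(set, path)
    attr(contigs, "path") <- path
  }
  contigs
}

# Sample a sequence of given length from a first-order Markov chain.
sample_markov <- function(len, transition) {
  s <- character(len)
  s[1] <- sample(BASES, 1L, prob = colMeans(transition))
  if (len > 1L) for (i in 2:len)
    s[i] <- sample(BASES, 1L, prob = transition[s[i - 1L], ])
  s
}

#' Plant class-labeled mutations into a genome
#'
#' Chooses non-overlapping sites (window spacing >= 21 bp), rewrites each
#' site's +/-10 bp window with a sequence drawn from the mutation class's
#' Markov context model, reads the reference base from the rewritten
#' genome, and samples an alternate base different from it.
#'
#' @param genome named character vector of contigs (see
#'   [generate_genome()]).
#' @param spec a [synthetic_spec()].
#' @return list with \code{genome} (rewritten contigs) and
#'   \code{mutations} (labeled mutation \code{data.frame}).
#' @export
plant_mutations <- function(genome, spec) {
  n_total <- spec$n_drivers + spec$n_passengers
  if (spec$n_drivers < 1L || spec$n_passengers < 1L)
    stop2("both classes need at least one mutation")
  half <- 10L; win <- 2L * half + 1L
  # non-overlapping candidate sites on a fixed lattice per contig
  sites <- do.call(rbind, lapply(names(genome), function(ct) {
    len <- nchar(genome[[ct]])
    pos <- seq(half + 1L, len - half, by = win + 1L)
    data.frame(chrom = ct, pos = pos, stringsAsFactors = FALSE)
  }))
  if (nrow(sites) < n_total)
    stop2("genome too small: ", nrow(sites), " sites available for ",
          n_total, " mutations")
  with_seed(derive_seed(spec$seed, 101L), {
    pick <- sites[sample.int(nrow(sites), n_total), ]
    labels <- sample(rep(c("driver", "passenger"),
                         c(spec$n_drivers, spec$n_passengers)))
    chains <- list(driver = spec$driver_context,
                   passenger = spec$passenger_context)
    refs <- character(n_total); alts <- character(n_total)
    for (i in seq_len(n_total)) {
      ctx <- paste(sample_markov(win, chains[[labels[i]]]), collapse = "")
      ct <- pick$chrom[i]; pos <- pick$pos[i]
      g <- genome[[ct]]
      substr(g, pos - half, pos + half) <- ctx
      genome[[ct]] <- g
      refs[i] <- substr(ctx, half + 1L, half + 1L)
      alts[i] <- sample(setdiff(BASES, refs[i]), 1L)
    }
    mutations <- data.frame(
      chrom = pick$chrom, pos = pick$pos, ref = refs, alt = alts,
      label = labels,
      gene = paste0("gene", 1L + (pick$pos %/% 5000L)),
      stringsAsFactors = FALSE)
    mutations <- mutations[order(mutations$chrom, mutations$pos), ]
    rownames(mutations) <- NULL
    list(genome = genome, mutations = mutations)
  })
}

#' Generate a synthetic descriptive feature table
#'
#' Emulates class-shifted annotation features: binary PTM-site-like and
#' region-of-interest-like indicators with class-specific rates, and two
#' Gaussian conservation-like scores whose driver mean is shifted by
#' \code{conservation_shift}.  A fraction \code{missing_rate} of cells is
#' masked \code{NA}.
#'
#' @param mutations labeled mutation \code{data.frame}.
#' @param spec a [synthetic_spec()].
#' @return \code{data.frame} with a \code{key} column and feature columns
#'   \code{ptm_site}, \code{region_of_interest}, \code{conservation1},
#'   \code{conservation2}.
#' @export
generate_descriptive_features <- function(mutations, spec) {
  if (!all(mutations$label %in% c("driver", "passenger")))
    stop2("mutations must be labeled")
  n <- nrow(mutations)
  is_d <- mutations$label == "driver"
  with_seed(derive_seed(spec$seed, 202L), {
    ptm <- rbinom(n, 1L, ifelse(is_d, spec$ptm_rates[1], spec$ptm_rates[2]))
    roi <- rbinom(n, 1L, ifelse(is_d, spec$region_rates[1],
                                spec$region_rates[2]))
    cons1 <- rnorm(n, mean = ifelse(is_d, spec$conservation_shift, 0))
    cons2 <- rnorm(n, mean = ifelse(is_d, spec$conservation_shift / 2, 0))
    out <- data.frame(key = mutation_key(mutations),
                      ptm_site = as.numeric(ptm),
                      region_of_interest = as.numeric(roi),
                      conservation1 = cons1, conservation2 = cons2,
                      stringsAsFactors = FALSE)
    if (spec$missing_rate > 0) {
      cells <- as.matrix(out[-1])
      mask <- matrix(runif(length(cells)) < spec$missing_rate,
                     nrow = nrow(cells))
      cells[mask] <- NA
      out[-1] <- as.data.frame(cells)
    }
    out
  })
}

#' @importFrom stats rbinom
#' @export
print.synthetic_spec <- function(x, ...) {
  cat("Synthetic data spec: ", x$n_contigs, " contig(s) x ",
      x$contig_length, " bp, ", x$n_drivers, " drivers / ",
      x$n_passengers, " passengers, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Generate a complete synthetic benchmark
#'
#' Convenience wrapper: genome, planted labeled mutations and descriptive
#' features in one call; optionally writes the FASTA / TSV / CSV triple.
#'
#' @param spec a [synthetic_spec()].
#' @param dir optional output directory; files \code{genome.fa},
#'   \code{mutations.tsv}, \code{descriptive.csv} are written there.
#' @return list with \code{genome}, \code{mutations}, \code{descriptive},
#'   and \code{files} (paths or \code{NULL}).
#' @export
generate_benchmark <- function(spec, dir = NULL) {
  genome <- generate_genome(spec)
  planted <- plant_mutations(genome, spec)
  desc <- generate_descriptive_features(planted$mutations, spec)
  files <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    fa <- file.path(dir, "genome.fa")
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(planted$genome), fa)
    tsv <- file.path(dir, "mutations.tsv")
    write_mutations(planted$mutations, tsv)
    csv <- file.path(dir, "descriptive.csv")
    write.csv(desc, csv, row.names = FALSE)
    files <- c(genome = fa, mutations = tsv, descriptive = csv)
  }
  list(genome = planted$genome, mutations = planted$mutations,
       descriptive = desc, files = files)
}

#' @importFrom utils write.csv
NULL
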