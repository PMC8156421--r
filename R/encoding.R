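## Feature encodings: one-hot flanks, overlapping k-mers with Count or
## TF-IDF vectorization, and merging of descriptive genomic feature tables.

# Slot order for one-hot encoding.  Fixed so that A -> <1,0,0,0> and
# G -> <0,1,0,0>; the remaining two bases follow in the order C, T.
OHE_BASE_ORDER <- c("A", "G", "C", "T")

#' One-hot encode mutation neighborhoods
#'
#' Each of the 2n flanking bases (the center wild-type base is excluded)
#' becomes a 4-slot binary indicator in the slot order A, G, C, T; the
#' chromosome code and substitution-type code are appended as two ordinal
#' columns, giving exactly \code{8n + 2} columns for window size n.
#'
#' @param neighborhoods a \code{"neighborhoods"} object from
#'   [extract_neighborhoods()].
#' @return numeric matrix (rows keyed by mutation) with named columns
#'   \code{flank<p>_<base>}, \code{chromosome}, \code{substitution_type};
#'   flank positions are -n..-1, 1..n relative to the mutated site.
#' @export
one_hot_encode <- function(neighborhoods) {
  n <- attr(neighborhoods, "window_size")
  if (is.null(n)) stop2("neighborhoods must carry a window_size attribute")
  len <- 2L * n + 1L
  if (any(nchar(neighborhoods$sequence) != len))
    stop2("all neighborhoods must share one window size")
  m <- nrow(neighborhoods)
  offsets <- setdiff(seq_len(len), n + 1L)        # flank positions only
  rel <- ifelse(offsets <= n, offsets - n - 1L, offsets - n - 1L)
  cols <- as.vector(vapply(rel, function(r)
    paste0("flank", r, "_", OHE_BASE_ORDER), character(4)))
  mat <- matrix(0, nrow = m, ncol = 8L * n,
                dimnames = list(neighborhoods$key, cols))
  chars <- do.call(rbind, strsplit(neighborhoods$sequence, "", fixed = TRUE))
  for (j in seq_along(offsets)) {
    base_idx <- match(chars[, offsets[j]], OHE_BASE_ORDER)
    mat[cbind(seq_len(m), (j - 1L) * 4L + base_idx)] <- 1
  }
  cbind(mat,
        chromosome = neighborhoods$chrom_code,
        substitution_type = neighborhoods$subst_code)
}

#' Decompose a sequence into overlapping k-mers
#'
#' Left-to-right overlapping substrings of length k, duplicates retained.
#' The center wild-type base participates like any other base.
#'
#' @param sequence a nucleotide string.
#' @param k k-mer length, \code{2 <= k <= nchar(sequence)}.
#' @return character vector of \code{nchar(sequence) - k + 1} k-mers.
#' @examples
#' decompose_kmers("ATTTGGA", 2)  # AT TT TT TG GG GA
#' @export
decompose_kmers <- function(sequence, k) {
  if (!is_count(k) || k < 2) stop2("k must be an integer >= 2")
  len <- nchar(sequence)
  if (k > len) stop2("k (", k, ") exceeds sequence length (", len, ")")
  starts <- seq_len(len - k + 1L)
  substring(sequence, starts, starts + k - 1L)
}

#' Fit a k-mer vocabulary on a training corpus
#'
#' Learns the ordered set of distinct k-mers (lexicographic), the per-term
#' document frequency d_i (number of neighborhoods containing the term at
#' least once) and the corpus size N.  Test-time encodings must reuse a
#' vocabulary fitted on training data only.
#'
#' @param corpus list of character vectors of k-mers
#'   (see [decompose_kmers()]), one element per neighborhood.
#' @param k k-mer length recorded in the vocabulary.
#' @return object of class \code{"kmer_vocabulary"}: list with \code{k},
#'   \code{terms}, \code{doc_freq}, \code{n_docs}.
#' @export
fit_vocabulary <- function(corpus, k) {
  if (!length(corpus)) stop2("cannot fit a vocabulary on an empty corpus")
  terms <- sort(unique(unlist(corpus, use.names = FALSE)))
  df <- integer(length(terms))
  names(df) <- terms
  for (doc in corpus) {
    u <- unique(doc)
    df[u] <- df[u] + 1L
  }
  structure(list(k = as.integer(k), terms = terms, doc_freq = df,
                 n_docs = length(corpus)),
            class = "kmer_vocabulary")
}

#' @export
print.kmer_vocabulary <- function(x, ...) {
  cat("k-mer vocabulary: k =", x$k, "|", length(x$terms), "terms over",
      x$n_docs, "neighborhoods\n")
  invisible(x)
}

# corpus -> m x |vocab| raw count matrix; out-of-vocabulary terms ignored
term_count_matrix <- function(corpus, vocab) {
  m <- length(corpus)
  mat <- matrix(0, nrow = m, ncol = length(vocab$terms),
                dimnames = list(names(corpus), vocab$terms))
  for (j in seq_len(m)) {
    tab <- table(corpus[[j]])
    hit <- intersect(names(tab), vocab$terms)
    if (length(hit)) mat[j, hit] <- as.numeric(tab[hit])
  }
  mat
}

#' Count-vectorize a k-mer corpus
#'
#' Entry (j, i) is the number of occurrences of vocabulary term i in
#' neighborhood j.  Terms absent from the vocabulary contribute nothing
#' (the transform discipline for unseen test data).
#'
#' @param corpus list of k-mer vectors; names become row names.
#' @param vocab a fitted [fit_vocabulary()] object.
#' @return non-negative integer-valued matrix, columns named by term.
#' @export
count_vectorize <- function(corpus, vocab) {
  stopifnot(inherits(vocab, "kmer_vocabulary"))
  term_count_matrix(corpus, vocab)
}

#' TF-IDF-vectorize a k-mer corpus
#'
#' Two variants are provided.  \code{"paper_formula"} is the plain
#' tf-idf score \eqn{freq_{ij} \log(N / d_i)} with the natural logarithm and
#' no row normalization.  \code{"smoothed_l2"} (default) is the common
#' vectorizer convention: \eqn{idf_i = \log((1 + N)/(1 + d_i)) + 1} followed
#' by row-wise L2 normalization.
#'
#' @param corpus list of k-mer vectors.
#' @param vocab a fitted [fit_vocabulary()] object (supplies N and d_i).
#' @param variant \code{"smoothed_l2"} (default) or \code{"paper_formula"}.
#' @return numeric matrix with one column per vocabulary term.
#' @export
tfidf_vectorize <- function(corpus, vocab,
                            variant = c("smoothed_l2", "paper_formula")) {
  variant <- match.arg(variant)
  stopifnot(inherits(vocab, "kmer_vocabulary"))
  if (any(vocab$doc_freq < 1L))
    stop2("vocabulary term with zero document frequency: inconsistent fit")
  counts <- term_count_matrix(corpus, vocab)
  N <- vocab$n_docs
  if (variant == "paper_formula") {
    idf <- log(N / vocab$doc_freq)
    return(sweep(counts, 2L, idf, "*"))
  }
  idf <- log((1 + N) / (1 + vocab$doc_freq)) + 1
  mat <- sweep(counts, 2L, idf, "*")
  norms <- sqrt(rowSums(mat^2))
  norms[norms == 0] <- 1
  mat / norms
}

#' Encode neighborhoods under one representation
#'
#' Convenience wrapper producing the full feature matrix for one of the
#' seven representations: one-hot (\code{"ohe"}), k-mer counts
#' (\code{"cv"}, k = 2, 3, 4) or k-mer TF-IDF (\code{"tf"}, k = 2, 3, 4).
#' For k-mer representations the chromosome and substitution-type codes are
#' appended as two ordinal columns.  When \code{vocab} is \code{NULL} a
#' vocabulary is fitted on \code{neighborhoods} itself (training usage);
#' supply the training vocabulary to transform test data.
#'
#' @param neighborhoods a \code{"neighborhoods"} object.
#' @param representation \code{"ohe"}, \code{"cv"} or \code{"tf"}.
#' @param k k-mer length (required unless \code{representation = "ohe"}).
#' @param vocab optional previously fitted vocabulary.
#' @param tfidf_variant passed to [tfidf_vectorize()].
#' @return list with \code{features} (numeric matrix) and \code{vocab}
#'   (\code{NULL} for one-hot).
#' @export
encode_neighborhoods <- function(neighborhoods,
                                 representation = c("tf", "cv", "ohe"),
                                 k = NULL, vocab = NULL,
                                 tfidf_variant = c("smoothed_l2",
                                                   "paper_formula")) {
  representation <- match.arg(representation)
  tfidf_variant <- match.arg(tfidf_variant)
  if (representation == "ohe")
    return(list(features = one_hot_encode(neighborhoods), vocab = NULL))
  if (is.null(k)) stop2("k is required for k-mer representations")
  corpus <- lapply(neighborhoods$sequence, decompose_kmers, k = k)
  names(corpus) <- neighborhoods$key
  if (is.null(vocab)) vocab <- fit_vocabulary(corpus, k)
  core <- if (representation == "cv") count_vectorize(corpus, vocab)
          else tfidf_vectorize(corpus, vocab, tfidf_variant)
  feats <- cbind(core,
                 chromosome = neighborhoods$chrom_code,
                 substitution_type = neighborhoods$subst_code)
  list(features = feats, vocab = vocab)
}

#' Append descriptive genomic features to an encoded matrix
#'
#' Column-binds a per-mutation descriptive feature table (e.g. conservation
#' scores, protein-domain indicators) onto sequence-derived features,
#' matching rows on the mutation key.  Rows without a descriptive entry get
#' NA values and are flagged in the \code{"missing_rows"} attribute for a
#' later imputation stage.  Descriptive columns whose names collide with
#' sequence-feature columns are renamed with a \code{"desc_"} prefix.
#'
#' @param encoded numeric matrix with mutation keys as row names.
#' @param descriptive \code{data.frame} with a \code{key} column and numeric
#'   feature columns, or \code{NULL} (returns \code{encoded} unchanged).
#' @return numeric matrix; attribute \code{"missing_rows"} lists row keys
#'   lacking descriptive values.
#' @export
assemble_features <- function(encoded, descriptive = NULL) {
  if (is.null(descriptive)) return(encoded)
  if (!("key" %in% names(descriptive)))
    stop2("descriptive table must have a 'key' column")
  idx <- match(rownames(encoded), descriptive$key)
  dnames <- setdiff(names(descriptive), "key")
  dmat <- as.matrix(descriptive[idx, dnames, drop = FALSE])
  rownames(dmat) <- rownames(encoded)
  clash <- intersect(colnames(dmat), colnames(encoded))
  if (length(clash)) {
    message("descriptive column(s) renamed with 'desc_' prefix: ",
            paste(clash, collapse = ", "))
    colnames(dmat)[colnames(dmat) %in% clash] <-
      paste0("desc_", clash)
  }
  out <- cbind(encoded, dmat)
  missing_rows <- rownames(encoded)[is.na(idx) | !complete.cases(dmat)]
  attr(out, "missing_rows") <- missing_rows
  out
}
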