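## Mutation tables, reference genomes and neighborhood extraction.
##
## A mutation is a point substitution: (chromosome, 1-based position,
## reference base, alternate base), optionally labeled driver/passenger and
## annotated with a gene symbol.  All coordinates are 1-based, fully closed,
## forward strand.

SUBSTITUTION_ORDER <- c(
  "A>T", "A>G", "A>C",
  "T>A", "T>G", "T>C",
  "G>A", "G>C", "G>T",
  "C>T", "C>A", "C>G"
)

BASES <- c("A", "C", "G", "T")

#' Read a mutation table
#'
#' Reads point substitutions from a TSV file with header columns
#' \code{chrom, pos, ref, alt} and optional \code{label} and \code{gene},
#' or from a minimal VCF (CHROM/POS/REF/ALT; only single-nucleotide rows
#' are kept, skipped rows are counted in a warning).
#'
#' Rows with a non-ACGT allele or with \code{ref == alt} are rejected with a
#' row-indexed warning; labels are parsed case-insensitively.  Duplicate
#' records on (chrom, pos, ref, alt) are de-duplicated with a logged count.
#'
#' @param path file path.
#' @param dialect \code{"tsv"} (default) or \code{"vcf-min"}.
#' @return a \code{data.frame} with columns \code{chrom} (character),
#'   \code{pos} (integer), \code{ref}, \code{alt} (character),
#'   \code{label} (\code{"driver"}/\code{"passenger"}/\code{NA}) and
#'   \code{gene} (character or \code{NA}).
#' @seealso [write_mutations()], [extract_neighborhoods()]
#' @export
read_mutations <- function(path, dialect = c("tsv", "vcf-min")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop2("mutation file not found: ", path)
  if (dialect == "tsv") {
    tab <- read.delim(path, header = TRUE, sep = "\t",
                      colClasses = "character", check.names = FALSE)
    required <- c("chrom", "pos", "ref", "alt")
    missing <- setdiff(required, names(tab))
    if (length(missing))
      stop2("mutation table is missing required column(s): ",
            paste(missing, collapse = ", "))
    out <- data.frame(
      chrom = as.character(tab$chrom),
      pos   = suppressWarnings(as.integer(tab$pos)),
      ref   = toupper(as.character(tab$ref)),
      alt   = toupper(as.character(tab$alt)),
      label = if ("label" %in% names(tab))
        tolower(as.character(tab$label)) else
          rep(NA_character_, nrow(tab)),
      gene  = if ("gene" %in% names(tab))
        as.character(tab$gene) else rep(NA_character_, nrow(tab)),
      stringsAsFactors = FALSE
    )
    out$label[out$label %in% c("", "na")] <- NA_character_
    out$gene[out$gene %in% c("", "NA")] <- NA_character_
  } else {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#")]
    lines <- lines[nzchar(lines)]
    n_skipped <- 0L
    rows <- list()
    for (ln in lines) {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(f) < 4L) { n_skipped <- n_skipped + 1L; next }
      ref <- toupper(f[4]); alt <- toupper(f[5])
      if (nchar(ref) != 1L || nchar(alt) != 1L) {        # not an SNV
        n_skipped <- n_skipped + 1L; next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = f[1], pos = suppressWarnings(as.integer(f[2])),
        ref = ref, alt = alt,
        label = NA_character_, gene = NA_character_,
        stringsAsFactors = FALSE)
    }
    if (n_skipped > 0L)
      warning(n_skipped, " non-SNV or malformed VCF row(s) skipped")
    out <- if (length(rows)) do.call(rbind, rows) else
      data.frame(chrom = character(), pos = integer(), ref = character(),
                 alt = character(), label = character(), gene = character(),
                 stringsAsFactors = FALSE)
  }
  validate_mutations(out)
}

validate_mutations <- function(mut) {
  if (nrow(mut) == 0L) return(mut)
  bad_allele <- !(mut$ref %in% BASES) | !(mut$alt %in% BASES)
  bad_same <- !bad_allele & mut$ref == mut$alt
  bad_pos <- is.na(mut$pos) | mut$pos < 1L
  bad <- bad_allele | bad_same | bad_pos
  if (any(bad)) {
    warning(sum(bad), " invalid mutation row(s) skipped (rows ",
            paste(which(bad), collapse = ", "), "): ",
            sum(bad_allele), " non-ACGT allele, ",
            sum(bad_same), " ref==alt, ", sum(bad_pos), " bad position")
    mut <- mut[!bad, , drop = FALSE]
  }
  known <- is.na(mut$label) | mut$label %in% c("driver", "passenger")
  if (any(!known)) {
    warning(sum(!known), " row(s) with unrecognized label set to NA")
    mut$label[!known] <- NA_character_
  }
  key <- mutation_key(mut)
  dup <- duplicated(key)
  if (any(dup)) {
    message(sum(dup), " duplicate mutation record(s) removed")
    mut <- mut[!dup, , drop = FALSE]
  }
  rownames(mut) <- NULL
  mut
}

#' Mutation identifier strings
#'
#' Canonical per-mutation key \code{chrom:pos:ref>alt}, used to align
#' feature matrices and descriptive feature tables.
#'
#' @param mutations mutation \code{data.frame} (see [read_mutations()]).
#' @return character vector of keys.
#' @export
mutation_key <- function(mutations) {
  if (nrow(mutations) == 0L) return(character(0))
  paste0(mutations$chrom, ":", mutations$pos, ":",
         mutations$ref, ">", mutations$alt)
}

#' Write a mutation table
#'
#' Writes the canonicalized TSV form read back identically by
#' [read_mutations()].
#'
#' @param mutations mutation \code{data.frame}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_mutations <- function(mutations, path) {
  out <- mutations[, c("chrom", "pos", "ref", "alt", "label", "gene")]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Encode substitution type as an integer
#'
#' Maps the 12 possible point substitutions onto the fixed codes 0-11 in the
#' order A>T, A>G, A>C, T>A, T>G, T>C, G>A, G>C, G>T, C>T, C>A, C>G.
#'
#' @param ref,alt reference and alternate bases (vectors recycled together).
#' @return integer vector of codes in 0..11.
#' @export
substitution_code <- function(ref, alt) {
  if (length(ref) == 0L) return(integer(0))
  ref <- toupper(ref); alt <- toupper(alt)
  if (any(!(ref %in% BASES)) || any(!(alt %in% BASES)))
    stop2("ref and alt must be one of A, C, G, T")
  if (any(ref == alt))
    stop2("ref and alt must differ (point substitution)")
  match(paste0(ref, ">", alt), SUBSTITUTION_ORDER) - 1L
}

#' Encode chromosome names as integers
#'
#' 1-22 map to themselves, X to 23, Y to 24; any other contig gets a stable
#' hash bucket above 24 (with a warning), so toy contig names remain usable.
#'
#' @param chrom character vector of contig names (a "chr" prefix is ignored).
#' @return integer vector.
#' @export
chromosome_code <- function(chrom) {
  ch <- sub("^chr", "", as.character(chrom))
  code <- suppressWarnings(as.integer(ch))
  code[!is.na(code) & (code < 1L | code > 22L)] <- NA_integer_
  code[toupper(ch) == "X"] <- 23L
  code[toupper(ch) == "Y"] <- 24L
  other <- is.na(code)
  if (any(other)) {
    warning("non-standard contig name(s) hashed to codes above 24: ",
            paste(unique(ch[other]), collapse = ", "))
    code[other] <- vapply(ch[other], function(s) {
      25L + as.integer(sum(utf8ToInt(s) * seq_len(nchar(s))) %% 1000L)
    }, integer(1))
  }
  code
}

#' Load a reference genome
#'
#' Accepts a FASTA path, a \code{Biostrings::DNAStringSet}, or a named
#' character vector of contig sequences; returns the uppercase named
#' character form used internally.
#'
#' @param genome FASTA path, \code{DNAStringSet}, or named character vector.
#' @return named character vector of uppercase contig sequences.
#' @export
load_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    set <- Biostrings::readDNAStringSet(genome)
    seqs <- as.character(set)
    names(seqs) <- sub("\\s.*$", "", names(set))   # drop FASTA description
    return(toupper(seqs))
  }
  if (methods::is(genome, "DNAStringSet")) {
    seqs <- as.character(genome)
    names(seqs) <- sub("\\s.*$", "", names(genome))
    return(toupper(seqs))
  }
  if (is.character(genome) && !is.null(names(genome)))
    return(toupper(genome))
  stop2("genome must be a FASTA path, a DNAStringSet, ",
        "or a named character vector")
}

#' Extract the nucleotide neighborhood of mutations
#'
#' For each mutation, takes the forward-strand window of \code{window_size}
#' bases on each side of the mutated position (string length
#' \code{2*window_size + 1}, center = wild-type base).  If the genome base at
#' the position disagrees with the recorded reference base, the genome base
#' is kept as the center and the disagreement is reported with a warning.
#' Windows containing an ambiguous base (N or other non-ACGT) are skipped
#' with a warning by default, or raise an error when \code{on_ambiguous =
#' "error"}.
#'
#' @param mutations mutation \code{data.frame} (see [read_mutations()]).
#' @param genome anything accepted by [load_genome()].
#' @param window_size integer n in 1..10.
#' @param on_ambiguous \code{"skip"} (default) or \code{"error"}.
#' @return a \code{data.frame} of class \code{"neighborhoods"} with columns
#'   \code{key}, \code{sequence}, \code{chrom_code}, \code{subst_code},
#'   \code{label}, \code{gene}, and attribute \code{window_size}.
#' @export
extract_neighborhoods <- function(mutations, genome, window_size,
                                  on_ambiguous = c("skip", "error")) {
  on_ambiguous <- match.arg(on_ambiguous)
  if (!is_count(window_size) || window_size < 1 || window_size > 10)
    stop2("window_size must be an integer in 1..10")
  genome <- load_genome(genome)
  n <- as.integer(window_size)
  m <- nrow(mutations)
  seqs <- character(m)
  keep <- rep(TRUE, m)
  mismatches <- integer(0)
  for (i in seq_len(m)) {
    contig <- as.character(mutations$chrom[i])
    if (!(contig %in% names(genome)))
      stop2("contig not found in genome: ", contig)
    contig_seq <- genome[[contig]]
    pos <- mutations$pos[i]
    lo <- pos - n; hi <- pos + n
    if (lo < 1L || hi > nchar(contig_seq))
      stop2("window [", lo, ",", hi, "] overruns contig '", contig,
            "' (length ", nchar(contig_seq), ") for mutation row ", i)
    s <- substr(contig_seq, lo, hi)
    if (grepl("[^ACGT]", s)) {
      if (on_ambiguous == "error")
        stop2("ambiguous base in window of mutation row ", i)
      keep[i] <- FALSE
      next
    }
    center <- substr(s, n + 1L, n + 1L)
    if (center != mutations$ref[i]) mismatches <- c(mismatches, i)
    seqs[i] <- s
  }
  if (length(mismatches))
    warning(length(mismatches), " mutation(s) where the recorded ref base ",
            "disagrees with the genome (rows ",
            paste(head(mismatches, 10L), collapse = ", "),
            if (length(mismatches) > 10L) ", ..." else "",
            "); genome base kept as center")
  if (any(!keep))
    warning(sum(!keep), " neighborhood(s) skipped due to ambiguous bases")
  mut <- mutations[keep, , drop = FALSE]
  out <- data.frame(
    key = mutation_key(mut),
    sequence = seqs[keep],
    chrom_code = chromosome_code(mut$chrom),
    subst_code = substitution_code(mut$ref, mut$alt),
    label = mut$label %||% NA_character_,
    gene = mut$gene %||% NA_character_,
    stringsAsFactors = FALSE
  )
  attr(out, "window_size") <- n
  class(out) <- c("neighborhoods", "data.frame")
  out
}

#' @export
print.neighborhoods <- function(x, ...) {
  cat("Mutation neighborhoods: ", nrow(x), " sequence(s), window size ",
      attr(x, "window_size"), " (string length ",
      2L * attr(x, "window_size") + 1L, ")\n", sep = "")
  NextMethod()
}
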