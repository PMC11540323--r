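# Canonical k-mer composition features, GC content, distinct-k-mer fraction.

# all 4^k k-mer strings in lexicographic (= 2-bit code) order
all_kmers <- function(k) {
  bases <- c("A", "C", "G", "T")
  do.call(paste0, rev(expand.grid(rep(list(bases), k),
                                  stringsAsFactors = FALSE)))
}

#' Reverse complement of nucleotide strings
#'
#' @param x Character vector over `A`,`C`,`G`,`T`,`N`.
#' @return Reverse-complemented strings.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]),
                                   collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

#' Canonical k-mer feature index
#'
#' Builds the ordered set of canonical k-mer keys: each k-mer and its reverse
#' complement share one key, the lexicographic minimum of the two. For k = 4
#' this reduces the feature space from 256 to 136 and makes a read and its
#' reverse complement produce identical count vectors. Keys are sorted
#' lexicographically, fixing the feature (column) order.
#'
#' @param k K-mer size, 1..8.
#' @return An object of class `canonical_index` with elements `k`, `keys`
#'   (canonical k-mer strings) and `colmap` (0-based column for each of the
#'   4^k noncanonical codes).
#' @export
canonical_index <- function(k) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > 8L) stop("k must be an integer in [1, 8]")
  km <- all_kmers(k)
  canon <- pmin(km, revcomp(km))
  keys <- sort(unique(canon))
  colmap <- match(canon, keys) - 1L
  structure(list(k = k, keys = keys, colmap = colmap),
            class = "canonical_index")
}

#' @export
print.canonical_index <- function(x, ...) {
  cat("canonical_index: k =", x$k, "with", length(x$keys), "keys\n")
  invisible(x)
}

#' Canonical k-mer counts of one record
#'
#' Windows containing `N` are skipped; the vector sums to the number of valid
#' windows, at most `length - k + 1`.
#'
#' @param seq A single nucleotide string (already normalised to A/C/G/T/N).
#' @param index A [canonical_index()].
#' @return Named integer vector of counts over the index keys, with attribute
#'   `too_short = TRUE` when the sequence is shorter than k.
#' @export
count_canonical <- function(seq, index) {
  stopifnot(inherits(index, "canonical_index"))
  v <- .cpp_count_canonical(seq, index$k, index$colmap, length(index$keys))
  names(v) <- index$keys
  if (nchar(seq) < index$k) attr(v, "too_short") <- TRUE
  v
}

#' Canonical k-mer count matrix over a record stream
#'
#' Consumes a [seq_stream()] (or a record data frame) chunk by chunk, so
#' working memory is bounded by one chunk plus the accumulating matrix, never
#' by re-expanded sequence copies. Row order is input order.
#'
#' @param records A [seq_stream()] closure or a [seq_records()] data frame.
#' @param index A [canonical_index()].
#' @param min_length Records shorter than this are excluded from the matrix
#'   and reported in the `excluded` attribute (default: k).
#' @return Integer matrix (reads x keys) with rownames = read ids, colnames =
#'   canonical keys, and attribute `excluded` listing skipped read ids.
#' @export
count_matrix <- function(records, index, min_length = index$k) {
  stopifnot(inherits(index, "canonical_index"))
  nxt <- if (is.function(records)) records else {
    sent <- FALSE
    function() { if (sent) NULL else { sent <<- TRUE; records } }
  }
  blocks <- list()
  ids <- list()
  excluded <- character(0)
  while (!is.null(ch <- nxt())) {
    if (nrow(ch) == 0L) next
    short <- ch$length < min_length
    excluded <- c(excluded, ch$id[short])
    ch <- ch[!short, , drop = FALSE]
    if (nrow(ch) == 0L) next
    blocks[[length(blocks) + 1L]] <-
      .cpp_count_matrix(ch$seq, index$k, index$colmap, length(index$keys))
    ids[[length(ids) + 1L]] <- ch$id
  }
  m <- if (length(blocks) == 0L) {
    matrix(0L, nrow = 0L, ncol = length(index$keys))
  } else {
    do.call(rbind, blocks)
  }
  rownames(m) <- unlist(ids)
  colnames(m) <- index$keys
  attr(m, "excluded") <- excluded
  m
}

#' GC content of sequences
#'
#' (#G + #C) / (#A + #C + #G + #T); `N`s are excluded from both numerator and
#' denominator. All-N or empty sequences give `NA`.
#'
#' @param seq Character vector of nucleotide strings.
#' @return Numeric vector of GC fractions in `[0, 1]` (or `NA`).
#' @export
gc_content <- function(seq) {
  vapply(seq, function(s) {
    ct <- .cpp_gc_counts(s)
    if (ct[2L] == 0) NA_real_ else ct[1L] / ct[2L]
  }, numeric(1), USE.NAMES = FALSE)
}

#' Distinct (noncanonical) k-mer fraction
#'
#' Number of distinct noncanonical N-free k-mers divided by the number of
#' N-free k-mer windows; in (0, 1]. Low values flag repetitive sequence. The
#' default k = 8 is chosen so 4^k exceeds the expected length of a HiFi read,
#' ensuring the count of distinct k-mers is not limited by the alphabet.
#'
#' @param seq Character vector of nucleotide strings.
#' @param k K-mer size (default 8).
#' @return Numeric vector; `NA` for sequences with no valid window.
#' @export
unique_kmer_fraction <- function(seq, k = 8L) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > 15L) stop("k must be an integer in [1, 15]")
  out <- vapply(seq, .cpp_unique_kmer_fraction, numeric(1), k = k,
                USE.NAMES = FALSE)
  out[out < 0] <- NA_real_
  out
}

#' Persist / load a k-mer count matrix as TSV
#'
#' Tab-separated text with an `id` column followed by one column per
#' canonical key, so matrices are portable across runs.
#'
#' @param m Count matrix from [count_matrix()].
#' @param path Output path.
#' @return `path` (write) or the matrix (read).
#' @export
write_count_matrix <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_table_file(df, path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  df <- read_table_file(path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$id
  m
}
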