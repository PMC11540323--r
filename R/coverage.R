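# K-mer multiplicity coverage: whole-set canonical 31-mer table, per-read
# median multiplicity, coverage histogram, coverage bands.

#' Build a canonical k-mer multiplicity table over a read set
#'
#' Tallies every N-free canonical k-mer window across all reads. The median
#' of a read's window multiplicities approximates its sequencing coverage,
#' provided reads are accurate (high-error reads fragment k-mers and are not
#' suitable). Default k = 31: large enough that most k-mers are
#' genome-unique, small enough to tolerate HiFi error rates. Counts are
#' capped (default 2^16 - 1) with an overflow tally so pathological repeats
#' cannot blow up a count.
#'
#' @param records A [seq_stream()] closure or [seq_records()] data frame.
#' @param k Odd k-mer size, default 31.
#' @param cap Count ceiling.
#' @return An object of class `multiplicity_table` (opaque handle plus `k`).
#' @export
build_multiplicity_table <- function(records, k = 31L, cap = 65535) {
  ptr <- .cpp_mt_new(as.integer(k), as.numeric(cap))
  nxt <- if (is.function(records)) records else {
    sent <- FALSE
    function() { if (sent) NULL else { sent <<- TRUE; records } }
  }
  while (!is.null(ch <- nxt())) {
    if (nrow(ch) > 0L) .cpp_mt_add(ptr, ch$seq)
  }
  structure(list(ptr = ptr, k = as.integer(k)), class = "multiplicity_table")
}

#' @export
print.multiplicity_table <- function(x, ...) {
  s <- multiplicity_stats(x)
  cat(sprintf(
    "multiplicity_table: k=%d, %.0f distinct k-mers, %.0f windows (%.0f capped)\n",
    s$k, s$distinct, s$total_windows, s$cap_losses))
  invisible(x)
}

#' Summary statistics of a multiplicity table
#'
#' @param table A [build_multiplicity_table()] result.
#' @return List with `k`, `cap`, `distinct`, `total_windows`, `cap_losses`.
#' @export
multiplicity_stats <- function(table) {
  stopifnot(inherits(table, "multiplicity_table"))
  .cpp_mt_stats(table$ptr)
}

#' Median k-mer multiplicity of reads
#'
#' For each read, the lower median over its N-free windows of whole-set k-mer
#' multiplicities — the coverage proxy. Reads without a valid window give
#' `NA`.
#'
#' @param seq Character vector of read sequences.
#' @param table A [build_multiplicity_table()] result.
#' @return Integer vector of median multiplicities.
#' @export
median_read_multiplicity <- function(seq, table) {
  stopifnot(inherits(table, "multiplicity_table"))
  .cpp_mt_median(table$ptr, seq)
}

#' Coverage histogram of a multiplicity table
#'
#' For each multiplicity value c, the number of distinct k-mers seen exactly
#' c times — the classic k-mer spectrum used to judge whether a sample is
#' sequenced deep enough and whether high-coverage contaminants are present.
#'
#' @param table A [build_multiplicity_table()] result.
#' @return Data frame with columns `multiplicity` and `n_kmers`.
#' @export
coverage_histogram <- function(table) {
  stopifnot(inherits(table, "multiplicity_table"))
  .cpp_mt_histogram(table$ptr)
}

#' Persist / load a multiplicity table (small tables only)
#'
#' Written as two-column TSV (`kmer`, `count`) with a `#k=` header comment.
#'
#' @param table A `multiplicity_table`.
#' @param path Output path.
#' @return `path` (write) or a rebuilt `multiplicity_table` (read).
#' @export
write_multiplicity_table <- function(table, path) {
  stopifnot(inherits(table, "multiplicity_table"))
  d <- .cpp_mt_dump(table$ptr)
  con <- file(path, "wt")
  on.exit(close(con))
  s <- multiplicity_stats(table)
  writeLines(sprintf("#k=%d cap=%.0f", s$k, s$cap), con)
  writeLines("kmer\tcount", con)
  writeLines(paste(d$kmer, format(d$count, scientific = FALSE, trim = TRUE),
                   sep = "\t"), con)
  invisible(path)
}

#' @rdname write_multiplicity_table
#' @export
read_multiplicity_table <- function(path) {
  hdr <- readLines(path, n = 1L)
  m <- regmatches(hdr, regexec("#k=(\\d+) cap=(\\d+)", hdr))[[1L]]
  if (length(m) != 3L) stop("not a multiplicity table file: ", path)
  d <- read.delim(path, skip = 1L, header = TRUE, stringsAsFactors = FALSE)
  ptr <- .cpp_mt_load(as.integer(m[2L]), as.numeric(m[3L]), d$kmer,
                      as.numeric(d$count))
  structure(list(ptr = ptr, k = as.integer(m[2L])),
            class = "multiplicity_table")
}

#' Assign per-read coverage values to bands
#'
#' Bands are either manual `[low, high]` ranges (non-overlapping, ordered) or
#' automatic logarithmic (powers of 10) bins. Values outside every band —
#' including `NA`s from flagged reads — are labelled `"outside"`.
#'
#' @param values Numeric vector of per-read median multiplicities.
#' @param bands For `scheme = "manual"`: a list of `c(low, high)` pairs or a
#'   two-column matrix. Ignored for `scheme = "log"`.
#' @param scheme `"manual"` or `"log"`.
#' @return Character vector of band labels, plus a `"bands"` attribute with
#'   the band definitions used.
#' @export
assign_coverage_bins <- function(values, bands = NULL,
                                 scheme = c("manual", "log")) {
  scheme <- match.arg(scheme)
  if (scheme == "log") {
    pos <- values[!is.na(values) & values > 0]
    if (length(pos) == 0L) {
      lab <- rep("outside", length(values))
      attr(lab, "bands") <- matrix(numeric(0), ncol = 2)
      return(lab)
    }
    lo <- floor(log10(min(pos)))
    hi <- ceiling(log10(max(pos)) + 1e-9)
    if (hi == lo) hi <- lo + 1
    edges <- 10^(lo:hi)
    bands <- cbind(edges[-length(edges)], edges[-1L])
  } else {
    if (is.null(bands)) stop("manual scheme requires band definitions")
    if (is.list(bands)) bands <- do.call(rbind, bands)
    bands <- matrix(as.numeric(bands), ncol = 2L)
    if (any(bands[, 1L] > bands[, 2L])) stop("band low > high")
    o <- order(bands[, 1L])
    bands <- bands[o, , drop = FALSE]
    if (nrow(bands) > 1L &&
        any(bands[-1L, 1L] <= bands[-nrow(bands), 2L]))
      stop("overlapping coverage bands")
  }
  labels <- sprintf("[%g,%g]", bands[, 1L], bands[, 2L])
  out <- rep("outside", length(values))
  for (i in seq_len(nrow(bands))) {
    inband <- !is.na(values) & values >= bands[i, 1L] & values <= bands[i, 2L]
    out[inband] <- labels[i]
  }
  attr(out, "bands") <- bands
  out
}
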