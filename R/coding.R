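# Estimated coding density: hexamer log-odds table trained on coding
# sequence, composition-controlled scoring of reads, maximal scoring
# segments, predicted-coding-length / length ratio.

base_counts <- function(seqs) {
  out <- c(A = 0, C = 0, G = 0, T = 0)
  for (b in names(out)) {
    out[b] <- sum(nchar(seqs) - nchar(gsub(b, "", seqs, fixed = TRUE)))
  }
  out
}

#' Train a hexamer coding-potential table
#'
#' Hexamer (dicodon) frequencies are tallied over codon-aligned (stride-3,
#' frame 0) windows of the training coding sequences, pseudocounted and
#' normalised; each hexamer's score is the log-odds of that frequency against
#' a product-of-mononucleotides null computed from the same training set.
#' Hexamers enriched in coding sequence beyond what base composition alone
#' explains score positive.
#'
#' @param coding_records A [seq_records()] data frame of in-frame coding
#'   sequences (frame 0 assumed).
#' @param pseudocount Added to every hexamer count before normalisation.
#' @param source Free-text provenance tag stored with the table.
#' @return An object of class `hexamer_table`: `scores` (4096 log-odds),
#'   `coding_freq` (4096, sums to 1), `train_log_base` (log mononucleotide
#'   frequencies), `pseudocount`, `source`.
#' @export
train_hexamer_table <- function(coding_records, pseudocount = 1,
                                source = "user") {
  if (is.function(coding_records)) {
    chunks <- list()
    while (!is.null(ch <- coding_records()))
      chunks[[length(chunks) + 1L]] <- ch
    coding_records <- do.call(rbind, chunks)
  }
  if (is.null(coding_records) || nrow(coding_records) == 0L)
    stop("empty training set")
  counts <- .cpp_hexamer_counts(coding_records$seq)
  if (sum(counts) == 0) stop("training set contains no hexamer window")
  fc <- (counts + pseudocount) / sum(counts + pseudocount)
  bc <- base_counts(coding_records$seq)
  if (sum(bc) == 0) stop("training set contains no unambiguous base")
  fb <- (bc + pseudocount) / sum(bc + pseudocount)
  # null log-probability of each hexamer under the training mononucleotide model
  hex <- all_kmers(6L)
  log_f0 <- vapply(strsplit(hex, "", fixed = TRUE), function(ch) {
    sum(log(fb[ch]))
  }, numeric(1))
  scores <- log(fc) - log_f0
  names(scores) <- hex
  structure(list(scores = scores, coding_freq = fc,
                 train_log_base = log(fb), pseudocount = pseudocount,
                 source = source),
            class = "hexamer_table")
}

#' @export
print.hexamer_table <- function(x, ...) {
  cat(sprintf("hexamer_table: 4096 scores, source='%s', pseudocount=%g\n",
              x$source, x$pseudocount))
  invisible(x)
}

#' Scoring configuration for coding-density estimation
#'
#' @param threshold Minimum total score for a maximal scoring segment to
#'   count as predicted coding (default 20, in log-odds units).
#' @param both_strands Score the reverse complement's three frames too
#'   (default TRUE; the resulting density ratio may then exceed 1).
#' @return A list of class `coding_config`.
#' @export
coding_config <- function(threshold = 20, both_strands = TRUE) {
  if (!is.numeric(threshold) || threshold <= 0) stop("threshold must be > 0")
  structure(list(threshold = threshold, both_strands = isTRUE(both_strands)),
            class = "coding_config")
}

#' Predicted coding length of sequences
#'
#' For each of three frames per strand, stride-3 hexamer scores (adjusted to
#' the record's own mononucleotide composition) are decomposed into maximal
#' scoring segments; segments with total score >= threshold contribute their
#' base span. Spans are summed across frames and strands without merging.
#'
#' @param seq Character vector of nucleotide strings.
#' @param table A [train_hexamer_table()] result.
#' @param config A [coding_config()].
#' @return Numeric vector of predicted coding bases (0 for sequences shorter
#'   than 6).
#' @export
predicted_coding_length <- function(seq, table, config = coding_config()) {
  stopifnot(inherits(table, "hexamer_table"), inherits(config, "coding_config"))
  vapply(seq, .cpp_predicted_coding_length, numeric(1),
         scores = unname(table$scores),
         train_log_base = unname(table$train_log_base),
         threshold = config$threshold,
         both_strands = config$both_strands, USE.NAMES = FALSE)
}

#' Estimated coding density
#'
#' Ratio of [predicted_coding_length()] to sequence length. With both strands
#' scored the ratio can exceed 1 (up to 2), since overlapping predictions on
#' opposite strands are summed, not merged.
#'
#' @inheritParams predicted_coding_length
#' @return Numeric vector of density ratios in `[0, 2]`.
#' @export
coding_density <- function(seq, table, config = coding_config()) {
  len <- nchar(seq)
  pcl <- predicted_coding_length(seq, table, config)
  ifelse(len > 0, pcl / len, 0)
}

#' Maximal scoring segments of a score vector
#'
#' Linear-time Ruzzo-Tompa decomposition into all maximal scoring
#' subsequences; exposed so segment finding can be checked against brute
#' force.
#'
#' @param scores Numeric vector of per-position scores.
#' @param threshold Keep only segments with total score >= threshold
#'   (default: keep all).
#' @return Data frame with 1-based inclusive `start`, `end` and `score`.
#' @export
max_scoring_segments <- function(scores, threshold = -Inf) {
  d <- .cpp_max_scoring_segments(as.numeric(scores))
  d[d$score >= threshold, , drop = FALSE]
}

#' Persist / load a hexamer table as TSV
#'
#' Two columns (`hexamer`, `score`) plus `#` metadata comment lines carrying
#' the coding frequencies' source, pseudocount and training base frequencies.
#'
#' @param table A `hexamer_table`.
#' @param path Output path.
#' @return `path` (write) or a `hexamer_table` (read).
#' @export
write_hexamer_table <- function(table, path) {
  stopifnot(inherits(table, "hexamer_table"))
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c(sprintf("#source=%s", table$source),
               sprintf("#pseudocount=%.17g", table$pseudocount),
               sprintf("#train_log_base=%s",
                       paste(sprintf("%.17g", table$train_log_base),
                             collapse = ",")),
               "hexamer\tscore\tcoding_freq"), con)
  writeLines(sprintf("%s\t%.17g\t%.17g", names(table$scores),
                     table$scores, table$coding_freq), con)
  invisible(path)
}

#' @rdname write_hexamer_table
#' @export
read_hexamer_table <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  getm <- function(key) sub(paste0("#", key, "="), "",
                            meta[startsWith(meta, paste0("#", key, "="))])
  d <- read.delim(text = lines[!startsWith(lines, "#")], sep = "\t",
                  header = TRUE, stringsAsFactors = FALSE)
  scores <- setNames(d$score, d$hexamer)
  structure(list(scores = scores, coding_freq = d$coding_freq,
                 train_log_base = as.numeric(strsplit(getm("train_log_base"),
                                                      ",")[[1L]]),
                 pseudocount = as.numeric(getm("pseudocount")),
                 source = getm("source")),
            class = "hexamer_table")
}
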