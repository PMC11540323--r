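# Sequence I/O: streamed FASTA/FASTQ ingest, table read/write, FASTA export.

#' Construct a set of sequence records
#'
#' Records are held as a plain data frame with columns `id`, `seq` and
#' `length`. Sequences are uppercased and any character outside `A`, `C`, `G`,
#' `T` is normalised to `N`, so downstream k-mer code only ever deals with one
#' ambiguity symbol.
#'
#' @param id Character vector of record identifiers (nonempty, unique).
#' @param seq Character vector of nucleotide strings.
#' @return A `data.frame` with columns `id`, `seq`, `length`.
#' @export
seq_records <- function(id, seq) {
  id <- as.character(id)
  seq <- as.character(seq)
  if (length(id) != length(seq)) stop("id and seq must have equal length")
  if (any(!nzchar(id))) stop("record ids must be nonempty")
  if (anyDuplicated(id)) stop("duplicate record ids: ", id[duplicated(id)][1L])
  seq <- normalize_seq(seq)
  data.frame(id = id, seq = seq, length = nchar(seq),
             stringsAsFactors = FALSE)
}

#' @rdname seq_records
#' @param x Character vector of raw sequences.
#' @export
normalize_seq <- function(x) {
  x <- toupper(x)
  gsub("[^ACGT]", "N", x, perl = TRUE)
}

detect_format <- function(path, first_line) {
  if (startsWith(first_line, ">")) return("fasta")
  if (startsWith(first_line, "@")) return("fastq")
  stop("cannot detect sequence format of ", path,
       ": first line starts with neither '>' nor '@'")
}

#' Open a chunked stream over a FASTA/FASTQ file
#'
#' Returns a closure that yields successive chunks of records (as
#' [seq_records()] data frames) and `NULL` at end of input. Gzip compression
#' is handled transparently. Memory use is bounded by the chunk, not the file:
#' the stream never holds more than one chunk of records at a time. FASTQ
#' quality strings are discarded.
#'
#' @param path Path to a FASTA or FASTQ file, optionally gzip-compressed.
#' @param format `"auto"` (detect from the first record), `"fasta"` or
#'   `"fastq"`.
#' @param chunk_size Records per chunk.
#' @return A function; each call returns a record data frame or `NULL`.
#' @export
seq_stream <- function(path, format = c("auto", "fasta", "fastq"),
                       chunk_size = 1000L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  con <- gzfile(path, "rt")
  buf <- character(0)
  n_seen <- 0L      # records already emitted (for error messages)
  eof <- FALSE
  done <- FALSE

  fill <- function(n_lines) {
    if (eof) return(invisible(NULL))
    lines <- readLines(con, n = n_lines)
    if (length(lines) < n_lines) eof <<- TRUE
    buf <<- c(buf, lines)
    invisible(NULL)
  }

  # Peek enough to detect the format
  fill(1L)
  buf <- buf[nzchar(buf)]
  if (length(buf) == 0L && eof) {
    fmt <- if (format == "auto") "fasta" else format
  } else {
    fmt <- if (format == "auto") detect_format(path, buf[1L]) else format
  }

  parse_fasta <- function(lines) {
    hdr <- which(startsWith(lines, ">"))
    if (length(hdr) == 0L || hdr[1L] != 1L)
      stop("malformed FASTA record ", n_seen + 1L, " in ", path)
    ends <- c(hdr[-1L] - 1L, length(lines))
    ids <- sub("^>(\\S*).*$", "\\1", lines[hdr])
    seqs <- vapply(seq_along(hdr), function(i) {
      if (ends[i] < hdr[i] + 1L) return("")
      paste0(lines[(hdr[i] + 1L):ends[i]], collapse = "")
    }, character(1))
    if (any(!nzchar(ids)))
      stop("malformed FASTA record ", n_seen + which(!nzchar(ids))[1L],
           " in ", path, ": empty id")
    list(id = ids, seq = seqs)
  }

  function() {
    if (done) return(NULL)
    if (fmt == "fastq") {
      while (!eof && length(buf) < 4L * chunk_size) fill(4L * chunk_size)
      buf <<- buf[!(eof & !nzchar(buf))] # drop blank trailing lines at EOF
      n_rec <- length(buf) %/% 4L
      if (!eof) n_rec <- min(n_rec, chunk_size)
      if (n_rec == 0L) {
        if (length(buf) > 0L)
          stop("malformed FASTQ record ", n_seen + 1L, " in ", path,
               ": truncated final record")
        close(con); done <<- TRUE
        return(NULL)
      }
      take <- buf[seq_len(4L * n_rec)]
      buf <<- buf[-seq_len(4L * n_rec)]
      l1 <- take[seq(1L, by = 4L, length.out = n_rec)]
      l3 <- take[seq(3L, by = 4L, length.out = n_rec)]
      bad <- which(!startsWith(l1, "@") | !startsWith(l3, "+"))
      if (length(bad) > 0L)
        stop("malformed FASTQ record ", n_seen + bad[1L], " in ", path)
      ids <- sub("^@(\\S*).*$", "\\1", l1)
      seqs <- take[seq(2L, by = 4L, length.out = n_rec)]
      n_seen <<- n_seen + n_rec
      seq_records(ids, seqs)
    } else {
      # Read until we can emit chunk_size complete records or hit EOF
      repeat {
        hdr <- which(startsWith(buf, ">"))
        if (eof || length(hdr) > chunk_size) break
        fill(4L * chunk_size)
      }
      buf <<- buf[nzchar(buf)]
      hdr <- which(startsWith(buf, ">"))
      if (length(hdr) == 0L) {
        if (length(buf) > 0L)
          stop("malformed FASTA record ", n_seen + 1L, " in ", path)
        close(con); done <<- TRUE
        return(NULL)
      }
      if (eof || length(hdr) <= chunk_size) {
        take <- buf; buf <<- character(0)
      } else {
        cut <- hdr[chunk_size + 1L]
        take <- buf[seq_len(cut - 1L)]
        buf <<- buf[cut:length(buf)]
      }
      rec <- parse_fasta(take)
      n_seen <<- n_seen + length(rec$id)
      seq_records(rec$id, rec$seq)
    }
  }
}

#' Read a whole FASTA/FASTQ file into a record data frame
#'
#' Convenience wrapper over [seq_stream()] for inputs that fit in memory.
#'
#' @inheritParams seq_stream
#' @return A [seq_records()] data frame (zero rows for an empty file).
#' @export
read_seq_file <- function(path, format = c("auto", "fasta", "fastq")) {
  st <- seq_stream(path, format)
  chunks <- list()
  while (!is.null(ch <- st())) chunks[[length(chunks) + 1L]] <- ch
  if (length(chunks) == 0L)
    return(data.frame(id = character(0), seq = character(0),
                      length = integer(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, chunks)
  rownames(out) <- NULL
  if (anyDuplicated(out$id))
    stop("duplicate record ids in ", path, ": ",
         out$id[duplicated(out$id)][1L])
  out
}

#' Write records as FASTA
#'
#' @param records A [seq_records()] data frame.
#' @param path Output path (plain text; `.gz` suffix writes gzip).
#' @param width Line width for sequence wrapping; `Inf` for single-line.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = Inf) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(paste0(">", records$id[i]), con)
    s <- records$seq[i]
    if (is.finite(width) && nchar(s) > width) {
      starts <- seq(1L, nchar(s), by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
    } else {
      writeLines(s, con)
    }
  }
  invisible(path)
}

#' Write an annotation or embedding table as TSV
#'
#' Tab-delimited text with a header row; round-trips losslessly through
#' [read_table_file()].
#'
#' @param table A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_file <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA")
  invisible(path)
}

#' @rdname write_table_file
#' @export
read_table_file <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Export a subset of records from a sequence file as FASTA
#'
#' Streams the source file and writes the requested ids in source order.
#' Absent ids are not an error; the number actually written is returned.
#'
#' @param src_path Source FASTA/FASTQ path.
#' @param ids Character vector (or set) of record ids to keep.
#' @param out_path Output FASTA path.
#' @return Integer count of records written.
#' @export
export_fasta_subset <- function(src_path, ids, out_path) {
  ids <- unique(as.character(ids))
  st <- seq_stream(src_path)
  con <- file(out_path, "wt")
  on.exit(close(con))
  n <- 0L
  while (!is.null(ch <- st())) {
    keep <- ch[ch$id %in% ids, , drop = FALSE]
    for (i in seq_len(nrow(keep))) {
      writeLines(c(paste0(">", keep$id[i]), keep$seq[i]), con)
    }
    n <- n + nrow(keep)
  }
  n
}

#' Read a per-read class-label table
#'
#' Two-column TSV (`id`, `class_label`), header optional; ids absent from the
#' read set mean "unassigned".
#'
#' @param path Path to the label TSV.
#' @return A data frame with columns `id` and `class_label`.
#' @export
read_label_table <- function(path) {
  tab <- read.delim(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("label table needs two columns: id, class_label")
  if (identical(tolower(tab[1, 1]), "id")) tab <- tab[-1L, , drop = FALSE]
  data.frame(id = as.character(tab[[1L]]),
             class_label = as.character(tab[[2L]]),
             stringsAsFactors = FALSE)
}
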