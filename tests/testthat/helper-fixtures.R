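# Shared fixtures and small oracles used across test files.

# deterministic random sequence over ACGT
rand_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# naive canonical k-mer counter (string-based oracle)
naive_count_canonical <- function(seq, index) {
  k <- index$k
  v <- setNames(integer(length(index$keys)), index$keys)
  n <- nchar(seq)
  if (n < k) return(v)
  for (i in 1:(n - k + 1L)) {
    w <- substr(seq, i, i + k - 1L)
    if (grepl("N", w, fixed = TRUE)) next
    key <- min(w, revcomp(w))
    v[key] <- v[key] + 1L
  }
  v
}

# naive distinct noncanonical k-mer fraction
naive_unique_fraction <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(NA_real_)
  ws <- substring(seq, 1:(n - k + 1L), k:n)
  ws <- ws[!grepl("N", ws, fixed = TRUE)]
  if (length(ws) == 0L) return(NA_real_)
  length(unique(ws)) / length(ws)
}

# naive multiplicity oracle: canonical k-mer -> count over a read set
naive_mult_table <- function(seqs, k) {
  tab <- new.env(parent = emptyenv())
  for (s in seqs) {
    n <- nchar(s)
    if (n < k) next
    ws <- substring(s, 1:(n - k + 1L), k:n)
    ws <- ws[!grepl("N", ws, fixed = TRUE)]
    for (w in ws) {
      key <- min(w, revcomp(w))
      tab[[key]] <- (if (is.null(tab[[key]])) 0L else tab[[key]]) + 1L
    }
  }
  tab
}

naive_median_mult <- function(seq, tab, k) {
  n <- nchar(seq)
  if (n < k) return(NA_real_)
  ws <- substring(seq, 1:(n - k + 1L), k:n)
  ws <- ws[!grepl("N", ws, fixed = TRUE)]
  if (length(ws) == 0L) return(NA_real_)
  cts <- vapply(ws, function(w) {
    key <- min(w, revcomp(w))
    if (is.null(tab[[key]])) 0L else tab[[key]]
  }, integer(1))
  unname(sort(cts)[(length(cts) + 1L) %/% 2L])  # lower median
}

# brute-force maximal scoring segment oracle: best-scoring window search,
# iteratively removing found segments (standard greedy equivalent for the
# Ruzzo-Tompa decomposition on short inputs)
brute_segments <- function(scores) {
  out <- data.frame(start = integer(0), end = integer(0), score = numeric(0))
  active <- rep(TRUE, length(scores))
  repeat {
    best <- -Inf; bi <- 0L; bj <- 0L
    for (i in seq_along(scores)) {
      if (!active[i]) next
      acc <- 0
      for (j in i:length(scores)) {
        if (!active[j]) break
        acc <- acc + scores[j]
        if (acc > best) { best <- acc; bi <- i; bj <- j }
      }
    }
    if (best <= 0) break
    out <- rbind(out, data.frame(start = bi, end = bj, score = best))
    active[bi:bj] <- FALSE
  }
  out[order(out$start), , drop = FALSE]
}

# small two-component mixture shared by several tests (cached per session)
fixture_env <- new.env(parent = emptyenv())

small_mixture <- function() {
  if (is.null(fixture_env$mix)) {
    specs <- list(
      component_spec("low_gc", 60000L, gc = 0.32, coding_fraction = 0.2,
                     coverage = 40, seed = 11L),
      component_spec("high_gc", 60000L, gc = 0.58, coding_fraction = 0.9,
                     coverage = 40, seed = 12L))
    fixture_env$mix <- generate_mixture(specs, seed = 400L)
  }
  fixture_env$mix
}
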