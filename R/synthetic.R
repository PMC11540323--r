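# Synthetic labelled mixtures with the statistical structure the method
# assumes: a heterogeneous low-coding host, compact coding-dense cobionts at
# distinct GC and coverage, a tiny very-high-coverage organelle, repeats.

CODONS <- local({
  b <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(sort(all64), c("TAA", "TAG", "TGA")) # sense codons only
})

#' Synthetic codon usage
#'
#' A fixed, seeded random codon preference vector over the 61 sense codons
#' (exponential weights). All synthetic "organisms" share this preference
#' structure — mirroring conserved codon/dicodon biology — while
#' [tilt_codon_usage()] shifts its GC per component.
#'
#' @param seed Integer seed.
#' @return Named probability vector over 61 codons.
#' @export
synthetic_codon_usage <- function(seed = 101L) {
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  w <- stats::rexp(length(CODONS))^2   # skewed: a few strongly preferred codons
  setNames(w / sum(w), CODONS)
}

codon_gc_frac <- function() {
  vapply(strsplit(CODONS, "", fixed = TRUE),
         function(ch) mean(ch %in% c("G", "C")), numeric(1))
}

#' Tilt a codon usage toward a target GC
#'
#' Reweights codons by `exp(g * gc_count)` with `g` solved so the expected
#' GC of sampled coding sequence matches `gc`.
#'
#' @param usage Codon probability vector from [synthetic_codon_usage()].
#' @param gc Target GC fraction in (0.1, 0.9).
#' @return Reweighted codon probability vector.
#' @export
tilt_codon_usage <- function(usage, gc) {
  gcf <- codon_gc_frac()
  f <- function(g) {
    w <- usage * exp(g * 3 * gcf)
    sum(w * gcf) / sum(w) - gc
  }
  g <- stats::uniroot(f, c(-15, 15))$root
  w <- usage * exp(g * 3 * gcf)
  w / sum(w)
}

#' Sample in-frame coding-like sequence from a codon usage
#'
#' @param n_bases Approximate length (rounded up to whole codons).
#' @param usage Codon probability vector.
#' @return One nucleotide string.
#' @export
sample_coding_sequence <- function(n_bases, usage) {
  n_codons <- ceiling(n_bases / 3)
  paste0(sample(names(usage), n_codons, replace = TRUE, prob = usage),
         collapse = "")
}

#' Default synthetic hexamer reference table
#'
#' Trains a [train_hexamer_table()] on sequence sampled from the untilted
#' synthetic codon usage — the stand-in for a coding reference (such as a
#' table trained on a model organism's CDS) in tests and demos.
#'
#' @param seed Integer seed.
#' @param n_records,record_length Training set size.
#' @return A `hexamer_table`.
#' @export
synthetic_coding_table <- function(seed = 101L, n_records = 200L,
                                   record_length = 1200L) {
  usage <- synthetic_codon_usage(seed)
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed + 1L)
  seqs <- vapply(seq_len(n_records),
                 function(i) sample_coding_sequence(record_length, usage),
                 character(1))
  train_hexamer_table(seq_records(paste0("cds_", seq_len(n_records)), seqs),
                      source = "synthetic codon model")
}

#' Specification of one mixture component
#'
#' @param name Component name (unique within a mixture).
#' @param genome_length Genome size in bases.
#' @param gc Target GC fraction in (0, 1).
#' @param markov_order Background chain order 0, 1 or 2 (orders > 0 add
#'   short-range base persistence).
#' @param n_blocks Number of compositional blocks (heterogeneity).
#' @param block_gc_spread Half-width of block GC around `gc`.
#' @param coding_fraction Fraction of the genome planted as coding blocks.
#' @param repeat_spec Optional `list(unit_length, copy_number)` tandem
#'   repeat to plant.
#' @param coverage Fold sequencing coverage.
#' @param read_length_mean,read_length_sd Read length distribution (bases).
#' @param error_rate Substitution errors per base, in [0, 0.05].
#' @param seed Integer seed for this component.
#' @return A list of class `component_spec`.
#' @export
component_spec <- function(name, genome_length, gc = 0.4, markov_order = 0L,
                           n_blocks = 1L, block_gc_spread = 0,
                           coding_fraction = 0, repeat_spec = NULL,
                           coverage = 10, read_length_mean = 8000,
                           read_length_sd = 1500, error_rate = 0.001,
                           seed = 1L) {
  if (gc <= 0 || gc >= 1) stop("gc must be in (0, 1)")
  if (coverage <= 0) stop("coverage must be > 0")
  if (error_rate < 0 || error_rate > 0.05)
    stop("error_rate must be in [0, 0.05]")
  if (coding_fraction < 0 || coding_fraction > 1)
    stop("coding_fraction must be in [0, 1]")
  if (!markov_order %in% 0:2) stop("markov_order must be 0, 1 or 2")
  structure(list(name = name, genome_length = as.integer(genome_length),
                 gc = gc, markov_order = as.integer(markov_order),
                 n_blocks = as.integer(n_blocks),
                 block_gc_spread = block_gc_spread,
                 coding_fraction = coding_fraction,
                 repeat_spec = repeat_spec, coverage = coverage,
                 read_length_mean = read_length_mean,
                 read_length_sd = read_length_sd, error_rate = error_rate,
                 seed = as.integer(seed)),
            class = "component_spec")
}

# background chain: stationary base probs p, order-m persistence lambda
sample_background <- function(n, gc, order, lambda = 0.3) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  bases <- names(p)
  if (order == 0L || n <= order) {
    return(sample(bases, n, replace = TRUE, prob = p))
  }
  out <- character(n)
  out[seq_len(order)] <- sample(bases, order, replace = TRUE, prob = p)
  fresh <- sample(bases, n, replace = TRUE, prob = p)
  copy <- runif(n) < lambda
  for (i in (order + 1L):n) {
    out[i] <- if (copy[i]) out[i - order] else fresh[i]
  }
  out
}

#' Generate one synthetic genome
#'
#' Background sequence is a (block-wise) Markov chain hitting the block GC
#' targets; coding blocks are planted at codon stride from the component's
#' GC-tilted codon usage; tandem repeats are planted verbatim. All planted
#' feature coordinates are recorded. Deterministic given `spec$seed`.
#'
#' @param spec A [component_spec()].
#' @param usage Base codon usage (default [synthetic_codon_usage()]).
#' @return List with `record` (one-row [seq_records()]) and `features`
#'   (data frame `type`, `start`, `end`).
#' @export
generate_genome <- function(spec, usage = synthetic_codon_usage()) {
  stopifnot(inherits(spec, "component_spec"))
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(spec$seed)
  n <- spec$genome_length
  # blocks with GC spread around the target
  nb <- max(1L, spec$n_blocks)
  gcs <- if (nb == 1L) spec$gc else
    seq(spec$gc - spec$block_gc_spread, spec$gc + spec$block_gc_spread,
        length.out = nb)
  bounds <- round(seq(0L, n, length.out = nb + 1L))
  g <- character(n)
  feats <- list()
  for (i in seq_len(nb)) {
    idx <- (bounds[i] + 1L):bounds[i + 1L]
    g[idx] <- sample_background(length(idx), gcs[i], spec$markov_order)
    feats[[length(feats) + 1L]] <-
      data.frame(type = sprintf("block_gc%.3f", gcs[i]),
                 start = bounds[i] + 1L, end = bounds[i + 1L])
  }
  # coding blocks, GC-tilted to the component target
  if (spec$coding_fraction > 0) {
    tilted <- tilt_codon_usage(usage, spec$gc)
    target <- spec$coding_fraction * n
    planted <- 0
    guard <- 0L
    while (planted < target && guard < 10000L) {
      guard <- guard + 1L
      len <- 3L * sample(200:500, 1L)           # 600-1500 base blocks
      len <- min(len, n)
      start <- sample.int(n - len + 1L, 1L)
      block <- strsplit(sample_coding_sequence(len, tilted), "",
                        fixed = TRUE)[[1L]][seq_len(len)]
      g[start:(start + len - 1L)] <- block
      feats[[length(feats) + 1L]] <-
        data.frame(type = "coding", start = start, end = start + len - 1L)
      planted <- planted + len
    }
  }
  # tandem repeat
  if (!is.null(spec$repeat_spec)) {
    ul <- spec$repeat_spec$unit_length
    cn <- spec$repeat_spec$copy_number
    span <- ul * cn
    if (span < n) {
      unit <- sample_background(ul, spec$gc, 0L)
      start <- sample.int(n - span + 1L, 1L)
      g[start:(start + span - 1L)] <- rep(unit, cn)
      feats[[length(feats) + 1L]] <-
        data.frame(type = "repeat", start = start, end = start + span - 1L)
    }
  }
  list(record = seq_records(spec$name, paste0(g, collapse = "")),
       features = do.call(rbind, feats))
}

#' Simulate HiFi-like reads from a genome
#'
#' Uniform start positions, random strand, truncated-normal lengths,
#' independent substitution errors. Read count is
#' `round(coverage * genome_length / read_length_mean)`.
#'
#' @param genome One-row [seq_records()] data frame.
#' @param spec The [component_spec()] (supplies coverage, lengths, errors,
#'   seed).
#' @param id_prefix Prefix for read ids (default the component name).
#' @return List with `reads` ([seq_records()]) and `truth` (data frame
#'   `id`, `component`, `start`, `strand`).
#' @export
simulate_reads <- function(genome, spec, id_prefix = spec$name) {
  stopifnot(inherits(spec, "component_spec"))
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(spec$seed + 7L)
  glen <- genome$length[1L]
  gseq <- genome$seq[1L]
  if (glen <= spec$read_length_mean / 2)
    stop("genome shorter than half the mean read length")
  n_reads <- max(1L, round(spec$coverage * glen / spec$read_length_mean))
  lens <- round(rnorm(n_reads, spec$read_length_mean, spec$read_length_sd))
  lens <- pmin(pmax(lens, 500L), glen)
  starts <- vapply(lens, function(l) sample.int(glen - l + 1L, 1L),
                   integer(1))
  strands <- ifelse(runif(n_reads) < 0.5, "+", "-")
  seqs <- substring(gseq, starts, starts + lens - 1L)
  flip <- strands == "-"
  if (any(flip)) seqs[flip] <- revcomp(seqs[flip])
  if (spec$error_rate > 0) {
    seqs <- vapply(seqs, function(s) {
      l <- nchar(s)
      ne <- rbinom(1L, l, spec$error_rate)
      if (ne == 0L) return(s)
      pos <- sample.int(l, ne)
      ch <- strsplit(s, "", fixed = TRUE)[[1L]]
      for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
      paste0(ch, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  ids <- sprintf("%s_read_%06d", id_prefix, seq_len(n_reads))
  list(reads = seq_records(ids, seqs),
       truth = data.frame(id = ids, component = spec$name, start = starts,
                          strand = strands, stringsAsFactors = FALSE))
}

#' Generate a labelled synthetic mixture
#'
#' Generates each component's genome and reads, interleaves reads in a
#' seeded random order, and optionally writes FASTA plus a truth TSV.
#'
#' @param specs List of [component_spec()]s with unique names.
#' @param seed Mixture-level seed (shuffling; also re-seeds components as
#'   `seed + index` unless a spec carries its own nondefault seed).
#' @param out_prefix Optional output path prefix; writes
#'   `<prefix>_reads.fasta` and `<prefix>_truth.tsv`.
#' @param usage Base codon usage shared by all components.
#' @return List with `reads`, `truth`, `genomes` (named list of
#'   [generate_genome()] results) and `paths` (if written).
#' @export
generate_mixture <- function(specs, seed = 1L, out_prefix = NULL,
                             usage = synthetic_codon_usage()) {
  nms <- vapply(specs, function(s) s$name, character(1))
  if (anyDuplicated(nms)) stop("duplicate component names")
  genomes <- list()
  reads <- list()
  truth <- list()
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    sp$seed <- sp$seed + seed * 1000L
    gen <- generate_genome(sp, usage = usage)
    sim <- simulate_reads(gen$record, sp)
    genomes[[sp$name]] <- gen
    reads[[i]] <- sim$reads
    truth[[i]] <- sim$truth
  }
  reads <- do.call(rbind, reads)
  truth <- do.call(rbind, truth)
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  ord <- sample.int(nrow(reads))
  reads <- reads[ord, , drop = FALSE]
  truth <- truth[match(reads$id, truth$id), , drop = FALSE]
  rownames(reads) <- rownames(truth) <- NULL
  paths <- NULL
  if (!is.null(out_prefix)) {
    fa <- paste0(out_prefix, "_reads.fasta")
    tt <- paste0(out_prefix, "_truth.tsv")
    write_fasta(reads, fa)
    write_table_file(truth, tt)
    paths <- list(reads = fa, truth = tt)
  }
  list(reads = reads, truth = truth, genomes = genomes, paths = paths)
}

#' Scaled-down study-like mixture preset
#'
#' Four components emulating a wild-caught specimen: a heterogeneous,
#' repeat-carrying, low-coding-density host (300 kb at 30x), a compact
#' coding-dense endosymbiont at distinct GC (150 kb at 120x), a tiny
#' very-high-coverage organelle (16 kb at 2000x), and a sparse contaminant
#' (100 kb at 3x). Genome sizes are ~100x below realistic values so the
#' full pipeline runs in minutes; coverages are kept realistic so
#' coverage-based contrasts survive the scaling.
#'
#' @param seed Integer seed.
#' @return Named list of [component_spec()]s.
#' @export
preset_specs <- function(seed = 1L) {
  list(
    host = component_spec("host", 300000L, gc = 0.37, markov_order = 1L,
                          n_blocks = 6L, block_gc_spread = 0.05,
                          coding_fraction = 0.2,
                          repeat_spec = list(unit_length = 500L,
                                             copy_number = 40L),
                          coverage = 30, seed = seed),
    endosymbiont = component_spec("endosymbiont", 150000L, gc = 0.55,
                                  coding_fraction = 0.9, coverage = 120,
                                  seed = seed + 1L),
    organelle = component_spec("organelle", 16000L, gc = 0.25,
                               coding_fraction = 0.85, coverage = 2000,
                               read_length_mean = 6000,
                               read_length_sd = 1000, seed = seed + 2L),
    contaminant = component_spec("contaminant", 100000L, gc = 0.65,
                                 coding_fraction = 0.85, coverage = 3,
                                 seed = seed + 3L)
  )
}
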