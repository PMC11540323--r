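test_that("generated genomes hit their target GC", {
  spec <- component_spec("g", 200000L, gc = 0.30, seed = 61L)
  g <- generate_genome(spec)
  expect_gte(gc_content(g$record$seq), 0.29)
  expect_lte(gc_content(g$record$seq), 0.31)
  # determinism
  g2 <- generate_genome(spec)
  expect_identical(g$record$seq, g2$record$seq)
})

test_that("heterogeneous blocks realize their per-block GC", {
  spec <- component_spec("h", 200000L, gc = 0.375, n_blocks = 2L,
                         block_gc_spread = 0.075, coding_fraction = 0,
                         seed = 62L)
  g <- generate_genome(spec)
  blocks <- g$features[startsWith(g$features$type, "block"), ]
  expect_equal(nrow(blocks), 2L)
  gcs <- vapply(seq_len(nrow(blocks)), function(i)
    gc_content(substr(g$record$seq, blocks$start[i], blocks$end[i])),
    numeric(1))
  expect_equal(gcs, c(0.30, 0.45), tolerance = 0.04)
})

test_that("coding blocks are planted with recorded coordinates", {
  spec <- component_spec("c", 60000L, gc = 0.5, coding_fraction = 0.5,
                         seed = 63L)
  g <- generate_genome(spec)
  coding <- g$features[g$features$type == "coding", ]
  expect_gt(nrow(coding), 0L)
  planted <- sum(coding$end - coding$start + 1L)
  expect_gte(planted, 0.5 * 60000)
  tab <- synthetic_coding_table()
  i <- which.max(coding$end - coding$start)
  block <- substr(g$record$seq, coding$start[i], coding$end[i])
  bg <- substr(g$record$seq, 1, 500)
  expect_gt(coding_density(block, tab), coding_density(bg, tab))
})

test_that("error-free reads are exact substrings of genome or revcomp", {
  spec <- component_spec("e", 50000L, gc = 0.45, coverage = 5,
                         error_rate = 0, read_length_mean = 3000,
                         read_length_sd = 500, seed = 64L)
  g <- generate_genome(spec)
  sim <- simulate_reads(g$record, spec)
  both <- c(g$record$seq, revcomp(g$record$seq))
  for (i in seq_len(nrow(sim$reads))) {
    expect_true(any(vapply(both, grepl, logical(1),
                           pattern = sim$reads$seq[i], fixed = TRUE)),
                info = sim$reads$id[i])
  }
})

test_that("read count, strand balance and truth rows match expectations", {
  spec <- component_spec("s", 100000L, gc = 0.5, coverage = 100,
                         read_length_mean = 10000, read_length_sd = 100,
                         seed = 65L)
  g <- generate_genome(spec)
  sim <- simulate_reads(g$record, spec)
  expect_equal(nrow(sim$reads), 1000L)
  expect_equal(nrow(sim$truth), nrow(sim$reads))
  expect_equal(sort(sim$truth$id), sort(sim$reads$id))
  frac_minus <- mean(sim$truth$strand == "-")
  expect_gte(frac_minus, 0.45)
  expect_lte(frac_minus, 0.55)
})

test_that("mixtures interleave reads, label all of them, and reproduce", {
  mix <- small_mixture()
  expect_equal(sort(mix$truth$id), sort(mix$reads$id))
  expect_setequal(unique(mix$truth$component), c("low_gc", "high_gc"))
  # same seeds -> byte-identical FASTA
  d <- withr::local_tempdir()
  specs <- list(component_spec("a", 20000L, coverage = 5, seed = 1L),
                component_spec("b", 20000L, gc = 0.6, coverage = 5, seed = 2L))
  m1 <- generate_mixture(specs, seed = 9L, out_prefix = file.path(d, "m1"))
  m2 <- generate_mixture(specs, seed = 9L, out_prefix = file.path(d, "m2"))
  expect_identical(readLines(m1$paths$reads), readLines(m2$paths$reads))
  expect_identical(readLines(m1$paths$truth), readLines(m2$paths$truth))
})

test_that("invalid component specs error", {
  expect_error(component_spec("x", 1000L, gc = 1.2), "gc")
  expect_error(component_spec("x", 1000L, coverage = 0), "coverage")
  expect_error(component_spec("x", 1000L, error_rate = 0.5), "error_rate")
  expect_error(component_spec("x", 1000L, coding_fraction = 1.5),
               "coding_fraction")
  expect_error(
    generate_mixture(list(component_spec("a", 5000L, coverage = 2),
                          component_spec("a", 5000L, coverage = 2))),
    "duplicate")
})

test_that("tilted codon usage moves coding GC toward the target", {
  usage <- synthetic_codon_usage()
  set.seed(71)
  for (target in c(0.3, 0.55)) {
    tilted <- tilt_codon_usage(usage, target)
    s <- sample_coding_sequence(60000, tilted)
    expect_equal(gc_content(s), target, tolerance = 0.02)
  }
})

test_that("preset components realize coverages within 15% of spec", {
  mix <- generate_mixture(preset_specs(2L), seed = 77L)
  depth <- function(comp, glen) {
    sel <- mix$truth$component == comp
    sum(mix$reads$length[match(mix$truth$id[sel], mix$reads$id)]) / glen
  }
  expect_equal(depth("host", 300000), 30, tolerance = 0.15)
  expect_equal(depth("endosymbiont", 150000), 120, tolerance = 0.15)
  expect_equal(depth("organelle", 16000), 2000, tolerance = 0.15)
  expect_equal(depth("contaminant", 100000), 3, tolerance = 0.15)
})
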