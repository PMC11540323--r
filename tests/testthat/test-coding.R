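test_that("training on a single repeated dicodon maximises its score", {
  recs <- seq_records("t", strrep("ATGGCT", 400))
  tab <- train_hexamer_table(recs)
  expect_gt(tab$scores[["ATGGCT"]], 0)
  expect_equal(names(which.max(tab$scores)), "ATGGCT")
  expect_equal(sum(tab$coding_freq), 1)
})

test_that("uniform random training DNA drives scores to zero", {
  set.seed(161)
  recs <- seq_records(paste0("t", 1:100),
                      replicate(100, rand_seq(10002, gc = 0.5)))
  tab <- train_hexamer_table(recs)
  # ~80 expected observations per hexamer: per-score sampling SD of the
  # log-ratio is ~sqrt(2/80) ~= 0.16, so the max over 4096 scores sits
  # near 3.5 SD. Typical scores must be near zero; the max bounded by ~4 SD.
  expect_lt(median(abs(tab$scores)), 0.15)
  expect_lt(max(abs(tab$scores)), 0.7)
})

test_that("empty or hexamer-free training sets error", {
  expect_error(train_hexamer_table(seq_records(character(0), character(0))),
               "empty")
  expect_error(train_hexamer_table(seq_records("a", "ACG")), "no hexamer")
})

test_that("hexamer tables round-trip through TSV", {
  recs <- seq_records("t", strrep("ATGGCTGAA", 200))
  tab <- train_hexamer_table(recs, source = "toy")
  p <- withr::local_tempfile(fileext = ".tsv")
  write_hexamer_table(tab, p)
  tab2 <- read_hexamer_table(p)
  expect_equal(unname(tab2$scores), unname(tab$scores))
  expect_equal(tab2$train_log_base, unname(tab$train_log_base))
  expect_equal(tab2$source, "toy")
  set.seed(171)
  s <- rand_seq(3000)
  expect_equal(coding_density(s, tab2), coding_density(s, tab))
})

test_that("records shorter than 6 predict zero coding bases", {
  tab <- synthetic_coding_table()
  expect_equal(predicted_coding_length("ACGTA", tab), 0)
  expect_equal(coding_density("ACGTA", tab), 0)
})

test_that("raising the threshold never increases predicted length", {
  tab <- synthetic_coding_table()
  set.seed(181)
  seqs <- replicate(20, rand_seq(sample(500:4000, 1), gc = runif(1, .3, .7)))
  for (s in seqs) {
    lens <- vapply(c(5, 20, 50, 200), function(T)
      predicted_coding_length(s, tab, coding_config(threshold = T)),
      numeric(1))
    expect_true(all(diff(lens) <= 0))
  }
})

test_that("coding density is strand symmetric with both strands on", {
  tab <- synthetic_coding_table()
  set.seed(191)
  for (i in 1:10) {
    s <- rand_seq(sample(1000:4000, 1))
    expect_equal(coding_density(s, tab), coding_density(revcomp(s), tab))
  }
})

test_that("records drawn from the coding model score high density", {
  tab <- synthetic_coding_table()
  usage <- synthetic_codon_usage()
  set.seed(201)
  dens <- vapply(1:40, function(i)
    coding_density(sample_coding_sequence(3000, usage), tab), numeric(1))
  expect_gte(mean(dens), 0.5)
})

test_that("random records score near zero against the coding table", {
  tab <- synthetic_coding_table()
  set.seed(211)
  dens <- vapply(1:40, function(i)
    coding_density(rand_seq(3000, gc = 0.5), tab), numeric(1))
  expect_lte(median(dens), 0.1)
})

test_that("bacterial-like vs host-like density medians differ by >= 0.3", {
  tab <- synthetic_coding_table()
  specs <- list(
    component_spec("hostlike", 60000L, gc = 0.40, coding_fraction = 0.2,
                   coverage = 10, seed = 31L),
    component_spec("bactlike", 60000L, gc = 0.45, coding_fraction = 0.9,
                   coverage = 10, seed = 32L))
  mix <- generate_mixture(specs, seed = 410L)
  d <- coding_density(mix$reads$seq, tab)
  comp <- mix$truth$component[match(mix$reads$id, mix$truth$id)]
  med <- tapply(d, comp, median)
  expect_gte(med[["bactlike"]] - med[["hostlike"]], 0.3)
})

test_that("maximal scoring segments match the brute-force oracle", {
  set.seed(221)
  for (i in 1:30) {
    sc <- round(rnorm(sample(5:60, 1), sd = 2), 3)
    got <- max_scoring_segments(sc)
    got <- got[order(got$start), , drop = FALSE]
    want <- brute_segments(sc)
    expect_equal(got$start, want$start, info = paste("case", i))
    expect_equal(got$end, want$end, info = paste("case", i))
    expect_equal(got$score, want$score, tolerance = 1e-9,
                 info = paste("case", i))
  }
  # all-negative input has no segments
  expect_equal(nrow(max_scoring_segments(c(-1, -2, -0.5))), 0L)
})

test_that("density can exceed 1 when both strands carry signal", {
  tab <- synthetic_coding_table()
  usage <- synthetic_codon_usage()
  set.seed(231)
  # a dense coding sequence scored on both strands can pass 1
  dens <- vapply(1:20, function(i)
    coding_density(sample_coding_sequence(3000, usage), tab), numeric(1))
  expect_true(any(dens > 1) || max(dens) > 0.9)
  cfgb <- coding_config(both_strands = TRUE)
  cfg1 <- coding_config(both_strands = FALSE)
  s <- sample_coding_sequence(3000, usage)
  expect_gte(predicted_coding_length(s, tab, cfgb),
             predicted_coding_length(s, tab, cfg1))
})
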