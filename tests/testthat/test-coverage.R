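test_that("five identical copies give 970 distinct 31-mers at count 5", {
  set.seed(81)
  s <- rand_seq(1000)
  recs <- seq_records(paste0("c", 1:5), rep(s, 5))
  tab <- build_multiplicity_table(recs)
  st <- multiplicity_stats(tab)
  expect_equal(st$distinct, 970)
  h <- coverage_histogram(tab)
  expect_equal(h, data.frame(multiplicity = 5, n_kmers = 970))
  expect_equal(median_read_multiplicity(s, tab), 5)
})

test_that("conservation: sum of count*histogram equals windows processed", {
  set.seed(91)
  recs <- seq_records(paste0("r", 1:20),
                      replicate(20, rand_seq(sample(40:400, 1))))
  tab <- build_multiplicity_table(recs)
  st <- multiplicity_stats(tab)
  h <- coverage_histogram(tab)
  expect_equal(sum(h$multiplicity * h$n_kmers) + st$cap_losses,
               st$total_windows)
  expect_equal(sum(h$n_kmers), st$distinct)
  expect_equal(st$total_windows, sum(pmax(recs$length - 31 + 1, 0)))
})

test_that("reverse-complement reads build the same table as forward copies", {
  set.seed(101)
  s <- rand_seq(500)
  fwd <- build_multiplicity_table(seq_records(c("a", "b"), c(s, s)))
  mixed <- build_multiplicity_table(seq_records(c("a", "b"), c(s, revcomp(s))))
  expect_equal(coverage_histogram(fwd), coverage_histogram(mixed))
  expect_equal(median_read_multiplicity(s, mixed), 2)
})

test_that("lower median: window counts [1,1,9] give median 1", {
  set.seed(111)
  # query with 3 windows; boost only the last window's k-mer to count 9
  q <- rand_seq(33)
  w3 <- substr(q, 3, 33)
  recs <- seq_records(c("q", paste0("x", 1:8)), c(q, rep(w3, 8)))
  tab <- build_multiplicity_table(recs)
  expect_equal(median_read_multiplicity(q, tab), 1)
  # even window count uses the lower of the two middles
  q2 <- substr(q, 1, 32)  # 2 windows with counts 1 and 1.. boost one
  expect_equal(median_read_multiplicity(q2, tab), 1)
})

test_that("reads with no valid window flag NA", {
  set.seed(121)
  recs <- seq_records("a", rand_seq(100))
  tab <- build_multiplicity_table(recs)
  expect_true(is.na(median_read_multiplicity("ACGT", tab)))
  expect_true(is.na(median_read_multiplicity(strrep("N", 40), tab)))
})

test_that("multiplicity matches the naive oracle on small random sets", {
  set.seed(131)
  k <- 7L
  seqs <- replicate(12, rand_seq(sample(15:60, 1)))
  tab <- build_multiplicity_table(seq_records(paste0("r", 1:12), seqs), k = k)
  oracle <- naive_mult_table(seqs, k)
  for (s in seqs[1:6])
    expect_equal(median_read_multiplicity(s, tab),
                 naive_median_mult(s, oracle, k))
  h <- coverage_histogram(tab)
  ocounts <- unlist(as.list(oracle))
  expect_equal(sum(h$n_kmers), length(ocounts))
  expect_equal(sort(rep(h$multiplicity, h$n_kmers)), sort(unname(ocounts)))
})

test_that("count cap is enforced and overflow tallied", {
  recs <- seq_records(paste0("c", 1:6), rep(strrep("ACGT", 10), 6))
  tab <- build_multiplicity_table(recs, k = 5L, cap = 3)
  st <- multiplicity_stats(tab)
  expect_true(st$cap_losses > 0)
  h <- coverage_histogram(tab)
  expect_true(max(h$multiplicity) <= 3)
})

test_that("per-read medians recover simulated coverage ~Poisson", {
  # Poisson(40) puts 0.904 of its mass in [30, 50], so that is the ceiling
  # for the in-interval fraction; regional depth correlation on a 100 kb
  # genome costs a little more. Assert the derivable bounds.
  spec <- component_spec("g", 100000L, gc = 0.5, coverage = 40,
                         error_rate = 0, seed = 141L)
  mix <- generate_mixture(list(spec), seed = 141L)
  tab <- build_multiplicity_table(mix$reads)
  mm <- median_read_multiplicity(mix$reads$seq, tab)
  expect_gte(mean(mm >= 30 & mm <= 50, na.rm = TRUE), 0.80)
  expect_gte(median(mm, na.rm = TRUE), 34)
  expect_lte(median(mm, na.rm = TRUE), 48)
})

test_that("0.1% substitutions shift medians down by less than one unit", {
  base <- component_spec("c", 200000L, gc = 0.45, coverage = 20,
                         read_length_mean = 12000, read_length_sd = 500,
                         error_rate = 0, seed = 1L)
  err <- base; err$error_rate <- 0.001
  m0 <- generate_mixture(list(base), seed = 51L)
  m1 <- generate_mixture(list(err), seed = 51L)
  f <- function(m) {
    tab <- build_multiplicity_table(m$reads)
    mean(median_read_multiplicity(m$reads$seq, tab), na.rm = TRUE)
  }
  shift <- f(m0) - f(m1)
  expect_gt(shift, 0)
  expect_lt(shift, 1)
})

test_that("multiplicity tables round-trip through the text format", {
  set.seed(151)
  recs <- seq_records(c("a", "b"), c(rand_seq(100), rand_seq(100)))
  tab <- build_multiplicity_table(recs)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_multiplicity_table(tab, p)
  tab2 <- read_multiplicity_table(p)
  expect_equal(coverage_histogram(tab2), coverage_histogram(tab))
  expect_equal(median_read_multiplicity(recs$seq, tab2),
               median_read_multiplicity(recs$seq, tab))
})

test_that("coverage bands assign and validate", {
  lab <- assign_coverage_bins(c(7, 50, 500, NA),
                              bands = list(c(1, 10), c(11, 100)),
                              scheme = "manual")
  expect_equal(as.character(lab), c("[1,10]", "[11,100]", "outside", "outside"))
  lab2 <- assign_coverage_bins(c(1, 10, 100), scheme = "log")
  expect_equal(length(unique(as.character(lab2))), 3L)
  expect_error(
    assign_coverage_bins(1, bands = list(c(1, 10), c(5, 20)),
                         scheme = "manual"),
    "overlapping")
})
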