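make_emb <- function(mu1, mu2) {
  ids <- if (length(mu1)) paste0("p", seq_along(mu1)) else character(0)
  data.frame(id = ids, mu1 = mu1, mu2 = mu2, stringsAsFactors = FALSE)
}

test_that("histogram conserves counts and flags degenerate input", {
  set.seed(311)
  emb <- make_emb(rnorm(500), rnorm(500))
  h <- latent_histogram(emb, bins = 50)
  expect_equal(sum(h$counts), 500)
  expect_false(h$degenerate)
  # all points identical -> single nonzero bin, degenerate flag
  h1 <- latent_histogram(make_emb(rep(1, 100), rep(2, 100)), bins = 50)
  expect_true(h1$degenerate)
  expect_equal(sum(h1$counts > 0), 1L)
  expect_equal(max(h1$counts), 100)
  expect_error(latent_histogram(make_emb(numeric(0), numeric(0))), "empty")
})

test_that("equalization rank-transforms nonzero bins to a uniform scale", {
  set.seed(321)
  emb <- make_emb(runif(400, 0, 10), runif(400, 0, 10))
  h <- latent_histogram(emb, bins = 20, equalize = TRUE, smooth = 0)
  nz <- h$values[h$counts > 0]
  expect_equal(sort(unique(rank(nz))), sort(unique(rank(h$counts[h$counts > 0]))))
  expect_true(all(nz > 0 & nz <= 1))
  # exact contract: average ranks of the counts, scaled to (0, 1]
  cnz <- h$counts[h$counts > 0]
  expect_equal(sort(nz),
               sort(rank(cnz, ties.method = "average") / length(cnz)))
  # distinct counts map to a permutation of uniform ranks
  if (!any(duplicated(h$counts[h$counts > 0]))) {
    k <- sum(h$counts > 0)
    expect_equal(sort(nz), (1:k) / k)
  }
})

test_that("a single occupied cell yields one peak with persistence = value", {
  emb <- make_emb(rep(0, 10), rep(0, 10))
  h <- latent_histogram(emb, bins = 30, equalize = FALSE, smooth = 0)
  pk <- find_peaks_topology(h, window = 5, min_persistence = 0)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$persistence, 10)
})

test_that("an all-zero value grid yields no peaks", {
  emb <- make_emb(rep(0, 5), rep(0, 5))
  h <- latent_histogram(emb, bins = 10, equalize = FALSE, smooth = 0)
  h$values <- h$values * 0
  pk <- find_peaks_topology(h, window = 5, min_persistence = 0)
  expect_equal(nrow(pk), 0L)
})

test_that("peak count is monotone non-increasing in the window", {
  set.seed(331)
  emb <- make_emb(c(rnorm(800, -2, .4), rnorm(800, 2, .4), rnorm(400, 0, 1.5)),
                  c(rnorm(800, 0, .4), rnorm(800, 1, .4), rnorm(400, 0, 1.5)))
  h <- latent_histogram(emb, bins = 100)
  n <- vapply(c(2L, 6L, 12L, 24L, 48L), function(w)
    nrow(find_peaks_topology(h, window = w, min_persistence = 0)),
    integer(1))
  expect_true(all(diff(n) <= 0))
})

test_that("two well-separated blobs give two dominant, localized peaks", {
  set.seed(341)
  emb <- make_emb(c(rnorm(5000, -3, .3), rnorm(5000, 3, .3)),
                  c(rnorm(5000, 0, .3), rnorm(5000, 1, .3)))
  h <- latent_histogram(emb, bins = 200)
  pk <- find_peaks_topology(h, window = 20)
  expect_equal(sum(pk$persistence >= 0.9), 2L)
  cx <- findInterval(c(-3, 3), h$xedges, rightmost.closed = TRUE,
                     all.inside = TRUE)
  cy <- findInterval(c(0, 1), h$yedges, rightmost.closed = TRUE,
                     all.inside = TRUE)
  d1 <- min(pmax(abs(pk$bx[1:2] - cx[1]), abs(pk$by[1:2] - cy[1])))
  d2 <- min(pmax(abs(pk$bx[1:2] - cx[2]), abs(pk$by[1:2] - cy[2])))
  expect_lte(max(d1, d2), 3)
})

test_that("sampling near peaks is seeded, reproducible and ring-expanding", {
  set.seed(351)
  emb <- make_emb(c(rnorm(200, 0, .01), 5), c(rnorm(200, 0, .01), 5))
  h <- latent_histogram(emb, bins = 20, equalize = FALSE, smooth = 0)
  pk <- find_peaks_topology(h, window = 2, min_persistence = 0)
  s1 <- sample_reads_near_peaks(pk, h, n_per_peak = 2, seed = 7)
  s2 <- sample_reads_near_peaks(pk, h, n_per_peak = 2, seed = 7)
  expect_identical(s1, s2)
  s3 <- sample_reads_near_peaks(pk, h, n_per_peak = 2, seed = 8)
  expect_false(identical(s1, s3))
  expect_true(all(lengths(s1) == 2L))
  # isolated single-read peak: second id must come from an expanded ring
  iso <- pk[order(pk$persistence), ][1, , drop = FALSE]
  lone <- sample_reads_near_peaks(iso, h, n_per_peak = 2, seed = 7)
  expect_equal(length(lone[[1]]), 2L)
  expect_true("p201" %in% lone[[1]])
  # n = 0 -> empty draws
  s0 <- sample_reads_near_peaks(pk, h, n_per_peak = 0, seed = 7)
  expect_true(all(lengths(s0) == 0L))
})

test_that("requesting more reads than exist flags the peak as short", {
  emb <- make_emb(c(0, 0, 0), c(0, 0, 0))
  h <- latent_histogram(emb, bins = 10, equalize = FALSE, smooth = 0)
  pk <- find_peaks_topology(h, window = 2, min_persistence = 0)
  s <- sample_reads_near_peaks(pk, h, n_per_peak = 5, seed = 1)
  expect_equal(sort(s[[1]]), c("p1", "p2", "p3"))
  expect_equal(attr(s, "short"), as.character(pk$rank[1]))
})

test_that("peak tables serialize with sample counts", {
  set.seed(361)
  emb <- make_emb(rnorm(300), rnorm(300))
  h <- latent_histogram(emb, bins = 40)
  pk <- find_peaks_topology(h, window = 10, min_persistence = 0)
  s <- sample_reads_near_peaks(pk, h, n_per_peak = 2, seed = 3)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_peak_table(pk, s, p)
  tab <- read_table_file(p)
  expect_equal(nrow(tab), nrow(pk))
  expect_true(all(tab$n_reads_sampled == 2L))
})
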