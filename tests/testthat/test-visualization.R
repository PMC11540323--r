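test_that("quantile bins place values per the worked example", {
  qb <- quantile_bins(1:100, 10L)
  expect_equal(qb$n_bins, 10L)
  expect_equal(qb$bin[5], 1L)
  expect_equal(qb$bin[95], 10L)
  expect_equal(qb$n_merged, 0L)
})

test_that("mass points collapse bins and the merge is reported", {
  v <- c(rep(0, 60), seq_len(40))
  qb <- quantile_bins(v, 10L)
  expect_gt(qb$n_merged, 0L)
  expect_lt(qb$n_bins, 10L)
  expect_true(all(qb$bin[v == 0] == 1L))
})

test_that("constant input gives a single flagged bin", {
  qb <- quantile_bins(rep(3.5, 20), 10L)
  expect_true(qb$single)
  expect_equal(qb$n_bins, 1L)
  expect_true(all(qb$bin == 1L))
})

test_that("bin populations differ by at most one on distinct values", {
  set.seed(371)
  v <- rnorm(1000)
  qb <- quantile_bins(v, 10L)
  pop <- table(qb$bin)
  expect_lte(max(pop) - min(pop), 1)
})

test_that("NA values stay unbinned", {
  qb <- quantile_bins(c(1, 2, NA, 4), 2L)
  expect_true(is.na(qb$bin[3]))
  expect_error(quantile_bins(c(NA_real_, NA_real_)), "finite")
})

test_that("scatter rendering is deterministic and errors on bad input", {
  set.seed(381)
  emb <- data.frame(id = paste0("r", 1:500),
                    mu1 = rnorm(500), mu2 = rnorm(500),
                    stringsAsFactors = FALSE)
  p1 <- withr::local_tempfile(fileext = ".png")
  p2 <- withr::local_tempfile(fileext = ".png")
  render_scatter(emb, out = p1)
  render_scatter(emb, out = p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  expect_error(render_scatter(emb[0, ], out = p1), "empty")
  expect_error(render_scatter(emb, colors = c(x = "a"), out = p1),
               "ids missing")
  expect_error(render_scatter(emb, colors = c("a", "b"), out = p1),
               "one entry per")
})

test_that("two labeled blobs color distinct image regions", {
  set.seed(391)
  n <- 2000
  emb <- data.frame(id = paste0("r", 1:(2 * n)),
                    mu1 = c(rnorm(n, -3, .2), rnorm(n, 3, .2)),
                    mu2 = c(rnorm(n, 0, .2), rnorm(n, 0, .2)),
                    stringsAsFactors = FALSE)
  cols <- rep(c("left", "right"), each = n)
  p <- withr::local_tempfile(fileext = ".png")
  res <- render_scatter(emb, colors = cols, out = p, width = 200L,
                        height = 200L)
  img <- png::readPNG(p)
  expect_equal(dim(img)[1:2], c(200L, 200L))
  pal <- grDevices::col2rgb(res$colors) / 255
  # per image half, the dominant palette color among non-background pixels.
  # Rendered pixels are palette colors blended toward white, so classify by
  # the best-fitting blend line: pixel ~ white + t * (pal - white)
  dominant <- function(cols_idx) {
    px <- matrix(img[, cols_idx, 1:3], ncol = 3)
    fg <- rowSums(px) < 2.97  # drop (near-)white background
    expect_gt(sum(fg), 0)
    v <- 1 - px[fg, , drop = FALSE]          # vector from white
    d <- vapply(seq_len(ncol(pal)), function(j) {
      u <- 1 - pal[, j]
      t <- pmax(0, (v %*% u) / sum(u^2))     # least-squares blend weight
      rowSums((v - t %*% t(u))^2)            # residual off the blend line
    }, numeric(sum(fg)))
    res$levels[which.max(tabulate(max.col(-d), ncol(pal)))]
  }
  expect_equal(dominant(1:100), "left")
  expect_equal(dominant(101:200), "right")
})

test_that("length weighting renders and validates its inputs", {
  set.seed(401)
  emb <- data.frame(id = paste0("r", 1:100), mu1 = rnorm(100),
                    mu2 = rnorm(100), stringsAsFactors = FALSE)
  p1 <- withr::local_tempfile(fileext = ".png")
  render_scatter(emb, point_scale = "by-length",
                 lengths = sample(500:20000, 100), out = p1)
  expect_equal(dim(png::readPNG(p1))[1:2], c(500L, 500L))
  # named lengths are matched by id
  lens <- setNames(sample(500:20000, 100), rev(emb$id))
  render_scatter(emb, point_scale = "by-length", lengths = lens, out = p1)
  expect_true(file.size(p1) > 0)
  expect_error(render_scatter(emb, point_scale = "by-length", out = p1),
               "requires lengths")
})

test_that("coverage filtering selects the closed range", {
  emb <- data.frame(id = c("a", "b", "c"), mu1 = 1:3, mu2 = 1:3,
                    stringsAsFactors = FALSE)
  ann <- data.frame(id = c("a", "b", "c"),
                    median_multiplicity = c(5, 50, NA),
                    stringsAsFactors = FALSE)
  expect_equal(filter_by_coverage(emb, ann, c(5, 5))$id, "a")
  expect_equal(filter_by_coverage(emb, ann, c(1, 100))$id, c("a", "b"))
  expect_equal(nrow(filter_by_coverage(emb, ann, c(1e6, 1e7))), 0L)
  expect_error(filter_by_coverage(emb, ann, c(10, 1)), "low <= high")
})

test_that("banded coverage plot writes a PNG and shares the palette", {
  hist <- data.frame(multiplicity = c(2, 5, 40, 300),
                     n_kmers = c(100, 400, 50, 20))
  bands <- list(c(1, 10), c(11, 100))
  p <- withr::local_tempfile(fileext = ".png")
  res <- banded_coverage_plot(hist, bands, p)
  expect_true(file.size(p) > 0)
  expect_equal(res$labels, c("[1,10]", "[11,100]"))
  expect_equal(res$colors, band_palette(2))
  expect_error(banded_coverage_plot(hist[0, ], bands, p), "empty")
})
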