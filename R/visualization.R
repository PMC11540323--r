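# Static figures: quantile-binned colouring, aggregated latent scatters
# (pixel rasters, bounded memory for millions of points), coverage-banded
# k-mer spectra, coverage-range filtering.

#' Quantile binning of a continuous annotation
#'
#' Bin edges are placed at empirical quantiles (deciles by default) so each
#' colour carries roughly equal point mass. Mass points (e.g. many zero
#' coding densities) produce duplicate edges; the affected bins are collapsed
#' into one and the merge is reported.
#'
#' @param values Numeric vector (NAs allowed; they stay unbinned).
#' @param n_bins Requested number of bins (default 10 = deciles).
#' @return Object of class `quantile_binning`: `edges`, `bin` (1-based bin
#'   per value, NA for non-finite), `labels`, `n_merged` (how many requested
#'   bins were collapsed), `single` flag for constant input.
#' @export
quantile_bins <- function(values, n_bins = 10L) {
  fin <- is.finite(values)
  if (!any(fin)) stop("need at least one finite value")
  probs <- seq(0, 1, length.out = n_bins + 1L)
  edges <- unname(quantile(values[fin], probs = probs, type = 7))
  uedges <- unique(edges)
  n_merged <- length(edges) - length(uedges)
  single <- length(uedges) == 1L
  if (single) uedges <- c(uedges, uedges)
  bin <- rep(NA_integer_, length(values))
  bin[fin] <- findInterval(values[fin], uedges, rightmost.closed = TRUE,
                           all.inside = TRUE)
  labels <- sprintf("[%.4g,%.4g%s", uedges[-length(uedges)], uedges[-1L],
                    c(rep(")", length(uedges) - 2L), "]"))
  structure(list(edges = uedges, bin = bin, labels = labels,
                 n_bins = length(uedges) - 1L, n_merged = n_merged,
                 single = single),
            class = "quantile_binning")
}

#' @export
print.quantile_binning <- function(x, ...) {
  cat(sprintf("quantile_binning: %d bins%s\n", x$n_bins,
              if (x$n_merged > 0)
                sprintf(" (%d requested bins merged at mass points)",
                        x$n_merged) else ""))
  invisible(x)
}

#' Fixed categorical palette shared by scatter and coverage-band figures
#'
#' @param n Number of colours.
#' @return Character vector of hex colours.
#' @export
band_palette <- function(n) {
  base <- c("#4477AA", "#EE6677", "#228833", "#CCBB44", "#66CCEE",
            "#AA3377", "#BBBBBB", "#000000", "#E69F00", "#56B4E9",
            "#009E73", "#D55E00")
  rep_len(base, n)
}

# ordered (sequential) palette for quantile bins, dark -> light
seq_palette <- function(n) {
  ramp <- grDevices::colorRamp(c("#440154", "#31688E", "#35B779", "#FDE725"))
  grDevices::rgb(ramp(seq(0, 1, length.out = n)), maxColorValue = 255)
}

#' Render a latent scatter as an aggregated raster image
#'
#' Points are binned into pixels; pixels are coloured by the most frequent
#' category (with log-count intensity), so memory and output size are
#' bounded regardless of point count. Axes are the two latent dimensions.
#' Unassigned/NA categories render neutral gray.
#'
#' @param embedding Data frame `id`, `mu1`, `mu2`.
#' @param colors Optional per-read categories: a vector aligned with
#'   `embedding` rows, or named by read id (every embedding id must then be
#'   present). NULL renders point density alone.
#' @param point_scale `"none"` or `"by-length"`; with `"by-length"`,
#'   `lengths` weights each point's contribution.
#' @param lengths Per-read lengths (aligned or named), used when
#'   `point_scale = "by-length"`.
#' @param out Output PNG path.
#' @param width,height Raster size in pixels.
#' @param palette Colour per category level (default [band_palette()];
#'   ordered factors get a sequential palette).
#' @return Invisibly, the category levels and colours used.
#' @export
render_scatter <- function(embedding, colors = NULL,
                           point_scale = c("none", "by-length"),
                           lengths = NULL, out, width = 500L, height = 500L,
                           palette = NULL) {
  point_scale <- match.arg(point_scale)
  if (is.null(embedding) || nrow(embedding) == 0L) stop("empty embedding")
  n <- nrow(embedding)
  align <- function(v, what) {
    if (is.null(v)) return(NULL)
    if (!is.null(names(v))) {
      miss <- setdiff(embedding$id, names(v))
      if (length(miss) > 0L)
        stop("ids missing from ", what, ": ",
             paste(head(miss, 3L), collapse = ", "))
      v <- v[embedding$id]
    } else if (length(v) != n) {
      stop(what, " must have one entry per embedded read")
    }
    v
  }
  colors <- align(colors, "colors")
  lengths <- align(lengths, "lengths")
  w <- if (point_scale == "by-length") {
    if (is.null(lengths)) stop("point_scale='by-length' requires lengths")
    as.numeric(lengths)
  } else rep(1, n)
  pad <- function(r) if (diff(r) == 0) r + c(-0.5, 0.5) else
    r + c(-1, 1) * 0.01 * diff(r)
  rx <- pad(range(embedding$mu1)); ry <- pad(range(embedding$mu2))
  px <- pmin(pmax(1L, 1L + floor((embedding$mu1 - rx[1L]) /
                                   diff(rx) * width)), width)
  py <- pmin(pmax(1L, 1L + floor((embedding$mu2 - ry[1L]) /
                                   diff(ry) * height)), height)
  pix <- (py - 1L) * width + px
  npix <- width * height
  img <- array(1, dim = c(height, width, 3L)) # white background
  fill_pixel <- function(idx, rgbcol, intensity) {
    # idx: pixel linear index (x-major); intensity in (0,1]
    row <- height - ((idx - 1L) %/% width) # mu2 increases upwards
    col <- ((idx - 1L) %% width) + 1L
    for (ch in 1:3) {
      v <- 1 - intensity * (1 - rgbcol[ch])
      img[cbind(row, col, ch)] <<- v
    }
  }
  total <- numeric(npix)
  tw <- tapply(w, pix, sum)
  total[as.integer(names(tw))] <- tw
  occupied <- which(total > 0)
  inten <- log1p(total[occupied]) / max(log1p(total[occupied]))
  if (is.null(colors)) {
    fill_pixel(occupied, c(0.1, 0.1, 0.35), inten)
    levels_used <- NULL; cols_used <- NULL
  } else {
    f <- if (is.factor(colors)) colors else factor(colors)
    lv <- levels(f)
    if (is.null(palette)) {
      palette <- if (is.ordered(f)) seq_palette(length(lv)) else
        band_palette(length(lv))
    }
    best_w <- numeric(npix); best_k <- integer(npix)
    for (k in seq_along(lv)) {
      sel <- which(!is.na(f) & f == lv[k])
      if (length(sel) == 0L) next
      tk <- tapply(w[sel], pix[sel], sum)
      ii <- as.integer(names(tk))
      upd <- tk > best_w[ii]
      best_w[ii[upd]] <- tk[upd]
      best_k[ii[upd]] <- k
    }
    gray <- c(0.7, 0.7, 0.7)
    for (k in seq_along(lv)) {
      idx <- occupied[best_k[occupied] == k]
      if (length(idx) == 0L) next
      fill_pixel(idx, grDevices::col2rgb(palette[k])[, 1L] / 255,
                 log1p(total[idx]) / max(log1p(total[occupied])))
    }
    idx_na <- occupied[best_k[occupied] == 0L]
    if (length(idx_na) > 0L)
      fill_pixel(idx_na, gray, log1p(total[idx_na]) /
                   max(log1p(total[occupied])))
    levels_used <- lv; cols_used <- palette[seq_along(lv)]
  }
  png::writePNG(img, out)
  invisible(list(levels = levels_used, colors = cols_used,
                 xlim = rx, ylim = ry))
}

#' Subset an embedding by a k-mer coverage range
#'
#' Keeps reads whose median k-mer multiplicity lies in the closed range —
#' the programmatic equivalent of the coverage-range display filter.
#'
#' @param embedding Data frame `id`, `mu1`, `mu2`.
#' @param annotation Annotation table with `id` and `median_multiplicity`.
#' @param range Numeric `c(low, high)`, `low <= high`.
#' @return The embedding rows whose reads fall in the range.
#' @export
filter_by_coverage <- function(embedding, annotation, range) {
  if (length(range) != 2L || is.na(range[1L]) || is.na(range[2L]) ||
      range[1L] > range[2L])
    stop("range must be c(low, high) with low <= high")
  mm <- annotation$median_multiplicity[match(embedding$id, annotation$id)]
  keep <- !is.na(mm) & mm >= range[1L] & mm <= range[2L]
  embedding[keep, , drop = FALSE]
}

#' Coverage histogram with colour bands
#'
#' Draws the k-mer spectrum (distinct k-mers per multiplicity value) with
#' bars coloured by coverage band; the same palette is shared with
#' [render_scatter()] so the two views cross-reference.
#'
#' @param hist A [coverage_histogram()] data frame.
#' @param bands Band definitions as for [assign_coverage_bins()] (manual
#'   list/matrix of `c(low, high)`).
#' @param out Output PNG path.
#' @param log_x Log-scale the multiplicity axis.
#' @param palette Colour per band (default [band_palette()]).
#' @return Invisibly, the band labels and colours used.
#' @export
banded_coverage_plot <- function(hist, bands, out, log_x = TRUE,
                                 palette = NULL) {
  if (is.null(hist) || nrow(hist) == 0L) stop("empty coverage histogram")
  lab <- assign_coverage_bins(hist$multiplicity, bands, scheme = "manual")
  bands_used <- attr(lab, "bands")
  band_labels <- sprintf("[%g,%g]", bands_used[, 1L], bands_used[, 2L])
  if (is.null(palette)) palette <- band_palette(length(band_labels))
  colmap <- setNames(palette[seq_along(band_labels)], band_labels)
  colmap["outside"] <- "#BBBBBB"
  grDevices::png(out, width = 700, height = 450)
  on.exit(grDevices::dev.off())
  x <- if (log_x) log10(pmax(hist$multiplicity, 1)) else hist$multiplicity
  graphics::plot(x, hist$n_kmers, type = "h", lwd = 2,
                 col = colmap[lab],
                 xlab = if (log_x) "log10 k-mer multiplicity" else
                   "k-mer multiplicity",
                 ylab = "distinct k-mers",
                 main = "k-mer coverage spectrum")
  graphics::legend("topright", legend = c(band_labels, "outside"),
                   col = colmap[c(band_labels, "outside")], lwd = 4,
                   bty = "n")
  invisible(list(labels = band_labels,
                 colors = unname(colmap[band_labels])))
}
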