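# Peak detection in the 2D latent histogram via topological persistence,
# plus seeded sampling of reads near peaks for external spot-checking.

# one pass of a 3x3 box mean (edge cells average their available
# neighbours); used to damp per-bin sampling noise before equalization
box_smooth <- function(m) {
  n <- nrow(m); k <- ncol(m)
  acc <- matrix(0, n, k); cnt <- matrix(0, n, k)
  for (dr in -1:1) {
    for (dc in -1:1) {
      rs <- max(1L, 1L + dr):min(n, n + dr); rt <- rs - dr
      cs <- max(1L, 1L + dc):min(k, k + dc); ct <- cs - dc
      acc[rt, ct] <- acc[rt, ct] + m[rs, cs]
      cnt[rt, ct] <- cnt[rt, ct] + 1
    }
  }
  acc / cnt
}

#' 2D histogram of a latent embedding
#'
#' Bins encoder means on a square grid over the (1%-padded) bounding box.
#' Bin intervals are half-open with the last bin closed, so boundary points
#' fall strictly inside the grid. With `equalize = TRUE` (the default used
#' for peak finding) nonzero bins are rank-transformed to a uniform value
#' scale, so peaks of minor components are not swamped by the target
#' genome's dense clusters.
#'
#' @param embedding Data frame with columns `id`, `mu1`, `mu2`.
#' @param bins Grid size per axis (default 200).
#' @param equalize Rank-transform nonzero bins before peak finding.
#' @param smooth Number of 3x3 box-mean passes applied to the counts before
#'   the (optional) equalization; damps per-bin sampling noise so diffuse
#'   clusters do not shatter into many spurious local maxima. `counts`
#'   always stays raw. Default 2; use 0 for no smoothing.
#' @return Object of class `latent_histogram`: `counts` (bins x bins, raw),
#'   `values` (smoothed/equalized or raw), `xedges`, `yedges`, per-read bin
#'   indices `ix`, `iy`, `id`, and flags `equalized`, `degenerate`.
#' @export
latent_histogram <- function(embedding, bins = 200L, equalize = TRUE,
                             smooth = 2L) {
  if (is.null(embedding) || nrow(embedding) == 0L)
    stop("empty embedding")
  bins <- as.integer(bins)
  x <- embedding$mu1; y <- embedding$mu2
  rngx <- range(x); rngy <- range(y)
  degenerate <- (diff(rngx) == 0 && diff(rngy) == 0)
  pad <- function(r) {
    w <- diff(r)
    if (w == 0) r + c(-0.5, 0.5) else r + c(-1, 1) * 0.01 * w
  }
  rngx <- pad(rngx); rngy <- pad(rngy)
  xedges <- seq(rngx[1L], rngx[2L], length.out = bins + 1L)
  yedges <- seq(rngy[1L], rngy[2L], length.out = bins + 1L)
  ix <- findInterval(x, xedges, rightmost.closed = TRUE, all.inside = TRUE)
  iy <- findInterval(y, yedges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- matrix(tabulate((iy - 1L) * bins + ix, nbins = bins * bins),
                   nrow = bins, ncol = bins)
  values <- counts
  smooth <- as.integer(smooth)
  for (s in seq_len(max(0L, smooth))) values <- box_smooth(values)
  if (equalize) {
    nz <- which(values > 0)
    if (length(nz) > 0L) {
      eq <- matrix(0, bins, bins)
      eq[nz] <- rank(values[nz], ties.method = "average") / length(nz)
      values <- eq
    }
  }
  structure(list(counts = counts, values = values,
                 xedges = xedges, yedges = yedges,
                 ix = ix, iy = iy, id = embedding$id,
                 bins = bins, equalized = isTRUE(equalize),
                 smooth = smooth, degenerate = degenerate),
            class = "latent_histogram")
}

#' Detect local peaks by topological persistence
#'
#' Sweeps the histogram value level from high to low; each cell that starts
#' a new connected component (8-neighbourhood, union-find) is a peak birth.
#' When two components meet, the younger dies and its persistence is birth
#' minus the merge level; components that never merge persist down to zero.
#' Candidate peaks closer than `window / 2` bins (Chebyshev distance) to a
#' stronger peak are suppressed; peaks below `min_persistence` are dropped.
#' Kept peaks are then localized by the raw-count-weighted centroid of the
#' bins within `window / 2` of the birth cell, which is far more stable
#' than the single argmax bin when a cluster is broad relative to the grid.
#'
#' @param hist A [latent_histogram()].
#' @param window Suppression neighbourhood diameter in bins (default 20).
#' @param min_persistence Minimum persistence kept; default is the median
#'   nonzero histogram value (a data-driven noise floor). Use 0 to keep all.
#' @return Data frame of class `peak_set`: `rank`, `bx`, `by` (bin
#'   coordinates), `mu1`, `mu2` (bin centres), `persistence`, sorted by
#'   descending persistence.
#' @export
find_peaks_topology <- function(hist, window = 20L, min_persistence = NULL) {
  stopifnot(inherits(hist, "latent_histogram"))
  v <- hist$values
  bins <- hist$bins
  if (is.null(min_persistence))
    min_persistence <- if (any(v > 0)) median(v[v > 0]) else 0
  empty <- data.frame(rank = integer(0), bx = integer(0), by = integer(0),
                      mu1 = numeric(0), mu2 = numeric(0),
                      persistence = numeric(0))
  class(empty) <- c("peak_set", "data.frame")
  if (!any(v > 0)) return(empty)
  df <- .cpp_persistence_peaks(v)
  df <- df[df$persistence >= min_persistence, , drop = FALSE]
  df <- df[order(-df$persistence, df$bx, df$by), , drop = FALSE]
  # non-maximum suppression within the window
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    ok <- TRUE
    if (any(keep)) {
      d <- pmax(abs(df$bx[keep] - df$bx[i]), abs(df$by[keep] - df$by[i]))
      if (any(d < window / 2)) ok <- FALSE
    }
    keep[i] <- ok
  }
  df <- df[keep, , drop = FALSE]
  cx <- (hist$xedges[-1L] + hist$xedges[-length(hist$xedges)]) / 2
  cy <- (hist$yedges[-1L] + hist$yedges[-length(hist$yedges)]) / 2
  # centroid refinement: assign every occupied cell to its nearest kept
  # peak (Voronoi partition in bin space) and move each peak to the
  # count-weighted centroid of its cells; a birth cell is just the argmax
  # bin and wanders on broad clusters, the basin centroid does not
  if (nrow(df) > 0L) {
    occ <- which(hist$counts > 0)
    ox <- ((occ - 1L) %% bins) + 1L
    oy <- ((occ - 1L) %/% bins) + 1L
    ow <- hist$counts[occ]
    d2 <- outer(ox, df$bx, `-`)^2 + outer(oy, df$by, `-`)^2
    nearest <- max.col(-d2, ties.method = "first")
    for (i in seq_len(nrow(df))) {
      sel <- nearest == i
      tw <- sum(ow[sel])
      if (tw > 0) {
        df$bx[i] <- as.integer(round(sum(ow[sel] * ox[sel]) / tw))
        df$by[i] <- as.integer(round(sum(ow[sel] * oy[sel]) / tw))
      }
    }
  }
  out <- data.frame(rank = seq_len(nrow(df)), bx = df$bx, by = df$by,
                    mu1 = cx[df$bx], mu2 = cy[df$by],
                    persistence = df$persistence)
  rownames(out) <- NULL
  class(out) <- c("peak_set", "data.frame")
  out
}

#' Sample reads near detected peaks
#'
#' For each peak, draws `n_per_peak` reads (seeded) from the peak's
#' histogram bin, expanding one Chebyshev ring at a time until enough
#' candidates exist. Reads strictly inside the outermost ring reached are
#' always included; the random draw only fills the remainder from that
#' outermost ring, so the sample is always the closest available reads.
#' Sampled reads are intended for external homology spot-checking
#' (e.g. BLAST) of what each latent cluster contains.
#'
#' @param peaks A [find_peaks_topology()] result.
#' @param hist The [latent_histogram()] the peaks were found on.
#' @param n_per_peak Reads per peak (default 2).
#' @param seed Integer seed.
#' @return Named list (by peak rank) of read-id character vectors; peaks
#'   with fewer reachable reads than requested are reported in the
#'   `"short"` attribute.
#' @export
sample_reads_near_peaks <- function(peaks, hist, n_per_peak = 2L, seed = 1L) {
  stopifnot(inherits(hist, "latent_histogram"))
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  out <- list()
  short <- character(0)
  for (i in seq_len(nrow(peaks))) {
    if (n_per_peak <= 0L) { out[[as.character(peaks$rank[i])]] <- character(0); next }
    cheb <- pmax(abs(hist$ix - peaks$bx[i]), abs(hist$iy - peaks$by[i]))
    radius <- 0L
    while (sum(cheb <= radius) < n_per_peak && radius < hist$bins)
      radius <- radius + 1L
    # all reads strictly inside the final ring are taken deterministically;
    # random choice only happens within the outermost ring reached, so the
    # sample is always the closest available reads
    inner <- if (radius > 0L) which(cheb <= radius - 1L) else integer(0)
    ring <- which(cheb <= radius & cheb > radius - 1L)
    cand <- c(hist$id[inner], hist$id[ring])
    if (length(cand) < n_per_peak) short <- c(short, as.character(peaks$rank[i]))
    need <- n_per_peak - length(inner)
    take <- if (length(cand) <= n_per_peak) cand else
      c(hist$id[inner],
        hist$id[ring][sample.int(length(ring), need)])
    out[[as.character(peaks$rank[i])]] <- take
  }
  attr(out, "short") <- short
  out
}

#' Write a peak set with sample counts as TSV
#'
#' @param peaks A `peak_set`.
#' @param samples Optional result of [sample_reads_near_peaks()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(peaks, samples = NULL, path) {
  df <- as.data.frame(peaks)
  df$n_reads_sampled <- if (is.null(samples)) 0L else
    vapply(as.character(df$rank), function(r)
      length(samples[[r]]), integer(1))
  write_table_file(df[, c("rank", "mu1", "mu2", "persistence",
                          "n_reads_sampled")], path)
}
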