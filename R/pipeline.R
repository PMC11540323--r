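# Pipeline orchestration: one-call workflow over a read set, merged
# annotation table, manifest, reproducible seed fan-out.

# stable per-stage seed derived from the global seed and the stage name,
# so adding a stage never perturbs earlier stages' randomness
stage_seed <- function(global_seed, stage) {
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 31 + code) %% 1048573
  as.integer((as.numeric(global_seed) * 1048573 + h) %% 2147483647)
}

#' Pipeline run configuration
#'
#' Defaults are the workflow's canonical parameters: tetranucleotide
#' features (k = 4), coverage k = 31, uniqueness k = 8, hexamer segment
#' threshold 20, beta-VAE (beta 0.1, 15 epochs, batch 256), 200 histogram
#' bins, peak window 20, 2 sampled reads per peak.
#'
#' @param input Path to the read FASTA/FASTQ (may be gzipped).
#' @param out_dir Output directory.
#' @param k_features,k_coverage,k_unique K-mer sizes per statistic.
#' @param coding A [coding_config()].
#' @param coding_table A `hexamer_table`, or a path to one, or NULL for the
#'   bundled synthetic table.
#' @param vae A [vae_config()] (its seed is overridden by the fan-out of
#'   `seed`).
#' @param bins,window,n_per_peak Peak detection/sampling parameters.
#' @param labels Optional path to a read-id/class-label TSV.
#' @param seed Global seed; every stage's randomness derives from it.
#' @param force Recompute stages whose outputs already exist.
#' @return A list of class `run_config`.
#' @export
run_config <- function(input, out_dir, k_features = 4L, k_coverage = 31L,
                       k_unique = 8L, coding = coding_config(),
                       coding_table = NULL, vae = vae_config(),
                       bins = 200L, window = 20L, n_per_peak = 2L,
                       labels = NULL, seed = 1L, force = FALSE) {
  if (!file.exists(input)) stop("input path does not exist: ", input)
  if (!is.null(labels) && !file.exists(labels))
    stop("label table does not exist: ", labels)
  structure(list(input = input, out_dir = out_dir,
                 k_features = as.integer(k_features),
                 k_coverage = as.integer(k_coverage),
                 k_unique = as.integer(k_unique),
                 coding = coding, coding_table = coding_table, vae = vae,
                 bins = as.integer(bins), window = as.integer(window),
                 n_per_peak = as.integer(n_per_peak), labels = labels,
                 seed = as.integer(seed), force = isTRUE(force)),
            class = "run_config")
}

#' Merge per-stage annotation tables
#'
#' Outer join on read id across stage outputs; missing statistics become
#' NA and reads without a class label are `"unassigned"`.
#'
#' @param tables List of data frames, each with an `id` column.
#' @param labels Optional label data frame (`id`, `class_label`).
#' @return One merged annotation data frame.
#' @export
merge_annotations <- function(tables, labels = NULL) {
  tables <- Filter(Negate(is.null), tables)
  if (length(tables) == 0L) stop("no tables to merge")
  out <- tables[[1L]]
  for (i in seq_along(tables)[-1L]) {
    if (length(intersect(out$id, tables[[i]]$id)) == 0L)
      stop("no overlapping read ids between annotation tables")
    out <- merge(out, tables[[i]], by = "id", all = TRUE, sort = FALSE)
  }
  if (!is.null(labels)) {
    out$class_label <- labels$class_label[match(out$id, labels$id)]
    out$class_label[is.na(out$class_label)] <- "unassigned"
  }
  out
}

#' Compute the per-read annotation table
#'
#' Length, GC, estimated coding density, median k-mer multiplicity and
#' distinct-k-mer fraction for every read.
#'
#' @param reads A [seq_records()] data frame.
#' @param table A `hexamer_table` for coding density.
#' @param mult A `multiplicity_table` built over the same read set.
#' @param coding A [coding_config()].
#' @param k_unique K for the distinct-k-mer fraction.
#' @return Data frame `id`, `length`, `gc`, `coding_density`,
#'   `median_multiplicity`, `unique_kmer_fraction`.
#' @export
annotate_reads <- function(reads, table, mult, coding = coding_config(),
                           k_unique = 8L) {
  data.frame(id = reads$id,
             length = reads$length,
             gc = gc_content(reads$seq),
             coding_density = coding_density(reads$seq, table, coding),
             median_multiplicity = median_read_multiplicity(reads$seq, mult),
             unique_kmer_fraction = unique_kmer_fraction(reads$seq, k_unique),
             stringsAsFactors = FALSE)
}

#' Run the full workflow
#'
#' count -> density -> coverage -> uniqueness -> embed -> peaks -> plots.
#' Writes an embedding TSV, merged annotation table, peak table, sampled-
#' read FASTA, three PNG figures and a JSON manifest into `out_dir`.
#' Re-runs skip stages whose outputs exist unless `force`.
#'
#' @param config A [run_config()].
#' @return The output directory path, invisibly; the manifest lists every
#'   artifact.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(config$out_dir, f)
  outputs <- c(annotation = pth("annotation.tsv"),
               embedding = pth("embedding.tsv"),
               peaks = pth("peaks.tsv"),
               sampled = pth("sampled_reads.fasta"),
               plot_density = pth("scatter_coding_density.png"),
               plot_coverage = pth("scatter_coverage_bands.png"),
               plot_covhist = pth("coverage_histogram.png"),
               manifest = pth("manifest.json"))
  if (!config$force && all(file.exists(outputs))) {
    message("all outputs present; skipping (use force = TRUE to recompute)")
    return(invisible(config$out_dir))
  }
  t0 <- Sys.time()
  reads <- read_seq_file(config$input)
  if (nrow(reads) == 0L) stop("stage ingest: no reads in ", config$input)
  idx <- canonical_index(config$k_features)
  counts <- count_matrix(reads, idx)
  ctab <- config$coding_table
  if (is.null(ctab)) ctab <- synthetic_coding_table()
  if (is.character(ctab)) ctab <- read_hexamer_table(ctab)
  mult <- build_multiplicity_table(reads, k = config$k_coverage)
  ann <- annotate_reads(reads, ctab, mult, config$coding, config$k_unique)
  labels <- if (!is.null(config$labels)) read_label_table(config$labels)
  ann <- merge_annotations(list(ann), labels)
  vcfg <- config$vae
  vcfg$seed <- stage_seed(config$seed, "embed")
  emb <- embed_reads(counts, vcfg)
  write_table_file(emb$embedding, outputs[["embedding"]])
  hist2d <- latent_histogram(emb$embedding, bins = config$bins,
                             equalize = TRUE)
  peaks <- find_peaks_topology(hist2d, window = config$window)
  samples <- sample_reads_near_peaks(peaks, hist2d,
                                     n_per_peak = config$n_per_peak,
                                     seed = stage_seed(config$seed, "peaks"))
  write_peak_table(peaks, samples, outputs[["peaks"]])
  export_fasta_subset(config$input, unique(unlist(samples)),
                      outputs[["sampled"]])
  # figures: coding-density deciles, coverage bands, banded spectrum
  qb <- quantile_bins(ann$coding_density[match(emb$embedding$id, ann$id)])
  dens_lab <- factor(qb$labels[qb$bin], levels = qb$labels, ordered = TRUE)
  render_scatter(emb$embedding, colors = dens_lab,
                 out = outputs[["plot_density"]])
  covvals <- ann$median_multiplicity[match(emb$embedding$id, ann$id)]
  cov_lab <- assign_coverage_bins(covvals, scheme = "log")
  cov_bands <- attr(cov_lab, "bands")
  band_levels <- c(sprintf("[%g,%g]", cov_bands[, 1L], cov_bands[, 2L]),
                   "outside")
  pal <- c(band_palette(nrow(cov_bands)), "#BBBBBB")
  render_scatter(emb$embedding,
                 colors = factor(cov_lab, levels = band_levels),
                 out = outputs[["plot_coverage"]], palette = pal)
  banded_coverage_plot(coverage_histogram(mult), cov_bands,
                       outputs[["plot_covhist"]],
                       palette = pal[seq_len(nrow(cov_bands))])
  write_table_file(ann, outputs[["annotation"]])
  manifest <- list(
    package_version = as.character(utils::packageVersion("readsieve")),
    r_version = R.version.string,
    input = config$input,
    seed = config$seed,
    stage_seeds = list(embed = stage_seed(config$seed, "embed"),
                       peaks = stage_seed(config$seed, "peaks")),
    parameters = list(k_features = config$k_features,
                      k_coverage = config$k_coverage,
                      k_unique = config$k_unique,
                      coding_threshold = config$coding$threshold,
                      beta = config$vae$beta, epochs = config$vae$epochs,
                      batch_size = config$vae$batch_size,
                      bins = config$bins, window = config$window,
                      n_per_peak = config$n_per_peak),
    rows = list(reads = nrow(reads), embedded = nrow(emb$embedding),
                peaks = nrow(peaks)),
    outputs = as.list(outputs),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, outputs[["manifest"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(config$out_dir)
}
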