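# readsieve

Composition-based exploration and decontamination of long-read sets.

High-accuracy long reads (HiFi-class, ~10–20 kb) carry enough sequence to be
classified individually. A read set from a single specimen is rarely a single
genome: symbionts and other cobionts, organelles, and laboratory contaminants
all contribute reads. `readsieve` separates these *without reference
databases*, using only signals computable from the reads themselves:

1. **Tetranucleotide composition** — each read is summarised by its 136
   canonical 4-mer counts (a 4-mer and its reverse complement share one
   feature, so both strands of the same locus look identical).
2. **β-VAE embedding** — a small variational autoencoder (136 → 150 → 150 → 2,
   written in plain R) compresses the composition vectors to a 2-D latent
   mean μ per read. With β < 1 the KL term is down-weighted, so the latent
   space stays informative and distinct genomes form distinct clouds.
3. **Per-read annotations** that explain the clouds:
   - *coding density*: fraction of the read covered by maximal-scoring
     hexamer log-odds segments (score ≥ 20, both strands; Ruzzo–Tompa
     decomposition). Prokaryotes are dense and homogeneous, animal genomes
     are not, so this separates cobionts from hosts.
   - *median 31-mer multiplicity*: the lower median, over a read's canonical
     31-mers, of each k-mer's count across the whole read set — a per-read
     sequencing-depth proxy that flags organelles (huge) and contaminants
     (tiny).
   - *distinct 8-mer fraction*: a repeat/low-complexity indicator.
4. **Peak detection and sampling** — the 2-D embedding is binned into a
   200×200 histogram, lightly smoothed, rank-equalized, and swept with a
   topological-persistence union-find to find cluster peaks. A few reads
   (default 2) are sampled near each peak and exported as FASTA for external
   spot-checking (e.g. BLAST), which is how unlabeled clouds get names.
5. **Figures** — pixel-aggregated PNG scatters of the embedding colored by
   any annotation, plus k-mer coverage histograms, rendered deterministically
   without a display.

A synthetic mixture generator (`component_spec()`, `generate_mixture()`,
`preset_specs()`) produces labelled read sets with the statistical structure
the method assumes, so every claim above is tested end to end.

## Worked example

```r
library(readsieve)

# 1. a labelled synthetic mixture: host + endosymbiont + organelle + contaminant
mix <- generate_mixture(preset_specs(1L), seed = 11L)   # ~2900 reads

# 2. composition -> embedding
counts <- count_matrix(mix$reads, canonical_index(4L))  # n x 136
emb    <- embed_reads(counts, vae_config(seed = 42L))   # beta = 0.1

# 3. annotations
ann <- annotate_reads(mix$reads,
                      synthetic_coding_table(),
                      build_multiplicity_table(mix$reads))

# 4. peaks and sampled reads
h  <- latent_histogram(emb$embedding, bins = 200)
pk <- find_peaks_topology(h, window = 20)
sm <- sample_reads_near_peaks(pk, h, n_per_peak = 2, seed = 3)

# 5. a figure
render_scatter(emb$embedding,
               colors = cut(ann$coding_density, c(-Inf, .2, .5, .8, Inf)),
               out = "scatter.png")
```

Representative numbers from this exact run (fixed seeds, CPU-only, ~1 min):

- a linear probe on μ recovers the true component labels with **98.7%**
  held-out accuracy;
- the endosymbiont's median coding density exceeds the host's by **0.54**;
- the organelle cloud's median 31-mer multiplicity is **~2800** versus ~30
  for the host, and its latent centroid sits **7.5×** the host cloud's median
  radius away from the host centroid;
- per-component median multiplicity recovers simulated depths 5/50/500
  within **20%** (ratios ≈ 1.20, 1.04, 1.05 — low depth is biased upward
  because a read always observes its own copy of each k-mer);
- with β = 100 the posterior collapses (latent variance < 10⁻³); with the
  default β = 0.1 it does not (max variance ≈ 0.9).

## Command line

`inst/cli/readsieve.R` wraps the package as subcommands:

```sh
Rscript inst/cli/readsieve.R simulate --preset paper-like --seed 1 --out mix
Rscript inst/cli/readsieve.R run-all --in mix_reads.fasta --out-dir run1 --seed 1
Rscript inst/cli/readsieve.R count --in reads.fa --out counts.tsv
Rscript inst/cli/readsieve.R merge dens.tsv cov.tsv --labels labels.tsv --out ann.tsv
```

`run-all` writes a full artifact set (annotation/embedding/peak tables,
sampled-read FASTA, three PNGs, and a JSON manifest) and skips stages whose
outputs already exist.

## Tests and reproduction

```sh
R CMD INSTALL .
Rscript -e 'testthat::test_dir("tests/testthat", load_package = "installed")'
```

The suite includes per-module unit tests with brute-force oracles and an
acceptance file (`tests/testthat/test-acceptance.R`) asserting the headline
properties above at fixed seeds. A standalone summary run:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

writes the main quantities (feature counts, KL Monte-Carlo error, coverage
recovery ratios, probe accuracy, coding-density gap, GC–latent Spearman
correlation, collapse variances, peak recovery and sampled-read purity) as
JSON.

See `vignettes/methods.Rmd` for the full description of each method and the
reasoning behind the defaults.
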