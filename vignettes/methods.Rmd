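---
title: "Methods: composition-based read-set exploration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composition-based read-set exploration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(readsieve)
```

`readsieve` treats every long read as a classifiable object. This vignette
walks through each method, its defaults, and why those defaults are what they
are. Heavy chunks are not evaluated at build time; all of them are exercised
by the test suite.

## 1. Canonical k-mer composition

A read and its reverse complement describe the same locus, so features must
be strand-symmetric. For each k-mer we use the lexicographic minimum of the
k-mer and its reverse complement as the canonical key. For even k a k-mer can
be its own reverse complement, so the canonical key count is
$(4^k + 4^{k/2})/2$; for $k = 4$ that is 136 (not $4^4/2 = 128$).

```{r}
length(canonical_index(4L)$keys)
```

`count_matrix()` streams FASTA/FASTQ (optionally gzipped) in chunks and
counts with an Rcpp kernel; windows containing `N` are skipped, and reads
shorter than k are excluded with a recorded attribute. Counting is exactly
reverse-complement invariant:

```{r}
s <- "ACGTACGTTTGACA"
m1 <- count_matrix(seq_records("f", s), canonical_index(4L))
m2 <- count_matrix(seq_records("r", revcomp(s)), canonical_index(4L))
all(m1 == m2)
```

## 2. The β-VAE embedding

Counts are converted to proportions, standardized (the scaler is stored so
new reads can be projected), and passed through an autoencoder
136 → 150 → 150 → (μ, log σ²) → 150 → 150 → 136 with ReLU activations,
trained with Adam on

$$\mathcal{L} = \underbrace{\tfrac{1}{B\,D}\sum \|x - \hat x\|^2}_{\text{reconstruction}}
  \; + \; \beta \cdot \underbrace{\tfrac{1}{B}\sum_i \mathrm{KL}(q_i \,\|\, \mathcal{N}(0, I))}_{\text{regularization}}$$

The KL term has the usual closed form, available directly:

```{r}
kl_gaussian(0, 0)          # standard normal: 0
kl_gaussian(c(1, 0), c(0, 0))  # unit mean shift in one of two dims: 0.5
```

Two latent dimensions are used because the embedding's purpose is a plot a
person can act on. β defaults to 0.1: with β ≥ 1 on this data the KL term
dominates and the posterior collapses — μ variance drops below 10⁻³ and all
structure disappears. The package warns when configured with β ≥ 1. Training
is deterministic given `vae_config(seed = )`; the RNG state is saved and
restored around training.

```{r, eval = FALSE}
emb <- embed_reads(counts, vae_config(beta = 0.1, epochs = 15L,
                                      batch_size = 256L, seed = 42L))
```

The defaults (15 epochs, batch 256) assume a few thousand reads. For small
sets (hundreds of reads) there are too few gradient updates per epoch;
raise `epochs` or lower `batch_size`.

## 3. Per-read annotations

**Coding density.** Each read is scored in all six frames with hexamer
log-odds (coding vs. background table; `synthetic_coding_table()` ships a
table trained on generator output, and `train_hexamer_table()` builds one
from any labelled sequence). Maximal-scoring segments are extracted with the
Ruzzo–Tompa algorithm; segments scoring ≥ 20 on either strand are merged and
the covered fraction is the read's coding density. The threshold trades
sensitivity against false segments: density is monotonically non-increasing
in the threshold, and scoring is exactly strand-symmetric — both properties
are asserted in the tests.

**Median multiplicity (coverage proxy).** A table of canonical 31-mer counts
is built over the whole read set; a read's annotation is the *lower median*
of its windows' counts. Medians recover simulated depth within 20% across
5–500×. Two systematic effects are worth knowing: a read always observes its
own copy of each k-mer, so at depth λ the median concentrates near λ + 1
(visible at low depth: ratio ≈ 1.2 at λ = 5), and substitution errors shift
medians down in proportion to depth (a 0.1% error rate corrupts ~3% of
31-mer windows).

**Distinct 8-mer fraction.** The number of distinct (non-canonical) 8-mers
divided by the number of valid windows; near 1 for complex sequence, low for
tandem repeats.

`annotate_reads()` computes all of these plus length and GC into one table;
`merge_annotations()` outer-joins per-stage tables and fills missing class
labels with `"unassigned"`.

## 4. Peak detection by topological persistence

The 2-D embedding is binned into a 200×200 histogram. Raw counts are kept,
but peak detection runs on a transformed copy: two 3×3 box-smoothing passes
(suppresses Poisson speckle that otherwise creates spurious local maxima),
then rank equalization of the nonzero bins to (0, 1] (makes persistence
comparable between dense and sparse clouds). Bins are swept from high to low
value; a union-find over the 8-neighbourhood tracks connected components. A
component born at value $b$ that merges into an older one at value $d$ has
persistence $b - d$. Peaks closer than half the `window` (Chebyshev
distance) to a stronger peak are suppressed, and each surviving peak is
relocated to the count-weighted centroid of its Voronoi cell of occupied
bins — the raw birth cell is a noisy extremum, the centroid is the cluster
centre.

```{r, eval = FALSE}
h  <- latent_histogram(emb$embedding, bins = 200, smooth = 2)
pk <- find_peaks_topology(h, window = 20)   # min_persistence: median nonzero
sm <- sample_reads_near_peaks(pk, h, n_per_peak = 2, seed = 3)
export_fasta_subset("reads.fasta", unique(unlist(sm)), "sampled.fasta")
```

Sampling draws reads from the bins nearest each peak, expanding in rings
until enough candidates exist, deterministically under the given seed. The
sampled FASTA is the bridge to reference-based tools: a handful of reads per
cluster is enough to name it.

## 5. Figures

`render_scatter()` rasterizes the embedding by pixel aggregation (majority
color per pixel, log-scaled intensity) and writes a PNG deterministically —
byte-identical across runs on the same input. Colors typically come from
`quantile_bins()` of an annotation column or from `assign_coverage_bins()`
(manual or log-spaced coverage bands). `coverage_spectrum_plot()` and
`banded_coverage_plot()` render the k-mer multiplicity histogram.

## 6. Synthetic mixtures

`component_spec()` describes one genome: length, GC, coding fraction
(realized by planting codon-usage-tilted coding blocks), number of
GC-heterogeneous blocks, coverage, read-length distribution, and substitution
error rate. `generate_mixture()` simulates reads from both strands,
interleaves components, and writes FASTA plus a truth table. Everything is
deterministic given the spec seeds and the mixture seed. `preset_specs()`
returns a four-component configuration (host 300 kb at 30×, endosymbiont
150 kb at 120× with high coding density, organelle 16 kb at 2000×,
contaminant 100 kb at 3×) that reproduces the qualitative structure the
method targets: four latent clouds, a coding-density gap ≥ 0.3 between
endosymbiont and host, and an organelle cloud at extreme multiplicity.

## 7. Pipeline and CLI

`run_all(run_config(...))` executes ingest → count → embed → annotate →
peaks → sample → render with per-stage seeds derived from one master seed,
writes a JSON manifest, and skips stages whose outputs already exist
(`force = TRUE` overrides). The same pipeline is available from the shell
via `inst/cli/readsieve.R` (see the README for subcommands).
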