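Package: readsieve
Title: Composition-Based Exploration and Decontamination of Long-Read Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to disentangle mixed high-accuracy long-read samples
    (target genome, cobionts, organelles, contaminants) without reference
    databases. Reads are summarised by canonical tetranucleotide counts,
    embedded into two dimensions with a beta-variational autoencoder, and
    annotated with estimated coding density (hexamer log-odds scoring),
    k-mer-median coverage (canonical 31-mers), and the distinct 8-mer
    fraction. Local peaks in the latent density are detected by topological
    persistence, reads near peaks can be sampled and exported for external
    spot-checking, and annotated scatter/coverage-histogram figures are
    rendered by pixel aggregation. A synthetic mixture generator provides
    labelled test data with the statistical structure the method assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    MASS,
    optparse,
    withr,
    yaml,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
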