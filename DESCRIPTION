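Package: mbstage
Title: Spatial and Pseudotemporal Staging of Midbrain Organoids Against
    Fetal Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for benchmarking iPSC-derived midbrain organoids against
    fetal midbrain tissue using Visium-style spatial transcriptomics and
    single-cell RNA-seq. Implements spot labeling by deconvolved cell-type
    abundance, neighboring-spot pair-composition profiles, similarity-weighted
    temporal alignment of organoids to gestational timepoints, running-average
    expression trends along annotated maturation paths, Moran's I spatial
    autocorrelation screening with permutation nulls, cluster-graph lineage
    extraction with a PC1 pseudotime proxy and binned expression profiles,
    gene-module activation scoring with a resampled permutation test, and
    pseudobulk Pearson-correlation staging. Includes a synthetic Visium-like
    data generator with known ground truth so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
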