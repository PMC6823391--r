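Package: rgcmarkers
Title: Marker-Gene Discovery for Single-Cell Retinal Ganglion Cell Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for discovering subset- and subtype-marker genes from small
    panels of single-cell transcriptomes, as used for parvalbumin-positive and
    functionally classified retinal ganglion cells profiled on Affymetrix
    microarrays. Provides series-matrix-style expression input/output, an
    in-silico library quality gate on required and contaminant marker genes, a
    two-component Gaussian-mixture variance filter that separates noise probesets
    from informative ones, agglomerative hierarchical clustering of cells with
    Pearson-correlation distance and average linkage, prevalence-based marker
    calling, seed-gene correlate screens with cross-dataset intersection, gene
    panel detection profiles, and a seeded synthetic-data generator that emulates
    the statistical structure of such experiments so the whole pipeline can be
    exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
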