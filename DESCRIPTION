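Package: mitoclade
Title: Comparative Mitogenomics of Closely Related Species Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of animal mitochondrial genomes in
    recently diverged species clusters: merging multiple per-coverage assemblies
    into a threshold consensus, composition and codon-usage characterization,
    sliding-window and pairwise p-distance profiling, alignment site
    classification, Nei-Gojobori (1986) dN/dS estimation per protein-coding
    gene, four-fold degenerate third-position site extraction, and simplified
    strict-clock divergence dating on neighbor-joining topologies. Includes a
    seeded simulator that builds annotated AT-rich mitogenomes, evolves them
    along a dated tree under per-gene purifying selection, and emits noisy
    assembly replicates, so the whole pipeline is testable without external
    sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    withr
Config/testthat/edition: 3
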