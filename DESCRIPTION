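Package: clonepath
Title: Joint Mutational and Transcriptional Analysis of Clonal Evolution
    from Single Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying cancer evolution and clonal selection from
    single-cell data in which both somatic mutations and gene expression are
    observed. Builds a rooted clonal tree by minimum spanning tree over
    clone genotype profiles, scores clones against gene-set collections
    (mutation Jaccard scores, expression module scores, mutated-gene
    expression, and mutated ligand-receptor scores), computes Spearman
    evolutionary-path and clonal-selection statistics along root-to-leaf
    paths, compares them across clinical contexts with rank-based tests and
    Benjamini-Hochberg correction, quantifies clone-cluster degeneracy
    (normalized entropy, mutual information, Simpson diversity, permutation
    null), and validates the statistics on simulated clonal trees with
    configurable genotype noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
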