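Package: crossec
Title: Cross-Species Conservation of Gene Expression from Tissue and
    Co-Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Computes per-ortholog expression conservation (EC) scores
    between two species from gene-by-tissue expression matrices, using a
    corresponding-tissue method (Pearson correlation of relative-abundance
    profiles over matched tissues) and three co-expression reference-set
    methods: correlation of pairwise-correlation-matrix rows over the
    whole 1-1 ortholog set, an iterative weighted-correlation refinement
    that down-weights reference orthologs with diverged expression, and a
    variant restricted to nodes of conserved co-expression networks
    identified against background correlation thresholds from random gene
    pairs. Includes Euclidean-distance divergence counterparts,
    random-pairing and permuted-reference null controls, method-agreement
    statistics, whole-data versus common-tissue comparisons, and a seeded
    latent-module simulator of paired two-species expression data with
    known per-gene conservation.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
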