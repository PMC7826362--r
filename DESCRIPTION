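Package: icmtools
Title: Spatial and Single-Cell Transcriptomic Analysis of Blastocyst Lineages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for quantitative analysis of preimplantation
    mouse embryos: a geometric inside/outside nucleus classifier for
    quantitative immunofluorescence built on an in-silico embryo surface
    (convex-hull triangulation of nuclear centroids and point-to-face
    distance features); highly-variable-gene selection from the mean-CV^2
    relationship of FPKM matrices; weighted coexpression network modules
    with eigengene summaries; diffusion-map embeddings, pseudotime and
    trajectory/gene-trend curve fitting; simplex-constrained least-squares
    lineage deconvolution ("fraction of identity"); and a family of
    group-comparison and gene-set statistics (rank-based differential
    expression with Benjamini-Hochberg control, ternary expression
    fractions with a permutation density-bias test, a cumulative-sum
    relative-percentage pathway statistic, hypergeometric enrichment and
    preranked GSEA). Includes ground-truthed synthetic data generators for
    blastocyst-like nuclear point clouds and structured single-cell FPKM
    matrices, so every stage is exercisable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fgsea
Config/testthat/edition: 3
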