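# icmtools

Tools for quantitative analysis of preimplantation mouse embryos, built for
studies that combine quantitative immunofluorescence (QIF) of segmented
nuclei with single-cell RNA-seq of blastocyst lineages (ICM, trophectoderm,
epiblast, primitive endoderm) — for example, dissecting how a mutant ICM
diverges toward a trophectoderm-like transcriptional program.

The package implements, as tested and reusable functions:

- **Spatial inside/outside classification.** An in-silico embryo surface is
  the convex-hull triangulation of all nuclear centroids (incremental 3-D
  hull, watertight with F = 2V − 4). For each nucleus, the distance to every
  surface face is computed; 2-means clustering of (minimum distance,
  variance of distances) calls nuclei *inside* (ICM: large minimum, low
  variance) or *outside* (TE: zero minimum, high variance). Genotype
  comparisons of normalized intensities use the Kruskal–Wallis test, with an
  exact small-sample permutation option.
- **Variable-gene selection** from the mean–CV² relationship of FPKM
  (select genes with mean log2FPKM > 0.5, logCV² > 0.5, above a loess
  trend), after an expressed-gene filter (FPKM > 0 in ≥ 1 condition).
- **Coexpression modules**: unsigned adjacency |r|^10, topological-overlap
  dissimilarity, average-linkage clustering cut at 0.35 with minimum module
  size 30, and first-PC module eigengenes with a deterministic sign.
- **Trajectory analysis**: PCA and diffusion-map embeddings, pseudotime as
  diffusion distance from a root cell, cubic smoothing-spline trajectories
  (λ = 0.01) and loess gene trends along pseudotime.
- **Fraction of identity**: simplex-constrained least-squares deconvolution
  of a query profile against per-lineage signature means,
  min ‖S f − x‖² with f ≥ 0, Σf = 1, solved by penalty-augmented
  nonnegative least squares (Lawson–Hanson).
- **Group and gene-set statistics**: rank-sum differential expression with
  Benjamini–Hochberg control, marker derivation (adjusted p < 0.05 +
  direction), ternary expression fractions with a permutation density-bias
  test, a cumulative-sum relative-percentage pathway statistic,
  hypergeometric over-representation, and preranked GSEA.
- **Synthetic data generators** for blastocyst-like nuclear point clouds
  and structured FPKM matrices (planted markers, high-variance genes,
  module programs, latent trajectories, known mixing fractions), so every
  stage can be validated against ground truth.

See `vignettes/methods.Rmd` for the models, parameter conventions and
design decisions, and `analysis/01…06_*.R` for a narrated end-to-end run.

## Worked example

Simulate an embryo, classify nuclei, and check against ground truth:

```r
library(icmtools)

sim   <- simulate_embryo(embryo_sim_params(seed = 1))
calls <- classify_embryos(sim$nuclei, seed = 1)
mean(calls$label == sim$truth$nucleus_labels)
#> [1] 0.9733333
```

Over the 50-embryo study condition (`analysis/02_spatial_qif.R` prints
`inside/outside accuracy vs ground truth: 98.7%`), the aggregate accuracy
is 98.7%: the rare misses are ICM nuclei that genuinely graze the
trophectoderm shell.

Deconvolve noisy mixtures of lineage signatures
(`analysis/05_deconvolution.R`):

```
mean absolute error of recovered fractions: 0.019 (30 queries)
median fractions by group:
           EPI   PrE    TE
TE_like  0.203 0.191 0.612
EPI_like 0.600 0.242 0.151
```

Queries constructed as ~60% TE are recovered with a TE median fraction of
0.612 and clearly separated groups (smallest pairwise Welch p ≈ 1e-23).
The full analysis sequence is:

```sh
Rscript analysis/01_simulate_data.R      # synthetic study datasets
Rscript analysis/02_spatial_qif.R        # surfaces, inside/outside, QIF tests
Rscript analysis/03_variable_genes_modules.R
Rscript analysis/04_trajectory_pseudotime.R
Rscript analysis/05_deconvolution.R
Rscript analysis/06_set_statistics.R
```

Each script writes its tables under `results/`.

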