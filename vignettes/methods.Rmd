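---
title: "Methods: spatial and transcriptomic analysis of blastocyst lineages"
author: "icmtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial and transcriptomic analysis of blastocyst lineages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icmtools)
```

`icmtools` re-implements, as a tested and reusable pipeline, the
computational procedures of a single-cell study of preimplantation mouse
embryos: spatial classification of nuclei from quantitative
immunofluorescence, variable-gene selection, coexpression-module eigengene
analysis, diffusion-map pseudotime, simplex-constrained lineage
deconvolution, and a family of group-comparison and gene-set statistics.
Every stage can be exercised on synthetic data with known ground truth, and
the package's tests do exactly that. This vignette explains the models,
the parameters that matter, and the design decisions taken where the
procedures admit more than one reading.

## The spatial stage: an in-silico embryo surface

A blastocyst consists of an outer trophectoderm (TE) shell surrounding the
inner cell mass (ICM). Given a table of segmented nuclei (centroid, volume,
per-channel fluorescence), the pipeline reconstructs the embryo surface as
the triangulated boundary of the nuclear centroid cloud: the convex-hull
boundary of the 3-D Delaunay complex. For a convex point cloud these
coincide, and the hull is the only watertight boundary the construction
defines; non-convex alpha-shape surfaces are deliberately out of scope. The
hull is built by an incremental algorithm with consistently oriented faces,
so every surface satisfies the closed-triangulation relation F = 2V - 4 and
every edge is shared by exactly two triangles — both audited in the tests.

For each nucleus the distance to *every* surface triangle is computed
(closest-point via the standard barycentric region decomposition). Two
features summarize the vector of face distances: the minimum and the
population variance. Interior (ICM) nuclei sit away from their nearest face
and at comparable distances from all faces (large minimum, small variance);
shell (TE) nuclei touch their nearest face but are far from faces across
the cavity (zero minimum, large variance). A 2-means clustering of the
standardized features assigns labels, with the convention that the cluster
with the larger mean minimum distance is "inside" (smaller mean variance on
ties). Because the procedure leaves initialization and scaling open, we
declare: features are standardized to unit variance, and k-means uses a
greedy farthest-point start plus ten seeded random restarts, making calls
deterministic given data and seed. Surfaces and clusterings are always per
embryo; nuclei never mix across embryos.

Two intensity normalizations are provided for genotype comparisons of
fluorescence, since published violin plots rarely state one: a per-embryo
z-score of log intensities (default) and division by the per-embryo median
of a reference channel. Group differences within a tissue are tested with
the Kruskal-Wallis rank test; for total n at most 10 an exact permutation
p-value by full enumeration is available alongside the chi-square
approximation. A caveat the tests document: at n = 8 the permutation null
of H is discrete with atoms of mass up to ~0.11, so the chi-square p can
differ from the exact tail probability by ~0.1 in the mid-range; the two
agree to ~0.02 only in the significance tail (p below about 0.05).

## Expression core: filtering and variable genes

Expression matrices are FPKM, genes by cells. The expressed-gene filter
keeps genes with FPKM > 0 in at least one condition. Log transformation is
log2(FPKM + 1); the pseudocount of 1 (so zero maps to zero) is a declared
convention, configurable.

Highly variable genes are selected from the mean-CV^2 relationship: per
gene, the mean of log2(FPKM + 1) and the squared coefficient of variation
of raw FPKM, reported as log10 ("logCV^2"). A locally weighted robust
regression (span 0.3) of logCV^2 on the mean captures the mean-variance
trend, and genes are selected when mean > 0.5, logCV^2 > 0.5 and — by
default — the trend residual is positive. The thresholds-only reading is
available as a switch (`require_above_trend = FALSE`), since the
two-threshold rule alone is also a defensible reading of the procedure.
The base of the CV^2 logarithm (log10) is likewise configurable.

## Coexpression modules and eigengenes

The network is unsigned: adjacency is |Pearson correlation|^beta with soft
threshold beta = 10. The topological overlap dissimilarity is
1 - (shared-neighbour sum + adjacency) / (min connectivity + 1 - adjacency).
Genes are clustered by average-linkage on this dissimilarity and modules
are a *static* cut at height 0.35 with minimum size 30 — the minimal
faithful reading of a single stated distance; dynamic tree cutting is out
of scope. Clusters below the size threshold dissolve to "unassigned"
(module 0) and surviving modules are renumbered by decreasing size.

A consequence worth stating: after raising correlations to the 10th power,
a cut at 0.35 only retains gene pairs with |r| of roughly 0.96 or more. The
synthetic generator therefore plants modules as two-state (on/off) lineage
programs — an on/off separation of 12 log2 units with graded within-state
variation — which is also the biologically natural picture for
lineage-restricted expression programs in the blastocyst (marker genes such
as those of the TE program switch between silence and hundreds of FPKM).
Planted modules with weaker, merely-correlated structure would not survive
a static 0.35 cut; passing module-recovery tests therefore demonstrates
recovery of strong programs, not of subtle covariation.

The module eigengene is the first principal component score of the
module's gene-standardized expression, scaled to unit variance and
sign-oriented to correlate nonnegatively with the module-average profile
("weighted average expression profile" is treated as a gloss for the first
PC, the standard definition). The sign convention makes eigengenes
bit-for-bit reproducible.

## Embeddings, pseudotime and trend curves

PCA is centered, unscaled, with a deterministic sign convention (the
largest-magnitude loading of each component is positive). The diffusion map
uses a Gaussian kernel on Euclidean distances with a single global width:
the median pairwise distance by default. (Locally adaptive kernel widths
are a common alternative; the global-width variant is declared and the
width is configurable.) With density normalization (default), the kernel is
divided by the outer product of its row sums before Markov normalization,
removing sampling-density effects. The embedding consists of right
eigenvectors 2..(m+1) of the row-stochastic transition matrix, each scaled
by its eigenvalue, computed through the symmetric conjugate operator for
numerical stability and given a deterministic sign.

Pseudotime is the diffusion distance from an explicit root cell —
Euclidean distance in the eigenvalue-scaled component space — min-max
scaled to [0, 1]. The root is a required input (earliest-stage cell by
default when stage labels exist); no branching detection is attempted, and
the figures' pseudotime axes in the source study are treated as a
qualitative target only, since the exact construction there is unstated.

Trajectory curves through the embedding are cubic smoothing splines
against pseudotime with roughness weight lambda = 0.01 ("cubic line");
per-coordinate fits collapse duplicate abscissae by averaging. As lambda
grows the fit tends to the least-squares line, and a noiseless line is
reproduced exactly — both are tested limits. Gene-level trends are
locally weighted regressions (tricube, degree 2, span 0.5) of log2
expression on pseudotime, evaluated on a 100-point grid.

## Fraction of identity (deconvolution)

Reference signatures are per-class arithmetic means of FPKM (e.g. E4.5
EPI, PrE, and mutant profiles). A query profile x is deconvolved by
solving min ||S f - x||^2 subject to f >= 0, sum(f) = 1, restricted to
genes expressed in the query and — by default — in every signature column
(the conservative reading of "overlapping expression data, FPKM > 0"; a
flag relaxes to query-only, and the threshold can be raised to FPKM > 1,
i.e. log2FPKM > 0). Mixing is modelled on linear FPKM, matching the linear
mixing model implicit in signature-based deconvolution. The sum constraint
is enforced by an augmented penalty row (weight 1e6) inside a nonnegative
least-squares solve, then exact renormalization onto the simplex. The NNLS
core is a Lawson-Hanson active-set solver written for this package with a
tolerance-based anti-stall rule, which converges reliably on
penalty-augmented systems. Tests verify exact recovery of noiseless
mixtures (max error below 1e-6), simplex feasibility for arbitrary inputs,
and optimality against a dense simplex grid search.

## Group and gene-set statistics

Differential expression is a deliberately transparent stand-in for
error-model-based single-cell machinery: a two-sided Wilcoxon rank-sum
test per gene on log2(FPKM + 1) (exact for combined n at most 12 when ties
permit, otherwise normal approximation with midrank correction), the mean
log2 difference as effect, and Benjamini-Hochberg adjustment. Published
adjusted p-values from error-model methods are therefore not numerical
targets; planted-effect recovery (recall and false-discovery proportion)
is what the tests assert. Lineage markers are genes with adjusted p < 0.05
and effect in the requested direction.

Ternary fractions are per-gene compositional coordinates: the three group
means normalized to sum to one. The density-bias test partitions the
simplex into seven regions — three apexes (dominant fraction > 0.6), three
edges (smallest fraction < 0.15), centre otherwise; declared conventions —
and compares region counts against a null obtained by permuting cell group
labels, one-sided per region with BH across regions.

The pathway cumulative-sum statistic formalizes a relative-percentage
comparison whose exact published form is unstated; the formalization here
is declared: per pathway gene, r = 100 * meanA / (meanA + meanB); the
reported curve is the cumulative sum of sorted r; the test statistic is
sum(r - 50), calibrated two-sided by permuting cell labels. The statistic
is antisymmetric under group swap, and identical groups give r = 50
exactly — both tested.

Over-representation uses the upper-tail hypergeometric p (one-sided, the
standard in pathway enrichment) with BH across sets; gene sets are read
from GMT files, and the universe is a required explicit input. Preranked
GSEA orders genes by decreasing score and takes the maximum-magnitude
running-sum deviation as ES (hit increments 1/k unweighted or
|score|-proportional at weight 1, miss decrements 1/(N-k)); the null is
uniform random gene-label permutation, NES divides ES by the mean |null
ES| of matching sign, and the permutation p uses the add-one convention so
it never reaches zero.

## The synthetic-data generators

`simulate_embryo()` emulates a mid-blastocyst at the scale the spatial
stage expects: 60 shell nuclei on a jittered sphere of radius 50 um
(jitter 1.5 um), 15 ICM nuclei in a Gaussian clump (sd 10 um) displaced
40% of the radius toward one pole and constrained inside the shell
(ellipsoidal norm < 0.85, by rejection), lognormal channel intensities
with lineage-dependent log-means, and lognormal volumes around 700 um^3.
With these conditions the aggregate inside/outside accuracy of the
classifier over 50 seeded embryos is above 98%; single embryos can dip
slightly below when clump nuclei genuinely graze the shell, which is the
biologically realistic ambiguity (the ICM is apposed to the polar TE).

`simulate_expression()` generates FPKM as 2^(baseline + effects + noise):
per-gene baselines uniform on log2 FPKM 1-6, lognormal noise with sd 0.9
log2 units (a typical single-cell scale), per-class signature effects
(default +2 log2), planted high-variance genes whose noise sd is 4x the
background, two-state module programs (above), and monotone trend genes
(+/- 3 log2 across the latent ordering, alternating sign). The background
noise scale was chosen so that, at the 4x multiplier, the true logCV^2 of
planted HVGs (~1.6) clears the 0.5 selection threshold with a margin that
survives 40-cell sampling noise while background genes (~-0.9) stay well
below it. All randomness flows through deterministic sub-streams of one
seed, so enlarging one block of draws never perturbs another, and every
generator is a pure function of its parameters.

What the generators do *not* emulate: dropout as a distinct zero-inflation
process (zeros arise only through the expression floor), count-level
sampling noise, batch effects, doublets, or gene-length effects in FPKM.
Passing tests therefore demonstrate correctness of the procedures under a
clean lognormal regime, not robustness to every artefact of real
single-cell data.

`simulate_mixtures()` composes known simplex fractions of signature
columns with optional multiplicative lognormal noise, providing exact
ground truth for deconvolution.

## Problem sizes and numerical choices

The test-suite and acceptance study conditions are: 50 embryos (75 nuclei
each) for the classifier; 2,000 genes x 40 cells with 100 planted HVGs
(10 seeds) for selection; 400 genes x 60 cells with 4 modules of 40 genes
(10 seeds) for module recovery; 100 mixtures over a 3-class signature for
deconvolution; 50-cell trajectories with 40 trend genes (10 seeds) for
pseudotime; and 2,000-gene, 20-vs-20 comparisons for differential
expression. Degenerate inputs fail loudly: coplanar centroids name the
embryo, zero-variance genes are listed, too-small loess windows advise a
larger span, and a numerically vanishing diffusion kernel advises a larger
sigma. Permutation p-values use the add-one convention; all clustering,
eigenvector and k-means sign/label freedoms are resolved by documented
deterministic rules.

## Known limitations

Beyond the generator caveats above: the surface construction assumes a
roughly convex embryo; TE subtypes (mural/polar) are not called; no
branching pseudotime, RNA velocity or batch correction; enrichment
requires user-supplied gene sets (no pathway-database client); and the
rank-based differential-expression stand-in will be conservative relative
to error-model methods at very small cell numbers.
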