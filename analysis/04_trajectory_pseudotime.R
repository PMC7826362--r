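#!/usr/bin/env Rscript

# Trajectory stage: diffusion-map embedding of cells, pseudotime from the
# earliest cell along the planted latent ordering, a smoothing-spline
# trajectory (lambda = 0.01) through the embedding, and loess trends of
# individual trend genes against pseudotime.
#
# Writes results/embedding.csv, results/pseudotime.csv,
# results/gene_trends.csv.

suppressPackageStartupMessages(library(icmtools))
dir.create("results", showWarnings = FALSE)

dat <- read_expression("results/data/expression.tsv", "results/data/annotation.csv")
truth <- jsonlite::read_json("results/data/expression_ground_truth.json",
                             simplifyVector = TRUE)
roles <- unlist(truth$gene_roles)
latent <- unlist(truth$latent_time)

lm2 <- log2_transform(dat$matrix)
trend_genes <- names(roles)[roles == "trend"]
emb <- diffusion_map(lm2[trend_genes, ], embedding_params(n_components = 3))
write.csv(data.frame(cell_id = rownames(emb$coordinates), emb$coordinates),
          "results/embedding.csv", row.names = FALSE)

root <- names(which.min(latent))
pt <- pseudotime(emb, root)
rho <- cor(pt$pseudotime, latent[names(pt$pseudotime)], method = "spearman")
cat(sprintf("pseudotime vs latent order: Spearman rho = %.3f (root %s)\n",
            rho, root))
write.csv(data.frame(cell_id = names(pt$pseudotime), pseudotime = pt$pseudotime),
          "results/pseudotime.csv", row.names = FALSE)

curve <- fit_trajectory_curve(pt$pseudotime, emb$coordinates[, 1:2], lambda = 0.01)
cat(sprintf("trajectory spline fitted (lambda = %.2g), RSS = %.3f\n",
            curve$lambda, sum((curve$fitted - emb$coordinates[, 1:2])^2)))

grids <- lapply(trend_genes[1:4], function(g) {
  tr <- fit_gene_trend(pt$pseudotime, lm2[g, ], span = 0.5)
  data.frame(gene = g, tr$grid)
})
write.csv(do.call(rbind, grids), "results/gene_trends.csv", row.names = FALSE)
cat("loess trends written for", 4, "trend genes\n")
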