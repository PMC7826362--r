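#!/usr/bin/env Rscript

# Group-comparison and gene-set stage: rank-based differential expression
# with BH control between two lineage classes, marker derivation, ternary
# expression fractions across the three classes with the density-bias
# permutation test, the cumulative-sum relative-percentage pathway
# statistic, hypergeometric enrichment of the planted signature sets, and
# preranked GSEA on the DE ranking.
#
# Writes results/de.csv, results/markers_*.txt, results/ternary.csv,
# results/ternary_bias.csv, results/enrichment.csv, results/gsea.csv.

suppressPackageStartupMessages(library(icmtools))
dir.create("results", showWarnings = FALSE)

dat <- read_expression("results/data/expression.tsv", "results/data/annotation.csv")
truth <- jsonlite::read_json("results/data/expression_ground_truth.json",
                             simplifyVector = TRUE)
roles <- unlist(truth$gene_roles)
ann <- dat$annotation
cells_of <- function(cl) ann$cell_id[ann$class == cl]

## differential expression EPI vs TE
de <- differential_expression(dat$matrix, cells_of("EPI"), cells_of("TE"))
write.csv(de, "results/de.csv", row.names = FALSE)
up_epi <- derive_lineage_markers(de, "up")
up_te <- derive_lineage_markers(de, "down")
writeLines(up_epi, "results/markers_epi.txt")
writeLines(up_te, "results/markers_te.txt")
cat(sprintf("markers: %d EPI-enriched, %d TE-enriched (adjusted p < 0.05)\n",
            length(up_epi), length(up_te)))

## ternary fractions + density bias across the three classes
groups3 <- list(EPI = cells_of("EPI"), PrE = cells_of("PrE"), TE = cells_of("TE"))
tf <- ternary_fractions(dat$matrix, groups3)
write.csv(tf, "results/ternary.csv", row.names = FALSE)
bias <- ternary_density_bias_test(dat$matrix[names(roles)[roles != "background"], ],
                                  groups3, n_permutations = 200, seed = 1)
write.csv(bias, "results/ternary_bias.csv", row.names = FALSE)
cat("ternary region counts (planted genes):\n")
print(bias[, c("region", "observed", "p_adjusted")], row.names = FALSE)

## pathway cumulative-sum statistic on the planted EPI signature
epi_sig <- names(roles)[roles == "signature:EPI"]
pw <- pathway_relative_percentage_test(dat$matrix, epi_sig,
                                       cells_of("EPI"), cells_of("TE"),
                                       n_permutations = 1000, seed = 1)
cat(sprintf("EPI-signature relative-percentage statistic: %.1f (p = %.4f)\n",
            pw$statistic, pw$p_value))

## hypergeometric enrichment of planted sets among the markers
collection <- list(
  epi_signature = names(roles)[roles == "signature:EPI"],
  pre_signature = names(roles)[roles == "signature:PrE"],
  te_signature = names(roles)[roles == "signature:TE"],
  module_1 = names(roles)[roles == "module:1"]
)
enr <- hypergeometric_enrichment(up_epi, collection, rownames(dat$matrix))
write.csv(enr, "results/enrichment.csv", row.names = FALSE)
cat("top enrichment:", enr$set[1], "p =", format(enr$p_value[1], digits = 3), "\n")

## preranked GSEA on the signed DE effect
scores <- setNames(de$effect, de$gene)
gs <- gsea_preranked(scores, collection$epi_signature,
                     n_permutations = 500, seed = 1)
cat(sprintf("GSEA (EPI signature vs EPI-TE ranking): ES = %.3f, NES = %.2f, p = %.4f\n",
            gs$es, gs$nes, gs$p_value))
write.csv(data.frame(set = "epi_signature", es = gs$es, nes = gs$nes,
                     p_value = gs$p_value, n_hits = gs$n_hits),
          "results/gsea.csv", row.names = FALSE)
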