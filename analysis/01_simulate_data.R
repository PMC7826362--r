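#!/usr/bin/env Rscript

# Generate the synthetic study datasets used by the downstream analysis
# scripts: a cohort of blastocyst-like nuclear point clouds (WT and MUT-like
# embryos) and a structured single-cell FPKM matrix with planted markers,
# variable genes, coexpression modules and a latent trajectory.
#
# Outputs (results/data/): nuclei.csv, expression.tsv, annotation.csv,
# ground_truth.json, plus a trajectory-focused matrix.

suppressPackageStartupMessages(library(icmtools))
seed <- 1L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

## cohort of 6 embryos; MUT-like embryos carry the "inside" channel at the
## outside level, emulating loss of an ICM-restricted factor
nuclei <- list()
truth_labels <- list()
for (i in 1:6) {
  geno <- if (i <= 3) "WT" else "MUT"
  ch_eff <- if (geno == "WT") {
    list(icm_marker = c(inside = 5.5, outside = 4.0),
         te_marker = c(inside = 4.0, outside = 5.5))
  } else {
    list(icm_marker = c(inside = 4.2, outside = 4.0),
         te_marker = c(inside = 5.0, outside = 5.5))
  }
  sim <- simulate_embryo(embryo_sim_params(channel_effects = ch_eff, seed = seed + i),
                         embryo_id = sprintf("%s_emb%d", geno, i))
  nuclei[[i]] <- sim$nuclei
  truth_labels[[i]] <- sim$truth$nucleus_labels
}
nuclei <- do.call(rbind, nuclei)
write_nuclei_csv(nuclei, file.path(out, "nuclei.csv"))
write_ground_truth_json(list(nucleus_labels = unlist(truth_labels)),
                        file.path(out, "nuclei_ground_truth.json"))
cat(sprintf("wrote %d nuclei across %d embryos\n", nrow(nuclei), 6))

## expression matrix: three lineage classes with planted structure
params <- expression_sim_params(
  n_genes = 2000,
  classes = c(EPI = 20L, PrE = 18L, TE = 22L),
  n_signature_per_class = 50L, signature_log2fc = 2,
  n_hvg = 100L, n_modules = 4L, module_size = 40L,
  pseudotime_genes = 50L, seed = seed)
sim <- simulate_expression(params)
write_expression_tsv(sim$matrix, file.path(out, "expression.tsv"))
write_annotation_csv(sim$annotation, file.path(out, "annotation.csv"))
write_ground_truth_json(
  list(gene_roles = as.list(sim$truth$gene_roles),
       cell_classes = as.list(sim$truth$cell_classes),
       latent_time = as.list(sim$truth$latent_time)),
  file.path(out, "expression_ground_truth.json"))
cat(sprintf("wrote %d x %d FPKM matrix (%d planted HVGs, %d modules, %d trend genes)\n",
            nrow(sim$matrix), ncol(sim$matrix), params$n_hvg,
            params$n_modules, params$pseudotime_genes))
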