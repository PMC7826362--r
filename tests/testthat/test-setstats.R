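test_that("differential expression recovers planted effects and honors BH", {
  p <- expression_sim_params(n_genes = 2000, classes = c(A = 20L, B = 20L),
                             n_signature_per_class = 25L, signature_log2fc = 2,
                             n_hvg = 0L, n_modules = 0L, pseudotime_genes = 0L,
                             seed = 1)
  sim <- simulate_expression(p)
  ann <- sim$annotation
  de <- differential_expression(sim$matrix,
                                ann$cell_id[ann$class == "A"],
                                ann$cell_id[ann$class == "B"])
  roles <- sim$truth$gene_roles[de$gene]
  hit <- de$p_adjusted < 0.05
  expect_gte(mean(hit[grepl("^signature", roles)]), 0.9)
  fdp <- if (any(hit)) mean(roles[hit] == "background") else 0
  expect_lte(fdp, 0.1)
  expect_true(all(de$p_adjusted >= de$p_value - 1e-15))

  # signature directions match the planted classes
  up_a <- derive_lineage_markers(de, "up")
  up_b <- derive_lineage_markers(de, "down")
  expect_gt(mean(roles[de$gene %in% up_a] == "signature:A"), 0.9)
  expect_gt(mean(roles[de$gene %in% up_b] == "signature:B"), 0.9)
  expect_length(intersect(up_a, up_b), 0)

  # identical groups: zero effects, p = 1
  mat <- sim$matrix[1:50, 1:6]
  de0 <- differential_expression(cbind(mat, mat + 0),
                                 colnames(mat), colnames(mat))
  expect_true(all(de0$effect == 0))
  expect_true(all(de0$p_value == 1))

  expect_error(differential_expression(sim$matrix, ann$cell_id[1:2],
                                       ann$cell_id[3:8]), ">= 3 cells")
})

test_that("BH adjustment follows the step-up rule", {
  de_like <- data.frame(p_value = c(0.01, 0.02, 0.03, 0.04))
  expect_equal(p.adjust(de_like$p_value, method = "BH"), rep(0.04, 4))
  expect_equal(p.adjust(c(0.002, 0.02, 0.9), method = "BH"),
               c(0.006, 0.03, 0.9))
})

test_that("ternary fractions are compositional coordinates", {
  mat <- rbind(gA = c(2, 2, 1, 1, 1, 1), gOnly = c(3, 5, 0, 0, 0, 0),
               gZero = c(0, 0, 0, 0, 0, 0))
  colnames(mat) <- paste0("c", 1:6)
  groups <- list(A = c("c1", "c2"), B = c("c3", "c4"), C = c("c5", "c6"))
  tf <- ternary_fractions(mat, groups)
  expect_equal(unname(unlist(tf[tf$gene == "gA", c("A", "B", "C")])),
               c(0.5, 0.25, 0.25))
  expect_equal(unname(unlist(tf[tf$gene == "gOnly", c("A", "B", "C")])),
               c(1, 0, 0))
  expect_equal(attr(tf, "dropped"), "gZero")
  expect_true(all(abs(rowSums(tf[, c("A", "B", "C")]) - 1) < 1e-12))

  # scale invariance
  tf10 <- ternary_fractions(mat * 10, groups)
  expect_equal(tf10[, c("A", "B", "C")], tf[, c("A", "B", "C")])

  expect_error(ternary_fractions(mat, groups[1:2]), "3 cell sets")
})

test_that("ternary density bias test finds construction and respects the null", {
  set.seed(2)
  # balanced expression across three identical-distribution groups
  mat <- matrix(rexp(100 * 18, 1 / 5) + 1, nrow = 100,
                dimnames = list(paste0("g", 1:100), paste0("c", 1:18)))
  groups <- list(A = paste0("c", 1:6), B = paste0("c", 7:12), C = paste0("c", 13:18))
  res <- ternary_density_bias_test(mat, groups, n_permutations = 200, seed = 1)
  expect_equal(res$region[which.max(res$observed)], "center")
  apex_rows <- grepl("^apex", res$region)
  expect_true(all(res$p_value[apex_rows] > 0.05))

  # genes expressed only in group A pile onto apex A
  mat2 <- mat
  mat2[1:40, c(groups$B, groups$C)] <- 0
  res2 <- ternary_density_bias_test(mat2, groups, n_permutations = 200, seed = 1)
  expect_gte(res2$observed[res2$region == "apex_A"], 40)
  expect_lt(res2$p_adjusted[res2$region == "apex_A"], 0.05)

  # reproducible given the seed
  res2b <- ternary_density_bias_test(mat2, groups, n_permutations = 200, seed = 1)
  expect_identical(res2, res2b)
  expect_error(ternary_density_bias_test(mat, groups, n_permutations = 50), "100")
})

test_that("pathway relative-percentage statistic behaves under symmetry", {
  set.seed(3)
  base <- matrix(2^rnorm(20 * 40, 3, 0.5), nrow = 20,
                 dimnames = list(paste0("g", 1:20), paste0("c", 1:40)))
  a_cells <- paste0("c", 1:20); b_cells <- paste0("c", 21:40)

  # identical groups by construction: duplicate the same cells
  matd <- cbind(base[, 1:20], base[, 1:20])
  colnames(matd) <- paste0("c", 1:40)
  res0 <- pathway_relative_percentage_test(matd, paste0("g", 1:10),
                                           a_cells, b_cells,
                                           n_permutations = 200, seed = 1)
  expect_true(all(abs(res0$relative_percentage - 50) < 1e-12))
  expect_equal(res0$statistic, 0)
  expect_gt(res0$p_value, 0.5)

  # uniform noise-free 4-fold shift: r = 80 for every pathway gene
  mat4b <- base
  mat4b[1:10, a_cells] <- 4 * matrix(rep(rowMeans(base[1:10, b_cells]), 20), ncol = 20)
  mat4b[1:10, b_cells] <- matrix(rep(rowMeans(base[1:10, b_cells]), 20), ncol = 20)
  res4 <- pathway_relative_percentage_test(mat4b, paste0("g", 1:10),
                                           a_cells, b_cells,
                                           n_permutations = 1000, seed = 1)
  expect_true(all(abs(res4$relative_percentage - 80) < 1e-9))
  expect_equal(res4$statistic, 30 * 10, tolerance = 1e-9)
  expect_lte(res4$p_value, 0.05)

  # antisymmetry under group swap
  res_ab <- pathway_relative_percentage_test(base, paste0("g", 1:10),
                                             a_cells, b_cells,
                                             n_permutations = 100, seed = 2)
  res_ba <- pathway_relative_percentage_test(base, paste0("g", 1:10),
                                             b_cells, a_cells,
                                             n_permutations = 100, seed = 2)
  expect_equal(res_ab$statistic, -res_ba$statistic, tolerance = 1e-9)
})

test_that("hypergeometric enrichment equals exhaustive enumeration", {
  universe <- paste0("g", 1:20)
  coll <- list(hit5 = paste0("g", 1:5), null3 = paste0("g", 18:20))
  res <- hypergeometric_enrichment(paste0("g", 1:5), coll, universe)
  row5 <- res[res$set == "hit5", ]
  expect_equal(row5$p_value, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(row5$p_value, oracle_hypergeom_p(20, 5, 5, 5), tolerance = 1e-12)

  # overlap 0: upper tail from zero is 1
  res0 <- hypergeometric_enrichment(paste0("g", 1:2),
                                    list(s = paste0("g", 10:12)), universe)
  expect_equal(res0$p_value, 1)

  set.seed(5)
  for (i in 1:5) {
    sel <- sample(universe, 6)
    set <- sample(universe, 4)
    r <- hypergeometric_enrichment(sel, list(s = set), universe)
    expect_equal(r$p_value,
                 oracle_hypergeom_p(20, 4, 6, length(intersect(sel, set))),
                 tolerance = 1e-12)
  }
})

test_that("GSEA enrichment scores match the running-sum oracle", {
  scores <- setNames(seq(10, 1), paste0("g", 1:10))
  top2 <- gsea_preranked(scores, c("g1", "g2"), n_permutations = 100, seed = 1)
  expect_equal(top2$es, 1)
  bottom2 <- gsea_preranked(scores, c("g9", "g10"), n_permutations = 100, seed = 1)
  expect_equal(bottom2$es, -1)

  set.seed(6)
  for (i in 1:10) {
    n <- sample(10:50, 1)
    sc <- setNames(rnorm(n), paste0("g", 1:n))
    gs <- sample(names(sc), sample(2:5, 1))
    for (w in c(0, 1)) {
      g <- gsea_preranked(sc, gs, n_permutations = 50, seed = 2, weight = w)
      ord <- order(sc, decreasing = TRUE)
      expect_equal(g$es, oracle_gsea_es(names(sc)[ord], unname(sc[ord]), gs, w),
                   tolerance = 1e-12)
      if (w == 0) expect_true(abs(g$es) <= 1 + 1e-12)
    }
  }

  # seed reproducibility and p-value range
  g1 <- gsea_preranked(scores, c("g1", "g3", "g5"), n_permutations = 200, seed = 7)
  g2 <- gsea_preranked(scores, c("g1", "g3", "g5"), n_permutations = 200, seed = 7)
  expect_identical(g1, g2)
  expect_gte(g1$p_value, 1 / 201)
  expect_lte(g1$p_value, 1)

  expect_error(gsea_preranked(scores, "absent"), "overlap")
})

test_that("GMT collections round-trip through the reader", {
  tmp <- tempfile(fileext = ".gmt")
  writeLines(c("pathA\tdesc\tg1\tg2\tg3", "pathB\tdesc\tg2\tg9"), tmp)
  sets <- read_gmt(tmp)
  expect_equal(sets, list(pathA = c("g1", "g2", "g3"), pathB = c("g2", "g9")))
  if (requireNamespace("fgsea", quietly = TRUE)) {
    expect_equal(fgsea::gmtPathways(tmp), sets)
  }
  writeLines(c("dup\td\tg1", "dup\td\tg2"), tmp)
  expect_error(read_gmt(tmp), "duplicate")
})
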