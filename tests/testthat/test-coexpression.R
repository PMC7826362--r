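make_cor_pair <- function(r, n = 20) {
  # two vectors with exact sample correlation r
  x <- scale(seq_len(n))[, 1]
  z <- scale(resid(lm(rnorm(n) ~ x)))[, 1]
  y <- r * x + sqrt(1 - r^2) * z
  rbind(g1 = x, g2 = y)
}

test_that("soft-threshold adjacency is |cor|^beta", {
  set.seed(1)
  m <- make_cor_pair(0.5)
  colnames(m) <- paste0("c", 1:20)
  a <- adjacency_matrix(m, coexpression_params(power = 10))
  expect_equal(a[1, 2], 0.5^10, tolerance = 1e-12)
  expect_equal(a[1, 2], 1 / 1024, tolerance = 1e-10)

  perf <- rbind(g1 = 1:10, g2 = 2 * (1:10) + 3)
  colnames(perf) <- paste0("c", 1:10)
  expect_equal(adjacency_matrix(perf)[1, 2], 1)

  set.seed(2)
  mm <- matrix(rnorm(50), 5, dimnames = list(paste0("g", 1:5), paste0("c", 1:10)))
  aa <- adjacency_matrix(mm)
  expect_true(isSymmetric(aa))
  expect_true(all(aa >= 0 & aa <= 1))

  mm[2, ] <- 4
  expect_error(adjacency_matrix(mm), "zero-variance.*g2")
})

test_that("topological overlap matches hand evaluation and stays bounded", {
  a2 <- matrix(c(1, 1, 1, 1), 2)
  d2 <- topological_overlap_dissimilarity(a2)
  expect_equal(d2, matrix(0, 2, 2))

  id5 <- diag(5)
  d5 <- topological_overlap_dissimilarity(id5)
  expect_true(all(d5[upper.tri(d5)] == 1))
  expect_true(all(diag(d5) == 0))

  set.seed(4)
  for (i in 1:5) {
    r <- matrix(runif(36), 6); r <- (r + t(r)) / 2; diag(r) <- 1
    d <- topological_overlap_dissimilarity(r)
    expect_true(all(d >= 0 & d <= 1))
    expect_true(isSymmetric(d))
  }
  expect_error(topological_overlap_dissimilarity(matrix(runif(9), 3)), "symmetric")
})

test_that("module detection recovers planted blocks", {
  p <- expression_sim_params(n_genes = 150, classes = c(A = 50L),
                             n_signature_per_class = 0L, n_hvg = 0L,
                             n_modules = 2L, module_size = 40L,
                             pseudotime_genes = 0L, seed = 1)
  sim <- simulate_expression(p)
  lm2 <- log2_transform(sim$matrix)
  mod <- detect_modules(topological_overlap_dissimilarity(adjacency_matrix(lm2)))
  expect_gte(oracle_ari(mod$modules, sim$truth$gene_roles), 0.9)
  expect_true(all(lengths(mod$gene_lists) >= 30))
  # module ids ordered by decreasing size
  expect_true(all(diff(lengths(mod$gene_lists)) <= 0))

  # gene permutation gives the same partition
  perm <- sample(nrow(lm2))
  mod_p <- detect_modules(topological_overlap_dissimilarity(adjacency_matrix(lm2[perm, ])))
  expect_equal(oracle_ari(mod_p$modules[names(mod$modules)], mod$modules), 1)
})

test_that("module detection respects size threshold and cut height", {
  set.seed(6)
  noise <- matrix(rnorm(50 * 30), 50, dimnames = list(paste0("g", 1:50), paste0("c", 1:30)))
  d <- topological_overlap_dissimilarity(adjacency_matrix(noise))
  mod <- detect_modules(d, coexpression_params(min_module_size = 30))
  expect_equal(max(mod$modules), 0)

  # cutting above the root of a connected dendrogram yields one module
  p <- expression_sim_params(n_genes = 40, classes = c(A = 30L),
                             n_signature_per_class = 0L, n_hvg = 0L,
                             n_modules = 1L, module_size = 40L,
                             pseudotime_genes = 0L, seed = 9)
  dd <- topological_overlap_dissimilarity(
    adjacency_matrix(log2_transform(simulate_expression(p)$matrix)))
  mod_all <- detect_modules(dd, coexpression_params(cut_height = 0.999,
                                                    min_module_size = 30))
  expect_true(all(mod_all$modules == 1))
})

test_that("eigengenes summarize modules with the documented conventions", {
  # rank-one module: eigengene equals the common z-scored profile
  base <- sin(seq_len(24))
  mod_mat <- rbind(outer(c(2, 3, 4), base) + c(1, 5, 9))
  rownames(mod_mat) <- paste0("g", 1:3)
  colnames(mod_mat) <- paste0("c", 1:24)
  assign_vec <- setNames(rep(1L, 3), rownames(mod_mat))
  me <- module_eigengenes(mod_mat, assign_vec)
  zprof <- as.numeric(scale(base))
  expect_equal(unname(me["ME1", ]), zprof, tolerance = 1e-8)
  expect_equal(sd(me["ME1", ]), 1, tolerance = 1e-9)
  expect_gte(cor(me["ME1", ], colMeans(t(scale(t(mod_mat))))), 0)

  # planted module eigengene tracks the simulator's latent factor
  p <- expression_sim_params(n_genes = 120, classes = c(A = 40L),
                             n_signature_per_class = 0L, n_hvg = 0L,
                             n_modules = 2L, module_size = 40L,
                             pseudotime_genes = 0L, seed = 3)
  sim <- simulate_expression(p)
  lm2 <- log2_transform(sim$matrix)
  mod <- detect_modules(topological_overlap_dissimilarity(adjacency_matrix(lm2)))
  me2 <- module_eigengenes(lm2, mod)
  best <- apply(abs(cor(t(me2), t(sim$truth$module_latent))), 1, max)
  expect_true(all(best >= 0.9))

  const_mod <- rbind(g1 = rep(1, 10), g2 = rnorm(10))
  colnames(const_mod) <- paste0("c", 1:10)
  expect_error(module_eigengenes(const_mod, setNames(c(1L, 1L), c("g1", "g2"))),
               "zero-variance.*g1")
})

test_that("hierarchical clustering follows the standard agglomeration", {
  two <- matrix(c(0, 0, 3, 4), 2, byrow = TRUE)
  hc <- hierarchical_cluster(two)
  expect_equal(hc$tree$height, 5)

  coll <- matrix(c(0, 1, 10), 3)
  cl <- hierarchical_cluster(coll, k = 2)$clusters
  expect_equal(cl[1], cl[2])
  expect_false(cl[1] == cl[3])

  set.seed(8)
  rnd <- matrix(rnorm(40), 10)
  for (link in c("average", "ward.D2")) {
    tr <- hierarchical_cluster(rnd, linkage = link)$tree
    expect_true(all(diff(tr$height) >= -1e-12))  # monotone merge heights
  }
  rnd[1, 1] <- NaN
  expect_error(hierarchical_cluster(rnd), "non-finite")
})
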