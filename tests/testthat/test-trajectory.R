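test_that("PCA embedding matches a direct covariance eigensolve", {
  set.seed(1)
  mat <- matrix(rnorm(20), nrow = 4,
                dimnames = list(paste0("g", 1:4), paste0("c", 1:5)))
  emb <- pca_embed(mat, n_components = 3)
  ev <- eigen(cov(t(mat)))
  centred <- t(mat) - matrix(colMeans(t(mat)), 5, 4, byrow = TRUE)
  for (j in 1:3) {
    ref <- centred %*% ev$vectors[, j]
    expect_lt(min(max(abs(emb$scores[, j] - ref)),
                  max(abs(emb$scores[, j] + ref))), 1e-9)
  }
  expect_lte(sum(emb$explained_variance), 1)
  full <- pca_embed(mat, n_components = 4)
  expect_equal(sum(full$explained_variance), 1, tolerance = 1e-9)

  # rank-one data: PC1 explains everything
  line <- outer(c(1, 2, 3), seq(0, 1, length.out = 6))
  dimnames(line) <- list(paste0("g", 1:3), paste0("c", 1:6))
  e1 <- pca_embed(line, 1)
  expect_equal(e1$explained_variance[1], 1, tolerance = 1e-12)

  # duplicating every cell keeps the component direction
  dup <- cbind(mat, mat)
  colnames(dup) <- paste0("c", 1:10)
  e2 <- pca_embed(dup, 2)
  expect_lt(min(max(abs(e2$loadings[, 1] - emb$loadings[, 1])),
                max(abs(e2$loadings[, 1] + emb$loadings[, 1]))), 1e-8)

  expect_error(pca_embed(mat, 10), "n_components")
})

test_that("diffusion transition matrix is Markov and separates clusters", {
  set.seed(2)
  x <- cbind(matrix(rnorm(40, 0), nrow = 4), matrix(rnorm(40, 8), nrow = 4))
  colnames(x) <- paste0("c", 1:20)
  rownames(x) <- paste0("g", 1:4)
  emb <- diffusion_map(x, embedding_params(n_components = 2), return_transition = TRUE)
  expect_true(all(abs(rowSums(emb$transition) - 1) < 1e-12))
  ev <- eigen(emb$transition)
  expect_equal(Re(ev$values[1]), 1, tolerance = 1e-10)
  v1 <- Re(ev$vectors[, 1])
  expect_lt(max(abs(v1 - mean(v1))), 1e-8)
  expect_true(all(emb$eigenvalues > -1 & emb$eigenvalues <= 1 + 1e-12))

  # DC1 sign splits the two clusters perfectly
  side <- sign(emb$coordinates[, 1])
  expect_true(all(side[1:10] != side[11:20]) || all(side[1:10] == -side[11:20]))
  expect_equal(length(unique(side[1:10])), 1)
  expect_equal(length(unique(side[11:20])), 1)

  # permutation of cells permutes the embedding (up to per-component sign)
  perm <- sample(20)
  emb_p <- diffusion_map(x[, perm], embedding_params(n_components = 2))
  for (j in 1:2) {
    a <- emb_p$coordinates[colnames(x), j]
    b <- emb$coordinates[, j]
    expect_lt(min(max(abs(a - b)), max(abs(a + b))), 1e-8)
  }

  expect_error(diffusion_map(x, embedding_params(kernel_sigma = 1e-12)), "sigma")
})

test_that("pseudotime recovers a latent ordering and reverses with the root", {
  p <- expression_sim_params(n_genes = 60, classes = c(A = 50L),
                             n_signature_per_class = 0L, n_hvg = 0L,
                             n_modules = 0L, pseudotime_genes = 40L, seed = 1)
  sim <- simulate_expression(p)
  genes <- names(sim$truth$gene_roles)[sim$truth$gene_roles == "trend"]
  emb <- diffusion_map(log2_transform(sim$matrix)[genes, ],
                       embedding_params(n_components = 3))
  root <- names(which.min(sim$truth$latent_time))
  pt <- pseudotime(emb, root)
  expect_equal(unname(pt$pseudotime[root]), 0)
  expect_equal(max(pt$pseudotime), 1)
  expect_gte(abs(cor(pt$pseudotime, sim$truth$latent_time, method = "spearman")),
             0.95)

  # noiseless 1-D arc: opposite roots give exactly reversed orderings
  arc <- rbind(g1 = seq(0, 5, length.out = 30), g2 = seq(1, 3, length.out = 30))
  colnames(arc) <- paste0("c", 1:30)
  e2 <- diffusion_map(arc, embedding_params(n_components = 2))
  p_left <- pseudotime(e2, "c1")$pseudotime
  p_right <- pseudotime(e2, "c30")$pseudotime
  expect_equal(cor(p_left, p_right, method = "spearman"), -1)

  expect_error(pseudotime(e2, "nope"), "unknown root")
})

test_that("smoothing splines obey their lambda limits", {
  t <- seq(0, 1, length.out = 40)
  line <- cbind(a = 2 * t + 1, b = -3 * t + 4)
  fit <- fit_trajectory_curve(t, line, lambda = 0.01)
  expect_lt(max(abs(fit$fitted - line)), 1e-8)

  set.seed(5)
  y <- sin(2 * pi * t) + rnorm(40, sd = 0.1)
  big <- fit_trajectory_curve(t, y, lambda = 1e7)
  ols <- fitted(lm(y ~ t))
  expect_lt(max(abs(big$fitted[, 1] - ols)), 1e-3)

  mid <- fit_trajectory_curve(t, y, lambda = 0.01)
  expect_lte(sum((mid$fitted[, 1] - y)^2), sum((ols - y)^2) + 1e-12)

  expect_error(fit_trajectory_curve(rep(1, 10), rnorm(10)), "distinct")
})

test_that("loess gene trends reproduce polynomial and planted signals", {
  t <- seq(0, 1, length.out = 50)
  flat <- fit_gene_trend(t, rep(2.5, 50))
  expect_lt(max(abs(flat$fitted - 2.5)), 1e-10)

  lin <- fit_gene_trend(t, 3 * t + 1)
  expect_lt(max(abs(lin$fitted - (3 * t + 1))), 1e-6)

  p <- expression_sim_params(n_genes = 60, classes = c(A = 50L),
                             n_signature_per_class = 0L, n_hvg = 0L,
                             n_modules = 0L, pseudotime_genes = 40L, seed = 2)
  sim <- simulate_expression(p)
  genes <- names(sim$truth$gene_roles)[sim$truth$gene_roles == "trend"]
  tt <- sim$truth$latent_time
  cors <- vapply(genes[1:5], function(g) {
    tr <- fit_gene_trend(tt, log2_transform(sim$matrix)[g, ])
    abs(cor(tr$fitted, tt, method = "spearman"))
  }, numeric(1))
  expect_gte(median(cors), 0.95)

  expect_error(fit_gene_trend(t[1:10], rnorm(10), span = 0.1), "span")
})
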