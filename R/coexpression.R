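#' Parameters of the weighted coexpression network analysis
#'
#' Defaults follow the study conditions of the module analyses: soft
#' threshold beta = 10, dendrogram cut at dissimilarity 0.35, minimum module
#' size 30, Pearson correlation and average linkage.
#'
#' @param power soft-threshold exponent (>= 1).
#' @param cut_height static dendrogram cut height in (0, 1).
#' @param min_module_size smallest retained module (>= 2).
#' @return parameter list.
#' @export
coexpression_params <- function(power = 10, cut_height = 0.35, min_module_size = 30L) {
  stopifnot(power >= 1, cut_height > 0, cut_height < 1, min_module_size >= 2)
  list(power = power, cut_height = cut_height,
       min_module_size = as.integer(min_module_size))
}

#' Soft-thresholded (unsigned) coexpression adjacency
#'
#' a_ij = |Pearson cor(g_i, g_j)|^beta, diagonal 1.
#'
#' @param mat log-expression matrix, genes x cells, restricted to the genes
#'   of interest.
#' @param params a [coexpression_params()] list.
#' @return symmetric genes x genes adjacency in \[0, 1\].
#' @export
adjacency_matrix <- function(mat, params = coexpression_params()) {
  if (nrow(mat) < 2 || ncol(mat) < 3) stop_fmt("need >= 2 genes and >= 3 cells")
  sds <- apply(mat, 1, stats::sd)
  if (any(sds == 0)) {
    stop_fmt("zero-variance gene(s): %s",
             paste(rownames(mat)[sds == 0], collapse = ", "))
  }
  a <- abs(stats::cor(t(mat)))^params$power
  diag(a) <- 1
  a
}

#' Topological-overlap dissimilarity
#'
#' TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij) with
#' connectivities k = row sums minus the diagonal and the sum over u
#' excluding i and j; dissimilarity is 1 - TOM with zero diagonal. Genes
#' sharing many strong neighbours get low dissimilarity even when their
#' direct correlation is moderate.
#'
#' @param adjacency symmetric matrix in \[0, 1\] with unit diagonal.
#' @return symmetric dissimilarity matrix in \[0, 1\], diagonal 0.
#' @export
topological_overlap_dissimilarity <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (!isSymmetric(unname(a), tol = 1e-10)) stop_fmt("adjacency must be symmetric")
  if (any(a < 0 | a > 1)) stop_fmt("adjacency entries must lie in [0, 1]")
  k <- rowSums(a) - diag(a)
  aa <- a %*% a
  shared <- aa - 2 * a          # removes the u = i and u = j terms (diag = 1)
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (shared + a) / denom
  diag(tom) <- 1
  d <- 1 - tom
  d[d < 0] <- 0                 # guard tiny negative round-off
  diag(d) <- 0
  d
}

#' Detect coexpression modules from a dissimilarity matrix
#'
#' Average-linkage hierarchical clustering of genes, a static cut at
#' `cut_height`, dissolution of clusters smaller than `min_module_size`
#' (their genes become unassigned, module 0), and renumbering of the
#' surviving modules by decreasing size (ties by first gene position).
#'
#' @param dissimilarity genes x genes dissimilarity.
#' @param params a [coexpression_params()] list.
#' @return list of class `module_assignment`: `modules` (named integer
#'   vector, 0 = unassigned), `gene_lists` (list of gene-id vectors per
#'   module), `dendrogram` (the hclust tree).
#' @export
detect_modules <- function(dissimilarity, params = coexpression_params()) {
  d <- as.matrix(dissimilarity)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  raw <- stats::cutree(hc, h = params$cut_height)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= params$min_module_size]
  modules <- integer(length(raw))
  names(modules) <- names(raw) %||% rownames(d) %||% as.character(seq_along(raw))
  if (length(keep)) {
    first_pos <- vapply(keep, function(k) which(raw == as.integer(k))[1], integer(1))
    ord <- keep[order(-as.integer(sizes[keep]), first_pos)]
    for (m in seq_along(ord)) modules[raw == as.integer(ord[m])] <- m
  }
  gene_lists <- lapply(seq_len(max(modules, 0)), function(m) names(modules)[modules == m])
  structure(list(modules = modules, gene_lists = gene_lists, dendrogram = hc),
            class = "module_assignment")
}

#' Module eigengenes
#'
#' Per module, genes are standardized (z-score across cells) and the first
#' principal component score across cells, scaled to unit variance, is the
#' eigengene. The sign is oriented so the eigengene correlates nonnegatively
#' with the module-average standardized profile, making results reproducible
#' bit-for-bit.
#'
#' @param mat log-expression matrix, genes x cells.
#' @param modules a `module_assignment` (or named integer vector of module
#'   ids).
#' @return matrix, modules x cells, rownames `ME1`, `ME2`, ...
#' @export
module_eigengenes <- function(mat, modules) {
  mod <- if (inherits(modules, "module_assignment")) modules$modules else modules
  ids <- sort(unique(mod[mod > 0]))
  if (!length(ids)) stop_fmt("no modules to summarize")
  out <- matrix(NA_real_, length(ids), ncol(mat),
                dimnames = list(paste0("ME", ids), colnames(mat)))
  for (m in ids) {
    genes <- names(mod)[mod == m]
    sub <- mat[genes, , drop = FALSE]
    sds <- apply(sub, 1, stats::sd)
    if (any(sds == 0)) {
      stop_fmt("module %d contains zero-variance gene(s): %s", m,
               paste(genes[sds == 0], collapse = ", "))
    }
    z <- t(scale(t(sub)))
    sv <- svd(z, nu = 0, nv = 1)
    eig <- sv$v[, 1]
    avg <- colMeans(z)
    r <- suppressWarnings(stats::cor(eig, avg))
    if (!is.na(r) && r < 0) eig <- -eig
    out[paste0("ME", m), ] <- eig / stats::sd(eig)
  }
  out
}

#' Hierarchical clustering of observations
#'
#' Euclidean distance with average or ward.D2 agglomeration (the ward.D2
#' convention squares distances inside the update rule). Merge order is the
#' deterministic lowest-index rule of [stats::hclust()].
#'
#' @param obs observations x variables matrix or data.frame.
#' @param linkage `"average"` or `"ward.D2"`.
#' @param k optional number of clusters for a cut.
#' @param h optional cut height (ignored when `k` given).
#' @return list: `tree` (hclust), `clusters` (named integer vector or NULL).
#' @export
hierarchical_cluster <- function(obs, linkage = c("average", "ward.D2"),
                                 k = NULL, h = NULL) {
  linkage <- match.arg(linkage)
  m <- as.matrix(obs)
  if (any(!is.finite(m))) stop_fmt("non-finite values in clustering input")
  if (nrow(m) < 2) stop_fmt("need >= 2 observations")
  tree <- stats::hclust(stats::dist(m), method = linkage)
  clusters <- NULL
  if (!is.null(k)) clusters <- stats::cutree(tree, k = k)
  else if (!is.null(h)) clusters <- stats::cutree(tree, h = h)
  list(tree = tree, clusters = clusters)
}
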