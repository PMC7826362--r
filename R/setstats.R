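#' Rank-based differential expression between two cell groups
#'
#' Two-sided Wilcoxon rank-sum test per gene on log2(FPKM + 1) — exact when
#' the combined sample size is at most 12 and ties permit, otherwise the
#' normal approximation with midrank tie correction — with the mean
#' difference as effect size and Benjamini-Hochberg adjustment across the
#' tested genes. This is a deliberately transparent stand-in for error-model
#' based single-cell DE machinery: directions and ranks are comparable,
#' published adjusted p-values are not numerical targets.
#'
#' @param mat genes x cells FPKM matrix.
#' @param group_a,group_b cell ids (>= 3 each).
#' @return data.frame: gene, effect (mean log2 difference, A - B),
#'   statistic (Wilcoxon W), p_value, p_adjusted.
#' @export
differential_expression <- function(mat, group_a, group_b) {
  if (length(group_a) < 3 || length(group_b) < 3) stop_fmt("each group needs >= 3 cells")
  missing <- setdiff(c(group_a, group_b), colnames(mat))
  if (length(missing)) stop_fmt("cells not in matrix: %s", paste(missing, collapse = ", "))
  la <- log2(mat[, group_a, drop = FALSE] + 1)
  lb <- log2(mat[, group_b, drop = FALSE] + 1)
  n <- length(group_a) + length(group_b)
  res <- t(vapply(seq_len(nrow(mat)), function(i) {
    a <- la[i, ]; b <- lb[i, ]
    if (max(c(a, b)) == min(c(a, b))) {
      return(c(effect = 0, statistic = length(a) * length(b) / 2, p_value = 1))
    }
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = n <= 12, correct = TRUE))
    c(effect = mean(a) - mean(b), statistic = unname(wt$statistic),
      p_value = unname(wt$p.value))
  }, numeric(3)))
  data.frame(gene = rownames(mat), effect = res[, "effect"],
             statistic = res[, "statistic"], p_value = res[, "p_value"],
             p_adjusted = stats::p.adjust(res[, "p_value"], method = "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Derive lineage markers from a differential-expression result
#'
#' Genes significant after adjustment (p_adjusted < `alpha`) and enriched in
#' the requested direction.
#'
#' @param de data.frame from [differential_expression()].
#' @param direction `"up"` (effect > 0) or `"down"`.
#' @param alpha adjusted-p threshold (default 0.05).
#' @return character vector of gene ids.
#' @export
derive_lineage_markers <- function(de, direction = c("up", "down"), alpha = 0.05) {
  direction <- match.arg(direction)
  sel <- de$p_adjusted < alpha &
    (if (direction == "up") de$effect > 0 else de$effect < 0)
  de$gene[sel]
}

#' Ternary expression fractions across three cell groups
#'
#' Per gene, the three group means of FPKM are normalized to fractions
#' summing to 1 — compositional coordinates for a ternary plot. Genes with
#' zero total mean are dropped and reported.
#'
#' @param mat genes x cells FPKM matrix.
#' @param groups named list of three disjoint, nonempty cell-id vectors.
#' @return data.frame: gene and one fraction column per group; attribute
#'   `dropped` lists zero-total genes.
#' @export
ternary_fractions <- function(mat, groups) {
  if (length(groups) != 3 || is.null(names(groups))) stop_fmt("groups must be a named list of 3 cell sets")
  if (any(lengths(groups) == 0)) stop_fmt("empty group")
  if (any(duplicated(unlist(groups)))) stop_fmt("groups must be disjoint")
  means <- vapply(groups, function(cells) rowMeans(mat[, cells, drop = FALSE]),
                  numeric(nrow(mat)))
  tot <- rowSums(means)
  if (all(tot == 0)) stop_fmt("all genes have zero total expression across the groups")
  keep <- tot > 0
  fr <- means[keep, , drop = FALSE] / tot[keep]
  out <- data.frame(gene = rownames(mat)[keep], fr, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "dropped") <- rownames(mat)[!keep]
  out
}

# assign each compositional point to one of 7 regions: 3 apexes (one
# fraction > apex), 3 edges (smallest fraction < edge, between the two
# dominant groups), centre otherwise; ties broken by first index
ternary_region <- function(fr, apex = 0.6, edge = 0.15) {
  groups <- colnames(fr)
  apply(fr, 1, function(f) {
    if (max(f) > apex) {
      paste0("apex_", groups[which.max(f)])
    } else if (min(f) < edge) {
      pair <- sort(groups[-which.min(f)])
      paste0("edge_", pair[1], "_", pair[2])
    } else "center"
  })
}

#' Permutation test for density bias on the ternary simplex
#'
#' Counts genes per simplex region (3 apexes at fraction > 0.6, 3 edges, 1
#' centre) and compares each count with a null obtained by permuting the
#' group labels of cells and recomputing the fractions. One-sided p per
#' region (enrichment), BH-adjusted across the 7 regions.
#'
#' @param mat genes x cells FPKM matrix.
#' @param groups named list of three disjoint cell-id vectors.
#' @param n_permutations at least 100.
#' @param seed integer seed.
#' @param apex apex-region threshold on the dominant fraction.
#' @return data.frame: region, observed count, p_value, p_adjusted.
#' @export
ternary_density_bias_test <- function(mat, groups, n_permutations = 1000L, seed = 1L,
                                      apex = 0.6) {
  if (n_permutations < 100) stop_fmt("n_permutations must be >= 100")
  coords <- ternary_fractions(mat, groups)
  fr <- as.matrix(coords[, names(groups), drop = FALSE])
  region_levels <- c(paste0("apex_", names(groups)),
                     paste0("edge_", vapply(utils::combn(sort(names(groups)), 2, simplify = FALSE),
                                            paste, character(1), collapse = "_")),
                     "center")
  count_regions <- function(f) {
    table(factor(ternary_region(f, apex = apex), levels = region_levels))
  }
  obs <- count_regions(fr)

  cells <- unlist(groups, use.names = FALSE)
  sizes <- lengths(groups)
  exceed <- stats::setNames(rep(0L, length(region_levels)), region_levels)
  with_seed(substream_seed(seed, 1L), {
    for (b in seq_len(n_permutations)) {
      perm <- sample(cells)
      pg <- split(perm, rep(names(groups), sizes))[names(groups)]
      pc <- ternary_fractions(mat, pg)
      cnt <- count_regions(as.matrix(pc[, names(groups), drop = FALSE]))
      exceed <- exceed + as.integer(cnt >= obs)
    }
  })
  p <- (exceed + 1) / (n_permutations + 1)
  data.frame(region = region_levels, observed = as.integer(obs),
             p_value = as.numeric(p),
             p_adjusted = stats::p.adjust(as.numeric(p), method = "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Cumulative-sum relative-percentage pathway statistic
#'
#' For each pathway gene g, the relative percentage
#' r_g = 100 * mean_A(g) / (mean_A(g) + mean_B(g)) measures how much of its
#' expression sits in group A (50 = balanced). The reported curve is the
#' cumulative sum of the sorted r_g; the test statistic sum(r_g - 50) is
#' calibrated by permuting cell group labels (two-sided p).
#'
#' @param mat genes x cells FPKM matrix.
#' @param pathway_genes gene ids (>= 3 present in the matrix after zero
#'   filtering).
#' @param group_a,group_b disjoint cell-id vectors.
#' @param n_permutations permutation count.
#' @param seed integer seed.
#' @return list: `relative_percentage` (named per gene), `cumulative`
#'   (cumulative sum of sorted percentages), `statistic`, `p_value`.
#' @export
pathway_relative_percentage_test <- function(mat, pathway_genes, group_a, group_b,
                                             n_permutations = 1000L, seed = 1L) {
  genes <- intersect(pathway_genes, rownames(mat))
  cells <- c(group_a, group_b)
  rel_pct <- function(ga, gb) {
    ma <- rowMeans(mat[genes, ga, drop = FALSE])
    mb <- rowMeans(mat[genes, gb, drop = FALSE])
    tot <- ma + mb
    100 * ma[tot > 0] / tot[tot > 0]
  }
  r <- rel_pct(group_a, group_b)
  if (length(r) < 3) stop_fmt("fewer than 3 expressed pathway genes")
  stat_obs <- sum(r - 50)
  na <- length(group_a)
  null_stats <- with_seed(substream_seed(seed, 1L), {
    vapply(seq_len(n_permutations), function(b) {
      perm <- sample(cells)
      rp <- rel_pct(perm[seq_len(na)], perm[-seq_len(na)])
      sum(rp - 50)
    }, numeric(1))
  })
  p <- (1 + sum(abs(null_stats) >= abs(stat_obs) - 1e-12)) / (n_permutations + 1)
  list(relative_percentage = r, cumulative = cumsum(sort(r)),
       statistic = stat_obs, p_value = p)
}

#' Read a GMT gene-set collection
#'
#' Tab-separated: set name, description, then gene ids. Names must be
#' unique and sets nonempty.
#'
#' @param path GMT file.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_fmt("GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  names(sets) <- vapply(parts, `[`, character(1), 1)
  if (anyDuplicated(names(sets))) stop_fmt("duplicate gene-set names in %s", path)
  if (any(lengths(sets) == 0)) stop_fmt("empty gene set(s): %s", paste(names(sets)[lengths(sets) == 0], collapse = ", "))
  sets
}

#' Hypergeometric over-representation of gene sets
#'
#' Upper-tail hypergeometric p of the overlap between a selection and each
#' set (both intersected with the universe), BH-adjusted across sets and
#' sorted by p.
#'
#' @param selection gene ids (subset of the universe).
#' @param collection named list of gene sets.
#' @param universe background gene ids.
#' @return data.frame: set, overlap, set_size, universe_size,
#'   selection_size, p_value, p_adjusted.
#' @export
hypergeometric_enrichment <- function(selection, collection, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop_fmt("empty universe")
  selection <- unique(intersect(selection, universe))
  if (!length(selection)) stop_fmt("empty selection (after intersecting with the universe)")
  rows <- lapply(names(collection), function(nm) {
    set <- intersect(collection[[nm]], universe)
    ov <- length(intersect(set, selection))
    p <- stats::phyper(ov - 1, length(set), length(universe) - length(set),
                       length(selection), lower.tail = FALSE)
    data.frame(set = nm, overlap = ov, set_size = length(set),
               universe_size = length(universe), selection_size = length(selection),
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# running-sum enrichment profile of a gene set along a ranked list
gsea_running_sum <- function(ranked_genes, scores, gene_set, weight) {
  hit <- ranked_genes %in% gene_set
  nh <- sum(hit)
  n <- length(ranked_genes)
  inc <- numeric(n)
  if (weight == 0) {
    inc[hit] <- 1 / nh
  } else {
    w <- abs(scores[hit])^weight
    if (sum(w) == 0) w <- rep(1, nh)
    inc[hit] <- w / sum(w)
  }
  inc[!hit] <- -1 / (n - nh)
  cumsum(inc)
}

#' Preranked gene-set enrichment analysis
#'
#' Genes are ordered by decreasing score; a running sum increments at set
#' members (equally for `weight = 0`, proportional to |score| for
#' `weight = 1`) and decrements at non-members. The enrichment score is the
#' maximum-magnitude deviation; the null distribution comes from uniform
#' random gene-label permutations, giving a normalized enrichment score
#' (ES divided by the mean |null ES| of matching sign) and a permutation p.
#'
#' @param scores named numeric vector (gene-level ranking statistic).
#' @param gene_set character vector of gene ids.
#' @param n_permutations permutation count.
#' @param seed integer seed.
#' @param weight 0 (classic/unweighted) or 1.
#' @return list: `es`, `nes`, `p_value`, `running_sum`, `n_hits`.
#' @export
gsea_preranked <- function(scores, gene_set, n_permutations = 1000L, seed = 1L,
                           weight = 0) {
  if (is.null(names(scores)) || anyDuplicated(names(scores))) {
    stop_fmt("scores must be named with unique gene ids")
  }
  if (!weight %in% c(0, 1)) stop_fmt("weight must be 0 or 1")
  ord <- order(scores, decreasing = TRUE)
  ranked <- names(scores)[ord]
  sc <- unname(scores[ord])
  hits <- intersect(gene_set, ranked)
  if (!length(hits)) stop_fmt("gene set does not overlap the ranked list")
  if (length(hits) == length(ranked)) stop_fmt("gene set covers the whole list")
  rs <- gsea_running_sum(ranked, sc, hits, weight)
  es <- rs[which.max(abs(rs))]

  nh <- length(hits)
  null_es <- with_seed(substream_seed(seed, 1L), {
    vapply(seq_len(n_permutations), function(b) {
      ph <- sample(ranked, nh)
      r0 <- gsea_running_sum(ranked, sc, ph, weight)
      r0[which.max(abs(r0))]
    }, numeric(1))
  })
  same_sign <- null_es[sign(null_es) == sign(es)]
  nes <- if (length(same_sign)) es / mean(abs(same_sign)) else NA_real_
  p <- if (length(same_sign)) {
    (1 + sum(abs(same_sign) >= abs(es) - 1e-12)) / (1 + length(same_sign))
  } else 1 / (n_permutations + 1)
  list(es = unname(es), nes = unname(nes), p_value = p,
       running_sum = rs, n_hits = nh)
}
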