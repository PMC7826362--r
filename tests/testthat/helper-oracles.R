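# Independent oracles used by the tests. None of these share code with the
# package implementations they check.

# Point-in-convex-hull feasibility: p is inside the hull of `shell` iff it is
# a convex combination of the shell points. Solved by accelerated projected
# gradient over the probability simplex — entirely independent of the
# package's hull construction and its active-set solver.
oracle_proj_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_along(u) > 0))
  pmax(v + (1 - css[rho]) / rho, 0)
}

oracle_point_in_hull <- function(p, shell, n_iter = 20000, rel_tol = 1e-4) {
  A <- t(shell)                       # 3 x m
  m <- ncol(A)
  L <- sum(A^2)                       # upper bound on the Lipschitz constant
  w <- rep(1 / m, m)
  y <- w
  tprev <- 1
  for (i in seq_len(n_iter)) {
    g <- crossprod(A, A %*% y - p)
    w_new <- oracle_proj_simplex(as.numeric(y - g / L))
    tcur <- (1 + sqrt(1 + 4 * tprev^2)) / 2
    y <- w_new + ((tprev - 1) / tcur) * (w_new - w)
    w <- w_new
    tprev <- tcur
  }
  sqrt(sum((A %*% w - p)^2)) < rel_tol * max(1, sqrt(sum(p^2)))
}

# Minimum distance from p to a triangulated surface by dense barycentric
# sampling of every triangle.
oracle_surface_min_dist <- function(p, vertices, triangles, n_grid = 60) {
  u <- seq(0, 1, length.out = n_grid)
  bary <- expand.grid(a = u, b = u)
  bary <- bary[bary$a + bary$b <= 1, ]
  best <- Inf
  for (f in seq_len(nrow(triangles))) {
    v1 <- vertices[triangles[f, 1], ]
    v2 <- vertices[triangles[f, 2], ]
    v3 <- vertices[triangles[f, 3], ]
    pts <- outer(1 - bary$a - bary$b, v1) + outer(bary$a, v2) + outer(bary$b, v3)
    best <- min(best, min(sqrt(rowSums(sweep(pts, 2, p)^2))))
  }
  best
}

# Watertightness audit independent of the package: every undirected edge in
# exactly two triangles, and F = 2V - 4.
oracle_surface_watertight <- function(vertices, triangles) {
  e <- rbind(triangles[, 1:2], triangles[, 2:3], triangles[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2) && nrow(triangles) == 2 * nrow(vertices) - 4
}

# Kruskal-Wallis H from the rank formula, and the exact permutation p by full
# enumeration of group assignments (recursive multiset split).
oracle_kw_h <- function(groups) {
  n <- sum(lengths(groups))
  r <- rank(unlist(groups))
  idx <- split(seq_len(n), rep(seq_along(groups), lengths(groups)))
  h <- 12 / (n * (n + 1)) *
    sum(vapply(idx, function(i) length(i) * (mean(r[i]) - (n + 1) / 2)^2, numeric(1)))
  ties <- table(unlist(groups))
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h / correction
}

oracle_kw_exact_p <- function(groups) {
  pooled <- unlist(groups, use.names = FALSE)
  sizes <- lengths(groups)
  h_obs <- oracle_kw_h(groups)
  hs <- c()
  recurse <- function(avail, gi, acc) {
    if (gi == length(sizes)) {
      gs <- c(acc, list(avail))
      hs <<- c(hs, oracle_kw_h(lapply(gs, function(i) pooled[i])))
      return(invisible())
    }
    for (pk in utils::combn(avail, sizes[gi], simplify = FALSE)) {
      recurse(setdiff(avail, pk), gi + 1L, c(acc, list(pk)))
    }
  }
  recurse(seq_along(pooled), 1L, list())
  mean(hs >= h_obs - 1e-12)
}

# Upper-tail hypergeometric p by exhaustive enumeration of all selections.
oracle_hypergeom_p <- function(universe_n, set_n, selection_n, overlap) {
  draws <- utils::combn(universe_n, selection_n, simplify = FALSE)
  in_set <- seq_len(set_n)
  mean(vapply(draws, function(d) sum(d %in% in_set) >= overlap, logical(1)))
}

# GSEA enrichment score by an independent position-by-position scan.
oracle_gsea_es <- function(ranked_genes, scores, gene_set, weight = 0) {
  n <- length(ranked_genes)
  hit <- ranked_genes %in% gene_set
  nh <- sum(hit)
  if (weight == 0) {
    up <- rep(1 / nh, n)
  } else {
    up <- abs(scores)^weight
    up <- up / sum(up[hit])
  }
  best <- 0
  run <- 0
  for (i in seq_len(n)) {
    run <- run + if (hit[i]) up[i] else -1 / (n - nh)
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# Dense simplex grid search for the 3-class deconvolution objective.
oracle_simplex_grid <- function(S, x, step = 0.01) {
  stopifnot(ncol(S) == 3)
  best <- NULL
  best_obj <- Inf
  for (f1 in seq(0, 1, by = step)) {
    for (f2 in seq(0, 1 - f1, by = step)) {
      f <- c(f1, f2, 1 - f1 - f2)
      obj <- sum((S %*% f - x)^2)
      if (obj < best_obj) {
        best_obj <- obj
        best <- f
      }
    }
  }
  list(fractions = best, objective = best_obj)
}

# Adjusted Rand index between two labelings (contingency-table closed form).
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_a * sum_b / n
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

rigid_motion <- function(pts, angle = 0.7, axis = c(1, 2, 3), shift = c(5, -3, 2)) {
  ax <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + s_ * K + (1 - c_) * (K %*% K)
  sweep(pts %*% t(R), 2, shift, `+`)
}

# Distance from p to one triangle by barycentric grid sampling with recursive
# window refinement (the distance is convex over the triangle, so zooming on
# the best sample converges to the global minimum).
oracle_tri_dist_refined <- function(p, v1, v2, v3, levels = 5, n_grid = 48,
                                    n_branch = 4) {
  eval_grid <- function(lo_a, hi_a, lo_b, hi_b) {
    a <- seq(lo_a, hi_a, length.out = n_grid)
    b <- seq(lo_b, hi_b, length.out = n_grid)
    gr <- expand.grid(a = a, b = b)
    gr <- gr[gr$a + gr$b <= 1 + 1e-12, , drop = FALSE]
    gr$b <- pmin(gr$b, 1 - gr$a)
    pts <- outer(1 - gr$a - gr$b, v1) + outer(gr$a, v2) + outer(gr$b, v3)
    gr$d <- sqrt(rowSums(sweep(pts, 2, p)^2))
    gr
  }
  windows <- data.frame(lo_a = 0, hi_a = 1, lo_b = 0, hi_b = 1)
  best <- Inf
  for (lev in seq_len(levels)) {
    cand <- data.frame()
    for (wi in seq_len(nrow(windows))) {
      g <- eval_grid(windows$lo_a[wi], windows$hi_a[wi],
                     windows$lo_b[wi], windows$hi_b[wi])
      step_a <- (windows$hi_a[wi] - windows$lo_a[wi]) / (n_grid - 1)
      step_b <- (windows$hi_b[wi] - windows$lo_b[wi]) / (n_grid - 1)
      g <- g[order(g$d)[seq_len(min(n_branch, nrow(g)))], , drop = FALSE]
      best <- min(best, g$d)
      cand <- rbind(cand, data.frame(
        lo_a = pmax(0, g$a - 2 * step_a), hi_a = pmin(1, g$a + 2 * step_a),
        lo_b = pmax(0, g$b - 2 * step_b), hi_b = pmin(1, g$b + 2 * step_b)))
    }
    cand <- unique(cand)
    windows <- cand[seq_len(min(n_branch, nrow(cand))), , drop = FALSE]
  }
  best
}
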