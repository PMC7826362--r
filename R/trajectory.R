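#' Principal component embedding of cells
#'
#' Centered (not scaled) PCA of cells over a gene subset, with a
#' deterministic sign convention: within each component the gene loading of
#' largest magnitude is made positive.
#'
#' @param mat log-expression matrix, genes x cells.
#' @param n_components number of components.
#' @return list: `scores` (cells x components), `loadings`,
#'   `explained_variance` (fractions of total variance; sums to <= 1).
#' @export
pca_embed <- function(mat, n_components = 2L) {
  if (ncol(mat) < 2 || nrow(mat) < 1) stop_fmt("need >= 2 cells and >= 1 gene")
  if (n_components > min(nrow(mat), ncol(mat))) {
    stop_fmt("n_components = %d exceeds min(genes, cells) = %d",
             n_components, min(nrow(mat), ncol(mat)))
  }
  pc <- stats::prcomp(t(mat), center = TRUE, scale. = FALSE)
  kmax <- min(n_components, ncol(pc$x))
  scores <- pc$x[, seq_len(kmax), drop = FALSE]
  loadings <- pc$rotation[, seq_len(kmax), drop = FALSE]
  for (j in seq_len(kmax)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  total_var <- sum(apply(t(mat), 2, stats::var))
  ev <- if (total_var > 0) pc$sdev[seq_len(kmax)]^2 / total_var else rep(0, kmax)
  list(scores = scores, loadings = loadings, explained_variance = ev)
}

#' Parameters of the diffusion-map embedding
#'
#' @param n_components number of nontrivial diffusion components.
#' @param kernel_sigma Gaussian kernel width; NULL selects the median of the
#'   nonzero pairwise Euclidean distances.
#' @param density_normalize if TRUE (default), the kernel is divided by the
#'   outer product of its row sums before Markov normalization, removing
#'   sampling-density effects.
#' @return parameter list.
#' @export
embedding_params <- function(n_components = 3L, kernel_sigma = NULL,
                             density_normalize = TRUE) {
  stopifnot(n_components >= 1, is.null(kernel_sigma) || kernel_sigma > 0)
  list(n_components = as.integer(n_components), kernel_sigma = kernel_sigma,
       density_normalize = density_normalize)
}

#' Diffusion-map embedding of cells
#'
#' A Gaussian kernel on Euclidean distances is (optionally) density
#' normalized, then row-normalized into a Markov transition matrix; the
#' right eigenvectors 2..(m+1), scaled by their eigenvalues, form the
#' embedding. Eigenvectors get a deterministic sign (largest-magnitude entry
#' positive), so the embedding is reproducible and order-invariant up to
#' nothing more than that convention.
#'
#' @param x log-expression matrix (genes x cells) or a precomputed cell
#'   distance matrix (`dist` or square symmetric matrix).
#' @param params an [embedding_params()] list.
#' @param return_transition if TRUE, include the row-stochastic transition
#'   matrix in the result.
#' @return list of class `diffusion_embedding`: `coordinates` (cells x
#'   components), `eigenvalues` (descending, trivial pair removed),
#'   `kernel_sigma`, `cell_ids`, and optionally `transition`.
#' @export
diffusion_map <- function(x, params = embedding_params(), return_transition = FALSE) {
  if (inherits(x, "dist")) {
    D <- as.matrix(x)
  } else if (is.matrix(x) && nrow(x) == ncol(x) && isSymmetric(unname(x), tol = 1e-8) &&
             all(abs(diag(x)) < 1e-12)) {
    D <- x
  } else {
    D <- as.matrix(stats::dist(t(x)))
  }
  n <- nrow(D)
  if (n < 3) stop_fmt("need >= 3 cells")
  cell_ids <- rownames(D) %||% as.character(seq_len(n))
  sigma <- params$kernel_sigma %||% stats::median(D[upper.tri(D)][D[upper.tri(D)] > 0])
  if (!is.finite(sigma) || sigma <= 0) stop_fmt("cannot derive a positive kernel_sigma")
  K <- exp(-D^2 / (2 * sigma^2))
  if (max(K[upper.tri(K)]) < 1e-300) {
    stop_fmt("kernel numerically zero: increase kernel_sigma (current %.3g)", sigma)
  }
  if (params$density_normalize) {
    q <- rowSums(K)
    K <- K / outer(q, q)
  }
  d <- rowSums(K)
  # symmetric conjugate of the Markov operator: same spectrum, stable eigensolve
  S <- K / outer(sqrt(d), sqrt(d))
  es <- eigen(S, symmetric = TRUE)
  lambda <- es$values
  phi <- es$vectors / sqrt(d)           # right eigenvectors of P = D^-1 K
  m <- min(params$n_components, n - 1L)
  coords <- matrix(0, n, m, dimnames = list(cell_ids, paste0("DC", seq_len(m))))
  for (j in seq_len(m)) {
    v <- phi[, j + 1L]
    v <- v / sqrt(sum(v^2))
    i <- which.max(abs(v))
    if (v[i] < 0) v <- -v
    coords[, j] <- lambda[j + 1L] * v
  }
  out <- list(coordinates = coords, eigenvalues = lambda[seq_len(m) + 1L],
              kernel_sigma = sigma, cell_ids = cell_ids)
  if (return_transition) out$transition <- K / d
  structure(out, class = "diffusion_embedding")
}

#' Pseudotime as diffusion distance from a root cell
#'
#' Euclidean distance from the root in the eigenvalue-scaled diffusion
#' component space, min-max scaled to \[0, 1\] (root at 0).
#'
#' @param embedding a `diffusion_embedding`.
#' @param root cell id of the root (e.g. an earliest-stage cell).
#' @return list of class `pseudotime_result`: `pseudotime` (named numeric in
#'   \[0, 1\]), `root`.
#' @export
pseudotime <- function(embedding, root) {
  stopifnot(inherits(embedding, "diffusion_embedding"))
  co <- embedding$coordinates
  if (!root %in% rownames(co)) stop_fmt("unknown root cell id '%s'", root)
  d <- sqrt(rowSums((co - matrix(co[root, ], nrow(co), ncol(co), byrow = TRUE))^2))
  rng <- range(d)
  pt <- if (diff(rng) > 0) (d - rng[1]) / diff(rng) else d * 0
  structure(list(pseudotime = pt, root = root), class = "pseudotime_result")
}

#' Fit a smooth trajectory curve through embedding coordinates
#'
#' Cubic smoothing spline (second-derivative roughness penalty with weight
#' `lambda`) of each embedding coordinate against pseudotime. Duplicate
#' abscissae are collapsed by averaging.
#'
#' @param t pseudotime values (abscissae).
#' @param coords matrix of embedding coordinates (cells x dims) or a vector.
#' @param lambda roughness penalty weight (default 0.01).
#' @return list of class `curve_fit`: `fitted` (at the observed abscissae),
#'   `predict` (function of new abscissae), `lambda`, `kind`.
#' @export
fit_trajectory_curve <- function(t, coords, lambda = 0.01) {
  coords <- as.matrix(coords)
  if (length(unique(t)) < 4) stop_fmt("need >= 4 distinct abscissae")
  fits <- lapply(seq_len(ncol(coords)), function(j) {
    stats::smooth.spline(t, coords[, j], lambda = lambda, cv = FALSE,
                         all.knots = TRUE, keep.data = FALSE)
  })
  fitted <- vapply(fits, function(f) stats::predict(f, t)$y, numeric(length(t)))
  colnames(fitted) <- colnames(coords)
  structure(list(
    fitted = fitted,
    predict = function(newt) {
      out <- vapply(fits, function(f) stats::predict(f, newt)$y, numeric(length(newt)))
      colnames(out) <- colnames(coords)
      out
    },
    lambda = lambda, kind = "cubic_smoothing_spline"
  ), class = "curve_fit")
}

#' Loess trend of a gene along pseudotime
#'
#' Locally weighted regression (tricube weights, degree 2) of log2
#' expression on pseudotime, evaluated at the observed pseudotimes and on a
#' 100-point grid.
#'
#' @param t pseudotime values.
#' @param y gene log2 expression.
#' @param span loess span (default 0.5).
#' @return list of class `curve_fit`: `fitted`, `grid` (data.frame t, y),
#'   `predict`, `span`, `kind`.
#' @export
fit_gene_trend <- function(t, y, span = 0.5) {
  if (length(t) < 5) stop_fmt("need >= 5 cells")
  if (span * length(t) < 3) stop_fmt("span %.3g leaves windows with < 3 points: increase span", span)
  df <- data.frame(t = t, y = y)
  fit <- stats::loess(y ~ t, data = df, span = span, degree = 2,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  grid_t <- seq(min(t), max(t), length.out = 100)
  structure(list(
    fitted = stats::predict(fit, data.frame(t = t)),
    grid = data.frame(t = grid_t, y = stats::predict(fit, data.frame(t = grid_t))),
    predict = function(newt) stats::predict(fit, data.frame(t = newt)),
    span = span, kind = "loess"
  ), class = "curve_fit")
}
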