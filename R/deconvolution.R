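#' Build a lineage signature matrix
#'
#' Per-gene arithmetic mean of FPKM within each reference class (e.g. E4.5
#' EPI, E4.5 PrE, E4.5 MUT).
#'
#' @param mat genes x cells FPKM matrix.
#' @param annotation data.frame with `cell_id` and the column named by
#'   `class_column`.
#' @param class_definitions named list: class name -> cell ids, or NULL to
#'   use every level of `class_column`.
#' @param class_column annotation column defining classes (default
#'   `"class"`).
#' @return genes x classes signature matrix.
#' @export
build_signature <- function(mat, annotation = NULL, class_definitions = NULL,
                            class_column = "class") {
  if (is.null(class_definitions)) {
    if (is.null(annotation)) stop_fmt("need annotation or class_definitions")
    stopifnot(all(c("cell_id", class_column) %in% names(annotation)))
    class_definitions <- split(annotation$cell_id, annotation[[class_column]])
  }
  sig <- vapply(names(class_definitions), function(cl) {
    cells <- intersect(class_definitions[[cl]], colnames(mat))
    if (!length(cells)) stop_fmt("class '%s' has no cells in the matrix", cl)
    rowMeans(mat[, cells, drop = FALSE])
  }, numeric(nrow(mat)))
  rownames(sig) <- rownames(mat)
  sig
}

#' Fraction of identity: simplex-constrained deconvolution of one profile
#'
#' Restricts to genes expressed (above `min_fpkm`) in the query and — unless
#' `overlap = "query"` — in every signature column, then solves
#' min ||S f - x||^2 subject to f >= 0 and sum(f) = 1. The sum constraint is
#' enforced by an augmented penalty row (weight 1e6) inside a nonnegative
#' least-squares solve, followed by renormalization onto the simplex.
#'
#' @param sample_fpkm named FPKM vector of the query profile.
#' @param signature genes x classes signature matrix.
#' @param min_fpkm expression threshold defining "expressed" (default 0;
#'   use 1 for the log2FPKM > 0 convention).
#' @param overlap `"both"` (default: query and all signature columns) or
#'   `"query"`.
#' @return list: `fractions` (named, on the simplex), `n_genes_used`,
#'   `objective` (residual sum of squares on the restricted genes),
#'   `rank_deficient` flag.
#' @export
fraction_of_identity <- function(sample_fpkm, signature, min_fpkm = 0,
                                 overlap = c("both", "query")) {
  overlap <- match.arg(overlap)
  signature <- as.matrix(signature)
  k <- ncol(signature)
  if (k < 2) stop_fmt("signature needs >= 2 classes")
  common <- intersect(names(sample_fpkm) %||% rownames(signature), rownames(signature))
  x <- if (is.null(names(sample_fpkm))) sample_fpkm else sample_fpkm[common]
  S <- signature[common, , drop = FALSE]
  use <- x > min_fpkm
  if (overlap == "both") use <- use & apply(S, 1, function(r) all(r > min_fpkm))
  if (sum(use) < k) stop_fmt("only %d usable genes for %d classes", sum(use), k)
  S <- S[use, , drop = FALSE]
  x <- x[use]

  rank_def <- qr(S)$rank < k
  if (rank_def) warning("restricted signature is rank deficient; fractions are a minimum-norm solution")

  w <- 1e6 * max(abs(S), 1)
  A <- rbind(S, rep(w, k))
  b <- c(x, w)
  f <- nnls_lawson_hanson(A, b)
  total <- sum(f)
  f <- if (total > 0) f / total else rep(1 / k, k)
  names(f) <- colnames(signature)
  list(fractions = f, n_genes_used = length(x),
       objective = sum((S %*% f - x)^2), rank_deficient = rank_def)
}

#' Fractions of identity for every column of a query matrix
#'
#' @param query genes x samples FPKM matrix.
#' @param signature genes x classes signature matrix.
#' @param ... passed to [fraction_of_identity()].
#' @return data.frame: sample, one column per class, n_genes_used.
#' @export
fraction_of_identity_matrix <- function(query, signature, ...) {
  res <- lapply(colnames(query) %||% seq_len(ncol(query)), function(cn) {
    fi <- fraction_of_identity(stats::setNames(query[, cn], rownames(query)),
                               signature, ...)
    c(as.list(fi$fractions), list(n_genes_used = fi$n_genes_used))
  })
  out <- do.call(rbind, lapply(res, as.data.frame))
  cbind(data.frame(sample = colnames(query) %||% as.character(seq_len(ncol(query))),
                   stringsAsFactors = FALSE), out)
}

#' Summarize identity fractions by group
#'
#' Per-group median fraction toward each reference class, plus pairwise
#' Welch two-sample t-tests between groups for each class.
#'
#' @param fractions data.frame from [fraction_of_identity_matrix()].
#' @param groups factor/character vector, one entry per row of `fractions`.
#' @return list: `medians` (group x class), `tests` (data.frame: class,
#'   group_a, group_b, t, p_value).
#' @export
summarize_fractions <- function(fractions, groups) {
  classes <- setdiff(names(fractions), c("sample", "n_genes_used"))
  if (length(unique(groups)) < 2) stop_fmt("need >= 2 groups")
  glev <- unique(groups)
  medians <- t(vapply(glev, function(g) {
    vapply(classes, function(cl) stats::median(fractions[[cl]][groups == g]), numeric(1))
  }, numeric(length(classes))))
  rownames(medians) <- glev
  pairs <- utils::combn(glev, 2, simplify = FALSE)
  tests <- do.call(rbind, lapply(pairs, function(pr) {
    do.call(rbind, lapply(classes, function(cl) {
      a <- fractions[[cl]][groups == pr[1]]
      b <- fractions[[cl]][groups == pr[2]]
      if (length(a) < 2 || length(b) < 2) stop_fmt("group with < 2 samples for t-test")
      tt <- if (stats::sd(c(a, b)) == 0) {
        list(statistic = 0, p.value = 1)
      } else {
        stats::t.test(a, b)
      }
      data.frame(class = cl, group_a = pr[1], group_b = pr[2],
                 t = unname(tt$statistic), p_value = unname(tt$p.value),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(tests) <- NULL
  list(medians = medians, tests = tests)
}
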