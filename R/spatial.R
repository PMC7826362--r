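#' Classify nuclei as inside (ICM) or outside (TE)
#'
#' 2-means clustering of the standardized (min_distance, distance_variance)
#' features. The cluster with the larger mean minimum distance is labelled
#' "inside" (ICM nuclei sit away from the surface); on a tie the cluster with
#' the smaller mean distance variance is "inside". Clustering uses a greedy
#' farthest-point initialization plus seeded random restarts, so the call is
#' deterministic given the features and seed.
#'
#' @param features data.frame from [compute_spatial_features()].
#' @param seed integer seed for the k-means restarts.
#' @param n_restarts random restarts in addition to the farthest-point start.
#' @return list of class `lineage_call`: `labels` (named character,
#'   "inside"/"outside"), `cluster_means` (2 x 2 matrix of feature means),
#'   `seed`.
#' @export
classify_inside_outside <- function(features, seed = 1L, n_restarts = 10L) {
  stopifnot(all(c("min_distance", "distance_variance") %in% names(features)))
  x <- as.matrix(features[, c("min_distance", "distance_variance")])
  if (nrow(x) < 2) stop_fmt("need at least 2 nuclei to classify")
  if (all(apply(x, 2, function(v) max(v) - min(v)) == 0)) {
    stop_fmt("all feature vectors identical: inside/outside clustering undefined")
  }
  # standardize each feature to unit variance (constant columns left as-is)
  xs <- apply(x, 2, function(v) {
    s <- stats::sd(v)
    if (s > 0) (v - mean(v)) / s else v - mean(v)
  })

  # greedy farthest-point start: farthest point from the centroid, then the
  # point farthest from it
  c1 <- which.max(rowSums(sweep(xs, 2, colMeans(xs))^2))
  c2 <- which.max(rowSums(sweep(xs, 2, xs[c1, ])^2))
  fits <- with_seed(substream_seed(seed, 1L), {
    f0 <- suppressWarnings(stats::kmeans(xs, centers = xs[c(c1, c2), , drop = FALSE]))
    fits <- list(f0)
    for (i in seq_len(n_restarts)) {
      idx <- sample(nrow(xs), 2)
      while (all(xs[idx[1], ] == xs[idx[2], ])) idx <- sample(nrow(xs), 2)
      fits[[i + 1L]] <- suppressWarnings(
        stats::kmeans(xs, centers = xs[idx, , drop = FALSE]))
    }
    fits
  })
  best <- fits[[which.min(vapply(fits, function(f) f$tot.withinss, numeric(1)))]]

  means_min <- tapply(x[, 1], best$cluster, mean)
  means_var <- tapply(x[, 2], best$cluster, mean)
  inside_cluster <- if (means_min[1] != means_min[2]) {
    as.integer(names(which.max(means_min)))
  } else {
    as.integer(names(which.min(means_var)))
  }
  labels <- ifelse(best$cluster == inside_cluster, "inside", "outside")
  names(labels) <- if ("nucleus_id" %in% names(features)) features$nucleus_id else seq_along(labels)
  cm <- cbind(mean_min_distance = means_min, mean_distance_variance = means_var)
  rownames(cm) <- ifelse(as.integer(rownames(cm)) == inside_cluster, "inside", "outside")
  structure(list(labels = labels, cluster_means = cm, seed = seed),
            class = "lineage_call")
}

#' Classify every embryo of a nucleus table
#'
#' Convenience wrapper: builds the surface, computes distance features and
#' calls [classify_inside_outside()] per embryo — surfaces and clusterings
#' never mix nuclei across embryos.
#'
#' @param nuclei nucleus table for one or more embryos.
#' @param seed integer seed.
#' @return data.frame: nucleus_id, embryo_id, min_distance,
#'   distance_variance, label.
#' @export
classify_embryos <- function(nuclei, seed = 1L) {
  stopifnot("embryo_id" %in% names(nuclei))
  out <- lapply(split(nuclei, nuclei$embryo_id), function(nuc) {
    surf <- build_surface(nuc)
    feat <- compute_spatial_features(nuc, surf)
    call <- classify_inside_outside(feat, seed = seed)
    cbind(feat, embryo_id = nuc$embryo_id, label = unname(call$labels))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Normalize per-nucleus fluorescence intensities
#'
#' Two conventions are provided, since published violin plots of quantitative
#' immunofluorescence rarely state one: `"zscore"` (default) log-transforms
#' and z-scores within each embryo; `"reference"` divides by the per-embryo
#' median of a reference channel (e.g. DAPI).
#'
#' @param nuclei nucleus table with intensity columns.
#' @param channel intensity column to normalize.
#' @param method `"zscore"` or `"reference"`.
#' @param reference_channel required for `method = "reference"`.
#' @return numeric vector of normalized values with attribute `method`.
#' @export
normalize_intensities <- function(nuclei, channel, method = c("zscore", "reference"),
                                  reference_channel = NULL) {
  method <- match.arg(method)
  if (!channel %in% names(nuclei)) stop_fmt("channel '%s' not found", channel)
  emb <- if ("embryo_id" %in% names(nuclei)) nuclei$embryo_id else rep("all", nrow(nuclei))
  v <- nuclei[[channel]]
  if (any(v < 0)) stop_fmt("intensities must be nonnegative")
  out <- numeric(length(v))
  if (method == "zscore") {
    lg <- log(v + 1)
    for (e in unique(emb)) {
      i <- emb == e
      s <- stats::sd(lg[i])
      if (!is.finite(s) || s == 0) stop_fmt("zero-variance intensities in embryo %s: z-score undefined", e)
      out[i] <- (lg[i] - mean(lg[i])) / s
    }
  } else {
    if (is.null(reference_channel) || !reference_channel %in% names(nuclei)) {
      stop_fmt("reference method requires a valid reference_channel")
    }
    r <- nuclei[[reference_channel]]
    for (e in unique(emb)) {
      i <- emb == e
      med <- stats::median(r[i])
      if (med <= 0) stop_fmt("nonpositive reference median in embryo %s", e)
      out[i] <- v[i] / med
    }
  }
  attr(out, "method") <- method
  out
}

#' Kruskal-Wallis rank test across groups
#'
#' H statistic and chi-square p-value (midrank tie correction) via
#' [stats::kruskal.test()]; for small samples an exact permutation p-value is
#' optionally computed by full enumeration of group assignments.
#'
#' @param groups list of >= 2 nonempty numeric vectors.
#' @param exact if TRUE and total n <= `exact_max_n`, also enumerate the
#'   exact permutation p-value.
#' @param exact_max_n largest total sample size for which enumeration is
#'   attempted (default 10).
#' @return list: `statistic` (H), `p_value` (chi-square approximation),
#'   `df`, and `p_exact` (NULL unless computed).
#' @export
kruskal_wallis <- function(groups, exact = FALSE, exact_max_n = 10L) {
  if (!is.list(groups) || length(groups) < 2) stop_fmt("need >= 2 groups")
  sizes <- lengths(groups)
  if (any(sizes == 0)) stop_fmt("empty group (index %d)", which(sizes == 0)[1])
  kt <- stats::kruskal.test(groups)
  out <- list(statistic = unname(kt$statistic), p_value = unname(kt$p.value),
              df = unname(kt$parameter), p_exact = NULL)
  n <- sum(sizes)
  if (exact && n <= exact_max_n) {
    out$p_exact <- kw_exact_p(groups)
  }
  out
}

# exact permutation p: enumerate all assignments of the pooled values into
# groups of the observed sizes; p = fraction with H >= observed
kw_exact_p <- function(groups) {
  pooled <- unlist(groups, use.names = FALSE)
  sizes <- lengths(groups)
  h_obs <- unname(stats::kruskal.test(groups)$statistic)
  n <- length(pooled)
  count <- 0L
  total <- 0L
  recurse <- function(avail, gi, acc) {
    if (gi == length(sizes)) {
      gs <- c(acc, list(avail))
      h <- unname(stats::kruskal.test(lapply(gs, function(i) pooled[i]))$statistic)
      total <<- total + 1L
      if (h >= h_obs - 1e-12) count <<- count + 1L
      return(invisible())
    }
    picks <- utils::combn(avail, sizes[gi], simplify = FALSE)
    for (pk in picks) recurse(setdiff(avail, pk), gi + 1L, c(acc, list(pk)))
  }
  recurse(seq_len(n), 1L, list())
  count / total
}
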