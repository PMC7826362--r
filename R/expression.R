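#' Read an expression matrix and its cell annotation
#'
#' The matrix is a TSV with genes in rows (first column `gene_id`, remaining
#' columns one per cell); the annotation is a CSV with at least a `cell_id`
#' column. Validation is strict: nonnegative finite values, unique gene and
#' cell ids, and an exact match between the matrix cells and the annotation.
#'
#' @param path expression TSV.
#' @param annotation_path annotation CSV (optional).
#' @return list with `matrix` (genes x cells) and `annotation` (data.frame
#'   or NULL).
#' @export
read_expression <- function(path, annotation_path = NULL) {
  if (!file.exists(path)) stop_fmt("expression file not found: %s", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop_fmt("expression file needs a gene id column plus >= 1 cell")
  gene_ids <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- gene_ids
  validate_expression_matrix(mat)
  annotation <- NULL
  if (!is.null(annotation_path)) {
    if (!file.exists(annotation_path)) stop_fmt("annotation file not found: %s", annotation_path)
    annotation <- utils::read.csv(annotation_path, stringsAsFactors = FALSE)
    if (!"cell_id" %in% names(annotation)) stop_fmt("annotation must have a cell_id column")
    missing_in_ann <- setdiff(colnames(mat), annotation$cell_id)
    missing_in_mat <- setdiff(annotation$cell_id, colnames(mat))
    if (length(missing_in_ann) || length(missing_in_mat)) {
      stop_fmt("annotation/matrix cell mismatch: missing from annotation [%s]; missing from matrix [%s]",
               paste(missing_in_ann, collapse = ", "),
               paste(missing_in_mat, collapse = ", "))
    }
    annotation <- annotation[match(colnames(mat), annotation$cell_id), , drop = FALSE]
    rownames(annotation) <- NULL
  }
  list(matrix = mat, annotation = annotation)
}

validate_expression_matrix <- function(mat) {
  if (anyDuplicated(rownames(mat))) {
    stop_fmt("duplicate gene ids: %s",
             paste(unique(rownames(mat)[duplicated(rownames(mat))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(mat))) {
    stop_fmt("duplicate cell ids: %s",
             paste(unique(colnames(mat)[duplicated(colnames(mat))]), collapse = ", "))
  }
  bad <- which(!is.finite(mat) | mat < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop_fmt("negative or non-finite value at gene '%s', cell '%s'",
             rownames(mat)[bad[1, 1]], colnames(mat)[bad[1, 2]])
  }
  invisible(mat)
}

#' Keep genes expressed (FPKM > 0) in at least one condition
#'
#' @param mat genes x cells FPKM matrix.
#' @param groups optional factor/character partition of cells into
#'   conditions; a gene is kept if its maximum FPKM within at least one
#'   condition is positive. With exhaustive groups (the default single
#'   group) this reduces to: maximum over all cells > 0.
#' @return the filtered matrix, gene order preserved.
#' @export
filter_expressed <- function(mat, groups = NULL) {
  if (is.null(groups)) groups <- rep("all", ncol(mat))
  if (length(groups) != ncol(mat)) stop_fmt("groups must have one entry per cell")
  if (any(table(groups) == 0)) stop_fmt("empty group")
  keep <- rep(FALSE, nrow(mat))
  for (g in unique(groups)) {
    sub <- mat[, groups == g, drop = FALSE]
    keep <- keep | (apply(sub, 1, max) > 0)
  }
  mat[keep, , drop = FALSE]
}

#' log2 transform with pseudocount
#'
#' @param mat FPKM matrix.
#' @param pseudocount positive offset added before taking log2 (default 1,
#'   so FPKM 0 maps to 0).
#' @return transformed matrix.
#' @export
log2_transform <- function(mat, pseudocount = 1) {
  if (pseudocount <= 0) stop_fmt("pseudocount must be > 0")
  log2(mat + pseudocount)
}

#' Parameters for highly-variable-gene selection
#'
#' @param min_mean threshold on average log2(FPKM + 1) (default 0.5).
#' @param min_logcv2 threshold on log10 of the squared coefficient of
#'   variation of FPKM (default 0.5).
#' @param trend_span span of the locally weighted mean-CV^2 trend.
#' @param require_above_trend if TRUE (default), selected genes must also
#'   lie above the fitted trend; FALSE reproduces the pure two-threshold
#'   rule.
#' @return parameter list.
#' @export
hvg_params <- function(min_mean = 0.5, min_logcv2 = 0.5, trend_span = 0.3,
                       require_above_trend = TRUE) {
  stopifnot(is.finite(min_mean), is.finite(min_logcv2), trend_span > 0)
  list(min_mean = min_mean, min_logcv2 = min_logcv2, trend_span = trend_span,
       require_above_trend = require_above_trend)
}

#' Select highly variable genes from the mean-CV^2 relationship
#'
#' Per gene, the average log2(FPKM + 1) and the squared coefficient of
#' variation of raw FPKM (reported as log10, `logcv2`) are computed. A
#' locally weighted regression of logCV^2 on the mean captures the
#' mean-variance trend; genes are selected when they exceed both axis
#' thresholds and (by default) lie above the trend.
#'
#' @param mat genes x cells FPKM matrix (pre-filtered by
#'   [filter_expressed()]).
#' @param params an [hvg_params()] list.
#' @return data.frame: gene, mean_log2, logcv2, trend_value, residual,
#'   selected.
#' @export
select_hvg <- function(mat, params = hvg_params()) {
  if (ncol(mat) < 2) stop_fmt("need >= 2 cells")
  mean_log2 <- rowMeans(log2(mat + 1))
  mu <- rowMeans(mat)
  v <- apply(mat, 1, stats::var)
  cv2 <- ifelse(mu > 0, v / mu^2, NA_real_)
  logcv2 <- ifelse(!is.na(cv2) & cv2 > 0, log10(cv2), -Inf)
  ok <- is.finite(logcv2)
  if (sum(mu > 0) < 10) stop_fmt("fewer than 10 genes with positive mean: trend unfittable")

  trend_value <- rep(NA_real_, nrow(mat))
  if (sum(ok) >= 10) {
    fit <- stats::loess(logcv2[ok] ~ mean_log2[ok], span = params$trend_span,
                        degree = 2, family = "symmetric",
                        control = stats::loess.control(surface = "direct"))
    trend_value[ok] <- stats::predict(fit, mean_log2[ok])
  }
  residual <- logcv2 - trend_value
  selected <- mean_log2 > params$min_mean & logcv2 > params$min_logcv2
  if (params$require_above_trend) {
    selected <- selected & !is.na(residual) & residual > 0
  }
  selected[!ok] <- FALSE
  data.frame(gene = rownames(mat), mean_log2 = mean_log2, logcv2 = logcv2,
             trend_value = trend_value, residual = residual,
             selected = selected, row.names = NULL, stringsAsFactors = FALSE)
}
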