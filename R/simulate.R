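#' Parameters for simulating a blastocyst nuclear point cloud
#'
#' The simulated embryo mimics the geometry the spatial classifier relies on:
#' an outer shell of trophectoderm-like nuclei on a jittered ellipsoid, and a
#' compact inner-cell-mass clump displaced toward one pole. Channel
#' intensities are drawn lognormally with lineage-dependent means, emulating
#' quantitative immunofluorescence of markers restricted to one lineage.
#'
#' Defaults describe a mid-blastocyst: ~60 outer and ~15 inner nuclei within
#' a sphere of radius 50 um, shell jitter 1.5 um, ICM clump offset 40% of the
#' radius toward the +z pole with 10 um spread.
#'
#' @param n_outer number of shell (TE-like) nuclei; at least 8.
#' @param n_inner number of interior (ICM-like) nuclei; may be 0.
#' @param outer_radius shell radius in um.
#' @param axis_ratios length-3 positive scaling of the ellipsoid axes
#'   (default sphere).
#' @param shell_jitter isotropic Gaussian jitter sd of shell nuclei (um).
#' @param icm_offset fraction of `outer_radius` the ICM clump centre is
#'   displaced toward the +z pole.
#' @param icm_spread Gaussian sd of the ICM clump (um); must be smaller than
#'   `outer_radius`.
#' @param channel_effects named list, one entry per fluorescence channel, each
#'   a numeric vector with elements `inside` and `outside`: mean log-intensity
#'   per lineage.
#' @param intensity_sd lognormal sd of channel intensities (log scale).
#' @param seed integer seed; the simulation is a pure function of the
#'   parameters including this seed.
#' @return a validated parameter list of class `embryo_sim_params`.
#' @export
embryo_sim_params <- function(n_outer = 60L, n_inner = 15L,
                              outer_radius = 50, axis_ratios = c(1, 1, 1),
                              shell_jitter = 1.5, icm_offset = 0.4,
                              icm_spread = 10,
                              channel_effects = list(
                                ch1 = c(inside = 5.5, outside = 4.0),
                                ch2 = c(inside = 4.0, outside = 5.5)
                              ),
                              intensity_sd = 0.3, seed = 1L) {
  if (n_outer < 8) stop_fmt("n_outer must be >= 8 (got %d): the hull of fewer shell points cannot enclose interior nuclei robustly", n_outer)
  if (n_inner < 0) stop_fmt("n_inner must be >= 0")
  if (outer_radius <= 0) stop_fmt("outer_radius must be > 0")
  if (icm_spread >= outer_radius) stop_fmt("icm_spread must be smaller than outer_radius")
  if (shell_jitter < 0 || intensity_sd < 0) stop_fmt("jitter and intensity_sd must be nonnegative")
  if (length(axis_ratios) != 3 || any(axis_ratios <= 0)) stop_fmt("axis_ratios must be 3 positive numbers")
  if (!is.list(channel_effects) || is.null(names(channel_effects)) ||
      !all(vapply(channel_effects, function(e) all(c("inside", "outside") %in% names(e)), logical(1)))) {
    stop_fmt("channel_effects must be a named list of vectors with 'inside' and 'outside' entries")
  }
  structure(list(n_outer = as.integer(n_outer), n_inner = as.integer(n_inner),
                 outer_radius = outer_radius, axis_ratios = axis_ratios,
                 shell_jitter = shell_jitter, icm_offset = icm_offset,
                 icm_spread = icm_spread, channel_effects = channel_effects,
                 intensity_sd = intensity_sd, seed = as.integer(seed)),
            class = "embryo_sim_params")
}

runif_sphere <- function(n) {
  # uniform directions on the unit sphere
  z <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(x = s * cos(phi), y = s * sin(phi), z = z)
}

#' Simulate a blastocyst-like nuclear point cloud
#'
#' Outer nuclei are placed on a jittered ellipsoidal shell; inner nuclei are
#' drawn from a Gaussian clump displaced toward one pole and constrained to
#' lie well inside the shell (the inner cell mass is physically confined by
#' the trophectoderm). Per-channel intensities are lognormal with
#' lineage-dependent log-means. Identical parameters (including seed) give
#' identical output.
#'
#' @param params an [embryo_sim_params()] object.
#' @param embryo_id identifier written into the nucleus table.
#' @return a list with `nuclei` (data.frame: nucleus_id, embryo_id, x, y, z,
#'   volume, one column per channel) and `truth` (list with `nucleus_labels`,
#'   "inside"/"outside" per row).
#' @export
simulate_embryo <- function(params, embryo_id = "embryo1") {
  stopifnot(inherits(params, "embryo_sim_params"))
  p <- params
  n <- p$n_outer + p$n_inner

  outer_pos <- with_seed(substream_seed(p$seed, 1L), {
    dirs <- runif_sphere(p$n_outer)
    pos <- dirs * rep(p$outer_radius * p$axis_ratios, each = p$n_outer)
    pos + matrix(stats::rnorm(3 * p$n_outer, sd = p$shell_jitter), ncol = 3)
  })

  inner_pos <- with_seed(substream_seed(p$seed, 2L), {
    if (p$n_inner == 0) {
      matrix(numeric(0), ncol = 3)
    } else {
      centre <- c(0, 0, p$icm_offset * p$outer_radius * p$axis_ratios[3])
      semi <- p$outer_radius * p$axis_ratios
      acc <- matrix(numeric(0), ncol = 3)
      # rejection step keeps the clump strictly interior (ellipsoidal norm < 0.85)
      while (nrow(acc) < p$n_inner) {
        cand <- matrix(stats::rnorm(3 * p$n_inner, sd = p$icm_spread), ncol = 3)
        cand <- sweep(cand, 2, centre, `+`)
        keep <- rowSums(sweep(cand, 2, semi, `/`)^2) < 0.85^2
        acc <- rbind(acc, cand[keep, , drop = FALSE])
      }
      acc[seq_len(p$n_inner), , drop = FALSE]
    }
  })

  volume <- with_seed(substream_seed(p$seed, 3L),
                      stats::rlnorm(n, meanlog = log(700), sdlog = 0.25))

  labels <- rep(c("outside", "inside"), c(p$n_outer, p$n_inner))
  intens <- with_seed(substream_seed(p$seed, 4L), {
    vapply(p$channel_effects, function(eff) {
      stats::rlnorm(n, meanlog = unname(eff[labels]), sdlog = p$intensity_sd)
    }, numeric(n))
  })
  if (n == 1L) intens <- matrix(intens, nrow = 1, dimnames = list(NULL, names(p$channel_effects)))

  pos <- rbind(outer_pos, inner_pos)
  nuclei <- data.frame(
    nucleus_id = sprintf("%s_n%03d", embryo_id, seq_len(n)),
    embryo_id = embryo_id,
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    volume = volume,
    stringsAsFactors = FALSE
  )
  nuclei <- cbind(nuclei, as.data.frame(intens))
  list(nuclei = nuclei, truth = list(nucleus_labels = labels))
}

#' Parameters for simulating a structured single-cell FPKM matrix
#'
#' The generated matrix carries the statistical structure the downstream
#' stages are designed to detect: per-class signature blocks (differential
#' expression), planted high-variance genes, planted coexpression modules
#' driven by latent factors, and genes with a monotone trend along a latent
#' cell ordering (pseudotime). All special gene sets are disjoint.
#'
#' FPKM values are `2^(log2 baseline + effects + N(0, sd))`, i.e. lognormal
#' noise around a structured log2 mean — matching the log2FPKM analyses the
#' pipeline performs (no count-level model is simulated).
#'
#' @param n_genes total number of genes.
#' @param classes named integer vector: cells per class (names are class
#'   labels, e.g. `c(WT = 20, MUT = 20)`).
#' @param n_signature_per_class marker genes planted per class.
#' @param signature_log2fc log2 fold-change of a signature gene in its class.
#' @param n_hvg planted high-variance genes.
#' @param hvg_cv_multiplier factor (> 1) multiplying the noise sd of HVGs.
#' @param n_modules number of planted coexpression modules.
#' @param module_size genes per module.
#' @param module_latent_sd on/off separation (log2 units) of the two-state\n#'   latent program driving a module; within-state variation has sd 1.
#' @param baseline_log2_mean_range interval for per-gene baseline log2 FPKM.
#' @param dispersion sd (log2 units) of the lognormal noise.
#' @param pseudotime_genes number of monotone-trend genes.
#' @param trend_log2fc log2 effect of a trend gene across the full ordering.
#' @param seed integer seed.
#' @return a validated parameter list of class `expression_sim_params`.
#' @export
expression_sim_params <- function(n_genes = 2000L, classes = c(A = 20L, B = 20L),
                                  n_signature_per_class = 50L, signature_log2fc = 2,
                                  n_hvg = 100L, hvg_cv_multiplier = 4,
                                  n_modules = 4L, module_size = 40L,
                                  module_latent_sd = 12,
                                  baseline_log2_mean_range = c(1, 6),
                                  dispersion = 0.9, pseudotime_genes = 50L,
                                  trend_log2fc = 3, seed = 1L) {
  counts <- c(n_genes, classes, n_signature_per_class, n_hvg, n_modules,
              module_size, pseudotime_genes)
  if (any(counts < 0)) stop_fmt("all counts must be nonnegative")
  if (is.null(names(classes)) || any(names(classes) == "")) stop_fmt("classes must be a named vector")
  if (hvg_cv_multiplier <= 1) stop_fmt("hvg_cv_multiplier must exceed 1")
  n_special <- length(classes) * n_signature_per_class + n_hvg +
    n_modules * module_size + pseudotime_genes
  if (n_special > n_genes) {
    stop_fmt("special gene sets overlap: %d signature + %d hvg + %d module + %d trend genes exceed n_genes = %d",
             length(classes) * n_signature_per_class, n_hvg,
             n_modules * module_size, pseudotime_genes, n_genes)
  }
  structure(list(n_genes = as.integer(n_genes), classes = classes,
                 n_signature_per_class = as.integer(n_signature_per_class),
                 signature_log2fc = signature_log2fc, n_hvg = as.integer(n_hvg),
                 hvg_cv_multiplier = hvg_cv_multiplier,
                 n_modules = as.integer(n_modules), module_size = as.integer(module_size),
                 module_latent_sd = module_latent_sd,
                 baseline_log2_mean_range = baseline_log2_mean_range,
                 dispersion = dispersion, pseudotime_genes = as.integer(pseudotime_genes),
                 trend_log2fc = trend_log2fc, seed = as.integer(seed)),
            class = "expression_sim_params")
}

sim_annotation <- function(cell_ids, cell_classes) {
  genotypes <- c("WT", "HET", "MUT")
  lineages <- c("EPI", "PrE", "TE", "ICM")
  data.frame(
    cell_id = cell_ids,
    embryo_id = paste0("sim_", cell_classes),
    stage = "other",
    genotype = ifelse(cell_classes %in% genotypes, cell_classes, NA_character_),
    lineage = ifelse(cell_classes %in% lineages, cell_classes, "unassigned"),
    class = cell_classes,
    stringsAsFactors = FALSE
  )
}

#' Simulate a gene-by-cell FPKM matrix with planted structure
#'
#' @param params an [expression_sim_params()] object.
#' @return list with `matrix` (genes x cells FPKM), `annotation`
#'   (data.frame; `class` column carries the simulation class), and `truth`
#'   (list: `gene_roles` — named character vector over genes, one of
#'   `signature:<class>`, `hvg`, `module:<k>`, `trend`, `background`;
#'   `cell_classes`; `latent_time` in \[0,1\]; `latent_order` — rank
#'   permutation of cells along the latent trajectory).
#' @export
simulate_expression <- function(params) {
  stopifnot(inherits(params, "expression_sim_params"))
  p <- params
  n_cells <- sum(p$classes)
  if (n_cells < 1) stop_fmt("at least one cell required")
  gene_ids <- sprintf("gene_%04d", seq_len(p$n_genes))
  cell_ids <- sprintf("cell_%03d", seq_len(n_cells))
  cell_classes <- rep(names(p$classes), p$classes)

  # disjoint role assignment, in gene order
  roles <- rep("background", p$n_genes)
  cursor <- 0L
  take <- function(k) {
    idx <- cursor + seq_len(k)
    cursor <<- cursor + k
    idx
  }
  sig_idx <- lapply(names(p$classes), function(cl) {
    idx <- take(p$n_signature_per_class)
    roles[idx] <<- paste0("signature:", cl)
    idx
  })
  names(sig_idx) <- names(p$classes)
  hvg_idx <- take(p$n_hvg); roles[hvg_idx] <- "hvg"
  mod_idx <- lapply(seq_len(p$n_modules), function(k) {
    idx <- take(p$module_size)
    roles[idx] <<- paste0("module:", k)
    idx
  })
  trend_idx <- take(p$pseudotime_genes); roles[trend_idx] <- "trend"
  names(roles) <- gene_ids

  baseline <- with_seed(substream_seed(p$seed, 1L),
                        stats::runif(p$n_genes, p$baseline_log2_mean_range[1],
                                     p$baseline_log2_mean_range[2]))
  latent_t <- with_seed(substream_seed(p$seed, 2L), stats::runif(n_cells))
  module_latent <- with_seed(substream_seed(p$seed, 3L), {
    # two-state lineage-program latent: on/off separation of module_latent_sd
    # log2 units plus graded within-state variation (sd 1)
    state <- matrix(stats::rbinom(p$n_modules * n_cells, 1, 0.5) - 0.5,
                    nrow = p$n_modules, ncol = n_cells)
    state * p$module_latent_sd +
      matrix(stats::rnorm(p$n_modules * n_cells), nrow = p$n_modules, ncol = n_cells)
  })
  loadings <- with_seed(substream_seed(p$seed, 4L),
                        stats::runif(p$n_modules * p$module_size, 0.8, 1))

  log2mu <- matrix(baseline, nrow = p$n_genes, ncol = n_cells)
  for (cl in names(p$classes)) {
    in_class <- cell_classes == cl
    log2mu[sig_idx[[cl]], in_class] <- log2mu[sig_idx[[cl]], in_class] + p$signature_log2fc
  }
  if (p$n_modules > 0 && p$module_size > 0) {
    for (k in seq_len(p$n_modules)) {
      lg <- loadings[(k - 1L) * p$module_size + seq_len(p$module_size)]
      log2mu[mod_idx[[k]], ] <- log2mu[mod_idx[[k]], ] + outer(lg, module_latent[k, ])
    }
  }
  if (p$pseudotime_genes > 0) {
    trend_sign <- rep(c(1, -1), length.out = p$pseudotime_genes)
    log2mu[trend_idx, ] <- log2mu[trend_idx, ] +
      (p$trend_log2fc * trend_sign) %o% latent_t
  }

  sd_gene <- rep(p$dispersion, p$n_genes)
  sd_gene[hvg_idx] <- p$dispersion * p$hvg_cv_multiplier
  noise <- with_seed(substream_seed(p$seed, 5L), {
    matrix(stats::rnorm(p$n_genes * n_cells), nrow = p$n_genes) * sd_gene
  })

  fpkm <- pmax(2^(log2mu + noise), 0)
  dimnames(fpkm) <- list(gene_ids, cell_ids)

  list(
    matrix = fpkm,
    annotation = sim_annotation(cell_ids, cell_classes),
    truth = list(gene_roles = roles, cell_classes = stats::setNames(cell_classes, cell_ids),
                 module_latent = if (p$n_modules > 0) {
                   matrix(module_latent, nrow = p$n_modules,
                          dimnames = list(paste0("module_", seq_len(p$n_modules)), cell_ids))
                 } else NULL,
                 latent_time = stats::setNames(latent_t, cell_ids),
                 latent_order = stats::setNames(rank(latent_t, ties.method = "first"), cell_ids))
  )
}

#' Simulate mixed expression profiles from a signature matrix
#'
#' Each sample is a known convex combination of the signature columns with
#' optional multiplicative lognormal noise — ground truth for the
#' fraction-of-identity deconvolution.
#'
#' @param signature genes x classes nonnegative matrix.
#' @param fractions samples x classes matrix; each row on the probability
#'   simplex (nonnegative, sums to 1 within 1e-9).
#' @param noise_sd sd (natural-log scale) of multiplicative lognormal noise.
#' @param seed integer seed.
#' @return list with `matrix` (genes x samples) and `truth`
#'   (`mixing_fractions`, the input fractions).
#' @export
simulate_mixtures <- function(signature, fractions, noise_sd = 0, seed = 1L) {
  signature <- as.matrix(signature)
  fractions <- matrix(fractions, ncol = ncol(signature))
  if (any(fractions < 0)) stop_fmt("mixing fractions must be nonnegative")
  sums <- rowSums(fractions)
  if (any(abs(sums - 1) > 1e-9)) stop_fmt("mixing fractions must sum to 1 (max deviation %.3g)", max(abs(sums - 1)))
  if (noise_sd < 0) stop_fmt("noise_sd must be nonnegative")
  mixed <- signature %*% t(fractions)
  if (noise_sd > 0) {
    mixed <- mixed * with_seed(substream_seed(seed, 1L), {
      matrix(stats::rlnorm(length(mixed), 0, noise_sd), nrow = nrow(mixed))
    })
  }
  colnames(mixed) <- sprintf("mix_%03d", seq_len(nrow(fractions)))
  rownames(mixed) <- rownames(signature)
  rownames(fractions) <- colnames(mixed)
  colnames(fractions) <- colnames(signature)
  list(matrix = mixed, truth = list(mixing_fractions = fractions))
}

#' Write a nucleus table to CSV
#' @param nuclei data.frame as returned by [simulate_embryo()].
#' @param path output file.
#' @export
write_nuclei_csv <- function(nuclei, path) {
  utils::write.csv(nuclei, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an expression matrix to TSV (genes in rows, first column `gene_id`)
#' @param mat genes x cells matrix with dimnames.
#' @param path output file.
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a cell-annotation table to CSV
#' @param annotation data.frame with a `cell_id` column.
#' @param path output file.
#' @export
write_annotation_csv <- function(annotation, path) {
  utils::write.csv(annotation, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write simulation ground truth to JSON
#' @param truth ground-truth list from a simulator.
#' @param path output file.
#' @export
write_ground_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
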