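#' Convex hull of a 3-D point cloud
#'
#' Incremental hull construction: an initial extreme tetrahedron is grown by
#' inserting each remaining point, deleting the faces it can see and stitching
#' new faces along the horizon. Faces are kept consistently oriented with
#' outward normals, so the result is a watertight triangulated boundary
#' satisfying F = 2V - 4. For the convex nuclear point clouds handled here
#' this boundary coincides with the boundary of the 3-D Delaunay complex.
#'
#' @param pts numeric matrix (n x 3), n >= 4.
#' @param tol distance tolerance for visibility/coplanarity tests; default
#'   1e-8 times the coordinate range.
#' @return list with `vertices` (matrix of hull-vertex coordinates),
#'   `triangles` (integer matrix, m x 3, indices into `vertices`), and
#'   `vertex_index` (indices of hull vertices in the input).
#' @export
convex_hull_3d <- function(pts, tol = NULL) {
  pts <- as.matrix(pts)
  if (ncol(pts) != 3) stop_fmt("points must have 3 columns")
  if (!all(is.finite(pts))) stop_fmt("coordinates must be finite")
  n <- nrow(pts)
  if (n < 4) stop_fmt("need at least 4 points for a 3-D hull (got %d)", n)
  scale <- max(apply(pts, 2, function(v) diff(range(v))), .Machine$double.eps)
  tol <- tol %||% (1e-8 * scale)

  cross3 <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                             u[3] * v[1] - u[1] * v[3],
                             u[1] * v[2] - u[2] * v[1])

  # --- initial extreme tetrahedron (lowest-index tie-breaks: deterministic)
  i1 <- which.min(pts[, 1])
  d1 <- sqrt(colSums((t(pts) - pts[i1, ])^2))
  i2 <- which.max(d1)
  if (d1[i2] <= tol) stop_fmt("degenerate geometry: all points coincide")
  u <- pts[i2, ] - pts[i1, ]
  vdiff <- sweep(pts, 2, pts[i1, ])
  cr <- t(apply(vdiff, 1, function(w) cross3(u, w)))
  dline <- sqrt(rowSums(cr^2)) / sqrt(sum(u^2))
  i3 <- which.max(dline)
  if (dline[i3] <= tol) stop_fmt("degenerate geometry: points are collinear")
  nrm <- cross3(pts[i2, ] - pts[i1, ], pts[i3, ] - pts[i1, ])
  nrm <- nrm / sqrt(sum(nrm^2))
  dplane <- abs(as.vector(vdiff %*% nrm))
  i4 <- which.max(dplane)
  if (dplane[i4] <= tol) stop_fmt("degenerate geometry: points are coplanar")

  init <- c(i1, i2, i3, i4)
  interior <- colMeans(pts[init, ])
  faces <- rbind(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))

  face_normals <- function(f) {
    a <- pts[f[, 1], , drop = FALSE]
    nr <- cbind(
      (pts[f[, 2], 2] - a[, 2]) * (pts[f[, 3], 3] - a[, 3]) - (pts[f[, 2], 3] - a[, 3]) * (pts[f[, 3], 2] - a[, 2]),
      (pts[f[, 2], 3] - a[, 3]) * (pts[f[, 3], 1] - a[, 1]) - (pts[f[, 2], 1] - a[, 1]) * (pts[f[, 3], 3] - a[, 3]),
      (pts[f[, 2], 1] - a[, 1]) * (pts[f[, 3], 2] - a[, 2]) - (pts[f[, 2], 2] - a[, 2]) * (pts[f[, 3], 1] - a[, 1])
    )
    len <- sqrt(rowSums(nr^2))
    list(normal = nr / len, origin = a, len = len)
  }
  orient_outward <- function(f) {
    fn <- face_normals(f)
    s <- rowSums(fn$normal * (matrix(interior, nrow(f), 3, byrow = TRUE) - fn$origin))
    flip <- s > 0
    f[flip, c(2, 3)] <- f[flip, c(3, 2)]
    f
  }
  faces <- orient_outward(faces)

  remaining <- setdiff(seq_len(n), init)
  for (ip in remaining) {
    fn <- face_normals(faces)
    sd <- rowSums(fn$normal * (matrix(pts[ip, ], nrow(faces), 3, byrow = TRUE) - fn$origin))
    vis <- sd > tol
    if (!any(vis)) next
    visf <- faces[vis, , drop = FALSE]
    edges <- rbind(visf[, c(1, 2)], visf[, c(2, 3)], visf[, c(3, 1)])
    ek <- paste(edges[, 1], edges[, 2])
    rk <- paste(edges[, 2], edges[, 1])
    horizon <- edges[!(rk %in% ek), , drop = FALSE]
    newf <- cbind(horizon, ip)
    faces <- rbind(faces[!vis, , drop = FALSE], orient_outward(newf))
  }

  vidx <- sort(unique(as.vector(faces)))
  remap <- integer(n)
  remap[vidx] <- seq_along(vidx)
  tri <- matrix(remap[faces], ncol = 3)
  list(vertices = pts[vidx, , drop = FALSE], triangles = tri, vertex_index = vidx)
}

#' Build the in-silico embryo surface from one embryo's nuclei
#'
#' Triangulates the boundary of the nuclear centroid cloud: the convex-hull
#' boundary of the 3-D Delaunay complex of all centroids of the embryo. The
#' surface is the reference against which per-nucleus distance features are
#' computed.
#'
#' @param nuclei data.frame with columns `x`, `y`, `z` (and optionally
#'   `nucleus_id`, `embryo_id`) for a single embryo.
#' @return an object of class `embryo_surface`: list with `vertices`,
#'   `triangles`, `vertex_index`, `embryo_id`.
#' @export
build_surface <- function(nuclei) {
  stopifnot(all(c("x", "y", "z") %in% names(nuclei)))
  embryo <- if ("embryo_id" %in% names(nuclei)) unique(nuclei$embryo_id) else "unknown"
  if (length(embryo) != 1) stop_fmt("build_surface expects nuclei of a single embryo (got: %s)", paste(embryo, collapse = ", "))
  pts <- as.matrix(nuclei[, c("x", "y", "z")])
  hull <- tryCatch(convex_hull_3d(pts),
                   error = function(e) stop_fmt("embryo %s: %s", embryo, conditionMessage(e)))
  structure(c(hull, list(embryo_id = embryo)), class = "embryo_surface")
}

#' Distances from one point to a set of triangles
#'
#' Closest-point computation on the closed triangle via the standard
#' barycentric region decomposition (vertex, edge and interior regions),
#' vectorised over triangles.
#'
#' @param p numeric length-3 point.
#' @param v1,v2,v3 m x 3 matrices of triangle vertices.
#' @return numeric vector of m Euclidean distances.
#' @export
dist_point_triangles <- function(p, v1, v2, v3) {
  v1 <- matrix(v1, ncol = 3); v2 <- matrix(v2, ncol = 3); v3 <- matrix(v3, ncol = 3)
  m <- nrow(v1)
  P <- matrix(p, m, 3, byrow = TRUE)
  ab <- v2 - v1; ac <- v3 - v1; ap <- P - v1
  area2 <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
                 ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
                 ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  if (any(rowSums(area2^2) <= (.Machine$double.eps * max(1, max(abs(cbind(v1, v2, v3)))))^2)) {
    stop_fmt("zero-area triangle encountered")
  }
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  bp <- P - v2
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  cp <- P - v3
  d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)
  vc <- d1 * d4 - d3 * d2
  vb <- d5 * d2 - d1 * d6
  va <- d3 * d6 - d4 * d5

  closest <- matrix(NA_real_, m, 3)
  done <- rep(FALSE, m)
  set_pts <- function(idx, val) {
    closest[idx, ] <<- val
    done[idx] <<- TRUE
  }
  r <- !done & d1 <= 0 & d2 <= 0                      # vertex A
  if (any(r)) set_pts(r, v1[r, , drop = FALSE])
  r <- !done & d3 >= 0 & d4 <= d3                     # vertex B
  if (any(r)) set_pts(r, v2[r, , drop = FALSE])
  r <- !done & vc <= 0 & d1 >= 0 & d3 <= 0            # edge AB
  if (any(r)) {
    t <- d1[r] / (d1[r] - d3[r])
    set_pts(r, v1[r, , drop = FALSE] + ab[r, , drop = FALSE] * t)
  }
  r <- !done & d6 >= 0 & d5 <= d6                     # vertex C
  if (any(r)) set_pts(r, v3[r, , drop = FALSE])
  r <- !done & vb <= 0 & d2 >= 0 & d6 <= 0            # edge AC
  if (any(r)) {
    t <- d2[r] / (d2[r] - d6[r])
    set_pts(r, v1[r, , drop = FALSE] + ac[r, , drop = FALSE] * t)
  }
  r <- !done & va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0  # edge BC
  if (any(r)) {
    t <- (d4[r] - d3[r]) / ((d4[r] - d3[r]) + (d5[r] - d6[r]))
    set_pts(r, v2[r, , drop = FALSE] + (v3[r, , drop = FALSE] - v2[r, , drop = FALSE]) * t)
  }
  r <- !done                                           # face interior
  if (any(r)) {
    denom <- 1 / (va[r] + vb[r] + vc[r])
    v <- vb[r] * denom; w <- vc[r] * denom
    set_pts(r, v1[r, , drop = FALSE] + ab[r, , drop = FALSE] * v + ac[r, , drop = FALSE] * w)
  }
  sqrt(rowSums((P - closest)^2))
}

#' Distance from a point to a single closed triangle
#'
#' @param p numeric length-3 point.
#' @param tri 3 x 3 matrix, one triangle vertex per row.
#' @return Euclidean distance (scalar).
#' @export
point_triangle_distance <- function(p, tri) {
  tri <- as.matrix(tri)
  stopifnot(length(p) == 3, all(dim(tri) == c(3, 3)))
  dist_point_triangles(p, tri[1, , drop = FALSE], tri[2, , drop = FALSE],
                       tri[3, , drop = FALSE])
}

#' Per-nucleus distance features relative to the embryo surface
#'
#' For every nucleus the distance to every surface triangle is computed; the
#' minimum and the population variance over faces are the two features used
#' to call nuclei inside (ICM) or outside (TE): interior nuclei sit far from
#' their nearest face and at comparable distance from all faces, surface
#' nuclei touch their nearest face but are very far from faces across the
#' cavity.
#'
#' @param nuclei data.frame with `x`, `y`, `z` and `nucleus_id`.
#' @param surface an `embryo_surface` built from the same embryo's nuclei.
#' @param keep_all_distances if TRUE, attach the full nucleus x face distance
#'   matrix as attribute `all_distances`.
#' @return data.frame: `nucleus_id`, `min_distance`, `distance_variance`.
#' @export
compute_spatial_features <- function(nuclei, surface, keep_all_distances = FALSE) {
  stopifnot(inherits(surface, "embryo_surface"))
  if (is.null(surface$triangles) || nrow(surface$triangles) == 0) stop_fmt("empty surface")
  tri <- surface$triangles
  v1 <- surface$vertices[tri[, 1], , drop = FALSE]
  v2 <- surface$vertices[tri[, 2], , drop = FALSE]
  v3 <- surface$vertices[tri[, 3], , drop = FALSE]
  pts <- as.matrix(nuclei[, c("x", "y", "z")])
  dmat <- t(vapply(seq_len(nrow(pts)),
                   function(i) dist_point_triangles(pts[i, ], v1, v2, v3),
                   numeric(nrow(tri))))
  if (nrow(tri) == 1L) dmat <- matrix(dmat, ncol = 1)
  mins <- apply(dmat, 1, min)
  vars <- rowMeans((dmat - rowMeans(dmat))^2)   # population variance over faces
  out <- data.frame(
    nucleus_id = if ("nucleus_id" %in% names(nuclei)) nuclei$nucleus_id else seq_len(nrow(pts)),
    min_distance = mins,
    distance_variance = vars,
    stringsAsFactors = FALSE
  )
  if (keep_all_distances) attr(out, "all_distances") <- dmat
  out
}

#' Audit that a surface is watertight
#'
#' Checks that every undirected edge is shared by exactly two triangles and
#' that the Euler relation for a closed triangulated surface, F = 2V - 4,
#' holds.
#'
#' @param surface an `embryo_surface` or the list returned by
#'   [convex_hull_3d()].
#' @return TRUE invisibly; stops with a message otherwise.
#' @export
audit_surface <- function(surface) {
  tri <- surface$triangles
  nv <- nrow(surface$vertices)
  edges <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  und <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  tab <- table(und)
  if (!all(tab == 2)) stop_fmt("surface not watertight: %d edge(s) not shared by exactly 2 triangles", sum(tab != 2))
  if (nrow(tri) != 2 * nv - 4) stop_fmt("Euler relation violated: F = %d, V = %d", nrow(tri), nv)
  invisible(TRUE)
}
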