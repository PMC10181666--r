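#' Moving-least-squares smoothing
#'
#' Projects each point onto a locally fitted polynomial surface: the
#' neighbourhood within `search_radius` defines a local tangent frame
#' (weighted covariance), a bivariate polynomial of order `poly_order` is
#' fitted to the heights with Gaussian weights, and the point is replaced by
#' its projection onto that surface.  Points whose neighbourhood is too
#' small for the polynomial pass through unsmoothed (with a warning).
#' The point count is preserved.
#'
#' @param points coordinate matrix or [leaf_cloud()] with at least 10
#'   points.
#' @param search_radius neighbourhood radius in meters (default 0.012,
#'   i.e. four 3-mm voxels).
#' @param poly_order 1 (plane) or 2 (quadric, default).
#' @return Same type as the input, with smoothed coordinates.
#' @export
mls_smooth <- function(points, search_radius = 0.012, poly_order = 2L) {
  X <- as_coords(points)
  if (nrow(X) < 10L) stop("MLS smoothing needs at least 10 points")
  if (search_radius <= 0) stop("`search_radius` must be positive")
  poly_order <- as.integer(poly_order)
  if (!poly_order %in% c(1L, 2L)) stop("`poly_order` must be 1 or 2")
  res <- cpp_mls_smooth(X, search_radius, poly_order)
  if (!all(res$smoothed))
    warning(sum(!res$smoothed),
            " point(s) had too few neighbours and passed through unsmoothed")
  if (inherits(points, "leaf_cloud")) {
    points$coords <- res$points
    points
  } else {
    res$points
  }
}

#' Surface triangulation of a leaf-like point cloud
#'
#' Projection-based triangulation: the points are projected onto their
#' principal (total-least-squares) plane, triangulated in 2-D by Delaunay
#' triangulation, and triangles are pruned when any 3-D edge exceeds
#' `mu` times the mean local nearest-neighbour spacing of its vertices or
#' when the triangle is degenerate.  This assumes the surface is injective
#' over its principal plane — true for leaves, including moderately folded
#' ones, and for any height-field-like patch.
#'
#' @param points coordinate matrix or [leaf_cloud()] with at least 3
#'   non-collinear points.
#' @param mu edge-length bound as a multiple of the local point spacing
#'   (default 3).
#' @param k_spacing number of neighbours used for the local spacing
#'   estimate (default 4).
#' @return An object of class `triangle_mesh`: list with `vertices`
#'   (`m x 3`) and `triangles` (`t x 3` vertex indices, 1-based).
#' @export
triangulate_surface <- function(points, mu = 3.0, k_spacing = 4L) {
  X <- as_coords(points)
  if (nrow(X) < 3L) stop("triangulation needs at least 3 points")
  if (mu <= 0) stop("`mu` must be positive")
  pl <- fit_plane_ls(X)
  # 2-D coordinates in the principal plane
  nrm <- pl$normal
  e1 <- if (abs(nrm[1]) < 0.9) cross3(nrm, c(1, 0, 0)) else cross3(nrm, c(0, 1, 0))
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- cross3(nrm, e1)
  Xc <- sweep(X, 2, pl$anchor)
  uv <- cbind(Xc %*% e1, Xc %*% e2)
  dup <- duplicated(uv)
  if (any(dup)) {
    X <- X[!dup, , drop = FALSE]
    uv <- uv[!dup, , drop = FALSE]
  }
  if (nrow(uv) < 3L) stop("triangulation needs at least 3 distinct points")
  tri <- cpp_delaunay(uv) + 1L
  if (nrow(tri) == 0L) stop("triangulation failed: points are collinear")
  # prune long and degenerate triangles
  spacing <- cpp_mean_knn_dist(X, min(as.integer(k_spacing), nrow(X) - 1L))
  A <- X[tri[, 1], , drop = FALSE]
  B <- X[tri[, 2], , drop = FALSE]
  C <- X[tri[, 3], , drop = FALSE]
  emax <- pmax(sqrt(rowSums((A - B)^2)),
               sqrt(rowSums((B - C)^2)),
               sqrt(rowSums((C - A)^2)))
  local_sp <- (spacing[tri[, 1]] + spacing[tri[, 2]] + spacing[tri[, 3]]) / 3
  area2 <- sqrt(rowSums(cross3_rows(B - A, C - A)^2))
  keep <- emax <= mu * local_sp & area2 > 1e-16
  tri <- tri[keep, , drop = FALSE]
  used <- sort(unique(as.integer(tri)))
  if (length(used) < nrow(X))
    message(nrow(X) - length(used),
            " point(s) left unreferenced by the triangulation")
  structure(list(vertices = X, triangles = tri), class = "triangle_mesh")
}

cross3_rows <- function(A, B) {
  cbind(A[, 2] * B[, 3] - A[, 3] * B[, 2],
        A[, 3] * B[, 1] - A[, 1] * B[, 3],
        A[, 1] * B[, 2] - A[, 2] * B[, 1])
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh: %d vertices, %d triangles, area %.6f m^2>\n",
              nrow(x$vertices), nrow(x$triangles), heron_area(x)))
  invisible(x)
}

#' Mesh surface area by Heron's formula
#'
#' For every triangle with side lengths `a`, `b`, `c` and half-perimeter
#' `p = (a + b + c) / 2`, the area is `sqrt(p (p-a) (p-b) (p-c))`; the mesh
#' area is the sum over triangles.  Tiny negative radicands from floating
#' point noise on near-degenerate triangles are clamped to zero.
#'
#' @param mesh a `triangle_mesh`.
#' @return Total surface area in square meters.
#' @export
heron_area <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (nrow(mesh$triangles) == 0L) return(0)
  V <- mesh$vertices
  tri <- mesh$triangles
  a <- sqrt(rowSums((V[tri[, 1], , drop = FALSE] -
                     V[tri[, 2], , drop = FALSE])^2))
  b <- sqrt(rowSums((V[tri[, 2], , drop = FALSE] -
                     V[tri[, 3], , drop = FALSE])^2))
  c <- sqrt(rowSums((V[tri[, 3], , drop = FALSE] -
                     V[tri[, 1], , drop = FALSE])^2))
  p <- (a + b + c) / 2
  sum(sqrt(pmax(p * (p - a) * (p - b) * (p - c), 0)))
}

#' Write a mesh as an ASCII PLY file
#' @param mesh a `triangle_mesh`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mesh_ply <- function(mesh, path) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  n <- nrow(mesh$vertices)
  t <- nrow(mesh$triangles)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", n),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", t),
               "property list uchar int vertex_indices",
               "end_header"), con)
  utils::write.table(mesh$vertices, con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, mesh$triangles - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
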