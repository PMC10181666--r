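#' Base and tip of a leaf point cloud
#'
#' The two mutually farthest points of the cloud are taken as the leaf base
#' `P` and tip `Q` (which is which is irrelevant for the midrib walk).
#' Distance ties are broken by the lexicographically smallest ordered
#' coordinate pair, so the result is deterministic.
#'
#' @param points coordinate matrix or [leaf_cloud()] with at least 2 points.
#' @return List with 3-vectors `P` and `Q` and their row indices `i`, `j`.
#' @export
find_base_tip <- function(points) {
  X <- as_coords(points)
  if (nrow(X) < 2L) stop("need at least 2 points")
  ij <- cpp_farthest_pair(X) + 1L
  list(P = X[ij[1], ], Q = X[ij[2], ], i = ij[1], j = ij[2])
}

#' Greedy midrib walk between two points of a cloud
#'
#' Starting from `start`, the walk repeatedly looks at the `k` nearest
#' not-yet-visited points of the current base point and moves to the one
#' minimising `D = ||n - b|| + ||n - end||`; the chosen point is removed
#' from the candidate cloud (the endpoint never is), and the walk stops
#' when it reaches `end`.  The visited sequence approximates the midrib
#' between a leaf's base and tip.
#'
#' @param points coordinate matrix or [leaf_cloud()].
#' @param start,end 3-vectors; must be members of `points` (within 1e-9 m).
#' @param k neighbourhood size of the walk (default 8).
#' @return An object of class `midrib_path`: list with `points` (ordered
#'   path coordinates, first row `start`, last row `end`) and `index` (row
#'   indices into the input).
#' @export
midrib_path <- function(points, start, end, k = 8L) {
  X <- as_coords(points)
  k <- as.integer(k)
  if (k < 1L) stop("`k` must be >= 1")
  si <- match_point(X, start)
  ei <- match_point(X, end)
  if (is.na(si)) stop("`start` is not a member of the cloud")
  if (is.na(ei)) stop("`end` is not a member of the cloud")
  idx <- cpp_midrib_walk(X, si - 1L, ei - 1L, k) + 1L
  structure(list(points = X[idx, , drop = FALSE], index = idx),
            class = "midrib_path")
}

match_point <- function(X, p, tol = 1e-9) {
  d2 <- colSums((t(X) - as.numeric(p))^2)
  i <- which.min(d2)
  if (d2[i] <= tol^2) i else NA_integer_
}

#' @export
print.midrib_path <- function(x, ...) {
  cat(sprintf("<midrib_path: %d points, length %.4f m>\n",
              nrow(x$points), path_length(x$points)))
  invisible(x)
}

path_length <- function(P) {
  if (nrow(P) < 2L) return(0)
  sum(sqrt(rowSums(diff(P)^2)))
}

#' Leaf length from a midrib path
#'
#' Projects the path points orthogonally onto the midrib projection plane
#' (keeping their order) and sums the consecutive projected distances.
#'
#' @param path a `midrib_path`.
#' @param s_vein the projection plane from [build_svein()].
#' @return Leaf length in meters.
#' @export
leaf_length <- function(path, s_vein) {
  stopifnot(inherits(path, "midrib_path"), inherits(s_vein, "fitted_plane"))
  path_length(project_plane(path$points, s_vein))
}

#' Leaf width via the half-width midrib walk
#'
#' `M` is the leaf point farthest from the midrib projection plane (a
#' boundary point of the widest cross section).  The fitted midrib is the
#' walk path projected onto that plane; `L` is its point nearest to `M`,
#' and the walk restarts from `M` towards the cloud point backing `L`.
#' The walk polyline, terminated on the fitted midrib, is projected onto
#' the cross-section plane `S` (through `M`, normal
#' `unit(n_leaf x n_vein)`); the leaf width is twice the projected path
#' length (the half-width).
#'
#' @param points the single-leaf cloud (matrix or [leaf_cloud()]).
#' @param midrib the leaf's `midrib_path`.
#' @param s_leaf,s_vein the fitted leaf plane and midrib projection plane.
#' @param k walk neighbourhood size (default 8).
#' @return Leaf width in meters.
#' @export
leaf_width <- function(points, midrib, s_leaf, s_vein, k = 8L) {
  stopifnot(inherits(midrib, "midrib_path"),
            inherits(s_leaf, "fitted_plane"),
            inherits(s_vein, "fitted_plane"))
  X <- as_coords(points)
  d <- abs(plane_distance(X, s_vein))
  M <- X[which.max(d), ]
  rib_fit <- project_plane(midrib$points, s_vein)   # fitted midrib
  j <- which.min(colSums((t(rib_fit) - M)^2))
  L <- midrib$points[j, ]          # cloud point backing the fitted point
  n_s <- cross3(s_leaf$normal, s_vein$normal)
  if (sqrt(sum(n_s^2)) < 1e-12)
    stop("degenerate geometry: leaf and vein planes are parallel")
  s_cross <- plane(n_s, M)
  if (sum((M - L)^2) == 0) return(0)
  half <- midrib_path(X, M, L, k = k)
  pts <- half$points
  # signed distance to the midrib plane, positive on M's side; the
  # half-width polyline ends where the walk reaches that plane
  sgn0 <- sign(plane_distance(rbind(M), s_vein))
  sd <- plane_distance(pts, s_vein) * sgn0
  if (sd[1] <= 0) return(0)              # M already on the midrib plane
  ci <- which(sd <= 0)[1]
  if (!is.na(ci)) {
    f <- sd[ci - 1] / (sd[ci - 1] - sd[ci])
    crossing <- pts[ci - 1, ] + f * (pts[ci, ] - pts[ci - 1, ])
    pts <- rbind(pts[seq_len(ci - 1), , drop = FALSE], crossing)
  } else {
    pts <- rbind(pts, rib_fit[j, ])      # walk stayed on M's side
  }
  2 * path_length(project_plane(pts, s_cross))
}
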