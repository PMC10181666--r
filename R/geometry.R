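#' Total least-squares plane fit
#'
#' Fits the plane minimising the sum of squared orthogonal distances to the
#' points (via the eigen-decomposition of the coordinate covariance; the
#' normal is the eigenvector of the smallest eigenvalue).  The normal sign
#' is fixed to a non-negative z component so the inclination angle against
#' the zenith is well defined; for exactly vertical planes the sign is fixed
#' by the largest-magnitude component instead.
#'
#' @param points an `n x 3` coordinate matrix or a [leaf_cloud()].
#' @return An object of class `fitted_plane`: list with `normal` (unit
#'   3-vector) and `anchor` (the centroid, a point on the plane).
#' @export
fit_plane_ls <- function(points) {
  X <- as_coords(points)
  if (nrow(X) < 3L) stop("plane fit needs at least 3 points")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  e <- eigen(crossprod(Xc), symmetric = TRUE)
  # eigenvalues descending: [3] = out-of-plane, [2] must be non-degenerate
  if (e$values[2] <= max(e$values[1], 1) * 1e-12)
    stop("degenerate input: points are collinear or coincident")
  nrm <- e$vectors[, 3]
  nrm <- fix_normal_sign(nrm)
  structure(list(normal = nrm, anchor = ctr), class = "fitted_plane")
}

fix_normal_sign <- function(nrm) {
  if (abs(nrm[3]) > 1e-12) {
    if (nrm[3] < 0) nrm <- -nrm
  } else if (nrm[which.max(abs(nrm))] < 0) {
    nrm <- -nrm
  }
  nrm
}

#' Construct a plane from a normal and an anchor point
#' @param normal 3-vector (normalized internally).
#' @param anchor 3-vector on the plane.
#' @return A `fitted_plane`.
#' @export
plane <- function(normal, anchor = c(0, 0, 0)) {
  nn <- sqrt(sum(normal^2))
  if (nn <= 0) stop("zero-length normal")
  structure(list(normal = normal / nn, anchor = as.numeric(anchor)),
            class = "fitted_plane")
}

#' @export
print.fitted_plane <- function(x, ...) {
  cat(sprintf("<plane: normal (%.4f, %.4f, %.4f), anchor (%.4f, %.4f, %.4f)>\n",
              x$normal[1], x$normal[2], x$normal[3],
              x$anchor[1], x$anchor[2], x$anchor[3]))
  invisible(x)
}

#' Signed distances of points to a plane
#' @param points coordinate matrix or [leaf_cloud()].
#' @param plane a `fitted_plane`.
#' @return Numeric vector of signed orthogonal distances (meters).
#' @export
plane_distance <- function(points, plane) {
  X <- as_coords(points)
  drop(sweep(X, 2, plane$anchor) %*% plane$normal)
}

#' Orthogonal projection of points onto a plane
#' @inheritParams plane_distance
#' @return Matrix of projected coordinates.
#' @export
project_plane <- function(points, plane) {
  X <- as_coords(points)
  d <- plane_distance(X, plane)
  X - outer(d, plane$normal)
}

#' Leaf inclination angle from a fitted plane
#'
#' The angle between the leaf plane's normal (approximating the ventral
#' normal) and the zenith axis z, folded into \[0, 90\] degrees:
#' `acos(|n . z|)`.
#'
#' @param plane a `fitted_plane` (e.g. from [fit_plane_ls()]).
#' @return Inclination in degrees, in \[0, 90\].
#' @export
leaf_inclination <- function(plane) {
  stopifnot(inherits(plane, "fitted_plane"))
  acos(min(1, abs(plane$normal[3]))) * 180 / pi
}

#' Midrib projection plane through the base and tip points
#'
#' The plane that contains the base point `P` and tip point `Q` and is
#' perpendicular to the leaf plane: its normal is `unit((Q - P) x r)` with
#' `r` the leaf-plane normal.
#'
#' @param P,Q base and tip points (3-vectors).
#' @param s_leaf the fitted leaf plane.
#' @return A `fitted_plane` anchored at `P`.
#' @export
build_svein <- function(P, Q, s_leaf) {
  stopifnot(inherits(s_leaf, "fitted_plane"))
  v <- as.numeric(Q) - as.numeric(P)
  if (sqrt(sum(v^2)) <= 0) stop("P and Q must differ")
  nrm <- cross3(v, s_leaf$normal)
  nn <- sqrt(sum(nrm^2))
  if (nn < 1e-12 * sqrt(sum(v^2)))
    stop("degenerate geometry: base-tip axis is parallel to the leaf normal")
  plane(nrm, as.numeric(P))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

as_coords <- function(points) {
  if (inherits(points, "leaf_cloud")) return(points$coords)
  X <- as.matrix(points)
  if (ncol(X) != 3L) stop("expected n x 3 coordinates")
  storage.mode(X) <- "double"
  X
}
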