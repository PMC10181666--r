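#' Statistical outlier removal
#'
#' Computes each point's mean distance to its `k` nearest neighbours and
#' discards points whose mean distance exceeds the global mean plus
#' `std_ratio` standard deviations of those per-point means.  Semantic and
#' instance labels are carried along.
#'
#' @param cloud a [leaf_cloud()].
#' @param k number of neighbours used for the per-point mean distance
#'   (default 16).
#' @param std_ratio threshold multiplier on the standard deviation
#'   (default 1.0).
#' @return The filtered [leaf_cloud()].
#' @export
remove_outliers <- function(cloud, k = 16L, std_ratio = 1.0) {
  stopifnot(inherits(cloud, "leaf_cloud"))
  k <- as.integer(k)
  if (k < 1L) stop("`k` must be a positive integer")
  if (std_ratio <= 0) stop("`std_ratio` must be positive")
  n <- n_points(cloud)
  if (n <= k) stop("need more than `k` = ", k, " points, got ", n)
  d <- cpp_mean_knn_dist(cloud$coords, k)
  # relative epsilon guards the exact-tie case (all means equal, sd ~ 0)
  keep <- d <= mean(d) + std_ratio * stats::sd(d) + 1e-12 * mean(d)
  cloud_subset(cloud, keep)
}

#' Voxel-grid thinning
#'
#' Partitions space into an axis-aligned cubic grid anchored at the
#' coordinate origin and keeps one point per occupied voxel: the centroid of
#' the voxel's points.  The semantic label is decided by majority vote
#' within the voxel (ties go to branch, 0); the instance id by majority
#' vote with ties going to the smallest id.
#'
#' @param cloud a [leaf_cloud()].
#' @param voxel voxel edge length in meters (default 0.003).
#' @return The thinned [leaf_cloud()].
#' @export
voxel_thin <- function(cloud, voxel = 0.003) {
  stopifnot(inherits(cloud, "leaf_cloud"))
  if (voxel <= 0) stop("`voxel` must be positive")
  X <- cloud$coords
  key <- paste(floor(X[, 1] / voxel), floor(X[, 2] / voxel),
               floor(X[, 3] / voxel))
  grp <- split(seq_len(nrow(X)), key)
  coords <- t(vapply(grp, function(ii) colMeans(X[ii, , drop = FALSE]),
                     numeric(3)))
  majority <- function(v, tie_min = FALSE) {
    tab <- table(v)
    top <- as.integer(names(tab)[tab == max(tab)])
    if (tie_min) min(top) else if (0L %in% top) 0L else top[1]
  }
  semantic <- if (!is.null(cloud$semantic))
    vapply(grp, function(ii) majority(cloud$semantic[ii]), integer(1))
  instance <- if (!is.null(cloud$instance))
    vapply(grp, function(ii) majority(cloud$instance[ii], tie_min = TRUE),
           integer(1))
  leaf_cloud(coords, semantic = semantic, instance = instance)
}

#' Farthest point sampling
#'
#' Subsamples a cloud to `m` points: a seeded random start point, then
#' iteratively the point maximising its minimum distance to the already
#' selected set.  If the cloud has fewer than `m` points it is returned
#' unchanged with a warning.
#'
#' @param cloud a [leaf_cloud()].
#' @param m target point count (default 2048).
#' @param seed integer seed selecting the start point.
#' @return A [leaf_cloud()] with `min(m, n)` points; labels carried along.
#' @export
farthest_point_sample <- function(cloud, m = 2048L, seed = 1L) {
  stopifnot(inherits(cloud, "leaf_cloud"))
  m <- as.integer(m)
  if (m < 1L) stop("`m` must be a positive integer")
  n <- n_points(cloud)
  if (n <= m) {
    if (n < m)
      warning("cloud has ", n, " points, fewer than m = ", m,
              "; returned unchanged")
    return(cloud)
  }
  start <- local_seed(seed, sample.int(n, 1L))
  idx <- cpp_fps(cloud$coords, m, start - 1L) + 1L
  cloud_subset(cloud, idx)
}

# run `expr` under a fixed RNG seed without disturbing the caller's RNG
local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(as.integer(seed))
  expr
}

#' Normalize a cloud into a centered cube
#'
#' Translates the centroid to the origin and applies one isotropic scale so
#' the largest axis-aligned extent equals `cube_side`.  The inverse mapping
#' is recorded so measurements can be taken back in original meters.
#'
#' @param cloud a [leaf_cloud()] with at least 2 distinct points.
#' @param cube_side side length of the target cube in normalized units
#'   (default 2).
#' @return A list with elements `cloud` (the normalized [leaf_cloud()]) and
#'   `transform` (class `norm_transform`: `center`, a 3-vector in meters,
#'   and `scale`, original meters per normalized unit).
#' @seealso [denormalize_cloud()]
#' @export
normalize_cloud <- function(cloud, cube_side = 2.0) {
  stopifnot(inherits(cloud, "leaf_cloud"))
  if (cube_side <= 0) stop("`cube_side` must be positive")
  X <- cloud$coords
  center <- colMeans(X)
  extent <- max(apply(X, 2, function(v) diff(range(v))))
  if (extent <= 0)
    stop("degenerate cloud: all points coincide, cannot normalize")
  scale <- extent / cube_side
  out <- cloud
  out$coords <- sweep(X, 2, center) / scale
  t <- structure(list(center = center, scale = scale),
                 class = "norm_transform")
  list(cloud = out, transform = t)
}

#' Undo a cube normalization
#'
#' @param cloud a normalized [leaf_cloud()].
#' @param transform the `norm_transform` recorded by [normalize_cloud()].
#' @return The [leaf_cloud()] in original coordinates (meters).
#' @export
denormalize_cloud <- function(cloud, transform) {
  stopifnot(inherits(cloud, "leaf_cloud"),
            inherits(transform, "norm_transform"))
  out <- cloud
  out$coords <- sweep(cloud$coords * transform$scale, 2, transform$center,
                      "+")
  out
}

#' @export
print.norm_transform <- function(x, ...) {
  cat(sprintf("<norm_transform: center (%.4f, %.4f, %.4f) m, scale %.6f m/unit>\n",
              x$center[1], x$center[2], x$center[3], x$scale))
  invisible(x)
}
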