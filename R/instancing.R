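#' Single-leaf instance segmentation by mean-shift clustering
#'
#' Partitions the leaf points of a branch cloud into single-leaf instances
#' with flat-kernel mean shift: seeds iterate to the centroid of the points
#' within `radius` until they converge on local density modes; modes closer
#' than `radius` are merged (the mode with more supporting points wins,
#' ties go to the lexicographically smaller center); every point is then
#' assigned to its nearest surviving mode.  No cluster count is required —
#' the bandwidth `radius` plays the role of the expected circumscribed
#' sphere radius of one leaf (35–55 mm for pear leaves, 45 mm balanced).
#'
#' Clusters with fewer than `min_points` members are dissolved and their
#' points reassigned to the nearest surviving center, so small fragments
#' from occlusion do not spawn spurious instances.
#'
#' Seeding is deterministic: either one seed per occupied cell of a grid of
#' size `radius` anchored at the cloud's minimum corner (`bin_seeding =
#' TRUE`, the default — translation-equivariant and fast), or every point
#' (`bin_seeding = FALSE`).
#'
#' @param cloud a [leaf_cloud()]; when semantic labels are present only the
#'   leaf points (label 1) are clustered.
#' @param radius clustering bandwidth in meters (default 0.045).
#' @param min_points minimum cluster size before dissolution (default 10).
#' @param max_iter maximum mean-shift iterations per seed (default 300).
#' @param tol convergence tolerance on mode displacement in meters
#'   (default 1e-4).
#' @param bin_seeding seed from a `radius`-sized grid (default) instead of
#'   from every point.
#' @return An object of class `instance_result`: list with `instance`
#'   (0-based id per clustered point), `centers` (k x 3 matrix of modes),
#'   `radius`, and `cloud` (the clustered points with instance ids set).
#' @export
mean_shift_segment <- function(cloud, radius = 0.045, min_points = 10L,
                               max_iter = 300L, tol = 1e-4,
                               bin_seeding = TRUE) {
  stopifnot(inherits(cloud, "leaf_cloud"))
  if (radius <= 0) stop("`radius` must be positive")
  pts <- if (!is.null(cloud$semantic)) leaf_points(cloud) else cloud
  X <- pts$coords
  n <- nrow(X)
  if (n < 1L) stop("no leaf points to segment")

  # --- seeds -------------------------------------------------------------
  if (bin_seeding && n > 1L) {
    lo <- apply(X, 2, min)           # min-corner anchor: translation-equivariant
    key <- paste(floor((X[, 1] - lo[1]) / radius),
                 floor((X[, 2] - lo[2]) / radius),
                 floor((X[, 3] - lo[3]) / radius))
    grp <- split(seq_len(n), key)
    seeds <- t(vapply(grp, function(ii) colMeans(X[ii, , drop = FALSE]),
                      numeric(3)))
  } else {
    seeds <- X
  }

  # --- iterate to modes, merge -------------------------------------------
  modes <- cpp_mean_shift(X, seeds, radius, as.integer(max_iter), tol)
  ok <- stats::complete.cases(modes)
  modes <- modes[ok, , drop = FALSE]
  if (nrow(modes) == 0L) stop("mean shift produced no modes")
  support <- cpp_radius_count(X, modes, radius)
  ord <- order(-support, modes[, 1], modes[, 2], modes[, 3])
  modes <- modes[ord, , drop = FALSE]
  keep <- integer(0)
  for (i in seq_len(nrow(modes))) {
    if (length(keep) == 0L) { keep <- i; next }
    d2 <- colSums((t(modes[keep, , drop = FALSE]) - modes[i, ])^2)
    if (min(d2) >= radius^2) keep <- c(keep, i)
  }
  centers <- modes[keep, , drop = FALSE]

  # --- assign, dissolve micro-clusters -----------------------------------
  assign_ids <- function(centers) cpp_nn1(centers, X) + 1L
  lab <- assign_ids(centers)
  repeat {
    cnt <- tabulate(lab, nbins = nrow(centers))
    small <- which(cnt < min_points)
    if (length(small) == 0L || length(small) == nrow(centers)) break
    drop1 <- small[which.min(cnt[small])]
    centers <- centers[-drop1, , drop = FALSE]
    lab <- assign_ids(centers)
  }
  # relabel contiguously from 0 by support (descending), then lexicographic
  cnt <- tabulate(lab, nbins = nrow(centers))
  ord <- order(-cnt, centers[, 1], centers[, 2], centers[, 3])
  centers <- centers[ord, , drop = FALSE]
  lab <- match(lab, ord) - 1L

  out_cloud <- pts
  out_cloud$instance <- as.integer(lab)
  structure(list(instance = as.integer(lab), centers = centers,
                 radius = radius, cloud = out_cloud),
            class = "instance_result")
}

#' @export
print.instance_result <- function(x, ...) {
  cat(sprintf("<instance_result: %d points, %d instances, radius %.0f mm>\n",
              length(x$instance), nrow(x$centers), 1000 * x$radius))
  cnt <- tabulate(x$instance + 1L, nbins = nrow(x$centers))
  cat("  points per instance: ", paste(cnt, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Attach instance ids from a segmentation back onto a full branch cloud
#'
#' Branch points (semantic 0) get instance id -1; leaf points receive the
#' ids from `result` (which must have been computed from this cloud's leaf
#' subset, in order).
#'
#' @param cloud the full [leaf_cloud()] with semantic labels.
#' @param result an `instance_result` from [mean_shift_segment()].
#' @return The full [leaf_cloud()] with the instance column set.
#' @export
apply_instances <- function(cloud, result) {
  stopifnot(inherits(cloud, "leaf_cloud"),
            inherits(result, "instance_result"))
  if (is.null(cloud$semantic)) stop("cloud has no semantic labels")
  ii <- which(cloud$semantic == 1L)
  if (length(ii) != length(result$instance))
    stop("segmentation does not match this cloud's leaf subset")
  inst <- rep(-1L, n_points(cloud))
  inst[ii] <- result$instance
  cloud$instance <- inst
  cloud
}
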