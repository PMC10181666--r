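#' Labeled point cloud
#'
#' The universal container of the pipeline: an `n x 3` coordinate matrix in
#' meters, optionally carrying a binary semantic label per point (0 = branch,
#' 1 = leaf) and an integer instance id per point (-1 for branch or
#' unassigned points, 0, 1, 2, ... for individual leaves).
#'
#' @param coords numeric `n x 3` matrix of x, y, z coordinates in meters.
#' @param semantic optional integer vector of length `n` with values in
#'   \{0, 1\}: 0 = branch point, 1 = leaf point.
#' @param instance optional integer vector of length `n`; -1 marks branch or
#'   unassigned points, non-negative ids mark leaf instances.
#' @return An object of class `leaf_cloud`: a list with elements `coords`,
#'   `semantic` and `instance`.
#' @examples
#' cl <- leaf_cloud(matrix(rnorm(30), ncol = 3))
#' cl
#' @export
leaf_cloud <- function(coords, semantic = NULL, instance = NULL) {
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || ncol(coords) != 3L)
    stop("`coords` must be a numeric n x 3 matrix")
  if (nrow(coords) < 1L) stop("a leaf_cloud needs at least one point")
  if (!all(is.finite(coords))) stop("`coords` must be finite")
  storage.mode(coords) <- "double"
  dimnames(coords) <- NULL
  n <- nrow(coords)
  if (!is.null(semantic)) {
    semantic <- as.integer(semantic)
    if (length(semantic) != n)
      stop("`semantic` must have one value per point")
    if (!all(semantic %in% c(0L, 1L)))
      stop("`semantic` labels must be 0 (branch) or 1 (leaf)")
  }
  if (!is.null(instance)) {
    instance <- as.integer(instance)
    if (length(instance) != n)
      stop("`instance` must have one value per point")
    if (any(instance < -1L))
      stop("`instance` ids must be >= -1")
  }
  structure(list(coords = coords, semantic = semantic, instance = instance),
            class = "leaf_cloud")
}

#' Number of points in a cloud
#' @param cloud a [leaf_cloud()].
#' @return Integer point count.
#' @export
n_points <- function(cloud) {
  stopifnot(inherits(cloud, "leaf_cloud"))
  nrow(cloud$coords)
}

#' Subset a cloud by point index
#'
#' Keeps coordinates and any labels aligned.
#'
#' @param cloud a [leaf_cloud()].
#' @param idx integer or logical index over points.
#' @return A [leaf_cloud()] with the selected points.
#' @export
cloud_subset <- function(cloud, idx) {
  stopifnot(inherits(cloud, "leaf_cloud"))
  leaf_cloud(cloud$coords[idx, , drop = FALSE],
             semantic = if (!is.null(cloud$semantic)) cloud$semantic[idx],
             instance = if (!is.null(cloud$instance)) cloud$instance[idx])
}

#' Leaf-labeled subset of a cloud
#' @param cloud a [leaf_cloud()] with semantic labels.
#' @return A [leaf_cloud()] containing only points with semantic label 1.
#' @export
leaf_points <- function(cloud) {
  stopifnot(inherits(cloud, "leaf_cloud"))
  if (is.null(cloud$semantic)) stop("cloud has no semantic labels")
  cloud_subset(cloud, cloud$semantic == 1L)
}

#' Remap instance ids to a contiguous 0-based range
#'
#' Branch/unassigned points (-1) are left untouched; leaf instance ids are
#' renumbered 0, 1, 2, ... in order of first appearance.
#'
#' @param cloud a [leaf_cloud()] with instance ids.
#' @return The cloud with compacted instance ids.
#' @export
compact_instances <- function(cloud) {
  stopifnot(inherits(cloud, "leaf_cloud"))
  if (is.null(cloud$instance)) return(cloud)
  inst <- cloud$instance
  pos <- inst >= 0L
  ids <- unique(inst[pos])
  inst[pos] <- match(inst[pos], ids) - 1L
  cloud$instance <- inst
  cloud
}

#' @export
print.leaf_cloud <- function(x, ...) {
  n <- nrow(x$coords)
  cat(sprintf("<leaf_cloud: %d points>\n", n))
  rng <- apply(x$coords, 2, range)
  cat(sprintf("  extent [m]: x %.4f..%.4f  y %.4f..%.4f  z %.4f..%.4f\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  if (!is.null(x$semantic))
    cat(sprintf("  semantic: %d branch, %d leaf\n",
                sum(x$semantic == 0L), sum(x$semantic == 1L)))
  if (!is.null(x$instance)) {
    k <- length(unique(x$instance[x$instance >= 0L]))
    cat(sprintf("  instances: %d leaf instance(s), %d unassigned point(s)\n",
                k, sum(x$instance < 0L)))
  }
  invisible(x)
}

#' @export
summary.leaf_cloud <- function(object, ...) {
  print(object)
  if (!is.null(object$instance)) {
    tab <- table(object$instance[object$instance >= 0L])
    if (length(tab)) {
      cat("  points per instance:\n")
      print(stats::setNames(as.integer(tab), names(tab)))
    }
  }
  invisible(object)
}
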