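#' Estimate the four phenotypic traits of a single leaf
#'
#' Runs the per-leaf estimation chain on one single-leaf point cloud (in
#' original, denormalized meters):
#' \enumerate{
#'   \item MLS smoothing ([mls_smooth()]);
#'   \item total-least-squares plane fit ([fit_plane_ls()]) and inclination
#'     angle against the zenith ([leaf_inclination()]);
#'   \item base/tip detection ([find_base_tip()]), greedy midrib walk
#'     ([midrib_path()]), projection plane ([build_svein()]) and leaf
#'     length ([leaf_length()]);
#'   \item half-width walk and leaf width ([leaf_width()]);
#'   \item surface triangulation ([triangulate_surface()]) and Heron area
#'     ([heron_area()]).
#' }
#'
#' @param points the single-leaf cloud (matrix or [leaf_cloud()]) with at
#'   least `min_points` points.
#' @param mls_radius MLS search radius in meters (default 0.012).
#' @param mls_order MLS polynomial order (default 2).
#' @param k midrib-walk neighbourhood size (default 8).
#' @param mu triangulation edge-length bound (default 3).
#' @param min_points minimum usable point count (default 30).
#' @param smooth apply MLS smoothing first (default TRUE).
#' @return A list of class `leaf_phenotype` with `inclination_deg`,
#'   `length_cm`, `width_cm`, `area_cm2` and `n_points`.
#' @export
estimate_phenotype <- function(points, mls_radius = 0.012, mls_order = 2L,
                               k = 8L, mu = 3.0, min_points = 30L,
                               smooth = TRUE) {
  X <- as_coords(points)
  if (nrow(X) < min_points)
    stop("leaf has ", nrow(X), " points, fewer than the minimum ",
         min_points)
  if (smooth)
    X <- suppressWarnings(mls_smooth(X, search_radius = mls_radius,
                                     poly_order = mls_order))
  s_leaf <- fit_plane_ls(X)
  incl <- leaf_inclination(s_leaf)
  bt <- find_base_tip(X)
  rib <- midrib_path(X, bt$P, bt$Q, k = k)
  s_vein <- build_svein(bt$P, bt$Q, s_leaf)
  len <- leaf_length(rib, s_vein)
  wid <- leaf_width(X, rib, s_leaf, s_vein, k = k)
  mesh <- suppressMessages(triangulate_surface(X, mu = mu))
  area <- heron_area(mesh)
  structure(list(inclination_deg = incl,
                 length_cm = 100 * len,
                 width_cm = 100 * wid,
                 area_cm2 = 1e4 * area,
                 n_points = nrow(X)),
            class = "leaf_phenotype")
}

#' @export
print.leaf_phenotype <- function(x, ...) {
  cat(sprintf(paste0("<leaf_phenotype: inclination %.1f deg, length %.2f cm, ",
                     "width %.2f cm, area %.2f cm^2 (%d points)>\n"),
              x$inclination_deg, x$length_cm, x$width_cm, x$area_cm2,
              x$n_points))
  invisible(x)
}

#' Estimate phenotypes for every leaf instance of a branch cloud
#'
#' Applies [estimate_phenotype()] to each leaf instance of an
#' instance-labeled cloud.  Per-leaf failures (degenerate geometry, too few
#' points) are recorded in the `status` column and do not stop the run.
#'
#' @param cloud a [leaf_cloud()] with instance ids (branch points -1).
#' @param ... passed on to [estimate_phenotype()].
#' @return A data frame of class `leaf_phenotypes` with one row per
#'   instance: `instance`, `inclination_deg`, `length_cm`, `width_cm`,
#'   `area_cm2`, `n_points`, `status` ("ok" or the error message).
#' @export
phenotype_leaves <- function(cloud, ...) {
  stopifnot(inherits(cloud, "leaf_cloud"))
  if (is.null(cloud$instance)) stop("cloud has no instance ids")
  ids <- sort(unique(cloud$instance[cloud$instance >= 0L]))
  rows <- lapply(ids, function(id) {
    sub <- cloud_subset(cloud, cloud$instance == id)
    res <- tryCatch(estimate_phenotype(sub, ...), error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(instance = id, inclination_deg = NA_real_,
                 length_cm = NA_real_, width_cm = NA_real_,
                 area_cm2 = NA_real_, n_points = n_points(sub),
                 status = paste0("error [instance ", id, "]: ",
                                 conditionMessage(res)))
    } else {
      data.frame(instance = id, inclination_deg = res$inclination_deg,
                 length_cm = res$length_cm, width_cm = res$width_cm,
                 area_cm2 = res$area_cm2, n_points = res$n_points,
                 status = "ok")
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("leaf_phenotypes", "data.frame")
  out
}

#' @export
print.leaf_phenotypes <- function(x, digits = 2, ...) {
  cat(sprintf("Leaf phenotypes: %d instance(s), %d ok\n",
              nrow(x), sum(x$status == "ok")))
  print.data.frame(x, digits = digits, ...)
  invisible(x)
}

#' @export
summary.leaf_phenotypes <- function(object, ...) {
  ok <- object[object$status == "ok", , drop = FALSE]
  cat(sprintf("Leaf phenotypes: %d instance(s), %d ok\n",
              nrow(object), nrow(ok)))
  if (nrow(ok)) {
    for (v in c("inclination_deg", "length_cm", "width_cm", "area_cm2"))
      cat(sprintf("  %-15s min %7.2f  mean %7.2f  max %7.2f\n", v,
                  min(ok[[v]]), mean(ok[[v]]), max(ok[[v]])))
  }
  invisible(object)
}
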