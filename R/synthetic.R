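#' Specification of a synthetic leaf
#'
#' A leaf is modelled in a local frame as a quadratic Bezier midrib in the
#' x-z plane (base at the origin, tip at `(chord, 0, 0)`, drooping control
#' point at mid-chord) with a smooth lateral width profile
#' `halfwidth(s) = (width / 2) * sin(pi * s^r)^width_power`, zero at both
#' ends and maximal (`width / 2`) at arc position `width_peak`
#' (`r = log(0.5) / log(width_peak)`).  The two lamina halves can be folded
#' about the midrib by a dihedral `fold_angle`.  The leaf is then posed by
#' a rotation (inclination about a horizontal axis, then azimuth about z)
#' and a translation.
#'
#' Ground truth recorded with every generated leaf: midrib arc length
#' (leaf length, adaptive quadrature), `width` (twice the maximal
#' half-width, exact), surface area (2-D quadrature over the parametric
#' surface), and inclination (angle between the posed normal of the
#' unfolded least-squares leaf plane and the zenith).
#'
#' @param chord base-to-tip chord of the midrib in meters (default 0.08).
#' @param width maximal leaf width in meters (default 0.04).
#' @param droop height of the Bezier control point as a fraction of the
#'   chord (default 0.06); 0 gives a straight midrib.
#' @param width_peak arc position of the widest cross section in (0, 1)
#'   (default 0.45).
#' @param width_power exponent shaping the width profile (default 1).
#' @param profile width-profile family: `"sinpow"` (default, ovate
#'   pear-leaf silhouettes) or `"ellipse"` (semi-elliptic half-width, so a
#'   flat straight-midrib leaf is an exact ellipse with area
#'   `pi * chord/2 * width/2`).
#' @param fold_angle dihedral fold about the midrib in degrees (default 0).
#' @param inclination,azimuth pose angles in degrees: rotation about the
#'   x axis by `inclination`, then about z by `azimuth`.
#' @param offset translation applied after rotation (3-vector, meters).
#' @param density sampling density in points per cm^2 (default 11,
#'   mirroring a 3-mm grid).
#' @param noise_sigma isotropic Gaussian jitter added to the sampled
#'   points, meters (default 0).
#' @param dropout fraction of the leaf removed as a random spherical cap
#'   in \[0, 1) (default 0).
#' @return An object of class `leaf_spec`.
#' @export
leaf_spec <- function(chord = 0.08, width = 0.04, droop = 0.06,
                      width_peak = 0.45, width_power = 1,
                      profile = c("sinpow", "ellipse"),
                      fold_angle = 0, inclination = 0, azimuth = 0,
                      offset = c(0, 0, 0), density = 11,
                      noise_sigma = 0, dropout = 0) {
  stopifnot(chord > 0, width > 0, droop >= 0,
            width_peak > 0, width_peak < 1, width_power > 0,
            density > 0, noise_sigma >= 0)
  if (dropout < 0 || dropout >= 1) stop("`dropout` must be in [0, 1)")
  structure(list(chord = chord, width = width, droop = droop,
                 width_peak = width_peak, width_power = width_power,
                 profile = match.arg(profile),
                 fold_angle = fold_angle, inclination = inclination,
                 azimuth = azimuth, offset = as.numeric(offset),
                 density = density, noise_sigma = noise_sigma,
                 dropout = dropout),
            class = "leaf_spec")
}

# quadratic Bezier midrib and its derivative in the local x-z plane
bezier_point <- function(spec, s) {
  h <- spec$droop * spec$chord
  cbind((1 - s)^2 * 0 + 2 * s * (1 - s) * (spec$chord / 2) + s^2 * spec$chord,
        0,
        2 * s * (1 - s) * h)
}

bezier_deriv <- function(spec, s) {
  h <- spec$droop * spec$chord
  cbind(2 * (1 - s) * (spec$chord / 2) + 2 * s * (spec$chord / 2),
        0,
        (2 - 4 * s) * h)
}

halfwidth_profile <- function(spec, s) {
  s <- pmin(pmax(s, 0), 1)
  if (identical(spec$profile, "ellipse"))
    return((spec$width / 2) * sqrt(pmax(1 - (2 * s - 1)^2, 0)))
  r <- log(0.5) / log(spec$width_peak)
  (spec$width / 2) * sin(pi * s^r)^spec$width_power
}

#' Midrib arc length of a leaf specification
#' @param spec a [leaf_spec()].
#' @return Arc length in meters (adaptive quadrature).
#' @export
midrib_arc_length <- function(spec) {
  stats::integrate(function(s) sqrt(rowSums(bezier_deriv(spec, s)^2)),
                   0, 1, rel.tol = 1e-10)$value
}

# map (s, t) parameter pairs, t in [-1, 1], to local 3-D surface points
leaf_surface_local <- function(spec, s, t) {
  B <- bezier_point(spec, s)
  hw <- halfwidth_profile(spec, s)
  if (spec$fold_angle == 0)
    return(B + cbind(0, t * hw, 0))
  phi <- spec$fold_angle * pi / 180 / 2
  Tg <- bezier_deriv(spec, s)
  Tg <- Tg / sqrt(rowSums(Tg^2))
  # up(s) = tangent x lateral, stays in the x-z plane
  up <- cbind(-Tg[, 3], 0, Tg[, 1])
  lat <- cbind(0, sign(t) * cos(phi), 0) + sin(phi) * up
  B + abs(t) * hw * lat
}

rot_x <- function(a) {
  a <- a * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}

rot_z <- function(a) {
  a <- a * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

pose_matrix <- function(spec) rot_z(spec$azimuth) %*% rot_x(spec$inclination)

pose_points <- function(spec, X) {
  sweep(X %*% t(pose_matrix(spec)), 2, spec$offset, "+")
}

#' Quadrature surface area of a leaf specification
#'
#' Midpoint-rule quadrature of the parametric surface-area element over the
#' (arc position, lateral) parameter grid; the recorded oracle truth for
#' the leaf area.  Doubling `ns`/`nt` changes the value by well under 0.1%
#' at the defaults.
#'
#' @param spec a [leaf_spec()].
#' @param ns,nt quadrature resolution along and across the midrib
#'   (defaults 600 and 40).
#' @return Surface area in square meters.
#' @export
leaf_surface_area <- function(spec, ns = 600L, nt = 40L) {
  s <- (seq_len(ns) - 0.5) / ns
  ds <- 1 / ns
  dt <- 1 / nt                       # per half, t in [0, 1]
  area <- 0
  for (side in c(-1, 1)) {
    t <- side * (seq_len(nt) - 0.5) / nt
    for (j in seq_len(nt)) {
      P0 <- leaf_surface_local(spec, s, rep(t[j], ns))
      Ps <- leaf_surface_local(spec, s + ds / 2, rep(t[j], ns)) -
            leaf_surface_local(spec, s - ds / 2, rep(t[j], ns))
      Pt <- leaf_surface_local(spec, s, rep(t[j] + side * dt / 2, ns)) -
            leaf_surface_local(spec, s, rep(t[j] - side * dt / 2, ns))
      cr <- cross3_rows(Ps / ds, Pt / (side * dt))
      area <- area + sum(sqrt(rowSums(cr^2))) * ds * dt
    }
  }
  area
}

# truth inclination: posed normal of the unfolded least-squares leaf plane
leaf_true_inclination <- function(spec) {
  flat <- spec
  flat$fold_angle <- 0
  s <- seq(0.01, 0.99, length.out = 60)
  grid <- expand.grid(s = s, t = seq(-1, 1, length.out = 21))
  X <- leaf_surface_local(flat, grid$s, grid$t)
  ctr <- colMeans(X)
  e <- eigen(crossprod(sweep(X, 2, ctr)), symmetric = TRUE)
  nrm <- pose_matrix(spec) %*% e$vectors[, 3]
  acos(min(1, abs(nrm[3]))) * 180 / pi
}

#' Generate a synthetic single-leaf point cloud with ground truth
#'
#' Samples the leaf surface on an arc-length-stratified grid at the
#' `leaf_spec` density, with jitter inside each cell; the silhouette boundary (the two
#' lamina edges, base and tip) is sampled explicitly so the physical leaf
#' margin is present, as it is in a real scan.  Gaussian noise and the
#' spherical-cap dropout of the `leaf_spec` are then applied.
#'
#' @param spec a [leaf_spec()].
#' @param seed integer seed for the sampling jitter, noise and dropout.
#' @return A list with `cloud` (a [leaf_cloud()], semantic all 1) and
#'   `truth` (list: `inclination_deg`, `length_cm`, `width_cm`, `area_cm2`,
#'   `centroid`).
#' @export
make_leaf <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "leaf_spec"))
  local_seed(seed, {
    delta <- 0.01 / sqrt(spec$density)          # target spacing in meters
    arc <- midrib_arc_length(spec)
    ns <- max(4L, ceiling(arc / delta))
    # invert the cumulative arc length for near-uniform s spacing
    sfine <- seq(0, 1, length.out = 512)
    cum <- c(0, cumsum(sqrt(rowSums(bezier_deriv(spec, sfine[-1] -
               diff(sfine) / 2)^2)) * diff(sfine)))
    s_rows <- stats::approx(cum / cum[length(cum)], sfine,
                            xout = seq(0, 1, length.out = ns + 1L))$y
    pts <- list()
    for (s in s_rows) {
      hw <- halfwidth_profile(spec, s)
      nt <- max(1L, round(2 * hw / delta))
      t <- if (nt == 1L) 0 else seq(-1, 1, length.out = nt)
      if (nt > 2L) {                     # jitter interior points only
        jit <- stats::runif(nt - 2L, -0.4, 0.4) * (2 / (nt - 1L))
        t[2:(nt - 1L)] <- pmin(pmax(t[2:(nt - 1L)] + jit, -1), 1)
      }
      pts[[length(pts) + 1L]] <- leaf_surface_local(spec, rep(s, nt), t)
    }
    X <- do.call(rbind, pts)
    if (nrow(X) < 30L)
      stop("sampling density too low: only ", nrow(X), " points generated")
    X <- pose_points(spec, X)
    if (spec$noise_sigma > 0)
      X <- X + matrix(stats::rnorm(length(X), 0, spec$noise_sigma),
                      ncol = 3)
    if (spec$dropout > 0) {
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      proj <- drop(X %*% u)
      ndrop <- ceiling(spec$dropout * nrow(X))
      X <- X[rank(-proj, ties.method = "first") > ndrop, , drop = FALSE]
    }
    truth <- list(inclination_deg = leaf_true_inclination(spec),
                  length_cm = 100 * arc,
                  width_cm = 100 * spec$width,
                  area_cm2 = 1e4 * leaf_surface_area(spec),
                  centroid = colMeans(X))
    list(cloud = leaf_cloud(X, semantic = rep(1L, nrow(X))), truth = truth)
  })
}

#' Specification of a synthetic branch with attached leaves
#'
#' The branch axis is a gently bowed curve along x; its surface is sampled
#' as a cylinder at 3-mm spacing.  Leaves are attached at spread-out
#' positions with randomized poses and sizes drawn from pear-scale ranges
#' (midrib chord such that leaf length falls in 4-12 cm, width 2-7 cm,
#' inclination 5-85 degrees), and placement is retried until all pairwise
#' leaf-centroid separations exceed `min_separation`.
#'
#' @param length branch length in meters (default 0.6; observed branches
#'   span 0.25-1.13 m).
#' @param radius branch cylinder radius in meters (default 0.004).
#' @param n_leaves number of leaves (default 14; observed range 8-26).
#' @param min_separation minimum pairwise leaf-centroid distance in meters
#'   (default 0).
#' @param max_retries placement retries before giving up (default 50).
#' @return An object of class `branch_spec`.
#' @export
branch_spec <- function(length = 0.6, radius = 0.004, n_leaves = 14L,
                        min_separation = 0, max_retries = 50L) {
  stopifnot(length > 0, radius > 0, n_leaves >= 0, min_separation >= 0)
  structure(list(length = length, radius = radius,
                 n_leaves = as.integer(n_leaves),
                 min_separation = min_separation,
                 max_retries = as.integer(max_retries)),
            class = "branch_spec")
}

# random pear-scale leaf spec (sizes in the observed trait ranges)
random_leaf_spec <- function() {
  chord <- stats::runif(1, 0.04, 0.11)
  width <- min(max(chord * stats::runif(1, 0.35, 0.65), 0.02), 0.07)
  leaf_spec(chord = chord, width = width,
            droop = stats::runif(1, 0.02, 0.08),
            width_peak = stats::runif(1, 0.35, 0.55),
            width_power = stats::runif(1, 0.8, 1.2),
            inclination = stats::runif(1, 5, 85),
            azimuth = stats::runif(1, 0, 360))
}

#' Generate a synthetic branch-with-leaves point cloud
#'
#' Branch points carry semantic label 0 and instance id -1; each leaf's
#' points carry semantic 1 and a unique instance id (0-based).  The
#' minimum pairwise leaf-centroid separation actually achieved is recorded
#' so tests can choose clustering radii relative to it.
#'
#' @param spec a [branch_spec()].
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return A list with `cloud` (labeled [leaf_cloud()]), `truth` (list of
#'   per-leaf ground-truth records, in instance-id order) and
#'   `min_separation` (meters; `Inf` with fewer than 2 leaves).
#' @export
make_branch <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "branch_spec"))
  local_seed(seed, {
    # --- branch cylinder ---------------------------------------------------
    sp <- 0.003
    nax <- max(2L, ceiling(spec$length / sp))
    u <- seq(0, 1, length.out = nax)
    axis <- cbind(u * spec$length, 0, 0.05 * spec$length * sin(pi * u))
    ncirc <- max(3L, ceiling(2 * pi * spec$radius / sp))
    th <- seq(0, 2 * pi, length.out = ncirc + 1L)[-1]
    ring <- cbind(0, cos(th), sin(th)) * spec$radius
    bX <- axis[rep(seq_len(nax), each = ncirc), ] +
      ring[rep(seq_len(ncirc), nax), ]
    # --- leaves with separation retries -----------------------------------
    for (try in seq_len(spec$max_retries)) {
      leaves <- vector("list", spec$n_leaves)
      ok <- TRUE
      if (spec$n_leaves > 0L) {
        upos <- (seq_len(spec$n_leaves) - stats::runif(spec$n_leaves, 0, 0.8)) /
          spec$n_leaves
        for (i in seq_len(spec$n_leaves)) {
          ls <- random_leaf_spec()
          # phyllotaxis-like layout: leaves alternate sides and point
          # outward from the axis, with jitter on the heading
          ls$azimuth <- 90 + 180 * (i %% 2L) + stats::runif(1, -30, 30)
          attach_pt <- c(upos[i] * spec$length, 0,
                         0.05 * spec$length * sin(pi * upos[i]))
          heading <- c(cos(ls$azimuth * pi / 180),
                       sin(ls$azimuth * pi / 180), 0)
          ls$offset <- attach_pt + heading * (spec$radius + 0.005)
          leaves[[i]] <- make_leaf(ls, seed = sample.int(2^30, 1))
        }
        ctrs <- t(vapply(leaves, function(l) l$truth$centroid, numeric(3)))
        minsep <- if (spec$n_leaves > 1L) min(stats::dist(ctrs)) else Inf
        if (minsep < spec$min_separation) ok <- FALSE
      } else minsep <- Inf
      if (ok) break
      if (try == spec$max_retries)
        stop("could not place ", spec$n_leaves,
             " leaves with pairwise separation >= ", spec$min_separation,
             " m in ", spec$max_retries, " attempts")
    }
    coords <- rbind(bX, do.call(rbind, lapply(leaves, function(l)
      l$cloud$coords)))
    semantic <- c(rep(0L, nrow(bX)), unlist(lapply(leaves, function(l)
      rep(1L, n_points(l$cloud)))))
    instance <- c(rep(-1L, nrow(bX)),
                  unlist(lapply(seq_along(leaves), function(i)
                    rep(i - 1L, n_points(leaves[[i]]$cloud)))))
    if (is.null(instance)) instance <- rep(-1L, nrow(bX))
    truth <- lapply(leaves, function(l) l$truth)
    list(cloud = leaf_cloud(coords, semantic = semantic,
                            instance = instance),
         truth = truth, min_separation = minsep)
  })
}

#' Perturb a cloud with noise and per-leaf dropout
#'
#' Adds isotropic Gaussian jitter to every point and, per leaf instance
#' (or over the whole cloud when no instance ids are present), removes a
#' seeded random spherical cap holding the stated fraction of the points.
#' Labels are preserved.
#'
#' @param cloud a [leaf_cloud()].
#' @param noise_sigma jitter standard deviation in meters (default 0).
#' @param dropout cap fraction in \[0, 1) (default 0).
#' @param seed integer seed.
#' @return The perturbed [leaf_cloud()].
#' @export
perturb_cloud <- function(cloud, noise_sigma = 0, dropout = 0, seed = 1L) {
  stopifnot(inherits(cloud, "leaf_cloud"))
  if (dropout < 0 || dropout >= 1) stop("`dropout` must be in [0, 1)")
  local_seed(seed, {
    X <- cloud$coords
    if (noise_sigma > 0)
      X <- X + matrix(stats::rnorm(length(X), 0, noise_sigma), ncol = 3)
    out <- cloud
    out$coords <- X
    if (dropout > 0) {
      groups <- if (!is.null(out$instance)) {
        ids <- unique(out$instance[out$instance >= 0L])
        lapply(ids, function(id) which(out$instance == id))
      } else list(seq_len(nrow(X)))
      drop_idx <- integer(0)
      for (g in groups) {
        u <- stats::rnorm(3)
        u <- u / sqrt(sum(u^2))
        proj <- drop(X[g, , drop = FALSE] %*% u)
        ndrop <- ceiling(dropout * length(g))
        drop_idx <- c(drop_idx,
                      g[rank(-proj, ties.method = "first") <= ndrop])
      }
      if (length(drop_idx))
        out <- cloud_subset(out, -drop_idx)
    }
    out
  })
}
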