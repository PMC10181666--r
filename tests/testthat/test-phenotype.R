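test_that("total-least-squares plane fit recovers known planes", {
  set.seed(1)
  flat <- cbind(runif(50), runif(50), 0)
  expect_equal(fit_plane_ls(flat)$normal, c(0, 0, 1), tolerance = 1e-12)

  tilted <- cbind(runif(50), runif(50), 0)
  tilted[, 3] <- -tilted[, 1]                 # x + z = 0
  expect_equal(abs(fit_plane_ls(tilted)$normal),
               c(1, 0, 1) / sqrt(2), tolerance = 1e-9)

  noisy <- cbind(runif(1000, 0, 0.1), runif(1000, 0, 0.1),
                 rnorm(1000, 0, 1e-3))
  ang <- acos(abs(fit_plane_ls(noisy)$normal[3])) * 180 / pi
  expect_lt(ang, 1)

  line <- cbind(1:10, 2 * (1:10), 3 * (1:10))
  expect_error(fit_plane_ls(line), "collinear|degenerate")
})

test_that("inclination is the folded angle between normal and zenith", {
  expect_equal(leaf_inclination(plane(c(0, 0, 1))), 0)
  expect_equal(leaf_inclination(plane(c(1, 0, 0))), 90)
  expect_equal(leaf_inclination(plane(c(1, 0, 1))), 45, tolerance = 1e-9)
  expect_equal(leaf_inclination(plane(c(0, 0, -1))), 0)  # sign-folded
})

test_that("the midrib projection plane holds P, Q and is perpendicular", {
  P <- c(0, 0, 0); Q <- c(1, 0, 0)
  s_leaf <- plane(c(0, 0, 1))
  sv <- build_svein(P, Q, s_leaf)
  expect_equal(abs(sv$normal), c(0, 1, 0), tolerance = 1e-12)
  expect_lt(abs(sum(sv$normal * s_leaf$normal)), 1e-9)
  expect_lt(max(abs(plane_distance(rbind(P, Q), sv))), 1e-9)

  # equivariance under a rigid rotation
  R <- rotation_matrix(c(1, 2, 3), 35)
  svr <- build_svein(drop(R %*% P), drop(R %*% Q),
                     plane(drop(R %*% c(0, 0, 1))))
  expect_equal(abs(svr$normal), abs(drop(R %*% sv$normal)),
               tolerance = 1e-9)

  expect_error(build_svein(c(0, 0, 0), c(0, 0, 1), plane(c(0, 0, 1))),
               "parallel|degenerate")
  expect_error(build_svein(P, P, s_leaf), "differ")
})

test_that("base/tip detection matches the exhaustive diameter oracle", {
  seg <- cbind(seq(0, 1, length.out = 20), 0, 0)
  bt <- find_base_tip(seg)
  expect_equal(sort(c(bt$P[1], bt$Q[1])), c(0, 1))

  # tie on the square: deterministic lexicographic diagonal
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  bt <- find_base_tip(sq)
  expect_equal(bt$P, c(0, 0, 0))
  expect_equal(bt$Q, c(1, 1, 0))

  set.seed(8)
  X <- matrix(rnorm(1500), ncol = 3)
  bt <- find_base_tip(X)
  ij <- oracle_farthest_pair(X)
  expect_equal(sqrt(sum((bt$P - bt$Q)^2)),
               sqrt(sum((X[ij[1], ] - X[ij[2], ])^2)))
})

test_that("the greedy midrib walk traverses lines and arcs", {
  line <- cbind(seq(0, 1, length.out = 11), 0, 0)
  p <- midrib_path(line, line[1, ], line[11, ], k = 3)
  expect_equal(nrow(p$points), 11L)
  expect_equal(p$points[, 1], seq(0, 1, length.out = 11))

  th <- seq(0, pi / 2, length.out = 300)
  arc <- cbind(cos(th), sin(th), 0) * 0.1
  p <- midrib_path(arc, arc[1, ], arc[300, ], k = 5)
  len <- sum(sqrt(rowSums(diff(p$points)^2)))
  expect_lt(abs(len - 0.1 * pi / 2) / (0.1 * pi / 2), 0.02)

  # degenerate: start equals end
  p0 <- midrib_path(line, line[4, ], line[4, ], k = 3)
  expect_equal(nrow(p0$points), 1L)

  expect_error(midrib_path(line, c(5, 5, 5), line[1, ], k = 3), "member")
})

test_that("leaf length is the projected midrib polyline length", {
  line <- cbind(seq(0, 0.1, length.out = 15), 0, 0)
  p <- midrib_path(line, line[1, ], line[15, ], k = 4)
  sv <- build_svein(line[1, ], line[15, ], plane(c(0, 0, 1)))
  expect_equal(leaf_length(p, sv), 0.1, tolerance = 1e-12)

  # out-of-plane zigzag shrinks under projection
  zig <- line
  set.seed(2)
  zig[, 2] <- rnorm(15, 0, 1e-3)       # lateral jitter, off S_vein
  pz <- structure(list(points = zig, index = seq_len(15)),
                  class = "midrib_path")
  raw <- sum(sqrt(rowSums(diff(zig)^2)))
  expect_lt(leaf_length(pz, sv), raw)

  # curved midrib: within 3% of the generator's analytic arc length
  sp <- leaf_spec(chord = 0.09, width = 0.045, droop = 0.08)
  lf <- make_leaf(sp, seed = 6)
  ph <- estimate_phenotype(lf$cloud)
  expect_lt(abs(ph$length_cm - lf$truth$length_cm) / lf$truth$length_cm,
            0.03)
})

test_that("leaf width recovers the widest cross section", {
  # flat symmetric elliptical leaf: width within 3% of the minor axis
  sp <- leaf_spec(chord = 0.10, width = 0.05, droop = 0,
                  profile = "ellipse")
  lf <- make_leaf(sp, seed = 4)
  ph <- estimate_phenotype(lf$cloud)
  expect_lt(abs(ph$width_cm - 5) / 5, 0.03)

  # folded leaf: projected half-width below the raw 3-D walk length
  spf <- leaf_spec(chord = 0.09, width = 0.05, droop = 0, fold_angle = 40)
  lff <- make_leaf(spf, seed = 5)
  X <- lff$cloud$coords
  s_leaf <- fit_plane_ls(X)
  bt <- find_base_tip(X)
  rib <- midrib_path(X, bt$P, bt$Q, k = 8)
  sv <- build_svein(bt$P, bt$Q, s_leaf)
  w <- leaf_width(X, rib, s_leaf, sv, k = 8)
  d <- abs(plane_distance(X, sv))
  M <- X[which.max(d), ]
  rib_fit <- project_plane(rib$points, sv)
  j <- which.min(colSums((t(rib_fit) - M)^2))
  raw <- midrib_path(X, M, rib$points[j, ], k = 8)
  # projection contracts: the projected half-width cannot exceed the 3-D
  # length of the walk polyline (plus its terminal midrib segment)
  raw_len <- sum(sqrt(rowSums(diff(raw$points)^2))) +
    sqrt(sum((rib$points[j, ] - rib_fit[j, ])^2))
  expect_lt(w / 2, raw_len)

  # degenerate flat strip: near-zero width
  strip <- cbind(seq(0, 0.1, length.out = 60), rnorm(60, 0, 1e-5), 0)
  s_leaf <- plane(c(0, 0, 1))
  bt <- find_base_tip(strip)
  rib <- midrib_path(strip, bt$P, bt$Q, k = 6)
  sv <- build_svein(bt$P, bt$Q, s_leaf)
  expect_lt(leaf_width(strip, rib, s_leaf, sv), 1e-3)
})

test_that("phenotypes are invariant to rigid motion and equivariant to scale", {
  sp <- leaf_spec(chord = 0.10, width = 0.05, droop = 0,
                  profile = "ellipse")
  lf <- make_leaf(sp, seed = 4)
  base <- estimate_phenotype(lf$cloud)
  expect_lt(base$inclination_deg, 1.5)
  expect_equal(base$length_cm, 10, tolerance = 0.03)
  expect_equal(base$width_cm, 5, tolerance = 0.03)
  expect_equal(base$area_cm2, pi * 5 * 2.5, tolerance = 0.02)

  # rotate 30 degrees about a horizontal axis: inclination follows,
  # intrinsic measures stay put
  sp30 <- sp; sp30$inclination <- 30
  rot <- estimate_phenotype(make_leaf(sp30, seed = 4)$cloud)
  expect_equal(rot$inclination_deg, 30, tolerance = 1)
  expect_equal(rot$length_cm, base$length_cm, tolerance = 0.005 * 10)
  expect_equal(rot$width_cm, base$width_cm, tolerance = 0.005 * 5)
  expect_equal(rot$area_cm2, base$area_cm2, tolerance = 0.005 * 40)

  # scale coordinates by s: lengths scale by s, area by s^2
  s <- 1.7
  scl <- lf$cloud
  scl$coords <- scl$coords * s
  ps <- estimate_phenotype(scl, mls_radius = 0.012 * s)
  expect_equal(ps$length_cm, s * base$length_cm,
               tolerance = 0.01 * s * base$length_cm)
  expect_equal(ps$width_cm, s * base$width_cm,
               tolerance = 0.01 * s * base$width_cm)
  expect_equal(ps$area_cm2, s^2 * base$area_cm2,
               tolerance = 0.01 * s^2 * base$area_cm2)

  # leaf length is never shorter than the base-tip chord (tolerance for
  # the projection step)
  chord <- 100 * sqrt(sum((find_base_tip(lf$cloud)$P -
                           find_base_tip(lf$cloud)$Q)^2))
  expect_gte(base$length_cm, chord - 0.05)
})

test_that("per-leaf failures carry the instance id and do not stop runs", {
  expect_error(estimate_phenotype(matrix(rnorm(27), 9, 3)), "fewer")

  br <- make_branch(branch_spec(length = 0.5, n_leaves = 6,
                                min_separation = 0.07), seed = 9)
  cl <- br$cloud
  # truncate one instance below the minimum point count
  idx <- which(cl$instance == 2L)
  cl <- cloud_subset(cl, -idx[-(1:10)])
  ph <- phenotype_leaves(cl)
  expect_s3_class(ph, "leaf_phenotypes")
  expect_equal(nrow(ph), 6L)
  bad <- ph[ph$instance == 2L, ]
  expect_match(bad$status, "instance 2")
  expect_true(all(ph$status[ph$instance != 2L] == "ok"))
})
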