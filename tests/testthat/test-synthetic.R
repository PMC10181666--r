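test_that("flat elliptical leaves carry closed-form ground truth", {
  sp <- leaf_spec(chord = 0.10, width = 0.05, droop = 0,
                  profile = "ellipse", inclination = 0)
  lf <- make_leaf(sp, seed = 1)
  expect_equal(lf$truth$inclination_deg, 0, tolerance = 1e-9)
  expect_equal(lf$truth$length_cm, 10, tolerance = 1e-9)
  expect_equal(lf$truth$width_cm, 5)
  expect_equal(lf$truth$area_cm2, pi * 5 * 2.5, tolerance = 1e-3 * pi * 12.5)
  expect_true(all(lf$cloud$semantic == 1L))
})

test_that("truth inclination follows the pose for unfolded leaves", {
  for (ang in c(5, 30, 60, 85)) {
    sp <- leaf_spec(chord = 0.08, width = 0.04, droop = 0,
                    inclination = ang, azimuth = 123)
    lf <- make_leaf(sp, seed = 2)
    expect_equal(lf$truth$inclination_deg, ang, tolerance = 1e-6)
  }
})

test_that("truth is spec-determined while samples follow the seed", {
  sp <- leaf_spec(chord = 0.07, width = 0.035, noise_sigma = 3e-4)
  a <- make_leaf(sp, seed = 10)
  b <- make_leaf(sp, seed = 11)
  expect_equal(a$truth[c("inclination_deg", "length_cm", "width_cm",
                         "area_cm2")],
               b$truth[c("inclination_deg", "length_cm", "width_cm",
                         "area_cm2")])
  expect_false(identical(a$cloud$coords, b$cloud$coords))
  a2 <- make_leaf(sp, seed = 10)
  expect_identical(a$cloud$coords, a2$cloud$coords)
})

test_that("the quadrature area oracle is converged", {
  sp <- leaf_spec(chord = 0.09, width = 0.05, droop = 0.07,
                  fold_angle = 25, width_peak = 0.4)
  a1 <- leaf_surface_area(sp)
  a2 <- leaf_surface_area(sp, ns = 1200, nt = 80)
  expect_lt(abs(a2 - a1) / a1, 0.001)
  # folding a straight-midrib leaf is isometric: area unchanged
  st <- leaf_spec(chord = 0.09, width = 0.05, droop = 0, fold_angle = 25,
                  width_peak = 0.4)
  st_flat <- leaf_spec(chord = 0.09, width = 0.05, droop = 0,
                       width_peak = 0.4)
  expect_equal(leaf_surface_area(st), leaf_surface_area(st_flat),
               tolerance = 1e-4 * leaf_surface_area(st_flat))
})

test_that("branches assemble labeled leaves with reported separation", {
  br <- make_branch(branch_spec(length = 1.0, n_leaves = 12,
                                min_separation = 0.095), seed = 11)
  cl <- br$cloud
  expect_length(br$truth, 12L)
  expect_gt(br$min_separation, 0.095)
  expect_setequal(unique(cl$instance[cl$semantic == 1L]), 0:11)
  expect_true(all(cl$instance[cl$semantic == 0L] == -1L))

  bare <- make_branch(branch_spec(length = 0.4, n_leaves = 0), seed = 1)
  expect_true(all(bare$cloud$semantic == 0L))
  expect_length(bare$truth, 0L)

  again <- make_branch(branch_spec(length = 1.0, n_leaves = 12,
                                   min_separation = 0.095), seed = 11)
  expect_identical(br$cloud$coords, again$cloud$coords)

  expect_error(make_branch(branch_spec(length = 0.2, n_leaves = 15,
                                       min_separation = 0.2,
                                       max_retries = 3), seed = 1),
               "could not place")
})

test_that("perturbation adds calibrated noise and per-leaf dropout", {
  cl <- leaf_cloud(matrix(0, 10000, 3))
  same <- perturb_cloud(cl, noise_sigma = 0, dropout = 0, seed = 5)
  expect_identical(same$coords, cl$coords)

  noisy <- perturb_cloud(cl, noise_sigma = 1e-3, seed = 5)
  expect_lt(abs(sd(noisy$coords) - 1e-3) / 1e-3, 0.05)

  br <- make_branch(branch_spec(length = 0.5, n_leaves = 5,
                                min_separation = 0.07), seed = 2)
  n2 <- sum(br$cloud$instance == 2L)
  dr <- perturb_cloud(br$cloud, dropout = 0.3, seed = 7)
  expect_equal(sum(dr$instance == 2L), n2 - ceiling(0.3 * n2))
  # branch points untouched by leaf dropout
  expect_equal(sum(dr$instance == -1L), sum(br$cloud$instance == -1L))

  expect_error(perturb_cloud(cl, dropout = 1), "dropout")
})
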