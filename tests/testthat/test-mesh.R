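test_that("MLS smoothing is exact on planes and denoises jitter", {
  set.seed(1)
  flat <- cbind(runif(600, 0, 0.06), runif(600, 0, 0.06), 0)
  out <- mls_smooth(flat, search_radius = 0.012, poly_order = 2)
  expect_lt(max(abs(out - flat)), 1e-9)

  noisy <- flat
  noisy[, 3] <- rnorm(600, 0, 1e-3)
  sm <- mls_smooth(noisy, search_radius = 0.010, poly_order = 2)
  expect_lt(sqrt(mean(sm[, 3]^2)), 0.5 * sqrt(mean(noisy[, 3]^2)))
  expect_equal(nrow(sm), nrow(noisy))

  # isolated points pass through untouched, with a warning
  sparse <- rbind(flat[1:20, ], c(10, 10, 10))
  expect_warning(out <- mls_smooth(sparse, search_radius = 0.012),
                 "unsmoothed")
  expect_equal(out[21, ], c(10, 10, 10))
})

test_that("triangulation covers planar patches and curved caps", {
  quad <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  mesh <- triangulate_surface(quad)
  expect_equal(nrow(mesh$triangles), 2L)
  expect_equal(heron_area(mesh), 1, tolerance = 1e-12)

  g <- as.matrix(expand.grid(x = 0:20 / 200, y = 0:10 / 200, z = 0))
  mg <- triangulate_surface(g)
  expect_equal(heron_area(mg), 0.1 * 0.05, tolerance = 0.01)

  # 60-degree spherical cap sampled with its rim: area = 2 pi R h.
  # Poisson sampling halves the mean NN spacing relative to the point
  # spacing, so the edge bound uses mu = 4 here.
  set.seed(2)
  R <- 0.05
  truth <- 2 * pi * R * (R - 0.5 * R)
  z <- runif(2000, 0.5, 1)
  th <- runif(2000, 0, 2 * pi)
  r <- sqrt(1 - z^2) * R
  nrim <- round(2 * pi * R * sqrt(0.75) / sqrt(truth / 2000))
  rim_th <- seq(0, 2 * pi, length.out = nrim + 1)[-1]
  cap <- rbind(cbind(r * cos(th), r * sin(th), R * z),
               cbind(R * sqrt(0.75) * cos(rim_th),
                     R * sqrt(0.75) * sin(rim_th), R * 0.5))
  mc <- suppressMessages(triangulate_surface(cap, mu = 4))
  expect_lt(abs(heron_area(mc) - truth) / truth, 0.05)

  expect_error(triangulate_surface(rbind(c(0, 0, 0), c(1, 1, 1))),
               "at least 3")
})

test_that("the planar Delaunay satisfies the empty-circumcircle property", {
  set.seed(4)
  for (rep in 1:5) {
    uv <- matrix(runif(60), ncol = 2)
    X <- cbind(uv, 0)
    mesh <- suppressMessages(triangulate_surface(X, mu = 1e6))
    tri <- mesh$triangles
    for (t in seq_len(nrow(tri))) {
      a <- uv[tri[t, 1], ]; b <- uv[tri[t, 2], ]; c <- uv[tri[t, 3], ]
      d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) +
                  c[1] * (a[2] - b[2]))
      ux <- (sum(a^2) * (b[2] - c[2]) + sum(b^2) * (c[2] - a[2]) +
               sum(c^2) * (a[2] - b[2])) / d
      uy <- (sum(a^2) * (c[1] - b[1]) + sum(b^2) * (a[1] - c[1]) +
               sum(c^2) * (b[1] - a[1])) / d
      r2 <- sum((a - c(ux, uy))^2)
      inside <- rowSums(sweep(uv, 2, c(ux, uy))^2) < r2 * (1 - 1e-9)
      inside[tri[t, ]] <- FALSE
      expect_false(any(inside))
    }
  }
})

test_that("Heron areas equal the cross-product oracle everywhere", {
  tri1 <- structure(list(vertices = rbind(c(0, 0, 0), c(1, 0, 0),
                                          c(0, 1, 0)),
                         triangles = matrix(c(1L, 2L, 3L), 1)),
                    class = "triangle_mesh")
  expect_equal(heron_area(tri1), 0.5, tolerance = 1e-15)

  degen <- structure(list(vertices = rbind(c(0, 0, 0), c(1, 1, 1),
                                           c(2, 2, 2)),
                          triangles = matrix(c(1L, 2L, 3L), 1)),
                     class = "triangle_mesh")
  expect_equal(heron_area(degen), 0)

  set.seed(6)
  for (rep in 1:20) {
    X <- cbind(matrix(runif(40), ncol = 2), rnorm(20, 0, 0.05))
    mesh <- suppressMessages(triangulate_surface(X, mu = 1e6))
    a <- heron_area(mesh)
    b <- oracle_mesh_area(mesh)
    expect_lt(abs(a - b) / b, 1e-10)
  }
})
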