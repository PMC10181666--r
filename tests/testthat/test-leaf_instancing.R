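test_that("well-separated blobs segment into pure instances", {
  a <- blob_cloud(200, c(0, 0, 0), seed = 1)
  b <- blob_cloud(200, c(0.2, 0, 0), seed = 2)
  cl <- leaf_cloud(rbind(a$coords, b$coords),
                   semantic = rep(1L, 400))
  seg <- mean_shift_segment(cl, radius = 0.045)
  expect_equal(nrow(seg$centers), 2L)
  # each blob maps to a single id
  expect_equal(length(unique(seg$instance[1:200])), 1L)
  expect_equal(length(unique(seg$instance[201:400])), 1L)
  expect_false(seg$instance[1] == seg$instance[201])

  one <- mean_shift_segment(a, radius = 0.045)
  expect_equal(nrow(one$centers), 1L)
  expect_true(all(one$instance == 0L))
})

test_that("instance labels partition the leaf points contiguously from 0", {
  br <- make_branch(branch_spec(length = 0.5, n_leaves = 8,
                                min_separation = 0.07), seed = 4)
  seg <- mean_shift_segment(br$cloud, radius = 0.045)
  nleaf <- sum(br$cloud$semantic == 1L)
  expect_length(seg$instance, nleaf)
  expect_true(all(seg$instance >= 0L))
  expect_setequal(unique(seg$instance), seq_len(nrow(seg$centers)) - 1L)
})

test_that("mean shift is deterministic and translation-equivariant", {
  br <- make_branch(branch_spec(length = 0.4, n_leaves = 6,
                                min_separation = 0.07), seed = 3)
  s1 <- mean_shift_segment(br$cloud, radius = 0.045)
  s1b <- mean_shift_segment(br$cloud, radius = 0.045)
  expect_identical(s1$instance, s1b$instance)
  expect_identical(s1$centers, s1b$centers)

  shift <- c(3.2, -1.7, 10.4)
  cl2 <- br$cloud
  cl2$coords <- sweep(cl2$coords, 2, shift, "+")
  s2 <- mean_shift_segment(cl2, radius = 0.045)
  expect_identical(s1$instance, s2$instance)
  expect_equal(sweep(s2$centers, 2, shift), s1$centers, tolerance = 1e-9)
})

test_that("micro-clusters dissolve into their nearest surviving instance", {
  a <- blob_cloud(150, c(0, 0, 0), seed = 5)
  stray <- matrix(rnorm(9, 0, 1e-4), ncol = 3)
  stray <- sweep(stray, 2, c(0.3, 0, 0), "+")      # 3 points, far blob
  cl <- leaf_cloud(rbind(a$coords, stray), semantic = rep(1L, 153))
  seg <- mean_shift_segment(cl, radius = 0.045, min_points = 10)
  expect_equal(nrow(seg$centers), 1L)
  expect_true(all(seg$instance == 0L))
})

test_that("smaller radii fragment at least as much as larger radii", {
  for (s in 1:3) {
    br <- make_branch(branch_spec(length = 0.45, n_leaves = 14), seed = s)
    cl <- perturb_cloud(br$cloud, noise_sigma = 5e-4, dropout = 0.15,
                        seed = s)
    counts <- vapply(c(0.035, 0.045, 0.055), function(r)
      nrow(mean_shift_segment(cl, radius = r)$centers), numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})
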