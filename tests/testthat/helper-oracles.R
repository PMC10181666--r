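# Independent brute-force oracles and small fixture builders used across
# the suite.  Everything here is deliberately naive (O(n^2) scans, explicit
# enumeration) so it cannot share a defect with the implementation.

# mean distance to the k nearest neighbours, from the full distance matrix
oracle_mean_knn <- function(X, k) {
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  apply(D, 1, function(d) mean(sort(d)[seq_len(k)]))
}

# exhaustive farthest pair (indices, unordered)
oracle_farthest_pair <- function(X) {
  D <- as.matrix(stats::dist(X))
  which(D == max(D), arr.ind = TRUE)[1, ]
}

# triangle-mesh area from the cross product, no Heron
oracle_mesh_area <- function(mesh) {
  V <- mesh$vertices
  tri <- mesh$triangles
  s <- 0
  for (r in seq_len(nrow(tri))) {
    a <- V[tri[r, 2], ] - V[tri[r, 1], ]
    b <- V[tri[r, 3], ] - V[tri[r, 1], ]
    cr <- c(a[2] * b[3] - a[3] * b[2],
            a[3] * b[1] - a[1] * b[3],
            a[1] * b[2] - a[2] * b[1])
    s <- s + 0.5 * sqrt(sum(cr^2))
  }
  s
}

# maximum number of one-to-one (true, pred) pairs with IoU > thr,
# by exhaustive branch-and-bound over assignments
oracle_match_count <- function(M, thr = 0.5) {
  G <- nrow(M)
  P <- ncol(M)
  best <- 0L
  rec <- function(i, used, cnt) {
    if (cnt + (G - i + 1L) <= best) return(invisible())
    if (i > G) {
      best <<- max(best, cnt)
      return(invisible())
    }
    rec(i + 1L, used, cnt)
    for (j in seq_len(P)) {
      if (!used[j] && M[i, j] > thr) {
        used[j] <- TRUE
        rec(i + 1L, used, cnt + 1L)
        used[j] <- FALSE
      }
    }
  }
  rec(1L, logical(P), 0L)
  best
}

iou_matrix_oracle <- function(tr, pr) {
  outer(seq_along(tr), seq_along(pr), Vectorize(function(i, j) {
    length(intersect(tr[[i]], pr[[j]])) / length(union(tr[[i]], pr[[j]]))
  }))
}

# random instance partition of 1..n into g contiguous-ish groups, plus a
# perturbed prediction (split/merge/jitter), as index-set lists
random_partition_fixture <- function(n, g, seed) {
  set.seed(seed)
  cuts <- sort(sample(seq_len(n - 1L), g - 1L))
  bounds <- c(0L, cuts, n)
  tr <- lapply(seq_len(g), function(i) (bounds[i] + 1L):bounds[i + 1L])
  pr <- tr
  op <- sample(c("keep", "split", "merge", "jitter"), 1)
  if (op == "split" && any(lengths(pr) >= 4L)) {
    i <- which(lengths(pr) >= 4L)[1]
    half <- pr[[i]][seq_len(length(pr[[i]]) %/% 2L)]
    pr <- c(pr[-i], list(half, setdiff(pr[[i]], half)))
  } else if (op == "merge" && length(pr) >= 2L) {
    pr <- c(pr[-(1:2)], list(c(pr[[1]], pr[[2]])))
  } else if (op == "jitter") {
    for (i in seq_along(pr)[-1]) {
      mv <- pr[[i]][seq_len(min(2L, length(pr[[i]]) - 1L))]
      pr[[i]] <- setdiff(pr[[i]], mv)
      pr[[i - 1L]] <- c(pr[[i - 1L]], mv)
    }
  }
  list(true = tr, pred = pr)
}

# isotropic Gaussian blob as a leaf_cloud
blob_cloud <- function(n, center, sd = 0.02, seed = 1) {
  set.seed(seed)
  leaf_cloud(sweep(matrix(rnorm(3 * n, 0, sd), ncol = 3), 2, center, "+"),
             semantic = rep(1L, n))
}

rotation_matrix <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}
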