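test_that("semantic metrics follow the standard (prose) definitions", {
  # NOTE: the source's printed formulas swap FP and FN between precision
  # and recall; the standard orientation (precision = TP/(TP+FP),
  # recall = TP/(TP+FN)) is asserted here on an asymmetric fixture.
  tr <- c(1, 1, 0, 0)
  pr <- c(1, 0, 1, 0)
  rep <- semantic_metrics(tr, pr)
  leaf <- rep["leaf", ]
  expect_equal(leaf$tp, 1L)
  expect_equal(leaf$fp, 1L)
  expect_equal(leaf$fn, 1L)
  expect_equal(leaf$precision, 0.5)
  expect_equal(leaf$recall, 0.5)
  expect_equal(leaf$f1, 0.5)
  expect_equal(leaf$iou, 1 / 3)
  # orientation check: one-sided errors separate precision from recall
  asym <- semantic_metrics(c(1, 0, 0, 0), c(1, 1, 1, 0))
  expect_equal(asym["leaf", "precision"], 1 / 3)  # TP=1, FP=2
  expect_equal(asym["leaf", "recall"], 1)         # FN=0

  perfect <- semantic_metrics(tr, tr)
  expect_true(all(perfect[, c("precision", "recall", "f1", "iou")] == 1))

  flipped <- semantic_metrics(tr, 1 - tr)
  expect_true(all(flipped[c("branch", "leaf"),
                          c("precision", "recall", "iou")] == 0))
})

test_that("semantic metrics are symmetric under class relabeling", {
  set.seed(3)
  tr <- rbinom(200, 1, 0.6)
  pr <- ifelse(runif(200) < 0.15, 1 - tr, tr)
  a <- semantic_metrics(tr, pr)
  b <- semantic_metrics(1 - tr, 1 - pr)
  expect_equal(a["branch", ], b["leaf", ], ignore_attr = TRUE)
  expect_equal(a["leaf", ], b["branch", ], ignore_attr = TRUE)
  expect_equal(a["mean", ], b["mean", ], ignore_attr = TRUE)
})

test_that("degenerate label vectors are flagged, not NaN", {
  rep <- semantic_metrics(c(1, 1, 1), c(1, 1, 1))
  expect_true(rep["branch", "undefined"])
  expect_equal(rep["branch", "precision"], 0)
  expect_error(semantic_metrics(integer(0), integer(0)), "empty")
  expect_error(semantic_metrics(c(0, 2), c(0, 1)), "binary")
  expect_error(semantic_metrics(c(0, 1), c(0, 1, 1)), "equal length")
})

test_that("instance IoU is plain set arithmetic", {
  expect_equal(instance_iou(1:10, 1:10), 1)
  expect_equal(instance_iou(1:5, 6:10), 0)
  expect_equal(instance_iou(1:10, 6:15), 1 / 3)
  both_empty <- instance_iou(integer(0), integer(0))
  expect_equal(as.numeric(both_empty), 0)
  expect_true(attr(both_empty, "undefined"))
})

test_that("mean coverage averages the best match per true instance", {
  tr <- list(1:10, 11:30)
  expect_equal(mcov(tr, tr), 1)
  # one true instance split evenly in two predictions
  expect_equal(mcov(list(1:10), list(1:5, 6:10)), 0.5)
  expect_equal(mcov(tr, list(31:40)), 0)
  expect_equal(mcov(tr, list()), 0)
  expect_error(mcov(list(), tr), "at least one")
})

test_that("instance precision/recall count one-to-one matches above 0.5", {
  tr <- lapply(0:11, function(i) i * 20 + 1:20)
  perfect <- instance_pr(tr, tr)
  expect_equal(perfect$t_matched, 12L)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$mcov, 1)

  # 10 true, 8 predicted, exactly 6 pairs overlapping above 0.5
  tr <- lapply(0:9, function(i) i * 10 + 1:10)
  pr <- c(lapply(0:5, function(i) i * 10 + 1:9),    # IoU 0.9
          list(61:65, 200:240))                     # IoU 0.5 (not >), 0
  rep <- instance_pr(tr, pr)
  expect_equal(rep$t_matched, 6L)
  expect_equal(rep$precision, 6 / 8)
  expect_equal(rep$recall, 6 / 10)

  # strict threshold: nothing imperfect matches at 1.0
  expect_equal(instance_pr(tr, pr, threshold = 1.0)$t_matched, 0L)

  undef <- instance_pr(tr, list())
  expect_true(undef$undefined)
  expect_equal(undef$precision, 0)
})

test_that("greedy matching equals exhaustive optimal on small fixtures", {
  for (seed in 1:12) {
    fx <- random_partition_fixture(n = 120, g = sample(3:8, 1), seed = seed)
    rep <- instance_pr(fx$true, fx$pred)
    M <- iou_matrix_oracle(fx$true, fx$pred)
    expect_equal(rep$t_matched, oracle_match_count(M, 0.5))
    expect_equal(rep$mcov, mean(apply(M, 1, max)))
  }
})

test_that("mCov reaches 1 only when every true instance is reproduced", {
  fx <- random_partition_fixture(150, 5, seed = 99)
  expect_equal(mcov(fx$true, fx$true), 1)
  jig <- fx$true
  jig[[1]] <- jig[[1]][-1]
  expect_lt(mcov(fx$true, jig), 1)
})
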