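# Hard NMS and Gaussian Soft-NMS, including the distance-IoU variant.

sb <- function(box, score, class_id = 1L) {
  list(box = box, score = score, class_id = class_id)
}

test_that("hard_nms keeps the top box among full overlaps, all among disjoint", {
  two_same <- list(sb(c(0, 0, 10, 10), 0.9), sb(c(0, 0, 10, 10), 0.8))
  kept <- hard_nms(two_same, 0.5)
  expect_length(kept, 1)
  expect_equal(kept[[1]]$score, 0.9)

  disjoint <- list(sb(c(0, 0, 10, 10), 0.9), sb(c(20, 20, 30, 30), 0.8))
  expect_length(hard_nms(disjoint, 0.5), 2)
})

test_that("hard_nms matches the exhaustive greedy reference on random sets", {
  set.seed(17)
  for (rep in 1:40) {
    n <- 8
    boxes <- t(replicate(n, random_box(60)))
    scores <- runif(n)
    dets <- lapply(seq_len(n), function(i) sb(boxes[i, ], scores[i]))
    thr <- runif(1, 0.2, 0.7)
    kept <- hard_nms(dets, thr)
    ref <- oracle_hard_nms(boxes, scores, thr)
    expect_equal(sort(vapply(kept, function(d) d$score, numeric(1))),
                 sort(scores[ref]))
  }
})

test_that("soft_nms applies the Gaussian decay and respects zero overlap", {
  two_same <- list(sb(c(0, 0, 10, 10), 0.9), sb(c(0, 0, 10, 10), 0.9))
  out <- soft_nms(two_same, sigma = 0.5, score_floor = 0.001)
  expect_equal(sort(vapply(out, function(d) d$score, numeric(1))),
               sort(c(0.9, 0.9 * exp(-1 / 0.5))))

  disjoint <- list(sb(c(0, 0, 10, 10), 0.9), sb(c(20, 20, 30, 30), 0.8))
  out2 <- soft_nms(disjoint, sigma = 0.5)
  expect_equal(vapply(out2, function(d) d$score, numeric(1)), c(0.9, 0.8))

  expect_error(soft_nms(two_same, sigma = 0), "sigma")
  expect_error(soft_nms(two_same, sigma = 0.5, score_floor = 1), "score_floor")
})

test_that("concentric boxes decay identically under iou and diou overlap", {
  dets <- list(sb(c(0, 0, 20, 20), 0.9), sb(c(5, 5, 15, 15), 0.8))
  a <- soft_nms(dets, sigma = 0.5, overlap_fn = "iou")
  b <- soft_nms(dets, sigma = 0.5, overlap_fn = "diou")
  expect_equal(vapply(a, function(d) d$score, numeric(1)),
               vapply(b, function(d) d$score, numeric(1)))
})

test_that("soft_nms never increases scores; classes never cross-suppress", {
  set.seed(29)
  for (rep in 1:30) {
    n <- 10
    dets <- lapply(seq_len(n), function(i) {
      sb(random_box(40), runif(1), class_id = sample(1:2, 1))
    })
    out <- soft_nms(dets, sigma = 0.4, score_floor = 0)
    expect_length(out, n)  # floor 0 keeps everything
    orig <- vapply(dets, function(d) d$score, numeric(1))
    news <- vapply(out, function(d) d$score, numeric(1))
    expect_true(all(sort(news, decreasing = TRUE) <= sort(orig, decreasing = TRUE) + 1e-12))
  }
  # two fully overlapping boxes of different classes: untouched
  cross <- list(sb(c(0, 0, 10, 10), 0.9, 1L), sb(c(0, 0, 10, 10), 0.8, 2L))
  outc <- soft_nms(cross, sigma = 0.5)
  expect_equal(sort(vapply(outc, function(d) d$score, numeric(1))), c(0.8, 0.9))
})

test_that("as sigma -> 0 soft-NMS selection converges to hard NMS", {
  set.seed(37)
  for (rep in 1:200) {
    n <- sample(4:9, 1)
    # integer-corner boxes bound every positive overlap away from zero, and
    # scores stay above the floor, so the limit is clean (generic inputs)
    boxes <- t(replicate(n, round(random_box(50))))
    scores <- runif(n, 0.05, 1)
    dets <- lapply(seq_len(n), function(i) sb(boxes[i, ], scores[i]))
    # sigma -> 0 sends any positive overlap's decay to zero, so with a
    # positive floor the selection is exactly hard NMS at threshold 0
    soft <- soft_nms(dets, sigma = 1e-9, score_floor = 0.01)
    soft_scores <- sort(vapply(soft, function(d) d$score, numeric(1)))
    hard0 <- hard_nms(dets, 0)
    expect_equal(soft_scores,
                 sort(vapply(hard0, function(d) d$score, numeric(1))))
  }
})

test_that("diou-mode decay is never stronger than iou-mode decay", {
  set.seed(43)
  for (rep in 1:50) {
    n <- 8
    dets <- lapply(seq_len(n), function(i) sb(random_box(50), runif(1)))
    a <- soft_nms(dets, sigma = 0.5, score_floor = 0, overlap_fn = "iou")
    b <- soft_nms(dets, sigma = 0.5, score_floor = 0, overlap_fn = "diou")
    sa <- sort(vapply(a, function(d) d$score, numeric(1)), decreasing = TRUE)
    sd <- sort(vapply(b, function(d) d$score, numeric(1)), decreasing = TRUE)
    expect_true(all(sd >= sa - 1e-12))
  }
})

test_that("survivors of hard NMS are a subset of soft-NMS survivors at floor 0", {
  set.seed(51)
  for (rep in 1:20) {
    n <- 9
    dets <- lapply(seq_len(n), function(i) sb(random_box(40), runif(1)))
    hard_boxes <- lapply(hard_nms(dets, 0.5), function(d) d$box)
    soft <- soft_nms(dets, sigma = 0.5, score_floor = 0)
    expect_length(soft, n)
  }
})
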