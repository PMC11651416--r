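# Box overlap measures and the line-distance metric.

test_that("iou handles identity, disjointness, and partial overlap", {
  a <- mt_box(0, 0, 2, 2)
  expect_equal(iou(a, a), 1)
  expect_equal(iou(a, mt_box(5, 5, 7, 7)), 0)
  b <- mt_box(1, 1, 3, 3)
  expect_equal(iou(a, b), 1 / 7)
  expect_equal(iou(a, b), oracle_iou_raster(a, b), tolerance = 0.01)
  expect_equal(iou(a, b), iou(b, a))
})

test_that("diou subtracts the normalized center-distance penalty", {
  a <- mt_box(0, 0, 2, 2)
  expect_equal(diou(a, a), 1)
  inner <- mt_box(0.5, 0.5, 1.5, 1.5)  # concentric
  expect_equal(diou(a, inner), iou(a, inner))
  b <- mt_box(1, 1, 3, 3)
  expect_equal(diou(a, b), 1 / 7 - 2 / 18)
  expect_error(diou(c(1, 1, 1, 1), c(1, 1, 1, 1)), "degenerate")
})

test_that("diou <= iou with equality iff centers coincide; both translation invariant", {
  set.seed(21)
  for (rep in 1:200) {
    a <- random_box(); b <- random_box()
    va <- iou(a, b); vd <- diou(a, b)
    expect_lte(vd, va + 1e-12)
    centers_equal <- isTRUE(all.equal((a[1] + a[3]) / 2, (b[1] + b[3]) / 2)) &&
      isTRUE(all.equal((a[2] + a[4]) / 2, (b[2] + b[4]) / 2))
    expect_equal(vd == va, centers_equal)
    sh <- runif(2, -50, 50)
    a2 <- a + sh[c(1, 2, 1, 2)]; b2 <- b + sh[c(1, 2, 1, 2)]
    expect_equal(iou(a2, b2), va)
    expect_equal(diou(a2, b2), vd)
    expect_equal(diou(b, a), vd)
  }
})

test_that("point_segment_distance covers the three projection cases", {
  r <- point_segment_distance(c(0, 0), c(0, 1), c(1, 1))
  expect_equal(r$case, "foot_before_A")
  expect_equal(r$distance, 1)
  expect_null(r$foot)

  r2 <- point_segment_distance(c(0.5, 0), c(0, 1), c(1, 1))
  expect_equal(r2$case, "foot_interior")
  expect_equal(r2$distance, 1)
  expect_equal(r2$foot, c(0.5, 1))

  r3 <- point_segment_distance(c(5, 1), c(0, 1), c(1, 1))
  expect_equal(r3$case, "foot_after_B")
  expect_equal(r3$distance, 4)

  degen <- point_segment_distance(c(3, 4), c(0, 0), c(0, 0))
  expect_equal(degen$case, "foot_before_A")
  expect_equal(degen$distance, 5)
})

test_that("segment distance matches the dense-sampling oracle and its bounds", {
  set.seed(33)
  for (rep in 1:300) {
    p <- runif(2, -50, 50); a <- runif(2, -50, 50); b <- runif(2, -50, 50)
    r <- point_segment_distance(p, a, b)
    expect_equal(r$distance, oracle_segment_distance(p, a, b, 2e4), tolerance = 1e-4)
    expect_lte(r$distance,
               min(sqrt(sum((p - a)^2)), sqrt(sum((p - b)^2))) + 1e-12)
  }
})

test_that("polyline distance is the minimum over segments", {
  poly <- rbind(c(0, 0), c(10, 0), c(10, 10))
  expect_equal(point_polyline_distance(c(10, 0), poly), 0)   # on a vertex
  expect_equal(point_polyline_distance(c(5, 3), rbind(c(0, 0), c(10, 0))), 3)
  expect_error(point_polyline_distance(c(1, 1), matrix(numeric(0), ncol = 2)), "at least one")

  set.seed(9)
  for (rep in 1:50) {
    poly <- cbind(cumsum(runif(10, -5, 8)), cumsum(runif(10, -5, 8)))
    p <- runif(2, -20, 60)
    expect_equal(point_polyline_distance(p, poly),
                 oracle_polyline_distance(p, poly, 5e3), tolerance = 1e-4)
  }
})

test_that("line_distance averages per-point polyline distances", {
  gt <- rbind(c(0, 0), c(10, 0))
  preds <- rbind(c(1, 1), c(5, -1), c(9, 0))
  expect_equal(line_distance(preds, gt), 2 / 3)
  on_line <- rbind(c(0, 0), c(3, 0), c(10, 0))
  expect_equal(line_distance(on_line, gt), 0)
  expect_equal(line_distance(rbind(c(4, 4)), rbind(c(4, 4))), 0)
  expect_error(line_distance(matrix(numeric(0), ncol = 2), gt), "at least one")
})

test_that("match_detections is greedy, score-ordered, one-to-one, class-aware", {
  gt <- list(list(box = mt_box(10, 10, 50, 50), category = "leaf",
                  points = rbind(c(15, 15), c(45, 45))))
  det_hit <- list(box = mt_box(10, 10, 50, 50), class = "leaf", score = 0.9,
                  keypoints = rbind(c(15, 15)))
  m1 <- match_detections(list(det_hit), gt)
  expect_equal(nrow(m1$pairs), 1)
  expect_length(m1$unmatched_detections, 0)
  expect_length(m1$unmatched_ground_truths, 0)

  det_wrong <- det_hit; det_wrong$class <- "stalk"
  m2 <- match_detections(list(det_wrong), gt)
  expect_equal(nrow(m2$pairs), 0)
  expect_equal(m2$unmatched_detections, 1L)
  expect_equal(m2$unmatched_ground_truths, 1L)

  det_lo <- det_hit; det_lo$score <- 0.4
  m3 <- match_detections(list(det_lo, det_hit), gt)
  expect_equal(m3$pairs[1, ], c(det = 2L, gt = 1L))
  expect_equal(m3$unmatched_detections, 1L)
  # and with the list order reversed the higher score still wins
  m4 <- match_detections(list(det_hit, det_lo), gt)
  expect_equal(m4$pairs[1, ], c(det = 1L, gt = 1L))
})

test_that("mean_line_distance averages LD over matched pairs", {
  gt <- list(
    list(box = mt_box(0, 0, 20, 20), category = "leaf",
         points = rbind(c(0, 10), c(20, 10))),
    list(box = mt_box(40, 40, 60, 60), category = "leaf",
         points = rbind(c(40, 50), c(60, 50))))
  dets <- list(
    list(box = mt_box(0, 0, 20, 20), class = "leaf", score = 0.9,
         keypoints = rbind(c(5, 11), c(10, 9))),          # LD = 1
    list(box = mt_box(40, 40, 60, 60), class = "leaf", score = 0.8,
         keypoints = rbind(c(45, 53), c(50, 47))))        # LD = 3
  m <- match_detections(dets, gt)
  rep <- mean_line_distance(m, dets, gt)
  expect_equal(rep$K, 2)
  expect_equal(sort(rep$per_target_ld), c(1, 3))
  expect_equal(rep$mld, 2)

  # perfect predictions give zero
  perfect <- lapply(seq_along(gt), function(i) {
    list(box = gt[[i]]$box, class = "leaf", score = 1, keypoints = gt[[i]]$points)
  })
  mp <- match_detections(perfect, gt)
  expect_equal(mean_line_distance(mp, perfect, gt)$mld, 0)

  # no matches: mld undefined, K = 0
  m0 <- match_detections(list(), gt)
  r0 <- mean_line_distance(m0, list(), gt)
  expect_equal(r0$K, 0)
  expect_true(is.na(r0$mld))
})

test_that("mLD is invariant under rigid motion and scales linearly with scale", {
  set.seed(77)
  base_polys <- lapply(1:3, function(i) {
    cbind(cumsum(runif(6, 1, 10)) + 20 * i, cumsum(runif(6, -4, 6)) + 30)
  })
  base_kps <- lapply(base_polys, function(p) p[c(1, 3, 5), ] + runif(6, -1.5, 1.5))
  scores <- runif(3, 0.5, 1)
  mld_of <- function(f) {
    gt <- lapply(base_polys, function(p) {
      poly <- f(p)
      list(box = mt_box(min(poly[, 1]) - 2, min(poly[, 2]) - 2,
                        max(poly[, 1]) + 2, max(poly[, 2]) + 2),
           category = "leaf", points = poly)
    })
    dets <- lapply(seq_along(gt), function(i) {
      list(box = gt[[i]]$box, class = "leaf", score = scores[i],
           keypoints = f(base_kps[[i]]))
    })
    m <- match_detections(dets, gt)
    mean_line_distance(m, dets, gt)$mld
  }
  m0 <- mld_of(identity)
  m_shift <- mld_of(function(p) sweep(p, 2, c(13.7, -8.2), "+"))
  expect_equal(m_shift, m0, tolerance = 1e-9)
  m_flip <- mld_of(function(p) cbind(500 - p[, 1], p[, 2]))
  expect_equal(m_flip, m0, tolerance = 1e-9)
  for (s in c(0.5, 2, 7)) {
    ms <- mld_of(function(p) p * s)
    expect_equal(ms, s * m0, tolerance = 1e-9)
  }
})
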