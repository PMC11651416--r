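# Precision/recall/AP/mAP and curve export.

gt_at <- function(box, category = "leaf") list(box = box, category = category)
det_at <- function(box, score, class = "leaf") list(box = box, class = class, score = score)

test_that("a perfect detector scores AP 1 per class and mAP 1", {
  gts <- list(list(gt_at(mt_box(0, 0, 10, 10), "leaf"),
                   gt_at(mt_box(30, 30, 50, 60), "stalk")))
  dets <- list(list(det_at(mt_box(0, 0, 10, 10), 0.9, "leaf"),
                    det_at(mt_box(30, 30, 50, 60), 0.8, "stalk")))
  rep <- evaluate_detections(dets, gts)
  expect_equal(unname(rep$results[["iou_0.5"]]$ap), c(1, 1))
  expect_equal(rep$map50, 1)
  expect_equal(rep$map75, 1)
})

test_that("no detections gives AP 0; detections without ground truth warn to 0", {
  gts <- list(list(gt_at(mt_box(0, 0, 10, 10))))
  rep <- evaluate_detections(list(list()), gts)
  expect_equal(rep$map50, 0)

  gts2 <- list(list(gt_at(mt_box(0, 0, 10, 10), "leaf")))
  dets2 <- list(list(det_at(mt_box(0, 0, 10, 10), 0.9, "stalk")))
  expect_warning(rep2 <- evaluate_detections(dets2, gts2, 0.5),
                 "no ground truths")
  expect_equal(unname(rep2$results[["iou_0.5"]]$ap["stalk"]), 0)
})

test_that("the [TP, FP] staircase over 2 ground truths gives AP 0.5", {
  gts <- list(list(gt_at(mt_box(0, 0, 10, 10)), gt_at(mt_box(40, 40, 60, 60))))
  dets <- list(list(det_at(mt_box(0, 0, 10, 10), 0.9),    # TP
                    det_at(mt_box(100, 100, 120, 130), 0.8)))  # FP
  rep <- evaluate_detections(dets, gts, iou_thresholds = 0.5)
  r <- rep$results[["iou_0.5"]]
  expect_equal(unname(r$per_class$leaf$precision), c(1, 0.5))
  expect_equal(unname(r$per_class$leaf$recall), c(0.5, 0.5))
  expect_equal(unname(r$ap["leaf"]), 0.5)
})

test_that("duplicate detections of one ground truth count one TP plus FPs", {
  gts <- list(list(gt_at(mt_box(0, 0, 10, 10))))
  dets <- list(list(det_at(mt_box(0, 0, 10, 10), 0.9),
                    det_at(mt_box(0, 0, 10, 10), 0.8),
                    det_at(mt_box(0, 0, 10, 10), 0.7)))
  rep <- evaluate_detections(dets, gts, iou_thresholds = 0.5)
  pc <- rep$results[["iou_0.5"]]$per_class$leaf
  expect_equal(sum(diff(c(0, pc$recall)) > 0), 1)  # exactly one TP
  expect_equal(unname(pc$ap), 1)  # the TP ranks first
})

test_that("AP equals the brute-force oracle on random small instances", {
  set.seed(83)
  for (rep in 1:60) {
    n_gt <- sample(1:6, 1)
    gts_img <- lapply(seq_len(n_gt), function(i) {
      gt_at(mt_box(20 * i, 20 * i, 20 * i + 10, 20 * i + 10))
    })
    n_det <- sample(1:20, 1)
    dets_img <- lapply(seq_len(n_det), function(i) {
      if (runif(1) < 0.5) {
        j <- sample(n_gt, 1)  # near a ground truth, maybe above/below 0.5 IoU
        shift <- runif(1, 0, 8)
        det_at(mt_box(20 * j + shift, 20 * j, 20 * j + 10 + shift, 20 * j + 10),
               runif(1))
      } else {
        det_at(mt_box(300 + 15 * i, 300, 310 + 15 * i, 310), runif(1))
      }
    })
    res <- evaluate_detections(list(dets_img), list(gts_img), iou_thresholds = 0.5)
    pc <- res$results[["iou_0.5"]]$per_class$leaf
    tp_sorted <- diff(c(0, pc$recall)) > 0
    expect_equal(unname(pc$ap), oracle_ap(tp_sorted, n_gt), tolerance = 1e-12)
  }
})

test_that("AP is invariant under monotone score transforms", {
  set.seed(91)
  gts <- list(lapply(1:4, function(i) gt_at(mt_box(20 * i, 0, 20 * i + 10, 10))))
  dets <- list(lapply(1:8, function(i) {
    det_at(mt_box(20 * (i %% 4 + 1) + runif(1, 0, 6), 0,
                  20 * (i %% 4 + 1) + 10, 10), runif(1))
  }))
  ap1 <- evaluate_detections(dets, gts, 0.5)$results[["iou_0.5"]]$ap["leaf"]
  dets2 <- list(lapply(dets[[1]], function(d) { d$score <- d$score^3 + 1; d }))
  ap2 <- evaluate_detections(dets2, gts, 0.5)$results[["iou_0.5"]]$ap["leaf"]
  expect_equal(ap1, ap2)
})

test_that("export_curves writes a lossless CSV and rejects empty curves", {
  curve <- data.frame(confidence = c(0.9, 0.5, 0.1),
                      precision = c(1, 0.5, 1 / 3),
                      recall = c(0.5, 0.5, 0.5),
                      f1 = c(2 / 3, 0.5, 0.4))
  out <- tempfile(fileext = ".csv")
  export_curves(curve, out, plot = FALSE)
  back <- read.csv(out)
  expect_equal(back, curve)
  expect_equal(nrow(back), 3)
  expect_error(export_curves(curve[0, ], out), "empty")
})
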