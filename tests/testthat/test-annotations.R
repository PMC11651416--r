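# Annotation I/O and the preprocessing operations.

test_that("read_labelme parses shapes, preserves order, validates labels", {
  pts <- cbind(c(10, 20, 30, 40, 50), c(5, 15, 25, 35, 45))
  path <- tmp_labelme(list(list(label = "Leaf", points = pts)))
  img <- read_labelme(path)
  expect_s3_class(img, "mt_annotated_image")
  expect_length(img$annotations, 1)
  expect_equal(img$annotations[[1]]$category, "leaf")
  expect_equal(img$annotations[[1]]$points, pts, ignore_attr = TRUE)

  empty <- read_labelme(tmp_labelme(list()))
  expect_length(empty$annotations, 0)

  bad <- tmp_labelme(list(list(label = "flower", points = pts)))
  expect_error(read_labelme(bad), "flower")
  expect_error(read_labelme(tempfile()), "not found")
})

test_that("labelme round-trip preserves coordinates and categories", {
  pts <- cbind(runif(7, 0, 199), runif(7, 0, 149))
  img <- mt_annotated_image("a.png", 200, 150, list(
    mt_polyline("leaf", pts), mt_polyline("stalk", pts[1:3, ])))
  out <- tempfile(fileext = ".json")
  write_labelme(img, out)
  back <- read_labelme(out)
  expect_equal(back$annotations[[1]]$points, img$annotations[[1]]$points)
  expect_equal(back$annotations[[2]]$category, "stalk")
})

test_that("scale_annotated_image divides size and coordinates", {
  pts <- rbind(c(400, 800), c(1200, 40))
  img <- mt_annotated_image("x.png", 6016, 4016, list(mt_polyline("leaf", pts)))
  down <- scale_annotated_image(img, 4)
  expect_equal(c(down$width, down$height), c(1504, 1004))
  expect_equal(down$annotations[[1]]$points[1, ], c(100, 200))
  ident <- scale_annotated_image(img, 1)
  expect_equal(ident$annotations[[1]]$points, img$annotations[[1]]$points)
  expect_equal(c(ident$width, ident$height), c(6016, 4016))
  expect_error(scale_annotated_image(img, 0), "positive")
})

test_that("derive_bbox pads by the offset and clips to the image", {
  ann <- mt_polyline("leaf", rbind(c(100, 200), c(300, 400), c(150, 250)))
  b <- derive_bbox(ann, offset = 20, image_size = c(1504, 1004))
  expect_equal(as.numeric(b), c(80, 180, 320, 420))

  tight <- derive_bbox(ann, offset = 0, image_size = c(1504, 1004))
  expect_equal(as.numeric(tight), c(100, 200, 300, 400))

  edge <- mt_polyline("leaf", rbind(c(5, 5), c(60, 80)))
  clipped <- derive_bbox(edge, offset = 20, image_size = c(1504, 1004))
  expect_equal(as.numeric(clipped)[1:2], c(0, 0))

  expect_error(derive_bbox(ann, offset = -1, image_size = c(100, 100)), "offset")
})

test_that("derive_bbox contains every point with the promised margin", {
  set.seed(41)
  for (rep in 1:20) {
    pts <- cbind(runif(6, 5, 250), runif(6, 5, 180))
    ann <- mt_polyline("leaf", pts)
    off <- runif(1, 0, 15)
    b <- derive_bbox(ann, off, c(256, 192))
    margin_x <- pmin(pts[, 1] - b[1], b[3] - pts[, 1])
    margin_y <- pmin(pts[, 2] - b[2], b[4] - pts[, 2])
    lim <- pmin(off, pmin(pts[, 1], pts[, 2], 256 - pts[, 1], 192 - pts[, 2]))
    expect_true(all(margin_x >= lim - 1e-9))
    expect_true(all(margin_y >= lim - 1e-9))
  }
})

test_that("densify_polyline walks the arc at the requested spacing", {
  out <- densify_polyline(rbind(c(0, 0), c(10, 0)), spacing = 1)
  expect_equal(nrow(out), 11)
  expect_equal(out[, 1], 0:10)
  expect_equal(out[, 2], rep(0, 11))

  single <- densify_polyline(rbind(c(3, 4)), spacing = 1)
  expect_equal(single, rbind(c(3, 4)), ignore_attr = TRUE)

  degen <- densify_polyline(rbind(c(2, 2), c(2, 2)), spacing = 1)
  expect_equal(nrow(degen), 1)
  expect_error(densify_polyline(rbind(c(0, 0), c(1, 1)), spacing = 0), "spacing")
})

test_that("densified points stay on the polyline with consecutive gaps <= spacing", {
  set.seed(7)
  for (rep in 1:15) {
    n <- sample(2:8, 1)
    poly <- cbind(runif(n, 0, 100), runif(n, 0, 100))
    sp <- runif(1, 0.5, 10)
    out <- densify_polyline(poly, sp)
    # endpoints retained, order along the path preserved
    expect_equal(out[1, ], poly[1, ], ignore_attr = TRUE)
    expect_equal(out[nrow(out), ], poly[n, ], ignore_attr = TRUE)
    gaps <- sqrt(rowSums((out[-1, , drop = FALSE] - out[-nrow(out), , drop = FALSE])^2))
    expect_true(all(gaps <= sp + 1e-9))
    d <- vapply(seq_len(nrow(out)), function(i) point_polyline_distance(out[i, ], poly), numeric(1))
    expect_true(all(d < 1e-9))
  }
})

test_that("subsample_equal_interval keeps the promised count and endpoints", {
  pts100 <- cbind(seq_len(100), seq_len(100))
  expect_equal(nrow(subsample_equal_interval(pts100, 0.3)), 30)

  expect_equal(subsample_equal_interval(pts100, 1), pts100, ignore_attr = TRUE)

  pts10 <- cbind(1:10, rep(0, 10))
  s <- subsample_equal_interval(pts10, 0.3)
  expect_equal(nrow(s), 3)
  expect_true(s[2, 1] %in% c(5, 6))  # middle index 4 or 5 (0-based)
  expect_equal(s[c(1, 3), 1], c(1, 10))
  expect_error(subsample_equal_interval(pts10, 0), "ratio")
  expect_error(subsample_equal_interval(pts10, 1.2), "ratio")
})

test_that("subsample output is always an order-preserving subsequence", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(1:60, 1)
    pts <- cbind(seq_len(n) + runif(n), runif(n))
    r <- runif(1, 0.05, 1)
    s <- subsample_equal_interval(pts, r)
    idx <- match(s[, 1], pts[, 1])
    expect_false(anyNA(idx))
    expect_true(all(diff(idx) > 0) || nrow(s) == 1)
    if (n >= 2) expect_true(all(c(1, n) %in% idx))
  }
})

test_that("split_dataset apportions by largest remainder, reproducibly", {
  sp <- split_dataset(as.list(1:10), c(0.7, 0.2, 0.1), seed = 5)
  expect_equal(vapply(sp[c("train", "val", "test")], length, integer(1)),
               c(train = 7L, val = 2L, test = 1L))
  expect_setequal(unlist(sp[c("train", "val", "test")]), 1:10)

  sp2 <- split_dataset(as.list(1:10), c(0.7, 0.2, 0.1), seed = 5)
  expect_identical(sp, sp2)

  sp3 <- split_dataset(as.list(1:3), c(0.7, 0.2, 0.1), seed = 1)
  expect_equal(vapply(sp3[c("train", "val", "test")], length, integer(1)),
               c(train = 2L, val = 1L, test = 0L))

  for (n in c(1, 2, 5, 17, 99)) {
    spn <- split_dataset(as.list(seq_len(n)), c(0.7, 0.2, 0.1), seed = 2)
    expect_equal(sum(vapply(spn[c("train", "val", "test")], length, integer(1))), n)
    expect_setequal(unlist(spn[c("train", "val", "test")]), seq_len(n))
  }
  expect_error(split_dataset(as.list(1:5), c(0.5, 0.2, 0.2), 1), "sum")
})

test_that("detection-dataset export round-trips and conserves counts", {
  img1 <- mt_annotated_image("a.png", 200, 150, list(
    mt_polyline("leaf", cbind(c(10, 50, 90), c(20, 60, 30))),
    mt_polyline("stalk", cbind(c(100, 102, 104), c(10, 70, 140)))))
  img2 <- mt_annotated_image("b.png", 200, 150, list(
    mt_polyline("leaf", cbind(c(30, 80), c(40, 90)))))
  out <- tempfile(fileext = ".json")
  export_detection_dataset(list(img1, img2), out, offset = 5, ratio = 0.5, spacing = 2)
  back <- import_detection_dataset(out)
  expect_length(back$images, 2)
  expect_length(back$images[[1]]$targets, 2)
  expect_length(back$images[[2]]$targets, 1)
  t1 <- back$images[[1]]$targets[[1]]
  expect_equal(t1$category, "leaf")
  expect_equal(t1$polyline, img1$annotations[[1]]$points, ignore_attr = TRUE)
  expect_equal(as.numeric(t1$box),
               as.numeric(derive_bbox(img1$annotations[[1]], 5, c(200, 150))))
  # exported keypoints lie on the original trajectory
  d <- vapply(seq_len(nrow(t1$keypoints)), function(i) {
    point_polyline_distance(t1$keypoints[i, ], t1$polyline)
  }, numeric(1))
  expect_true(all(d < 1e-9))
  expect_error(export_detection_dataset(list(), out), "no images")
})
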