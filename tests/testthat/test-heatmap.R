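# Single-heatmap rendering and peak extraction.

test_that("render_target_heatmap peaks at 1 on each keypoint cell", {
  box <- mt_box(10, 20, 74, 84)
  hm <- render_target_heatmap(rbind(c(42, 52)), box, size = 16, sigma_hm = 2)
  expect_true(all(hm$grid >= 0 & hm$grid <= 1))
  am <- which(hm$grid == max(hm$grid), arr.ind = TRUE)
  expect_equal(nrow(am), 1)
  # the exact box center sits on the cell boundary; floor maps it into the
  # upper of the two central cells of the even-sized grid
  expect_equal(as.integer(am), c(9, 9))
  expect_equal(max(hm$grid), 1)

  # two well-separated keypoints give two unit local maxima
  hm2 <- render_target_heatmap(rbind(c(15, 25), c(70, 80)), box,
                               size = 32, sigma_hm = 1.5)
  expect_equal(sum(hm2$grid == 1), 2)

  # corner and off-box keypoints clip to boundary cells
  hm3 <- render_target_heatmap(rbind(c(10, 20), c(200, 300)), box,
                               size = 8, sigma_hm = 1)
  expect_equal(hm3$grid[1, 1], 1)
  expect_equal(hm3$grid[8, 8], 1)

  # empty keypoints -> all-zero heatmap, not an error
  hm0 <- render_target_heatmap(NULL, box, size = 8, sigma_hm = 1)
  expect_true(all(hm0$grid == 0))
})

test_that("extract_keypoints finds isolated peaks and maps them back", {
  box <- mt_box(20, 30, 148, 158)
  kp <- rbind(c(50, 60), c(120, 140))
  hm <- render_target_heatmap(kp, box, size = 32, sigma_hm = 2)
  peaks <- extract_keypoints(hm, min_separation = 3)
  expect_length(peaks, 2)
  xy <- do.call(rbind, lapply(peaks, `[[`, "image_xy"))
  cell_extent <- (148 - 20) / 32
  for (i in 1:2) {
    d <- sqrt(rowSums(sweep(xy, 2, kp[i, ])^2))
    expect_lte(min(d), cell_extent)  # within one cell's image extent
  }
  # flat heatmap yields nothing
  flat <- structure(list(grid = matrix(0, 16, 16), box = box, size = 16),
                    class = "mt_heatmap")
  expect_length(extract_keypoints(flat), 0)
  expect_error(extract_keypoints(list(grid = NULL, box = box)), "malformed")
})

test_that("render -> extract round-trips well-separated keypoint sets exactly", {
  set.seed(61)
  box <- mt_box(0, 0, 112, 112)
  size <- 28
  for (rep in 1:60) {
    k <- sample(1:6, 1)
    # rejection-sample grid cells with pairwise Chebyshev distance >= 3
    cells <- matrix(numeric(0), ncol = 2)
    while (nrow(cells) < k) {
      cand <- c(sample(size, 1), sample(size, 1))
      if (nrow(cells) == 0 ||
          all(pmax(abs(cells[, 1] - cand[1]), abs(cells[, 2] - cand[2])) >= 3)) {
        cells <- rbind(cells, cand)
      }
    }
    # image points at those cell centers (row -> y, col -> x)
    pts <- cbind((cells[, 2] - 0.5) * 4, (cells[, 1] - 0.5) * 4)
    hm <- render_target_heatmap(pts, box, size = size, sigma_hm = 2)
    peaks <- extract_keypoints(hm, value_threshold = 0.3, min_separation = 2)
    got <- do.call(rbind, lapply(peaks, function(p) as.integer(p$grid_cell)))
    expect_equal(nrow(got), k)
    expect_setequal(paste(got[, 1], got[, 2]), paste(cells[, 1], cells[, 2]))
  }
})

test_that("extracted peaks respect separation, threshold, cap, and tie order", {
  set.seed(71)
  box <- mt_box(0, 0, 64, 64)
  for (rep in 1:20) {
    grid <- matrix(runif(32 * 32), 32, 32)
    hm <- structure(list(grid = grid, box = box, size = 32), class = "mt_heatmap")
    pk <- extract_keypoints(hm, value_threshold = 0.5, min_separation = 4,
                            max_points = 5)
    expect_lte(length(pk), 5)
    if (length(pk) > 1) {
      cells <- do.call(rbind, lapply(pk, function(p) as.numeric(p$grid_cell)))
      for (i in seq_len(nrow(cells) - 1)) {
        cheb <- pmax(abs(cells[-(1:i), 1, drop = FALSE] - cells[i, 1]),
                     abs(cells[-(1:i), 2, drop = FALSE] - cells[i, 2]))
        expect_true(all(cheb >= 4))
      }
    }
    expect_true(all(vapply(pk, `[[`, numeric(1), "value") >= 0.5))
    # determinism
    pk2 <- extract_keypoints(hm, value_threshold = 0.5, min_separation = 4,
                             max_points = 5)
    expect_identical(pk, pk2)
  }
  # plateau ties break lexicographically by (row, col): a uniform plateau has
  # no strict local maxima, so embed two equal isolated peaks instead
  g <- matrix(0, 16, 16)
  g[4, 10] <- 0.8; g[4, 3] <- 0.8
  hm <- structure(list(grid = g, box = box, size = 16), class = "mt_heatmap")
  pk <- extract_keypoints(hm, value_threshold = 0.3, min_separation = 2)
  cells <- do.call(rbind, lapply(pk, function(p) as.integer(p$grid_cell)))
  expect_equal(cells[1, ], c(4L, 3L))  # equal values: lower column first
  expect_equal(cells[2, ], c(4L, 10L))
})

test_that("keypoint_loss is the mean per-cell BCE with the right limits", {
  target_half <- matrix(0.5, 8, 8)
  expect_equal(keypoint_loss(matrix(0, 8, 8), target_half), log(2))
  target0 <- matrix(0, 8, 8)
  expect_lt(keypoint_loss(matrix(-50, 8, 8), target0), 1e-6)
  expect_error(keypoint_loss(matrix(0, 8, 8), matrix(0, 4, 4)), "shape")
  # matched logits are (near) optimal against their own sigmoid target
  set.seed(5)
  z <- matrix(rnorm(64, 0, 3), 8, 8)
  t <- 1 / (1 + exp(-z))
  expect_gte(keypoint_loss(matrix(rnorm(64), 8, 8), t), keypoint_loss(z, t))
})
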