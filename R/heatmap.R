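# Single-heatmap keypoint representation: every trajectory point of one
# detected instance lives in one probability grid registered to the
# detection box. Rendering builds the Gaussian training target; peak
# extraction inverts it at inference.
#
# Grid convention: size x size matrix indexed [row, col] (row = y), 1-based.
# The box-to-grid affine map sends image point (x, y) inside box
# (x1, y1, x2, y2) to cell col = floor((x - x1) / w * S) + 1 (clamped),
# likewise for rows; the inverse maps a cell to its center
# x = x1 + (col - 0.5) * w / S.

kp_to_cell <- function(xy, box, size) {
  w <- box[3] - box[1]; h <- box[4] - box[2]
  col <- floor((xy[1] - box[1]) / w * size) + 1
  row <- floor((xy[2] - box[2]) / h * size) + 1
  c(row = min(max(row, 1), size), col = min(max(col, 1), size))
}

cell_to_image <- function(row, col, box, size) {
  w <- box[3] - box[1]; h <- box[4] - box[2]
  c(x = box[1] + (col - 0.5) * w / size,
    y = box[2] + (row - 0.5) * h / size)
}

#' Render a Gaussian target heatmap for an instance's keypoints
#'
#' Maps each keypoint into the `size x size` grid registered to the box
#' (points outside the box are clipped to the boundary cell) and renders an
#' unnormalized Gaussian of scale `sigma_hm` grid cells centered on the
#' keypoint's cell, with peak value exactly 1 there. Overlapping Gaussians
#' are combined by the pointwise maximum, so an arbitrary number of
#' trajectory points coexist in the one channel. An empty keypoint list
#' yields the all-zero heatmap.
#'
#' @param keypoints An `n x 2` matrix of image-coordinate points (may be empty).
#' @param box The registration box `c(x1, y1, x2, y2)` with positive area.
#' @param size Grid side length, `>= 2`.
#' @param sigma_hm Gaussian scale in grid cells, `> 0`.
#' @return A list of class `mt_heatmap` with `grid` (values in `[0, 1]`),
#'   `box`, and `size`.
#' @export
render_target_heatmap <- function(keypoints, box, size = 56, sigma_hm = 2) {
  if (size < 2) stop("heatmap size must be >= 2")
  if (sigma_hm <= 0) stop("sigma_hm must be > 0")
  if (box[3] <= box[1] || box[4] <= box[2]) stop("registration box must have positive area")
  grid <- matrix(0, size, size)
  keypoints <- if (is.null(keypoints) || NROW(keypoints) == 0) {
    matrix(numeric(0), ncol = 2)
  } else as_points_matrix(keypoints)
  if (nrow(keypoints) > 0) {
    rows <- matrix(rep(seq_len(size), size), size, size)
    cols <- t(rows)
    for (i in seq_len(nrow(keypoints))) {
      cell <- kp_to_cell(keypoints[i, ], box, size)
      g <- exp(-((rows - cell["row"])^2 + (cols - cell["col"])^2) / (2 * sigma_hm^2))
      grid <- pmax(grid, g)
    }
  }
  structure(list(grid = grid, box = box, size = size), class = "mt_heatmap")
}

#' Extract keypoints from a detection's heatmap
#'
#' Candidate cells are strict local maxima over the 8-neighborhood with value
#' at least `value_threshold`. Candidates are then kept greedily in
#' descending value order (ties broken by row, then column), suppressing any
#' candidate within `min_separation` (Chebyshev distance) of an already-kept
#' peak, up to `max_points`. Kept cell centers are mapped back to image
#' coordinates through the inverse of the box-to-grid affine map.
#'
#' @param hm An `mt_heatmap` (or a list with `grid` and `box`).
#' @param box Optional override of the registration box.
#' @param value_threshold Minimum peak value, in `[0, 1]`.
#' @param min_separation Minimum Chebyshev distance between kept peaks, cells.
#' @param max_points Maximum number of peaks returned.
#' @return A list of peaks, each with `grid_cell` `c(row, col)`, `value`, and
#'   `image_xy` `c(x, y)`; empty when nothing clears the threshold.
#' @export
extract_keypoints <- function(hm, box = NULL, value_threshold = 0.3,
                              min_separation = 2, max_points = 32) {
  grid <- hm$grid
  if (is.null(grid) || !is.matrix(grid)) stop("malformed heatmap: no grid matrix")
  if (value_threshold < 0 || value_threshold > 1) stop("value_threshold must be in [0, 1]")
  if (is.null(box)) box <- hm$box
  S <- nrow(grid)
  # strict local maxima over the 8-neighborhood (borders padded with -Inf)
  pad <- matrix(-Inf, S + 2, S + 2)
  pad[2:(S + 1), 2:(S + 1)] <- grid
  is_max <- matrix(TRUE, S, S)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- pad[(2 + dr):(S + 1 + dr), (2 + dc):(S + 1 + dc)]
    is_max <- is_max & (grid > nb)
  }
  cand <- which(is_max & grid >= value_threshold, arr.ind = TRUE)
  if (nrow(cand) == 0) return(list())
  vals <- grid[cand]
  ord <- order(-vals, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  vals <- vals[ord]
  kept <- matrix(numeric(0), ncol = 2)
  kept_vals <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    if (nrow(kept) >= max_points) break
    if (nrow(kept) > 0) {
      cheb <- pmax(abs(kept[, 1] - cand[i, 1]), abs(kept[, 2] - cand[i, 2]))
      if (any(cheb < min_separation)) next
    }
    kept <- rbind(kept, cand[i, ])
    kept_vals <- c(kept_vals, vals[i])
  }
  lapply(seq_len(nrow(kept)), function(i) {
    xy <- cell_to_image(kept[i, 1], kept[i, 2], box, S)
    list(grid_cell = c(row = kept[i, 1], col = kept[i, 2]),
         value = kept_vals[i],
         image_xy = unname(xy))
  })
}
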