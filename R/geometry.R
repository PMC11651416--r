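# Box and trajectory geometry: overlap measures and the line-distance metric.
#
# Boxes are numeric vectors c(x1, y1, x2, y2) in 0-based pixel coordinates
# with the corner convention x1 <= x2, y1 <= y2 and area (x2-x1)*(y2-y1).
# Polylines / point sets are n x 2 matrices with columns (x, y).

#' Construct an axis-aligned box
#'
#' @param x1,y1,x2,y2 Corner coordinates in pixels; `x1 <= x2`, `y1 <= y2`.
#' @return A numeric vector `c(x1, y1, x2, y2)` of class `mt_box`.
#' @export
mt_box <- function(x1, y1, x2, y2) {
  b <- c(x1, y1, x2, y2)
  if (any(!is.finite(b))) stop("box coordinates must be finite")
  if (x2 < x1 || y2 < y1) stop("box corners must satisfy x1 <= x2, y1 <= y2")
  structure(as.numeric(b), class = "mt_box")
}

box_area <- function(b) (b[3] - b[1]) * (b[4] - b[2])

box_center <- function(b) c((b[1] + b[3]) / 2, (b[2] + b[4]) / 2)

#' Intersection over union of two boxes
#'
#' The ratio of the intersection area to the union area. Degenerate unions
#' (both boxes of zero area) yield 0.
#'
#' @param a,b Boxes as `c(x1, y1, x2, y2)`.
#' @return A fraction in `[0, 1]`.
#' @export
iou <- function(a, b) {
  ix <- min(a[3], b[3]) - max(a[1], b[1])
  iy <- min(a[4], b[4]) - max(a[2], b[2])
  if (ix <= 0 || iy <= 0) return(0)
  inter <- ix * iy
  un <- box_area(a) + box_area(b) - inter
  if (un <= 0) return(0)
  inter / un
}

#' Distance-IoU of two boxes
#'
#' IoU minus a center-distance penalty: `iou(a, b) - rho^2 / c^2`, where
#' `rho` is the Euclidean distance between the two box centers and `c` the
#' diagonal length of the smallest box enclosing both. Always `<= iou(a, b)`,
#' with equality exactly when the centers coincide.
#'
#' @param a,b Boxes as `c(x1, y1, x2, y2)`.
#' @return A score in `(-1, 1]`.
#' @export
diou <- function(a, b) {
  ca <- box_center(a); cb <- box_center(b)
  ex <- max(a[3], b[3]) - min(a[1], b[1])
  ey <- max(a[4], b[4]) - min(a[2], b[2])
  c2 <- ex^2 + ey^2
  if (c2 <= 0) stop("diou undefined: both boxes degenerate to the same point")
  rho2 <- sum((ca - cb)^2)
  iou(a, b) - rho2 / c2
}

#' Shortest distance from a point to a line segment
#'
#' Projects `p` onto the segment `[a, b]`. With `C = <AB, AP>` and projection
#' parameter `t = C / |AB|^2`, the distance is to `a` when `t <= 0`
#' (`foot_before_A`), to `b` when `t >= 1` (`foot_after_B`), and to the
#' perpendicular foot otherwise (`foot_interior`). A zero-length segment
#' degenerates to the distance to the single point, case `foot_before_A`.
#'
#' @param p Point `c(x, y)`.
#' @param a,b Segment endpoints `c(x, y)`.
#' @return A list with `case` (one of `"foot_before_A"`, `"foot_after_B"`,
#'   `"foot_interior"`), `distance` (pixels), and `foot` (the perpendicular
#'   foot, present only for `foot_interior`).
#' @export
point_segment_distance <- function(p, a, b) {
  if (any(!is.finite(c(p, a, b)))) stop("coordinates must be finite")
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) {
    return(list(case = "foot_before_A", distance = sqrt(sum((p - a)^2)), foot = NULL))
  }
  cc <- sum(ab * (p - a))
  t <- cc / len2
  if (t <= 0) {
    list(case = "foot_before_A", distance = sqrt(sum((p - a)^2)), foot = NULL)
  } else if (t >= 1) {
    list(case = "foot_after_B", distance = sqrt(sum((p - b)^2)), foot = NULL)
  } else {
    foot <- a + t * ab
    list(case = "foot_interior", distance = sqrt(sum((p - foot)^2)), foot = foot)
  }
}

#' Shortest distance from a point to a polyline
#'
#' Minimum of [point_segment_distance()] over consecutive vertex pairs; a
#' single-vertex polyline degenerates to the plain point distance.
#'
#' @param p Point `c(x, y)`.
#' @param polyline An `n x 2` matrix of ordered vertices, `n >= 1`.
#' @return Distance in pixels.
#' @export
point_polyline_distance <- function(p, polyline) {
  polyline <- as_points_matrix(polyline)
  n <- nrow(polyline)
  if (n == 0) stop("polyline must have at least one vertex")
  if (n == 1) return(sqrt(sum((p - polyline[1, ])^2)))
  # vectorized over segments
  ax <- polyline[-n, 1]; ay <- polyline[-n, 2]
  bx <- polyline[-1, 1]; by <- polyline[-1, 2]
  abx <- bx - ax; aby <- by - ay
  len2 <- abx^2 + aby^2
  t <- ifelse(len2 > 0, ((p[1] - ax) * abx + (p[2] - ay) * aby) / pmax(len2, .Machine$double.xmin), 0)
  t <- pmin(pmax(t, 0), 1)
  fx <- ax + t * abx; fy <- ay + t * aby
  min(sqrt((p[1] - fx)^2 + (p[2] - fy)^2))
}

#' Line distance of a predicted point set to a ground-truth trajectory
#'
#' The mean, over the `M` predicted points, of each point's shortest distance
#' to the ground-truth polyline: the per-target `LD` underlying [mean_line_distance()].
#'
#' @param pred_points An `M x 2` matrix of predicted trajectory points, `M >= 1`.
#' @param gt_polyline A `G x 2` matrix of ordered ground-truth vertices, `G >= 1`.
#' @return `LD` in pixels.
#' @export
line_distance <- function(pred_points, gt_polyline) {
  pred_points <- as_points_matrix(pred_points)
  if (nrow(pred_points) == 0) stop("need at least one predicted point")
  d <- vapply(seq_len(nrow(pred_points)), function(i) {
    point_polyline_distance(pred_points[i, ], gt_polyline)
  }, numeric(1))
  mean(d)
}

as_points_matrix <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 2, byrow = FALSE)
  x <- as.matrix(x)
  if (ncol(x) != 2) stop("points must be an n x 2 matrix")
  storage.mode(x) <- "double"
  x
}

#' Match detections to ground-truth targets
#'
#' Greedy one-to-one matching in descending detection-score order: each
#' detection is paired with the unmatched same-class ground truth of highest
#' box IoU, provided that IoU reaches `iou_threshold`. Deterministic given its
#' inputs (score ties broken by detection index).
#'
#' @param dets List of detections, each a list with `box`, `class`
#'   (`"leaf"`/`"stalk"`), `score`, and optionally `keypoints`.
#' @param gts List of ground truths, each a list with `box`, `category`, and
#'   `points` (the annotated trajectory, a `G x 2` matrix).
#' @param iou_threshold Minimum box IoU for a pair, in `[0, 1]`.
#' @return A list of class `mt_match_table` with `pairs` (two-column matrix of
#'   detection index, ground-truth index), `unmatched_detections`,
#'   `unmatched_ground_truths`.
#' @export
match_detections <- function(dets, gts, iou_threshold = 0.5) {
  if (iou_threshold < 0 || iou_threshold > 1) stop("iou_threshold must be in [0, 1]")
  nd <- length(dets); ng <- length(gts)
  pairs <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("det", "gt")))
  gt_used <- rep(FALSE, ng)
  det_used <- rep(FALSE, nd)
  if (nd > 0 && ng > 0) {
    scores <- vapply(dets, function(d) d$score, numeric(1))
    ord <- order(-scores, seq_len(nd))
    for (i in ord) {
      best_j <- 0L; best_iou <- -1
      for (j in seq_len(ng)) {
        if (gt_used[j]) next
        if (!identical(dets[[i]]$class, gts[[j]]$category)) next
        v <- iou(dets[[i]]$box, gts[[j]]$box)
        if (v > best_iou) { best_iou <- v; best_j <- j }
      }
      if (best_j > 0L && best_iou >= iou_threshold) {
        pairs <- rbind(pairs, c(i, best_j))
        gt_used[best_j] <- TRUE
        det_used[i] <- TRUE
      }
    }
  }
  structure(list(
    pairs = pairs,
    unmatched_detections = which(!det_used),
    unmatched_ground_truths = which(!gt_used)
  ), class = "mt_match_table")
}

#' Mean line distance over matched targets
#'
#' For each matched detection/ground-truth pair `k`, `LD_k` is the average
#' shortest distance from the detection's `M` predicted trajectory points to
#' the ground-truth polyline; `mLD` is the arithmetic mean of `LD_k` over the
#' `K` matched pairs. Matched detections without predicted points contribute
#' no `LD` and are dropped from `K`. With `K = 0`, `mld` is `NA`.
#'
#' @param matches A match table from [match_detections()].
#' @param dets,gts The detection and ground-truth lists the table refers to.
#' @return A list of class `mt_ld_report` with `per_target_ld`, `mld`, `K`,
#'   `M` (predicted-point counts), `G` (ground-truth vertex counts), and the
#'   `pairs` used.
#' @export
mean_line_distance <- function(matches, dets, gts) {
  pairs <- matches$pairs
  lds <- numeric(0); Ms <- integer(0); Gs <- integer(0)
  keep <- matrix(integer(0), ncol = 2)
  if (nrow(pairs) > 0) {
    for (r in seq_len(nrow(pairs))) {
      d <- dets[[pairs[r, 1]]]
      g <- gts[[pairs[r, 2]]]
      kp <- d$keypoints
      if (is.null(kp) || NROW(kp) == 0) next
      kp <- as_points_matrix(kp[, 1:2, drop = FALSE])
      lds <- c(lds, line_distance(kp, g$points))
      Ms <- c(Ms, nrow(kp))
      Gs <- c(Gs, NROW(g$points))
      keep <- rbind(keep, pairs[r, , drop = FALSE])
    }
  }
  K <- length(lds)
  structure(list(
    per_target_ld = lds,
    mld = if (K > 0) mean(lds) else NA_real_,
    K = K, M = Ms, G = Gs,
    pairs = keep,
    unmatched_detections = matches$unmatched_detections,
    unmatched_ground_truths = matches$unmatched_ground_truths
  ), class = "mt_ld_report")
}

#' @export
print.mt_ld_report <- function(x, ...) {
  cat("Mean line distance report\n")
  cat(sprintf("  matched targets (K): %d\n", x$K))
  cat(sprintf("  unmatched detections: %d, unmatched ground truths: %d\n",
              length(x$unmatched_detections), length(x$unmatched_ground_truths)))
  if (x$K > 0) {
    cat(sprintf("  mLD: %.3f px  (per-target LD range %.3f - %.3f)\n",
                x$mld, min(x$per_target_ld), max(x$per_target_ld)))
  } else {
    cat("  mLD: undefined (no matched targets)\n")
  }
  invisible(x)
}
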