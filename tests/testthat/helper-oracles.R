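# Independent brute-force oracles used to validate the closed-form
# implementations.

# shortest distance from p to segment [a, b] by dense sampling
oracle_segment_distance <- function(p, a, b, n = 1e5) {
  t <- seq(0, 1, length.out = n)
  min(sqrt((p[1] - (a[1] + t * (b[1] - a[1])))^2 +
           (p[2] - (a[2] + t * (b[2] - a[2])))^2))
}

oracle_polyline_distance <- function(p, poly, n = 1e4) {
  if (nrow(poly) == 1) return(sqrt(sum((p - poly[1, ])^2)))
  min(vapply(seq_len(nrow(poly) - 1), function(i) {
    oracle_segment_distance(p, poly[i, ], poly[i + 1, ], n)
  }, numeric(1)))
}

# IoU by counting covered cells on a fine grid over the union extent
oracle_iou_raster <- function(a, b, n = 400) {
  x1 <- min(a[1], b[1]); x2 <- max(a[3], b[3])
  y1 <- min(a[2], b[2]); y2 <- max(a[4], b[4])
  xs <- seq(x1, x2, length.out = n); ys <- seq(y1, y2, length.out = n)
  gx <- matrix(rep(xs, each = n), n); gy <- matrix(rep(ys, times = n), n)
  ina <- gx >= a[1] & gx <= a[3] & gy >= a[2] & gy <= a[4]
  inb <- gx >= b[1] & gx <= b[3] & gy >= b[2] & gy <= b[4]
  un <- sum(ina | inb)
  if (un == 0) return(0)
  sum(ina & inb) / un
}

# greedy hard-NMS reference: repeatedly take the top survivor, drop overlaps
oracle_hard_nms <- function(boxes, scores, thr) {
  alive <- rep(TRUE, nrow(boxes))
  kept <- integer(0)
  while (any(alive)) {
    i <- which(alive)[which.max(scores[alive])]
    kept <- c(kept, i)
    alive[i] <- FALSE
    for (j in which(alive)) {
      if (iou(boxes[i, ], boxes[j, ]) > thr) alive[j] <- FALSE
    }
  }
  kept
}

# all-point-interpolated AP from first principles: for each ground truth
# rank k, the envelope precision at recall >= k / n_gt
oracle_ap <- function(tp_sorted, n_gt) {
  if (n_gt == 0 || length(tp_sorted) == 0) return(0)
  prec <- cumsum(tp_sorted) / seq_along(tp_sorted)
  rec <- cumsum(tp_sorted) / n_gt
  total <- 0
  for (k in seq_len(n_gt)) {
    r <- k / n_gt
    cand <- prec[rec >= r - 1e-12]
    if (length(cand) > 0) total <- total + max(cand)
  }
  total / n_gt
}

# random valid box within a field
random_box <- function(lim = 100, min_side = 2) {
  x1 <- runif(1, 0, lim - min_side); y1 <- runif(1, 0, lim - min_side)
  c(x1, y1, x1 + runif(1, min_side, lim - x1), y1 + runif(1, min_side, lim - y1))
}
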