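# Non-maximum suppression variants. Suppression is always class-wise:
# leaves and stalks never suppress each other.

#' Hard non-maximum suppression
#'
#' Per class, iteratively keeps the highest-score box and discards any
#' remaining box whose IoU with it exceeds `overlap_threshold`.
#'
#' @param dets List of scored boxes, each a list with `box`, `score`, and
#'   `class_id` (or `class`).
#' @param overlap_threshold IoU above which a lower-scored box is discarded,
#'   in `[0, 1]`.
#' @return The kept subset, sorted by score descending.
#' @export
hard_nms <- function(dets, overlap_threshold = 0.5) {
  if (overlap_threshold < 0 || overlap_threshold > 1) {
    stop("overlap_threshold must be in [0, 1]")
  }
  soft <- soft_nms(dets, sigma = 1, score_floor = 0, overlap_fn = "iou",
                   hard_threshold = overlap_threshold)
  soft
}

#' Soft non-maximum suppression with Gaussian score decay
#'
#' Iteratively selects the highest-score remaining box, then rescales every
#' other remaining score by `exp(-o^2 / sigma)`, where `o` is the overlap of
#' that box with the selected one (`max(overlap, 0)`; relevant for the D-IoU
#' overlap, which can be negative). Boxes whose score falls below
#' `score_floor` are dropped. With `overlap_fn = "diou"` this is the
#' distance-IoU-integrated variant: because `diou <= iou`, its decay is never
#' stronger than plain-IoU decay on the same input.
#'
#' @param dets List of scored boxes (`box`, `score`, `class_id` or `class`).
#' @param sigma Gaussian decay scale, `> 0`.
#' @param score_floor Scores below this are removed, in `[0, 1)`.
#' @param overlap_fn `"iou"` or `"diou"`.
#' @param hard_threshold Internal: when non-`NULL`, boxes overlapping a keeper
#'   above this threshold are removed outright instead of decayed (classic NMS).
#' @return The surviving boxes with (possibly decayed) scores, sorted by final
#'   score descending within the original class structure.
#' @export
soft_nms <- function(dets, sigma = 0.5, score_floor = 0.001,
                     overlap_fn = c("iou", "diou"), hard_threshold = NULL) {
  if (sigma <= 0) stop("sigma must be > 0")
  if (score_floor < 0 || score_floor >= 1) stop("score_floor must be in [0, 1)")
  overlap_fn <- match.arg(overlap_fn)
  ov <- if (overlap_fn == "iou") iou else diou
  if (length(dets) == 0) return(dets)

  cls <- vapply(dets, det_class_key, character(1))
  out <- list()
  for (cl in unique(cls)) {
    idx <- which(cls == cl)
    pool <- dets[idx]
    scores <- vapply(pool, function(d) d$score, numeric(1))
    alive <- rep(TRUE, length(pool))
    kept <- list()
    while (any(alive)) {
      i <- which(alive)[which.max(scores[alive])]
      d <- pool[[i]]
      d$score <- scores[i]
      kept[[length(kept) + 1]] <- d
      alive[i] <- FALSE
      for (j in which(alive)) {
        o <- max(ov(pool[[i]]$box, pool[[j]]$box), 0)
        if (!is.null(hard_threshold)) {
          if (o > hard_threshold) alive[j] <- FALSE
        } else {
          scores[j] <- scores[j] * exp(-o^2 / sigma)
          if (scores[j] < score_floor) alive[j] <- FALSE
        }
      }
      if (is.null(hard_threshold)) {
        # floor of 0 keeps everything; guard against infinite loops is the
        # alive bookkeeping itself (the selected box always leaves the pool)
        alive[scores < score_floor & alive] <- FALSE
      }
    }
    out <- c(out, kept)
  }
  fs <- vapply(out, function(d) d$score, numeric(1))
  out[order(-fs)]
}

det_class_key <- function(d) {
  if (!is.null(d$class_id)) as.character(d$class_id)
  else if (!is.null(d$class)) as.character(d$class)
  else "0"
}

#' Apply the configured suppression mode
#'
#' Dispatch helper used by the prediction pipeline: `mode` is one of
#' `"hard"`, `"soft"` (Gaussian Soft-NMS on IoU) or `"soft_diou"` (Gaussian
#' Soft-NMS on distance-IoU, the combination used for heavily occluded
#' scenes).
#'
#' @param dets List of scored boxes.
#' @param mode Suppression mode.
#' @param iou_threshold Hard-NMS discard threshold.
#' @param sigma,score_floor Soft-NMS parameters.
#' @return Surviving boxes, score-sorted.
#' @export
apply_nms <- function(dets, mode = c("soft_diou", "soft", "hard"),
                      iou_threshold = 0.5, sigma = 0.5, score_floor = 0.001) {
  mode <- match.arg(mode)
  switch(mode,
    hard = hard_nms(dets, iou_threshold),
    soft = soft_nms(dets, sigma, score_floor, "iou"),
    soft_diou = soft_nms(dets, sigma, score_floor, "diou")
  )
}
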