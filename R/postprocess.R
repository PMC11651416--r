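# From raw detector output to final trajectory predictions: box-level
# suppression first, then heatmap peak extraction on the survivors only.

#' Convert raw detections into final trajectory predictions
#'
#' Applies the configured box-level suppression ([apply_nms()]) to the raw
#' detections, then runs [extract_keypoints()] on each survivor's heatmap;
#' suppressed detections contribute no keypoints. The result is the
#' detection list consumed by [mean_line_distance()] and
#' [evaluate_detections()].
#'
#' @param raw_dets Raw detections from [forward_image()] (each with `box`,
#'   `class`, `score`, `heatmap`).
#' @param nms List: `mode` (`"hard"`, `"soft"`, `"soft_diou"`),
#'   `iou_threshold`, `sigma`, `score_floor`.
#' @param peak List: `value_threshold`, `min_separation`, `max_points`.
#' @return List of final detections, each with `box`, `class`, `score`, and
#'   `keypoints` (an `M x 3` matrix of `x`, `y`, peak value; zero rows when
#'   no peak clears the threshold).
#' @export
detections_to_predictions <- function(raw_dets,
                                      nms = list(mode = "soft_diou",
                                                 iou_threshold = 0.5,
                                                 sigma = 0.5, score_floor = 0.05),
                                      peak = list(value_threshold = 0.3,
                                                  min_separation = 2,
                                                  max_points = 32)) {
  if (length(raw_dets) == 0) return(list())
  kept <- apply_nms(raw_dets, mode = nms$mode,
                    iou_threshold = if (is.null(nms$iou_threshold)) 0.5 else nms$iou_threshold,
                    sigma = if (is.null(nms$sigma)) 0.5 else nms$sigma,
                    score_floor = if (is.null(nms$score_floor)) 0.05 else nms$score_floor)
  lapply(kept, function(d) {
    pk <- extract_keypoints(d$heatmap, box = d$box,
                            value_threshold = peak$value_threshold,
                            min_separation = peak$min_separation,
                            max_points = peak$max_points)
    kp <- if (length(pk) == 0) {
      matrix(numeric(0), ncol = 3, dimnames = list(NULL, c("x", "y", "value")))
    } else {
      do.call(rbind, lapply(pk, function(p) c(p$image_xy, p$value)))
    }
    list(box = d$box, class = d$class, class_id = d$class_id,
         score = d$score, keypoints = kp)
  })
}

#' Write predictions to JSON
#'
#' Per image: a list of `{class, score, bbox [x, y, w, h], keypoints
#' [[x, y, value], ...]}` records.
#'
#' @param preds Per-image prediction lists from [predict_images()].
#' @param path Destination JSON path.
#' @param image_names Optional image identifiers (default indices).
#' @return `path`, invisibly.
#' @export
write_predictions <- function(preds, path, image_names = NULL) {
  if (is.null(image_names)) image_names <- as.character(seq_along(preds))
  doc <- lapply(seq_along(preds), function(i) {
    list(image = image_names[i],
         detections = lapply(preds[[i]], function(d) {
           list(class = d$class, score = d$score,
                bbox = c(d$box[1], d$box[2], d$box[3] - d$box[1], d$box[4] - d$box[2]),
                keypoints = if (nrow(d$keypoints) > 0) {
                  lapply(seq_len(nrow(d$keypoints)), function(r) as.numeric(d$keypoints[r, ]))
                } else list())
         }))
  })
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read predictions written by [write_predictions()]
#'
#' @param path Predictions JSON path.
#' @return Per-image list of detections (`box`, `class`, `score`, `keypoints`).
#' @export
read_predictions <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(doc, function(im) {
    lapply(im$detections, function(d) {
      bb <- as.numeric(unlist(d$bbox))
      kp <- if (length(d$keypoints) > 0) {
        do.call(rbind, lapply(d$keypoints, function(p) as.numeric(unlist(p))))
      } else matrix(numeric(0), ncol = 3)
      list(box = mt_box(bb[1], bb[2], bb[1] + bb[3], bb[2] + bb[4]),
           class = d$class, score = d$score, keypoints = kp)
    })
  })
}
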