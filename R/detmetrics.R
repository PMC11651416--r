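# Detection metrics: precision, recall, per-class AP, and mAP at box-IoU
# thresholds 0.5 / 0.75, with the PR/confidence curves behind them.
#
# Matching per class: detections sorted by score descending; each detection
# claims the unmatched ground truth (same image, same class) of highest IoU,
# and counts as a true positive when that IoU reaches the threshold.
# Duplicate detections of one ground truth count one TP + rest FP. AP is the
# area under the precision-recall curve with all-point interpolation (the
# monotone precision envelope).

#' Evaluate detections against ground truth
#'
#' @param dets List over images: each element a list of detections
#'   (`box`, `class`, `score`).
#' @param gts List over images (same length/order): each element a list of
#'   ground truths (`box`, `category`).
#' @param iou_thresholds IoU thresholds to evaluate; default `c(0.5, 0.75)`.
#' @return A list of class `mt_eval_report`: per threshold, per-class `ap`,
#'   `map`, and the PR curve (`confidence`, `precision`, `recall`, `f1` per
#'   detection rank, pooled over classes); `map50`/`map75` shortcuts when the
#'   default thresholds are used.
#' @export
evaluate_detections <- function(dets, gts, iou_thresholds = c(0.5, 0.75)) {
  stopifnot(length(dets) == length(gts))
  out <- list()
  for (thr in iou_thresholds) {
    per_class <- list()
    for (cl in CATEGORIES) {
      per_class[[cl]] <- ap_one_class(dets, gts, cl, thr)
    }
    aps <- vapply(per_class, function(p) p$ap, numeric(1))
    curve <- pooled_curve(dets, gts, thr)
    out[[sprintf("iou_%g", thr)]] <- list(
      threshold = thr,
      ap = aps,
      map = mean(aps),
      curve = curve,
      per_class = per_class
    )
  }
  rep <- structure(list(thresholds = iou_thresholds, results = out),
                   class = "mt_eval_report")
  if (0.5 %in% iou_thresholds) rep$map50 <- out[[sprintf("iou_%g", 0.5)]]$map
  if (0.75 %in% iou_thresholds) rep$map75 <- out[[sprintf("iou_%g", 0.75)]]$map
  rep
}

# score-ordered TP/FP flags for one class at one threshold
match_flags <- function(dets, gts, cl, thr) {
  scores <- numeric(0); tp <- logical(0)
  n_gt <- 0L
  for (i in seq_along(dets)) {
    g_idx <- which(vapply(gts[[i]], function(g) identical(g$category, cl), logical(1)))
    n_gt <- n_gt + length(g_idx)
    d_idx <- which(vapply(dets[[i]], function(d) identical(d$class, cl), logical(1)))
    if (length(d_idx) == 0) next
    d_sc <- vapply(dets[[i]][d_idx], function(d) d$score, numeric(1))
    ord <- d_idx[order(-d_sc, seq_along(d_idx))]
    used <- rep(FALSE, length(g_idx))
    for (di in ord) {
      best <- 0; best_j <- 0L
      for (jj in seq_along(g_idx)) {
        if (used[jj]) next
        v <- iou(dets[[i]][[di]]$box, gts[[i]][[g_idx[jj]]]$box)
        if (v > best) { best <- v; best_j <- jj }
      }
      hit <- best_j > 0L && best >= thr
      if (hit) used[best_j] <- TRUE
      scores <- c(scores, dets[[i]][[di]]$score)
      tp <- c(tp, hit)
    }
  }
  ord <- order(-scores)
  list(scores = scores[ord], tp = tp[ord], n_gt = n_gt)
}

ap_one_class <- function(dets, gts, cl, thr) {
  mf <- match_flags(dets, gts, cl, thr)
  n_det <- length(mf$tp)
  if (mf$n_gt == 0) {
    if (n_det > 0) warning(sprintf("detections present for class '%s' but no ground truths; AP set to 0", cl))
    return(list(ap = 0, precision = numeric(0), recall = numeric(0),
                scores = mf$scores, n_gt = 0L))
  }
  if (n_det == 0) {
    return(list(ap = 0, precision = numeric(0), recall = numeric(0),
                scores = numeric(0), n_gt = mf$n_gt))
  }
  ctp <- cumsum(mf$tp)
  prec <- ctp / seq_len(n_det)
  rec <- ctp / mf$n_gt
  list(ap = ap_all_point(prec, rec), precision = prec, recall = rec,
       scores = mf$scores, n_gt = mf$n_gt)
}

# area under PR with the monotone precision envelope (all-point interpolation)
ap_all_point <- function(precision, recall) {
  if (length(precision) == 0) return(0)
  mrec <- c(0, recall, recall[length(recall)])
  mpre <- c(0, precision, 0)
  for (i in rev(seq_len(length(mpre) - 1))) {
    mpre[i] <- max(mpre[i], mpre[i + 1])
  }
  idx <- which(mrec[-1] != mrec[-length(mrec)])
  sum((mrec[idx + 1] - mrec[idx]) * mpre[idx + 1])
}

pooled_curve <- function(dets, gts, thr) {
  rows <- list()
  for (cl in CATEGORIES) {
    mf <- match_flags(dets, gts, cl, thr)
    if (length(mf$tp) > 0) {
      rows[[cl]] <- data.frame(score = mf$scores, tp = mf$tp, n_gt = mf$n_gt,
                               class = cl, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(confidence = numeric(0), precision = numeric(0),
                      recall = numeric(0), f1 = numeric(0)))
  }
  df <- do.call(rbind, rows)
  df <- df[order(-df$score), , drop = FALSE]
  total_gt <- sum(vapply(gts, length, integer(1)))
  ctp <- cumsum(df$tp)
  prec <- ctp / seq_len(nrow(df))
  rec <- if (total_gt > 0) ctp / total_gt else rep(0, nrow(df))
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  data.frame(confidence = df$score, precision = prec, recall = rec, f1 = f1)
}

#' @export
print.mt_eval_report <- function(x, ...) {
  cat("Detection evaluation\n")
  for (nm in names(x$results)) {
    r <- x$results[[nm]]
    cat(sprintf("  IoU %.2f: mAP %.4f (%s)\n", r$threshold, r$map,
                paste(sprintf("%s %.4f", names(r$ap), r$ap), collapse = ", ")))
  }
  invisible(x)
}

#' Export PR/confidence curves to CSV (and optionally PNG plots)
#'
#' Writes the pooled curve of an evaluation result as CSV with columns
#' `confidence`, `precision`, `recall`, `f1` (values round-trip exactly), and,
#' when `plot = TRUE`, renders precision-recall and F1-confidence plots as
#' PNG files next to it.
#'
#' @param curve A curve data frame (from `evaluate_detections()$results[[i]]$curve`).
#' @param out_path CSV destination path.
#' @param plot Also write PNG plots (default `TRUE`).
#' @return Paths of the written files, invisibly.
#' @export
export_curves <- function(curve, out_path, plot = TRUE) {
  if (is.null(curve) || nrow(curve) == 0) stop("cannot export an empty curve")
  utils::write.csv(curve, out_path, row.names = FALSE)
  written <- out_path
  if (plot) {
    base <- sub("\\.csv$", "", out_path)
    pr_png <- paste0(base, "_pr.png")
    f1_png <- paste0(base, "_f1.png")
    ok <- try({
      grDevices::png(pr_png, width = 600, height = 480)
      graphics::plot(curve$recall, curve$precision, type = "l", xlim = c(0, 1),
                     ylim = c(0, 1), xlab = "Recall", ylab = "Precision",
                     main = "Precision-recall")
      grDevices::dev.off()
      grDevices::png(f1_png, width = 600, height = 480)
      graphics::plot(curve$confidence, curve$f1, type = "l", ylim = c(0, 1),
                     xlab = "Confidence", ylab = "F1", main = "F1-confidence")
      grDevices::dev.off()
    }, silent = TRUE)
    if (!inherits(ok, "try-error")) written <- c(written, pr_png, f1_png)
  }
  invisible(written)
}
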