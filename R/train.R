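# Training: SGD with momentum and step learning-rate decay over per-image
# gradient steps. Each step supervises the RPN (objectness + box deltas on
# sampled anchors), the box head (class + box regression on sampled
# proposals, with ground-truth boxes added to the proposal pool), and the
# keypoint branch (per-cell BCE against max-combined Gaussian targets on
# sampled foreground proposals).

#' Configure training
#'
#' Defaults mirror the full-scale schedule: SGD with momentum, initial
#' learning rate 1e-3, weight decay 1e-4, learning rate decayed by 0.66 every
#' 10 epochs, 200 epochs, random horizontal flip and color jitter.
#'
#' @param epochs Training epochs.
#' @param base_lr Initial learning rate, `> 0`.
#' @param weight_decay L2 penalty on conv/fc weights.
#' @param momentum SGD momentum.
#' @param lr_step Epochs per learning-rate decay step.
#' @param lr_gamma Decay factor per step, in `(0, 1)`.
#' @param seed Global seed controlling shuffling, augmentation and sampling.
#' @param flip_prob Probability of a horizontal flip per sample.
#' @param color_jitter Relative channel-gain jitter amplitude (0 disables).
#' @param rpn_batch Anchors sampled per image for the RPN loss.
#' @param roi_batch Proposals sampled per image for the box head.
#' @param kp_rois Foreground proposals per image for the keypoint loss.
#' @param eval_every Validation-evaluation period in epochs.
#' @return A list of class `mt_train_config`.
#' @export
train_config <- function(epochs = 200, base_lr = 1e-3, weight_decay = 1e-4,
                         momentum = 0.9, lr_step = 10, lr_gamma = 0.66,
                         seed = 1L, flip_prob = 0.5, color_jitter = 0.2,
                         rpn_batch = 64, roi_batch = 32, kp_rois = 8,
                         eval_every = 1) {
  if (base_lr <= 0) stop("base_lr must be > 0")
  if (lr_gamma <= 0 || lr_gamma >= 1) stop("lr_gamma must be in (0, 1)")
  structure(as.list(environment()), class = "mt_train_config")
}

#' Learning rate at a given epoch
#'
#' Step decay: `base_lr * lr_gamma ^ floor(epoch / lr_step)` (epoch 0-based).
#'
#' @param cfg A [train_config()].
#' @param epoch 0-based epoch index.
#' @return The learning rate.
#' @export
lr_at_epoch <- function(cfg, epoch) {
  cfg$base_lr * cfg$lr_gamma^floor(epoch / cfg$lr_step)
}

#' Augment an annotated image
#'
#' Random horizontal flip (every x maps to `width - 1 - x`, point order kept)
#' and random per-channel color gain; color jitter never touches coordinates.
#' With a fixed `seed` the output is deterministic.
#'
#' @param image Array `[height, width, 3]` in `[0, 1]`.
#' @param anns An [mt_annotated_image()] describing `image`.
#' @param flip_prob Flip probability.
#' @param color_jitter Channel-gain amplitude.
#' @param seed Optional integer seed.
#' @return A list with `image` and `anns`.
#' @export
augment <- function(image, anns, flip_prob = 0.5, color_jitter = 0.2,
                    seed = NULL) {
  run <- function() {
    W <- anns$width
    if (runif(1) < flip_prob) {
      image <- image[, rev(seq_len(dim(image)[2])), , drop = FALSE]
      anns$annotations <- lapply(anns$annotations, function(a) {
        a$points[, 1] <- W - 1 - a$points[, 1]
        a
      })
    }
    if (color_jitter > 0) {
      gains <- 1 + runif(3, -color_jitter, color_jitter)
      for (ch in 1:3) image[, , ch] <- pmin(pmax(image[, , ch] * gains[ch], 0), 1)
    }
    list(image = image, anns = anns)
  }
  if (is.null(seed)) run() else with_local_seed(seed, run())
}

# flip manifest-style targets (box, keypoints, polyline) horizontally
flip_targets <- function(targets, W) {
  lapply(targets, function(t) {
    b <- t$box
    t$box <- mt_box(W - 1 - b[3], b[2], W - 1 - b[1], b[4])
    t$keypoints[, 1] <- W - 1 - t$keypoints[, 1]
    t$polyline[, 1] <- W - 1 - t$polyline[, 1]
    t
  })
}

## ---- per-image gradient step ---------------------------------------------

rpn_assign <- function(anchors, gt_boxes) {
  n <- nrow(anchors)
  labels <- rep(-1L, n)        # -1 ignore, 0 neg, 1 pos
  match_gt <- rep(0L, n)
  if (nrow(gt_boxes) == 0) {
    labels[] <- 0L
    return(list(labels = labels, match_gt = match_gt))
  }
  M <- cpp_iou_matrix(anchors, gt_boxes)
  best <- apply(M, 1, max)
  bestj <- max.col(M, ties.method = "first")
  labels[best < 0.3] <- 0L
  labels[best >= 0.7] <- 1L
  # every ground truth claims its best anchor(s)
  for (j in seq_len(ncol(M))) {
    mx <- max(M[, j])
    if (mx > 0) labels[M[, j] >= mx - 1e-7] <- 1L
  }
  match_gt <- bestj
  list(labels = labels, match_gt = match_gt)
}

sample_idx <- function(pos, neg, total, pos_frac = 0.5) {
  n_pos <- min(length(pos), round(total * pos_frac))
  p <- if (n_pos > 0) pos[sample.int(length(pos), n_pos)] else integer(0)
  n_neg <- min(length(neg), total - n_pos)
  q <- if (n_neg > 0) neg[sample.int(length(neg), n_neg)] else integer(0)
  list(pos = p, neg = q)
}

train_step <- function(model, img, targets, tcfg) {
  cfg <- model$cfg
  H0 <- dim(img)[1]; W0 <- dim(img)[2]
  x <- pad_image(normalize_image(img), cfg$strides[cfg$n_levels])
  bb <- backbone_forward(model, x)
  fp <- fpn_forward(model, bb$taps)
  ro <- rpn_forward(model, fp$P)
  gt_boxes <- if (length(targets) > 0) {
    do.call(rbind, lapply(targets, function(t) as.numeric(t$box)))
  } else matrix(numeric(0), ncol = 4)
  gt_class <- vapply(targets, function(t) match(t$category, CATEGORIES), integer(1))

  A <- length(cfg$anchor_ratios)
  losses <- c(rpn_cls = 0, rpn_reg = 0, box_cls = 0, box_reg = 0, kp = 0)
  dcls <- vector("list", length(fp$P))
  dreg <- vector("list", length(fp$P))

  # --- RPN targets, pooled across levels then split back ---
  level_rows <- list(); anchors_all <- list()
  for (l in seq_along(fp$P)) {
    Hl <- dim(ro[[l]]$cls)[1]; Wl <- dim(ro[[l]]$cls)[2]
    anc <- anchors_level(Hl, Wl, cfg$strides[l], cfg$anchor_areas[l], cfg$anchor_ratios)
    anchors_all[[l]] <- anc
    level_rows[[l]] <- nrow(anc)
  }
  anchors_cat <- do.call(rbind, anchors_all)
  asg <- rpn_assign(anchors_cat, gt_boxes)
  pos <- which(asg$labels == 1L); neg <- which(asg$labels == 0L)
  sm <- sample_idx(pos, neg, tcfg$rpn_batch)
  samp <- c(sm$pos, sm$neg)
  n_samp <- length(samp)
  if (n_samp > 0) {
    logits_cat <- unlist(lapply(ro, function(o) as.vector(o$cls)))
    tvec <- as.numeric(asg$labels[samp] == 1L)
    z <- logits_cat[samp]
    bc <- bce_with_logits(z, tvec)
    losses["rpn_cls"] <- bc$loss
    dlog <- numeric(length(logits_cat))
    dlog[samp] <- bc$dz
    # regression on positives
    dreg_cat <- matrix(0, nrow(anchors_cat), 4)
    if (length(sm$pos) > 0) {
      anc_p <- anchors_cat[sm$pos, , drop = FALSE]
      tgt <- encode_deltas(anc_p, gt_boxes[asg$match_gt[sm$pos], , drop = FALSE])
      # predicted deltas for those anchors
      pred <- matrix(0, length(sm$pos), 4)
      offs <- c(0, cumsum(unlist(level_rows)))
      for (l in seq_along(fp$P)) {
        inl <- which(sm$pos > offs[l] & sm$pos <= offs[l + 1])
        if (length(inl) == 0) next
        rows <- sm$pos[inl] - offs[l]
        Hl <- dim(ro[[l]]$cls)[1]; Wl <- dim(ro[[l]]$cls)[2]
        a_idx <- (rows - 1) %/% (Hl * Wl) + 1
        cell <- (rows - 1) %% (Hl * Wl) + 1
        ch_map <- matrix(ro[[l]]$reg, Hl * Wl, 4 * A)
        for (cch in 1:4) {
          pred[inl, cch] <- ch_map[cbind(cell, (a_idx - 1) * 4 + cch)]
        }
      }
      diff <- pred - tgt
      losses["rpn_reg"] <- sum(smooth_l1(diff)) / n_samp
      dreg_cat[sm$pos, ] <- smooth_l1_grad(diff) / n_samp
    }
    # scatter gradients back into per-level cubes
    offs <- c(0, cumsum(unlist(level_rows)))
    for (l in seq_along(fp$P)) {
      Hl <- dim(ro[[l]]$cls)[1]; Wl <- dim(ro[[l]]$cls)[2]
      rows <- (offs[l] + 1):offs[l + 1]
      dcl <- array(dlog[rows], dim = c(Hl, Wl, A))
      drg <- array(0, dim = c(Hl, Wl, 4 * A))
      dsub <- dreg_cat[rows, , drop = FALSE]
      for (a in seq_len(A)) {
        arow <- (a - 1) * Hl * Wl + seq_len(Hl * Wl)
        for (cch in 1:4) {
          drg[, , (a - 1) * 4 + cch] <- array(dsub[arow, cch], dim = c(Hl, Wl))
        }
      }
      dcls[[l]] <- dcl; dreg[[l]] <- drg
    }
  }

  # --- proposals + box head ---
  props <- rpn_proposals(model, ro, W0, H0, pre = 600, post = 60)
  if (nrow(gt_boxes) > 0) props <- rbind(props, gt_boxes)
  bh_cache <- NULL; kp_cache <- NULL
  dbh_cls <- NULL; dbh_reg <- NULL; dkp <- NULL
  if (nrow(props) > 0 && nrow(gt_boxes) > 0) {
    M <- cpp_iou_matrix(props, gt_boxes)
    best <- apply(M, 1, max); bestj <- max.col(M, ties.method = "first")
    fg <- which(best >= 0.5); bg <- which(best < 0.5)
    sm2 <- sample_idx(fg, bg, tcfg$roi_batch)
    rois_idx <- c(sm2$pos, sm2$neg)
    if (length(rois_idx) > 0) {
      rois <- props[rois_idx, , drop = FALSE]
      labels <- c(gt_class[bestj[sm2$pos]], rep(0L, length(sm2$neg)))
      bh <- box_head_forward(model, fp$P, rois)
      bh_cache <- bh$cache
      ce <- softmax_ce(bh$cls, labels)
      losses["box_cls"] <- ce$loss
      dbh_cls <- ce$dz
      dbh_reg <- matrix(0, 4, length(rois_idx))
      if (length(sm2$pos) > 0) {
        tgt <- encode_deltas(rois[seq_along(sm2$pos), , drop = FALSE],
                             gt_boxes[bestj[sm2$pos], , drop = FALSE])
        pred <- t(bh$reg)[seq_along(sm2$pos), , drop = FALSE]
        diff <- pred - tgt
        losses["box_reg"] <- sum(smooth_l1(diff)) / length(rois_idx)
        dbh_reg[, seq_along(sm2$pos)] <- t(smooth_l1_grad(diff) / length(rois_idx))
      }
      # --- keypoint branch on foreground rois ---
      if (length(sm2$pos) > 0) {
        kp_take <- seq_len(min(tcfg$kp_rois, length(sm2$pos)))
        kp_boxes <- rois[kp_take, , drop = FALSE]
        kh <- kp_head_forward(model, fp$P, kp_boxes)
        kp_cache <- kh$cache
        dkp <- vector("list", length(kp_take))
        kls <- 0
        for (r in kp_take) {
          g <- bestj[rois_idx[r]]
          tg <- render_target_heatmap(targets[[g]]$keypoints, kp_boxes[r, ],
                                      size = cfg$heatmap_size,
                                      sigma_hm = cfg$sigma_hm)$grid
          bcr <- bce_with_logits(kh$logits[[r]], tg)
          kls <- kls + bcr$loss
          dkp[[r]] <- bcr$dz / length(kp_take)
        }
        losses["kp"] <- kls / length(kp_take)
      }
    }
  }

  # --- backward ---
  gr <- new_param_env()
  model$gr <- gr
  dP <- lapply(fp$P, function(p) array(0, dim = dim(p)))
  if (!is.null(kp_cache)) dP <- kp_head_backward(model, kp_cache, dkp, dP)
  if (!is.null(bh_cache)) dP <- box_head_backward(model, bh_cache, dbh_cls, dbh_reg, dP)
  dP <- rpn_backward(model, fp$P, ro, dcls, dreg, dP)
  dtaps <- fpn_backward(model, fp$cache, dP)
  backbone_backward(model, bb$cache, dtaps)
  list(losses = losses, gr = gr)
}

## ---- training loop --------------------------------------------------------

#' Train the detector
#'
#' Per-image SGD with momentum under the step learning-rate schedule. Each
#' epoch logs the mean box loss (RPN objectness + RPN regression + box-head
#' classification + box-head regression) and keypoint loss; when a validation
#' set is given, validation mAP50 and mLD are computed every `eval_every`
#' epochs and the parameters of the best-mAP50 epoch are retained in the
#' returned checkpoint.
#'
#' @param model A [build_model()] model (modified in place: its parameter
#'   environment is updated).
#' @param dataset A list with `train` (and optionally `val`): each a list of
#'   samples `list(image = array, targets = list(box, category, keypoints,
#'   polyline))` as produced by [load_detection_dataset()].
#' @param cfg A [train_config()].
#' @param nms_mode Suppression mode used for validation evaluation.
#' @param log_csv Optional path: per-epoch log written as CSV (columns epoch,
#'   lr, box_loss, kp_loss, val_map50, val_mld).
#' @param verbose Print per-epoch progress.
#' @return A checkpoint list: `params` (best-epoch parameters), `final_params`,
#'   `history` (data frame), `best_epoch`, `best_map50`, `config`, `seed`.
#' @export
train <- function(model, dataset, cfg = train_config(), nms_mode = "soft_diou",
                  log_csv = NULL, verbose = interactive()) {
  stopifnot(inherits(cfg, "mt_train_config"))
  samples <- dataset$train
  if (length(samples) == 0) stop("training set is empty")
  vel <- new_param_env()
  history <- data.frame()
  best <- list(map50 = -Inf, epoch = NA_integer_, params = NULL)
  set.seed(cfg$seed)
  for (epoch in seq_len(cfg$epochs) - 1L) {
    lr <- lr_at_epoch(cfg, epoch)
    ord <- sample(length(samples))
    ep_losses <- c(rpn_cls = 0, rpn_reg = 0, box_cls = 0, box_reg = 0, kp = 0)
    for (si in ord) {
      s <- samples[[si]]
      img <- s$image; tgts <- s$targets
      W0 <- dim(img)[2]
      if (runif(1) < cfg$flip_prob) {
        img <- img[, rev(seq_len(W0)), , drop = FALSE]
        tgts <- flip_targets(tgts, W0)
      }
      if (cfg$color_jitter > 0) {
        gains <- 1 + runif(3, -cfg$color_jitter, cfg$color_jitter)
        for (ch in 1:3) img[, , ch] <- pmin(pmax(img[, , ch] * gains[ch], 0), 1)
      }
      st <- train_step(model, img, tgts, cfg)
      ep_losses <- ep_losses + st$losses
      sgd_step(model$par, st$gr, vel, lr, cfg$momentum, cfg$weight_decay)
    }
    ep_losses <- ep_losses / length(samples)
    box_loss <- sum(ep_losses[c("rpn_cls", "rpn_reg", "box_cls", "box_reg")])
    val_map50 <- NA_real_; val_mld <- NA_real_
    if (!is.null(dataset$val) && length(dataset$val) > 0 &&
        (epoch %% cfg$eval_every == 0 || epoch == cfg$epochs - 1)) {
      ev <- evaluate_model(model, dataset$val, nms_mode = nms_mode)
      val_map50 <- ev$map50
      val_mld <- ev$mld
      if (!is.na(val_map50) && val_map50 > best$map50) {
        best$map50 <- val_map50
        best$epoch <- epoch
        best$params <- as.list(model$par)
      }
    }
    history <- rbind(history, data.frame(
      epoch = epoch, lr = lr, box_loss = box_loss, kp_loss = ep_losses[["kp"]],
      val_map50 = val_map50, val_mld = val_mld))
    if (isTRUE(verbose)) {
      cat(sprintf("epoch %3d  lr %.2e  box %.4f  kp %.4f  val mAP50 %s  val mLD %s\n",
                  epoch, lr, box_loss, ep_losses[["kp"]],
                  ifelse(is.na(val_map50), "-", sprintf("%.3f", val_map50)),
                  ifelse(is.na(val_mld), "-", sprintf("%.2f", val_mld))))
    }
  }
  if (is.null(best$params)) {
    best$params <- as.list(model$par)
    best$epoch <- cfg$epochs - 1L
    best$map50 <- NA_real_
  }
  if (!is.null(log_csv)) utils::write.csv(history, log_csv, row.names = FALSE)
  list(params = best$params, final_params = as.list(model$par),
       history = history, best_epoch = best$epoch, best_map50 = best$map50,
       config = cfg, model_config = model$cfg, seed = cfg$seed)
}

#' Restore checkpoint parameters into a model
#'
#' @param model A [build_model()] model (same configuration).
#' @param params A named parameter list (e.g. `checkpoint$params`).
#' @return The model, invisibly (its parameter store is updated in place).
#' @export
restore_params <- function(model, params) {
  for (nm in names(params)) model$par[[nm]] <- params[[nm]]
  invisible(model)
}

#' Predict final trajectory detections for a set of images
#'
#' [forward_image()] followed by [detections_to_predictions()] per image.
#'
#' @param model The trained model.
#' @param images List of image arrays.
#' @param nms Suppression settings: `mode`, `iou_threshold`, `sigma`,
#'   `score_floor`.
#' @param peak Peak-extraction settings: `value_threshold`, `min_separation`,
#'   `max_points`.
#' @param score_threshold Raw-detection score cut before suppression.
#' @return Per image, a list of detections with `box`, `class`, `score`,
#'   `keypoints` (matrix `[x, y, value]`).
#' @export
predict_images <- function(model, images,
                           nms = list(mode = "soft_diou", iou_threshold = 0.5,
                                      sigma = 0.5, score_floor = 0.05),
                           peak = list(value_threshold = 0.3, min_separation = 2,
                                       max_points = 32),
                           score_threshold = 0.3) {
  lapply(images, function(img) {
    raw <- forward_image(model, img, score_threshold = score_threshold)
    detections_to_predictions(raw, nms = nms, peak = peak)
  })
}

#' Evaluate a model on annotated samples
#'
#' Runs prediction on every sample, then computes detection mAP (IoU 0.5 and
#' 0.75) and the mean line distance against the annotated trajectories.
#'
#' @param model The model.
#' @param samples Samples as from [load_detection_dataset()].
#' @param nms_mode Suppression mode.
#' @param score_threshold Raw-detection score cut.
#' @return A list with `map50`, `map75`, `mld`, the full `det_report` and
#'   `ld_reports`.
#' @export
evaluate_model <- function(model, samples, nms_mode = "soft_diou",
                           score_threshold = 0.3) {
  nms <- list(mode = nms_mode, iou_threshold = 0.5, sigma = 0.5,
              score_floor = 0.05)
  preds <- predict_images(model, lapply(samples, `[[`, "image"), nms = nms,
                          score_threshold = score_threshold)
  gts <- lapply(samples, function(s) {
    lapply(s$targets, function(t) list(box = t$box, category = t$category,
                                       points = t$polyline))
  })
  det_rep <- evaluate_detections(preds, gts)
  lds <- numeric(0)
  ld_reports <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    mt <- match_detections(preds[[i]], gts[[i]], iou_threshold = 0.5)
    ldr <- mean_line_distance(mt, preds[[i]], gts[[i]])
    ld_reports[[i]] <- ldr
    lds <- c(lds, ldr$per_target_ld)
  }
  list(map50 = det_rep$map50, map75 = det_rep$map75,
       mld = if (length(lds) > 0) mean(lds) else NA_real_,
       det_report = det_rep, ld_reports = ld_reports)
}

#' Load a preprocessed detection dataset into memory
#'
#' Reads the COCO-style manifest of [export_detection_dataset()] and the PNG
#' images it refers to.
#'
#' @param manifest_path Manifest JSON path.
#' @param image_dir Directory holding the image files named in the manifest.
#' @return A list of samples: `image` (array) + `targets`.
#' @export
load_detection_dataset <- function(manifest_path, image_dir) {
  ds <- import_detection_dataset(manifest_path)
  lapply(ds$images, function(im) {
    img <- png::readPNG(file.path(image_dir, im$file_name))
    if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
    if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
    list(image = img, targets = im$targets, file_name = im$file_name)
  })
}
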