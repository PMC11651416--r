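# The two-stage trajectory detector: configurable residual conv backbone
# with a feature pyramid, a region proposal network, an RoIAlign box head,
# and a lightweight keypoint branch that predicts all of an instance's
# trajectory points in one single-channel heatmap.
#
# Backbone profiles share one generic layout: a 2-conv stride-4 stem, then
# stages of basic residual blocks (two 3x3 convs + identity skip), each
# stage after the first entered through a stride-2 downsampling conv. Stage
# outputs ("taps") feed the pyramid: 1x1 lateral convs, nearest-neighbor
# top-down upsampling, 3x3 smoothing, plus parameter-free stride-2 extra
# levels on top when the anchor ladder asks for more levels than the
# backbone has taps.

backbone_plan <- function(name) {
  switch(name,
    tiny_fpn = list(stem = 8, widths = c(16, 32), blocks = c(1, 1),
                    n_taps = 2, fpn = 16, kp_ch = 16),
    mobilenet_fpn = list(stem = 16, widths = c(24, 32, 64, 128),
                         blocks = c(1, 2, 3, 2), n_taps = 4, fpn = 64, kp_ch = 32),
    resnet50_fpn = list(stem = 32, widths = c(64, 128, 256, 512),
                        blocks = c(3, 4, 6, 3), n_taps = 4, fpn = 256, kp_ch = 64),
    resnet101_fpn = list(stem = 32, widths = c(64, 128, 256, 512),
                         blocks = c(3, 4, 23, 3), n_taps = 4, fpn = 256, kp_ch = 64),
    stop(sprintf("unknown backbone '%s'", name))
  )
}

#' Configure the trajectory detection model
#'
#' The default profile mirrors the full-scale configuration: ResNet-101-style
#' backbone with feature pyramid, five anchor areas (32^2 ... 512^2), 4000
#' proposals kept before and 2000 after RPN suppression, RoIAlign output 14.
#' The `tiny_fpn` profile is a CPU-scale configuration (two pyramid levels,
#' narrow channels) used for training on small synthetic scenes; the other
#' profiles keep the stage layouts of the architectures they are named after.
#'
#' @param backbone One of `"resnet101_fpn"`, `"resnet50_fpn"`,
#'   `"mobilenet_fpn"`, `"tiny_fpn"`.
#' @param anchor_areas Anchor box areas in square pixels, one per pyramid
#'   level; full-scale profiles require exactly 5.
#' @param anchor_ratios Height/width aspect ratios per anchor location.
#' @param rpn_pre_nms,rpn_post_nms Proposals kept before/after RPN NMS
#'   (`rpn_pre_nms >= rpn_post_nms > 0`).
#' @param roi_align_size RoIAlign output side for the box head.
#' @param heatmap_size Keypoint-branch heatmap side (one channel per
#'   detection).
#' @param fc_dim Box-head hidden width.
#' @param sigma_hm Gaussian target scale in heatmap cells.
#' @param num_classes Number of foreground classes (leaf, stalk).
#' @return A list of class `mt_model_config`.
#' @export
model_config <- function(backbone = "resnet101_fpn",
                         anchor_areas = NULL,
                         anchor_ratios = c(0.5, 1, 2),
                         rpn_pre_nms = NULL, rpn_post_nms = NULL,
                         roi_align_size = NULL, heatmap_size = NULL,
                         fc_dim = NULL, sigma_hm = 2, num_classes = 2) {
  plan <- backbone_plan(backbone)
  tiny <- identical(backbone, "tiny_fpn")
  if (is.null(anchor_areas)) {
    anchor_areas <- if (tiny) c(24^2, 64^2) else c(32, 64, 128, 256, 512)^2
  }
  if (!tiny && length(anchor_areas) != 5) {
    stop("full-scale profiles use exactly 5 anchor areas")
  }
  if (length(anchor_areas) < plan$n_taps) {
    stop("need at least one anchor area per backbone pyramid tap")
  }
  if (is.null(rpn_pre_nms)) rpn_pre_nms <- if (tiny) 600 else 4000
  if (is.null(rpn_post_nms)) rpn_post_nms <- if (tiny) 100 else 2000
  if (rpn_post_nms <= 0 || rpn_pre_nms < rpn_post_nms) {
    stop("need rpn_pre_nms >= rpn_post_nms > 0")
  }
  if (is.null(roi_align_size)) roi_align_size <- if (tiny) 7 else 14
  if (roi_align_size <= 0) stop("roi_align_size must be > 0")
  if (is.null(heatmap_size)) heatmap_size <- if (tiny) 28 else 56
  if (heatmap_size %% 2 != 0) stop("heatmap_size must be even")
  if (is.null(fc_dim)) fc_dim <- if (tiny) 128 else 1024
  structure(list(
    backbone = backbone, plan = plan,
    anchor_areas = anchor_areas, anchor_ratios = anchor_ratios,
    n_levels = length(anchor_areas),
    strides = 4 * 2^(seq_along(anchor_areas) - 1),
    rpn_pre_nms = rpn_pre_nms, rpn_post_nms = rpn_post_nms,
    roi_align_size = roi_align_size, heatmap_size = heatmap_size,
    kp_roi_size = heatmap_size %/% 2,
    fc_dim = fc_dim, sigma_hm = sigma_hm,
    num_classes = num_classes
  ), class = "mt_model_config")
}

#' Build the detector
#'
#' Allocates and initializes all parameters (He-normal convs, zero biases;
#' the RPN objectness bias starts at -2 so early proposals are sparse). The
#' forward contract is [forward_image()]: an image in, a list of scored class
#' boxes each carrying one single-channel keypoint heatmap out.
#'
#' @param cfg A [model_config()].
#' @param seed Integer seed for weight initialization.
#' @return A list of class `mt_model` with the config and a parameter store.
#' @export
build_model <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "mt_model_config"))
  plan <- cfg$plan
  par <- new_param_env()
  with_local_seed(seed, {
    init_conv(par, "stem1", 3, plan$stem, 3); init_in(par, "stem1n", plan$stem)
    init_conv(par, "stem2", plan$stem, plan$widths[1], 3)
    init_in(par, "stem2n", plan$widths[1])
    for (s in seq_along(plan$widths)) {
      if (s > 1) {
        init_conv(par, sprintf("down%d", s), plan$widths[s - 1], plan$widths[s], 3)
        init_in(par, sprintf("down%dn", s), plan$widths[s])
      }
      for (b in seq_len(plan$blocks[s])) {
        init_conv(par, sprintf("s%db%dc1", s, b), plan$widths[s], plan$widths[s], 3)
        init_in(par, sprintf("s%db%dc1n", s, b), plan$widths[s])
        init_conv(par, sprintf("s%db%dc2", s, b), plan$widths[s], plan$widths[s], 3)
        init_in(par, sprintf("s%db%dc2n", s, b), plan$widths[s])
      }
    }
    for (l in seq_len(plan$n_taps)) {
      init_conv(par, sprintf("lat%d", l), plan$widths[l], plan$fpn, 1)
      init_conv(par, sprintf("smooth%d", l), plan$fpn, plan$fpn, 3)
      init_in(par, sprintf("smooth%dn", l), plan$fpn)
    }
    A <- length(cfg$anchor_ratios)
    init_conv(par, "rpn_conv", plan$fpn, plan$fpn, 3)
    init_in(par, "rpn_convn", plan$fpn)
    init_conv(par, "rpn_cls", plan$fpn, A, 1, bias = -2)
    init_conv(par, "rpn_reg", plan$fpn, 4 * A, 1)
    S <- cfg$roi_align_size
    init_fc(par, "box_fc1", S * S * plan$fpn, cfg$fc_dim)
    init_fc(par, "box_cls", cfg$fc_dim, cfg$num_classes + 1)
    init_fc(par, "box_reg", cfg$fc_dim, 4)
    init_conv(par, "kp_c1", plan$fpn, plan$kp_ch, 3)
    init_in(par, "kp_c1n", plan$kp_ch)
    init_conv(par, "kp_c2", plan$kp_ch, plan$kp_ch, 3)
    init_in(par, "kp_c2n", plan$kp_ch)
    init_conv(par, "kp_out", plan$kp_ch, 1, 3, bias = -2)
  })
  structure(list(cfg = cfg, par = par, seed = as.integer(seed)),
            class = "mt_model")
}

#' @export
print.mt_model <- function(x, ...) {
  cat(sprintf("Trajectory detector (%s): %s parameters, %d pyramid levels\n",
              x$cfg$backbone, format(param_count(x$par), big.mark = ","),
              x$cfg$n_levels))
  cat(sprintf("  anchors: areas %s, ratios %s\n",
              paste(round(sqrt(x$cfg$anchor_areas)), collapse = "/"),
              paste(x$cfg$anchor_ratios, collapse = "/")))
  cat(sprintf("  RPN pre/post NMS %d/%d, RoIAlign %d, heatmap %d\n",
              x$cfg$rpn_pre_nms, x$cfg$rpn_post_nms,
              x$cfg$roi_align_size, x$cfg$heatmap_size))
  invisible(x)
}

# pad H, W up to a multiple of the coarsest stride (zeros, bottom/right)
pad_image <- function(img, stride_max) {
  d <- dim(img)
  H <- ceiling(d[1] / stride_max) * stride_max
  W <- ceiling(d[2] / stride_max) * stride_max
  if (H == d[1] && W == d[2]) return(img)
  out <- array(0, dim = c(H, W, d[3]))
  out[seq_len(d[1]), seq_len(d[2]), ] <- img
  out
}

normalize_image <- function(img) (img - 0.45) / 0.25

## ---- backbone + FPN -------------------------------------------------------

backbone_forward <- function(m, x) {
  par <- m$par; plan <- m$cfg$plan
  cache <- list(x = x)
  c1 <- conv_fwd(par, "stem1", x, 3, 2L)
  n1 <- in_fwd(par, "stem1n", c1); s1 <- relu(n1$y)
  c2 <- conv_fwd(par, "stem2", s1, 3, 2L)
  n2 <- in_fwd(par, "stem2n", c2); h <- relu(n2$y)
  cache$stem <- list(c1 = c1, n1 = n1, s1 = s1, c2 = c2, n2 = n2)
  taps <- list(); stages <- list()
  for (s in seq_along(plan$widths)) {
    st <- list()
    if (s > 1) {
      st$down_in <- h
      dc <- conv_fwd(par, sprintf("down%d", s), h, 3, 2L)
      dn <- in_fwd(par, sprintf("down%dn", s), dc)
      st$down_c <- dc; st$down_n <- dn
      h <- relu(dn$y)
    }
    st$blocks <- list()
    for (b in seq_len(plan$blocks[s])) {
      nb1 <- sprintf("s%db%dc1", s, b); nb2 <- sprintf("s%db%dc2", s, b)
      p1 <- conv_fwd(par, nb1, h, 3, 1L)
      q1 <- in_fwd(par, paste0(nb1, "n"), p1)
      a1 <- relu(q1$y)
      p2 <- conv_fwd(par, nb2, a1, 3, 1L)
      q2 <- in_fwd(par, paste0(nb2, "n"), p2)
      sm <- h + q2$y
      st$blocks[[b]] <- list(h_in = h, p1 = p1, q1 = q1, a1 = a1,
                             p2 = p2, q2 = q2, sm = sm)
      h <- relu(sm)
    }
    st$out <- h
    stages[[s]] <- st
    if (s <= plan$n_taps) taps[[s]] <- h
  }
  cache$stages <- stages
  list(taps = taps, cache = cache)
}

backbone_backward <- function(m, cache, dtaps) {
  par <- m$par; gr <- m$gr; plan <- m$cfg$plan
  dh <- NULL
  for (s in rev(seq_along(plan$widths))) {
    st <- cache$stages[[s]]
    if (is.null(dh)) dh <- 0 * st$out
    if (s <= plan$n_taps && !is.null(dtaps[[s]])) dh <- dh + dtaps[[s]]
    for (b in rev(seq_len(plan$blocks[s]))) {
      bl <- st$blocks[[b]]
      nb1 <- sprintf("s%db%dc1", s, b); nb2 <- sprintf("s%db%dc2", s, b)
      dsm <- relu_bwd(bl$sm, dh)
      dq2 <- in_bwd(par, gr, paste0(nb2, "n"), bl$q2, dsm)
      da1 <- conv_bwd(par, gr, nb2, bl$a1, dq2, 3, 1L)
      dq1 <- relu_bwd(bl$q1$y, da1)
      dp1 <- in_bwd(par, gr, paste0(nb1, "n"), bl$q1, dq1)
      dh <- conv_bwd(par, gr, nb1, bl$h_in, dp1, 3, 1L) + dsm
    }
    if (s > 1) {
      dd <- relu_bwd(st$down_n$y, dh)
      dd <- in_bwd(par, gr, sprintf("down%dn", s), st$down_n, dd)
      dh <- conv_bwd(par, gr, sprintf("down%d", s), st$down_in, dd, 3, 2L)
    }
  }
  stc <- cache$stem
  dn2 <- relu_bwd(stc$n2$y, dh)
  dc2 <- in_bwd(par, gr, "stem2n", stc$n2, dn2)
  ds1 <- conv_bwd(par, gr, "stem2", stc$s1, dc2, 3, 2L)
  dn1 <- relu_bwd(stc$n1$y, ds1)
  dc1 <- in_bwd(par, gr, "stem1n", stc$n1, dn1)
  invisible(conv_bwd(par, gr, "stem1", cache$x, dc1, 3, 2L))
}

fpn_forward <- function(m, taps) {
  par <- m$par; plan <- m$cfg$plan
  L <- plan$n_taps
  lat <- lapply(seq_len(L), function(l) conv_fwd(par, sprintf("lat%d", l), taps[[l]], 1, 1L, 0L))
  tt <- vector("list", L)
  tt[[L]] <- lat[[L]]
  if (L > 1) for (l in (L - 1):1) tt[[l]] <- lat[[l]] + upsample2(tt[[l + 1]])
  sn <- vector("list", L)
  P <- vector("list", L)
  for (l in seq_len(L)) {
    sc <- conv_fwd(par, sprintf("smooth%d", l), tt[[l]], 3, 1L)
    sn[[l]] <- in_fwd(par, sprintf("smooth%dn", l), sc)
    P[[l]] <- sn[[l]]$y
  }
  n_extra <- m$cfg$n_levels - L
  if (n_extra > 0) {
    for (e in seq_len(n_extra)) P[[L + e]] <- subsample2(P[[L + e - 1]])
  }
  list(P = P, cache = list(taps = taps, tt = tt, sn = sn))
}

fpn_backward <- function(m, cache, dP) {
  par <- m$par; gr <- m$gr; plan <- m$cfg$plan
  L <- plan$n_taps
  n_extra <- m$cfg$n_levels - L
  # fold extra-level gradients down onto the top real level
  if (n_extra > 0) {
    for (e in rev(seq_len(n_extra))) {
      src <- dP[[L + e]]
      if (is.null(src)) next
      tgt_dim <- dim(dP[[L + e - 1]])
      dP[[L + e - 1]] <- dP[[L + e - 1]] +
        subsample2_bwd(src, tgt_dim[1], tgt_dim[2])
    }
  }
  dtt <- vector("list", L)
  for (l in seq_len(L)) {
    dsc <- in_bwd(par, gr, sprintf("smooth%dn", l), cache$sn[[l]], dP[[l]])
    dtt[[l]] <- conv_bwd(par, gr, sprintf("smooth%d", l), cache$tt[[l]], dsc, 3, 1L)
  }
  dtaps <- vector("list", L)
  if (L > 1) {
    for (l in seq_len(L - 1)) {
      # dtt[l] feeds lat[l] directly and tt[l+1] through the upsample
      dtt[[l + 1]] <- dtt[[l + 1]] + downsum2(dtt[[l]])
    }
  }
  for (l in seq_len(L)) {
    dtaps[[l]] <- conv_bwd(par, gr, sprintf("lat%d", l), cache$taps[[l]], dtt[[l]], 1, 1L, 0L)
  }
  dtaps
}

## ---- RPN ------------------------------------------------------------------

rpn_forward <- function(m, P) {
  par <- m$par
  out <- list()
  for (l in seq_along(P)) {
    r_c <- conv_fwd(par, "rpn_conv", P[[l]], 3, 1L)
    r_n <- in_fwd(par, "rpn_convn", r_c)
    r <- relu(r_n$y)
    out[[l]] <- list(
      r_c = r_c, r_n = r_n, r = r,
      cls = conv_fwd(par, "rpn_cls", r, 1, 1L, 0L),
      reg = conv_fwd(par, "rpn_reg", r, 1, 1L, 0L)
    )
  }
  out
}

rpn_backward <- function(m, P, rpn_out, dcls, dreg, dP) {
  par <- m$par; gr <- m$gr
  for (l in seq_along(P)) {
    if (is.null(dcls[[l]]) && is.null(dreg[[l]])) next
    ro <- rpn_out[[l]]
    dr <- 0 * ro$r
    if (!is.null(dcls[[l]])) dr <- dr + conv_bwd(par, gr, "rpn_cls", ro$r, dcls[[l]], 1, 1L, 0L)
    if (!is.null(dreg[[l]])) dr <- dr + conv_bwd(par, gr, "rpn_reg", ro$r, dreg[[l]], 1, 1L, 0L)
    dr_n <- relu_bwd(ro$r_n$y, dr)
    dr_c <- in_bwd(par, gr, "rpn_convn", ro$r_n, dr_n)
    dP[[l]] <- dP[[l]] + conv_bwd(par, gr, "rpn_conv", P[[l]], dr_c, 3, 1L)
  }
  dP
}

# anchors for one level, ordered to match as.vector() of the (H, W, A) cls
# cube: anchor index (i, j, a) at row (a-1)*H*W + (j-1)*H + i
anchors_level <- function(Hl, Wl, stride, area, ratios) {
  cx <- (rep(seq_len(Wl), each = Hl) - 0.5) * stride
  cy <- (rep(seq_len(Hl), times = Wl) - 0.5) * stride
  out <- vector("list", length(ratios))
  for (a in seq_along(ratios)) {
    h <- sqrt(area * ratios[a]); w <- sqrt(area / ratios[a])
    out[[a]] <- cbind(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2)
  }
  do.call(rbind, out)
}

encode_deltas <- function(anc, gt) {
  aw <- anc[, 3] - anc[, 1]; ah <- anc[, 4] - anc[, 2]
  ax <- anc[, 1] + aw / 2; ay <- anc[, 2] + ah / 2
  gw <- gt[, 3] - gt[, 1]; gh <- gt[, 4] - gt[, 2]
  gx <- gt[, 1] + gw / 2; gy <- gt[, 2] + gh / 2
  cbind((gx - ax) / aw, (gy - ay) / ah, log(gw / aw), log(gh / ah))
}

decode_deltas <- function(anc, d) {
  aw <- anc[, 3] - anc[, 1]; ah <- anc[, 4] - anc[, 2]
  ax <- anc[, 1] + aw / 2; ay <- anc[, 2] + ah / 2
  d3 <- pmin(pmax(d[, 3], -4), 4); d4 <- pmin(pmax(d[, 4], -4), 4)
  w <- aw * exp(d3); h <- ah * exp(d4)
  x <- ax + d[, 1] * aw; y <- ay + d[, 2] * ah
  cbind(x - w / 2, y - h / 2, x + w / 2, y + h / 2)
}

clip_boxes <- function(b, W, H) {
  b[, c(1, 3)] <- pmin(pmax(b[, c(1, 3)], 0), W)
  b[, c(2, 4)] <- pmin(pmax(b[, c(2, 4)], 0), H)
  b
}

# decode RPN outputs into score-ranked proposals (class-agnostic)
rpn_proposals <- function(m, rpn_out, img_w, img_h, pre = NULL, post = NULL) {
  cfg <- m$cfg
  if (is.null(pre)) pre <- cfg$rpn_pre_nms
  if (is.null(post)) post <- cfg$rpn_post_nms
  A <- length(cfg$anchor_ratios)
  all_boxes <- list(); all_scores <- list()
  for (l in seq_along(rpn_out)) {
    cls <- rpn_out[[l]]$cls; reg <- rpn_out[[l]]$reg
    Hl <- dim(cls)[1]; Wl <- dim(cls)[2]
    anc <- anchors_level(Hl, Wl, cfg$strides[l], cfg$anchor_areas[l], cfg$anchor_ratios)
    sc <- as.vector(cls)
    dl <- matrix(0, Hl * Wl * A, 4)
    for (a in seq_len(A)) {
      rows <- (a - 1) * Hl * Wl + seq_len(Hl * Wl)
      for (cch in 1:4) dl[rows, cch] <- as.vector(reg[, , (a - 1) * 4 + cch])
    }
    bx <- clip_boxes(decode_deltas(anc, dl), img_w, img_h)
    keep <- (bx[, 3] - bx[, 1] >= 2) & (bx[, 4] - bx[, 2] >= 2)
    all_boxes[[l]] <- bx[keep, , drop = FALSE]
    all_scores[[l]] <- sc[keep]
  }
  boxes <- do.call(rbind, all_boxes)
  scores <- do.call(c, all_scores)
  if (length(scores) == 0) return(matrix(numeric(0), ncol = 4))
  ord <- order(-scores)[seq_len(min(pre, length(scores)))]
  boxes <- boxes[ord, , drop = FALSE]; scores <- scores[ord]
  keep <- nms_indices(boxes, scores, 0.7, post)
  boxes[keep, , drop = FALSE]
}

## ---- RoI heads ------------------------------------------------------------

# pyramid level for each roi by closeness of sqrt(area) to the anchor ladder
assign_roi_level <- function(boxes, cfg) {
  a <- pmax((boxes[, 3] - boxes[, 1]) * (boxes[, 4] - boxes[, 2]), 1)
  sq <- sqrt(a)
  ref <- sqrt(cfg$anchor_areas)
  vapply(sq, function(s) which.min(abs(log2(s / ref))), integer(1))
}

box_head_forward <- function(m, P, boxes) {
  cfg <- m$cfg; par <- m$par
  n <- nrow(boxes)
  S <- cfg$roi_align_size; F <- cfg$plan$fpn
  lv <- assign_roi_level(boxes, cfg)
  feats <- array(0, dim = c(S, S, F, n))
  for (l in unique(lv)) {
    idx <- which(lv == l)
    rois_f <- boxes[idx, , drop = FALSE] / cfg$strides[l]
    fl <- cpp_roi_align_forward(P[[l]], rois_f, as.integer(S))
    feats[, , , idx] <- fl
  }
  X <- matrix(feats, nrow = S * S * F, ncol = n)
  h_pre <- fc_fwd(par, "box_fc1", X)
  h <- relu(h_pre)
  list(cls = fc_fwd(par, "box_cls", h),   # (C+1) x n
       reg = fc_fwd(par, "box_reg", h),   # 4 x n
       cache = list(boxes = boxes, lv = lv, X = X, h_pre = h_pre, h = h))
}

box_head_backward <- function(m, cache, dcls, dreg, dP) {
  cfg <- m$cfg; par <- m$par; gr <- m$gr
  dh <- fc_bwd(par, gr, "box_cls", cache$h, dcls) +
        fc_bwd(par, gr, "box_reg", cache$h, dreg)
  dh <- relu_bwd(cache$h_pre, dh)
  dX <- fc_bwd(par, gr, "box_fc1", cache$X, dh)
  S <- cfg$roi_align_size; F <- cfg$plan$fpn
  n <- ncol(dX)
  dfeats <- array(dX, dim = c(S, S, F, n))
  for (l in unique(cache$lv)) {
    idx <- which(cache$lv == l)
    rois_f <- cache$boxes[idx, , drop = FALSE] / cfg$strides[l]
    d <- dim(P_level_dim <- dP[[l]])
    dP[[l]] <- dP[[l]] + cpp_roi_align_backward(
      d[1], d[2], d[3], rois_f, as.integer(S),
      dfeats[, , , idx, drop = FALSE])
  }
  dP
}

# keypoint branch: RoIAlign on the finest pyramid level, two 3x3 convs,
# nearest x2 upsample, 3x3 conv to one logit channel per roi
kp_head_forward <- function(m, P, boxes) {
  cfg <- m$cfg; par <- m$par
  n <- nrow(boxes)
  Sk <- cfg$kp_roi_size
  rois_f <- boxes / cfg$strides[1]
  feats <- cpp_roi_align_forward(P[[1]], rois_f, as.integer(Sk))
  rois <- vector("list", n)
  logits <- vector("list", n)
  for (r in seq_len(n)) {
    x0 <- array(feats[, , , r], dim = dim(feats)[1:3])
    p1 <- conv_fwd(par, "kp_c1", x0, 3, 1L)
    q1 <- in_fwd(par, "kp_c1n", p1); a1 <- relu(q1$y)
    p2 <- conv_fwd(par, "kp_c2", a1, 3, 1L)
    q2 <- in_fwd(par, "kp_c2n", p2); a2 <- relu(q2$y)
    up <- upsample2(a2)
    lg <- conv_fwd(par, "kp_out", up, 3, 1L)
    rois[[r]] <- list(x0 = x0, p1 = p1, q1 = q1, a1 = a1,
                      p2 = p2, q2 = q2, a2 = a2, up = up)
    logits[[r]] <- lg[, , 1]
  }
  list(logits = logits, cache = list(boxes = boxes, rois = rois, rois_f = rois_f))
}

kp_head_backward <- function(m, cache, dlogits, dP) {
  cfg <- m$cfg; par <- m$par; gr <- m$gr
  n <- length(cache$rois)
  Sk <- cfg$kp_roi_size; F <- cfg$plan$fpn
  dfeats <- array(0, dim = c(Sk, Sk, F, n))
  for (r in seq_len(n)) {
    if (is.null(dlogits[[r]])) next
    rc <- cache$rois[[r]]
    dlg <- array(dlogits[[r]], dim = c(dim(dlogits[[r]]), 1))
    dup <- conv_bwd(par, gr, "kp_out", rc$up, dlg, 3, 1L)
    da2 <- downsum2(dup)
    dq2 <- relu_bwd(rc$q2$y, da2)
    dp2 <- in_bwd(par, gr, "kp_c2n", rc$q2, dq2)
    da1 <- conv_bwd(par, gr, "kp_c2", rc$a1, dp2, 3, 1L)
    dq1 <- relu_bwd(rc$q1$y, da1)
    dp1 <- in_bwd(par, gr, "kp_c1n", rc$q1, dq1)
    dfeats[, , , r] <- conv_bwd(par, gr, "kp_c1", rc$x0, dp1, 3, 1L)
  }
  d <- dim(dP[[1]])
  dP[[1]] <- dP[[1]] + cpp_roi_align_backward(d[1], d[2], d[3], cache$rois_f,
                                              as.integer(Sk), dfeats)
  dP
}

## ---- inference ------------------------------------------------------------

#' Run the detector on one image
#'
#' Full forward pass: backbone + pyramid, RPN proposals, box head, per-class
#' score thresholding, then the keypoint branch on the surviving boxes. No
#' box-level suppression is applied here; that (plus peak extraction) is
#' [detections_to_predictions()].
#'
#' @param model An [build_model()] model.
#' @param img Image array `[height, width, 3]` with values in `[0, 1]`.
#' @param score_threshold Minimum class score for a raw detection.
#' @param max_dets Cap on raw detections (score-ordered) per image.
#' @return List of raw detections: each has `box` (clipped to the image),
#'   `class` (`"leaf"`/`"stalk"`), `class_id`, `score`, and `heatmap`
#'   (an `mt_heatmap` registered to the box).
#' @export
forward_image <- function(model, img, score_threshold = 0.05, max_dets = 60) {
  cfg <- model$cfg
  H0 <- dim(img)[1]; W0 <- dim(img)[2]
  x <- pad_image(normalize_image(img), cfg$strides[cfg$n_levels])
  bb <- backbone_forward(model, x)
  fp <- fpn_forward(model, bb$taps)
  ro <- rpn_forward(model, fp$P)
  props <- rpn_proposals(model, ro, W0, H0,
                         pre = min(cfg$rpn_pre_nms, 2000), post = min(cfg$rpn_post_nms, 200))
  if (nrow(props) == 0) return(list())
  bh <- box_head_forward(model, fp$P, props)
  probs <- softmax_cols(bh$cls)
  dets <- list()
  for (cl in seq_len(cfg$num_classes)) {
    sc <- probs[cl + 1, ]
    keep <- which(sc >= score_threshold)
    if (length(keep) == 0) next
    bx <- clip_boxes(decode_deltas(props[keep, , drop = FALSE],
                                   t(bh$reg)[keep, , drop = FALSE]), W0, H0)
    ok <- which(bx[, 3] - bx[, 1] >= 2 & bx[, 4] - bx[, 2] >= 2)
    for (i in ok) {
      dets[[length(dets) + 1]] <- list(
        box = bx[i, ], class = CATEGORIES[cl], class_id = cl, score = sc[keep[i]]
      )
    }
  }
  if (length(dets) == 0) return(list())
  scores <- vapply(dets, function(d) d$score, numeric(1))
  dets <- dets[order(-scores)][seq_len(min(max_dets, length(dets)))]
  boxes <- do.call(rbind, lapply(dets, function(d) d$box))
  kp <- kp_head_forward(model, fp$P, boxes)
  for (i in seq_along(dets)) {
    grid <- 1 / (1 + exp(-kp$logits[[i]]))
    dets[[i]]$heatmap <- structure(
      list(grid = grid, box = dets[[i]]$box, size = cfg$heatmap_size),
      class = "mt_heatmap")
  }
  dets
}

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}
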