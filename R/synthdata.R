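# Synthetic maize-like field scenes with dotted-line ground truth.
#
# Each plant is one near-vertical jittered stalk polyline plus leaves drawn
# as quadratic Bezier arcs rooted on the stalk, rendered as thick
# anti-aliased strokes in green-hue palettes over a soil background (plain
# or cluttered). Every drawn curve has a matching polyline annotation whose
# points lie on the stroke centerline, so the generator's own output is
# pixel-faithful ground truth for the whole pipeline.
#
# Images are arrays [height, width, 3] with values in [0, 1].

STAGE_PRESETS <- list(
  early  = list(n_plants = 2, leaves_per_plant = c(2, 4), occlusion_level = 0.1,
                stalk_height = c(0.30, 0.45), leaf_len = c(0.12, 0.20),
                background = "plain"),
  middle = list(n_plants = 3, leaves_per_plant = c(4, 6), occlusion_level = 0.3,
                stalk_height = c(0.45, 0.60), leaf_len = c(0.18, 0.30),
                background = "clutter"),
  late   = list(n_plants = 5, leaves_per_plant = c(5, 7), occlusion_level = 0.6,
                stalk_height = c(0.55, 0.75), leaf_len = c(0.25, 0.40),
                background = "clutter")
)

#' Configure a synthetic field scene
#'
#' Presets mirror three growth periods: `early` (few small plants, little
#' overlap), `middle` (more and longer leaves), and `late` (dense planting
#' and long leaves, so strokes from distinct instances routinely intersect).
#' Any preset field can be overridden.
#'
#' @param image_size `c(width, height)` in pixels.
#' @param stage `"early"`, `"middle"`, or `"late"`.
#' @param n_plants Number of plants (`>= 1`); preset default when `NULL`.
#' @param leaves_per_plant Inclusive integer range `c(lo, hi)`.
#' @param occlusion_level Fraction in `[0, 1]`; scales leaf length and
#'   tightens plant spacing.
#' @param background `"plain"` or `"clutter"`.
#' @param seed Integer seed; identical config + seed gives a pixel-identical
#'   scene.
#' @return A list of class `mt_scene_config`.
#' @export
scene_config <- function(image_size = c(256, 256), stage = "middle",
                         n_plants = NULL, leaves_per_plant = NULL,
                         occlusion_level = NULL, background = NULL,
                         seed = 1L) {
  if (!stage %in% names(STAGE_PRESETS)) stop("stage must be early, middle, or late")
  p <- STAGE_PRESETS[[stage]]
  cfg <- list(
    image_size = as.numeric(image_size),
    stage = stage,
    n_plants = if (is.null(n_plants)) p$n_plants else as.integer(n_plants),
    leaves_per_plant = if (is.null(leaves_per_plant)) p$leaves_per_plant else leaves_per_plant,
    occlusion_level = if (is.null(occlusion_level)) p$occlusion_level else occlusion_level,
    background = if (is.null(background)) p$background else background,
    stalk_height = p$stalk_height,
    leaf_len = p$leaf_len,
    seed = as.integer(seed)
  )
  if (any(cfg$image_size < 64)) stop("image_size must be at least 64 x 64")
  if (cfg$n_plants < 1) stop("n_plants must be >= 1")
  if (cfg$occlusion_level < 0 || cfg$occlusion_level > 1) stop("occlusion_level must be in [0, 1]")
  if (!cfg$background %in% c("plain", "clutter")) stop("background must be plain or clutter")
  structure(cfg, class = "mt_scene_config")
}

# anti-aliased thick stroke along a polyline, composited in place
draw_stroke <- function(img, pts, thickness, color) {
  H <- dim(img)[1]; W <- dim(img)[2]
  r <- thickness / 2
  x1 <- max(1, floor(min(pts[, 1]) - r - 1)); x2 <- min(W, ceiling(max(pts[, 1]) + r + 2))
  y1 <- max(1, floor(min(pts[, 2]) - r - 1)); y2 <- min(H, ceiling(max(pts[, 2]) + r + 2))
  if (x2 < x1 || y2 < y1) return(img)
  xs <- (x1:x2) - 1  # pixel centers, 0-based coords
  ys <- (y1:y2) - 1
  px <- matrix(rep(xs, each = length(ys)), nrow = length(ys))
  py <- matrix(rep(ys, times = length(xs)), nrow = length(ys))
  dmin <- matrix(Inf, length(ys), length(xs))
  n <- nrow(pts)
  for (i in seq_len(max(n - 1, 1))) {
    a <- pts[i, ]; b <- if (n > 1) pts[i + 1, ] else pts[i, ]
    abx <- b[1] - a[1]; aby <- b[2] - a[2]
    len2 <- abx^2 + aby^2
    if (len2 == 0) {
      d <- sqrt((px - a[1])^2 + (py - a[2])^2)
    } else {
      t <- ((px - a[1]) * abx + (py - a[2]) * aby) / len2
      t[t < 0] <- 0; t[t > 1] <- 1
      d <- sqrt((px - (a[1] + t * abx))^2 + (py - (a[2] + t * aby))^2)
    }
    dmin <- pmin(dmin, d)
  }
  cov <- pmin(pmax(r + 0.5 - dmin, 0), 1)
  for (ch in 1:3) {
    sub <- img[y1:y2, x1:x2, ch]
    img[y1:y2, x1:x2, ch] <- sub * (1 - cov) + color[ch] * cov
  }
  img
}

clamp_pts <- function(pts, W, H) {
  pts[, 1] <- pmin(pmax(pts[, 1], 2), W - 3)
  pts[, 2] <- pmin(pmax(pts[, 2], 2), H - 3)
  pts
}

bezier_quad <- function(p0, p1, p2, n = 20) {
  t <- seq(0, 1, length.out = n)
  cbind((1 - t)^2 * p0[1] + 2 * (1 - t) * t * p1[1] + t^2 * p2[1],
        (1 - t)^2 * p0[2] + 2 * (1 - t) * t * p1[2] + t^2 * p2[2])
}

make_background <- function(W, H, kind) {
  base <- c(0.36, 0.27, 0.18)
  img <- array(0, dim = c(H, W, 3))
  for (ch in 1:3) img[, , ch] <- base[ch] + rnorm(H * W, 0, 0.02)
  if (kind == "clutter") {
    for (b in seq_len(18)) {
      cx <- runif(1, 0, W - 1); cy <- runif(1, 0, H - 1)
      rx <- runif(1, 3, W / 12); ry <- runif(1, 3, H / 12)
      shade <- runif(1, -0.12, 0.12)
      tint <- c(shade, shade * runif(1, 0.6, 1), shade * runif(1, 0.3, 0.8))
      x1 <- max(1, floor(cx - rx)); x2 <- min(W, ceiling(cx + rx))
      y1 <- max(1, floor(cy - ry)); y2 <- min(H, ceiling(cy + ry))
      if (x2 < x1 || y2 < y1) next
      xs <- (x1:x2) - 1; ys <- (y1:y2) - 1
      px <- matrix(rep(xs, each = length(ys)), nrow = length(ys))
      py <- matrix(rep(ys, times = length(xs)), nrow = length(ys))
      mask <- ((px - cx) / rx)^2 + ((py - cy) / ry)^2 <= 1
      for (ch in 1:3) {
        sub <- img[y1:y2, x1:x2, ch]
        sub[mask] <- sub[mask] + tint[ch]
        img[y1:y2, x1:x2, ch] <- sub
      }
    }
    img <- img + array(rnorm(H * W * 3, 0, 0.02), dim = dim(img))
  }
  pmin(pmax(img, 0), 1)
}

#' Generate one synthetic maize field scene
#'
#' @param cfg A [scene_config()].
#' @return A list with `image` (array `[height, width, 3]` in `[0, 1]`) and
#'   `ann` (an [mt_annotated_image()] whose polylines are the exact stroke
#'   centerlines: one `stalk` plus one `leaf` per drawn leaf, per plant).
#' @export
generate_scene <- function(cfg) {
  stopifnot(inherits(cfg, "mt_scene_config"))
  W <- cfg$image_size[1]; H <- cfg$image_size[2]
  with_local_seed(cfg$seed, {
    img <- make_background(W, H, cfg$background)
    occ <- cfg$occlusion_level
    n <- cfg$n_plants
    spacing <- W / n
    base_x <- (seq_len(n) - 0.5) * spacing +
      runif(n, -0.25, 0.25) * spacing * (1 - 0.5 * occ)
    base_y <- runif(n, 0.80 * H, 0.95 * H)
    ord <- order(base_y)  # draw back-to-front
    anns <- list(); iid <- 0L
    for (pi in ord) {
      stalk_h <- runif(1, cfg$stalk_height[1], cfg$stalk_height[2]) * H
      ys <- seq(base_y[pi], base_y[pi] - stalk_h, length.out = 5)
      lean <- runif(1, -0.03, 0.03) * H
      xs <- base_x[pi] + seq(0, lean, length.out = 5) + c(0, rnorm(4, 0, W / 180))
      stalk <- clamp_pts(cbind(xs, ys), W, H)
      scol <- pmin(pmax(c(0.22, 0.42, 0.16) + rnorm(3, 0, 0.03), 0), 1)
      img <- draw_stroke(img, stalk, thickness = max(3, round(W / 64)), color = scol)
      iid <- iid + 1L
      anns[[iid]] <- mt_polyline("stalk", stalk, instance_id = iid)

      leaf_range <- cfg$leaves_per_plant[1]:cfg$leaves_per_plant[2]
      n_leaves <- leaf_range[sample.int(length(leaf_range), 1)]
      for (li in seq_len(n_leaves)) {
        side <- if (li %% 2 == 0) 1 else -1
        attach_t <- runif(1, 0.25, 0.95)  # fraction up the stalk
        k <- 1 + attach_t * 3             # position along the 5 stalk points
        k0 <- floor(k); fr <- k - k0
        root <- stalk[k0, ] + fr * (stalk[min(k0 + 1, 5), ] - stalk[k0, ])
        len <- runif(1, cfg$leaf_len[1], cfg$leaf_len[2]) * W * (1 + 0.5 * occ)
        droop <- runif(1, 0.1, 0.5) * len
        lift <- runif(1, 0.3, 0.8) * len
        tip <- root + c(side * len, droop - 0.2 * len)
        ctrl <- root + c(side * len * 0.45, -lift * 0.6)
        leaf <- clamp_pts(bezier_quad(root, ctrl, tip, n = 20), W, H)
        lcol <- pmin(pmax(c(0.28, 0.55, 0.20) + rnorm(3, 0, 0.05), 0), 1)
        img <- draw_stroke(img, leaf, thickness = max(2, round(W / 85)), color = lcol)
        iid <- iid + 1L
        anns[[iid]] <- mt_polyline("leaf", leaf, instance_id = iid)
      }
    }
    list(image = img,
         ann = mt_annotated_image("", W, H, anns),
         config = cfg)
  })
}

#' Generate a dataset of synthetic scenes on disk
#'
#' Writes `n_scenes` PNG/Labelme-JSON pairs (readable by [read_labelme()])
#' plus a `manifest.json` recording the per-scene seeds. Per-scene seeds are
#' derived from `cfg$seed` by a fixed affine step, so the whole dataset is a
#' deterministic function of one seed.
#'
#' @param n_scenes Number of scenes, `>= 1`.
#' @param cfg A [scene_config()] (its `seed` seeds the whole dataset). May
#'   also be a list of per-scene configs of length `n_scenes` (e.g. mixed
#'   growth stages).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `images`, `annotations` (file paths) and
#'   `seeds`.
#' @export
generate_dataset <- function(n_scenes, cfg, out_dir) {
  if (n_scenes < 1) stop("n_scenes must be >= 1")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop(sprintf("cannot create output directory %s", out_dir))
  cfgs <- if (inherits(cfg, "mt_scene_config")) {
    lapply(seq_len(n_scenes), function(i) {
      ci <- cfg
      ci$seed <- as.integer((cfg$seed + 7919 * (i - 1)) %% 2147483629L)
      ci
    })
  } else {
    stopifnot(length(cfg) == n_scenes)
    cfg
  }
  img_files <- character(n_scenes); ann_files <- character(n_scenes)
  seeds <- integer(n_scenes)
  for (i in seq_len(n_scenes)) {
    sc <- generate_scene(cfgs[[i]])
    img_files[i] <- file.path(out_dir, sprintf("scene_%04d.png", i))
    ann_files[i] <- file.path(out_dir, sprintf("scene_%04d.json", i))
    png::writePNG(sc$image, img_files[i])
    sc$ann$image_path <- basename(img_files[i])
    write_labelme(sc$ann, ann_files[i])
    seeds[i] <- cfgs[[i]]$seed
  }
  manifest <- list(n_scenes = n_scenes, seeds = seeds,
                   images = basename(img_files), annotations = basename(ann_files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(images = img_files, annotations = ann_files, seeds = seeds))
}
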