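# Dotted-line annotation handling: Labelme-dialect JSON in, preprocessing
# (coordinate scaling, ground-truth box synthesis, polyline interpolation,
# equal-interval keypoint subsampling, dataset splitting), COCO-style
# manifest out.
#
# Coordinates are 0-based pixels; valid positions satisfy 0 <= x < width.

CATEGORIES <- c("leaf", "stalk")

#' Construct a polyline annotation
#'
#' One labeled leaf or stalk trajectory: a category plus an ordered list of
#' 2-D points tracing the path.
#'
#' @param category `"leaf"` or `"stalk"` (case-insensitive).
#' @param points An `n x 2` matrix of ordered `(x, y)` pixel coordinates,
#'   `n >= 1`, finite and non-negative.
#' @param instance_id Integer instance label.
#' @return A list of class `mt_polyline`.
#' @export
mt_polyline <- function(category, points, instance_id = 1L) {
  category <- tolower(as.character(category))
  if (!category %in% CATEGORIES) {
    stop(sprintf("unknown category '%s' (expected one of: %s)",
                 category, paste(CATEGORIES, collapse = ", ")))
  }
  points <- as_points_matrix(points)
  if (nrow(points) < 1) stop("annotation needs at least one point")
  if (any(!is.finite(points))) stop("annotation points must be finite")
  if (any(points < 0)) stop("annotation points must be non-negative")
  structure(list(category = category, instance_id = as.integer(instance_id),
                 points = points), class = "mt_polyline")
}

#' Construct an annotated image
#'
#' @param image_path Path of the image file (may be relative or empty for
#'   in-memory scenes).
#' @param width,height Image size in pixels, `> 0`.
#' @param annotations List of [mt_polyline()] objects; points are clipped to
#'   `[0, width - 1] x [0, height - 1]`.
#' @return A list of class `mt_annotated_image`.
#' @export
mt_annotated_image <- function(image_path, width, height, annotations = list()) {
  if (width <= 0 || height <= 0) stop("image size must be positive")
  annotations <- lapply(annotations, function(a) {
    stopifnot(inherits(a, "mt_polyline"))
    a$points[, 1] <- pmin(pmax(a$points[, 1], 0), width - 1)
    a$points[, 2] <- pmin(pmax(a$points[, 2], 0), height - 1)
    a
  })
  structure(list(image_path = image_path, width = as.numeric(width),
                 height = as.numeric(height), annotations = annotations),
            class = "mt_annotated_image")
}

#' @export
print.mt_annotated_image <- function(x, ...) {
  tab <- table(vapply(x$annotations, function(a) a$category, character(1)))
  cat(sprintf("Annotated image %s (%g x %g): %d annotations (%s)\n",
              x$image_path, x$width, x$height, length(x$annotations),
              paste(sprintf("%s %s", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Read a Labelme-dialect annotation file
#'
#' Expects the JSON layout written by the Labelme tool for line-strip
#' annotations: `imagePath`, `imageWidth`, `imageHeight`, and `shapes`, each
#' shape carrying a `label` and an ordered `points` list. Labels are
#' normalized case-insensitively to `leaf`/`stalk`; any other label is an
#' error naming the offender.
#'
#' @param path Path of the JSON file.
#' @return An [mt_annotated_image()].
#' @export
read_labelme <- function(path) {
  if (!file.exists(path)) stop(sprintf("annotation file not found: %s", path))
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  w <- doc$imageWidth; h <- doc$imageHeight
  if (is.null(w) || is.null(h)) stop("annotation file lacks imageWidth/imageHeight")
  shapes <- doc$shapes
  anns <- vector("list", length(shapes))
  for (i in seq_along(shapes)) {
    s <- shapes[[i]]
    lab <- tolower(as.character(s$label))
    if (!lab %in% CATEGORIES) {
      stop(sprintf("unknown label '%s' in %s (expected leaf or stalk)", s$label, path))
    }
    pts <- do.call(rbind, lapply(s$points, function(p) as.numeric(unlist(p))))
    anns[[i]] <- mt_polyline(lab, pts, instance_id = i)
  }
  mt_annotated_image(
    image_path = if (!is.null(doc$imagePath)) doc$imagePath else "",
    width = as.numeric(w), height = as.numeric(h), annotations = anns
  )
}

#' Write a Labelme-dialect annotation file
#'
#' Inverse of [read_labelme()]: writes `shapes` with `label`, `points`
#' (line-strip) and the image size.
#'
#' @param img An [mt_annotated_image()].
#' @param path Destination JSON path.
#' @return `path`, invisibly.
#' @export
write_labelme <- function(img, path) {
  shapes <- lapply(img$annotations, function(a) {
    list(label = a$category,
         points = lapply(seq_len(nrow(a$points)), function(i) as.numeric(a$points[i, ])),
         group_id = a$instance_id,
         shape_type = "linestrip", flags = setNames(list(), character(0)))
  })
  doc <- list(version = "5.0.1", flags = setNames(list(), character(0)),
              shapes = shapes,
              imagePath = img$image_path,
              imageHeight = img$height, imageWidth = img$width)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}

#' Downscale an annotated image
#'
#' Divides the image size and every annotation coordinate by `factor`
#' (rounding the size), mirroring the workflow of downsampling full-resolution
#' field frames by 4x for training while rescaling the stored annotation
#' coordinates accordingly.
#'
#' @param img An [mt_annotated_image()].
#' @param factor Positive scale divisor (4 reduces 6016 x 4016 to 1504 x 1004).
#' @return The rescaled [mt_annotated_image()].
#' @export
scale_annotated_image <- function(img, factor) {
  if (!is.numeric(factor) || length(factor) != 1 || factor <= 0) {
    stop("factor must be a positive number")
  }
  w <- round(img$width / factor); h <- round(img$height / factor)
  anns <- lapply(img$annotations, function(a) {
    a$points <- a$points / factor
    a
  })
  mt_annotated_image(img$image_path, w, h, anns)
}

#' Derive a ground-truth detection box from a trajectory annotation
#'
#' The minimum point coordinates give the upper-left corner and the maximum
#' coordinates the lower-right corner; each side is then padded outward by
#' `offset` pixels and the result clipped to the image. Degenerate (zero-area)
#' boxes after clipping are rejected.
#'
#' @param ann An [mt_polyline()].
#' @param offset Outward padding per side, pixels, `>= 0` (the working-scale
#'   default in the full-resolution pipeline is 20).
#' @param image_size `c(width, height)` used for clipping.
#' @return An [mt_box()].
#' @export
derive_bbox <- function(ann, offset = 20, image_size) {
  if (nrow(ann$points) == 0) stop("cannot derive a box from an empty point list")
  if (offset < 0) stop("offset must be >= 0")
  x1 <- min(ann$points[, 1]) - offset
  y1 <- min(ann$points[, 2]) - offset
  x2 <- max(ann$points[, 1]) + offset
  y2 <- max(ann$points[, 2]) + offset
  x1 <- min(max(x1, 0), image_size[1]); x2 <- min(max(x2, 0), image_size[1])
  y1 <- min(max(y1, 0), image_size[2]); y2 <- min(max(y2, 0), image_size[2])
  b <- mt_box(x1, y1, x2, y2)
  if (box_area(b) <= 0) stop("derived box is degenerate (zero area)")
  b
}

#' Densify a polyline by arc-length interpolation
#'
#' Piecewise-linear interpolation that inserts points so that consecutive
#' output points are at most `spacing` apart along the path. Every output
#' point lies exactly on the input polyline; the first and last input points
#' are retained and order is preserved. Used to expand the sparse hand-labeled
#' trajectory points before keypoint subsampling.
#'
#' @param points An `n x 2` matrix of ordered vertices, `n >= 1`.
#' @param spacing Maximum arc-length gap between consecutive output points,
#'   `> 0` (default 5 px at working resolution).
#' @return An `m x 2` matrix, `m >= n` up to removal of duplicate vertices.
#' @export
densify_polyline <- function(points, spacing = 5) {
  if (spacing <= 0) stop("spacing must be > 0")
  points <- as_points_matrix(points)
  n <- nrow(points)
  if (n == 0) stop("need at least one point")
  if (n == 1) return(points)
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] - points[-n, , drop = FALSE])^2))
  total <- sum(seg)
  if (total == 0) return(points[1, , drop = FALSE])
  out <- list(points[1, ])
  for (i in seq_len(n - 1)) {
    if (seg[i] == 0) next
    k <- ceiling(seg[i] / spacing)           # pieces for this segment
    ts <- seq_len(k) / k
    a <- points[i, ]; b <- points[i + 1, ]
    for (t in ts) out[[length(out) + 1]] <- a + t * (b - a)
  }
  do.call(rbind, out)
}

#' Subsample trajectory points at equal index intervals
#'
#' Keeps `k = max(2, round(n * ratio))` points (1 when `n = 1`) at equally
#' spaced indices including the first and last point, producing the
#' ground-truth keypoint set from a densified trajectory (the working-pipeline
#' ratio is 30%).
#'
#' @param points An `n x 2` matrix of ordered points, `n >= 1`.
#' @param ratio Fraction of points to keep, in `(0, 1]`.
#' @return A `k x 2` matrix that is a subsequence of the input.
#' @export
subsample_equal_interval <- function(points, ratio = 0.3) {
  if (ratio <= 0 || ratio > 1) stop("ratio must be in (0, 1]")
  points <- as_points_matrix(points)
  n <- nrow(points)
  if (n == 0) stop("need at least one point")
  if (n == 1) return(points)
  k <- max(2L, as.integer(round(n * ratio)))
  k <- min(k, n)
  idx <- unique(round(seq(1, n, length.out = k)))
  points[idx, , drop = FALSE]
}

#' Split a dataset reproducibly by ratio
#'
#' Seeded uniform shuffle followed by largest-remainder apportionment of the
#' item count to the three ratios, so sizes always sum to `n` (for 10 items at
#' 7:2:1 this is 7/2/1). The same seed always yields the same partition.
#'
#' @param items A list or vector to split.
#' @param ratios `c(train, val, test)` fractions summing to 1.
#' @param seed Integer RNG seed.
#' @return A list with `train`, `val`, `test` (disjoint, exhaustive) and the
#'   `seed` used.
#' @export
split_dataset <- function(items, ratios = c(0.7, 0.2, 0.1), seed = 1L) {
  if (length(ratios) != 3 || any(ratios < 0) || abs(sum(ratios) - 1) > 1e-9) {
    stop("ratios must be three non-negative fractions summing to 1")
  }
  n <- length(items)
  if (n < 1) stop("cannot split an empty dataset")
  sizes <- largest_remainder(n, ratios)
  perm <- with_local_seed(seed, sample.int(n))
  bounds <- cumsum(sizes)
  tr <- perm[seq_len(sizes[1])]
  va <- if (sizes[2] > 0) perm[(bounds[1] + 1):bounds[2]] else integer(0)
  te <- if (sizes[3] > 0) perm[(bounds[2] + 1):bounds[3]] else integer(0)
  list(train = items[sort(tr)], val = items[sort(va)], test = items[sort(te)],
       seed = as.integer(seed))
}

largest_remainder <- function(n, ratios) {
  exact <- n * ratios
  sizes <- floor(exact)
  left <- n - sum(sizes)
  if (left > 0) {
    frac <- exact - sizes
    give <- order(-frac, seq_along(ratios))[seq_len(left)]
    sizes[give] <- sizes[give] + 1
  }
  as.integer(sizes)
}

# Run expr under a fixed seed without disturbing the caller's RNG state.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Export a preprocessed detection dataset as a COCO-style manifest
#'
#' Composes the preprocessing steps: for every annotation, densifies the
#' trajectory ([densify_polyline()]), subsamples ground-truth keypoints
#' ([subsample_equal_interval()]), and derives the detection box
#' ([derive_bbox()]), then writes a single COCO-style JSON manifest with
#' `images`, `categories` (leaf = 1, stalk = 2) and `annotations` carrying
#' `bbox` as `[x, y, w, h]`, a flat `keypoints` array `[x1, y1, v1, ...]`
#' (visibility always 2), and the original `polyline` vertices. Coordinates
#' round-trip exactly through [import_detection_dataset()].
#'
#' @param images List of [mt_annotated_image()] objects, non-empty.
#' @param out_path Path of the manifest JSON to write.
#' @param offset Box padding per side in pixels.
#' @param ratio Keypoint subsampling fraction.
#' @param spacing Densification spacing in pixels.
#' @return The manifest path, invisibly.
#' @export
export_detection_dataset <- function(images, out_path, offset = 20,
                                     ratio = 0.3, spacing = 5) {
  if (length(images) == 0) stop("no images to export")
  imgs <- list(); anns <- list(); aid <- 0L
  for (i in seq_along(images)) {
    im <- images[[i]]
    imgs[[i]] <- list(id = i, file_name = im$image_path,
                      width = im$width, height = im$height)
    for (a in im$annotations) {
      aid <- aid + 1L
      dense <- densify_polyline(a$points, spacing)
      kps <- subsample_equal_interval(dense, ratio)
      box <- derive_bbox(a, offset, c(im$width, im$height))
      flat <- as.numeric(t(cbind(kps, 2)))
      anns[[aid]] <- list(
        id = aid, image_id = i,
        category_id = match(a$category, CATEGORIES),
        bbox = c(box[1], box[2], box[3] - box[1], box[4] - box[2]),
        area = box_area(box),
        keypoints = flat, num_keypoints = nrow(kps),
        polyline = as.numeric(t(a$points)),
        iscrowd = 0
      )
    }
  }
  doc <- list(
    info = list(description = "maize leaf/stalk trajectory detection manifest",
                offset = offset, ratio = ratio, spacing = spacing),
    images = imgs,
    categories = list(list(id = 1, name = "leaf"), list(id = 2, name = "stalk")),
    annotations = anns
  )
  jsonlite::write_json(doc, out_path, auto_unbox = TRUE, digits = NA)
  invisible(out_path)
}

#' Read back a COCO-style manifest written by [export_detection_dataset()]
#'
#' @param path Manifest path.
#' @return A list with `images` (each carrying `id`, `file_name`, `width`,
#'   `height`, and `targets`: per-annotation `box`, `category`, `keypoints`
#'   matrix, `polyline` matrix) plus the manifest `info`.
#' @export
import_detection_dataset <- function(path) {
  if (!file.exists(path)) stop(sprintf("manifest not found: %s", path))
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  cats <- vapply(doc$categories, function(cc) cc$name, character(1))
  ids <- vapply(doc$categories, function(cc) cc$id, numeric(1))
  images <- lapply(doc$images, function(im) {
    list(id = im$id, file_name = im$file_name,
         width = im$width, height = im$height, targets = list())
  })
  names(images) <- vapply(doc$images, function(im) as.character(im$id), character(1))
  for (a in doc$annotations) {
    bb <- as.numeric(unlist(a$bbox))
    kp <- matrix(as.numeric(unlist(a$keypoints)), ncol = 3, byrow = TRUE)
    pl <- matrix(as.numeric(unlist(a$polyline)), ncol = 2, byrow = TRUE)
    tgt <- list(box = mt_box(bb[1], bb[2], bb[1] + bb[3], bb[2] + bb[4]),
                category = cats[match(a$category_id, ids)],
                keypoints = kp[, 1:2, drop = FALSE],
                polyline = pl)
    key <- as.character(a$image_id)
    images[[key]]$targets <- c(images[[key]]$targets, list(tgt))
  }
  list(images = unname(images), info = doc$info)
}
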