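# Shared fixture builders (everything is generated in code at test time).

tmp_labelme <- function(shapes, width = 200, height = 150) {
  path <- tempfile(fileext = ".json")
  doc <- list(
    version = "5.0.1",
    shapes = lapply(shapes, function(s) {
      list(label = s$label,
           points = lapply(seq_len(nrow(s$points)), function(i) as.numeric(s$points[i, ])),
           shape_type = "linestrip")
    }),
    imagePath = "img.png", imageWidth = width, imageHeight = height
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  path
}

# a raw detection with a rendered heatmap, as forward_image() would emit
fake_raw_det <- function(box, class = "leaf", score = 0.9, keypoints = NULL,
                         size = 28) {
  hm <- render_target_heatmap(keypoints, box, size = size, sigma_hm = 2)
  list(box = box, class = class, class_id = match(class, c("leaf", "stalk")),
       score = score, heatmap = hm)
}

small_scene_samples <- function(n = 4, seed = 1, image_size = 192) {
  dir <- tempfile("scenes")
  cfgs <- lapply(seq_len(n), function(i) {
    scene_config(image_size = c(image_size, image_size),
                 stage = c("early", "middle")[(i - 1) %% 2 + 1],
                 seed = as.integer(seed + 101 * (i - 1)))
  })
  files <- generate_dataset(n, cfgs, dir)
  manifest <- file.path(dir, "manifest_det.json")
  export_detection_dataset(lapply(files$annotations, read_labelme), manifest,
                           offset = 5, ratio = 0.3, spacing = 3)
  load_detection_dataset(manifest, dir)
}
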