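# Serialization: 8-bit grayscale PNG images, COCO-style ground-truth JSON,
# YAML configs.

#' Write an image as 8-bit grayscale PNG
#'
#' Intensity `i` is stored as `round(255 * i)`.
#'
#' @param image matrix in `[0, 1]`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(round(clip01(image) * 255) / 255, path)
  invisible(path)
}

#' Read an 8-bit grayscale PNG
#'
#' @param path PNG file path.
#' @return A matrix in `[0, 1]` (first channel if the file has several).
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}

#' Write a 0/255 binary mask PNG
#' @param mask 0/1 matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask != 0), nrow(mask), ncol(mask)), path)
  invisible(path)
}

nodule_to_json <- function(nd) {
  list(
    bbox = as.numeric(nd$bbox),
    ellipse = list(center = as.numeric(nd$center),
                   semi_axes = as.numeric(nd$semi_axes),
                   rotation = nd$rotation, contrast = nd$contrast),
    category_id = 1L
  )
}

#' Serialize a phantom dataset to a directory
#'
#' Images as 8-bit grayscale PNGs and ground truth as a COCO-style JSON
#' (`category_id 1 = "nodule"`, half-open `[x0, y0, x1, y1]` boxes).
#'
#' @param dataset a `sono_phantom_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gt <- list(categories = list(list(id = 1L, name = "nodule")),
             images = list())
  for (i in seq_along(dataset$items)) {
    it <- dataset$items[[i]]
    fn <- sprintf("img_%04d.png", i)
    write_image_png(it$image, file.path(dir, fn))
    gt$images[[i]] <- list(
      file_name = fn, split = dataset$split[i],
      annotations = lapply(it$nodules, nodule_to_json)
    )
  }
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Serialize an annotated image to a directory
#'
#' Writes the marker-layered image PNG, the 0/255 mask PNG and a JSON of
#' the marker groups (`rect`, `points`, `group_size`, `is_pseudo`).
#'
#' @param annotated a `sono_annotated`.
#' @param dir output directory.
#' @param stem file-name stem.
#' @return `dir`, invisibly.
#' @export
write_annotated <- function(annotated, dir, stem = "annotated") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_image_png(annotated$image, file.path(dir, paste0(stem, ".png")))
  write_mask_png(annotated$mask, file.path(dir, paste0(stem, "_mask.png")))
  groups <- lapply(annotated$groups, function(g) {
    list(rect = as.numeric(g$rect),
         points = apply(unname(g$points), 1, as.numeric, simplify = FALSE),
         group_size = g$group_size, is_pseudo = g$is_pseudo)
  })
  jsonlite::write_json(list(groups = groups),
                       file.path(dir, paste0(stem, "_groups.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a YAML configuration file
#'
#' Recognized top-level sections (`phantom`, `detector`, `classifier`,
#' `texsynth`) are merged over the package defaults.
#'
#' @param path YAML file path.
#' @return Named list of config objects.
#' @export
read_config_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- list()
  if (!is.null(raw$phantom)) {
    out$phantom <- do.call(phantom_config, raw$phantom)
  }
  if (!is.null(raw$classifier)) {
    out$classifier <- do.call(classifier_config, raw$classifier)
  }
  if (!is.null(raw$detector)) {
    args <- raw$detector
    if (!is.null(out$classifier)) args$classifier <- out$classifier
    out$detector <- do.call(detector_config, args)
  }
  if (!is.null(raw$texsynth)) {
    out$texsynth <- do.call(texsynth_params, raw$texsynth)
  }
  out
}
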