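# Dataset writer: materializes synthetic crops/scenes on disk in the
# exchange layouts the pipeline consumes.
#
#   classification: <out>/<split>/<class_name>/crop_XXXX.ppm
#   detection:      <out>/images/<split>/scene_XXXX.ppm
#                   <out>/labels/<split>/scene_XXXX.txt   (YOLO lines)
#
# plus a manifest.json listing per-split counts. Split assignment, item
# seeds and hence file bytes are all functions of the top-level seed.

split_assign <- function(n, split_ratios, seed) {
  stopifnot(abs(sum(split_ratios) - 1) < 1e-8)
  counts <- floor(split_ratios * n)
  rem <- n - sum(counts)
  if (rem > 0) {  # hand leftovers to the largest splits, deterministically
    o <- order(-split_ratios)
    for (i in seq_len(rem)) counts[o[(i - 1L) %% length(counts) + 1L]] <-
        counts[o[(i - 1L) %% length(counts) + 1L]] + 1L
  }
  lab <- rep(names(split_ratios), counts)
  with_seed(seed, sample(lab))
}

#' Write a synthetic dataset to disk
#'
#' Generates and writes either fine-grained classification crops (one
#' directory per class under each split) or multi-object detection scenes
#' (images plus YOLO-format label files), with a `manifest.json` of
#' per-split counts. Byte-identical re-runs under the same seed.
#'
#' @param out_dir output directory (created).
#' @param library species library from [fgr_make_species_library()].
#' @param n_items total crops (classification, spread round-robin over
#'   classes) or scenes (detection).
#' @param split_ratios named ratios summing to 1, e.g.
#'   `c(train = 0.7, test = 0.3)`.
#' @param type `"classification"` or `"detection"`.
#' @param size crop side (classification).
#' @param scene template [fgr_scene_spec()] whose seed is re-derived per
#'   scene (detection).
#' @param augment augment classification crops (train-style jitter).
#' @param seed master seed.
#' @return manifest list (also written as JSON), invisibly.
#' @export
fgr_write_dataset <- function(out_dir, library, n_items,
                              split_ratios = c(train = 0.7, test = 0.3),
                              type = c("classification", "detection"),
                              size = 64L, scene = fgr_scene_spec(),
                              augment = TRUE, seed = 1L) {
  type <- match.arg(type)
  if (is.null(names(split_ratios))) {
    stop("split_ratios must be named (e.g. c(train = .7, test = .3))")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  splits <- split_assign(n_items, split_ratios, child_seed(seed, "split"))
  counts <- stats::setNames(rep(0L, length(split_ratios)), names(split_ratios))
  if (type == "classification") {
    K <- length(library)
    for (i in seq_len(n_items)) {
      spec <- library[[(i - 1L) %% K + 1L]]
      sp <- splits[i]
      d <- file.path(out_dir, sp, spec$name)
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      img <- fgr_render_crop(spec, size = size, augment = augment,
                             seed = child_seed(seed, paste0("crop", i)))
      fgr_write_ppm(img, file.path(d, sprintf("crop_%04d.ppm", i)))
      counts[sp] <- counts[sp] + 1L
    }
  } else {
    for (sp in names(split_ratios)) {
      dir.create(file.path(out_dir, "images", sp), recursive = TRUE,
                 showWarnings = FALSE)
      dir.create(file.path(out_dir, "labels", sp), recursive = TRUE,
                 showWarnings = FALSE)
    }
    for (i in seq_len(n_items)) {
      sp <- splits[i]
      sc <- scene
      sc$seed <- child_seed(seed, paste0("scene", i))
      rs <- fgr_render_scene(library, sc)
      fgr_write_ppm(rs$image,
                    file.path(out_dir, "images", sp,
                              sprintf("scene_%04d.ppm", i)))
      fgr_write_yolo(rs$truth,
                     file.path(out_dir, "labels", sp,
                               sprintf("scene_%04d.txt", i)),
                     image_size = c(sc$image_size, sc$image_size))
      counts[sp] <- counts[sp] + 1L
    }
  }
  manifest <- list(type = type, seed = seed, n_items = n_items,
                   classes = vapply(library, `[[`, "", "name"),
                   counts = as.list(counts))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

# Load a classification split: list of images plus 0-based labels.
load_classification_split <- function(data_dir, split) {
  d <- file.path(data_dir, split)
  if (!dir.exists(d)) stop("missing split directory ", d)
  cls_dirs <- sort(list.dirs(d, recursive = FALSE))
  if (!length(cls_dirs)) stop("no class directories under ", d)
  imgs <- list(); labels <- integer(0); files <- character(0)
  for (ci in seq_along(cls_dirs)) {
    fs <- sort(list.files(cls_dirs[ci], pattern = "\\.ppm$", full.names = TRUE))
    for (f in fs) {
      imgs[[length(imgs) + 1L]] <- fgr_read_ppm(f)
      labels <- c(labels, ci - 1L)
      files <- c(files, f)
    }
  }
  list(images = imgs, labels = labels, files = files,
       class_names = basename(cls_dirs))
}

# Load a detection split: images plus truth tables.
load_detection_split <- function(data_dir, split) {
  di <- file.path(data_dir, "images", split)
  dl <- file.path(data_dir, "labels", split)
  if (!dir.exists(di)) stop("missing split directory ", di)
  fs <- sort(list.files(di, pattern = "\\.ppm$", full.names = TRUE))
  items <- lapply(fs, function(f) {
    img <- fgr_read_ppm(f)
    lab <- file.path(dl, sub("\\.ppm$", ".txt", basename(f)))
    truth <- fgr_read_yolo(lab, image_size = c(dim(img)[2L], dim(img)[1L]))
    list(image = img, truth = truth, file = f)
  })
  items
}
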