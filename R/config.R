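# Run configuration: one flat named list covering every pipeline knob,
# serializable to JSON and round-trippable.

#' Build a run configuration
#'
#' Defaults are the toy profile: 64x64 crops, 8 classes, CPU-sized
#' widths, a few dozen epochs on cached embeddings. `profile = "full"`
#' switches to the published large-scale regime (448x448 inputs, batch
#' 128, 150 epochs, cosine period 20) as a named preset; it is not the
#' test surface.
#'
#' @param task one of `"generate"`, `"classify"`, `"detect"`,
#'   `"evaluate"`, `"ablate"`.
#' @param profile `"toy"` (default) or `"full"`.
#' @param ... overrides for any field.
#' @return named list of class `fgr_config`.
#' @export
fgr_config <- function(task = "classify", profile = c("toy", "full"), ...) {
  profile <- match.arg(profile)
  cfg <- list(
    task = task,
    profile = profile,
    data_dir = "data",
    out_dir = "runs/run1",
    n_classes = 8L,
    similarity = 0.9,
    image_size = 64L,
    scene_size = 128L,
    n_train_per_class = 100L,
    n_val_per_class = 10L,
    n_scenes = 60L,
    stage_widths = c(32L, 64L, 96L, 128L),
    n_blocks = c(1L, 1L, 1L, 1L),
    shuffle_groups = 2L,
    Dh = 32L,
    max_nodes = 32L,
    eps = 0.1,
    lr = 0.15,
    momentum = 0.9,
    weight_decay = 2e-3,
    cosine_period = 50L,
    batch_size = 16L,
    epochs = 100L,
    det_epochs = 150L,
    det_lr = 1.0,
    det_box_lr = 0.02,
    anchors = c(28, 22, 44, 34),
    Nt = 0.5,
    score_floor = 0.001,
    conf_thresh = 0.20,
    iou_thresh = 0.5,
    seed = 1L,
    nms = "soft"
  )
  if (profile == "full") {
    cfg$image_size <- 448L
    cfg$batch_size <- 128L
    cfg$epochs <- 150L
    cfg$cosine_period <- 20L
    cfg$stage_widths <- c(64L, 128L, 256L, 512L)
    cfg$n_blocks <- c(2L, 3L, 3L, 2L)
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  validate_config(canonical_config(cfg))
}

canonical_config <- function(cfg) {
  ints <- c("n_classes", "image_size", "scene_size", "n_train_per_class",
            "n_val_per_class", "n_scenes", "stage_widths", "n_blocks",
            "shuffle_groups", "Dh", "max_nodes", "cosine_period",
            "batch_size", "epochs", "det_epochs", "seed")
  for (f in ints) cfg[[f]] <- as.integer(cfg[[f]])
  nums <- c("similarity", "eps", "lr", "momentum", "weight_decay",
            "anchors", "Nt", "score_floor", "conf_thresh", "iou_thresh",
            "det_lr", "det_box_lr")
  for (f in nums) cfg[[f]] <- as.numeric(cfg[[f]])
  structure(cfg, class = "fgr_config")
}

validate_config <- function(cfg) {
  stopifnot(cfg$n_classes >= 2L, cfg$lr > 0, cfg$momentum >= 0,
            cfg$cosine_period >= 1L, cfg$batch_size >= 1L,
            cfg$epochs >= 1L, cfg$Nt > 0, cfg$Nt < 1,
            cfg$score_floor >= 0, cfg$score_floor < 1,
            cfg$iou_thresh > 0, cfg$iou_thresh < 1,
            cfg$eps >= 0, cfg$eps < 1, cfg$seed >= 0L)
  cfg
}

#' Serialize / parse a configuration
#'
#' JSON on disk; `fgr_read_config(fgr_write_config(cfg, path))` restores a
#' configuration equal to `cfg`.
#'
#' @param cfg an [fgr_config()].
#' @param path file path.
#' @return `fgr_write_config` returns `path` invisibly; `fgr_read_config`
#'   returns the configuration.
#' @export
fgr_write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname fgr_write_config
#' @export
fgr_read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_config(canonical_config(raw))
}
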