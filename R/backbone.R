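# Cross-stage partial (CSP) backbone.
#
# Each stage splits its input into a processed "base" branch (a 1x1
# projection followed by n residual bottleneck blocks) and a "cross"
# shortcut branch (a plain 1x1 projection). The two halves are
# concatenated, mixed by channel shuffling, and downsampled by a stride-2
# 3x3 convolution. Splitting the stage this way cuts parameters and
# duplicate gradient flow relative to running every block at full width.

#' Construct a feature map
#'
#' Wraps an `H x W x C` activation array with its backbone stage index.
#'
#' @param values numeric array `H x W x C`, all finite.
#' @param stage_index integer in 1..4.
#' @return object of class `fgr_feature_map` (the array with attributes).
#' @export
fgr_feature_map <- function(values, stage_index = 1L) {
  stopifnot(length(dim(values)) == 3L, all(dim(values) >= 1L),
            all(is.finite(values)),
            stage_index >= 1L, stage_index <= 4L)
  structure(values, stage_index = as.integer(stage_index),
            class = c("fgr_feature_map", "array"))
}

#' @export
print.fgr_feature_map <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<fgr_feature_map stage %d: %d x %d x %d>\n",
              attr(x, "stage_index"), d[1], d[2], d[3]))
  invisible(x)
}

stage_of <- function(x) attr(x, "stage_index")

#' Stage configuration for the CSP backbone
#'
#' @param n_blocks number of residual bottleneck blocks in the base branch
#'   (`n_blocks = 0` leaves both branches as bare 1x1 projections).
#' @param in_channels,out_channels positive channel counts; each branch
#'   projects to `out_channels / 2` so the concatenation restores the width.
#' @param shuffle_groups group count for channel shuffling of the
#'   concatenated branches; must divide `out_channels`.
#' @return list of class `fgr_stage_config`.
#' @export
fgr_stage_config <- function(n_blocks, in_channels, out_channels,
                             shuffle_groups = 2L) {
  stopifnot(n_blocks >= 0L, in_channels >= 1L, out_channels >= 2L,
            shuffle_groups >= 1L)
  if (out_channels %% 2L != 0L) {
    stop("out_channels must be even (two equal-width branches)")
  }
  if (out_channels %% shuffle_groups != 0L) {
    stop("shuffle_groups must divide the concatenated channel count")
  }
  structure(list(n_blocks = as.integer(n_blocks),
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 shuffle_groups = as.integer(shuffle_groups)),
            class = "fgr_stage_config")
}

#' Channel shuffle
#'
#' Deterministic channel permutation: reshape the `C` channels to
#' `(groups, C/groups)`, transpose, flatten. Mixes information between the
#' grouped branches at zero parameter cost. The per-pixel multiset of
#' values is preserved.
#'
#' @param x feature map or plain `H x W x C` array.
#' @param groups positive integer dividing `C`.
#' @return same type as `x` with permuted channels.
#' @export
fgr_channel_shuffle <- function(x, groups) {
  d <- dim(x); C <- d[3L]
  groups <- as.integer(groups)
  if (C %% groups != 0L) stop("groups (", groups, ") does not divide C (", C, ")")
  perm <- as.vector(matrix(seq_len(C), nrow = groups, byrow = TRUE))
  y <- x[, , perm, drop = FALSE]
  if (inherits(x, "fgr_feature_map")) {
    fgr_feature_map(unclass(y), stage_of(x))
  } else y
}

# Parameters for one CSP stage: branch projections, n bottleneck blocks,
# stride-2 downsampling conv. Norm layers are per-channel affine transforms
# that are the identity at initialization.
init_csp_stage <- function(cfg) {
  half <- cfg$out_channels %/% 2L
  blocks <- lapply(seq_len(cfg$n_blocks), function(i) {
    mid <- max(1L, half %/% 2L)
    list(w1 = he_conv(1L, 1L, half, mid), b1 = rand_bias(mid),
         w2 = dirac_conv(3L, 3L, mid, half), b2 = rand_bias(half))
  })
  list(cfg = cfg,
       w_base = he_conv(1L, 1L, cfg$in_channels, half),
       b_base = rand_bias(half),
       w_cross = he_conv(1L, 1L, cfg$in_channels, half),
       b_cross = rand_bias(half),
       blocks = blocks,
       w_down = dirac_conv(3L, 3L, cfg$out_channels, cfg$out_channels),
       b_down = rand_bias(cfg$out_channels))
}

# Instance normalization: standardize each channel over its spatial
# positions. Deterministic at inference with no batch statistics, which is
# what a frozen random-feature backbone needs; it keeps activation scale
# O(1) through depth so downstream attention does not collapse to uniform.
instance_norm <- function(x, eps = 1e-5) {
  d <- dim(x)
  m <- matrix(x, d[1L] * d[2L], d[3L])
  mu <- colMeans(m)
  sdv <- sqrt(colMeans(m^2) - mu^2 + eps)
  array(sweep(sweep(m, 2L, mu), 2L, sdv, `/`), d)
}

# conv -> instance norm -> channel threshold -> SiLU, the standard block
# everywhere in the backbone. The per-channel bias sits after the norm so
# it acts as a response threshold; pooled activations then behave like
# soft occupancy counts, which is what gives an untrained random backbone
# usable color/texture statistics.
conv_block <- function(x, w, b = NULL, stride = 1L, pad = 0L) {
  h <- instance_norm(fgr_conv2d(x, w, stride = stride, pad = pad))
  if (!is.null(b)) h <- sweep(h, 3L, b, `+`)
  fgr_silu(h)
}

# Threshold biases spread over the working range of normalized responses.
rand_bias <- function(n) stats::runif(n, -1.5, 1.5)

# 3x3 residual bottleneck: 1x1 reduce -> 3x3 expand -> residual add.
bottleneck_forward <- function(x, blk) {
  h <- conv_block(x, blk$w1, blk$b1)
  h <- instance_norm(fgr_conv2d(h, blk$w2, pad = 1L))
  h <- sweep(h, 3L, blk$b2, `+`)
  fgr_silu(x + h)
}

#' Run one CSP stage
#'
#' `out = Fdown(S(XBase, XCross))` with `XBase = Fbase(f1x1(X))` (the
#' projected input pushed through `n_blocks` residual bottlenecks),
#' `XCross = f1x1(X)` the shortcut projection, `S` channel shuffling of the
#' concatenation and `Fdown` a stride-2 3x3 convolution halving H and W.
#'
#' @param x input `fgr_feature_map` with `cfg$in_channels` channels.
#' @param cfg an [fgr_stage_config()].
#' @param params stage parameters from the model checkpoint; if `NULL`,
#'   fresh parameters are drawn from the current RNG state.
#' @return `fgr_feature_map` of shape `ceil(H/2) x ceil(W/2) x out_channels`
#'   tagged with the next stage index.
#' @export
fgr_csp_stage <- function(x, cfg, params = NULL) {
  d <- dim(x)
  if (d[3L] != cfg$in_channels) {
    stop("csp_stage: input has ", d[3L], " channels, config expects ",
         cfg$in_channels)
  }
  if (d[1L] <= 1L || d[2L] <= 1L) {
    stop("csp_stage: spatial extent ", d[1L], "x", d[2L],
         " is degenerate before downsampling")
  }
  if (is.null(params)) params <- init_csp_stage(cfg)
  xv <- unclass(x)
  base <- conv_block(xv, params$w_base, params$b_base)
  for (blk in params$blocks) base <- bottleneck_forward(base, blk)
  cross <- conv_block(xv, params$w_cross, params$b_cross)
  cat_ <- array(c(base, cross), c(dim(base)[1:2], cfg$out_channels))
  mixed <- fgr_channel_shuffle(cat_, cfg$shuffle_groups)
  down <- conv_block(mixed, params$w_down, params$b_down,
                     stride = 2L, pad = 1L)
  fgr_feature_map(down, min(4L, stage_of(x) + 1L))
}

#' Default toy backbone configuration
#'
#' Four stages with small CPU-sized widths. The stage widths of the original
#' design are unpublished, so these are an explicit package choice.
#'
#' @param widths channel count per stage.
#' @param n_blocks residual blocks per stage.
#' @param shuffle_groups shuffle group count.
#' @return list of [fgr_stage_config()]s.
#' @export
fgr_default_stages <- function(widths = c(32L, 64L, 96L, 128L),
                               n_blocks = c(1L, 1L, 1L, 1L),
                               shuffle_groups = 2L) {
  ins <- c(3L, widths[-length(widths)])
  Map(function(n, ci, co) fgr_stage_config(n, ci, co, shuffle_groups),
      n_blocks, ins, widths)
}

# Initialize all backbone parameters (stages + the phi conv appended to each
# pyramid stage for cross-layer attention).
init_backbone <- function(configs, seed = NULL) {
  with_seed(seed, {
    stages <- lapply(configs, init_csp_stage)
    phi <- lapply(configs, function(cfg) {
      list(w = he_conv(3L, 3L, cfg$out_channels, cfg$out_channels),
           b = rand_bias(cfg$out_channels))
    })
    list(configs = configs, stages = stages, phi = phi)
  })
}

#' Backbone forward pass
#'
#' Runs the image through every CSP stage and returns the stage-2, stage-3
#' and stage-4 feature maps (the pyramid levels used downstream).
#'
#' @param image numeric array `H x W x 3` with `H`, `W` divisible by the
#'   total downsampling factor `2^n_stages` (or set `resize = TRUE` to crop
#'   to the nearest multiple).
#' @param backbone parameter set from [init_backbone()] /
#'   [fgr_model()]`$backbone`.
#' @param resize if `TRUE`, center-crop indivisible inputs instead of
#'   failing.
#' @param all_stages if `TRUE` return every stage, not just 2..4.
#' @return named list of `fgr_feature_map`s (`stage2`, `stage3`, `stage4`).
#' @export
fgr_backbone_forward <- function(image, backbone, resize = FALSE,
                                 all_stages = FALSE) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3L] == 3L)
  factor <- 2L^length(backbone$configs)
  d <- dim(image)
  if (d[1L] %% factor != 0L || d[2L] %% factor != 0L) {
    if (!resize) {
      stop("image ", d[1L], "x", d[2L], " not divisible by downsampling factor ",
           factor, " (set resize = TRUE to center-crop)")
    }
    nh <- (d[1L] %/% factor) * factor; nw <- (d[2L] %/% factor) * factor
    if (nh < factor || nw < factor) stop("image too small for backbone")
    r0 <- (d[1L] - nh) %/% 2L; c0 <- (d[2L] - nw) %/% 2L
    image <- image[r0 + seq_len(nh), c0 + seq_len(nw), , drop = FALSE]
  }
  x <- fgr_feature_map(image, 1L)
  out <- vector("list", length(backbone$configs))
  for (s in seq_along(backbone$configs)) {
    x <- fgr_csp_stage(x, backbone$configs[[s]], backbone$stages[[s]])
    out[[s]] <- fgr_feature_map(unclass(x), s)
  }
  names(out) <- paste0("stage", seq_along(out))
  if (all_stages) out else out[c("stage2", "stage3", "stage4")]
}

#' Count learnable scalars in a parameter tree
#'
#' @param params nested list of numeric arrays.
#' @return total number of scalar parameters.
#' @export
fgr_param_count <- function(params) {
  if (is.numeric(params)) return(length(params))
  if (is.list(params)) return(sum(vapply(params, fgr_param_count, 0)))
  0
}

#' Save / load a checkpoint
#'
#' A checkpoint is a single-file archive of the named parameter arrays of a
#' model (written with `saveRDS`). Runtime artifact only.
#'
#' @param model model object (nested parameter list).
#' @param path file path.
#' @return `fgr_save_checkpoint` returns `path` invisibly;
#'   `fgr_load_checkpoint` returns the model.
#' @export
fgr_save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname fgr_save_checkpoint
#' @export
fgr_load_checkpoint <- function(path) readRDS(path)
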