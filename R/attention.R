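# Cross-stage trilinear attention (CTA).
#
# For a stage feature map X (H x W x C) and phi(X), the output of one extra
# 3x3 conv appended to the same stage, the module builds a channel-channel
# relation matrix
#
#   Fc = N(M((1/WH) X^T phi(X)))            (C x C, row-stochastic)
#
# with M the signed square root and N a row-wise softmax, then multiplies
# the relation back onto phi(X) to obtain one spatial attention map per
# channel:
#
#   Fd = N(M(Fc^T phi(X)))                  (C x HW, each row sums to 1)
#
# Applying CTA at stages k = 2, 3, 4 yields an attention pyramid whose
# levels attend to parts of different physical sizes.

#' Attention map container
#'
#' @param maps array `C' x H x W`; every part-channel's spatial map is
#'   nonnegative and sums to 1.
#' @param level pyramid level (backbone stage index), integer in 2..4.
#' @return object of class `fgr_attention`.
#' @export
fgr_attention <- function(maps, level) {
  stopifnot(length(dim(maps)) == 3L, all(is.finite(maps)), all(maps >= 0))
  sums <- apply(maps, 1L, sum)
  stopifnot(all(abs(sums - 1) < 1e-5))
  structure(list(maps = maps, level = as.integer(level)),
            class = "fgr_attention")
}

#' @export
print.fgr_attention <- function(x, ...) {
  d <- dim(x$maps)
  cat(sprintf("<fgr_attention level %d: %d part maps of %d x %d>\n",
              x$level, d[1], d[2], d[3]))
  invisible(x)
}

#' Bilinear pooling of two feature streams
#'
#' The second-order descriptor `v((1/WH) sum_ij (XA)_ij^T (XB)_ij)`: the
#' spatial mean of per-position outer products, flattened column-major
#' (`CA` index fastest). The classic bilinear-CNN feature; kept as a
#' baseline primitive.
#'
#' @param xa,xb feature maps sharing H and W (channel counts may differ).
#' @return numeric vector of length `CA * CB`.
#' @export
fgr_bilinear_pool <- function(xa, xb) {
  da <- dim(xa); db <- dim(xb)
  if (!all(da[1:2] == db[1:2])) {
    stop("bilinear_pool: spatial sizes differ (", da[1], "x", da[2], " vs ",
         db[1], "x", db[2], ")")
  }
  A <- as_position_matrix(unclass(xa))
  B <- as_position_matrix(unclass(xb))
  as.vector(crossprod(A, B) / nrow(A))
}

#' Cross-channel relation matrix
#'
#' `Fc = N(M((1/WH) X^T phi(X)))`: raw channel correlations across the
#' stage and its appended layer, signed-square-rooted and row-softmaxed.
#' Each row of the result sums to 1.
#'
#' @param x stage feature map (`H x W x C`).
#' @param phi_x output of the layer appended to the same stage; must match
#'   `x` in stage index (when both are tagged) and spatial size.
#' @return `C x C` row-stochastic matrix of class `fgr_relation`.
#' @export
fgr_cross_channel_relation <- function(x, phi_x) {
  if (inherits(x, "fgr_feature_map") && inherits(phi_x, "fgr_feature_map") &&
      !identical(stage_of(x), stage_of(phi_x))) {
    stop("cross_channel_relation: maps come from different stages")
  }
  dx <- dim(x); dp <- dim(phi_x)
  if (!all(dx[1:2] == dp[1:2])) stop("cross_channel_relation: spatial mismatch")
  X <- as_position_matrix(unclass(x))
  P <- as_position_matrix(unclass(phi_x))
  raw <- crossprod(X, P) / nrow(X)
  fc <- fgr_softmax(fgr_signed_sqrt(raw), rows = TRUE)
  structure(fc, class = c("fgr_relation", "matrix"))
}

#' Trilinear attention maps
#'
#' `Fd = N(M(Fc^T phi(X)))` with `phi(X)` reshaped to `C x HW`; the softmax
#' runs over the `HW` spatial axis so every part map is a distribution over
#' positions.
#'
#' @param fc `C x C` relation matrix from [fgr_cross_channel_relation()].
#' @param phi_x feature map with `C` channels.
#' @return [fgr_attention()] with `C` part maps, tagged with `phi_x`'s stage
#'   (level 2 if untagged).
#' @export
fgr_trilinear_attention <- function(fc, phi_x) {
  C <- dim(phi_x)[3L]
  if (!all(dim(fc) == c(C, C))) {
    stop("trilinear_attention: relation is ", nrow(fc), "x", ncol(fc),
         " but phi has ", C, " channels")
  }
  H <- dim(phi_x)[1L]; W <- dim(phi_x)[2L]
  P <- t(as_position_matrix(unclass(phi_x)))        # C x HW
  fd <- fgr_softmax(fgr_signed_sqrt(t(unclass(fc)) %*% P), rows = TRUE)
  maps <- array(0, c(C, H, W))
  for (i in seq_len(C)) maps[i, , ] <- matrix(fd[i, ], H, W)
  lvl <- if (inherits(phi_x, "fgr_feature_map")) stage_of(phi_x) else 2L
  fgr_attention(maps, lvl)
}

# One full CTA application to a stage map given its phi conv parameters.
cta_apply <- function(stage_map, phi_w) {
  phi <- fgr_feature_map(
    conv_block(unclass(stage_map), phi_w$w, phi_w$b, pad = 1L),
    stage_of(stage_map))
  fc <- fgr_cross_channel_relation(stage_map, phi)
  list(attention = fgr_trilinear_attention(fc, phi), phi = phi, fc = fc)
}

#' Attention pyramid over stages 2..4
#'
#' Applies CTA to each supplied pyramid stage; output levels are ordered
#' (2, 3, 4).
#'
#' @param stages named list with `stage2`, `stage3`, `stage4` feature maps
#'   (as returned by [fgr_backbone_forward()]).
#' @param backbone backbone parameter set (supplies the per-stage phi
#'   convolutions).
#' @return list of [fgr_attention()] objects with levels 2, 3, 4.
#' @export
fgr_attention_pyramid <- function(stages, backbone) {
  need <- paste0("stage", 2:4)
  if (!all(need %in% names(stages))) {
    stop("attention_pyramid: stages must contain ", paste(need, collapse = ", "))
  }
  lapply(need, function(nm) {
    sm <- stages[[nm]]
    cta_apply(sm, backbone$phi[[stage_of(sm)]])$attention
  })
}

# Nearest-neighbour upsampling of a matrix by integer factor.
upsample_nn <- function(m, fh, fw = fh) {
  m[rep(seq_len(nrow(m)), each = fh), rep(seq_len(ncol(m)), each = fw),
    drop = FALSE]
}

# Bilinear resize of a matrix to nh x nw (used when the scale factor is not
# an integer; documented interpolation).
resize_bilinear <- function(m, nh, nw) {
  h <- nrow(m); w <- ncol(m)
  ry <- (seq_len(nh) - 0.5) * h / nh - 0.5
  rx <- (seq_len(nw) - 0.5) * w / nw - 0.5
  y0 <- pmin(pmax(floor(ry), 0), h - 1); x0 <- pmin(pmax(floor(rx), 0), w - 1)
  y1 <- pmin(y0 + 1, h - 1); x1 <- pmin(x0 + 1, w - 1)
  wy <- pmin(pmax(ry - y0, 0), 1); wx <- pmin(pmax(rx - x0, 0), 1)
  a <- m[y0 + 1, x0 + 1, drop = FALSE]; b <- m[y0 + 1, x1 + 1, drop = FALSE]
  c_ <- m[y1 + 1, x0 + 1, drop = FALSE]; d <- m[y1 + 1, x1 + 1, drop = FALSE]
  top <- a * rep((1 - wx), each = nh) + b * rep(wx, each = nh)
  bot <- c_ * rep((1 - wx), each = nh) + d * rep(wx, each = nh)
  top * (1 - wy) + bot * wy
}

#' Render an attention heat map overlay
#'
#' Sums the part maps of one pyramid level into a single spatial mass map,
#' upsamples it to the image size (nearest-neighbour for integer scale
#' factors, bilinear otherwise), normalizes to [0, 1] and alpha-blends a
#' red-yellow ramp onto the image. The overlay is clamped to display range
#' and written as a binary PPM.
#'
#' @param att an [fgr_attention()] object.
#' @param image `H x W x 3` array in [0, 1].
#' @param path output file path (`.ppm`).
#' @param alpha blend weight of the heat ramp.
#' @return `path`, invisibly.
#' @export
fgr_render_attention_heatmap <- function(att, image, path, alpha = 0.5) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3L] == 3L)
  mass <- apply(att$maps, c(2L, 3L), sum)
  H <- dim(image)[1L]; W <- dim(image)[2L]
  if (H %% nrow(mass) == 0L && W %% ncol(mass) == 0L) {
    up <- upsample_nn(mass, H %/% nrow(mass), W %/% ncol(mass))
  } else {
    up <- resize_bilinear(mass, H, W)
  }
  rng <- range(up)
  heat <- if (diff(rng) > 0) (up - rng[1]) / diff(rng) else up * 0 + 0.5
  overlay <- image
  overlay[, , 1] <- (1 - alpha) * image[, , 1] + alpha * 1.0 * heat
  overlay[, , 2] <- (1 - alpha) * image[, , 2] + alpha * 0.8 * heat
  overlay[, , 3] <- (1 - alpha) * image[, , 3] + alpha * 0.1 * heat
  overlay <- pmin(pmax(overlay, 0), 1)
  fgr_write_ppm(overlay, path)
  invisible(path)
}
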