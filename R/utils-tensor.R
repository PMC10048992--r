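# Activation grids are dense arrays dim = c(H, W, C), row-major image
# convention: origin top-left, 0-based pixel coordinates in the geometry
# helpers, 1-based array indices internally.

#' Sigmoid and SiLU activations
#'
#' `fgr_sigmoid(x)` is the logistic function; `fgr_silu(x) = x * sigmoid(x)`
#' is the smooth gated activation used after every convolution in the
#' backbone.
#'
#' @param x numeric vector/array.
#' @return object of the same shape as `x`.
#' @export
fgr_sigmoid <- function(x) 1 / (1 + exp(-x))

#' @rdname fgr_sigmoid
#' @export
fgr_silu <- function(x) x * fgr_sigmoid(x)

#' Numerically stable softmax
#'
#' @param x numeric vector, or matrix when `rows = TRUE`.
#' @param rows if `TRUE`, apply softmax independently to each row of a
#'   matrix.
#' @return normalized vector or row-stochastic matrix.
#' @export
fgr_softmax <- function(x, rows = FALSE) {
  if (rows) {
    stopifnot(is.matrix(x))
    m <- apply(x, 1L, max)
    e <- exp(x - m)
    e / rowSums(e)
  } else {
    e <- exp(x - max(x))
    e / sum(e)
  }
}

#' Signed square root (power normalization)
#'
#' The elementwise moment normalization `sign(x) * sqrt(|x|)` applied to
#' second-order feature statistics before softmax normalization. It fixes
#' the bursty dynamic range of raw channel-correlation entries: it is odd,
#' monotone increasing, and maps 0 to 0.
#'
#' @param x numeric vector/array.
#' @return same shape as `x`.
#' @export
fgr_signed_sqrt <- function(x) sign(x) * sqrt(abs(x))

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards. All stochastic entry points funnel through
# this so that a seed fully determines every artifact.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a child seed from a parent seed and a stream label; keeps every
# derived seed inside the 32-bit signed range.
child_seed <- function(seed, label) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.double(seed) * 48271 + h) %% 2147483562) + 1L
}

#' 2-D convolution over an H x W x C grid
#'
#' im2col + BLAS matrix multiply. Weights are laid out
#' `kh x kw x Cin x Cout`; padding is symmetric zero padding.
#'
#' @param x array `H x W x Cin`.
#' @param w array `kh x kw x Cin x Cout`.
#' @param b optional bias vector of length `Cout`.
#' @param stride positive integer stride.
#' @param pad nonnegative integer zero-padding on every side.
#' @return array `H' x W' x Cout` with `H' = floor((H + 2 pad - kh)/stride) + 1`.
#' @export
fgr_conv2d <- function(x, w, b = NULL, stride = 1L, pad = 0L) {
  stopifnot(length(dim(x)) == 3L, length(dim(w)) == 4L)
  d <- dim(x); H <- d[1L]; W <- d[2L]; Cin <- d[3L]
  kh <- dim(w)[1L]; kw <- dim(w)[2L]
  if (dim(w)[3L] != Cin) {
    stop("fgr_conv2d: input has ", Cin, " channels but weights expect ", dim(w)[3L])
  }
  Cout <- dim(w)[4L]
  stride <- as.integer(stride); pad <- as.integer(pad)
  oh <- (H + 2L * pad - kh) %/% stride + 1L
  ow <- (W + 2L * pad - kw) %/% stride + 1L
  if (oh < 1L || ow < 1L) stop("fgr_conv2d: kernel larger than padded input")
  if (pad > 0L) {
    xp <- array(0, c(H + 2L * pad, W + 2L * pad, Cin))
    xp[pad + seq_len(H), pad + seq_len(W), ] <- x
  } else xp <- x
  # column blocks ordered (channel fastest) per (di, dj) offset, matching a
  # weight matrix permuted to (Cin, kh, kw, Cout)
  cols <- matrix(0, oh * ow, kh * kw * Cin)
  blk <- 0L
  ri <- function(di) di + stride * (seq_len(oh) - 1L)
  ci <- function(dj) dj + stride * (seq_len(ow) - 1L)
  for (dj in seq_len(kw)) {
    for (di in seq_len(kh)) {
      s <- xp[ri(di), ci(dj), , drop = FALSE]
      cols[, blk + seq_len(Cin)] <- matrix(s, oh * ow, Cin)
      blk <- blk + Cin
    }
  }
  wm <- matrix(aperm(w, c(3L, 1L, 2L, 4L)), kh * kw * Cin, Cout)
  y <- cols %*% wm
  if (!is.null(b)) y <- sweep(y, 2L, b, `+`)
  array(y, c(oh, ow, Cout))
}

# He init plus a central identity (Dirac) component mapping input channel
# ((o-1) mod Cin)+1 to output channel o. With a frozen random backbone the
# identity path carries input information through depth instead of washing
# it out layer by layer; the random part still adds new features.
dirac_conv <- function(kh, kw, cin, cout, scale = 1) {
  w <- he_conv(kh, kw, cin, cout)
  kc <- (kh + 1L) %/% 2L; kcw <- (kw + 1L) %/% 2L
  for (o in seq_len(cout)) {
    ci <- (o - 1L) %% cin + 1L
    w[kc, kcw, ci, o] <- w[kc, kcw, ci, o] + scale
  }
  w
}

# Kaiming/He normal initialization for a conv weight tensor.
he_conv <- function(kh, kw, cin, cout) {
  fan_in <- kh * kw * cin
  array(stats::rnorm(kh * kw * cin * cout, sd = sqrt(2 / fan_in)),
        c(kh, kw, cin, cout))
}

# Flatten H x W x C -> (H*W) x C matrix (positions ordered column-major over
# the spatial grid, i.e. row index fastest).
as_position_matrix <- function(x) {
  d <- dim(x)
  matrix(x, d[1L] * d[2L], d[3L])
}

relu <- function(x) pmax(x, 0)
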