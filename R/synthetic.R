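# Synthetic fine-grained bird data.
#
# The generator emulates the data challenges of field imagery for
# fine-grained species work: classes share a common body plan and differ
# only in small part traits (beak size/color, wing stripes, eye ring),
# backgrounds are cluttered, scenes hold several small targets, and
# instances may be partially occluded. Everything is deterministic under a
# seed, down to file bytes.
#
# A similarity dial in [0, 1] controls how close the classes sit: the
# continuous parameters (hues, beak size, body proportions) contract
# toward the shared template as similarity -> 1, while the discrete traits
# (stripe count, eye ring, beak hue family) always differ, so a
# high-similarity library is only separable through its parts - the
# fine-grained premise.

hsv_rgb <- function(h, s, v) {
  as.numeric(grDevices::col2rgb(grDevices::hsv(h %% 1, s, v))) / 255
}

#' Species specification library
#'
#' All classes share one base body template drawn from the seed; classes
#' differ in part parameters whose inter-class spread shrinks linearly in
#' `1 - similarity`.
#'
#' @param n_classes at least 2.
#' @param similarity in [0, 1]; 0 = coarse-grained (body hue and all parts
#'   spread wide), 1 = classes identical up to discrete part traits.
#' @param seed integer seed; same seed gives an identical library.
#' @return list of `fgr_species` specs with fields class_id, body_hue,
#'   body_axes, beak_size, beak_hue, wing_stripe_count, eye_ring.
#' @export
fgr_make_species_library <- function(n_classes, similarity = 0.9,
                                     seed = 1L) {
  if (n_classes < 2L) stop("need at least 2 classes")
  stopifnot(similarity >= 0, similarity <= 1)
  spread <- 1 - similarity
  with_seed(seed, {
    base_hue <- stats::runif(1, 0.05, 0.65)
    base_axes <- c(0.30, 0.20)
    base_beak_hue <- stats::runif(1, 0.02, 0.12)   # warm beak tones
    lapply(seq_len(n_classes) - 1L, function(i) {
      dh <- stats::runif(1, -0.35, 0.35)
      db <- stats::runif(1, -0.03, 0.03)
      da <- stats::runif(2, -0.25, 0.25)
      dbh <- stats::runif(1, -0.3, 0.3)
      structure(list(
        class_id = i,
        name = sprintf("species_%02d", i),
        body_hue = (base_hue + spread * dh) %% 1,
        body_axes = base_axes * (1 + spread * da),
        # structural trait: alternate short/long beaks, plus a shrinking
        # continuous offset
        beak_size = 0.09 + 0.05 * (i %% 2L) + spread * db,
        beak_hue = (base_beak_hue + spread * dbh) %% 1,
        wing_stripe_count = i %% 4L,
        eye_ring = (i %/% 4L) %% 2L == 1L
      ), class = "fgr_species")
    })
  })
}

#' Mean pairwise continuous part-parameter distance of a library
#'
#' Euclidean distance over (beak_size, beak_hue, body_hue, body_axes);
#' shrinks as the similarity used to build the library grows.
#'
#' @param library output of [fgr_make_species_library()].
#' @return nonnegative scalar.
#' @export
fgr_species_distance <- function(library) {
  P <- t(vapply(library, function(s) {
    c(s$beak_size, s$beak_hue, s$body_hue, s$body_axes)
  }, numeric(5)))
  mean(stats::dist(P))
}

# Render one bird sprite at `size` pixels; returns list(rgb, mask).
# Coordinates are fractions of the sprite: x right (columns), y down.
render_bird_sprite <- function(spec, size, seed = NULL, jitter = 0) {
  with_seed(seed, {
    j <- function(sd) if (jitter > 0) stats::rnorm(1, 0, sd * jitter) else 0
    S <- size
    px <- (col(matrix(0, S, S)) - 0.5) / S
    py <- (row(matrix(0, S, S)) - 0.5) / S
    hue <- (spec$body_hue + j(0.01)) %% 1
    ax <- spec$body_axes[1] * (1 + j(0.05))
    ay <- spec$body_axes[2] * (1 + j(0.05))
    val <- 0.55 + j(0.05)

    body <- ((px - 0.45) / ax)^2 + ((py - 0.58) / ay)^2 <= 1
    head <- ((px - 0.70) / 0.14)^2 + ((py - 0.32) / 0.14)^2 <= 1
    neck <- ((px - 0.60) / 0.12)^2 + ((py - 0.45) / 0.15)^2 <= 1
    tail <- (px >= 0.45 - ax - 0.12) & (px <= 0.45 - ax + 0.06) &
      (abs(py - 0.55) <= 0.55 * (px - (0.45 - ax - 0.12)) / 0.18 * 0.12 + 0.01)
    bk0 <- 0.70 + 0.13
    bklen <- spec$beak_size * (1 + j(0.05))
    beak <- (px >= bk0) & (px <= bk0 + bklen) &
      (abs(py - 0.32) <= 0.45 * bklen * (1 - (px - bk0) / bklen))
    eye <- ((px - 0.73)^2 + (py - 0.285)^2) <= 0.022^2
    ring_r <- sqrt((px - 0.73)^2 + (py - 0.285)^2)
    ring <- spec$eye_ring & ring_r > 0.028 & ring_r <= 0.045

    rgb_body <- hsv_rgb(hue, 0.55, val)
    rgb_head <- hsv_rgb(hue, 0.45, min(1, val + 0.12))
    rgb_beak <- hsv_rgb(spec$beak_hue, 0.85, 0.8)

    img <- array(0, c(S, S, 3))
    mask <- body | neck | tail
    for (ch in 1:3) {
      m <- matrix(img[, , ch], S, S)
      m[body] <- rgb_body[ch]; m[neck] <- rgb_body[ch]
      m[tail] <- rgb_body[ch] * 0.8
      m[head] <- rgb_head[ch]
      m[beak] <- rgb_beak[ch]
      img[, , ch] <- m
    }
    mask <- mask | head | beak
    # wing stripes: dark bars across the body
    nstr <- spec$wing_stripe_count
    if (nstr > 0) {
      for (sdx in seq_len(nstr)) {
        x0 <- 0.45 - ax * 0.6 + (sdx - 0.5) * (1.2 * ax / nstr)
        stripe <- body & abs(px - x0) <= 0.022
        for (ch in 1:3) {
          m <- matrix(img[, , ch], S, S); m[stripe] <- m[stripe] * 0.35
          img[, , ch] <- m
        }
      }
    }
    if (any(ring)) {
      for (ch in 1:3) {
        m <- matrix(img[, , ch], S, S); m[ring] <- c(0.95, 0.95, 0.9)[ch]
        img[, , ch] <- m
      }
      mask <- mask | ring
    }
    for (ch in 1:3) {
      m <- matrix(img[, , ch], S, S); m[eye] <- 0.05
      img[, , ch] <- m
    }
    list(rgb = img, mask = mask)
  })
}

# Perlin-like value noise: coarse uniform grid bilinearly upsampled.
value_noise <- function(h, w, cells = 6L, amplitude = 1) {
  g <- matrix(stats::runif(cells * cells), cells, cells)
  resize_bilinear(g, h, w) * amplitude
}

render_background <- function(h, w, clutter_level = 1) {
  hue <- stats::runif(1, 0.2, 0.45)          # foliage/sky tones
  top <- hsv_rgb(hue, 0.35, 0.75)
  bot <- hsv_rgb(hue + 0.06, 0.5, 0.45)
  grad <- (row(matrix(0, h, w)) - 1) / max(1, h - 1)
  img <- array(0, c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- top[ch] * (1 - grad) + bot[ch] * grad
  if (clutter_level > 0) {
    for (ch in 1:3) {
      img[, , ch] <- img[, , ch] +
        value_noise(h, w, cells = 5L, amplitude = 0.25 * clutter_level) -
        0.125 * clutter_level
    }
    # foliage-like strokes: thin oriented bars of darker/lighter tone
    nstroke <- round(6 * clutter_level)
    px <- col(matrix(0, h, w)); py <- row(matrix(0, h, w))
    for (s in seq_len(nstroke)) {
      x0 <- stats::runif(1, 1, w); y0 <- stats::runif(1, 1, h)
      ang <- stats::runif(1, 0, pi); len <- stats::runif(1, 0.2, 0.6) * w
      th <- stats::runif(1, 0.8, 2.2)
      dx <- cos(ang); dy <- sin(ang)
      t <- (px - x0) * dx + (py - y0) * dy
      dseg <- abs(-(px - x0) * dy + (py - y0) * dx)
      m <- dseg <= th & t >= 0 & t <= len
      shade <- stats::runif(1, -0.25, 0.25)
      for (ch in 1:3) {
        mm <- matrix(img[, , ch], h, w); mm[m] <- mm[m] + shade
        img[, , ch] <- mm
      }
    }
  }
  pmin(pmax(img, 0), 1)
}

#' Render one classification crop
#'
#' Draws the species sprite over a gradient-plus-noise background. Without
#' augmentation the bird is centered (within a 2-pixel construction
#' margin) and repeated calls with one seed give identical pixels; with
#' `augment = TRUE` a horizontal flip, +/-3 px crop shift and lighting
#' jitter are applied, all driven by `seed`.
#'
#' @param spec one `fgr_species` entry.
#' @param size crop side in pixels (>= 32).
#' @param augment logical flag.
#' @param seed integer seed.
#' @return `size x size x 3` array in [0, 1].
#' @export
fgr_render_crop <- function(spec, size = 64L, augment = FALSE, seed = 1L) {
  if (size < 32L) stop("crop size must be >= 32")
  with_seed(seed, {
    bg <- render_background(size, size, clutter_level = 0.6)
    sp <- render_bird_sprite(spec, size, seed = NULL,
                             jitter = if (augment) 1 else 0)
    img <- bg
    off <- if (augment) round(stats::runif(2, -3, 3)) else c(0L, 0L)
    rows <- seq_len(size) + off[1]; cols <- seq_len(size) + off[2]
    ok <- rows >= 1 & rows <= size & cols >= 1 & cols <= size
    for (ch in 1:3) {
      m <- matrix(img[, , ch], size, size)
      src <- matrix(sp$rgb[, , ch], size, size)
      msk <- sp$mask
      m[rows[ok], cols[ok]][msk[ok, ok]] <- src[ok, ok][msk[ok, ok]]
      img[, , ch] <- m
    }
    if (augment) {
      if (stats::runif(1) < 0.5) img <- img[, rev(seq_len(size)), , drop = FALSE]
      img <- img * stats::runif(1, 0.85, 1.15)
    }
    pmin(pmax(img, 0), 1)
  })
}

#' Scene specification
#'
#' @param image_size square scene side in pixels.
#' @param n_instances birds per scene.
#' @param occlusion_prob probability that a placed instance is partially
#'   covered by a foreground occluder.
#' @param clutter_level background clutter intensity (>= 0).
#' @param scale_range instance size range `(min, max)` in pixels.
#' @param seed integer seed fixing all randomness.
#' @return list of class `fgr_scene_spec`.
#' @export
fgr_scene_spec <- function(image_size = 128L, n_instances = 4L,
                           occlusion_prob = 0.35, clutter_level = 1,
                           scale_range = c(24L, 48L), seed = 1L) {
  stopifnot(image_size >= 48L, n_instances >= 0L,
            occlusion_prob >= 0, occlusion_prob <= 1, clutter_level >= 0,
            scale_range[1] >= 16L, scale_range[2] <= image_size,
            scale_range[1] <= scale_range[2])
  structure(list(image_size = as.integer(image_size),
                 n_instances = as.integer(n_instances),
                 occlusion_prob = occlusion_prob,
                 clutter_level = clutter_level,
                 scale_range = as.integer(scale_range),
                 seed = as.integer(seed)),
            class = "fgr_scene_spec")
}

#' Render a multi-instance detection scene
#'
#' Places `n_instances` birds of randomly drawn species at random scales
#' and positions over a cluttered background. Each ground-truth box is the
#' tight bounding box of the full rendered instance (occlusion overlays do
#' not shrink it); all boxes lie within the image. With probability
#' `occlusion_prob` an instance is partially covered by a foliage-colored
#' blob drawn on top of it.
#'
#' @param library species library.
#' @param scene an [fgr_scene_spec()].
#' @return list with `image` (`S x S x 3`) and `truth` data.frame
#'   (class_id, x1, y1, x2, y2; 0-based pixel corners).
#' @export
fgr_render_scene <- function(library, scene) {
  with_seed(scene$seed, {
    S <- scene$image_size
    img <- render_background(S, S, scene$clutter_level)
    truth <- data.frame(class_id = integer(0), x1 = numeric(0),
                        y1 = numeric(0), x2 = numeric(0), y2 = numeric(0))
    occl <- list()
    for (k in seq_len(scene$n_instances)) {
      sz <- round(stats::runif(1, scene$scale_range[1], scene$scale_range[2]))
      r0 <- round(stats::runif(1, 0, S - sz))
      c0 <- round(stats::runif(1, 0, S - sz))
      which_cls <- sample.int(length(library), 1L)
      spec <- library[[which_cls]]
      sp <- render_bird_sprite(spec, sz, seed = NULL, jitter = 1)
      mrows <- which(rowSums(sp$mask) > 0); mcols <- which(colSums(sp$mask) > 0)
      if (!length(mrows)) next
      for (ch in 1:3) {
        m <- matrix(img[, , ch], S, S)
        src <- matrix(sp$rgb[, , ch], sz, sz)
        sel <- sp$mask
        sub <- m[r0 + seq_len(sz), c0 + seq_len(sz)]
        sub[sel] <- src[sel]
        m[r0 + seq_len(sz), c0 + seq_len(sz)] <- sub
        img[, , ch] <- m
      }
      truth <- rbind(truth, data.frame(
        class_id = spec$class_id,
        x1 = c0 + min(mcols) - 1, y1 = r0 + min(mrows) - 1,
        x2 = c0 + max(mcols), y2 = r0 + max(mrows)))
      if (stats::runif(1) < scene$occlusion_prob) {
        occl[[length(occl) + 1L]] <- c(
          cx = c0 + stats::runif(1, 0.25, 0.75) * sz,
          cy = r0 + stats::runif(1, 0.25, 0.75) * sz,
          rx = stats::runif(1, 0.25, 0.45) * sz,
          ry = stats::runif(1, 0.2, 0.4) * sz,
          hue = stats::runif(1, 0.25, 0.4))
      }
    }
    # draw occluders after all instances so they sit in the foreground
    if (length(occl)) {
      px <- col(matrix(0, S, S)); py <- row(matrix(0, S, S))
      for (o in occl) {
        m <- ((px - o["cx"]) / o["rx"])^2 + ((py - o["cy"]) / o["ry"])^2 <= 1
        colr <- hsv_rgb(o["hue"], 0.6, 0.35)
        for (ch in 1:3) {
          mm <- matrix(img[, , ch], S, S); mm[m] <- colr[ch]
          img[, , ch] <- mm
        }
      }
    }
    list(image = pmin(pmax(img, 0), 1), truth = truth)
  })
}
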