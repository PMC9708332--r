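# Synthetic histology-style scenes: clustered elliptical nuclei with known
# instance/type maps, so segmentation, encoding, post-processing and
# evaluation are all testable without external datasets or training.

ellipse_pixels <- function(center, axes, angle, height, width) {
  # 0-based (row, col) center; returns linear indices (1-based, column-major)
  rmax <- ceiling(max(axes))
  r0 <- max(0L, floor(center[1] - rmax)); r1 <- min(height - 1L, ceiling(center[1] + rmax))
  c0 <- max(0L, floor(center[2] - rmax)); c1 <- min(width - 1L, ceiling(center[2] + rmax))
  if (r0 > r1 || c0 > c1) return(integer(0))
  rr <- r0:r1; cc <- c0:c1
  dr <- rep(rr - center[1], times = length(cc))
  dc <- rep(cc - center[2], each = length(rr))
  ca <- cos(angle); sa <- sin(angle)
  u <- (dc * ca + dr * sa) / axes[1]
  v <- (-dc * sa + dr * ca) / axes[2]
  inside <- u * u + v * v <= 1
  rows <- rep(rr, times = length(cc))[inside]
  cols <- rep(cc, each = length(rr))[inside]
  rows + 1L + height * cols
}

# does mask a touch (8-neighbourhood) or overlap mask b?
touches <- function(idx, occupied, height, width) {
  if (any(occupied[idx])) return(TRUE)
  rows <- (idx - 1L) %% height
  cols <- (idx - 1L) %/% height
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    r2 <- rows + dr; c2 <- cols + dc
    ok <- r2 >= 0L & r2 < height & c2 >= 0L & c2 < width
    if (any(occupied[r2[ok] + 1L + height * c2[ok]])) return(TRUE)
  }
  FALSE
}

#' Generate a synthetic histology-style scene
#'
#' Places `n_nuclei` rotated ellipses on an `height` x `width` tile. A
#' fraction of approximately `overlap_fraction` of the nuclei is placed
#' touching or abutting an earlier nucleus (contested pixels always belong
#' to the earlier-placed nucleus, so instances never share pixels); the rest
#' are separated by at least one background pixel. Each nucleus receives a
#' uniformly drawn type in `1..n_types`. The rendered RGB image shows nuclei
#' darker than the background with per-type mean colors, per-nucleus jitter,
#' and additive Gaussian noise.
#'
#' @param height,width tile size in pixels (at least 32).
#' @param n_nuclei number of nuclei to place.
#' @param n_types number of nuclear types C.
#' @param overlap_fraction fraction of nuclei placed touching a neighbor,
#'   in `[0, 1]`.
#' @param noise_sd standard deviation of the additive Gaussian image noise
#'   (intensity units; the image lives in `[0, 1]`).
#' @param seed integer seed; the same seed and parameters reproduce the
#'   scene bit-exactly.
#' @param axis_range semi-axis range (pixels) nuclei are drawn from;
#'   the default emulates nuclei at 40x magnification (about 0.25 um/px,
#'   nuclear diameters roughly 15-30 px).
#' @return a `synthetic_scene`: list with `image` (H x W x 3 in `[0,1]`),
#'   `instances` (integer instance map, 0 = background, labels `1..N`),
#'   `types` (integer type map, 0 = background), `specs` (data.frame of
#'   per-nucleus center/axes/angle/type), and `seed`.
#' @examples
#' sc <- generate_scene(96, 96, 8, 4, 0.25, 0.02, seed = 1)
#' table(sc$types[sc$instances > 0])
#' @export
generate_scene <- function(height, width, n_nuclei, n_types,
                           overlap_fraction = 0.3, noise_sd = 0.02, seed = 1L,
                           axis_range = c(8, 15)) {
  stopifnot(height >= 32L, width >= 32L, n_nuclei >= 0L, n_types >= 1L,
            overlap_fraction >= 0, overlap_fraction <= 1, noise_sd >= 0,
            length(axis_range) == 2L, axis_range[1] >= 1)
  height <- as.integer(height); width <- as.integer(width)
  n_nuclei <- as.integer(n_nuclei)
  withr::with_seed(as.integer(seed), {
    instances <- matrix(0L, height, width)
    occupied <- matrix(FALSE, height, width)
    specs <- vector("list", n_nuclei)
    n_touch <- min(round(overlap_fraction * n_nuclei), max(0L, n_nuclei - 1L))
    touch_flags <- c(rep(FALSE, n_nuclei - n_touch), rep(TRUE, n_touch))
    max_attempts <- 200L
    for (i in seq_len(n_nuclei)) {
      placed <- FALSE
      for (att in seq_len(max_attempts)) {
        a <- stats::runif(1, axis_range[1], axis_range[2])
        b <- stats::runif(1, max(1, 0.6 * a), a)
        ang <- stats::runif(1, 0, pi)
        if (touch_flags[i]) {
          anchor <- specs[[sample.int(i - 1L, 1L)]]
          theta <- stats::runif(1, 0, 2 * pi)
          dist <- stats::runif(1, 0.92, 1.08) * (mean(anchor$axes) + (a + b) / 2)
          ctr <- c(anchor$center[1] + dist * sin(theta),
                   anchor$center[2] + dist * cos(theta))
          if (ctr[1] < 1 || ctr[1] > height - 2 || ctr[2] < 1 || ctr[2] > width - 2) next
        } else {
          m <- max(a, b)
          if (height - 1 - m <= m || width - 1 - m <= m) next
          ctr <- c(stats::runif(1, m, height - 1 - m), stats::runif(1, m, width - 1 - m))
        }
        idx <- ellipse_pixels(ctr, c(a, b), ang, height, width)
        if (length(idx) < 4L) next
        free <- idx[!occupied[idx]]
        if (touch_flags[i]) {
          # must touch or overlap earlier foreground, keep most of its pixels
          if (!touches(idx, occupied, height, width)) next
          if (length(free) < 0.85 * length(idx) || length(free) < 4L) next
        } else {
          # must be separated from earlier nuclei by >= 1 background pixel
          if (touches(idx, occupied, height, width)) next
        }
        instances[free] <- i
        occupied[free] <- TRUE
        specs[[i]] <- list(center = ctr, axes = c(a, b), angle = ang,
                           type_id = sample.int(n_types, 1L), touching = touch_flags[i])
        placed <- TRUE
        break
      }
      if (!placed) {
        stop("could not place nucleus ", i, " after ", max_attempts,
             " attempts; reduce n_nuclei or ",
             if (touch_flags[i]) "overlap_fraction" else "nucleus size",
             " for a ", height, "x", width, " tile")
      }
    }
    spec_df <- if (n_nuclei > 0L) {
      data.frame(label = seq_len(n_nuclei),
                 center_row = vapply(specs, function(s) s$center[1], numeric(1)),
                 center_col = vapply(specs, function(s) s$center[2], numeric(1)),
                 axis_a = vapply(specs, function(s) s$axes[1], numeric(1)),
                 axis_b = vapply(specs, function(s) s$axes[2], numeric(1)),
                 angle = vapply(specs, function(s) s$angle, numeric(1)),
                 type_id = vapply(specs, function(s) s$type_id, integer(1)),
                 touching = vapply(specs, function(s) s$touching, logical(1)))
    } else {
      data.frame(label = integer(0), center_row = numeric(0), center_col = numeric(0),
                 axis_a = numeric(0), axis_b = numeric(0), angle = numeric(0),
                 type_id = integer(0), touching = logical(0))
    }
    types <- matrix(0L, height, width)
    if (n_nuclei > 0L) {
      fg <- instances > 0L
      types[fg] <- spec_df$type_id[instances[fg]]
    }
    # render: light background, darker per-type hues, per-nucleus jitter
    base_cols <- grDevices::hsv(h = (seq_len(n_types) - 1) / max(1L, n_types),
                                s = 0.45, v = 0.45)
    base_rgb <- grDevices::col2rgb(base_cols) / 255
    image <- array(rep(c(0.88, 0.82, 0.86), each = height * width),
                   dim = c(height, width, 3L))
    for (i in seq_len(n_nuclei)) {
      idx <- which(instances == i)
      jit <- stats::rnorm(3L, 0, 0.03)
      col <- pmin(pmax(base_rgb[, spec_df$type_id[i]] + jit, 0), 1)
      for (ch in 1:3) image[idx + (ch - 1L) * height * width] <- col[ch]
    }
    if (noise_sd > 0) {
      image <- image + stats::rnorm(length(image), 0, noise_sd)
    }
    image <- pmin(pmax(image, 0), 1)
    structure(list(image = image, instances = instances, types = types,
                   specs = spec_df, seed = as.integer(seed),
                   params = list(height = height, width = width, n_nuclei = n_nuclei,
                                 n_types = n_types, overlap_fraction = overlap_fraction,
                                 noise_sd = noise_sd, axis_range = axis_range)),
              class = "synthetic_scene")
  })
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat("Synthetic nuclear scene", x$params$height, "x", x$params$width,
      "|", max(x$instances), "nuclei,", x$params$n_types, "types",
      "| seed", x$seed, "\n")
  invisible(x)
}

#' Ideal prediction stack for a scene
#'
#' Builds the prediction maps a perfect network would output for a scene:
#' the nuclear-pixel probability `q` is the (optionally Gaussian-blurred)
#' binary foreground, the horizontal/vertical maps are the exact
#' distance-map encoding of the instances (see [encode_hover()]), and the
#' class stack is the one-hot encoding of the type map (background channel
#' first), blurred identically to `q`. With `blur_sd = 0` the maps are
#' exact. Used as the oracle input for post-processing tests.
#'
#' @param scene a `synthetic_scene`.
#' @param blur_sd Gaussian blur sigma in pixels (0 = no blur).
#' @return a `prediction_stack`: list with `q` (H x W), `hv` (H x W x 2,
#'   horizontal then vertical), `classes` (H x W x (C+1)), `n_types`.
#' @export
ideal_prediction_stack <- function(scene, blur_sd = 0) {
  stopifnot(inherits(scene, "synthetic_scene"), blur_sd >= 0)
  np <- encode_np(scene$instances)
  hv <- encode_hover(scene$instances)
  C <- scene$params$n_types
  classes <- array(0, dim = c(nrow(np), ncol(np), C + 1L))
  classes[, , 1] <- (scene$types == 0L) * 1
  for (cl in seq_len(C)) classes[, , cl + 1L] <- (scene$types == cl) * 1
  q <- np
  if (blur_sd > 0) {
    # FFT-based blur can overshoot [0,1] by tiny ringing; clamp to the
    # probability range
    q <- pmin(pmax(gaussian_blur(np, blur_sd), 0), 1)
    for (cl in seq_len(C + 1L)) {
      classes[, , cl] <- pmin(pmax(gaussian_blur(classes[, , cl], blur_sd), 0), 1)
    }
  }
  structure(list(q = q, hv = hv, classes = classes, n_types = C),
            class = "prediction_stack")
}

# Gaussian blur of a 2D map (EBImage expects the transposed x/y layout;
# blurring is symmetric so the transpose is only for shape bookkeeping)
gaussian_blur <- function(m, sigma) {
  as.matrix(EBImage::gblur(m, sigma = sigma, radius = 2 * ceiling(3 * sigma) + 1))
}
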