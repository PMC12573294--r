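# Deterministic synthetic leaf images for the five recognition classes.
# Each image is an elongated green blade on a plain or cluttered background
# with class-specific lesions composited on top: large irregular gray-brown
# patches (botrytis), many small round orange pustules (rust), brown
# necrosis advancing from the tip (blight), elongated purple-centered spots
# (purple), or nothing (healthy). Classes are constructed to be disjoint in
# lesion color space at zero jitter so a trivial nearest-centroid color
# classifier separates them perfectly; jitter and clutter dial difficulty up.

#' Class labels of the leaf disease recognition task
#'
#' @return `c("botrytis", "rust", "blight", "purple", "healthy")`.
#' @export
leaf_classes <- function() c("botrytis", "rust", "blight", "purple", "healthy")

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Per-class lesion paint colors (RGB in [0,1]); chosen pairwise distant.
lesion_palette <- function() {
  list(botrytis = c(0.55, 0.50, 0.42),  # soft gray-brown
       rust     = c(0.85, 0.45, 0.05),  # orange pustule
       blight   = c(0.42, 0.26, 0.08),  # dark necrotic brown
       purple   = c(0.48, 0.12, 0.50))  # purple spot core
}

#' Generate one synthetic leaf image
#'
#' @param class_label One of [leaf_classes()].
#' @param image_size Square image side in pixels (>= 32).
#' @param lesion_density Multiplier on the class's lesion count (default 1).
#' @param lesion_scale Multiplier on lesion radii (default 1).
#' @param color_jitter Standard deviation of a global per-channel color
#'   perturbation, in [0,1] pixel units (default 0.02).
#' @param background `"plain"` or `"cluttered"`.
#' @param seed Integer seed; identical arguments give a bit-identical image.
#' @return A list with `image` (`image_size x image_size x 3` array in
#'   [0,1]), `label`, and `lesion_mask` (logical matrix; all `FALSE` for the
#'   healthy class).
#' @export
generate_leaf <- function(class_label, image_size = 96L, lesion_density = 1,
                          lesion_scale = 1, color_jitter = 0.02,
                          background = c("plain", "cluttered"), seed = 1L) {
  class_label <- match.arg(class_label, leaf_classes())
  background <- match.arg(background)
  if (image_size < 32L) stop("image_size must be at least 32 pixels")
  with_seed(seed, draw_leaf(class_label, as.integer(image_size), lesion_density,
                            lesion_scale, color_jitter, background))
}

draw_leaf <- function(class_label, sz, density, scale, jitter, background) {
  # coordinate grid in [-1, 1]
  g <- seq(-1, 1, length.out = sz)
  px <- matrix(g, sz, sz)            # varies along rows  (y axis)
  py <- matrix(g, sz, sz, byrow = TRUE)

  # leaf axis: near-vertical with a small random tilt
  th <- stats::runif(1, -0.25, 0.25)
  u <- cos(th) * px + sin(th) * py   # along the blade
  v <- -sin(th) * px + cos(th) * py  # across the blade
  a <- stats::runif(1, 0.78, 0.9)    # half length
  b <- stats::runif(1, 0.16, 0.24)   # half width
  leaf <- (u / a)^2 + (v / b)^2 <= 1

  img <- array(0, dim = c(sz, sz, 3))
  bg <- c(0.40, 0.35, 0.28)
  for (ch in 1:3)
    img[, , ch] <- bg[ch] + matrix(stats::rnorm(sz * sz, sd = 0.02), sz, sz)
  if (background == "cluttered") {
    for (i in seq_len(8L)) {
      cx <- stats::runif(1, -1, 1); cy <- stats::runif(1, -1, 1)
      r <- stats::runif(1, 0.1, 0.35)
      alpha <- exp(-(((px - cx)^2 + (py - cy)^2) / r^2))
      col <- stats::runif(3, 0.1, 0.8)
      for (ch in 1:3) img[, , ch] <- img[, , ch] * (1 - 0.6 * alpha) +
        col[ch] * 0.6 * alpha
    }
  }

  # blade: green with lengthwise shading and fine texture; darker midrib
  base <- c(0.18, 0.55, 0.16)
  shade <- 1 - 0.25 * (u / a + 1) / 2
  tex <- matrix(stats::rnorm(sz * sz, sd = 0.025), sz, sz)
  midrib <- abs(v) < 0.015
  for (ch in 1:3) {
    blade_col <- base[ch] * shade + tex
    blade_col[midrib] <- blade_col[midrib] * 0.75
    img[, , ch][leaf] <- clamp01(blade_col)[leaf]
  }

  mask <- matrix(FALSE, sz, sz)
  pal <- lesion_palette()
  paint <- function(alpha, col) {
    alpha <- alpha * leaf
    mask <<- mask | (alpha > 0.5)
    for (ch in 1:3) img[, , ch] <<- img[, , ch] * (1 - alpha) + col[ch] * alpha
  }
  blob_alpha <- function(cx, cy, r, soft = 2, wobble = 0) {
    d <- sqrt((u - cx)^2 + (v - cy)^2)
    rr <- r
    if (wobble > 0) {
      ang <- atan2(v - cy, u - cx)
      rr <- r * (1 + wobble * sin(3 * ang + stats::runif(1, 0, 2 * pi)))
    }
    clamp01(1.2 * exp(-(d / rr)^soft) - 0.2)
  }
  inside <- function() c(stats::runif(1, -0.5 * a, 0.5 * a),
                         stats::runif(1, -0.5 * b, 0.5 * b))

  if (class_label == "botrytis") {
    n <- max(1L, round(3 * density))
    for (i in seq_len(n)) {
      cc <- inside()
      paint(blob_alpha(cc[1], cc[2], scale * stats::runif(1, 0.12, 0.2),
                       soft = 2, wobble = 0.3), pal$botrytis)
    }
  } else if (class_label == "rust") {
    n <- max(3L, round(18 * density))
    for (i in seq_len(n)) {
      cc <- c(stats::runif(1, -0.8 * a, 0.8 * a), stats::runif(1, -0.8 * b, 0.8 * b))
      paint(blob_alpha(cc[1], cc[2], scale * stats::runif(1, 0.02, 0.04),
                       soft = 6), pal$rust)
    }
  } else if (class_label == "blight") {
    # necrosis advancing from the blade tip with a ragged front
    front <- a * (0.35 + 0.1 * sin(6 * v / b) +
                    0.05 * stats::rnorm(1))
    alpha <- clamp01((u - front) / (0.12 * a) + 1) # soft ramp past the front
    alpha[u < front - 0.12 * a] <- 0
    paint(alpha, pal$blight)
  } else if (class_label == "purple") {
    n <- max(1L, round(5 * density))
    for (i in seq_len(n)) {
      cc <- inside()
      d <- sqrt(((u - cc[1]) / (3.2 * scale * 0.035))^2 +
                  ((v - cc[2]) / (scale * 0.035))^2)
      paint(clamp01(1.3 * exp(-d^2) - 0.3), pal$purple)
    }
  } # healthy: no lesions

  if (jitter > 0) {
    shift <- stats::rnorm(3, sd = jitter)
    for (ch in 1:3) img[, , ch] <- img[, , ch] + shift[ch]
  }
  list(image = clamp01(img), label = class_label, lesion_mask = mask)
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n_per_class` PNG images per class into `dir/<class>/` and a CSV
#' manifest (`path,label,split`, split left unassigned) at
#' `dir/manifest.csv`. Per-image seeds are derived from `seed`, so equal
#' seeds give identical images and manifests.
#'
#' @param n_per_class Images per class (>= 1).
#' @param dir Output directory (created if missing).
#' @param image_size,lesion_density,lesion_scale,color_jitter,background
#'   Passed to [generate_leaf()].
#' @param seed Integer master seed.
#' @return The manifest as a data.frame (invisibly also written to disk);
#'   paths are relative to `dir`.
#' @export
generate_dataset <- function(n_per_class, dir, image_size = 96L,
                             lesion_density = 1, lesion_scale = 1,
                             color_jitter = 0.02,
                             background = c("plain", "cluttered"), seed = 1L) {
  if (n_per_class < 1L) stop("n_per_class must be >= 1")
  background <- match.arg(background)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  rows <- list()
  for (cl in leaf_classes()) {
    cdir <- file.path(dir, cl)
    dir.create(cdir, showWarnings = FALSE)
    for (i in seq_len(n_per_class)) {
      leaf <- generate_leaf(cl, image_size = image_size,
                            lesion_density = lesion_density,
                            lesion_scale = lesion_scale,
                            color_jitter = color_jitter,
                            background = background,
                            seed = derive_seed(seed, paste0(cl, i)))
      rel <- file.path(cl, sprintf("%s_%04d.png", cl, i))
      png::writePNG(leaf$image, file.path(dir, rel))
      rows[[length(rows) + 1L]] <-
        data.frame(path = rel, label = cl, split = "", stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(dir, "manifest.csv"))
  manifest
}

#' Stack images into a network input tensor
#'
#' @param images List of `H x W x 3` arrays in [0,1] (equal sizes).
#' @return A `(N, 3, H, W)` array.
#' @export
images_to_tensor <- function(images) {
  d <- dim(images[[1L]])
  x <- array(0, dim = c(length(images), 3L, d[1], d[2]))
  for (i in seq_along(images)) {
    im <- images[[i]]
    if (!identical(dim(im), d)) stop("all images must share one size")
    x[i, , , ] <- aperm(im, c(3L, 1L, 2L))
  }
  x
}

#' Read the images of a manifest from disk
#'
#' @param manifest A manifest data.frame (`path`, `label`, `split`).
#' @param dir Directory the manifest paths are relative to.
#' @return List with `images` (list of arrays) and `labels` (integer codes
#'   into [leaf_classes()] ordering of the manifest's label factor).
#' @export
load_images <- function(manifest, dir) {
  paths <- file.path(dir, manifest$path)
  missing <- !file.exists(paths)
  if (any(missing)) stop("missing image file(s): ", paths[which(missing)[1L]])
  images <- lapply(paths, function(p) {
    im <- png::readPNG(p)
    if (length(dim(im)) == 2L) im <- array(rep(im, 3L), c(dim(im), 3L))
    im[, , 1:3, drop = FALSE]
  })
  list(images = images,
       labels = match(manifest$label, leaf_classes()))
}
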