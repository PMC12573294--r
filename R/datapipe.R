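# Dataset manifests, the per-class 3:1:1 split, and robustness
# augmentations (brightness, contrast, additive noise, simulated shadow).

split_levels <- c("train", "val", "test")

#' Read / write a dataset manifest
#'
#' A manifest is a CSV with header `path,label,split`; labels must come from
#' [leaf_classes()] (or `classes`), split entries from
#' `train`/`val`/`test`/empty. The round-trip is lossless.
#'
#' @param path CSV file path.
#' @param classes Allowed label set (default [leaf_classes()]).
#' @return `read_manifest()` returns the manifest data.frame.
#' @export
read_manifest <- function(path, classes = leaf_classes()) {
  if (!file.exists(path)) stop("manifest file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("path", "label", "split")
  if (!all(need %in% names(df)))
    stop("manifest must have columns path,label,split")
  df <- df[, need]
  df$split[is.na(df$split)] <- ""
  bad <- which(!df$label %in% classes)
  if (length(bad))
    stop(sprintf("manifest line %d: unknown label '%s'", bad[1L] + 1L, df$label[bad[1L]]))
  badsplit <- which(!(df$split %in% c(split_levels, "")))
  if (length(badsplit))
    stop(sprintf("manifest line %d: unknown split '%s'",
                 badsplit[1L] + 1L, df$split[badsplit[1L]]))
  if (anyDuplicated(df$path))
    stop("manifest paths must be unique: ", df$path[duplicated(df$path)][1L])
  df
}

#' @rdname read_manifest
#' @param manifest A manifest data.frame.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(all(c("path", "label", "split") %in% names(manifest)))
  utils::write.csv(manifest[, c("path", "label", "split")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Stratified train/validation/test split
#'
#' Splits each class independently at the given ratios (default 3:1:1).
#' Within a class the records are shuffled under `seed`; quotas are
#' `n * r_i / sum(r)` allocated by floors first, with the remaining items
#' distributed by largest fractional remainder, ties broken toward the later
#' split (test before val before train). This policy reproduces the
#' published per-class 3:1:1 partitions of class sizes 1961, 1873, 1625 and
#' 1846 exactly.
#'
#' @param manifest A manifest with all `split` entries unassigned (`""`).
#' @param ratios Positive numeric vector of length 3 (train, val, test).
#' @param seed Integer seed for the per-class shuffles.
#' @return The manifest with `split` filled in; splits partition each class.
#' @export
stratified_split <- function(manifest, ratios = c(3, 1, 1), seed = 1L) {
  if (length(ratios) != 3L || any(ratios <= 0))
    stop("ratios must be three positive numbers")
  if (any(manifest$split != ""))
    stop("manifest already carries split assignments")
  out <- manifest
  for (cl in unique(manifest$label)) {
    idx <- which(manifest$label == cl)
    n <- length(idx)
    if (n < 3L) stop("class '", cl, "' has fewer records than splits")
    sizes <- largest_remainder(n, ratios)
    perm <- with_seed(derive_seed(seed, cl), sample.int(n))
    assign <- rep(split_levels, times = sizes)
    out$split[idx[perm]] <- assign
  }
  out
}

# Largest-remainder apportionment of n items over ratios; ties between equal
# fractional remainders go to the later split.
largest_remainder <- function(n, ratios) {
  quota <- n * ratios / sum(ratios)
  base <- floor(quota)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- quota - base
    # order by decreasing remainder, ties by decreasing position (later wins)
    ord <- order(-frac, -seq_along(frac))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Split sizes per class of a split manifest
#'
#' @param manifest A manifest with assigned splits.
#' @return A data.frame with one row per class: train, val, test, total.
#' @export
split_table <- function(manifest) {
  tab <- table(factor(manifest$label, levels = unique(manifest$label)),
               factor(manifest$split, levels = split_levels))
  df <- as.data.frame.matrix(tab)
  df$total <- rowSums(df)
  cbind(class = rownames(df), df, row.names = NULL)
}

#' Augmentation configuration
#'
#' @param brightness_range Multiplicative brightness factor interval.
#' @param contrast_range Contrast factor interval (rescaling about the image
#'   mean).
#' @param noise_std Additive Gaussian noise standard deviation in [0,1] pixel
#'   units.
#' @param shadow_max_polygons Maximum number of simulated shadow polygons.
#' @param shadow_opacity Interval of shadow darkening strength in (0,1).
#' @param prob Per-operation application probability.
#' @return A list of class `augment_config`.
#' @export
augment_config <- function(brightness_range = c(0.8, 1.2),
                           contrast_range = c(0.8, 1.2),
                           noise_std = 0.02,
                           shadow_max_polygons = 2L,
                           shadow_opacity = c(0.3, 0.6),
                           prob = 0.5) {
  chk <- function(r, nm) {
    if (length(r) != 2L || r[1] > r[2]) stop(nm, " must be a valid interval")
  }
  chk(brightness_range, "brightness_range")
  chk(contrast_range, "contrast_range")
  chk(shadow_opacity, "shadow_opacity")
  if (noise_std < 0) stop("noise_std must be non-negative")
  if (prob < 0 || prob > 1) stop("prob must lie in [0,1]")
  structure(list(brightness_range = brightness_range,
                 contrast_range = contrast_range,
                 noise_std = noise_std,
                 shadow_max_polygons = as.integer(shadow_max_polygons),
                 shadow_opacity = shadow_opacity,
                 prob = prob),
            class = "augment_config")
}

#' Augment one image
#'
#' Applies, each with probability `cfg$prob`: a multiplicative brightness
#' factor; a contrast rescale about the image mean; additive Gaussian noise;
#' and multiplicative darkening inside 1..N random convex polygons
#' (simulated shadow). The result is clamped to [0,1]. Deterministic given
#' the RNG state (call inside [with_seed] semantics via `seed`).
#'
#' @param image `H x W x 3` array in [0,1].
#' @param cfg An [augment_config()].
#' @param seed Optional integer; when given, the draw is seeded.
#' @return The augmented image, same shape, values in [0,1].
#' @export
augment <- function(image, cfg = augment_config(), seed = NULL) {
  stopifnot(inherits(cfg, "augment_config"))
  if (min(image) < 0 || max(image) > 1) stop("image values must lie in [0,1]")
  run <- function() {
    img <- image
    if (stats::runif(1) < cfg$prob) {
      f <- stats::runif(1, cfg$brightness_range[1], cfg$brightness_range[2])
      img <- img * f
    }
    if (stats::runif(1) < cfg$prob) {
      f <- stats::runif(1, cfg$contrast_range[1], cfg$contrast_range[2])
      m <- mean(img)
      img <- (img - m) * f + m
    }
    if (stats::runif(1) < cfg$prob && cfg$noise_std > 0) {
      img <- img + array(stats::rnorm(length(img), sd = cfg$noise_std), dim(img))
    }
    if (stats::runif(1) < cfg$prob && cfg$shadow_max_polygons > 0) {
      n <- sample.int(cfg$shadow_max_polygons, 1L)
      d <- dim(img)
      gx <- matrix(seq(0, 1, length.out = d[1]), d[1], d[2])
      gy <- matrix(seq(0, 1, length.out = d[2]), d[1], d[2], byrow = TRUE)
      for (i in seq_len(n)) {
        # convex region: intersection of 3 random half-planes through a point
        cx <- stats::runif(1); cy <- stats::runif(1)
        inside <- matrix(TRUE, d[1], d[2])
        for (j in 1:3) {
          th <- stats::runif(1, 0, 2 * pi)
          off <- stats::runif(1, 0.05, 0.4)
          inside <- inside & (cos(th) * (gx - cx) + sin(th) * (gy - cy) < off)
        }
        op <- stats::runif(1, cfg$shadow_opacity[1], cfg$shadow_opacity[2])
        fac <- 1 - op * inside
        for (ch in 1:3) img[, , ch] <- img[, , ch] * fac
      }
    }
    clamp01(img)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Channel normalization statistics of a training split
#'
#' @param images List of `H x W x 3` arrays.
#' @return List with `mean` and `sd`, each length 3 (per RGB channel).
#' @export
compute_norm_stats <- function(images) {
  acc <- vapply(images, function(im) c(colMeans(matrix(im, ncol = 3L)),
                                       colMeans(matrix(im, ncol = 3L)^2)),
                numeric(6L))
  m <- rowMeans(acc)[1:3]
  m2 <- rowMeans(acc)[4:6]
  sd <- sqrt(pmax(m2 - m^2, 1e-8))
  list(mean = m, sd = sd)
}

# Normalize an (N,3,H,W) tensor by per-channel statistics.
normalize_tensor <- function(x, stats) {
  d <- dim4(x)
  for (ch in 1:3)
    x[, ch, , ] <- (x[, ch, , ] - stats$mean[ch]) / stats$sd[ch]
  x
}
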