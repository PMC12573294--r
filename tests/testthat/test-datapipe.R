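# Manifests, the stratified 3:1:1 split, augmentation, and normalization.

make_manifest <- function(counts) {
  rows <- lapply(names(counts), function(cl)
    data.frame(path = sprintf("%s/%s_%04d.png", cl, cl, seq_len(counts[[cl]])),
               label = cl, split = "", stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

test_that("largest-remainder 3:1:1 apportionment matches hand-checked cases", {
  lr <- rt("largest_remainder")
  expect_identical(lr(1961L, c(3, 1, 1)), c(1177L, 392L, 392L))
  expect_identical(lr(1873L, c(3, 1, 1)), c(1124L, 374L, 375L))
  expect_identical(lr(1625L, c(3, 1, 1)), c(975L, 325L, 325L))
  expect_identical(lr(1846L, c(3, 1, 1)), c(1108L, 369L, 369L))
  # remainder ties go to the later split: 7 = 4.2 + 1.4 + 1.4 -> 4/1/2
  expect_identical(lr(7L, c(3, 1, 1)), c(4L, 1L, 2L))
  expect_identical(lr(5L, c(3, 1, 1)), c(3L, 1L, 1L))
})

test_that("stratified_split partitions every class exactly and conserves rows", {
  man <- make_manifest(c(botrytis = 37, rust = 23, blight = 11,
                         purple = 8, healthy = 41))
  out <- stratified_split(man, seed = 5L)
  expect_identical(sort(out$path), sort(man$path))
  expect_true(all(out$split %in% c("train", "val", "test")))
  for (cl in unique(man$label)) {
    n <- sum(man$label == cl)
    sizes <- table(out$split[out$label == cl])
    expect_equal(sum(sizes), n)
    expect_identical(as.integer(sizes[c("train", "val", "test")]),
                     rt("largest_remainder")(n, c(3, 1, 1)))
  }
})

test_that("the split is deterministic in the seed and varies across seeds", {
  man <- make_manifest(c(rust = 30, healthy = 30, blight = 30))
  a <- stratified_split(man, seed = 2L)
  b <- stratified_split(man, seed = 2L)
  c <- stratified_split(man, seed = 3L)
  expect_identical(a, b)
  expect_false(identical(a$split, c$split))
})

test_that("splitting an already-assigned manifest or bad ratios errors", {
  man <- make_manifest(c(rust = 10))
  out <- stratified_split(man, seed = 1L)
  expect_error(stratified_split(out), "already")
  expect_error(stratified_split(man, ratios = c(3, 1)), "three positive")
  expect_error(stratified_split(man, ratios = c(3, 0, 1)), "three positive")
  expect_error(stratified_split(make_manifest(c(rust = 2))), "fewer records")
})

test_that("split_table tabulates per-class split sizes", {
  man <- stratified_split(make_manifest(c(rust = 25, healthy = 15)), seed = 1L)
  tab <- split_table(man)
  expect_equal(tab$total, c(25, 15))
  expect_equal(tab$train + tab$val + tab$test, tab$total)
})

test_that("manifest round trip is lossless and malformed input is located", {
  man <- make_manifest(c(rust = 3, healthy = 2))
  man$split <- c("train", "val", "test", "", "train")
  p <- tempfile(fileext = ".csv")
  write_manifest(man, p)
  expect_identical(read_manifest(p), man)
  bad <- man
  bad$label[3] <- "mildew"
  write_manifest(bad, p)
  expect_error(read_manifest(p), "line 4: unknown label 'mildew'")
  bad2 <- man
  bad2$split[2] <- "holdout"
  write_manifest(bad2, p)
  expect_error(read_manifest(p), "line 3: unknown split")
  dup <- rbind(man, man[1, ])
  write_manifest(dup, p)
  expect_error(read_manifest(p), "unique")
})

test_that("augment is deterministic under a seed, bounded, and shape-preserving", {
  set.seed(801)
  img <- array(runif(24 * 24 * 3, 0.2, 0.8), c(24, 24, 3))
  cfg <- augment_config(prob = 1)
  a <- augment(img, cfg, seed = 4L)
  b <- augment(img, cfg, seed = 4L)
  expect_identical(a, b)
  expect_equal(dim(a), dim(img))
  expect_true(all(a >= 0 & a <= 1))
  expect_false(identical(a, img))
  # prob = 0 is the identity
  expect_identical(augment(img, augment_config(prob = 0), seed = 4L), img)
  expect_error(augment(img * 2, cfg), "\\[0,1\\]")
  expect_error(augment_config(brightness_range = c(2, 1)), "interval")
  expect_error(augment_config(noise_std = -1), "non-negative")
})

test_that("normalization statistics standardize the training tensor", {
  set.seed(802)
  imgs <- lapply(1:8, function(i) array(runif(16 * 16 * 3), c(16, 16, 3)))
  st <- compute_norm_stats(imgs)
  expect_length(st$mean, 3L)
  x <- rt("normalize_tensor")(images_to_tensor(imgs), st)
  for (ch in 1:3) {
    v <- as.vector(x[, ch, , ])
    expect_equal(mean(v), 0, tolerance = 1e-8)
    expect_equal(sqrt(mean(v^2)), 1, tolerance = 1e-3)
  }
})
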