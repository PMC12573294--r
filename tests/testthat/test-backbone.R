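# Backbone assembly: parameter accounting, module placement, the variant
# grid, forward shapes, and checkpoint round trips.

test_that("the plain 5-class backbone has exactly 11,179,077 parameters", {
  m <- build_variant("resnet18", num_classes = 5L, input_size = c(64L, 64L),
                     seed = 1L)
  rep <- profile_model(m)
  expect_identical(rep$totals$params, 11179077)
  # the profiler agrees with a direct element count of the weights
  direct <- sum(vapply(m$params, function(p) length(p$value), numeric(1)))
  expect_equal(direct, 11179077)
})

test_that("module placement matches the design: 1 triplet, 8 CBAM, 13 PConv", {
  m <- build_variant("rtcb", num_classes = 5L, input_size = c(64L, 64L), seed = 1L)
  expect_equal(placement_counts(m),
               c(triplet = 1L, cbam = 8L, pconv = 13L))
  base <- build_variant("resnet18", num_classes = 5L, input_size = c(64L, 64L),
                        seed = 1L)
  expect_equal(placement_counts(base), c(triplet = 0L, cbam = 0L, pconv = 0L))
  single <- build_variant("rtcb", num_classes = 5L, input_size = c(64L, 64L),
                          pconv_scope = "single", seed = 1L)
  expect_equal(placement_counts(single)[["pconv"]], 1L)
})

test_that("every PConv-bearing variant is strictly lighter than its dense counterpart", {
  pro <- function(v, ...) profile_model(
    build_variant(v, num_classes = 5L, input_size = c(64L, 64L), seed = 1L, ...))$totals
  dense <- pro("resnet18_cbam_triplet")
  light <- pro("rtcb")
  expect_lt(light$params, dense$params)
  expect_lt(light$flops, dense$flops)
  dense2 <- pro("resnet18_cbam")
  light2 <- pro("resnet18_cbam_pconv")
  expect_lt(light2$params, dense2$params)
  expect_lt(light2$flops, dense2$flops)
  single <- pro("rtcb", pconv_scope = "single")
  expect_lt(single$params, dense$params)
  expect_gt(single$params, light$params)
})

test_that("each profiled pconv layer costs exactly 1/16 of its dense replacement", {
  m <- build_variant("rtcb", num_classes = 5L, input_size = c(64L, 64L), seed = 1L)
  per <- profile_model(m)$per_layer
  pc <- per[per$kind == "pconv", ]
  expect_gt(nrow(pc), 0)
  dense <- build_variant("resnet18_cbam_triplet", num_classes = 5L,
                         input_size = c(64L, 64L), seed = 1L)
  dper <- profile_model(dense)$per_layer
  for (nm in pc$layer) {
    expect_equal(pc$flops[pc$layer == nm] / dper$flops[dper$layer == nm], 1 / 16,
                 info = nm)
  }
})

test_that("forward produces (N, num_classes) logits at several input sizes", {
  for (sz in c(33L, 64L)) {
    m <- build_variant("rtcb", num_classes = 3L, input_size = c(sz, sz), seed = 2L)
    x <- array(rnorm(2 * 3 * sz * sz), c(2, 3, sz, sz))
    logits <- rt("ag_value")(m$forward(x, training = FALSE))
    expect_equal(dim(logits), c(2L, 3L))
    expect_true(all(is.finite(logits)))
  }
})

test_that("unknown variant names are rejected", {
  expect_error(build_variant("resnet50"), "variant")
})

test_that("seeded construction is reproducible", {
  m1 <- build_variant("rtcb", num_classes = 3L, input_size = c(33L, 33L), seed = 9L)
  m2 <- build_variant("rtcb", num_classes = 3L, input_size = c(33L, 33L), seed = 9L)
  for (nm in names(m1$params))
    expect_identical(m1$params[[nm]]$value, m2$params[[nm]]$value)
})

test_that("checkpoints round-trip weights, running stats and predictions", {
  set.seed(701)
  m <- build_variant("rtcb", num_classes = 3L, input_size = c(33L, 33L), seed = 3L)
  # perturb running stats away from initialization so the test is not vacuous
  x <- array(rnorm(2 * 3 * 33 * 33), c(2, 3, 33, 33))
  invisible(m$forward(x, training = TRUE))
  m$norm_stats <- list(mean = c(0.1, 0.2, 0.3), sd = c(1, 2, 3))
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path, meta = list(norm_stats = m$norm_stats, note = "t"))
  m2 <- load_checkpoint(path)
  expect_equal(m2$norm_stats, m$norm_stats)
  p1 <- predict_classes(m, x)
  p2 <- predict_classes(m2, x)
  expect_equal(p1$prob, p2$prob, tolerance = 1e-12)
  expect_identical(p1$label, p2$label)
})

test_that("predict_classes returns normalized probabilities and labels", {
  m <- build_variant("resnet18", num_classes = 5L, input_size = c(33L, 33L),
                     class_names = leaf_classes(), seed = 4L)
  x <- array(rnorm(3 * 3 * 33 * 33), c(3, 3, 33, 33))
  p <- predict_classes(m, x)
  expect_equal(rowSums(p$prob), rep(1, 3), tolerance = 1e-12)
  expect_true(all(p$label >= 1 & p$label <= 5))
  expect_equal(colnames(p$prob), leaf_classes())
})
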