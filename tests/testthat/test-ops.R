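# Compiled numeric kernels against direct-loop oracles.

test_that("conv2d forward matches the loop oracle over shapes, strides and padding", {
  set.seed(401)
  cases <- list(
    list(d = c(2, 3, 9, 9), cout = 4, k = 3, s = 1, p = 1),
    list(d = c(3, 5, 8, 10), cout = 2, k = 3, s = 2, p = 1),
    list(d = c(2, 4, 7, 7), cout = 3, k = 1, s = 1, p = 0),
    list(d = c(1, 2, 12, 6), cout = 5, k = 7, s = 2, p = 3))
  for (cs in cases) {
    x <- array(rnorm(prod(cs$d)), cs$d)
    w <- array(rnorm(cs$cout * cs$d[2] * cs$k^2), c(cs$cout, cs$d[2], cs$k, cs$k))
    b <- rnorm(cs$cout)
    got <- rt("cpp_conv2d_fwd")(x, w, b, cs$s, cs$p)
    want <- oracle_conv2d(x, w, b, cs$s, cs$p)
    expect_equal(got, want, tolerance = 1e-12)
    # bias-free path
    expect_equal(rt("cpp_conv2d_fwd")(x, w, NULL, cs$s, cs$p),
                 oracle_conv2d(x, w, NULL, cs$s, cs$p), tolerance = 1e-12)
  }
})

test_that("cached conv forward/backward agree with the uncached kernels", {
  set.seed(402)
  x <- array(rnorm(2 * 3 * 8 * 8), c(2, 3, 8, 8))
  w <- array(rnorm(4 * 3 * 9), c(4, 3, 3, 3))
  b <- rnorm(4)
  r <- rt("cpp_conv2d_fwd_cache")(x, w, b, 1L, 1L)
  expect_equal(r$y, rt("cpp_conv2d_fwd")(x, w, b, 1L, 1L), tolerance = 1e-14)
  g <- array(rnorm(length(r$y)), dim(r$y))
  got <- rt("cpp_conv2d_bwd_cache")(r$col, w, g, dim(x), 1L, 1L, TRUE, TRUE)
  ref <- rt("cpp_conv2d_bwd")(x, w, g, 1L, 1L, TRUE, TRUE)
  expect_equal(got$gw, ref$gw, tolerance = 1e-12)
  expect_equal(got$gb, ref$gb, tolerance = 1e-12)
  expect_equal(got$gx, ref$gx, tolerance = 1e-12)
})

test_that("conv2d backward matches finite differences of the forward", {
  set.seed(403)
  x <- array(rnorm(2 * 3 * 6 * 6), c(2, 3, 6, 6))
  w <- array(rnorm(4 * 3 * 9, sd = 0.5), c(4, 3, 3, 3))
  b <- rnorm(4)
  seed <- array(rnorm(2 * 4 * 6 * 6), c(2, 4, 6, 6))
  g <- rt("cpp_conv2d_bwd")(x, w, seed, 1L, 1L, TRUE, TRUE)
  eps <- 1e-6
  loss <- function() sum(rt("cpp_conv2d_fwd")(x, w, b, 1L, 1L) * seed)
  for (i in sample(length(x), 5)) {
    v <- x[i]
    x[i] <- v + eps; lp <- loss()
    x[i] <- v - eps; lm <- loss()
    x[i] <- v
    expect_equal(g$gx[i], (lp - lm) / (2 * eps), tolerance = 1e-5)
  }
  for (i in sample(length(w), 5)) {
    v <- w[i]
    w[i] <- v + eps; lp <- loss()
    w[i] <- v - eps; lm <- loss()
    w[i] <- v
    expect_equal(g$gw[i], (lp - lm) / (2 * eps), tolerance = 1e-5)
  }
  expect_equal(g$gb, apply(seed, 2, sum), tolerance = 1e-10)
})

test_that("z-pool kernel matches the loop oracle", {
  set.seed(404)
  x <- array(rnorm(2 * 7 * 5 * 6), c(2, 7, 5, 6))
  expect_equal(rt("cpp_zpool_fwd")(x)$y, oracle_zpool(x), tolerance = 1e-14)
})

test_that("max pooling matches a loop oracle with padding", {
  set.seed(405)
  x <- array(rnorm(2 * 3 * 7 * 7), c(2, 3, 7, 7))
  r <- rt("cpp_maxpool2d_fwd")(x, 3L, 2L, 1L)
  d <- dim(x)
  Ho <- (d[3] + 2 - 3) %/% 2 + 1
  for (n in 1:2) for (c in 1:3) for (ho in seq_len(Ho)) for (wo in seq_len(Ho)) {
    hs <- max(1, (ho - 1) * 2); he <- min(d[3], (ho - 1) * 2 + 2)
    ws <- max(1, (wo - 1) * 2); we <- min(d[4], (wo - 1) * 2 + 2)
    expect_equal(r$y[n, c, ho, wo], max(x[n, c, hs:he, ws:we]))
  }
})

test_that("batch-norm kernels match a plain R computation", {
  set.seed(406)
  x <- array(rnorm(3 * 5 * 4 * 6, mean = 2, sd = 3), c(3, 5, 4, 6))
  st <- rt("cpp_bn2d_stats")(x)
  expect_equal(st$mean, apply(x, 2, mean), tolerance = 1e-12)
  expect_equal(st$var, apply(x, 2, function(z) mean((z - mean(z))^2)),
               tolerance = 1e-12)
  gamma <- runif(5, 0.5, 2); beta <- rnorm(5)
  iv <- 1 / sqrt(st$var + 1e-5)
  y <- rt("cpp_bn2d_fwd")(x, st$mean, iv, gamma, beta)
  want <- x
  for (c in 1:5) want[, c, , ] <- gamma[c] * (x[, c, , ] - st$mean[c]) * iv[c] + beta[c]
  expect_equal(y, want, tolerance = 1e-12)
})

test_that("the spatial-gate kernel and its backward match loop oracles", {
  set.seed(407)
  x <- array(rnorm(3 * 5 * 4 * 6), c(3, 5, 4, 6))
  g <- array(runif(3 * 1 * 4 * 6), c(3, 1, 4, 6))
  y <- rt("cpp_sgate_fwd")(x, g)
  want <- x
  for (c in 1:5) want[, c, , ] <- x[, c, , ] * g[, 1, , ]
  expect_equal(y, want, tolerance = 1e-14)
  gr <- array(rnorm(length(x)), dim(x))
  r <- rt("cpp_sgate_bwd")(x, g, gr, TRUE)
  gg <- array(0, dim(g))
  for (c in 1:5) gg[, 1, , ] <- gg[, 1, , ] + gr[, c, , ] * x[, c, , ]
  gx <- gr
  for (c in 1:5) gx[, c, , ] <- gr[, c, , ] * g[, 1, , ]
  expect_equal(r$gg, gg, tolerance = 1e-13)
  expect_equal(r$gx, gx, tolerance = 1e-13)
})

test_that("the 4-D permute kernel agrees with aperm", {
  set.seed(408)
  x <- array(rnorm(3 * 6 * 5 * 4), c(3, 6, 5, 4))
  for (p in list(c(1, 4, 3, 2), c(1, 3, 2, 4), c(1, 2, 4, 3), c(1, 4, 2, 3)))
    expect_identical(rt("cpp_aperm4")(x, as.integer(p)), aperm(x, p))
  expect_error(rt("cpp_aperm4")(x, c(2L, 1L, 3L, 4L)), "axis 1 first")
})

test_that("relu kernels are exact and mask on the forward sign", {
  x <- array(c(-1, 0, 2, -3, 4, 5), c(1, 1, 2, 3))
  y <- rt("cpp_relu_fwd")(x)
  expect_equal(as.vector(y), c(0, 0, 2, 0, 4, 5))
  g <- array(rep(1, 6), dim(x))
  expect_equal(as.vector(rt("cpp_relu_bwd")(g, y)), c(0, 0, 1, 0, 1, 1))
})

test_that("conv kernels validate their inputs", {
  x <- array(0, c(1, 3, 4, 4))
  w_bad <- array(0, c(2, 4, 3, 3))
  expect_error(rt("cpp_conv2d_fwd")(x, w_bad, NULL, 1L, 1L), "channels")
  w_rect <- array(0, c(2, 3, 3, 5))
  expect_error(rt("cpp_conv2d_fwd")(x, w_rect, NULL, 1L, 1L), "square")
  w <- array(0, c(2, 3, 3, 3))
  expect_error(rt("cpp_conv2d_fwd")(x, w, NULL, 1L, -1L))
  expect_error(rt("cpp_conv2d_fwd")(array(0, c(1, 3, 2, 2)), array(0, c(2, 3, 7, 7)),
                                    NULL, 1L, 0L), "too small")
})
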