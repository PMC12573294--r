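# Brute-force reference implementations used to validate the package's
# vectorized / compiled kernels, plus small shared test utilities. All
# oracles are written as plain loops with no shared code paths with the
# package internals.

rt <- function(name) get(name, asNamespace("rtcbnet"))

# Direct-loop 2-D convolution over a (N, C, H, W) array with a
# (Cout, Cin, k, k) kernel.
oracle_conv2d <- function(x, w, b = NULL, stride = 1L, pad = 0L) {
  d <- dim(x)
  wd <- dim(w)
  k <- wd[3]
  Ho <- (d[3] + 2 * pad - k) %/% stride + 1L
  Wo <- (d[4] + 2 * pad - k) %/% stride + 1L
  xp <- array(0, c(d[1], d[2], d[3] + 2 * pad, d[4] + 2 * pad))
  xp[, , pad + seq_len(d[3]), pad + seq_len(d[4])] <- x
  y <- array(0, c(d[1], wd[1], Ho, Wo))
  for (n in seq_len(d[1])) for (co in seq_len(wd[1]))
    for (ho in seq_len(Ho)) for (wo in seq_len(Wo)) {
      acc <- if (is.null(b)) 0 else b[co]
      for (ci in seq_len(d[2])) for (ki in seq_len(k)) for (kj in seq_len(k))
        acc <- acc + xp[n, ci, (ho - 1L) * stride + ki, (wo - 1L) * stride + kj] *
          w[co, ci, ki, kj]
      y[n, co, ho, wo] <- acc
    }
  y
}

# Per-position channel max / mean, by explicit loops.
oracle_zpool <- function(x) {
  d <- dim(x)
  y <- array(0, c(d[1], 2L, d[3], d[4]))
  for (n in seq_len(d[1])) for (h in seq_len(d[3])) for (w in seq_len(d[4])) {
    v <- x[n, , h, w]
    y[n, 1L, h, w] <- max(v)
    y[n, 2L, h, w] <- mean(v)
  }
  y
}

# One triplet-attention branch by loops: optionally permute, Z-pool,
# convolve (k x k, same padding), sigmoid, re-weight, permute back.
oracle_triplet <- function(x, block) {
  p <- lapply(block$params, function(t) t$value)
  k <- block$kernel_size
  pad <- block$pad
  branch <- function(xr, w, b) {
    g <- 1 / (1 + exp(-oracle_conv2d(oracle_zpool(xr), w, b, 1L, pad)))
    out <- xr
    for (c in seq_len(dim(xr)[2])) out[, c, , ] <- xr[, c, , ] * g[, 1L, , ]
    out
  }
  o1 <- aperm(branch(aperm(x, c(1, 4, 3, 2)), p$w1, p$b1), c(1, 4, 3, 2))
  o2 <- aperm(branch(aperm(x, c(1, 3, 2, 4)), p$w2, p$b2), c(1, 3, 2, 4))
  o3 <- branch(x, p$w3, p$b3)
  (o1 + o2 + o3) / 3
}

# CBAM by loops from the block's raw parameter values.
oracle_cbam_channel_gate <- function(x, block) {
  p <- lapply(block$params, function(t) t$value)
  d <- dim(x)
  mlp <- function(v) {
    h <- pmax(as.vector(v %*% p$w_mlp1) + p$b_mlp1, 0)
    as.vector(h %*% p$w_mlp2) + p$b_mlp2
  }
  g <- matrix(0, d[1], d[2])
  for (n in seq_len(d[1])) {
    avg <- vapply(seq_len(d[2]), function(c) mean(x[n, c, , ]), numeric(1))
    mx <- vapply(seq_len(d[2]), function(c) max(x[n, c, , ]), numeric(1))
    g[n, ] <- 1 / (1 + exp(-(mlp(rbind(avg)) + mlp(rbind(mx)))))
  }
  g
}

oracle_cbam <- function(x, block) {
  p <- lapply(block$params, function(t) t$value)
  cg <- oracle_cbam_channel_gate(x, block)
  f1 <- x
  for (n in seq_len(dim(x)[1])) for (c in seq_len(dim(x)[2]))
    f1[n, c, , ] <- x[n, c, , ] * cg[n, c]
  sg <- 1 / (1 + exp(-oracle_conv2d(oracle_zpool(f1), p$w_sp, p$b_sp, 1L, block$pad)))
  out <- f1
  for (c in seq_len(dim(x)[2])) out[, c, , ] <- f1[, c, , ] * sg[, 1L, , ]
  out
}

# Partial convolution by loops: dense conv on the first c_p channels,
# identity on the rest.
oracle_pconv <- function(x, layer) {
  w <- layer$params$w$value
  b <- if (is.null(layer$params$b)) NULL else layer$params$b$value
  y <- x
  xs <- x[, seq_len(layer$c_p), , , drop = FALSE]
  y[, seq_len(layer$c_p), , ] <- oracle_conv2d(xs, w, b, 1L, layer$pad)
  y
}

# Central-difference gradient check of a scalar-valued builder against the
# recorded gradients of the listed parameter tensors. Returns the largest
# relative error over `per` sampled coordinates per tensor.
gradcheck_max_rel <- function(make_loss, tensors, eps = 1e-5, per = 3L) {
  loss <- make_loss()
  rt("ag_backward")(loss)
  grads <- lapply(tensors, function(t) t$grad)
  worst <- 0
  for (j in seq_along(tensors)) {
    t <- tensors[[j]]
    for (i in sample(length(t$value), min(per, length(t$value)))) {
      v0 <- t$value[i]
      t$value[i] <- v0 + eps
      lp <- make_loss()$value
      t$value[i] <- v0 - eps
      lm <- make_loss()$value
      t$value[i] <- v0
      num <- (lp - lm) / (2 * eps)
      worst <- max(worst, abs(num - grads[[j]][i]) / max(1, abs(num)))
    }
  }
  worst
}

# A deterministic tiny dataset on disk for pipeline tests; created once per
# test run and shared read-only.
tiny_dataset <- local({
  dir <- NULL
  function() {
    if (is.null(dir)) {
      dir <<- file.path(tempdir(), "tinydata")
      if (!dir.exists(dir))
        generate_dataset(6L, dir, image_size = 32L, seed = 7L)
    }
    dir
  }
})

# Like tiny_dataset(), but at the smallest size the backbone accepts, for
# tests that actually train or evaluate a model on it.
tiny_dataset33 <- local({
  dir <- NULL
  function() {
    if (is.null(dir)) {
      dir <<- file.path(tempdir(), "tinydata33")
      if (!dir.exists(dir))
        generate_dataset(6L, dir, image_size = 33L, seed = 7L)
    }
    dir
  }
})
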