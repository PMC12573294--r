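# Differentiable operations over (N, C, H, W) activation arrays. Heavy
# kernels (convolution, pooling, Z-pool) live in src/tensor_ops.cpp; the
# rest are expressed with matrix views of the flat array: matrix(x, N*C)
# has rows indexed by n + N*(c-1) and columns by the spatial position, so
# per-channel and per-position broadcasts become vector recycling.

dim4 <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) != 4L) stop("expected a 4-D (N, C, H, W) array")
  d
}

# ---- convolution -----------------------------------------------------------

ag_conv2d <- function(x, w, b = NULL, stride = 1L, pad = 0L) {
  bv <- if (is.null(b)) NULL else b$value
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  if (!ag_grad_enabled())
    return(ag_op(cpp_conv2d_fwd(x$value, w$value, bv, as.integer(stride),
                                as.integer(pad)), parents, NULL))
  # keep the im2col matrix from the forward pass for reuse in backward
  r <- cpp_conv2d_fwd_cache(x$value, w$value, bv, as.integer(stride),
                            as.integer(pad))
  xdim <- dim(x$value)
  ag_op(r$y, parents, function(g) {
    gr <- cpp_conv2d_bwd_cache(r$col, w$value, g, xdim, as.integer(stride),
                               as.integer(pad), x$requires_grad, !is.null(b))
    out <- list(gr$gx, gr$gw)
    if (!is.null(b)) out[[3L]] <- gr$gb
    out
  })
}

# Partial convolution: dense conv on the first c_p channels, identity on the
# rest (both directions of the gradient follow the same split).
ag_pconv <- function(x, w, b = NULL, c_p, pad = 0L) {
  d <- dim4(x$value)
  if (c_p < 1L || c_p > d[2]) stop("partial channel count must lie in [1, C]")
  xs <- x$value[, seq_len(c_p), , , drop = FALSE]
  bv <- if (is.null(b)) NULL else b$value
  cache <- ag_grad_enabled()
  if (cache) {
    rf <- cpp_conv2d_fwd_cache(xs, w$value, bv, 1L, as.integer(pad))
    ys <- rf$y
  } else {
    ys <- cpp_conv2d_fwd(xs, w$value, bv, 1L, as.integer(pad))
  }
  y <- x$value
  y[, seq_len(c_p), , ] <- ys
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  ag_op(y, parents, function(g) {
    gs <- g[, seq_len(c_p), , , drop = FALSE]
    r <- cpp_conv2d_bwd_cache(rf$col, w$value, gs, dim(xs), 1L,
                              as.integer(pad), x$requires_grad, !is.null(b))
    gx <- NULL
    if (x$requires_grad) {
      gx <- g
      gx[, seq_len(c_p), , ] <- r$gx
    }
    out <- list(gx, r$gw)
    if (!is.null(b)) out[[3L]] <- r$gb
    out
  })
}

# ---- pointwise -------------------------------------------------------------

ag_relu <- function(x) {
  y <- cpp_relu_fwd(x$value)
  ag_op(y, list(x), function(g) list(cpp_relu_bwd(g, y)))
}

ag_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$value))
  ag_op(s, list(x), function(g) list(g * s * (1 - s)))
}

ag_add <- function(x, y) {
  ag_op(x$value + y$value, list(x, y), function(g) list(g, g))
}

ag_scale <- function(x, s) {
  ag_op(x$value * s, list(x), function(g) list(g * s))
}

# ---- reductions and broadcast gates ---------------------------------------

# axis permutation (pure relabeling; backward applies the inverse). All
# call sites keep the batch axis first, which the C++ kernel exploits.
ag_permute <- function(x, perm) {
  inv <- order(perm)
  ag_op(cpp_aperm4(x$value, as.integer(perm)), list(x),
        function(g) list(cpp_aperm4(g, as.integer(inv))))
}

ag_zpool <- function(x) {
  d <- dim4(x$value)
  r <- cpp_zpool_fwd(x$value)
  ag_op(r$y, list(x), function(g) list(cpp_zpool_bwd(g, r$argmax, d[2])))
}

# global average pool (N,C,H,W) -> (N,C)
ag_gap <- function(x) {
  d <- dim4(x$value)
  hw <- d[3] * d[4]
  v <- .rowMeans(x$value, d[1] * d[2], hw)
  ag_op(matrix(v, d[1], d[2]), list(x), function(g) {
    gx <- matrix(as.vector(g) / hw, d[1] * d[2], hw)
    dim(gx) <- d
    list(gx)
  })
}

# global max pool (N,C,H,W) -> (N,C)
ag_gmp <- function(x) {
  d <- dim4(x$value)
  r <- cpp_gmp_fwd(x$value)
  ag_op(r$y, list(x), function(g) {
    gx <- numeric(prod(d))
    gx[r$argmax + 1L] <- as.vector(g)
    dim(gx) <- d
    list(gx)
  })
}

ag_maxpool2d <- function(x, k = 3L, stride = 2L, pad = 1L) {
  d <- dim4(x$value)
  r <- cpp_maxpool2d_fwd(x$value, as.integer(k), as.integer(stride), as.integer(pad))
  ag_op(r$y, list(x), function(g) list(cpp_maxpool2d_bwd(g, r$argmax, d)))
}

# multiply by a per-channel gate g: (N, C) in (0,1)
ag_mul_cgate <- function(x, g) {
  d <- dim4(x$value)
  hw <- d[3] * d[4]
  gv <- as.vector(g$value) # index n + N*(c-1); recycles over spatial columns
  y <- x$value * gv
  ag_op(y, list(x, g), function(gr) {
    gx <- if (x$requires_grad) gr * gv else NULL
    gg <- .rowSums(gr * x$value, d[1] * d[2], hw)
    list(gx, matrix(gg, d[1], d[2]))
  })
}

# multiply by a per-position gate g: (N, 1, H, W) in (0,1)
ag_mul_sgate <- function(x, g) {
  dim4(x$value)
  y <- cpp_sgate_fwd(x$value, g$value)
  ag_op(y, list(x, g), function(gr) {
    r <- cpp_sgate_bwd(x$value, g$value, gr, x$requires_grad)
    list(r$gx, r$gg)
  })
}

# ---- batch normalization ---------------------------------------------------

chan_sum <- function(x, d) {
  rs <- .rowSums(x, d[1] * d[2], d[3] * d[4])
  .colSums(rs, d[1], d[2])
}

# Per-channel broadcasts: a length-N*C vector recycles over the spatial
# columns of the flat (N, C, H, W) array, so no reshape copy is needed.
chan_bcast_mul <- function(x, v, d) {
  y <- x * rep(v, each = d[1])
  if (is.null(dim(y))) dim(y) <- d
  y
}

chan_bcast_add <- function(x, v, d) {
  y <- x + rep(v, each = d[1])
  if (is.null(dim(y))) dim(y) <- d
  y
}

# Batch norm over (N, H, W) per channel. `layer` is an environment carrying
# running_mean / running_var, updated in training mode with `momentum`.
# Forward and backward are fused C++ passes (see src/tensor_ops.cpp).
ag_bn2d <- function(x, gamma, beta, layer, training, momentum = 0.1, eps = 1e-5) {
  d <- dim4(x$value)
  m <- d[1] * d[3] * d[4]
  if (training) {
    st <- cpp_bn2d_stats(x$value)
    mu <- st$mean
    var <- st$var
    layer$running_mean <- (1 - momentum) * layer$running_mean + momentum * mu
    # unbiased running variance, matching the usual framework convention
    ub <- if (m > 1) var * m / (m - 1) else var
    layer$running_var <- (1 - momentum) * layer$running_var + momentum * ub
  } else {
    mu <- layer$running_mean
    var <- layer$running_var
  }
  invstd <- 1 / sqrt(var + eps)
  y <- cpp_bn2d_fwd(x$value, mu, invstd, gamma$value, beta$value)
  ag_op(y, list(x, gamma, beta), function(g) {
    r <- cpp_bn2d_bwd(x$value, g, gamma$value, mu, invstd, training,
                      x$requires_grad)
    list(r$gx, r$dgamma, r$dbeta)
  })
}

# ---- dense head ------------------------------------------------------------

ag_linear <- function(x, w, b = NULL) {
  y <- x$value %*% w$value
  if (!is.null(b)) y <- sweep(y, 2L, b$value, "+")
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  ag_op(y, parents, function(g) {
    out <- list(if (x$requires_grad) g %*% t(w$value) else NULL,
                crossprod(x$value, g))
    if (!is.null(b)) out[[3L]] <- colSums(g)
    out
  })
}

# Fused softmax + mean cross-entropy. labels are 1-based class indices.
ag_softmax_ce <- function(logits, labels) {
  z <- logits$value
  z <- z - apply(z, 1L, max)
  ez <- exp(z)
  p <- ez / rowSums(ez)
  n <- nrow(z)
  idx <- cbind(seq_len(n), labels)
  loss <- -mean(log(pmax(p[idx], 1e-300)))
  ag_op(loss, list(logits), function(g) {
    gz <- p
    gz[idx] <- gz[idx] - 1
    list(gz * (g / n))
  })
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  ez <- exp(z)
  ez / rowSums(ez)
}
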