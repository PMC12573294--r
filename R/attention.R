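# Attention blocks: triplet attention (three rotated Z-pool branches) and
# the convolutional block attention module (CBAM). Blocks are environments
# holding learnable tensors plus a forward() that records onto the tape;
# the exported functional API wraps plain arrays for interactive use and
# for oracle testing.

check_odd_kernel <- function(k, what) {
  if (length(k) != 1L || k < 3L || k %% 2L == 0L)
    stop(what, " must be an odd integer >= 3")
  as.integer(k)
}

#' Z-pool channel compression
#'
#' Compresses the channel axis of a feature map into two channels: the
#' per-position maximum over channels and the per-position mean. This is the
#' descriptor both triplet-attention branches and the CBAM spatial gate are
#' built on.
#'
#' @param x A 4-D numeric array with dimensions `(N, C, H, W)`.
#' @return A 4-D array `(N, 2, H, W)`; channel 1 is the max, channel 2 the
#'   mean, so channel 1 >= channel 2 everywhere.
#' @examples
#' x <- array(rnorm(1 * 3 * 4 * 4), dim = c(1, 3, 4, 4))
#' z <- z_pool(x)
#' dim(z) # 1 2 4 4
#' @export
z_pool <- function(x) {
  dim4(x)
  cpp_zpool_fwd(x)$y
}

#' Rotate a feature map about a spatial axis
#'
#' A pure axis permutation with no value change: rotating anticlockwise about
#' the H axis swaps the channel and width axes; rotating about the W axis
#' swaps the channel and height axes. Each rotation is its own inverse, so
#' `"cw"` undoes `"ccw"` exactly.
#'
#' @param x A 4-D numeric array `(N, C, H, W)`.
#' @param axis `"H"` or `"W"`, the axis held fixed.
#' @param direction `"ccw"` or `"cw"`.
#' @return The permuted array.
#' @export
rotate <- function(x, axis = c("H", "W"), direction = c("ccw", "cw")) {
  dim4(x)
  axis <- match.arg(axis)
  direction <- match.arg(direction)
  perm <- if (axis == "H") c(1L, 4L, 3L, 2L) else c(1L, 3L, 2L, 4L)
  aperm(x, perm)
}

rotation_perm <- function(axis) if (axis == "H") c(1L, 4L, 3L, 2L) else c(1L, 3L, 2L, 4L)

#' Construct a triplet attention block
#'
#' Three branches each compress their (possibly rotated) input with Z-pool,
#' convolve the 2-channel descriptor down to a single attention map, gate it
#' through a sigmoid and multiply it back onto the branch input. Branch 1
#' rotates about H (coupling channels with width), branch 2 about W
#' (coupling channels with height), branch 3 operates in place; the three
#' gated maps are un-rotated and averaged.
#'
#' @param kernel_size Odd receptive field of each branch convolution
#'   (default 7, the convention of the attention literature); padding is
#'   `(kernel_size - 1) / 2` so shapes are preserved.
#' @param init `"he"` for He-normal kernels with zero biases, `"zero"` for
#'   all-zero state (under which the block returns exactly `x / 2`).
#' @return A block environment with fields `params`, `forward(x, training)`,
#'   and `complexity(c, h, w)`.
#' @export
triplet_attention_block <- function(kernel_size = 7L, init = c("he", "zero")) {
  k <- check_odd_kernel(kernel_size, "kernel_size")
  init <- match.arg(init)
  pad <- (k - 1L) %/% 2L
  blk <- new.env(parent = emptyenv())
  blk$kind <- "triplet"
  blk$kernel_size <- k
  blk$pad <- pad
  kern <- function() if (init == "he") he_kernel(1L, 2L, k) else array(0, c(1L, 2L, k, k))
  blk$params <- list(
    w1 = ag_param(kern()), b1 = ag_param(numeric(1)),
    w2 = ag_param(kern()), b2 = ag_param(numeric(1)),
    w3 = ag_param(kern()), b3 = ag_param(numeric(1)))
  branch <- function(xt, w, b, perm) {
    xr <- if (is.null(perm)) xt else ag_permute(xt, perm)
    gate <- ag_sigmoid(ag_conv2d(ag_zpool(xr), w, b, stride = 1L, pad = pad))
    out <- ag_mul_sgate(xr, gate)
    if (is.null(perm)) out else ag_permute(out, perm)
  }
  blk$forward <- function(xt, training = FALSE) {
    p <- blk$params
    o1 <- branch(xt, p$w1, p$b1, rotation_perm("H"))
    o2 <- branch(xt, p$w2, p$b2, rotation_perm("W"))
    o3 <- branch(xt, p$w3, p$b3, NULL)
    ag_scale(ag_add(ag_add(o1, o2), o3), 1 / 3)
  }
  blk$complexity <- function(c, h, w) {
    pk <- 2L * k * k + 1L
    data.frame(
      layer = c("triplet.branch_hw", "triplet.branch_wh", "triplet.branch_hw2"),
      kind = "conv",
      params = rep(pk, 3L),
      flops = as.numeric(k)^2 * 2 * c(h * c, c * w, h * w))
  }
  class(blk) <- "rtcb_block"
  blk
}

validate_triplet_weights <- function(w) {
  d <- dim(w)
  if (length(d) != 4L || d[1] != 1L || d[2] != 2L)
    stop("triplet branch convolution must map 2 channels to 1 channel")
}

#' Apply triplet attention to a feature map
#'
#' Functional form of [triplet_attention_block()]: runs the three-branch
#' rotate / Z-pool / convolve / sigmoid / re-weight computation and averages
#' the branches. Shape is preserved.
#'
#' @param x A 4-D numeric array `(N, C, H, W)`.
#' @param block A block from [triplet_attention_block()].
#' @return An array with the same dimensions as `x`.
#' @export
triplet_attention <- function(x, block) {
  stopifnot(identical(block$kind, "triplet"))
  for (nm in c("w1", "w2", "w3")) validate_triplet_weights(block$params[[nm]]$value)
  ag_value(block$forward(as_ag(x), training = FALSE))
}

#' Construct a CBAM block
#'
#' Channel gate: global average and global max pooled channel descriptors
#' pass through a shared two-layer bottleneck MLP; the two outputs are summed
#' and squashed by a sigmoid into one weight per channel. Spatial gate: the
#' channel-max/channel-mean pair (Z-pool) of the channel-reweighted map is
#' convolved with a single odd kernel and squashed into one weight per
#' position. The block applies both gates in sequence.
#'
#' @param channels Number of input channels `C`.
#' @param reduction Bottleneck ratio `r`; the hidden width is
#'   `max(1, floor(C / r))`, clamped so narrow layers stay valid.
#' @param spatial_kernel Odd kernel for the spatial gate (default 7).
#' @param init `"he"` or `"zero"` (all-zero state gives exactly `F / 4`).
#' @return A block environment with `params`, `forward(x, training)`,
#'   `channel_gate(x)`, `spatial_gate(x)` and `complexity(c, h, w)`.
#' @export
cbam_block <- function(channels, reduction = 16L, spatial_kernel = 7L,
                       init = c("he", "zero")) {
  init <- match.arg(init)
  if (channels < 1L) stop("channels must be positive")
  if (reduction < 1L) stop("reduction must be a positive integer")
  k <- check_odd_kernel(spatial_kernel, "spatial_kernel")
  hidden <- max(1L, channels %/% as.integer(reduction))
  pad <- (k - 1L) %/% 2L
  blk <- new.env(parent = emptyenv())
  blk$kind <- "cbam"
  blk$channels <- as.integer(channels)
  blk$hidden <- hidden
  blk$spatial_kernel <- k
  blk$pad <- pad
  mk <- function(f) if (init == "he") f else f * 0
  blk$params <- list(
    w_mlp1 = ag_param(mk(he_linear(channels, hidden))),
    b_mlp1 = ag_param(numeric(hidden)),
    w_mlp2 = ag_param(mk(he_linear(hidden, channels))),
    b_mlp2 = ag_param(numeric(channels)),
    w_sp = ag_param(mk(he_kernel(1L, 2L, k))),
    b_sp = ag_param(numeric(1)))
  mlp <- function(v) {
    p <- blk$params
    ag_linear(ag_relu(ag_linear(v, p$w_mlp1, p$b_mlp1)), p$w_mlp2, p$b_mlp2)
  }
  blk$channel_gate_t <- function(xt) {
    ag_sigmoid(ag_add(mlp(ag_gap(xt)), mlp(ag_gmp(xt))))
  }
  blk$spatial_gate_t <- function(xt) {
    p <- blk$params
    ag_sigmoid(ag_conv2d(ag_zpool(xt), p$w_sp, p$b_sp, stride = 1L, pad = pad))
  }
  blk$forward <- function(xt, training = FALSE) {
    d <- dim4(xt$value)
    if (d[2] != blk$channels)
      stop("CBAM block built for ", blk$channels, " channels, got ", d[2])
    f1 <- ag_mul_cgate(xt, blk$channel_gate_t(xt))
    ag_mul_sgate(f1, blk$spatial_gate_t(f1))
  }
  blk$complexity <- function(c, h, w) {
    data.frame(
      layer = c("cbam.mlp1", "cbam.mlp2", "cbam.spatial"),
      kind = c("linear", "linear", "conv"),
      params = c(c * hidden + hidden, hidden * c + c, 2L * k * k + 1L),
      flops = c(2 * c * hidden, 2 * hidden * c, as.numeric(h) * w * k^2 * 2))
  }
  class(blk) <- "rtcb_block"
  blk
}

#' CBAM channel gate weights
#'
#' @param x A 4-D numeric array `(N, C, H, W)`.
#' @param block A block from [cbam_block()].
#' @return An `(N, C)` matrix of per-channel weights, each strictly in (0, 1).
#' @export
cbam_channel_gate <- function(x, block) {
  stopifnot(identical(block$kind, "cbam"))
  ag_value(block$channel_gate_t(as_ag(x)))
}

#' CBAM spatial gate weights
#'
#' @inheritParams cbam_channel_gate
#' @return An `(N, 1, H, W)` array of per-position weights in (0, 1).
#' @export
cbam_spatial_gate <- function(x, block) {
  stopifnot(identical(block$kind, "cbam"))
  ag_value(block$spatial_gate_t(as_ag(x)))
}

#' Apply a CBAM block to a feature map
#'
#' @inheritParams cbam_channel_gate
#' @param bypass_gates Test hook: when `TRUE` both gates are treated as the
#'   identity (weight 1 everywhere) so the output equals `x` exactly.
#' @return An array with the same dimensions as `x`.
#' @export
cbam <- function(x, block, bypass_gates = FALSE) {
  stopifnot(identical(block$kind, "cbam"))
  if (bypass_gates) return(x)
  ag_value(block$forward(as_ag(x), training = FALSE))
}
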