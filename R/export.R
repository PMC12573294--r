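# Portable model export. The model is flattened into a JSON list of
# primitive graph nodes (convolutions, folded batch-norm affines, pooling,
# gates, permutations) plus a flat float64 weight file, and a standalone
# interpreter replays the graph from those files. The interpreter never
# touches the training-time layer objects, so export/replay parity is a
# real end-to-end check of the serialization: attention blocks are
# decomposed into primitives and batch norm is folded into per-channel
# affine transforms at export time.

graph_builder <- function() {
  b <- new.env(parent = emptyenv())
  b$nodes <- list()
  b$weights <- list()
  b$offset <- 0L
  b$add_weight <- function(v) {
    ref <- list(offset = b$offset, n = length(v), dims = as.integer(dim(v) %||% length(v)))
    b$weights[[length(b$weights) + 1L]] <- as.numeric(v)
    b$offset <- b$offset + length(v)
    ref
  }
  b$node <- function(op, inputs = integer(), attrs = list(), params = list()) {
    inputs <- as.integer(inputs) # force before taking an id: nested node()
    id <- length(b$nodes) + 1L   # calls in the argument must register first
    prefs <- lapply(params, b$add_weight)
    b$nodes[[id]] <- list(id = id, op = op, inputs = as.integer(inputs),
                          attrs = attrs, params = prefs)
    id
  }
  b
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fold_bn <- function(bn, eps = 1e-5) {
  scale <- bn$params$gamma$value / sqrt(bn$running_var + eps)
  list(scale = scale, shift = bn$params$beta$value - bn$running_mean * scale)
}

emit_conv <- function(b, x, ly) {
  params <- list(w = ly$params$w$value)
  if (!is.null(ly$params$b)) params$b <- ly$params$b$value
  b$node("conv", x, list(stride = ly$stride, pad = ly$pad), params)
}

emit_bn <- function(b, x, bn) {
  f <- fold_bn(bn)
  b$node("affine_c", x, list(), list(scale = f$scale, shift = f$shift))
}

emit_pconv <- function(b, x, ly) {
  params <- list(w = ly$params$w$value)
  if (!is.null(ly$params$b)) params$b <- ly$params$b$value
  if (ly$c_p == ly$channels)
    return(b$node("conv", x, list(stride = 1L, pad = ly$pad), params))
  head <- b$node("slice_c", x, list(from = 1L, to = ly$c_p))
  conv <- b$node("conv", head, list(stride = 1L, pad = ly$pad), params)
  tail <- b$node("slice_c", x, list(from = ly$c_p + 1L, to = ly$channels))
  b$node("concat_c", c(conv, tail))
}

emit_block_conv <- function(b, x, ly) {
  if (identical(ly$kind, "pconv")) emit_pconv(b, x, ly) else emit_conv(b, x, ly)
}

emit_triplet <- function(b, x, blk) {
  branch <- function(perm, w, bias) {
    xr <- if (is.null(perm)) x else b$node("permute", x, list(perm = perm))
    z <- b$node("zpool", xr)
    a <- b$node("conv", z, list(stride = 1L, pad = blk$pad),
                list(w = w$value, b = bias$value))
    g <- b$node("sigmoid", a)
    xg <- b$node("mul_spatial", c(xr, g))
    if (is.null(perm)) xg else b$node("permute", xg, list(perm = perm))
  }
  p <- blk$params
  o1 <- branch(rotation_perm("H"), p$w1, p$b1)
  o2 <- branch(rotation_perm("W"), p$w2, p$b2)
  o3 <- branch(NULL, p$w3, p$b3)
  s <- b$node("add", c(b$node("add", c(o1, o2)), o3))
  b$node("scale", s, list(s = 1 / 3))
}

emit_cbam <- function(b, x, blk) {
  p <- blk$params
  mlp <- function(v) {
    h <- b$node("linear", v, list(), list(w = p$w_mlp1$value, b = p$b_mlp1$value))
    h <- b$node("relu", h)
    b$node("linear", h, list(), list(w = p$w_mlp2$value, b = p$b_mlp2$value))
  }
  s <- b$node("sigmoid", b$node("add", c(mlp(b$node("gap", x)),
                                         mlp(b$node("gmp", x)))))
  f1 <- b$node("mul_channel", c(x, s))
  g <- b$node("sigmoid",
              b$node("conv", b$node("zpool", f1),
                     list(stride = 1L, pad = blk$pad),
                     list(w = p$w_sp$value, b = p$b_sp$value)))
  b$node("mul_spatial", c(f1, g))
}

emit_basic_block <- function(b, x, blk) {
  h <- b$node("relu", emit_bn(b, emit_block_conv(b, x, blk$conv1), blk$bn1))
  h <- emit_bn(b, emit_block_conv(b, h, blk$conv2), blk$bn2)
  if (!is.null(blk$cbam)) h <- emit_cbam(b, h, blk$cbam)
  short <- if (is.null(blk$downsample)) x
           else emit_bn(b, emit_conv(b, x, blk$downsample$conv), blk$downsample$bn)
  b$node("relu", b$node("add", c(h, short)))
}

#' Export a model as a portable graph
#'
#' Writes `graph.json` (a topologically ordered list of primitive nodes
#' with weight references) and `weights.bin` (flat little-endian float64)
#' into `dir`. Batch norm is folded into per-channel affines using the
#' model's running statistics, attention blocks are decomposed into
#' primitive nodes, and the model's normalization statistics (when present)
#' travel in the JSON metadata. [run_exported()] replays the files with an
#' independent interpreter.
#'
#' @param model An `rtcb_model` (initialized or trained).
#' @param dir Output directory (created if missing).
#' @return Invisibly, the directory.
#' @export
export_model <- function(model, dir) {
  stopifnot(inherits(model, "rtcb_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  b <- graph_builder()
  x <- b$node("input", attrs = list(channels = 3L))
  h <- b$node("relu", emit_bn(b, emit_conv(b, x, model$stem$conv), model$stem$bn))
  if (!is.null(model$triplet)) h <- emit_triplet(b, h, model$triplet)
  h <- b$node("maxpool", h, list(k = 3L, stride = 2L, pad = 1L))
  for (st in model$stages) for (blk in st) h <- emit_basic_block(b, h, blk)
  h <- b$node("gap", h)
  out <- b$node("linear", h, list(),
                list(w = model$fc$params$w$value, b = model$fc$params$b$value))
  graph <- list(format = "rtcb-graph", version = 1L,
                input = list(shape = c(3L, model$spec$input_size)),
                output = out,
                meta = list(spec = model$spec,
                            norm_stats = model$norm_stats),
                weights = list(file = "weights.bin", dtype = "float64",
                               n = b$offset),
                nodes = b$nodes)
  jsonlite::write_json(graph, file.path(dir, "graph.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  con <- file(file.path(dir, "weights.bin"), "wb")
  on.exit(close(con))
  for (wv in b$weights) writeBin(wv, con, size = 8L, endian = "little")
  invisible(dir)
}

# ---- standalone interpreter ------------------------------------------------

read_graph <- function(dir) {
  g <- jsonlite::read_json(file.path(dir, "graph.json"), simplifyVector = TRUE,
                           simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  wpath <- file.path(dir, g$weights$file)
  w <- readBin(wpath, "double", n = g$weights$n, size = 8L, endian = "little")
  if (length(w) != g$weights$n) stop("weight file truncated")
  list(graph = g, w = w)
}

fetch_param <- function(ref, w) {
  v <- w[(ref$offset + 1L):(ref$offset + ref$n)]
  dims <- unlist(ref$dims)
  if (length(dims) > 1L) dim(v) <- dims
  v
}

#' Run an exported graph
#'
#' Evaluates the graph written by [export_model()] on a batch of inputs,
#' using only the serialized files (an independent execution path from the
#' model's own forward).
#'
#' @param dir Directory holding `graph.json` and `weights.bin`.
#' @param x A `(N, 3, H, W)` input array (already normalized).
#' @return The `(N, K)` logit matrix.
#' @export
run_exported <- function(dir, x) {
  ge <- read_graph(dir)
  g <- ge$graph
  vals <- vector("list", length(g$nodes))
  for (nd in g$nodes) {
    ins <- lapply(unlist(nd$inputs), function(i) vals[[i]])
    pr <- lapply(nd$params, fetch_param, w = ge$w)
    at <- nd$attrs
    vals[[nd$id]] <- switch(nd$op,
      input = x,
      conv = cpp_conv2d_fwd(ins[[1]], pr$w, pr$b, at$stride, at$pad),
      affine_c = {
        d <- dim(ins[[1]])
        y <- matrix(ins[[1]], d[1] * d[2], d[3] * d[4]) * rep(pr$scale, each = d[1]) +
          rep(pr$shift, each = d[1])
        dim(y) <- d
        y
      },
      relu = pmax(ins[[1]], 0) * 1,
      sigmoid = 1 / (1 + exp(-ins[[1]])),
      add = ins[[1]] + ins[[2]],
      scale = ins[[1]] * at$s,
      permute = aperm(ins[[1]], unlist(at$perm)),
      zpool = cpp_zpool_fwd(ins[[1]])$y,
      maxpool = cpp_maxpool2d_fwd(ins[[1]], at$k, at$stride, at$pad)$y,
      gap = {
        d <- dim(ins[[1]])
        matrix(rowMeans(matrix(ins[[1]], d[1] * d[2], d[3] * d[4])), d[1], d[2])
      },
      gmp = cpp_gmp_fwd(ins[[1]])$y,
      mul_channel = {
        d <- dim(ins[[1]])
        y <- matrix(ins[[1]], d[1] * d[2], d[3] * d[4]) * as.vector(ins[[2]])
        dim(y) <- d
        y
      },
      mul_spatial = {
        d <- dim(ins[[1]])
        gm <- matrix(ins[[2]], d[1], d[3] * d[4])[rep(seq_len(d[1]), d[2]), , drop = FALSE]
        y <- matrix(ins[[1]], d[1] * d[2], d[3] * d[4]) * gm
        dim(y) <- d
        y
      },
      slice_c = ins[[1]][, at$from:at$to, , , drop = FALSE],
      concat_c = {
        d1 <- dim(ins[[1]]); d2 <- dim(ins[[2]])
        y <- array(0, c(d1[1], d1[2] + d2[2], d1[3], d1[4]))
        y[, seq_len(d1[2]), , ] <- ins[[1]]
        y[, d1[2] + seq_len(d2[2]), , ] <- ins[[2]]
        y
      },
      linear = {
        y <- ins[[1]] %*% pr$w
        sweep(y, 2L, pr$b, "+")
      },
      stop("unsupported graph op during replay: ", nd$op))
  }
  vals[[g$output]]
}

#' Export/replay parity check
#'
#' Exports the model, evaluates `n` random input batches both natively and
#' through [run_exported()], and reports the maximum absolute logit
#' difference.
#'
#' @param model An `rtcb_model`.
#' @param dir Export directory.
#' @param n Number of random inputs (default 16).
#' @param input_size Spatial size of the random inputs (default the model's
#'   configured size).
#' @param seed Seed for the random inputs.
#' @return The maximum absolute difference across all inputs and classes.
#' @export
export_parity <- function(model, dir, n = 16L, input_size = NULL, seed = 1L) {
  if (is.null(input_size)) input_size <- model$spec$input_size
  if (length(input_size) == 1L) input_size <- rep(input_size, 2L)
  export_model(model, dir)
  x <- with_seed(seed,
    array(stats::rnorm(n * 3L * input_size[1] * input_size[2]),
          dim = c(n, 3L, input_size[1], input_size[2])))
  native <- ag_no_grad(ag_value(model$forward(x, training = FALSE)))
  replay <- run_exported(dir, x)
  max(abs(native - replay))
}
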