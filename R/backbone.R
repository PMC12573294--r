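# ResNet18 skeleton and its attention/PConv variants. The stem is a 7x7/2
# convolution + BN + ReLU (+ optional triplet attention) + 3x3/2 max pool;
# four stages of two basic blocks follow, then global average pooling and a
# linear head. CBAM sits after each block's second conv BN, before the
# residual addition; PConv replaces stride-1 3x3 convolutions with equal
# input/output channel counts.

conv_out_hw <- function(hw, k, stride, pad) {
  (hw + 2L * pad - k) %/% stride + 1L
}

layer_conv2d <- function(cin, cout, k, stride = 1L, pad = 0L, bias = FALSE) {
  ly <- new.env(parent = emptyenv())
  ly$kind <- "conv"
  ly$cin <- cin; ly$cout <- cout; ly$k <- k; ly$stride <- stride; ly$pad <- pad
  ly$params <- list(w = ag_param(he_kernel(cout, cin, k)))
  if (bias) ly$params$b <- ag_param(numeric(cout))
  ly$forward <- function(xt, training = FALSE)
    ag_conv2d(xt, ly$params$w, ly$params$b, stride = stride, pad = pad)
  class(ly) <- "rtcb_layer"
  ly
}

layer_bn2d <- function(channels) {
  ly <- new.env(parent = emptyenv())
  ly$kind <- "bn"
  ly$channels <- channels
  ly$params <- list(gamma = ag_param(rep(1, channels)),
                    beta = ag_param(numeric(channels)))
  ly$running_mean <- numeric(channels)
  ly$running_var <- rep(1, channels)
  ly$forward <- function(xt, training = FALSE)
    ag_bn2d(xt, ly$params$gamma, ly$params$beta, ly, training)
  class(ly) <- "rtcb_layer"
  ly
}

layer_linear <- function(fin, fout) {
  ly <- new.env(parent = emptyenv())
  ly$kind <- "linear"
  ly$fin <- fin; ly$fout <- fout
  ly$params <- list(w = ag_param(he_linear(fin, fout)),
                    b = ag_param(numeric(fout)))
  ly$forward <- function(xt, training = FALSE)
    ag_linear(xt, ly$params$w, ly$params$b)
  class(ly) <- "rtcb_layer"
  ly
}

# A stride-1 3x3 conv slot is replaceable by PConv only when cin == cout.
make_block_conv <- function(cin, cout, stride, use_pconv, pconv_divisor) {
  if (use_pconv && stride == 1L && cin == cout)
    pconv_layer(cout, c_p = max(1L, cout %/% pconv_divisor), kernel_size = 3L)
  else
    layer_conv2d(cin, cout, 3L, stride = stride, pad = 1L)
}

basic_block <- function(cin, cout, stride, use_cbam, use_pconv, cfg) {
  blk <- new.env(parent = emptyenv())
  blk$kind <- "basic_block"
  blk$conv1 <- make_block_conv(cin, cout, stride, use_pconv, cfg$pconv_divisor)
  blk$bn1 <- layer_bn2d(cout)
  blk$conv2 <- make_block_conv(cout, cout, 1L, use_pconv, cfg$pconv_divisor)
  blk$bn2 <- layer_bn2d(cout)
  blk$cbam <- if (use_cbam)
    cbam_block(cout, reduction = cfg$cbam_reduction, spatial_kernel = cfg$cbam_kernel)
  blk$downsample <- NULL
  if (stride != 1L || cin != cout) {
    blk$downsample <- list(conv = layer_conv2d(cin, cout, 1L, stride = stride, pad = 0L),
                           bn = layer_bn2d(cout))
  }
  blk$forward <- function(xt, training = FALSE) {
    out <- ag_relu(blk$bn1$forward(blk$conv1$forward(xt, training), training))
    out <- blk$bn2$forward(blk$conv2$forward(out, training), training)
    if (!is.null(blk$cbam)) out <- blk$cbam$forward(out, training)
    short <- if (is.null(blk$downsample)) xt
             else blk$downsample$bn$forward(blk$downsample$conv$forward(xt, training), training)
    ag_relu(ag_add(out, short))
  }
  blk
}

variant_flags <- function(name) {
  switch(name,
    resnet18              = c(triplet = FALSE, cbam = FALSE, pconv = FALSE),
    resnet18_triplet      = c(triplet = TRUE,  cbam = FALSE, pconv = FALSE),
    resnet18_cbam         = c(triplet = FALSE, cbam = TRUE,  pconv = FALSE),
    resnet18_cbam_pconv   = c(triplet = FALSE, cbam = TRUE,  pconv = TRUE),
    resnet18_cbam_triplet = c(triplet = TRUE,  cbam = TRUE,  pconv = FALSE),
    rtcb                  = c(triplet = TRUE,  cbam = TRUE,  pconv = TRUE),
    stop("unknown variant name: ", name))
}

#' Names of the ablation-grid variants
#'
#' @return Character vector of the six model variants, from the plain
#'   ResNet18 baseline to the full triplet + CBAM + PConv model.
#' @export
variant_names <- function() {
  c("resnet18", "resnet18_triplet", "resnet18_cbam",
    "resnet18_cbam_pconv", "resnet18_cbam_triplet", "rtcb")
}

#' Build a ResNet18 variant
#'
#' Assembles the standard ResNet18 skeleton and, depending on the variant,
#' inserts a triplet attention block after the stem activation (before the
#' max pool), a CBAM block after each basic block's second convolution's BN
#' (before the residual addition), and replaces stride-1 3x3 convolutions
#' that keep their channel count with partial convolutions at
#' `c_p = c / pconv_divisor`.
#'
#' @param name One of [variant_names()].
#' @param num_classes Number of output classes (default 5).
#' @param input_size `(height, width)` the complexity profile and export are
#'   computed at (default `c(224, 224)`); a single value is used for both
#'   dimensions. The forward pass itself accepts any spatial size >= 33.
#' @param class_names Optional character vector of class labels.
#' @param triplet_kernel,cbam_reduction,cbam_kernel,pconv_divisor Block
#'   hyperparameters; defaults 7, 16, 7 and 4 (the ratio under which PConv
#'   costs exactly 1/16 of the dense convolution).
#' @param pconv_scope `"all"` replaces every eligible stride-1 3x3 conv;
#'   `"single"` replaces only the one with the most parameters (the second
#'   convolution of the last stage-4 block).
#' @param seed Optional integer; when given, parameter initialization is
#'   reproducible (He-normal kernels, unit-gain BN, zero gate biases).
#' @return An object of class `rtcb_model`.
#' @export
build_variant <- function(name = "rtcb", num_classes = 5L,
                          input_size = c(224L, 224L), class_names = NULL,
                          triplet_kernel = 7L, cbam_reduction = 16L,
                          cbam_kernel = 7L, pconv_divisor = 4L,
                          pconv_scope = c("all", "single"), seed = NULL) {
  flags <- variant_flags(name)
  pconv_scope <- match.arg(pconv_scope)
  if (num_classes < 2L) stop("num_classes must be >= 2")
  if (length(input_size) == 1L) input_size <- rep(input_size, 2L)
  if (length(input_size) != 2L) stop("input_size must be a (height, width) pair")
  if (any(input_size < 33L)) stop("input_size must be at least 33 pixels")
  if (!is.null(class_names) && length(class_names) != num_classes)
    stop("class_names length must equal num_classes")
  cfg <- list(triplet_kernel = triplet_kernel, cbam_reduction = cbam_reduction,
              cbam_kernel = cbam_kernel, pconv_divisor = pconv_divisor)

  build <- function() {
    m <- new.env(parent = emptyenv())
    m$spec <- list(name = name, num_classes = as.integer(num_classes),
                   input_size = as.integer(input_size),
                   class_names = class_names,
                   triplet_kernel = as.integer(triplet_kernel),
                   cbam_reduction = as.integer(cbam_reduction),
                   cbam_kernel = as.integer(cbam_kernel),
                   pconv_divisor = as.integer(pconv_divisor),
                   pconv_scope = pconv_scope, seed = seed)
    m$stem <- list(conv = layer_conv2d(3L, 64L, 7L, stride = 2L, pad = 3L),
                   bn = layer_bn2d(64L))
    m$triplet <- if (flags[["triplet"]])
      triplet_attention_block(kernel_size = triplet_kernel)
    widths <- c(64L, 128L, 256L, 512L)
    use_pconv_all <- flags[["pconv"]] && pconv_scope == "all"
    m$stages <- lapply(seq_len(4L), function(s) {
      cin <- if (s == 1L) 64L else widths[s - 1L]
      stride1 <- if (s == 1L) 1L else 2L
      list(basic_block(cin, widths[s], stride1, flags[["cbam"]], use_pconv_all, cfg),
           basic_block(widths[s], widths[s], 1L, flags[["cbam"]], use_pconv_all, cfg))
    })
    if (flags[["pconv"]] && pconv_scope == "single") {
      # replace the most parameter-expensive eligible conv: conv2 of the
      # last stage-4 block (ties among equal-cost convs break to the deepest)
      blk <- m$stages[[4L]][[2L]]
      blk$conv2 <- pconv_layer(512L, c_p = max(1L, 512L %/% pconv_divisor),
                               kernel_size = 3L)
    }
    m$fc <- layer_linear(512L, as.integer(num_classes))
    m
  }
  m <- if (is.null(seed)) build() else with_seed(seed, build())

  m$forward <- function(x, training = FALSE) {
    xt <- as_ag(x)
    d <- dim4(xt$value)
    if (d[2] != 3L) stop("expected 3 input channels, got ", d[2])
    if (d[3] < 33L || d[4] < 33L) stop("spatial input must be at least 33 pixels")
    h <- ag_relu(m$stem$bn$forward(m$stem$conv$forward(xt, training), training))
    if (!is.null(m$triplet)) h <- m$triplet$forward(h, training)
    h <- ag_maxpool2d(h, 3L, 2L, 1L)
    for (st in m$stages) for (blk in st) h <- blk$forward(h, training)
    m$fc$forward(ag_gap(h), training)
  }

  m$params <- collect_params(m)
  m$bn_layers <- collect_bn(m)
  m$complexity_table <- build_complexity_table(m, input_size)
  class(m) <- "rtcb_model"
  m
}

# Named flat views of the model's learnable tensors and BN layers; names are
# stable across rebuilds of the same spec, which checkpointing relies on.
collect_params <- function(m) {
  out <- list()
  add <- function(prefix, obj) {
    if (is.null(obj)) return(invisible(NULL))
    for (nm in names(obj$params))
      out[[paste(prefix, nm, sep = ".")]] <<- obj$params[[nm]]
    invisible(NULL)
  }
  add("stem.conv", m$stem$conv); add("stem.bn", m$stem$bn)
  add("triplet", m$triplet)
  for (s in seq_along(m$stages)) for (b in 1:2) {
    blk <- m$stages[[s]][[b]]
    pre <- sprintf("layer%d.%d", s, b - 1L)
    add(paste0(pre, ".conv1"), blk$conv1); add(paste0(pre, ".bn1"), blk$bn1)
    add(paste0(pre, ".conv2"), blk$conv2); add(paste0(pre, ".bn2"), blk$bn2)
    add(paste0(pre, ".cbam"), blk$cbam)
    if (!is.null(blk$downsample)) {
      add(paste0(pre, ".downsample.conv"), blk$downsample$conv)
      add(paste0(pre, ".downsample.bn"), blk$downsample$bn)
    }
  }
  add("fc", m$fc)
  out
}

collect_bn <- function(m) {
  out <- list(stem.bn = m$stem$bn)
  for (s in seq_along(m$stages)) for (b in 1:2) {
    blk <- m$stages[[s]][[b]]
    pre <- sprintf("layer%d.%d", s, b - 1L)
    out[[paste0(pre, ".bn1")]] <- blk$bn1
    out[[paste0(pre, ".bn2")]] <- blk$bn2
    if (!is.null(blk$downsample))
      out[[paste0(pre, ".downsample.bn")]] <- blk$downsample$bn
  }
  out
}

conv_entry <- function(id, ly, h, w) {
  if (ly$kind == "conv") {
    hout <- conv_out_hw(h, ly$k, ly$stride, ly$pad)
    wout <- conv_out_hw(w, ly$k, ly$stride, ly$pad)
    np <- ly$cout * ly$cin * ly$k^2 + if (is.null(ly$params$b)) 0L else ly$cout
    list(row = data.frame(layer = id, kind = "conv", params = np,
                          flops = dense_conv_flops(hout, wout, ly$k, ly$cin, ly$cout)),
         h = hout, w = wout)
  } else { # pconv, stride 1, same padding
    np <- ly$c_p^2 * ly$kernel_size^2 +
      if (is.null(ly$params$b)) 0L else ly$c_p
    list(row = data.frame(layer = id, kind = "pconv", params = np,
                          flops = pconv_flops(h, w, ly$kernel_size, ly$c_p)),
         h = h, w = w)
  }
}

bn_entry <- function(id, ly) {
  data.frame(layer = id, kind = "bn", params = 2L * ly$channels, flops = 0)
}

build_complexity_table <- function(m, input_size) {
  rows <- list()
  push <- function(df) rows[[length(rows) + 1L]] <<- df
  h <- input_size[1]; w <- input_size[2]
  ce <- conv_entry("stem.conv", m$stem$conv, h, w)
  push(ce$row); push(bn_entry("stem.bn", m$stem$bn))
  h <- ce$h; w <- ce$w
  if (!is.null(m$triplet)) push(m$triplet$complexity(64L, h, w))
  h <- conv_out_hw(h, 3L, 2L, 1L); w <- conv_out_hw(w, 3L, 2L, 1L)
  push(data.frame(layer = "stem.maxpool", kind = "pool", params = 0L, flops = 0))
  for (s in seq_along(m$stages)) for (b in 1:2) {
    blk <- m$stages[[s]][[b]]
    pre <- sprintf("layer%d.%d", s, b - 1L)
    hin <- h; win <- w
    ce <- conv_entry(paste0(pre, ".conv1"), blk$conv1, h, w)
    push(ce$row); h <- ce$h; w <- ce$w
    push(bn_entry(paste0(pre, ".bn1"), blk$bn1))
    ce <- conv_entry(paste0(pre, ".conv2"), blk$conv2, h, w)
    push(ce$row); h <- ce$h; w <- ce$w
    push(bn_entry(paste0(pre, ".bn2"), blk$bn2))
    if (!is.null(blk$cbam)) {
      cb <- blk$cbam$complexity(blk$bn2$channels, h, w)
      cb$layer <- paste0(pre, ".", cb$layer)
      push(cb)
    }
    if (!is.null(blk$downsample)) {
      ce <- conv_entry(paste0(pre, ".downsample.conv"), blk$downsample$conv, hin, win)
      push(ce$row)
      push(bn_entry(paste0(pre, ".downsample.bn"), blk$downsample$bn))
    }
  }
  push(data.frame(layer = "gap", kind = "pool", params = 0L, flops = 0))
  push(data.frame(layer = "fc", kind = "linear",
                  params = m$fc$fin * m$fc$fout + m$fc$fout,
                  flops = as.numeric(m$fc$fin) * m$fc$fout))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.rtcb_model <- function(x, ...) {
  tot <- sum(x$complexity_table$params)
  cat(sprintf("<rtcb_model '%s': %d classes, %s params>\n",
              x$spec$name, x$spec$num_classes, format(tot, big.mark = ",")))
  invisible(x)
}

#' Count a model's attention and PConv placements
#'
#' Programmatic audit of where the variant's modules landed: the number of
#' triplet blocks, CBAM blocks and PConv layers in the assembled model.
#'
#' @param model An `rtcb_model`.
#' @return Named integer vector with entries `triplet`, `cbam`, `pconv`.
#' @export
placement_counts <- function(model) {
  stopifnot(inherits(model, "rtcb_model"))
  n_cbam <- 0L; n_pconv <- 0L
  for (st in model$stages) for (blk in st) {
    if (!is.null(blk$cbam)) n_cbam <- n_cbam + 1L
    if (identical(blk$conv1$kind, "pconv")) n_pconv <- n_pconv + 1L
    if (identical(blk$conv2$kind, "pconv")) n_pconv <- n_pconv + 1L
  }
  c(triplet = if (is.null(model$triplet)) 0L else 1L,
    cbam = n_cbam, pconv = n_pconv)
}

#' Class probabilities and labels for a batch of images
#'
#' Runs the model in evaluation mode (batch-norm running statistics) and
#' applies a softmax over the logits. Ties in the argmax break to the
#' lowest class index.
#'
#' @param model An `rtcb_model`.
#' @param x A 4-D array `(N, 3, H, W)` of preprocessed (normalized) images.
#' @return A list with `prob` (`N x K` matrix, rows summing to 1) and
#'   `label` (integer vector of 1-based class indices; a `class` character
#'   vector is added when the model carries class names).
#' @export
predict_classes <- function(model, x) {
  stopifnot(inherits(model, "rtcb_model"))
  logits <- ag_no_grad(ag_value(model$forward(x, training = FALSE)))
  prob <- softmax_rows(logits)
  lab <- apply(prob, 1L, which.max)
  out <- list(prob = prob, label = as.integer(lab))
  if (!is.null(model$spec$class_names)) {
    colnames(out$prob) <- model$spec$class_names
    out$class <- model$spec$class_names[out$label]
  }
  out
}

# ---- checkpointing ---------------------------------------------------------

#' Save / load a model checkpoint
#'
#' `save_checkpoint()` writes the variant spec, every learnable tensor and
#' the batch-norm running statistics to `path` (RDS), plus a human-readable
#' JSON sidecar (`<path>.json`) carrying the model's `spec` field and
#' metadata. Reloading
#' rebuilds the variant and restores the state, reproducing forward outputs
#' bit-for-bit on the saving platform.
#'
#' @param model An `rtcb_model`.
#' @param path Checkpoint file path.
#' @param meta Optional named list stored alongside (epoch, seed record, ...).
#' @return `save_checkpoint()` returns `path` invisibly; `load_checkpoint()`
#'   returns the restored model.
#' @export
save_checkpoint <- function(model, path, meta = list()) {
  stopifnot(inherits(model, "rtcb_model"))
  state <- lapply(model$params, function(p) p$value)
  bn <- lapply(model$bn_layers, function(l)
    list(mean = l$running_mean, var = l$running_var))
  saveRDS(list(spec = model$spec, state = state, bn = bn, meta = meta), path)
  jsonlite::write_json(list(spec = model$spec, meta = meta),
                       paste0(path, ".json"), auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  sp <- ck$spec
  m <- build_variant(sp$name, num_classes = sp$num_classes,
                     input_size = sp$input_size, class_names = sp$class_names,
                     triplet_kernel = sp$triplet_kernel,
                     cbam_reduction = sp$cbam_reduction,
                     cbam_kernel = sp$cbam_kernel,
                     pconv_divisor = sp$pconv_divisor,
                     pconv_scope = sp$pconv_scope)
  restore_state(m, ck$state, ck$bn)
  m$meta <- ck$meta
  if (!is.null(ck$meta$norm_stats)) m$norm_stats <- ck$meta$norm_stats
  m
}

restore_state <- function(model, state, bn) {
  if (!setequal(names(state), names(model$params)))
    stop("checkpoint state does not match the rebuilt architecture")
  for (nm in names(state)) model$params[[nm]]$value <- state[[nm]]
  for (nm in names(bn)) {
    model$bn_layers[[nm]]$running_mean <- bn[[nm]]$mean
    model$bn_layers[[nm]]$running_var <- bn[[nm]]$var
  }
  invisible(model)
}

model_state <- function(model) {
  list(state = lapply(model$params, function(p) p$value),
       bn = lapply(model$bn_layers, function(l)
         list(mean = l$running_mean, var = l$running_var)))
}
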