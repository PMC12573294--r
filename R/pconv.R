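# Partial convolution: a dense k x k convolution over the first c_p of c
# channels with the remaining channels passed through untouched, plus the
# exact multiply-accumulate bookkeeping that motivates it.

#' Construct a partial convolution layer
#'
#' Convolves the first `c_p` channels densely (`c_p -> c_p`, stride 1,
#' same-padding) and passes channels `c_p + 1 .. c` through bit-identically,
#' so input and output channel counts are equal. At the default ratio
#' `c_p = c / 4` the layer costs exactly 1/16 of the dense convolution it
#' replaces.
#'
#' @param channels Total channel count `c`.
#' @param c_p Number of leading channels convolved; default `max(1, c / 4)`.
#' @param kernel_size Odd kernel size (default 3).
#' @param bias Add a bias on the convolved slice? Default `FALSE`, matching
#'   convolution-before-batch-norm usage.
#' @return A layer environment with `params`, `forward(x, training)` and
#'   metadata used by [profile_model()].
#' @export
pconv_layer <- function(channels, c_p = NULL, kernel_size = 3L, bias = FALSE) {
  k <- check_odd_kernel(kernel_size, "kernel_size")
  channels <- as.integer(channels)
  if (is.null(c_p)) c_p <- max(1L, channels %/% 4L)
  c_p <- as.integer(c_p)
  if (c_p < 1L || c_p > channels)
    stop("c_p must satisfy 1 <= c_p <= channels")
  pad <- (k - 1L) %/% 2L
  ly <- new.env(parent = emptyenv())
  ly$kind <- "pconv"
  ly$channels <- channels
  ly$c_p <- c_p
  ly$kernel_size <- k
  ly$pad <- pad
  ly$params <- list(w = ag_param(he_kernel(c_p, c_p, k)))
  if (bias) ly$params$b <- ag_param(numeric(c_p))
  ly$forward <- function(xt, training = FALSE) {
    ag_pconv(xt, ly$params$w, ly$params$b, c_p = c_p, pad = pad)
  }
  class(ly) <- "rtcb_layer"
  ly
}

#' Apply a partial convolution to a feature map
#'
#' @param x A 4-D numeric array `(N, C, H, W)`; `C` must equal the layer's
#'   channel count.
#' @param layer A layer from [pconv_layer()].
#' @return An array of the same shape; channels beyond `c_p` are returned
#'   exactly as given.
#' @export
partial_conv <- function(x, layer) {
  stopifnot(identical(layer$kind, "pconv"))
  d <- dim4(x)
  if (d[2] != layer$channels)
    stop("layer expects ", layer$channels, " channels, got ", d[2])
  ag_value(layer$forward(as_ag(x)))
}

#' Multiply-accumulate count of a partial convolution
#'
#' The forward cost of a PConv layer over an `h x w` output map with kernel
#' size `k` acting on `c_p` channels is `h * w * k^2 * c_p^2`
#' multiply-accumulates. At `c_p = c / 4` this is 1/16 of the dense cost
#' `h * w * k^2 * c^2`.
#'
#' @param h,w Output spatial dimensions.
#' @param k Kernel size.
#' @param c_p Number of convolved channels.
#' @return The exact count, as a double to avoid integer overflow.
#' @export
pconv_flops <- function(h, w, k, c_p) {
  args <- c(h = h, w = w, k = k, c_p = c_p)
  if (any(args < 1) || any(args != floor(args)))
    stop("all arguments must be positive integers")
  as.numeric(h) * w * k^2 * c_p^2
}

dense_conv_flops <- function(h, w, k, c_in, c_out) {
  as.numeric(h) * w * k^2 * c_in * c_out
}

#' Profile a model's parameters and FLOPs
#'
#' Walks the model layer by layer and reports exact parameter counts and
#' forward multiply-accumulate (MAC) counts: dense convolutions cost
#' `h_out * w_out * k^2 * c_in * c_out`, partial convolutions cost
#' [pconv_flops()] exactly, linear layers cost `in * out`; batch-norm and
#' pooling layers contribute parameters (affine pairs) but zero MACs under
#' this convention. Profiling is a pure function of the architecture.
#'
#' @param model A model from [build_variant()].
#' @return An object of class `complexity_report`: a list with `per_layer`
#'   (data.frame of layer, kind, params, flops) and `totals`.
#' @export
profile_model <- function(model) {
  stopifnot(inherits(model, "rtcb_model"))
  per <- model$complexity_table
  known <- c("conv", "pconv", "bn", "linear", "pool")
  bad <- setdiff(unique(per$kind), known)
  if (length(bad))
    stop("unsupported layer kind in profile: ", paste(bad, collapse = ", "))
  rep <- list(per_layer = per,
              totals = list(params = sum(per$params), flops = sum(per$flops)))
  class(rep) <- "complexity_report"
  rep
}

#' @export
print.complexity_report <- function(x, ...) {
  cat("Complexity report:", nrow(x$per_layer), "layers\n")
  cat(sprintf("  total params: %s\n  total MACs:   %s\n",
              format(x$totals$params, big.mark = ","),
              format(x$totals$flops, big.mark = ",")))
  invisible(x)
}

#' Serialize a complexity report to JSON
#'
#' @param report A `complexity_report` from [profile_model()].
#' @param path Output file path.
#' @export
write_complexity_json <- function(report, path) {
  stopifnot(inherits(report, "complexity_report"))
  jsonlite::write_json(
    list(per_layer = report$per_layer, totals = report$totals),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
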