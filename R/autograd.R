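#' @useDynLib rtcbnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- minimal reverse-mode tape over R arrays -------------------------------
#
# A tensor is an environment carrying a value, an optional gradient, and --
# when it was produced by a recorded op -- its parents plus a closure that
# maps the incoming gradient to per-parent gradients. Recording is skipped
# whenever no input requires a gradient, so the same code path serves
# training and inference.

ag_tensor <- function(value, requires_grad = FALSE, name = NULL) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$requires_grad <- requires_grad
  e$parents <- NULL
  e$backward_fn <- NULL
  e$name <- name
  class(e) <- "ag_tensor"
  e
}

is_ag_tensor <- function(x) inherits(x, "ag_tensor")

# Global tape switch: while disabled, ag_op records nothing, so pure
# inference passes skip all backward bookkeeping and caching.
.ag_state <- new.env(parent = emptyenv())
.ag_state$enabled <- TRUE

ag_grad_enabled <- function() .ag_state$enabled

# Runs expr with gradient recording off, restoring the previous state.
ag_no_grad <- function(expr) {
  old <- .ag_state$enabled
  .ag_state$enabled <- FALSE
  on.exit(.ag_state$enabled <- old)
  expr
}

# Wrap plain arrays as constant tensors.
as_ag <- function(x) if (is_ag_tensor(x)) x else ag_tensor(x)

ag_value <- function(x) x$value

ag_op <- function(value, parents, backward_fn) {
  rg <- FALSE
  if (.ag_state$enabled)
    for (p in parents) if (p$requires_grad) { rg <- TRUE; break }
  t <- ag_tensor(value, requires_grad = rg)
  if (rg) {
    t$parents <- parents
    t$backward_fn <- backward_fn
  }
  t
}

# Reverse-mode sweep from a scalar (or explicitly seeded) root. Gradients
# accumulate on every tensor with requires_grad = TRUE reachable from root.
ag_backward <- function(root, grad = NULL) {
  if (is.null(grad)) {
    if (length(root$value) != 1L)
      stop("backward() on a non-scalar tensor needs an explicit seed gradient")
    grad <- 1
  }
  topo <- vector("list", 256L)
  ntopo <- 0L
  visit <- function(node) {
    if (isTRUE(node$.visited)) return(invisible(NULL))
    node$.visited <- TRUE
    for (p in node$parents) if (p$requires_grad) visit(p)
    ntopo <<- ntopo + 1L
    if (ntopo > length(topo)) length(topo) <<- 2L * ntopo
    topo[[ntopo]] <<- node
    invisible(NULL)
  }
  visit(root)
  root$grad <- if (is.null(root$grad)) grad else root$grad + grad
  for (i in seq(ntopo, 1L)) {
    node <- topo[[i]]
    node$.visited <- NULL
    if (is.null(node$backward_fn) || is.null(node$grad)) next
    gs <- node$backward_fn(node$grad)
    ps <- node$parents
    for (j in seq_along(ps)) {
      if (is.null(gs[[j]]) || !ps[[j]]$requires_grad) next
      p <- ps[[j]]
      p$grad <- if (is.null(p$grad)) gs[[j]] else p$grad + gs[[j]]
    }
    # free intermediate gradient storage early
    if (!is.null(node$backward_fn)) node$grad <- NULL
  }
  invisible(root)
}

ag_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# ---- parameter construction ------------------------------------------------

#' @noRd
ag_param <- function(value, name = NULL) ag_tensor(value, requires_grad = TRUE, name = name)

# He-normal fan-in initialization for a (Cout, Cin, k, k) kernel.
he_kernel <- function(cout, cin, k) {
  sd <- sqrt(2 / (cin * k * k))
  array(stats::rnorm(cout * cin * k * k, sd = sd), dim = c(cout, cin, k, k))
}

he_linear <- function(fin, fout) {
  matrix(stats::rnorm(fin * fout, sd = sqrt(2 / fin)), fin, fout)
}
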