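# Confusion tables, the five per-class one-vs-rest metrics, model deltas,
# and Pearson metric-correlation matrices.

#' Build a confusion table
#'
#' @param preds,labels Equal-length integer vectors of 1-based class codes.
#' @param classes Character vector of class names (defines K).
#' @return A `confusion_table`: K x K integer matrix, rows = true class,
#'   columns = predicted class.
#' @export
confusion <- function(preds, labels, classes = leaf_classes()) {
  K <- length(classes)
  if (length(preds) != length(labels)) stop("preds and labels differ in length")
  if (any(preds < 1L | preds > K) || any(labels < 1L | labels > K))
    stop("class codes must lie in 1..K")
  ct <- table(factor(labels, levels = seq_len(K)),
              factor(preds, levels = seq_len(K)))
  m <- matrix(as.integer(ct), K, K, dimnames = list(true = classes, pred = classes))
  class(m) <- c("confusion_table", class(m))
  m
}

#' Confusion table from per-class correct/total counts
#'
#' Reconstructs the diagonal and a single off-diagonal residual per row from
#' published per-class totals and correct counts (the misclassified
#' destination is unknown, so errors are pooled into an arbitrary other
#' column; all trace-based quantities are exact).
#'
#' @param total,correct Integer vectors, one entry per class.
#' @param classes Class names.
#' @return A `confusion_table`.
#' @export
confusion_from_counts <- function(total, correct, classes = leaf_classes()) {
  K <- length(classes)
  stopifnot(length(total) == K, length(correct) == K, all(correct <= total))
  m <- matrix(0L, K, K, dimnames = list(true = classes, pred = classes))
  diag(m) <- as.integer(correct)
  for (i in seq_len(K)) {
    j <- if (i == K) 1L else i + 1L
    m[i, j] <- m[i, j] + as.integer(total[i] - correct[i])
  }
  class(m) <- c("confusion_table", class(m))
  m
}

#' Overall accuracy of a confusion table
#'
#' @param ct A `confusion_table`.
#' @return `trace / grand total`, a fraction in [0,1].
#' @export
overall_accuracy <- function(ct) {
  tot <- sum(ct)
  if (tot == 0) stop("empty confusion table")
  sum(diag(unclass(ct))) / tot
}

#' Per-class one-vs-rest metrics
#'
#' For every class computes TP/FP/FN/TN against the rest and reports
#' precision `TP/(TP+FP)`, sensitivity (recall) `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, F1 `2PR/(P+R)` and per-class accuracy `(TP+TN)/total`.
#' Undefined ratios (zero denominators, e.g. a never-predicted class's
#' precision) are returned as `NaN` and flagged, never silently zeroed;
#' macro averages exclude them with a warning.
#'
#' @param ct A `confusion_table` with K >= 2 classes.
#' @return A data.frame with one row per class plus attributes
#'   `overall_accuracy` and `macro` (named vector of macro-averaged metrics).
#' @export
per_class_metrics <- function(ct) {
  K <- nrow(ct)
  if (K < 2L) stop("need at least 2 classes")
  m <- unclass(ct)
  tot <- sum(m)
  ratio <- function(num, den) ifelse(den > 0, num / den, NaN)
  rows <- lapply(seq_len(K), function(i) {
    tp <- m[i, i]
    fp <- sum(m[-i, i])
    fn <- sum(m[i, -i])
    tn <- tot - tp - fp - fn
    p <- ratio(tp, tp + fp)
    r <- ratio(tp, tp + fn)
    data.frame(class = rownames(m)[i],
               precision = p,
               sensitivity = r,
               specificity = ratio(tn, tn + fp),
               f1 = ratio(2 * p * r, p + r),
               accuracy = (tp + tn) / tot)
  })
  df <- do.call(rbind, rows)
  metric_cols <- c("precision", "sensitivity", "specificity", "f1", "accuracy")
  if (anyNA(df[metric_cols]))
    warning("undefined metric(s) flagged NaN; excluded from macro averages")
  attr(df, "overall_accuracy") <- overall_accuracy(ct)
  attr(df, "macro") <- vapply(df[metric_cols], mean, numeric(1), na.rm = TRUE)
  df
}

#' Accuracy difference in percentage points
#'
#' @param a,b Accuracies as fractions in [0,1].
#' @return `(a - b) * 100`, half-up rounded to 2 decimals.
#' @export
accuracy_delta <- function(a, b) {
  if (any(c(a, b) < 0) || any(c(a, b) > 1)) stop("accuracies must lie in [0,1]")
  round_half_up((a - b) * 100, 2L)
}

#' Pearson correlation matrix of a models-by-metrics table
#'
#' @param x Numeric matrix with >= 2 rows (models) and >= 2 columns
#'   (metrics). Zero-variance columns give flagged `NA` entries (with a
#'   warning), never silent values.
#' @return Symmetric correlation matrix with unit diagonal, entries in
#'   [-1, 1].
#' @export
metric_correlation <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L || ncol(x) < 2L) stop("need at least 2 rows and 2 columns")
  v <- apply(x, 2L, stats::var)
  if (any(v == 0))
    warning("zero-variance column(s): ",
            paste(colnames(x)[v == 0], collapse = ", "),
            "; correlations flagged NA")
  r <- suppressWarnings(stats::cor(x))
  diag(r) <- 1
  r
}

#' Write evaluation reports
#'
#' Writes `confusion.csv` (full table), `counts.csv` (per-class Tot / Cor /
#' Inc), `metrics.csv`, and `correlation.csv` when a metric matrix is
#' given; optional radar and heatmap PNGs.
#'
#' @param ct A `confusion_table`.
#' @param metrics Output of [per_class_metrics()] (computed from `ct` when
#'   `NULL`).
#' @param out_dir Output directory (created if missing).
#' @param metric_matrix Optional models x metrics matrix for
#'   [metric_correlation()].
#' @param plots Also write `radar.png` / `heatmap.png`?
#' @return Invisible character vector of the files written.
#' @export
write_report <- function(ct, metrics = NULL, out_dir, metric_matrix = NULL,
                         plots = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(metrics)) metrics <- per_class_metrics(ct)
  files <- character()
  w <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
  }
  m <- unclass(ct)
  w(cbind(class = rownames(m), as.data.frame(m)), "confusion.csv")
  w(data.frame(class = rownames(m), tot = rowSums(m), cor = diag(m),
               inc = rowSums(m) - diag(m)), "counts.csv")
  w(metrics, "metrics.csv")
  corr <- NULL
  if (!is.null(metric_matrix)) {
    corr <- metric_correlation(metric_matrix)
    w(cbind(metric = rownames(corr), as.data.frame(corr)), "correlation.csv")
  }
  if (plots) {
    p <- file.path(out_dir, "radar.png")
    grDevices::png(p, 600, 600)
    radar_plot(metrics)
    grDevices::dev.off()
    files <- c(files, p)
    if (!is.null(corr)) {
      p <- file.path(out_dir, "heatmap.png")
      grDevices::png(p, 600, 600)
      corr_heatmap(corr)
      grDevices::dev.off()
      files <- c(files, p)
    }
  }
  invisible(files)
}

radar_plot <- function(metrics) {
  cols <- c("precision", "sensitivity", "specificity", "f1", "accuracy")
  k <- length(cols)
  ang <- seq(0, 2 * pi, length.out = k + 1L)[-(k + 1L)]
  graphics::plot(NA, xlim = c(-1.2, 1.2), ylim = c(-1.2, 1.2), asp = 1,
                 axes = FALSE, xlab = "", ylab = "", main = "Per-class metrics")
  for (r in c(0.5, 1)) graphics::polygon(r * cos(ang), r * sin(ang), border = "gray")
  graphics::text(1.12 * cos(ang), 1.12 * sin(ang), cols, cex = 0.8)
  for (i in seq_len(nrow(metrics))) {
    v <- as.numeric(metrics[i, cols])
    v[!is.finite(v)] <- 0
    graphics::polygon(v * cos(ang), v * sin(ang), border = i + 1L)
  }
  graphics::legend("topleft", legend = metrics$class, col = seq_len(nrow(metrics)) + 1L,
                   lty = 1, cex = 0.7, bty = "n")
}

corr_heatmap <- function(corr) {
  k <- ncol(corr)
  pal <- grDevices::hcl.colors(51, "Blue-Red 3")
  graphics::image(seq_len(k), seq_len(k), t(corr[k:1, , drop = FALSE]),
                  zlim = c(-1, 1), col = pal, axes = FALSE, xlab = "", ylab = "",
                  main = "Metric correlation")
  graphics::axis(1, seq_len(k), colnames(corr), las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_len(k), rev(rownames(corr)), las = 2, cex.axis = 0.7)
}
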