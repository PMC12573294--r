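# Confusion tables, per-class metrics, deltas, and correlation matrices,
# including invariants on randomly generated tables.

rand_ct <- function(k = 5L) {
  m <- matrix(rpois(k * k, 3), k, k) + diag(sample(5:60, k, replace = TRUE))
  cls <- paste0("c", seq_len(k))
  dimnames(m) <- list(true = cls, pred = cls)
  storage.mode(m) <- "integer"
  class(m) <- c("confusion_table", class(m))
  m
}

test_that("confusion tabulates predictions against labels", {
  labels <- c(1L, 1L, 2L, 3L, 3L, 3L)
  preds  <- c(1L, 2L, 2L, 3L, 3L, 1L)
  ct <- confusion(preds, labels, classes = c("a", "b", "c"))
  expect_equal(unclass(ct),
               matrix(c(1L, 0L, 1L, 1L, 1L, 0L, 0L, 0L, 2L), 3, 3,
                      dimnames = list(true = c("a", "b", "c"),
                                      pred = c("a", "b", "c"))),
               ignore_attr = "class")
  expect_equal(sum(ct), 6)
  expect_error(confusion(c(1L, 4L), c(1L, 1L), classes = c("a", "b", "c")),
               "1\\.\\.K")
  expect_error(confusion(1L, c(1L, 2L), classes = c("a", "b")), "length")
})

test_that("confusion_from_counts preserves totals, trace and row sums", {
  total <- c(392L, 375L, 325L, 358L, 369L)
  correct <- c(390L, 373L, 318L, 350L, 368L)
  ct <- confusion_from_counts(total, correct)
  expect_equal(unname(rowSums(ct)), as.numeric(total))
  expect_equal(unname(diag(unclass(ct))), as.numeric(correct))
  expect_equal(overall_accuracy(ct), sum(correct) / sum(total))
  expect_error(confusion_from_counts(c(5L, 5L), c(6L, 5L), classes = c("a", "b")))
})

test_that("per_class_metrics matches a hand-computed 3-class example", {
  m <- matrix(c(50L, 2L, 3L,
                4L, 40L, 1L,
                0L, 5L, 45L), 3, 3, byrow = TRUE,
              dimnames = list(true = c("a", "b", "c"), pred = c("a", "b", "c")))
  class(m) <- c("confusion_table", class(m))
  df <- per_class_metrics(m)
  # class "a": tp=50, fp=4, fn=5, tn=91
  expect_equal(df$precision[1], 50 / 54)
  expect_equal(df$sensitivity[1], 50 / 55)
  expect_equal(df$specificity[1], 91 / 95)
  p <- 50 / 54; r <- 50 / 55
  expect_equal(df$f1[1], 2 * p * r / (p + r))
  expect_equal(df$accuracy[1], 141 / 150)
  expect_equal(attr(df, "overall_accuracy"), 135 / 150)
  expect_equal(unname(attr(df, "macro")["precision"]),
               mean(df$precision))
})

test_that("metric invariants hold on random confusion tables", {
  set.seed(901)
  for (rep in 1:20) {
    ct <- rand_ct(sample(3:6, 1))
    df <- per_class_metrics(ct)
    vals <- unlist(df[c("precision", "sensitivity", "specificity", "f1",
                        "accuracy")])
    expect_true(all(is.nan(vals) | (vals >= 0 & vals <= 1)))
    acc <- overall_accuracy(ct)
    expect_true(acc >= 0 && acc <= 1)
    # per-class accuracy never falls below the overall-error complement
    expect_true(all(df$accuracy >= acc - 1e-12))
    # sensitivity agrees with diag/rowSums wherever defined
    rs <- rowSums(unclass(ct))
    ok <- rs > 0
    expect_equal(df$sensitivity[ok], unname((diag(unclass(ct)) / rs)[ok]))
  }
})

test_that("undefined ratios surface as NaN with a warning, never as zero", {
  m <- matrix(c(5L, 0L, 0L,
                3L, 0L, 0L,
                2L, 0L, 0L), 3, 3, byrow = TRUE,
              dimnames = list(true = c("a", "b", "c"), pred = c("a", "b", "c")))
  class(m) <- c("confusion_table", class(m))
  expect_warning(df <- per_class_metrics(m), "NaN")
  # classes b and c are never predicted: precision undefined
  expect_true(is.nan(df$precision[2]) && is.nan(df$precision[3]))
  expect_false(any(df$precision == 0, na.rm = TRUE))
  macro <- attr(df, "macro")
  expect_true(all(is.finite(macro)))
})

test_that("accuracy_delta reports half-up-rounded percentage points", {
  expect_equal(accuracy_delta(0.989, 0.9769), 1.21)
  expect_equal(accuracy_delta(0.5, 0.5), 0)
  expect_equal(rt("round_half_up")(0.125, 2L), 0.13) # half rounds up, not to even
  expect_equal(rt("round_half_up")(-0.125, 2L), -0.13)
  expect_equal(accuracy_delta(0.4, 0.5), -10)
  expect_error(accuracy_delta(1.2, 0.5), "\\[0,1\\]")
})

test_that("metric_correlation is symmetric, unit-diagonal and bounded", {
  set.seed(902)
  x <- matrix(rnorm(6 * 4), 6, 4,
              dimnames = list(NULL, c("p", "r", "s", "f")))
  r <- metric_correlation(x)
  expect_equal(r, t(r))
  expect_equal(unname(diag(r)), rep(1, 4))
  expect_true(all(abs(r) <= 1 + 1e-12))
  expect_equal(r["p", "r"], cor(x[, "p"], x[, "r"]))
  # a perfectly collinear pair correlates to exactly +/- 1
  y <- cbind(a = 1:5, b = 2 * (1:5), c = -(1:5) + 0.5)
  ry <- metric_correlation(y)
  expect_equal(ry["a", "b"], 1)
  expect_equal(ry["a", "c"], -1)
  expect_error(metric_correlation(x[1, , drop = FALSE]), "at least 2")
})

test_that("zero-variance columns are flagged NA with a warning", {
  x <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  expect_warning(r <- metric_correlation(x), "zero-variance")
  expect_true(is.na(r["a", "b"]))
  expect_equal(r["a", "a"], 1) # diagonal stays defined
})

test_that("write_report emits the CSV set and optional plots", {
  set.seed(903)
  ct <- rand_ct(4L)
  out <- file.path(tempdir(), "report_out")
  mm <- matrix(rnorm(12), 4, 3, dimnames = list(NULL, c("x", "y", "z")))
  files <- write_report(ct, out_dir = out, metric_matrix = mm, plots = TRUE)
  expect_true(all(file.exists(file.path(
    out, c("confusion.csv", "counts.csv", "metrics.csv", "correlation.csv",
           "radar.png", "heatmap.png")))))
  counts <- read.csv(file.path(out, "counts.csv"))
  expect_equal(counts$tot, unname(rowSums(unclass(ct))))
  expect_equal(counts$cor + counts$inc, counts$tot)
  conf <- read.csv(file.path(out, "confusion.csv"))
  expect_equal(as.matrix(conf[, -1]), unclass(ct), ignore_attr = TRUE)
  unlink(out, recursive = TRUE)
})
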