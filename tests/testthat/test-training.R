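# The cosine schedule, the SGD update rule, and a miniature end-to-end
# training run.

test_that("cosine annealing hits its endpoints and midpoint exactly", {
  expect_equal(cosine_lr(0, 100, 0.02, 1e-5), 0.02)
  expect_equal(cosine_lr(100, 100, 0.02, 1e-5), 1e-5)
  expect_equal(cosine_lr(50, 100, 0.02, 1e-5), (0.02 + 1e-5) / 2)
  # monotone decreasing over the whole horizon
  lrs <- cosine_lr(0:100, 100)
  expect_true(all(diff(lrs) < 0))
  expect_error(cosine_lr(-1, 100), "\\[0, T_max\\]")
  expect_error(cosine_lr(101, 100), "\\[0, T_max\\]")
  expect_error(cosine_lr(5, 100, lr_max = 1e-5, lr_min = 0.02), "smaller")
})

test_that("schedule_lr starts at lr_max and follows the configured schedule", {
  sch <- rt("schedule_lr")
  cfg <- train_config(epochs = 10L, augment = NULL)
  expect_equal(sch(cfg, 1L), cfg$lr_max)
  expect_equal(sch(cfg, 6L), cosine_lr(5, 10, cfg$lr_max, cfg$lr_min))
  fixed <- train_config(epochs = 10L, schedule = "fixed", augment = NULL)
  expect_equal(sch(fixed, 7L), fixed$lr_max)
})

test_that("train_config validates its arguments", {
  expect_error(train_config(epochs = 0L), ">= 1")
  expect_error(train_config(lr_max = 1e-5, lr_min = 0.02), "smaller")
  expect_error(train_config(schedule = "step"))
})

test_that("sgd_step applies momentum and decays matrix weights only", {
  step <- rt("sgd_step")
  param <- rt("ag_param")
  w0 <- matrix(c(1, -2, 3, 0.5), 2, 2)
  b0 <- c(0.2, -0.1)
  model <- list(params = list(
    w = param(w0, name = "w"),
    b = param(b0, name = "b")))
  model$params$w$grad <- matrix(0.1, 2, 2)
  model$params$b$grad <- c(0.3, -0.3)
  opt <- new.env(parent = emptyenv())
  lr <- 0.1; wd <- 0.01; mom <- 0.9

  step(model, opt, lr, wd, mom)
  gw1 <- matrix(0.1, 2, 2) + wd * w0        # decay hits the matrix weight
  gb1 <- c(0.3, -0.3)                        # but not the 1-d bias
  vw1 <- -lr * gw1; vb1 <- -lr * gb1
  expect_equal(model$params$w$value, w0 + vw1)
  expect_equal(model$params$b$value, b0 + vb1)
  expect_null(model$params$w$grad)

  model$params$w$grad <- matrix(0.2, 2, 2)
  model$params$b$grad <- c(0.1, 0.1)
  step(model, opt, lr, wd, mom)
  gw2 <- matrix(0.2, 2, 2) + wd * (w0 + vw1)
  vw2 <- mom * vw1 - lr * gw2
  vb2 <- mom * vb1 - lr * c(0.1, 0.1)
  expect_equal(model$params$w$value, w0 + vw1 + vw2)
  expect_equal(model$params$b$value, b0 + vb1 + vb2)
  # a parameter with no grad is untouched
  expect_identical(opt$w, vw2)
})

test_that("a miniature training run lowers the loss and is seed-deterministic", {
  dir <- tiny_dataset33()
  man <- stratified_split(read_manifest(file.path(dir, "manifest.csv")),
                          seed = 7L)
  m1 <- build_variant("rtcb", num_classes = 5L, input_size = c(33L, 33L),
                      seed = 8L)
  cfg <- train_config(epochs = 2L, batch_size = 8L, augment = NULL, seed = 9L)
  r1 <- train_model(m1, man, dir, cfg, verbose = FALSE)
  expect_named(r1$history,
               c("epoch", "lr", "train_loss", "train_accuracy",
                 "val_loss", "val_accuracy"))
  expect_equal(nrow(r1$history), 2L)
  expect_lt(r1$history$train_loss[2], r1$history$train_loss[1])
  expect_true(all(is.finite(unlist(r1$history[-1]))))
  expect_true(r1$best$val_accuracy >= 0 && r1$best$val_accuracy <= 1)

  m2 <- build_variant("rtcb", num_classes = 5L, input_size = c(33L, 33L),
                      seed = 8L)
  r2 <- train_model(m2, man, dir, cfg, verbose = FALSE)
  expect_equal(r1$history, r2$history, tolerance = 1e-12)
})

test_that("train_model writes a loadable checkpoint of the best epoch", {
  dir <- tiny_dataset33()
  man <- stratified_split(read_manifest(file.path(dir, "manifest.csv")),
                          seed = 7L)
  m <- build_variant("resnet18", num_classes = 5L, input_size = c(33L, 33L),
                     seed = 8L)
  ck <- tempfile(fileext = ".rds")
  cfg <- train_config(epochs = 1L, batch_size = 8L, augment = NULL, seed = 9L)
  r <- train_model(m, man, dir, cfg, checkpoint_path = ck, verbose = FALSE)
  expect_true(file.exists(ck))
  m2 <- load_checkpoint(ck)
  expect_length(m2$norm_stats$mean, 3L)
  expect_equal(m2$norm_stats, r$model$norm_stats)
  file.remove(ck)
})
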