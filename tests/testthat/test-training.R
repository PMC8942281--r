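# Training: loss closed forms, optimization, early stopping, fine-tuning,
# whole-trip window-mean prediction.

test_that("weighted BCE matches its closed forms and reductions", {
  expect_equal(weighted_bce(0.5, 1, 30), 30 * log(2), tolerance = 1e-12)
  expect_equal(weighted_bce(0.5, 0, 30), log(2), tolerance = 1e-12)
  expect_equal(weighted_bce(0.5, 0, 1), log(2), tolerance = 1e-12)
  # perfect hard predictions: loss at the clipping floor
  expect_lt(weighted_bce(c(1, 0), c(1, 0), 30), 1e-5)
  # w = 1 reduces to the unweighted binary cross-entropy
  set.seed(1)
  p <- runif(50); y <- rbinom(50, 1, 0.5)
  expect_equal(weighted_bce(p, y, 1),
               mean(-(y * log(p) + (1 - y) * log(1 - p))), tolerance = 1e-12)
  expect_error(weighted_bce(c(0.5, 0.5), 1), "same shape")
})

test_that("weighted BCE is monotone in the class weight", {
  set.seed(2)
  p <- runif(30, 0.05, 0.95); y <- rbinom(30, 1, 0.5)
  ws <- c(1, 5, 30, 100)
  ls <- vapply(ws, function(w) weighted_bce(p, y, w), 0)
  expect_true(all(diff(ls) > 0))
})

test_that("training learns a separable toy problem and is deterministic", {
  trw <- separable_windows(160, seed = 1)
  vaw <- separable_windows(60, seed = 2)
  for (kind in c("FCNET", "CNNET")) {
    m <- build_network(kind, seed = 1)
    init_loss <- divetrace:::eval_loss(m, trw, 5)
    fit <- train_network(m, trw, vaw,
                         train_config(class_weight = 5, seed = 1,
                                      patience = 50, max_epochs = 50))
    expect_lt(min(fit$history$train_loss), 0.1 * init_loss)
    fit2 <- train_network(build_network(kind, seed = 1), trw, vaw,
                          train_config(class_weight = 5, seed = 1,
                                       patience = 50, max_epochs = 50))
    expect_identical(fit$history, fit2$history)
    expect_identical(fit$model$params, fit2$model$params)
  }
})

test_that("early stopping returns the best-validation weights", {
  trw <- separable_windows(120, seed = 3)
  vaw <- separable_windows(50, seed = 4)
  fit <- train_network(build_network("CNNET", seed = 2), trw, vaw,
                       train_config(class_weight = 5, seed = 2,
                                    patience = 1, max_epochs = 30))
  h <- fit$history
  best <- attr(h, "best_epoch")
  stopped <- attr(h, "stopped_epoch")
  expect_identical(best, which.min(h$validation_loss))
  expect_lte(stopped, 30L)
  # with patience 1 the run stops at the first epoch that fails to improve
  if (stopped < 30L) {
    expect_gte(h$validation_loss[stopped], h$validation_loss[best])
    expect_identical(best, stopped - 1L)
  }
  # the returned weights reproduce the recorded best validation loss
  expect_equal(divetrace:::eval_loss(fit$model, vaw, 5),
               min(h$validation_loss), tolerance = 1e-12)
  empty <- suppressWarnings(make_windows(straight_trip(10), vaw$norm_stats))
  expect_error(train_network(build_network("CNNET", 1), empty, vaw,
                             train_config()), "non-empty")
})

test_that("fine_tune with zero epochs is a no-op and keeps outputs in (0,1)", {
  trw <- separable_windows(80, seed = 5)
  vaw <- separable_windows(30, seed = 6)
  pre <- train_network(build_network("CNNET", seed = 3), trw, vaw,
                       train_config(class_weight = 5, seed = 3,
                                    max_epochs = 3, patience = 3))$model
  noop <- fine_tune(pre, trw, vaw,
                    train_config(class_weight = 5, seed = 4, max_epochs = 0))
  expect_identical(noop$model$params, pre$params)
  tuned <- fine_tune(pre, trw, vaw,
                     train_config(class_weight = 5, seed = 4, max_epochs = 3,
                                  patience = 3))
  p <- forward(tuned$model, trw$x[, , 1])
  expect_true(all(p > 0 & p < 1))
})

test_that("predict_trip averages stride-1 windows position by position", {
  tr <- random_trip(45, seed = 8)
  ns <- fit_norm_stats(list(tr))
  # a constant network: all weights zero, head bias z -> sigmoid(z) everywhere
  m <- build_network("CNNET", seed = 1)
  for (nm in names(m$params)) {
    m$params[[nm]]$W[] <- 0
    m$params[[nm]]$b[] <- 0
  }
  m$params$head$b <- 0.847
  m$norm_stats <- ns
  pred <- predict_trip(m, tr)
  expect_equal(pred$p_dive, rep(1 / (1 + exp(-0.847)), 45), tolerance = 1e-12)

  # general network: compare against an explicit per-window average
  m2 <- build_network("CNNET", seed = 9)
  m2$norm_stats <- ns
  pred2 <- predict_trip(m2, tr)
  ws <- make_windows(tr, ns, stride = 1)
  sums <- numeric(45); cnts <- numeric(45)
  for (j in seq_len(n_windows(ws))) {
    p <- forward(m2, ws$x[, , j])
    pos <- ws$start[j] + 0:19
    sums[pos] <- sums[pos] + p
    cnts[pos] <- cnts[pos] + 1
  }
  expect_equal(pred2$p_dive, sums / cnts, tolerance = 1e-12)
  # stride-1 combinatorics: the ends are covered by 1 window, the middle by L
  expect_equal(cnts[1], 1)
  expect_equal(cnts[45], 1)
  expect_equal(max(cnts), 20)

  expect_error(predict_trip(m2, random_trip(10, seed = 1)), "shorter")
})
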