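## Small separable window problem: two classes distinguished by the phase of
## a sinusoid across 6 channels, windows of 40 samples.
separable_pool <- function(n, seed = 1) {
  set.seed(seed)
  W <- 40L; C <- 6L
  x <- array(0, c(W, C, n))
  y <- sample(c("A", "B"), n, replace = TRUE)
  tt <- seq_len(W) / 10
  for (i in seq_len(n)) {
    ph <- if (y[i] == "A") 0 else pi
    for (c in seq_len(C)) {
      x[, c, i] <- sin(2 * pi * tt + ph + c / 3) + rnorm(W, 0, 0.2)
    }
  }
  list(x = x, y = y)
}

tiny_spec <- model_spec(filters = c(6, 4), kernel_time = 7, dense = 8,
                        dropout = 0)

test_that("model outputs are probability simplices for any input", {
  set.seed(2)
  fit <- har_cnn(separable_pool(40)$x, separable_pool(40)$y, tiny_spec,
                 train_control(max_epochs = 1, seed = 1))
  P <- predict(fit, array(rnorm(40 * 6 * 13, sd = 100), c(40, 6, 13)),
               type = "prob")
  expect_true(all(P >= 0 & P <= 1))
  expect_equal(rowSums(P), rep(1, 13))
  expect_equal(dim(P), c(13L, 2L))
})

test_that("construction is reproducible and validates the input shape", {
  set.seed(10); p1 <- repwatch:::init_cnn_params(tiny_spec, c(40L, 6L), 2L)
  set.seed(10); p2 <- repwatch:::init_cnn_params(tiny_spec, c(40L, 6L), 2L)
  expect_identical(p1, p2)
  expect_gt(repwatch:::count_params(p1), 0)
  expect_equal(repwatch:::count_params(p1),
               repwatch:::count_params(
                 local({set.seed(99)
                        repwatch:::init_cnn_params(tiny_spec, c(40L, 6L), 2L)})))
  expect_error(repwatch:::init_cnn_params(tiny_spec, c(40L, 7L), 2L),
               "divisible by 3")
  expect_error(repwatch:::init_cnn_params(
    model_spec(filters = c(4, 4, 4), kernel_time = 15, dense = 4),
    c(40L, 6L), 2L), "too short")
  ## default architecture builds for the 18-channel, 4 s input
  set.seed(1)
  pd <- repwatch:::init_cnn_params(model_spec(), c(400L, 18L), 11L)
  expect_equal(length(pd$conv), 5L)
  expect_equal(vapply(pd$conv, function(l) dim(l$W)[3], integer(1)),
               c(100L, 75L, 25L, 25L, 75L))
})

test_that("training is deterministic given a seed and learns separable data", {
  pool <- separable_pool(120, seed = 4)
  val <- separable_pool(60, seed = 5)
  ctrl <- train_control(batch_size = 20, learning_rate = 0.05,
                        max_epochs = 12, seed = 123)
  fit1 <- har_cnn(pool$x, pool$y, tiny_spec, ctrl,
                  validation = list(x = val$x, y = val$y))
  fit2 <- har_cnn(pool$x, pool$y, tiny_spec, ctrl,
                  validation = list(x = val$x, y = val$y))
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$params, fit2$params)
  ## held-out accuracy on fresh separable windows
  test <- separable_pool(100, seed = 6)
  expect_gte(mean(predict(fit1, test$x) == test$y), 0.99)
  expect_gte(max(fit1$history$val_acc, na.rm = TRUE), 0.99)
})

test_that("constant inputs cannot beat chance on balanced classes", {
  set.seed(8)
  n <- 80
  x <- array(0, c(40, 6, n))
  y <- rep(c("A", "B"), n / 2)
  fit <- har_cnn(x, y, tiny_spec,
                 train_control(max_epochs = 3, learning_rate = 0.01, seed = 2))
  P <- predict(fit, x, type = "prob")
  expect_true(all(abs(P[, 1] - P[1, 1]) < 1e-8))  # identical outputs
  expect_equal(mean(predict(fit, x) == y), 0.5, tolerance = 0.01)
})

test_that("batched and one-by-one prediction agree", {
  pool <- separable_pool(50, seed = 9)
  fit <- har_cnn(pool$x, pool$y, tiny_spec,
                 train_control(max_epochs = 2, seed = 3))
  P <- predict(fit, pool$x, type = "prob")
  single <- t(vapply(seq_len(10), function(i) {
    predict(fit, pool$x[, , i], type = "prob")[1, ]
  }, numeric(2)))
  expect_equal(unname(P[1:10, ]), unname(single), tolerance = 1e-12)
  expect_error(predict(fit, array(0, c(30, 6, 2))), "does not match")
})

test_that("early stopping returns the best-validation-loss weights", {
  pool <- separable_pool(100, seed = 12)
  val <- separable_pool(50, seed = 13)
  ctrl <- train_control(batch_size = 20, learning_rate = 0.08,
                        max_epochs = 40, patience = 3, seed = 7)
  fit <- har_cnn(pool$x, pool$y, tiny_spec, ctrl,
                 validation = list(x = val$x, y = val$y))
  h <- fit$history
  expect_equal(fit$best_epoch, which.min(h$val_loss))
  ## a stalled model stops after `patience` epochs without improvement
  stall <- har_cnn(pool$x, pool$y, tiny_spec,
                   train_control(learning_rate = 1e-300, max_epochs = 40,
                                 patience = 2, seed = 7),
                   validation = list(x = val$x, y = val$y))
  expect_equal(nrow(stall$history), 3L)        # epoch 1 best, then 2 stale
  ## returned weights reproduce the best recorded validation loss
  xv <- sweep(sweep(val$x, 2, fit$norm$mu, "-"), 2, fit$norm$sd, "/")
  P <- repwatch:::predict_engine(fit$params, fit$spec, xv)
  vl <- repwatch:::cross_entropy(P, match(val$y, fit$classes))
  expect_equal(vl, min(h$val_loss), tolerance = 1e-10)
})

test_that("elu and extra dense variants train and predict", {
  pool <- separable_pool(60, seed = 20)
  spec <- model_spec(filters = 5, kernel_time = 7, dense = 8,
                     extra_dense = TRUE, dropout = 0.1, activation = "elu")
  fit <- har_cnn(pool$x, pool$y, spec,
                 train_control(max_epochs = 2, seed = 11))
  expect_equal(length(fit$params$dense), 4L)   # 8, 4, 4, output
  P <- predict(fit, pool$x, type = "prob")
  expect_equal(rowSums(P), rep(1, 60))
})
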