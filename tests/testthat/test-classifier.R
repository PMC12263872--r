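tiny_spec <- function(T = 16, C = 2) {
  model_spec(conv_filters = c(2, 3, 4), kernel_size = 3, pool_size = 2,
             dropout_rate = 0, temporal_pool_factor = 2,
             lstm_units = c(3, 2), dense_units = 3, input_shape = c(T, C))
}

# separable sequence set: class 1 has a mean shift on channel 1
make_seq_data <- function(n, T = 64, C = 4, shift = 1.5, seed = 1) {
  set.seed(seed)
  y <- rep(c(0, 1), length.out = n)
  x <- array(rnorm(n * T * C), c(n, T, C))
  for (i in which(y == 1)) x[i, , 1] <- x[i, , 1] + shift
  list(x = x, y = y)
}

test_that("pad_or_truncate center-crops and zero-pads", {
  m <- matrix(1:40, 10, 4)
  expect_identical(pad_or_truncate(m, 10), m)

  crop <- pad_or_truncate(m, 4)
  expect_equal(crop, m[4:7, ])  # frames 3..6 zero-based

  pad <- pad_or_truncate(m[1:2, ], 4)
  expect_equal(pad[3:4, ], matrix(0, 2, 4))
  expect_equal(pad[1:2, ], m[1:2, ])
})

test_that("model construction honors the spec contract", {
  expect_error(model_spec(conv_filters = c(64, 32, 128)),
               "strictly increasing")
  expect_error(model_spec(dropout_rate = 1), "dropout")

  # seeded init is reproducible
  m1 <- build_model(tiny_spec(), seed = 5)
  m2 <- build_model(tiny_spec(), seed = 5)
  expect_identical(m1$params, m2$params)

  # single probability per input
  x <- array(rnorm(3 * 16 * 2), c(3, 16, 2))
  p <- predict(m1, x)
  expect_equal(nrow(p), 3L)
  expect_true(all(p$prob >= 0 & p$prob <= 1))

  # conv stack halves time 3x: 512 -> 64 before temporal pooling
  spec <- model_spec(input_shape = c(512, 13))
  model <- build_model(spec, seed = 1)
  fw <- swarmspeech:::nn_forward(model, array(0, c(1, 512, 13)))
  expect_equal(dim(fw$caches[[3]]$bn$out)[2], 64L)
  expect_equal(dim(fw$avg$out)[2], 16L)  # /4 temporal average pooling
})

test_that("parameter count is a pure function of the spec (golden value)", {
  # independent closed-form tally for the default spec:
  # conv: K*Cin*Cout + Cout; bn: 2*Cout; lstm: 4u*(Cin+u) + 4u;
  # dense: in*out + out
  conv <- function(K, ci, co) K * ci * co + co
  lstm <- function(ci, u) 4 * u * (ci + u) + 4 * u
  expected <- conv(5, 13, 32) + 2 * 32 + conv(5, 32, 64) + 2 * 64 +
    conv(5, 64, 128) + 2 * 128 + lstm(128, 64) + lstm(64, 32) +
    (32 * 32 + 32) + (32 + 1)
  expect_equal(model_param_count(model_spec()), expected)
  expect_equal(expected, 116865)
})

test_that("backpropagation matches numerical gradients", {
  model <- build_model(tiny_spec(), seed = 42)
  set.seed(7)
  X <- array(rnorm(4 * 16 * 2), c(4, 16, 2))
  y <- c(0, 1, 1, 0)
  w <- c(1, 2, 1, 2)  # exercise the class-weight path
  loss_of <- function(m) {
    fw <- swarmspeech:::nn_forward(m, X, training = TRUE)
    swarmspeech:::bce_loss(fw$logits, y, w)$loss
  }
  fw <- swarmspeech:::nn_forward(model, X, training = TRUE)
  grads <- swarmspeech:::nn_backward(
    model, fw, swarmspeech:::bce_loss(fw$logits, y, w)$dlogits)
  eps <- 1e-5
  set.seed(13)
  for (nm in names(model$params)) {
    p <- model$params[[nm]]
    for (i in sample(length(p), min(4, length(p)))) {
      mp <- model; mp$params[[nm]][i] <- p[i] + eps
      mm <- model; mm$params[[nm]][i] <- p[i] - eps
      num <- (loss_of(mp) - loss_of(mm)) / (2 * eps)
      expect_equal(grads[[nm]][i], num, tolerance = 1e-4,
                   label = sprintf("analytic grad of %s[%d]", nm, i))
    }
  }
})

test_that("dropout is stochastic in training and absent at inference", {
  spec <- model_spec(conv_filters = c(2, 3, 4), kernel_size = 3,
                     pool_size = 2, dropout_rate = 0.5,
                     temporal_pool_factor = 2, lstm_units = c(3, 2),
                     dense_units = 3, input_shape = c(16, 2))
  model <- build_model(spec, seed = 1)
  X <- array(rnorm(2 * 16 * 2), c(2, 16, 2))
  set.seed(1)
  a <- swarmspeech:::nn_forward(model, X, training = TRUE)$prob
  set.seed(2)
  b <- swarmspeech:::nn_forward(model, X, training = TRUE)$prob
  expect_false(identical(a, b))

  c1 <- swarmspeech:::nn_forward(model, X, training = FALSE)$prob
  c2 <- swarmspeech:::nn_forward(model, X, training = FALSE)$prob
  expect_identical(c1, c2)
})

test_that("training learns a separable problem and early-stops", {
  dat <- make_seq_data(40, seed = 2)
  spec <- model_spec(conv_filters = c(4, 6, 8), kernel_size = 3,
                     pool_size = 2, dropout_rate = 0.1,
                     temporal_pool_factor = 2, lstm_units = c(8, 4),
                     dense_units = 4, input_shape = c(64, 4))
  model <- build_model(spec, seed = 1)
  tr <- 1:28; va <- 29:40
  fit <- suppressWarnings(train(
    model, list(x = dat$x[tr, , , drop = FALSE], y = dat$y[tr]),
    list(x = dat$x[va, , , drop = FALSE], y = dat$y[va]),
    train_config(epochs = 20, batch_size = 8, seed = 1)))
  expect_gte(max(fit$history$val_macro_f1), 0.95)
  expect_lte(nrow(fit$history), 20)

  # loss decreases on the separable set (median over seeds)
  drops <- vapply(1:5, function(s) {
    m <- build_model(spec, seed = s)
    f <- suppressWarnings(train(
      m, list(x = dat$x[tr, , , drop = FALSE], y = dat$y[tr]),
      cfg = train_config(epochs = 5, batch_size = 8, seed = s)))
    f$history$loss[5] <= f$history$loss[1]
  }, logical(1))
  expect_gte(sum(drops), 3)
})

test_that("zero-epoch training is a no-op with empty history", {
  model <- build_model(tiny_spec(), seed = 3)
  dat <- make_seq_data(8, T = 16, C = 2, seed = 3)
  fit <- train(model, dat, cfg = train_config(epochs = 0))
  expect_identical(fit$params, model$params)
  expect_equal(nrow(fit$history), 0L)
  expect_error(train(model, list(x = dat$x, y = rep(1, 8)),
                     cfg = train_config(epochs = 1)), "both classes")
})

test_that("prediction is deterministic and batching-equivalent", {
  model <- build_model(tiny_spec(), seed = 4)
  X <- array(rnorm(7 * 16 * 2), c(7, 16, 2))
  p1 <- predict(model, X)
  p2 <- predict(model, X)
  expect_identical(p1, p2)

  per_item <- vapply(1:7, function(i) {
    predict(model, X[i, , , drop = FALSE])$prob
  }, numeric(1))
  expect_equal(p1$prob, per_item, tolerance = 1e-5)

  batched <- predict(model, X, batch_size = 3)
  expect_equal(p1$prob, batched$prob, tolerance = 1e-5)

  expect_error(predict(model, array(0, c(2, 16, 5))), "shape")
})

test_that("label-independent features stay at chance (no leakage)", {
  dat <- make_seq_data(80, T = 32, C = 3, shift = 0, seed = 6)
  spec <- model_spec(conv_filters = c(3, 4, 5), kernel_size = 3,
                     pool_size = 2, dropout_rate = 0.1,
                     temporal_pool_factor = 1, lstm_units = c(4, 3),
                     dense_units = 3, input_shape = c(32, 3))
  model <- build_model(spec, seed = 2)
  tr <- 1:24; va <- 25:36; te <- 37:80  # fresh test split, unseen by
  fit <- suppressWarnings(train(       # training or early stopping
    model, list(x = dat$x[tr, , , drop = FALSE], y = dat$y[tr]),
    list(x = dat$x[va, , , drop = FALSE], y = dat$y[va]),
    train_config(epochs = 6, batch_size = 8, seed = 2)))
  pred <- predict(fit, dat$x[te, , , drop = FALSE])
  f1 <- suppressWarnings(macro_metrics(dat$y[te], pred$label))$macro_f1
  expect_gte(f1, 0.25)  # ~3 sd band around chance at n = 44
  expect_lte(f1, 0.75)
})

test_that("literal global-average-pooling mode runs and predicts", {
  spec <- model_spec(conv_filters = c(2, 3, 4), kernel_size = 3,
                     pool_size = 2, dropout_rate = 0,
                     temporal_pool_factor = 2, lstm_units = c(3, 2),
                     dense_units = 3, input_shape = c(16, 2),
                     literal_gap = TRUE)
  model <- build_model(spec, seed = 1)
  X <- array(rnorm(3 * 16 * 2), c(3, 16, 2))
  fw <- swarmspeech:::nn_forward(model, X)
  expect_equal(dim(fw$avg$out)[2], 1L)  # time axis collapsed
  expect_true(all(is.finite(fw$prob)))
})

test_that("model checkpoints round-trip", {
  model <- build_model(tiny_spec(), seed = 9)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(model, path)
  back <- load_model(path)
  X <- array(rnorm(2 * 16 * 2), c(2, 16, 2))
  expect_identical(predict(model, X), predict(back, X))
})
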