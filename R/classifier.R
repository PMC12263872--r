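#' CNN-LSTM architecture specification
#'
#' Declarative description of the sequence classifier: three 1D
#' convolution blocks with strictly increasing filter counts (each
#' block: Conv1D + ReLU, max pooling, dropout, batch normalization),
#' a sequence-preserving temporal average pooling, two stacked LSTM
#' layers (the second returning only its final state), a ReLU dense
#' layer, and a single sigmoid output unit.
#'
#' A literal global average pooling before the LSTMs would collapse
#' the time axis the LSTMs need; the default therefore pools by
#' `temporal_pool_factor` and keeps a sequence, while
#' `literal_gap = TRUE` switches to the literal global pooling
#' (feeding the LSTMs a length-1 sequence) for comparison.
#'
#' @param conv_filters Three strictly increasing filter counts.
#' @param kernel_size Convolution kernel width (odd recommended).
#' @param pool_size Max-pooling factor per block.
#' @param dropout_rate Dropout rate in [0, 1).
#' @param temporal_pool_factor Average-pooling factor before the LSTMs.
#' @param lstm_units Two LSTM layer widths.
#' @param dense_units Width of the penultimate dense layer.
#' @param input_shape `c(T_fixed, n_channels)`.
#' @param literal_gap Use literal global average pooling instead.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(conv_filters = c(32, 64, 128), kernel_size = 5,
                       pool_size = 2, dropout_rate = 0.3,
                       temporal_pool_factor = 4, lstm_units = c(64, 32),
                       dense_units = 32, input_shape = c(512, 13),
                       literal_gap = FALSE) {
  if (length(conv_filters) != 3L || any(diff(conv_filters) <= 0)) {
    stop("conv_filters must be three strictly increasing counts",
         call. = FALSE)
  }
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("dropout_rate must be in [0,1)", call. = FALSE)
  }
  if (length(lstm_units) != 2L) stop("need two LSTM widths", call. = FALSE)
  T_conv <- input_shape[1] %/% pool_size^3
  T_seq <- if (literal_gap) 1L else T_conv %/% temporal_pool_factor
  if (T_seq < 1L) {
    stop("input too short for the pooling configuration", call. = FALSE)
  }
  structure(list(conv_filters = as.integer(conv_filters),
                 kernel_size = as.integer(kernel_size),
                 pool_size = as.integer(pool_size),
                 dropout_rate = dropout_rate,
                 temporal_pool_factor = as.integer(temporal_pool_factor),
                 lstm_units = as.integer(lstm_units),
                 dense_units = as.integer(dense_units),
                 input_shape = as.integer(input_shape),
                 literal_gap = isTRUE(literal_gap)),
            class = "model_spec")
}

#' Training configuration for the CNN-LSTM
#'
#' @param epochs Maximum epochs (0 returns the initialized model).
#' @param batch_size Minibatch size.
#' @param learning_rate Adam learning rate.
#' @param early_stop_patience Epochs without validation macro-F1
#'   improvement before stopping (only active with a validation set).
#' @param seed Seed controlling shuffling and dropout.
#' @param class_weighting Weight samples by inverse class frequency.
#' @param verbose Print per-epoch progress.
#' @return Object of class `train_config`.
#' @export
train_config <- function(epochs = 50, batch_size = 16, learning_rate = 1e-3,
                         early_stop_patience = 8, seed = 1,
                         class_weighting = TRUE, verbose = FALSE) {
  if (epochs < 0 || batch_size < 1 || learning_rate <= 0 ||
      early_stop_patience < 1) {
    stop("invalid training configuration", call. = FALSE)
  }
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 early_stop_patience = as.integer(early_stop_patience),
                 seed = as.integer(seed),
                 class_weighting = isTRUE(class_weighting),
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Build an untrained CNN-LSTM model
#'
#' Initializes all parameters (Glorot-uniform weights, zero biases,
#' LSTM forget-gate bias 1) from the seed; two builds from the same
#' spec and seed are identical.
#'
#' @param spec A [model_spec()].
#' @param seed Integer seed for the initialization.
#' @return Object of class `swarm_nn`.
#' @export
build_model <- function(spec = model_spec(), seed = 1) {
  stopifnot(inherits(spec, "model_spec"))
  set.seed(as.integer(seed))
  K <- spec$kernel_size
  chans <- c(spec$input_shape[2], spec$conv_filters)
  p <- list()
  bn_state <- list()
  for (l in 1:3) {
    cin <- chans[l]; cout <- chans[l + 1]
    p[[paste0("conv", l, "_W")]] <- glorot(K * cin, K * cout,
                                           c(K, cin, cout))
    p[[paste0("conv", l, "_b")]] <- numeric(cout)
    p[[paste0("bn", l, "_gamma")]] <- rep(1, cout)
    p[[paste0("bn", l, "_beta")]] <- numeric(cout)
    bn_state[[l]] <- list(mean = numeric(cout), var = rep(1, cout))
  }
  u1 <- spec$lstm_units[1]; u2 <- spec$lstm_units[2]
  cin <- spec$conv_filters[3]
  p$lstm1_Wx <- glorot(cin, 4 * u1, c(cin, 4L * u1))
  p$lstm1_Wh <- glorot(u1, 4 * u1, c(u1, 4L * u1))
  p$lstm1_b <- c(numeric(u1), rep(1, u1), numeric(2L * u1))
  p$lstm2_Wx <- glorot(u1, 4 * u2, c(u1, 4L * u2))
  p$lstm2_Wh <- glorot(u2, 4 * u2, c(u2, 4L * u2))
  p$lstm2_b <- c(numeric(u2), rep(1, u2), numeric(2L * u2))
  p$dense_W <- glorot(u2, spec$dense_units, c(u2, spec$dense_units))
  p$dense_b <- numeric(spec$dense_units)
  p$out_W <- glorot(spec$dense_units, 1, c(spec$dense_units, 1L))
  p$out_b <- 0
  structure(list(spec = spec, params = p, bn_state = bn_state,
                 history = data.frame(epoch = integer(), loss = numeric(),
                                      val_macro_f1 = numeric()),
                 trained = FALSE, seed = as.integer(seed)),
            class = "swarm_nn")
}

#' Number of trainable parameters of a model or spec
#'
#' @param x A `swarm_nn` or [model_spec()].
#' @return Integer parameter count.
#' @export
model_param_count <- function(x) {
  if (inherits(x, "model_spec")) x <- build_model(x, seed = 1)
  sum(vapply(x$params, length, integer(1)))
}

#' @export
print.swarm_nn <- function(x, ...) {
  s <- x$spec
  cat(sprintf("<swarm_nn: conv(%s) k=%d -> avgpool/%s -> lstm(%d,%d) -> dense(%d) -> 1;\n",
              paste(s$conv_filters, collapse = ","), s$kernel_size,
              if (s$literal_gap) "global" else s$temporal_pool_factor,
              s$lstm_units[1], s$lstm_units[2], s$dense_units))
  cat(sprintf("  input %dx%d, %d parameters, %s>\n", s$input_shape[1],
              s$input_shape[2], model_param_count(x),
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

#' Fix the length of a feature sequence
#'
#' Sequences longer than `T_fixed` are center-cropped (floor offset);
#' shorter ones are zero-padded at the end.
#'
#' @param seq A `feature_sequence` or `T x C` matrix.
#' @param T_fixed Target number of frames.
#' @return A `T_fixed x C` matrix.
#' @export
pad_or_truncate <- function(seq, T_fixed) {
  values <- if (inherits(seq, "feature_sequence")) seq$values else seq
  if (!is.matrix(values) || nrow(values) == 0L) {
    stop("expected a non-empty frame matrix", call. = FALSE)
  }
  T_cur <- nrow(values)
  if (T_cur >= T_fixed) {
    off <- (T_cur - T_fixed) %/% 2L
    values[off + seq_len(T_fixed), , drop = FALSE]
  } else {
    rbind(values, matrix(0, T_fixed - T_cur, ncol(values)))
  }
}

#' Stack feature sequences into a batch array
#'
#' @param seqs List of `feature_sequence` objects or matrices.
#' @param T_fixed Target frame count (see [pad_or_truncate()]).
#' @param channel_mask Optional logical vector selecting coefficient
#'   channels to keep.
#' @return `(B, T_fixed, C)` array.
#' @export
sequences_to_array <- function(seqs, T_fixed, channel_mask = NULL) {
  mats <- lapply(seqs, pad_or_truncate, T_fixed = T_fixed)
  if (!is.null(channel_mask)) {
    mats <- lapply(mats, function(m) m[, channel_mask, drop = FALSE])
  }
  C <- ncol(mats[[1]])
  out <- array(0, c(length(mats), T_fixed, C))
  for (i in seq_along(mats)) out[i, , ] <- mats[[i]]
  out
}

#' Train the CNN-LSTM classifier
#'
#' Minimizes (class-weighted) binary cross-entropy with Adam. With a
#' validation set, validation macro F1 is computed after every epoch;
#' training stops after `early_stop_patience` epochs without
#' improvement and the best-validation checkpoint is returned.
#'
#' @param model An untrained (or previously trained) `swarm_nn`.
#' @param train_set `list(x = (B,T,C) array, y = 0/1 labels)`; both
#'   classes must be present.
#' @param val_set Optional validation set of the same form.
#' @param cfg A [train_config()].
#' @return The trained `swarm_nn` with a `history` data frame
#'   (`epoch`, `loss`, `val_macro_f1`).
#' @export
train <- function(model, train_set, val_set = NULL, cfg = train_config()) {
  stopifnot(inherits(model, "swarm_nn"), inherits(cfg, "train_config"))
  x <- train_set$x; y <- train_set$y
  if (length(unique(y)) < 2L) {
    stop("training set must contain both classes", call. = FALSE)
  }
  if (cfg$epochs == 0L) return(model)
  set.seed(cfg$seed)
  n <- dim(x)[1]
  w_sample <- rep(1, n)
  if (cfg$class_weighting) {
    n1 <- sum(y == 1)
    w_sample <- ifelse(y == 1, n / (2 * n1), n / (2 * (n - n1)))
  }
  adam <- adam_init(model$params)
  history <- data.frame(epoch = integer(), loss = numeric(),
                        val_macro_f1 = numeric())
  best <- list(f1 = -Inf, params = model$params, bn_state = model$bn_state,
               epoch = 0L)
  stale <- 0L
  for (ep in seq_len(cfg$epochs)) {
    perm <- sample.int(n)
    ep_loss <- 0
    n_batch <- 0L
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- perm[start:min(start + cfg$batch_size - 1L, n)]
      xb <- x[idx, , , drop = FALSE]
      fw <- nn_forward(model, xb, training = TRUE)
      model$bn_state <- fw$bn_state
      loss <- bce_loss(fw$logits, y[idx], w_sample[idx])
      grads <- nn_backward(model, fw, loss$dlogits)
      upd <- adam_update(model$params, grads, adam, cfg$learning_rate)
      model$params <- upd$params
      adam <- upd$state
      ep_loss <- ep_loss + loss$loss
      n_batch <- n_batch + 1L
    }
    ep_loss <- ep_loss / n_batch
    val_f1 <- NA_real_
    if (!is.null(val_set)) {
      pred <- predict(model, val_set$x)
      val_f1 <- macro_metrics(val_set$y, pred$label)$macro_f1
      if (val_f1 > best$f1) {
        best <- list(f1 = val_f1, params = model$params,
                     bn_state = model$bn_state, epoch = ep)
        stale <- 0L
      } else {
        stale <- stale + 1L
      }
    }
    history <- rbind(history, data.frame(epoch = ep, loss = ep_loss,
                                         val_macro_f1 = val_f1))
    if (cfg$verbose) {
      message(sprintf("epoch %3d  loss %.4f  val macro F1 %s", ep, ep_loss,
                      ifelse(is.na(val_f1), "-", sprintf("%.4f", val_f1))))
    }
    if (!is.null(val_set) && stale >= cfg$early_stop_patience) break
  }
  if (!is.null(val_set) && is.finite(best$f1)) {
    model$params <- best$params
    model$bn_state <- best$bn_state
  }
  model$history <- history
  model$trained <- TRUE
  model
}

#' Predict class probabilities and labels
#'
#' Inference-mode forward pass (dropout off, batch-norm running
#' statistics), so predictions are deterministic and independent of
#' batching.
#'
#' @param object A `swarm_nn`.
#' @param newdata `(B, T, C)` array matching the spec's input shape,
#'   or a list of sequences/matrices (padded automatically).
#' @param batch_size Internal chunk size.
#' @param ... Unused.
#' @return `data.frame(prob, label)`.
#' @export
predict.swarm_nn <- function(object, newdata, batch_size = 32, ...) {
  if (is.list(newdata) && !is.array(newdata)) {
    newdata <- sequences_to_array(newdata, object$spec$input_shape[1])
  }
  if (length(dim(newdata)) != 3L ||
      dim(newdata)[3] != object$spec$input_shape[2]) {
    stop(sprintf("input shape %s does not match spec (T x %d)",
                 paste(dim(newdata), collapse = "x"),
                 object$spec$input_shape[2]), call. = FALSE)
  }
  n <- dim(newdata)[1]
  prob <- numeric(n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    fw <- nn_forward(object, newdata[idx, , , drop = FALSE],
                     training = FALSE)
    prob[idx] <- fw$prob
  }
  data.frame(prob = prob, label = as.integer(prob >= 0.5))
}

#' Export a training history as delimited text
#'
#' @param model A trained `swarm_nn`.
#' @param path Output CSV path (`epoch`, `loss`, `val_macro_f1`).
#' @return `path`, invisibly.
#' @export
write_training_history <- function(model, path) {
  stopifnot(inherits(model, "swarm_nn"))
  utils::write.csv(model$history, path, row.names = FALSE)
  invisible(path)
}

#' Save / load a model checkpoint
#'
#' Native R serialization (binary; a run-time artifact, not a data
#' format for distribution).
#'
#' @param model A `swarm_nn`.
#' @param path Checkpoint path.
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "swarm_nn"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "swarm_nn"))
  model
}
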