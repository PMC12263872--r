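#' Wrapper feature-selection configuration
#'
#' Controls the swarm-driven wrapper: which optimizer explores the
#' continuous `[0,1]^d` relaxation, how positions are binarized, and
#' how candidate masks are scored. The fitness (minimized) is
#' `(1 - macroF1_cv) + lambda * n_selected / d`, i.e. cross-validated
#' macro F1 of a surrogate classifier on the masked columns plus a
#' small sparsity penalty; `lambda = 0.01` keeps accuracy dominant.
#'
#' @param optimizer_kind `"dragonfly"`, `"firefly"` or `"mothflame"`.
#' @param optimizer Matching `*_config()`; defaults to the kind's
#'   defaults.
#' @param sparsity_weight Sparsity penalty weight `lambda >= 0`.
#' @param threshold Binarization threshold `theta` in (0, 1).
#' @param surrogate `"linear"` (ridge logistic regression, default) or
#'   `"cnn_lstm"` (a tiny sequence model; only sensible with very small
#'   budgets).
#' @param cv_folds Stratified cross-validation folds for the fitness.
#' @param seed Integer seed; folds and the swarm both derive from it so
#'   fitness is a pure function of (mask, seed).
#' @return Object of class `selection_config`.
#' @export
selection_config <- function(optimizer_kind = "firefly", optimizer = NULL,
                             sparsity_weight = 0.01, threshold = 0.5,
                             surrogate = c("linear", "cnn_lstm"),
                             cv_folds = 3, seed = 1) {
  surrogate <- match.arg(surrogate)
  if (!optimizer_kind %in% c("dragonfly", "firefly", "mothflame")) {
    stop("unknown optimizer_kind: ", optimizer_kind, call. = FALSE)
  }
  if (sparsity_weight < 0) stop("sparsity_weight must be >= 0", call. = FALSE)
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must be in (0,1)", call. = FALSE)
  }
  structure(list(optimizer_kind = optimizer_kind, optimizer = optimizer,
                 sparsity_weight = sparsity_weight, threshold = threshold,
                 surrogate = surrogate, cv_folds = as.integer(cv_folds),
                 seed = as.integer(seed)),
            class = "selection_config")
}

#' Decode a continuous swarm position into a feature mask
#'
#' Feature j is selected iff `position[j] >= threshold`. If nothing
#' passes, the single feature with the largest position value is
#' selected (first index on ties), so every decoded mask is non-empty.
#'
#' @param position Numeric vector in `[0, 1]^d`.
#' @param threshold Threshold in (0, 1).
#' @return Object of class `feature_mask`: list with logical
#'   `selected` and integer `n_selected`.
#' @export
decode_mask <- function(position, threshold = 0.5) {
  sel <- position >= threshold
  if (!any(sel)) sel[which.max(position)] <- TRUE
  structure(list(selected = unname(sel), n_selected = sum(sel)),
            class = "feature_mask")
}

#' @export
print.feature_mask <- function(x, ...) {
  cat(sprintf("<feature_mask: %d of %d features selected>\n",
              x$n_selected, length(x$selected)))
  invisible(x)
}

# Cross-validated macro F1 of the surrogate on the masked columns;
# predictions are pooled across folds before scoring.
surrogate_cv_macro_f1 <- function(x, y, selected, cfg, folds) {
  xm <- x[, selected, drop = FALSE]
  pred <- integer(length(y))
  for (k in seq_len(cfg$cv_folds)) {
    tr <- folds != k
    if (cfg$surrogate == "linear") {
      fit <- ridge_logistic_fit(xm[tr, , drop = FALSE], y[tr])
      pred[!tr] <- as.integer(ridge_logistic_predict(
        fit, xm[!tr, , drop = FALSE]) >= 0.5)
    } else {
      pred[!tr] <- surrogate_cnn_lstm_predict(xm[tr, , drop = FALSE], y[tr],
                                              xm[!tr, , drop = FALSE],
                                              seed = cfg$seed + k)
    }
  }
  macro_metrics(y, pred)$macro_f1
}

# Tiny CNN-LSTM surrogate: treats the masked feature vector as a
# 1-channel sequence and trains a minimal model for a few epochs.
# Orders of magnitude slower than the linear surrogate; only for
# very small selection budgets.
surrogate_cnn_lstm_predict <- function(xtr, ytr, xte, seed = 1) {
  d <- ncol(xtr)
  spec <- model_spec(conv_filters = c(2, 3, 4), kernel_size = 3,
                     pool_size = 1, dropout_rate = 0, temporal_pool_factor = 1,
                     lstm_units = c(4, 4), dense_units = 4,
                     input_shape = c(d, 1))
  to_arr <- function(m) {
    a <- array(0, dim = c(nrow(m), d, 1))
    a[, , 1] <- m
    a
  }
  model <- build_model(spec, seed = seed)
  trained <- train(model, list(x = to_arr(xtr), y = ytr),
                   cfg = train_config(epochs = 8, batch_size = 16,
                                      seed = seed, verbose = FALSE))
  as.integer(predict(trained, to_arr(xte))$label)
}

#' Wrapper fitness of a feature mask
#'
#' `(1 - macroF1_cv) + lambda * n_selected / d`, where `macroF1_cv` is
#' the stratified cross-validated macro F1 of the surrogate classifier
#' trained on the masked columns. Lower is better; the value lies in
#' `[0, 1 + lambda]`. Deterministic given `(mask, cfg$seed)`: fold
#' assignment uses its own seeded generator and never touches the
#' global RNG.
#'
#' @param mask A [decode_mask()] result (or logical vector).
#' @param x Numeric feature matrix (rows = recordings).
#' @param y Binary labels in \{0, 1\}; both classes required.
#' @param cfg A [selection_config()].
#' @param folds Optional precomputed fold assignment (internal reuse).
#' @return Scalar fitness.
#' @export
mask_fitness <- function(mask, x, y, cfg = selection_config(), folds = NULL) {
  if (inherits(mask, "feature_mask")) mask <- mask$selected
  x <- as.matrix(x)
  if (length(mask) != ncol(x)) {
    stop("mask length must equal the number of feature columns", call. = FALSE)
  }
  if (length(unique(y)) < 2L) {
    stop("both classes must be present", call. = FALSE)
  }
  if (!any(mask)) stop("mask selects no features", call. = FALSE)
  if (is.null(folds)) folds <- stratified_folds(y, cfg$cv_folds, cfg$seed)
  f1 <- surrogate_cv_macro_f1(x, y, mask, cfg, folds)
  (1 - f1) + cfg$sparsity_weight * sum(mask) / ncol(x)
}

#' Swarm-driven wrapper feature selection
#'
#' Runs the configured optimizer over `[0,1]^d`, scoring each decoded
#' mask with [mask_fitness()], and returns the best mask together with
#' the convergence history and the per-feature selection frequency in
#' the final population.
#'
#' @param table Data frame with numeric feature columns and a binary
#'   `label` column, or a list `list(x, y)`.
#' @param cfg A [selection_config()].
#' @return Object of class `selection_result`: `mask`, `best_fitness`,
#'   `selected_features` (names), `history`, `frequency`,
#'   `feature_names`, `config`.
#' @examples
#' tab <- generate_feature_table(n_per_class = 30, d = 6, k = 2,
#'                               delta = 2, seed = 1)
#' cfg <- selection_config(optimizer = fa_config(pop_size = 8, n_iter = 10))
#' res <- select_features(tab$table, cfg)
#' res$selected_features
#' @export
select_features <- function(table, cfg = selection_config()) {
  stopifnot(inherits(cfg, "selection_config"))
  if (is.data.frame(table)) {
    if (!"label" %in% names(table)) {
      stop("table must contain a `label` column", call. = FALSE)
    }
    y <- table$label
    x <- as.matrix(table[, setdiff(names(table), "label"), drop = FALSE])
  } else {
    x <- as.matrix(table$x); y <- table$y
  }
  d <- ncol(x)
  if (d < 2L) stop("need at least 2 features", call. = FALSE)
  if (min(table(y)) < 2L * cfg$cv_folds) {
    stop("need at least 2 * cv_folds rows per class", call. = FALSE)
  }
  folds <- stratified_folds(y, cfg$cv_folds, cfg$seed)
  objective <- function(pos) {
    mask_fitness(decode_mask(pos, cfg$threshold), x, y, cfg, folds)
  }
  opt <- swarm_optimize(objective, lower = rep(0, d), upper = rep(1, d),
                        kind = cfg$optimizer_kind, config = cfg$optimizer,
                        seed = cfg$seed)
  best <- decode_mask(opt$best_position, cfg$threshold)
  final_masks <- t(apply(opt$final_positions, 1, function(p) {
    decode_mask(p, cfg$threshold)$selected
  }))
  fnames <- colnames(x)
  if (is.null(fnames)) fnames <- sprintf("f%02d", seq_len(d))
  structure(list(mask = best, best_fitness = opt$best_fitness,
                 selected_features = fnames[best$selected],
                 history = opt$history, frequency = colMeans(final_masks),
                 feature_names = fnames, config = cfg),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result: %d/%d features, fitness %.4f (%s)>\n",
              x$mask$n_selected, length(x$mask$selected), x$best_fitness,
              x$config$optimizer_kind))
  cat("  selected:", paste(x$selected_features, collapse = ", "), "\n")
  invisible(x)
}

#' Write a selection report and mask file
#'
#' @param result A `selection_result`.
#' @param report_path Path for the structured-text report (chosen
#'   features and fitness history).
#' @param mask_path Optional path for the mask file (one selected
#'   feature name per line) consumed by the classifier stage.
#' @return `report_path`, invisibly.
#' @export
write_selection_report <- function(result, report_path, mask_path = NULL) {
  stopifnot(inherits(result, "selection_result"))
  lines <- c(
    sprintf("optimizer: %s", result$config$optimizer_kind),
    sprintf("best_fitness: %.10g", result$best_fitness),
    sprintf("n_selected: %d", result$mask$n_selected),
    sprintf("selected: %s", paste(result$selected_features, collapse = ",")),
    "history:",
    sprintf("  %d,%.10g", seq_along(result$history), result$history)
  )
  writeLines(lines, report_path)
  if (!is.null(mask_path)) writeLines(result$selected_features, mask_path)
  invisible(report_path)
}
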