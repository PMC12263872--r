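#' Pipeline configuration
#'
#' Single nested configuration for the end-to-end pipeline
#' (simulate/load -> MFCC -> functionals -> wrapper selection ->
#' CNN-LSTM -> evaluation). Every default equals the corresponding
#' module default; unknown keys are rejected. `config` may be a path
#' to a JSON file with the same structure.
#'
#' @param config Named list (or JSON file path) of overrides.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  defaults <- list(
    seed = 1,
    io = list(audio_dir = NULL, out_dir = NULL),
    simulate = list(n_per_class = 50, sample_rate = 16000),
    mfcc = list(frame_length_ms = 25, hop_length_ms = 10, n_fft = 512,
                n_mels = 40, n_coeffs = 13, preemph = 0.97, fmin = 0,
                fmax = 8000, log_floor = 1e-10),
    selection = list(optimizer_kind = "firefly", pop_size = 50,
                     n_iter = 200, sparsity_weight = 0.01, threshold = 0.5,
                     surrogate = "linear", cv_folds = 3),
    model = list(conv_filters = c(32, 64, 128), kernel_size = 5,
                 pool_size = 2, dropout_rate = 0.3,
                 temporal_pool_factor = 4, lstm_units = c(64, 32),
                 dense_units = 32, t_fixed = 512, literal_gap = FALSE),
    training = list(epochs = 50, batch_size = 16, learning_rate = 1e-3,
                    early_stop_patience = 8, class_weighting = TRUE)
  )
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  if (!is.list(config)) stop("config must be a list or file path",
                             call. = FALSE)
  merged <- merge_config(defaults, config, path = "")
  if (!merged$selection$optimizer_kind %in%
        c("dragonfly", "firefly", "mothflame")) {
    stop("selection.optimizer_kind must be dragonfly, firefly or mothflame",
         call. = FALSE)
  }
  structure(merged, class = "pipeline_config")
}

merge_config <- function(defaults, overrides, path) {
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown config key%s: %s",
                 if (length(unknown) > 1) "s" else "",
                 paste0(path, unknown, collapse = ", ")), call. = FALSE)
  }
  for (nm in names(overrides)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      ov <- overrides[[nm]]
      if (!is.list(ov)) stop("config section ", path, nm,
                             " must be a table", call. = FALSE)
      defaults[[nm]] <- merge_config(defaults[[nm]], ov,
                                     paste0(path, nm, "."))
    } else {
      defaults[[nm]] <- overrides[[nm]]
    }
  }
  defaults
}

# Stratified 60/20/20 split by recording, deterministic from the seed.
stratified_split <- function(labels, seed, props = c(0.6, 0.2, 0.2)) {
  part <- character(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[seeded_permutation(length(idx), seed + 31 * as.numeric(cl))]
    n <- length(idx)
    n_tr <- round(props[1] * n)
    n_va <- round(props[2] * n)
    part[idx[seq_len(n_tr)]] <- "train"
    part[idx[n_tr + seq_len(n_va)]] <- "val"
    if (n_tr + n_va < n) part[idx[(n_tr + n_va + 1):n]] <- "test"
  }
  part
}

# Map a functional-level mask (names like c03_sd) back to the cepstral
# coefficients whose channels feed the sequence model: a coefficient is
# kept iff any of its four functionals was selected.
coefficients_from_functionals <- function(selected_names, n_coeffs) {
  coef_idx <- unique(as.integer(sub("^c([0-9]+)_.*$", "\\1",
                                    selected_names))) + 1L
  keep <- seq_len(n_coeffs) %in% coef_idx
  if (!any(keep)) keep[1] <- TRUE
  keep
}

load_audio_dir <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  signals <- lapply(file.path(dir, manifest$filename), read_wav)
  structure(list(signals = signals, labels = manifest$label,
                 sample_rate = signals[[1]]$sample_rate,
                 manifest = manifest, seed = NA_integer_),
            class = "audio_dataset")
}

#' Run the full screening pipeline
#'
#' Executes extract -> functionals -> wrapper selection (training split
#' only) -> mask-restricted CNN-LSTM training (train/val splits) ->
#' macro metrics on the untouched test split. All stages are seeded
#' from the single global seed. Input audio comes from
#' `io$audio_dir` (WAV files + `manifest.csv`) or, when absent, from
#' the synthetic generator configured in the `simulate` section.
#'
#' @param config A [pipeline_config()], a named list of overrides, or
#'   a JSON config path.
#' @param quiet Suppress progress messages.
#' @return Object of class `run_report`: `config`,
#'   `selected_features`, `kept_coefficients`, `selection`,
#'   `model_history`, `metrics` (test-split `screen_metrics`),
#'   `val_macro_f1`, `split_sizes`, `elapsed_s`.
#' @export
run_pipeline <- function(config = list(), quiet = FALSE) {
  t0 <- Sys.time()
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  say <- function(...) if (!quiet) message(sprintf(...))
  seed <- as.integer(config$seed)

  if (!is.null(config$io$audio_dir)) {
    say("loading audio from %s", config$io$audio_dir)
    ds <- load_audio_dir(config$io$audio_dir)
  } else {
    say("simulating %d recordings/class (seed %d)",
        config$simulate$n_per_class, seed)
    ds <- generate_audio_dataset(n_per_class = config$simulate$n_per_class,
                                 sample_rate = config$simulate$sample_rate,
                                 seed = seed)
  }

  mcfg <- do.call(mfcc_config, config$mfcc)
  say("extracting MFCCs (%d recordings)", length(ds$signals))
  seqs <- lapply(ds$signals, extract_mfcc, cfg = mcfg)
  feats <- t(vapply(seqs, functionals,
                    numeric(4L * mcfg$n_coeffs)))
  table <- as.data.frame(feats)
  table$label <- ds$labels

  part <- stratified_split(ds$labels, seed)
  tr <- part == "train"; va <- part == "val"; te <- part == "test"

  sel_cfg <- selection_config(
    optimizer_kind = config$selection$optimizer_kind,
    optimizer = switch(config$selection$optimizer_kind,
      dragonfly = da_config(config$selection$pop_size,
                            config$selection$n_iter),
      firefly = fa_config(config$selection$pop_size,
                          config$selection$n_iter),
      mothflame = mfo_config(config$selection$pop_size,
                             config$selection$n_iter)),
    sparsity_weight = config$selection$sparsity_weight,
    threshold = config$selection$threshold,
    surrogate = config$selection$surrogate,
    cv_folds = config$selection$cv_folds,
    seed = seed + 1L)
  say("selecting features (%s, pop %d, %d iterations) on the training split",
      sel_cfg$optimizer_kind, sel_cfg$optimizer$pop_size,
      sel_cfg$optimizer$n_iter)
  sel <- select_features(table[tr, , drop = FALSE], sel_cfg)

  keep_coef <- coefficients_from_functionals(sel$selected_features,
                                             mcfg$n_coeffs)
  say("kept %d/%d cepstral coefficients", sum(keep_coef), mcfg$n_coeffs)

  mc <- config$model
  spec <- model_spec(conv_filters = mc$conv_filters,
                     kernel_size = mc$kernel_size, pool_size = mc$pool_size,
                     dropout_rate = mc$dropout_rate,
                     temporal_pool_factor = mc$temporal_pool_factor,
                     lstm_units = mc$lstm_units,
                     dense_units = mc$dense_units,
                     input_shape = c(mc$t_fixed, sum(keep_coef)),
                     literal_gap = mc$literal_gap)
  x_all <- sequences_to_array(seqs, mc$t_fixed, channel_mask = keep_coef)
  tcfg <- train_config(epochs = config$training$epochs,
                       batch_size = config$training$batch_size,
                       learning_rate = config$training$learning_rate,
                       early_stop_patience = config$training$early_stop_patience,
                       seed = seed + 2L,
                       class_weighting = config$training$class_weighting)
  say("training CNN-LSTM (%d parameters, %d epochs max)",
      model_param_count(spec), tcfg$epochs)
  model <- build_model(spec, seed = seed + 2L)
  model <- train(model,
                 list(x = x_all[tr, , , drop = FALSE], y = ds$labels[tr]),
                 list(x = x_all[va, , , drop = FALSE], y = ds$labels[va]),
                 tcfg)

  pred <- predict(model, x_all[te, , , drop = FALSE])
  metrics <- macro_metrics(ds$labels[te], pred$label)
  val_f1 <- max(model$history$val_macro_f1, na.rm = TRUE)
  say("test macro F1: %.4f", metrics$macro_f1)

  report <- structure(list(
    config = unclass(config),
    selected_features = sel$selected_features,
    kept_coefficients = which(keep_coef) - 1L,
    selection = list(best_fitness = sel$best_fitness,
                     history = sel$history, frequency = sel$frequency),
    model_history = model$history,
    metrics = metrics,
    val_macro_f1 = val_f1,
    split_sizes = c(train = sum(tr), val = sum(va), test = sum(te)),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ), class = "run_report")

  if (!is.null(config$io$out_dir)) {
    write_run_report(report, config$io$out_dir, model = model)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  selected features (%d): %s\n",
              length(x$selected_features),
              paste(utils::head(x$selected_features, 8), collapse = ", ")))
  cat(sprintf("  kept coefficients: %s\n",
              paste(x$kept_coefficients, collapse = ",")))
  cat(sprintf("  test macro F1: %.4f (val best %.4f)\n",
              x$metrics$macro_f1, x$val_macro_f1))
  cat(sprintf("  elapsed: %.1f s\n", x$elapsed_s))
  invisible(x)
}

#' Write a run report to a directory
#'
#' Writes `report.json` (self-contained: config snapshot, selected
#' features, metrics), `mask.txt`, `selection_history.csv`,
#' `training_history.csv` and optionally the model checkpoint.
#'
#' @param report A `run_report`.
#' @param out_dir Output directory (created if needed).
#' @param model Optional trained model to checkpoint.
#' @return `out_dir`, invisibly.
#' @export
write_run_report <- function(report, out_dir, model = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(list(
    config = report$config,
    selected_features = report$selected_features,
    kept_coefficients = report$kept_coefficients,
    metrics = list(macro_precision = report$metrics$macro_precision,
                   macro_recall = report$metrics$macro_recall,
                   macro_f1 = report$metrics$macro_f1),
    val_macro_f1 = report$val_macro_f1,
    split_sizes = as.list(report$split_sizes),
    elapsed_s = report$elapsed_s
  ), file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
     null = "null")
  writeLines(report$selected_features, file.path(out_dir, "mask.txt"))
  utils::write.csv(data.frame(iteration = seq_along(report$selection$history),
                              best_fitness = report$selection$history),
                   file.path(out_dir, "selection_history.csv"),
                   row.names = FALSE)
  utils::write.csv(report$model_history,
                   file.path(out_dir, "training_history.csv"),
                   row.names = FALSE)
  if (!is.null(model)) save_model(model, file.path(out_dir, "model.rds"))
  invisible(out_dir)
}
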