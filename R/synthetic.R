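#' Acoustic parameters of a synthetic speech class
#'
#' Describes the statistical structure of one class of synthetic
#' "speech": a harmonic stack whose fundamental is drawn per recording
#' from `Normal(f0_mean, f0_sd)`, amplitude-modulated at
#' `energy_mod_rate` (a syllable-rate proxy), interrupted by silent
#' gaps totaling `pause_fraction` of the duration, plus Gaussian
#' noise. The two default classes differ in pitch level, pitch
#' variability, energy-modulation rate and pause fraction — the cue
#' families the depression-screening literature associates with
#' depressed speech (lower, flatter pitch; slower rate; more pauses).
#'
#' @param f0_mean,f0_sd Fundamental-frequency distribution across
#'   recordings, Hz.
#' @param n_harmonics Number of harmonics in the stack.
#' @param energy_mod_rate Amplitude-modulation rate, Hz.
#' @param pause_fraction Fraction of the recording silenced, in [0, 1).
#' @param duration_s Recording length in seconds.
#' @param noise_sd Additive Gaussian noise standard deviation (0 for
#'   noise-free test signals).
#' @return Object of class `audio_class_params`.
#' @export
audio_class_params <- function(f0_mean, f0_sd, n_harmonics = 5,
                               energy_mod_rate = 4, pause_fraction = 0.2,
                               duration_s = 4, noise_sd = 0.005) {
  if (f0_mean <= 0) stop("f0_mean must be positive", call. = FALSE)
  if (pause_fraction < 0 || pause_fraction >= 1) {
    stop("pause_fraction must be in [0,1)", call. = FALSE)
  }
  structure(list(f0_mean = f0_mean, f0_sd = f0_sd,
                 n_harmonics = as.integer(n_harmonics),
                 energy_mod_rate = energy_mod_rate,
                 pause_fraction = pause_fraction, duration_s = duration_s,
                 noise_sd = noise_sd),
            class = "audio_class_params")
}

#' Default control-class acoustic parameters
#' @return An [audio_class_params()]: f0 180 +/- 25 Hz, 5 Hz energy
#'   modulation, 10% pauses.
#' @export
control_class_params <- function() {
  audio_class_params(f0_mean = 180, f0_sd = 25, energy_mod_rate = 5,
                     pause_fraction = 0.10)
}

#' Default case-class acoustic parameters
#' @return An [audio_class_params()]: f0 120 +/- 8 Hz, 2 Hz energy
#'   modulation, 35% pauses.
#' @export
case_class_params <- function() {
  audio_class_params(f0_mean = 120, f0_sd = 8, energy_mod_rate = 2,
                     pause_fraction = 0.35)
}

# One synthetic recording; assumes the RNG is already seeded.
synth_recording <- function(params, sample_rate) {
  n <- round(params$duration_s * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  f0 <- max(40, stats::rnorm(1, params$f0_mean, params$f0_sd))
  x <- numeric(n)
  for (h in seq_len(params$n_harmonics)) {
    x <- x + sin(2 * pi * h * f0 * t + stats::runif(1, 0, 2 * pi)) / h
  }
  # energy modulation with depth 0.9
  x <- x * (0.55 + 0.45 * sin(2 * pi * params$energy_mod_rate * t +
                                stats::runif(1, 0, 2 * pi)))
  if (params$pause_fraction > 0) {
    # one gap per quarter, random offset within its quarter: gaps never
    # overlap and total exactly pause_fraction (up to rounding)
    n_gaps <- 4L
    slot <- n %/% n_gaps
    gap_len <- round(params$pause_fraction * n / n_gaps)
    for (gi in seq_len(n_gaps)) {
      if (gap_len < 1L) break
      off <- floor(stats::runif(1, 0, slot - gap_len))
      from <- (gi - 1L) * slot + off + 1L
      x[from:(from + gap_len - 1L)] <- 0
    }
  }
  if (params$noise_sd > 0) x <- x + stats::rnorm(n, 0, params$noise_sd)
  audio_signal(0.95 * x / max(abs(x)), sample_rate)
}

#' Generate a labeled two-class synthetic audio dataset
#'
#' Fully reproducible from the seed. Optionally writes 16-bit PCM WAV
#' files plus a `manifest.csv` (`filename`, `label`).
#'
#' @param n_per_class Recordings per class.
#' @param params_class0,params_class1 [audio_class_params()] for the
#'   control (label 0) and case (label 1) classes.
#' @param sample_rate Sampling rate, Hz.
#' @param seed Integer seed.
#' @param out_dir Optional directory for WAV output.
#' @return Object of class `audio_dataset`: list with `signals` (list
#'   of [audio_signal()]), `labels`, `sample_rate`, and `manifest`
#'   (data frame; filenames filled when written).
#' @export
generate_audio_dataset <- function(n_per_class = 50,
                                   params_class0 = control_class_params(),
                                   params_class1 = case_class_params(),
                                   sample_rate = 16000, seed = 1,
                                   out_dir = NULL) {
  set.seed(as.integer(seed))
  n_total <- 2L * n_per_class
  labels <- rep(c(0L, 1L), n_per_class)   # interleaved, balanced
  signals <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    p <- if (labels[i] == 0L) params_class0 else params_class1
    signals[[i]] <- synth_recording(p, sample_rate)
  }
  manifest <- data.frame(
    filename = sprintf("rec%03d_class%d.wav", seq_len(n_total), labels),
    label = labels)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_len(n_total)) {
      write_wav(signals[[i]], file.path(out_dir, manifest$filename[i]))
    }
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  structure(list(signals = signals, labels = labels,
                 sample_rate = sample_rate, manifest = manifest,
                 seed = as.integer(seed)),
            class = "audio_dataset")
}

#' @export
print.audio_dataset <- function(x, ...) {
  cat(sprintf("<audio_dataset: %d recordings (%d per class) @ %d Hz>\n",
              length(x$signals), sum(x$labels == 0L), x$sample_rate))
  invisible(x)
}

#' Generate a labeled Gaussian feature table with known informative set
#'
#' `k` informative columns are `Normal(-delta/2, 1)` for class 0 and
#' `Normal(+delta/2, 1)` for class 1; the remaining `d - k` columns are
#' `Normal(0, 1)` regardless of class. The Gaussian design makes the
#' Bayes error analytic (per-feature d' = delta), which is what the
#' selection tests are calibrated against. Informative columns are
#' placed at seeded random positions and reported in the returned mask.
#'
#' @param n_per_class Rows per class.
#' @param d Total features.
#' @param k Informative features (`<= d`).
#' @param delta Class mean separation in noise-sd units.
#' @param seed Integer seed.
#' @return List: `table` (data frame, columns `f01..`, plus `label`),
#'   `informative` (logical ground-truth mask), `informative_names`.
#' @export
generate_feature_table <- function(n_per_class = 200, d = 30, k = 5,
                                   delta = 2, seed = 1) {
  if (k > d) stop("k must be <= d", call. = FALSE)
  if (delta < 0) stop("delta must be >= 0", call. = FALSE)
  set.seed(as.integer(seed))
  n <- 2L * n_per_class
  labels <- rep(c(0L, 1L), each = n_per_class)
  info_idx <- sort(sample.int(d, k))
  x <- matrix(stats::rnorm(n * d), n, d)
  shift <- ifelse(labels == 1L, delta / 2, -delta / 2)
  for (j in info_idx) x[, j] <- x[, j] + shift
  colnames(x) <- sprintf("f%02d", seq_len(d))
  tab <- as.data.frame(x)
  tab$label <- labels
  informative <- seq_len(d) %in% info_idx
  list(table = tab, informative = informative,
       informative_names = colnames(x)[informative])
}

#' Write a feature table as delimited text
#'
#' @param table Data frame with a `label` column.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Read a labeled feature table from delimited text
#'
#' @param path CSV path; header row of feature names, final column
#'   `label` in \{0, 1\}.
#' @return Data frame.
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.csv(path)
  if (!"label" %in% names(tab)) {
    stop("feature table must contain a `label` column", call. = FALSE)
  }
  tab
}
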