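#' MFCC extraction configuration
#'
#' Parameters of the Mel-frequency cepstral coefficient front end. The
#' defaults are the standard wideband-speech conventions: 25 ms Hamming
#' frames with a 10 ms hop, 512-point FFT, 0.97 pre-emphasis, 40
#' triangular Mel filters between 0 Hz and 8 kHz, and 13 retained
#' cepstral coefficients (coefficient 0, the frame log-energy proxy,
#' is kept — downstream feature selection can drop it).
#'
#' @param frame_length_ms Frame length in milliseconds.
#' @param hop_length_ms Hop (frame shift) in milliseconds; must not
#'   exceed the frame length.
#' @param n_fft FFT size; frames shorter than `n_fft` are zero-padded.
#' @param n_mels Number of Mel filters.
#' @param n_coeffs Number of retained cepstral coefficients
#'   (`<= n_mels`).
#' @param preemph Pre-emphasis coefficient in [0, 1).
#' @param fmin,fmax Filterbank frequency range in Hz.
#' @param log_floor Floor applied to Mel energies before the log, so
#'   silence maps to `log(log_floor)` instead of `-Inf`.
#' @return An object of class `mfcc_config`.
#' @export
mfcc_config <- function(frame_length_ms = 25, hop_length_ms = 10,
                        n_fft = 512, n_mels = 40, n_coeffs = 13,
                        preemph = 0.97, fmin = 0, fmax = 8000,
                        log_floor = 1e-10) {
  if (hop_length_ms > frame_length_ms) {
    stop("hop_length_ms must not exceed frame_length_ms", call. = FALSE)
  }
  if (n_coeffs > n_mels) stop("n_coeffs must be <= n_mels", call. = FALSE)
  if (preemph < 0 || preemph >= 1) stop("preemph must be in [0,1)", call. = FALSE)
  if (fmin >= fmax) stop("fmin must be < fmax", call. = FALSE)
  if (log_floor <= 0) stop("log_floor must be positive", call. = FALSE)
  structure(list(frame_length_ms = frame_length_ms,
                 hop_length_ms = hop_length_ms, n_fft = as.integer(n_fft),
                 n_mels = as.integer(n_mels), n_coeffs = as.integer(n_coeffs),
                 preemph = preemph, fmin = fmin, fmax = fmax,
                 log_floor = log_floor),
            class = "mfcc_config")
}

#' Pre-emphasis filter
#'
#' First-order high-pass difference `y[t] = x[t] - coeff * x[t-1]`
#' (with `y[1] = x[1]`), boosting high frequencies flattened by the
#' glottal spectral tilt.
#'
#' @param signal An [audio_signal()].
#' @param coeff Pre-emphasis coefficient in [0, 1); 0 is the identity.
#' @return A filtered [audio_signal()] of the same length.
#' @export
preemphasize <- function(signal, coeff = 0.97) {
  stopifnot(inherits(signal, "audio_signal"))
  if (coeff < 0 || coeff >= 1) stop("coeff must be in [0,1)", call. = FALSE)
  x <- signal$samples
  y <- c(x[1], x[-1] - coeff * x[-length(x)])
  audio_signal(y, signal$sample_rate)
}

mel_from_hz <- function(f) 2595 * log10(1 + f / 700)
hz_from_mel <- function(m) 700 * (10^(m / 2595) - 1)

#' Slice a signal into overlapping Hamming-windowed frames
#'
#' Frames start at multiples of the hop; no centering or edge padding
#' is applied, so the frame count is exactly
#' `floor((len - L) / H) + 1` for signals of at least one frame.
#'
#' @param signal An [audio_signal()].
#' @param cfg An [mfcc_config()].
#' @param window `"hamming"` (default) or `"rect"`.
#' @return A `T x L` matrix, one windowed frame per row.
#' @export
frame_signal <- function(signal, cfg = mfcc_config(), window = "hamming") {
  stopifnot(inherits(signal, "audio_signal"), inherits(cfg, "mfcc_config"))
  sr <- signal$sample_rate
  L <- as.integer(round(cfg$frame_length_ms * sr / 1000))
  H <- as.integer(round(cfg$hop_length_ms * sr / 1000))
  n <- length(signal$samples)
  if (n < L) {
    stop(sprintf("signal (%d samples) shorter than one frame (%d)", n, L),
         call. = FALSE)
  }
  n_frames <- (n - L) %/% H + 1L
  idx <- outer(seq_len(L), (seq_len(n_frames) - 1L) * H, `+`)  # L x T
  frames <- matrix(signal$samples[idx], nrow = L)
  w <- switch(window,
    hamming = 0.54 - 0.46 * cos(2 * pi * (seq_len(L) - 1) / (L - 1)),
    rect = rep(1, L),
    stop("unknown window: ", window, call. = FALSE))
  t(frames * w)
}

#' Single-sided power spectrum of framed audio
#'
#' `|FFT|^2 / n_fft` per frame, bins 0..n_fft/2. Frames shorter than
#' `n_fft` are zero-padded on the right.
#'
#' @param frames `T x L` frame matrix (rows are frames).
#' @param n_fft FFT size, `>=` frame length. Non-power-of-two sizes
#'   work but trigger a performance warning.
#' @return Non-negative `T x (n_fft/2 + 1)` matrix.
#' @export
power_spectrum <- function(frames, n_fft = 512) {
  if (!is.matrix(frames)) frames <- matrix(frames, nrow = 1)
  L <- ncol(frames)
  if (n_fft < L) stop("n_fft must be >= frame length", call. = FALSE)
  if (bitwAnd(n_fft, n_fft - 1L) != 0L) {
    warning("n_fft is not a power of two; FFT will be slower", call. = FALSE)
  }
  padded <- matrix(0, nrow = n_fft, ncol = nrow(frames))
  padded[seq_len(L), ] <- t(frames)
  spec <- stats::mvfft(padded)
  n_bins <- n_fft %/% 2L + 1L
  t(Mod(spec[seq_len(n_bins), , drop = FALSE])^2) / n_fft
}

#' Triangular Mel filterbank
#'
#' `n_mels` triangular filters with peaks uniformly spaced on the Mel
#' scale `m = 2595 log10(1 + f/700)` between `fmin` and `fmax`.
#' Triangle vertices are snapped to FFT bin indices (the HTK-style
#' integer-bin construction), so each interior filter's peak bin
#' carries zero weight in both neighboring filters.
#'
#' @param cfg An [mfcc_config()].
#' @param sample_rate Sampling rate in Hz.
#' @return `n_mels x (n_fft/2 + 1)` non-negative weight matrix.
#' @export
mel_filterbank <- function(cfg = mfcc_config(), sample_rate = 16000) {
  stopifnot(inherits(cfg, "mfcc_config"))
  if (cfg$fmax > sample_rate / 2) {
    stop("fmax must be <= sample_rate / 2", call. = FALSE)
  }
  n_bins <- cfg$n_fft %/% 2L + 1L
  mel_pts <- seq(mel_from_hz(cfg$fmin), mel_from_hz(cfg$fmax),
                 length.out = cfg$n_mels + 2L)
  bin <- floor((cfg$n_fft + 1L) * hz_from_mel(mel_pts) / sample_rate)
  bin <- pmin(bin, n_bins - 1L)  # 0-based bin indices
  fb <- matrix(0, nrow = cfg$n_mels, ncol = n_bins)
  for (m in seq_len(cfg$n_mels)) {
    lo <- bin[m]; mid <- bin[m + 1L]; hi <- bin[m + 2L]
    if (hi == lo) {
      stop(sprintf(paste0("Mel filter %d is empty: n_mels too large for ",
                          "the FFT resolution"), m), call. = FALSE)
    }
    if (mid > lo) fb[m, (lo:mid) + 1L] <- (lo:mid - lo) / (mid - lo)
    if (hi > mid) fb[m, (mid:hi) + 1L] <- (hi - mid:hi) / (hi - mid)
    fb[m, mid + 1L] <- 1  # peak (rising/falling edges both end at 1)
  }
  fb
}

#' Log Mel-band energies
#'
#' Applies the filterbank to a power spectrum and takes the natural log,
#' flooring energies at `log_floor` so silent frames stay finite.
#'
#' @param power_spec `T x n_bins` power-spectrum matrix.
#' @param filterbank `n_mels x n_bins` weight matrix.
#' @param log_floor Positive floor applied before the log.
#' @return `T x n_mels` matrix of finite log energies.
#' @export
log_mel_energies <- function(power_spec, filterbank, log_floor = 1e-10) {
  if (!is.matrix(power_spec)) power_spec <- matrix(power_spec, nrow = 1)
  if (ncol(power_spec) != ncol(filterbank)) {
    stop("power spectrum and filterbank bin counts differ", call. = FALSE)
  }
  log(pmax(power_spec %*% t(filterbank), log_floor))
}

#' Orthonormal DCT-II cepstra from log Mel energies
#'
#' Applies the orthonormal type-II discrete cosine transform along the
#' Mel axis and keeps the first `n_coeffs` coefficients, decorrelating
#' the bands and compacting the envelope.
#'
#' @param log_mel `T x n_mels` matrix.
#' @param n_coeffs Number of coefficients to keep (`<= n_mels`).
#' @return `T x n_coeffs` matrix.
#' @export
dct_cepstra <- function(log_mel, n_coeffs = 13) {
  if (!is.matrix(log_mel)) log_mel <- matrix(log_mel, nrow = 1)
  M <- ncol(log_mel)
  if (n_coeffs > M) stop("n_coeffs must be <= n_mels", call. = FALSE)
  log_mel %*% t(dct_matrix(M)[seq_len(n_coeffs), , drop = FALSE])
}

# Orthonormal DCT-II matrix (M x M); row i (0-based) has scale
# sqrt(1/M) for i = 0 and sqrt(2/M) otherwise.
dct_matrix <- function(M) {
  i <- 0:(M - 1)
  D <- sqrt(2 / M) * cos(pi / M * outer(i, i + 0.5))
  D[1, ] <- sqrt(1 / M)
  D
}

#' Extract an MFCC frame sequence from audio
#'
#' Full front end: pre-emphasis, Hamming framing, power spectrum, Mel
#' filterbank, log compression, orthonormal DCT-II. Deterministic for
#' fixed input and configuration.
#'
#' @param signal An [audio_signal()].
#' @param cfg An [mfcc_config()].
#' @return An object of class `feature_sequence`: list with `values`
#'   (`T x n_coeffs` matrix), `frame_times` (frame-center seconds),
#'   `sample_rate`, and the `config` snapshot.
#' @examples
#' sig <- audio_signal(sin(2 * pi * 220 * seq(0, 1, length.out = 16000)),
#'                     16000)
#' seq <- extract_mfcc(sig)
#' dim(seq$values)  # 98 x 13
#' @export
extract_mfcc <- function(signal, cfg = mfcc_config()) {
  stopifnot(inherits(signal, "audio_signal"), inherits(cfg, "mfcc_config"))
  sr <- signal$sample_rate
  pre <- preemphasize(signal, cfg$preemph)
  frames <- frame_signal(pre, cfg)
  ps <- power_spectrum(frames, cfg$n_fft)
  fb <- mel_filterbank(cfg, sr)
  lm <- log_mel_energies(ps, fb, cfg$log_floor)
  cep <- dct_cepstra(lm, cfg$n_coeffs)
  L <- round(cfg$frame_length_ms * sr / 1000)
  H <- round(cfg$hop_length_ms * sr / 1000)
  times <- ((seq_len(nrow(cep)) - 1) * H + L / 2) / sr
  structure(list(values = cep, frame_times = times, sample_rate = sr,
                 config = cfg),
            class = "feature_sequence")
}

#' @export
print.feature_sequence <- function(x, ...) {
  cat(sprintf("<feature_sequence: %d frames x %d coefficients>\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Recording-level functionals of an MFCC sequence
#'
#' Summarizes each cepstral coefficient track by mean, standard
#' deviation (denominator `T - 1`), min and max, giving a fixed-length
#' per-recording vector (`4 * n_coeffs` entries, coefficient-major)
#' for the wrapper feature selector's surrogate fitness.
#'
#' @param seq A `feature_sequence` (or bare `T x C` matrix).
#' @return Named numeric vector with entries like `c03_sd`.
#' @export
functionals <- function(seq) {
  values <- if (inherits(seq, "feature_sequence")) seq$values else seq
  if (!is.matrix(values)) stop("expected a feature sequence", call. = FALSE)
  if (nrow(values) < 2L) {
    stop("need at least 2 frames (sd undefined)", call. = FALSE)
  }
  stats_fun <- list(mean = colMeans,
                    sd = function(m) apply(m, 2, stats::sd),
                    min = function(m) apply(m, 2, min),
                    max = function(m) apply(m, 2, max))
  per_stat <- lapply(stats_fun, function(f) f(values))
  n_c <- ncol(values)
  out <- numeric(4L * n_c)
  nms <- character(4L * n_c)
  stat_names <- names(stats_fun)
  for (ci in seq_len(n_c)) {
    for (si in seq_along(stat_names)) {
      k <- (ci - 1L) * 4L + si
      out[k] <- per_stat[[si]][ci]
      nms[k] <- sprintf("c%02d_%s", ci - 1L, stat_names[si])
    }
  }
  names(out) <- nms
  out
}

#' Write a feature sequence or functional table as CSV
#'
#' @param x A `feature_sequence`, or a data frame of per-recording
#'   functionals.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(x, path) {
  if (inherits(x, "feature_sequence")) {
    df <- as.data.frame(x$values)
    names(df) <- sprintf("c%02d", seq_len(ncol(x$values)) - 1L)
    df <- cbind(time = x$frame_times, df)
  } else {
    df <- as.data.frame(x)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
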