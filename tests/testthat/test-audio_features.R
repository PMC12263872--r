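test_that("preemphasis implements the difference equation", {
  sig <- audio_signal(c(0.1, -0.2, 0.3), 16000)
  expect_equal(preemphasize(sig, 0)$samples, sig$samples)

  const <- preemphasize(audio_signal(rep(1, 5), 16000), 0.97)
  expect_equal(const$samples, c(1, rep(0.03, 4)))

  expect_equal(preemphasize(audio_signal(c(0, 1, 0), 8000), 0.5)$samples,
               c(0, 1, -0.5))
  expect_error(preemphasize(audio_signal(1, 8000), 1.0), "\\[0,1\\)")
  expect_error(audio_signal(numeric(0), 16000), "non-empty")
})

test_that("framing count matches the closed form", {
  cfg <- mfcc_config()  # 400-sample frames, 160 hop at 16 kHz
  f <- frame_signal(audio_signal(rnorm(16000), 16000), cfg)
  expect_equal(dim(f), c(98L, 400L))

  # exactly one frame at the boundary
  f1 <- frame_signal(audio_signal(rnorm(400), 16000), cfg)
  expect_equal(nrow(f1), 1L)

  # no overlap when hop = frame length
  cfg2 <- mfcc_config(frame_length_ms = 25, hop_length_ms = 25)
  expect_equal(nrow(frame_signal(audio_signal(rnorm(1200), 16000), cfg2)), 3L)

  expect_error(frame_signal(audio_signal(rnorm(399), 16000), cfg),
               "shorter than one frame")
})

test_that("frame count law holds across random (len, L, H)", {
  set.seed(21)
  for (i in 1:30) {
    L_ms <- sample(10:40, 1)
    H_ms <- sample(5:L_ms, 1)
    sr <- 8000
    L <- round(L_ms * sr / 1000); H <- round(H_ms * sr / 1000)
    len <- L + sample(0:4000, 1)
    f <- frame_signal(audio_signal(rnorm(len), sr),
                      mfcc_config(frame_length_ms = L_ms, hop_length_ms = H_ms))
    expect_equal(nrow(f), (len - L) %/% H + 1)
  }
})

test_that("power spectrum matches the DFT definition and is homogeneous", {
  expect_equal(power_spectrum(matrix(0, 1, 64), 64),
               matrix(0, 1, 33))

  # bin-centered sinusoid concentrates in its bin (rectangular window)
  sr <- 1600; n_fft <- 128
  f0 <- 10 * sr / n_fft  # exactly bin 10
  x <- sin(2 * pi * f0 * (0:(n_fft - 1)) / sr)
  ps <- power_spectrum(matrix(x, 1), n_fft)
  expect_equal(which.max(ps[1, ]) - 1L, 10L)
  expect_equal(ps[1, ], oracle_power_spectrum(x, n_fft), tolerance = 1e-10)

  # |.|^2 homogeneity
  fr <- matrix(rnorm(64), 1)
  expect_equal(power_spectrum(3 * fr, 64), 9 * power_spectrum(fr, 64))

  expect_warning(power_spectrum(matrix(rnorm(60), 1), 60), "power of two")
  expect_error(power_spectrum(matrix(rnorm(80), 1), 64), ">= frame length")
})

test_that("mel filterbank geometry: scale, support, neighbor overlap", {
  expect_equal(swarmspeech:::mel_from_hz(0), 0)
  expect_equal(swarmspeech:::mel_from_hz(700), 2595 * log10(2))

  cfg <- mfcc_config()
  fb <- mel_filterbank(cfg, 16000)
  expect_equal(dim(fb), c(40L, 257L))
  expect_true(all(fb >= 0))
  for (m in 1:40) {
    support <- which(fb[m, ] > 0)
    expect_true(length(support) >= 1)
    expect_equal(support, support[1]:support[length(support)])  # interval
  }
  # interior filter peaks: zero weight in both neighbors, 1 in its own row
  for (m in 2:39) {
    peak <- which.max(fb[m, ])
    expect_equal(fb[m, peak], 1)
    expect_equal(fb[m - 1, peak], 0)
    expect_equal(fb[m + 1, peak], 0)
  }
  expect_error(mel_filterbank(mfcc_config(n_fft = 64, n_mels = 40), 16000),
               "empty")
})

test_that("log mel energies floor silence and respect homomorphisms", {
  cfg <- mfcc_config()
  fb <- mel_filterbank(cfg, 16000)
  silent <- matrix(0, 2, 257)
  lm <- log_mel_energies(silent, fb, 1e-10)
  expect_true(all(lm == log(1e-10)))

  set.seed(2)
  ps <- matrix(abs(rnorm(2 * 257)), 2)
  expect_equal(log_mel_energies(2 * ps, fb, 1e-30),
               log_mel_energies(ps, fb, 1e-30) + log(2))

  # unit energy in a single bin under one filter -> log of that weight
  m <- 20L
  peak <- which.max(fb[m, ])
  ps1 <- matrix(0, 1, 257); ps1[1, peak] <- 1
  expect_equal(log_mel_energies(ps1, fb, 1e-30)[1, m], log(fb[m, peak]))
})

test_that("orthonormal DCT: constants, invertibility, energy-scale shift", {
  M <- 40
  lm <- matrix(3.5, 1, M)
  cep <- dct_cepstra(lm, 13)
  expect_equal(cep[1, 1], 3.5 * sqrt(M))
  expect_equal(cep[1, -1], rep(0, 12))

  # full DCT is orthonormal: D^T D = I, so round trip reproduces input
  D <- swarmspeech:::dct_matrix(M)
  expect_equal(crossprod(D), diag(M), tolerance = 1e-12)
  set.seed(3)
  lm <- matrix(rnorm(2 * M), 2)
  expect_equal(dct_cepstra(lm, M) %*% D, lm, tolerance = 1e-12)

  expect_error(dct_cepstra(lm, M + 1), "<= n_mels")
})

test_that("waveform gain shifts only coefficient 0", {
  cfg <- mfcc_config(log_floor = 1e-30)
  set.seed(31)
  x <- runif(3200, -0.08, 0.08)
  base <- extract_mfcc(audio_signal(x, 16000), cfg)$values
  for (g in c(0.5, 2, 10)) {
    scaled <- extract_mfcc(audio_signal(g * x, 16000), cfg)$values
    expect_equal(scaled[, -1], base[, -1], tolerance = 1e-6)
    expect_equal(scaled[, 1] - base[, 1],
                 rep(sqrt(cfg$n_mels) * log(g^2), nrow(base)),
                 tolerance = 1e-6)
  }
})

test_that("full pipeline matches the from-first-principles oracle", {
  cfg <- mfcc_config()
  set.seed(32)
  for (i in 1:3) {
    x <- runif(2000, -1, 1)
    mine <- extract_mfcc(audio_signal(x, 16000), cfg)$values
    ref <- oracle_mfcc(x, 16000, cfg)
    expect_equal(mine, ref, tolerance = 1e-8)
  }
})

test_that("extract_mfcc is deterministic with contract shapes", {
  sig <- audio_signal(sin(2 * pi * 150 * (0:15999) / 16000), 16000)
  a <- extract_mfcc(sig)
  b <- extract_mfcc(sig)
  expect_identical(a$values, b$values)
  expect_equal(dim(a$values), c(98L, 13L))

  cfg <- mfcc_config(n_coeffs = 7, n_mels = 24)
  expect_equal(ncol(extract_mfcc(sig, cfg)$values), 7L)
})

test_that("outputs stay finite on adversarial inputs", {
  sr <- 16000
  adversarial <- list(
    silence = rep(0, 8000),
    impulse = c(1, rep(0, 7999)),
    square = rep(c(1, -1), each = 40, length.out = 8000))
  for (x in adversarial) {
    v <- extract_mfcc(audio_signal(x, sr))$values
    expect_true(all(is.finite(v)))
  }
})

test_that("functionals summarize coefficient tracks coefficient-major", {
  const <- matrix(2, 10, 3)
  fv <- functionals(const)
  expect_equal(unname(fv[c("c00_mean", "c00_sd", "c00_min", "c00_max")]),
               c(2, 0, 2, 2))

  seq13 <- structure(list(values = matrix(rnorm(20 * 13), 20, 13)),
                     class = "feature_sequence")
  fv <- functionals(seq13)
  expect_length(fv, 52)
  expect_equal(names(fv)[1:5],
               c("c00_mean", "c00_sd", "c00_min", "c00_max", "c01_mean"))

  # order-free statistics
  m <- matrix(rnorm(30), 10, 3)
  expect_equal(functionals(m), functionals(m[sample(10), , drop = FALSE]))

  expect_error(functionals(matrix(1, 1, 3)), "at least 2 frames")
})

test_that("WAV files round-trip through write_wav/read_wav", {
  set.seed(41)
  x <- runif(800, -0.9, 0.9)
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(audio_signal(x, 8000), path)
  back <- read_wav(path)
  expect_equal(back$sample_rate, 8000L)
  expect_equal(back$samples, x, tolerance = 1e-4)  # 16-bit quantization
})
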