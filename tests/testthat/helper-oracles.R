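# Independent oracles used across the suite. These deliberately share no
# code with the package: the DFT is the literal cos/sin definition, the
# Mel triangles and DCT are written out from their formulas, and the
# metrics reference is scikit-learn called through the system python.

# Brute-force DFT power spectrum of one frame (explicit basis matrices).
oracle_power_spectrum <- function(frame, n_fft) {
  fr <- numeric(n_fft)
  fr[seq_along(frame)] <- frame
  k <- 0:(n_fft / 2)
  n <- 0:(n_fft - 1)
  re <- cos(-2 * pi * outer(k, n) / n_fft) %*% fr
  im <- sin(-2 * pi * outer(k, n) / n_fft) %*% fr
  drop(re^2 + im^2) / n_fft
}

# Full from-first-principles MFCC chain (loops and explicit formulas).
oracle_mfcc <- function(x, sr, cfg) {
  y <- x
  for (t in length(x):2) y[t] <- x[t] - cfg$preemph * x[t - 1]
  L <- round(cfg$frame_length_ms * sr / 1000)
  H <- round(cfg$hop_length_ms * sr / 1000)
  n_frames <- floor((length(y) - L) / H) + 1
  ham <- 0.54 - 0.46 * cos(2 * pi * (0:(L - 1)) / (L - 1))
  nb <- cfg$n_fft / 2 + 1
  mel <- function(f) 2595 * log10(1 + f / 700)
  imel <- function(m) 700 * (10^(m / 2595) - 1)
  pts <- seq(mel(cfg$fmin), mel(cfg$fmax), length.out = cfg$n_mels + 2)
  bins <- pmin(floor((cfg$n_fft + 1) * imel(pts) / sr), nb - 1)
  fb <- matrix(0, cfg$n_mels, nb)
  for (m in 1:cfg$n_mels) {
    for (kk in 0:(nb - 1)) {
      if (kk >= bins[m] && kk <= bins[m + 1] && bins[m + 1] > bins[m]) {
        fb[m, kk + 1] <- (kk - bins[m]) / (bins[m + 1] - bins[m])
      }
      if (kk >= bins[m + 1] && kk <= bins[m + 2] &&
            bins[m + 2] > bins[m + 1]) {
        fb[m, kk + 1] <- (bins[m + 2] - kk) / (bins[m + 2] - bins[m + 1])
      }
      if (kk == bins[m + 1]) fb[m, kk + 1] <- 1
    }
  }
  M <- cfg$n_mels
  out <- matrix(0, n_frames, cfg$n_coeffs)
  for (ti in 1:n_frames) {
    seg <- y[((ti - 1) * H + 1):((ti - 1) * H + L)] * ham
    ps <- oracle_power_spectrum(seg, cfg$n_fft)
    lm <- log(pmax(drop(fb %*% ps), cfg$log_floor))
    for (ci in 0:(cfg$n_coeffs - 1)) {
      scale <- if (ci == 0) sqrt(1 / M) else sqrt(2 / M)
      out[ti, ci + 1] <- scale * sum(lm * cos(pi / M * ((0:(M - 1)) + 0.5) * ci))
    }
  }
  out
}

# Macro precision/recall/F1 for a batch of label-vector pairs via
# scikit-learn (one python process for the whole batch). `cases` is a
# list of list(y_true, y_pred); returns a (n_cases x 3) matrix.
sklearn_macro_prf <- function(cases) {
  df <- do.call(rbind, lapply(seq_along(cases), function(i) {
    data.frame(case = i, yt = cases[[i]]$y_true, yp = cases[[i]]$y_pred)
  }))
  inp <- tempfile(fileext = ".csv")
  outp <- tempfile(fileext = ".csv")
  utils::write.csv(df, inp, row.names = FALSE)
  script <- paste0(
    "import pandas as pd\n",
    "from sklearn.metrics import precision_recall_fscore_support as prfs\n",
    "d = pd.read_csv('", inp, "')\n",
    "rows = []\n",
    "for c, g in d.groupby('case'):\n",
    "    p, r, f, _ = prfs(g.yt, g.yp, labels=[0, 1], average='macro',",
    " zero_division=0)\n",
    "    rows.append((c, p, r, f))\n",
    "pd.DataFrame(rows, columns=['case','p','r','f']).to_csv('", outp,
    "', index=False)\n")
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  status <- system2("python", sf, stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("python/sklearn oracle failed")
  res <- utils::read.csv(outp)
  res <- res[order(res$case), ]
  as.matrix(res[, c("p", "r", "f")])
}

# All non-empty masks of d features as a logical matrix (2^d - 1 rows).
all_masks <- function(d) {
  codes <- 1:(2^d - 1)
  t(vapply(codes, function(code) as.logical(bitwAnd(code, 2^(0:(d - 1)))),
           logical(d)))
}

# Random-search baseline: best sphere value over n uniform samples.
random_search_best <- function(objective, lower, upper, n, seed) {
  set.seed(seed)
  pts <- matrix(stats::runif(n * length(lower), rep(lower, each = n),
                             rep(upper, each = n)), nrow = n)
  min(apply(pts, 1, objective))
}

sphere <- function(x) sum(x^2)

make_config <- function(kind, pop, iters) {
  switch(kind,
         dragonfly = da_config(pop, iters),
         firefly = fa_config(pop, iters),
         mothflame = mfo_config(pop, iters))
}
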