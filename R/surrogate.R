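# Ridge-regularized logistic regression fit by IRLS. Small, dependency-free
# and microsecond-fast for the d <= 10^2 problems the wrapper generates;
# the intercept is unpenalized. Used as the default surrogate fitness
# classifier inside the feature-selection loop.
ridge_logistic_fit <- function(x, y, lambda = 1e-2, max_iter = 30,
                               tol = 1e-8) {
  x <- as.matrix(x)
  n <- nrow(x); d <- ncol(x)
  if (length(unique(y)) < 2L) stop("single-class training set", call. = FALSE)
  xm <- colMeans(x)
  xs <- apply(x, 2, stats::sd)
  xs[xs == 0] <- 1
  xz <- sweep(sweep(x, 2, xm, `-`), 2, xs, `/`)
  X <- cbind(1, xz)
  beta <- numeric(d + 1L)
  pen <- diag(c(0, rep(lambda, d)), d + 1L)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-6)
    # penalized Newton step on the standardized design
    g <- crossprod(X, y - p) - pen %*% beta
    H <- crossprod(X * w, X) + pen
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  list(beta = beta, center = xm, scale = xs)
}

ridge_logistic_predict <- function(fit, x) {
  x <- as.matrix(x)
  xz <- sweep(sweep(x, 2, fit$center, `-`), 2, fit$scale, `/`)
  stats::plogis(drop(cbind(1, xz) %*% fit$beta))
}

# Deterministic permutation of 1..n from an integer seed via a local
# linear congruential generator; never touches R's global RNG stream, so
# fitness evaluations stay pure functions of (mask, seed) even when
# called from inside an optimizer's RNG-driven loop.
seeded_permutation <- function(n, seed) {
  # Lehmer generator modulo the Mersenne prime 2^31 - 1; the product
  # 48271 * state stays below 2^53 so double arithmetic is exact.
  state <- (abs(as.numeric(seed)) %% 2147483646) + 1
  keys <- numeric(n)
  for (i in seq_len(n)) {
    state <- (48271 * state) %% 2147483647
    keys[i] <- state
  }
  order(keys)
}

# Stratified fold assignment: within each class, rows are permuted
# deterministically from the seed and dealt round-robin to folds.
stratified_folds <- function(y, k, seed) {
  folds <- integer(length(y))
  for (cl in sort(unique(y))) {
    idx <- which(y == cl)
    perm <- idx[seeded_permutation(length(idx), seed + as.numeric(cl))]
    folds[perm] <- rep_len(seq_len(k), length(perm))
  }
  folds
}
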