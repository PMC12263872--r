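# Minimal dependency-free neural-network primitives for the 1D-CNN + LSTM
# classifier: forward passes with caches, manual backpropagation, and Adam.
# Batches are (B, T, C) arrays; all time-distributed dense algebra is done
# on (B*T, C) matrix views so everything vectorizes across batch and time.
#
# No deep-learning backend is available in the target environment, which is
# why these ~400 lines exist; correctness is pinned by numerical-gradient
# tests (tests/testthat/test-classifier.R).

as_bt_matrix <- function(X) {
  d <- dim(X)
  dim(X) <- c(d[1] * d[2], d[3])
  X
}

as_btc_array <- function(M, B, T) {
  dim(M) <- c(B, T, ncol(M))
  M
}

conv1d_fwd <- function(X, W, b) {
  d <- dim(X); B <- d[1]; T <- d[2]; Cin <- d[3]
  K <- dim(W)[1]; Cout <- dim(W)[3]
  pad_l <- (K - 1L) %/% 2L
  Xp <- array(0, c(B, T + K - 1L, Cin))
  Xp[, pad_l + seq_len(T), ] <- X
  out <- matrix(b, B * T, Cout, byrow = TRUE)
  for (k in seq_len(K)) {
    Xk <- Xp[, k:(k + T - 1L), , drop = FALSE]
    dim(Xk) <- c(B * T, Cin)
    out <- out + Xk %*% matrix(W[k, , ], Cin, Cout)
  }
  list(out = as_btc_array(out, B, T), Xp = Xp)
}

conv1d_bwd <- function(dOut, Xp, W) {
  d <- dim(dOut); B <- d[1]; T <- d[2]; Cout <- d[3]
  K <- dim(W)[1]; Cin <- dim(W)[2]
  dM <- as_bt_matrix(dOut)
  dW <- array(0, dim(W))
  dXp <- array(0, dim(Xp))
  for (k in seq_len(K)) {
    Xk <- Xp[, k:(k + T - 1L), , drop = FALSE]
    dim(Xk) <- c(B * T, Cin)
    dW[k, , ] <- crossprod(Xk, dM)
    dXk <- dM %*% t(matrix(W[k, , ], Cin, Cout))
    dim(dXk) <- c(B, T, Cin)
    dXp[, k:(k + T - 1L), ] <- dXp[, k:(k + T - 1L), , drop = FALSE] + dXk
  }
  pad_l <- (K - 1L) %/% 2L
  list(dX = dXp[, pad_l + seq_len(T), , drop = FALSE], dW = dW,
       db = colSums(dM))
}

relu_fwd <- function(X) {
  mask <- X > 0
  X[!mask] <- 0
  list(out = X, mask = mask)
}

# Max pooling over time; trailing frames that do not fill a block are
# dropped. p = 1 is the identity.
maxpool_fwd <- function(X, p) {
  if (p == 1L) return(list(out = X, arg = NULL, Tin = dim(X)[2]))
  d <- dim(X); B <- d[1]; T <- d[2]; C <- d[3]
  Tn <- T %/% p
  out <- X[, seq(1L, Tn * p, by = p), , drop = FALSE]
  arg <- array(1L, dim(out))
  for (j in 2:p) {
    Sj <- X[, seq(j, Tn * p, by = p), , drop = FALSE]
    upd <- Sj > out
    out[upd] <- Sj[upd]
    arg[upd] <- j
  }
  list(out = out, arg = arg, Tin = T)
}

maxpool_bwd <- function(dOut, pool, p) {
  if (p == 1L) return(dOut)
  d <- dim(dOut); B <- d[1]; Tn <- d[2]; C <- d[3]
  dX <- array(0, c(B, pool$Tin, C))
  for (j in seq_len(p)) {
    mask <- pool$arg == j
    slice <- array(0, dim(dOut))
    slice[mask] <- dOut[mask]
    dX[, seq(j, Tn * p, by = p), ] <- slice
  }
  dX
}

dropout_fwd <- function(X, rate, training) {
  if (!training || rate == 0) return(list(out = X, mask = NULL))
  keep <- 1 - rate
  mask <- array(stats::runif(length(X)) < keep, dim(X)) / keep
  list(out = X * mask, mask = mask)
}

bn_fwd <- function(X, gamma, beta, run_mean, run_var, training,
                   momentum = 0.9, eps = 1e-5) {
  d <- dim(X); B <- d[1]; T <- d[2]; C <- d[3]
  M <- as_bt_matrix(X)
  if (training) {
    mu <- colMeans(M)
    ctr <- sweep(M, 2, mu)
    v <- colMeans(ctr^2)
    run_mean <- momentum * run_mean + (1 - momentum) * mu
    run_var <- momentum * run_var + (1 - momentum) * v
  } else {
    mu <- run_mean; v <- run_var
    ctr <- sweep(M, 2, mu)
  }
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- sweep(ctr, 2, inv_sd, `*`)
  out <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  list(out = as_btc_array(out, B, T), xhat = xhat, inv_sd = inv_sd,
       run_mean = run_mean, run_var = run_var)
}

bn_bwd <- function(dOut, cache, gamma) {
  d <- dim(dOut); B <- d[1]; T <- d[2]
  dY <- as_bt_matrix(dOut)
  xhat <- cache$xhat
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dxhat <- sweep(dY, 2, gamma, `*`)
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * xhat)
  dX <- sweep(dxhat, 2, m1) - sweep(xhat, 2, m2, `*`)
  dX <- sweep(dX, 2, cache$inv_sd, `*`)
  list(dX = as_btc_array(dX, B, T), dgamma = dgamma, dbeta = dbeta)
}

# Sequence-preserving temporal average pooling by integer factor f;
# f = "global" averages the whole time axis to a length-1 sequence
# (the literal global-average-pooling reading).
avgpool_fwd <- function(X, f) {
  d <- dim(X); T <- d[2]
  if (identical(f, "global")) f <- T
  f <- as.integer(f)
  if (f == 1L) return(list(out = X, f = 1L, Tin = T))
  Tn <- T %/% f
  acc <- X[, seq(1L, Tn * f, by = f), , drop = FALSE]
  for (j in 2:f) acc <- acc + X[, seq(j, Tn * f, by = f), , drop = FALSE]
  list(out = acc / f, f = f, Tin = T)
}

avgpool_bwd <- function(dOut, pool) {
  f <- pool$f
  if (f == 1L) return(dOut)
  d <- dim(dOut); B <- d[1]; Tn <- d[2]; C <- d[3]
  dX <- array(0, c(B, pool$Tin, C))
  for (j in seq_len(f)) dX[, seq(j, Tn * f, by = f), ] <- dOut / f
  dX
}

# LSTM with gate order (input, forget, cell, output) packed in columns
# of Wx (Cin x 4u), Wh (u x 4u), b (4u).
lstm_fwd <- function(X, Wx, Wh, b) {
  d <- dim(X); B <- d[1]; T <- d[2]
  u <- ncol(Wh) %/% 4L
  H <- matrix(0, B, u); Cc <- matrix(0, B, u)
  gates <- array(0, c(B, T, 4L * u))
  Cs <- array(0, c(B, T, u)); Hs <- array(0, c(B, T, u))
  tanhCs <- array(0, c(B, T, u))
  for (t in seq_len(T)) {
    z <- matrix(X[, t, ], B) %*% Wx + H %*% Wh + matrix(b, B, 4L * u,
                                                        byrow = TRUE)
    i <- stats::plogis(z[, 1:u, drop = FALSE])
    f <- stats::plogis(z[, u + 1:u, drop = FALSE])
    g <- tanh(z[, 2L * u + 1:u, drop = FALSE])
    o <- stats::plogis(z[, 3L * u + 1:u, drop = FALSE])
    Cc <- f * Cc + i * g
    tC <- tanh(Cc)
    H <- o * tC
    gates[, t, ] <- cbind(i, f, g, o)
    Cs[, t, ] <- Cc; Hs[, t, ] <- H; tanhCs[, t, ] <- tC
  }
  list(out = Hs, gates = gates, Cs = Cs, tanhCs = tanhCs)
}

# dHs: (B, T, u) gradient on the hidden-state sequence (zero-filled
# except the last step when only the final state is consumed).
lstm_bwd <- function(dHs, cache, X, Wx, Wh) {
  d <- dim(X); B <- d[1]; T <- d[2]; Cin <- d[3]
  u <- ncol(Wh) %/% 4L
  dWx <- matrix(0, Cin, 4L * u); dWh <- matrix(0, u, 4L * u)
  db <- numeric(4L * u)
  dX <- array(0, dim(X))
  dH_next <- matrix(0, B, u); dC_next <- matrix(0, B, u)
  for (t in rev(seq_len(T))) {
    i <- matrix(cache$gates[, t, 1:u], B)
    f <- matrix(cache$gates[, t, u + 1:u], B)
    g <- matrix(cache$gates[, t, 2L * u + 1:u], B)
    o <- matrix(cache$gates[, t, 3L * u + 1:u], B)
    tC <- matrix(cache$tanhCs[, t, ], B)
    Cprev <- if (t > 1L) matrix(cache$Cs[, t - 1L, ], B) else matrix(0, B, u)
    Hprev <- if (t > 1L) matrix(cache$out[, t - 1L, ], B) else matrix(0, B, u)
    dH <- matrix(dHs[, t, ], B) + dH_next
    dC <- dH * o * (1 - tC^2) + dC_next
    dz <- cbind((dC * g) * i * (1 - i),
                (dC * Cprev) * f * (1 - f),
                (dC * i) * (1 - g^2),
                (dH * tC) * o * (1 - o))
    dWx <- dWx + crossprod(matrix(X[, t, ], B), dz)
    dWh <- dWh + crossprod(Hprev, dz)
    db <- db + colSums(dz)
    dH_next <- dz %*% t(Wh)
    dC_next <- dC * f
    dX[, t, ] <- dz %*% t(Wx)
  }
  list(dX = dX, dWx = dWx, dWh = dWh, db = db)
}

glorot <- function(fan_in, fan_out, dims) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dims)
}

# Full forward pass. Returns probabilities plus every cache needed for
# backprop (cached only when `training`). Updates to batch-norm running
# statistics are returned in `bn_state`, not applied in place.
nn_forward <- function(model, X, training = FALSE) {
  p <- model$params
  spec <- model$spec
  bn_state <- model$bn_state
  caches <- list()
  h <- X
  for (l in 1:3) {
    cv <- conv1d_fwd(h, p[[paste0("conv", l, "_W")]],
                     p[[paste0("conv", l, "_b")]])
    rl <- relu_fwd(cv$out)
    mp <- maxpool_fwd(rl$out, spec$pool_size)
    dr <- dropout_fwd(mp$out, spec$dropout_rate, training)
    bs <- bn_state[[l]]
    bn <- bn_fwd(dr$out, p[[paste0("bn", l, "_gamma")]],
                 p[[paste0("bn", l, "_beta")]],
                 bs$mean, bs$var, training)
    bn_state[[l]] <- list(mean = bn$run_mean, var = bn$run_var)
    caches[[l]] <- list(conv = cv, relu = rl, pool = mp, drop = dr, bn = bn)
    h <- bn$out
  }
  ap <- avgpool_fwd(h, if (spec$literal_gap) "global" else
                         spec$temporal_pool_factor)
  l1 <- lstm_fwd(ap$out, p$lstm1_Wx, p$lstm1_Wh, p$lstm1_b)
  l2 <- lstm_fwd(l1$out, p$lstm2_Wx, p$lstm2_Wh, p$lstm2_b)
  Tn <- dim(l2$out)[2]
  hlast <- matrix(l2$out[, Tn, ], dim(X)[1])      # final state only
  d1 <- hlast %*% p$dense_W +
    matrix(p$dense_b, nrow(hlast), length(p$dense_b), byrow = TRUE)
  d1r <- relu_fwd(d1)
  logits <- drop(d1r$out %*% p$out_W + p$out_b)
  list(prob = stats::plogis(logits), logits = logits, caches = caches,
       avg = ap, lstm1 = l1, lstm2 = l2, hlast = hlast, d1r = d1r,
       conv_in = X, bn_state = bn_state)
}

# Backward pass from d(loss)/d(logits); returns gradients named like the
# trainable parameters.
nn_backward <- function(model, fw, dlogits) {
  p <- model$params
  spec <- model$spec
  g <- list()
  B <- length(dlogits)
  dlog <- matrix(dlogits, B, 1)
  g$out_W <- crossprod(fw$d1r$out, dlog)
  g$out_b <- sum(dlog)
  dd1 <- dlog %*% t(p$out_W)
  dd1[!fw$d1r$mask] <- 0
  g$dense_W <- crossprod(fw$hlast, dd1)
  g$dense_b <- colSums(dd1)
  dhlast <- dd1 %*% t(p$dense_W)

  Tn <- dim(fw$lstm2$out)[2]
  dHs2 <- array(0, dim(fw$lstm2$out))
  dHs2[, Tn, ] <- dhlast
  b2 <- lstm_bwd(dHs2, fw$lstm2, fw$lstm1$out, p$lstm2_Wx, p$lstm2_Wh)
  g$lstm2_Wx <- b2$dWx; g$lstm2_Wh <- b2$dWh; g$lstm2_b <- b2$db
  b1 <- lstm_bwd(b2$dX, fw$lstm1, fw$avg$out, p$lstm1_Wx, p$lstm1_Wh)
  g$lstm1_Wx <- b1$dWx; g$lstm1_Wh <- b1$dWh; g$lstm1_b <- b1$db

  dh <- avgpool_bwd(b1$dX, fw$avg)
  for (l in 3:1) {
    cc <- fw$caches[[l]]
    bb <- bn_bwd(dh, cc$bn, p[[paste0("bn", l, "_gamma")]])
    g[[paste0("bn", l, "_gamma")]] <- bb$dgamma
    g[[paste0("bn", l, "_beta")]] <- bb$dbeta
    dh <- bb$dX
    if (!is.null(cc$drop$mask)) dh <- dh * cc$drop$mask
    dh <- maxpool_bwd(dh, cc$pool, spec$pool_size)
    dh[!cc$relu$mask] <- 0
    cv <- conv1d_bwd(dh, cc$conv$Xp, p[[paste0("conv", l, "_W")]])
    g[[paste0("conv", l, "_W")]] <- cv$dW
    g[[paste0("conv", l, "_b")]] <- cv$db
    dh <- cv$dX
  }
  g
}

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0L)
}

adam_update <- function(params, grads, state, lr, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gnm <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gnm
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gnm^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / corr1) / (sqrt(state$v[[nm]] / corr2) + eps)
  }
  list(params = params, state = state)
}

# Weighted binary cross-entropy on logits (numerically stable) and its
# gradient; weights are normalized to sum to 1 within the batch.
bce_loss <- function(logits, y, w) {
  w <- w / sum(w)
  # log(1 + exp(z)) - y z, computed stably
  loss <- sum(w * (pmax(logits, 0) - y * logits +
                     log1p(exp(-abs(logits)))))
  dlogits <- w * (stats::plogis(logits) - y)
  list(loss = loss, dlogits = dlogits)
}
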