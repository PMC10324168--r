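# Internal neural-network engine for the victim models: dense / LSTM /
# temporal-convolution heads in R (BLAS), 3x3 conv + 2x2 pool in C++.
# Everything is deterministic given the R RNG state.

he_mat <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
}

relu_fwd <- function(x) {
  x[x < 0] <- 0
  x
}

dense_fwd <- function(W, b, X) crossprod(W, X) + b  # (Dout x N)
dense_bwd <- function(W, X, dY) {
  list(dW = X %*% t(dY), db = rowSums(dY), dX = W %*% dY)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

lstm_fwd <- function(Wx, Wh, b, F3) {
  # F3: (D, T, N); returns last hidden state (Hd x N) + cache
  D <- dim(F3)[1]; Tn <- dim(F3)[2]; N <- dim(F3)[3]
  Hd <- nrow(Wh)
  h <- matrix(0, Hd, N); cc <- matrix(0, Hd, N)
  cache <- vector("list", Tn)
  gi <- seq_len(Hd); gf <- Hd + gi; gg <- 2L * Hd + gi; go <- 3L * Hd + gi
  for (t in seq_len(Tn)) {
    xt <- matrix(F3[, t, ], D, N)
    z <- crossprod(Wx, xt) + crossprod(Wh, h) + b
    i <- sigmoid(z[gi, , drop = FALSE]); f <- sigmoid(z[gf, , drop = FALSE])
    g <- tanh(z[gg, , drop = FALSE]);    o <- sigmoid(z[go, , drop = FALSE])
    c_prev <- cc
    cc <- f * c_prev + i * g
    tc <- tanh(cc)
    h_prev <- h
    h <- o * tc
    cache[[t]] <- list(xt = xt, i = i, f = f, g = g, o = o,
                       c_prev = c_prev, cc = cc, tc = tc, h_prev = h_prev)
  }
  list(h = h, cache = cache, dims = c(D, Tn, N))
}

lstm_bwd <- function(Wx, Wh, fw, dh_last) {
  D <- fw$dims[1]; Tn <- fw$dims[2]; N <- fw$dims[3]
  Hd <- nrow(Wh)
  gi <- seq_len(Hd); gf <- Hd + gi; gg <- 2L * Hd + gi; go <- 3L * Hd + gi
  dWx <- matrix(0, nrow(Wx), ncol(Wx)); dWh <- matrix(0, Hd, 4L * Hd)
  db <- numeric(4L * Hd)
  dF3 <- array(0, c(D, Tn, N))
  dh <- dh_last; dc <- matrix(0, Hd, N)
  for (t in rev(seq_len(Tn))) {
    cs <- fw$cache[[t]]
    do_ <- dh * cs$tc
    dct <- dc + dh * cs$o * (1 - cs$tc^2)
    di <- dct * cs$g; df <- dct * cs$c_prev; dg <- dct * cs$i
    dz <- matrix(0, 4L * Hd, N)
    dz[gi, ] <- di * cs$i * (1 - cs$i)
    dz[gf, ] <- df * cs$f * (1 - cs$f)
    dz[gg, ] <- dg * (1 - cs$g^2)
    dz[go, ] <- do_ * cs$o * (1 - cs$o)
    dWx <- dWx + cs$xt %*% t(dz)
    dWh <- dWh + cs$h_prev %*% t(dz)
    db <- db + rowSums(dz)
    dF3[, t, ] <- Wx %*% dz
    dh <- Wh %*% dz
    dc <- dct * cs$f
  }
  list(dWx = dWx, dWh = dWh, db = db, dF3 = dF3)
}

tconv_fwd <- function(Wt, bt, F3) {
  # width-3 1-D convolution over the slice axis, zero padded; relu
  D <- dim(F3)[1]; Tn <- dim(F3)[2]; N <- dim(F3)[3]
  nf <- ncol(Wt)
  Y <- array(0, c(nf, Tn, N))
  X0 <- matrix(0, D, N)
  win <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    xm <- if (t > 1) matrix(F3[, t - 1, ], D, N) else X0
    x0 <- matrix(F3[, t, ], D, N)
    xp <- if (t < Tn) matrix(F3[, t + 1, ], D, N) else X0
    w3 <- rbind(xm, x0, xp)
    win[[t]] <- w3
    Y[, t, ] <- relu_fwd(crossprod(Wt, w3) + bt)
  }
  list(Y = Y, win = win, dims = c(D, Tn, N))
}

tconv_bwd <- function(Wt, fw, dY) {
  D <- fw$dims[1]; Tn <- fw$dims[2]; N <- fw$dims[3]
  dWt <- matrix(0, nrow(Wt), ncol(Wt)); dbt <- numeric(ncol(Wt))
  dF3 <- array(0, c(D, Tn, N))
  for (t in seq_len(Tn)) {
    dyt <- matrix(dY[, t, ], ncol(Wt), N)
    dyt[fw$Y[, t, , drop = FALSE] <= 0] <- 0
    dWt <- dWt + fw$win[[t]] %*% t(dyt)
    dbt <- dbt + rowSums(dyt)
    dw3 <- Wt %*% dyt
    if (t > 1) dF3[, t - 1, ] <- dF3[, t - 1, ] + dw3[seq_len(D), ]
    dF3[, t, ] <- dF3[, t, ] + dw3[D + seq_len(D), ]
    if (t < Tn) dF3[, t + 1, ] <- dF3[, t + 1, ] + dw3[2L * D + seq_len(D), ]
  }
  list(dWt = dWt, dbt = dbt, dF3 = dF3)
}

softmax_rows <- function(Z) {
  # Z: (K x N) logits -> probabilities, columnwise
  Zm <- sweep(Z, 2, apply(Z, 2, max))
  E <- exp(Zm)
  sweep(E, 2, colSums(E), "/")
}

xent_loss <- function(logits, y) {
  P <- softmax_rows(logits)
  N <- ncol(P)
  eps <- 1e-12
  loss <- -mean(log(pmax(P[cbind(y, seq_len(N))], eps)))
  dZ <- P
  dZ[cbind(y, seq_len(N))] <- dZ[cbind(y, seq_len(N))] - 1
  list(loss = loss, P = P, dZ = dZ / N)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, betas, eps = 1e-8, l2 = 0) {
  state$t <- state$t + 1L
  b1 <- betas[1]; b2 <- betas[2]
  bc1 <- 1 - b1^state$t; bc2 <- 1 - b2^state$t
  for (k in names(params)) {
    g <- grads[[k]]
    if (l2 > 0 && !grepl("^b", k)) g <- g + l2 * params[[k]]
    state$m[[k]] <- b1 * state$m[[k]] + (1 - b1) * g
    state$v[[k]] <- b2 * state$v[[k]] + (1 - b2) * g^2
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(params = params, state = state)
}
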