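# Minimal dense/convolutional/recurrent network engine used by the activity
# classifier. Everything is vectorised base R over batch-major arrays:
# convolutional activations are (batch, height, width, channels) arrays,
# sequences are (batch, time, features). Convolution padding and output-size
# semantics follow the 'same' convention: out = ceil(in / stride), zero
# padding appended at the trailing edge.

sigmoid <- function(x) 1 / (1 + exp(-x))

# column-wise broadcast helpers for an N x C matrix
bc_add <- function(m, v) m + rep(v, each = nrow(m))
bc_mul <- function(m, v) m * rep(v, each = nrow(m))

glorot_uniform <- function(dims, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

orthogonal_init <- function(nrow_, ncol_) {
  n <- max(nrow_, ncol_)
  q <- qr.Q(qr(matrix(stats::rnorm(n * n), n, n)))
  q[seq_len(nrow_), seq_len(ncol_), drop = FALSE]
}

same_pad <- function(n, k, s) {
  out <- ceiling(n / s)
  pad <- max((out - 1L) * s + k - n, 0L)
  list(out = as.integer(out), pad = as.integer(pad))
}

conv2d_forward <- function(X, W, b, stride) {
  d <- dim(X); B <- d[1]; H <- d[2]; Wd <- d[3]; Cin <- d[4]
  k1 <- dim(W)[1]; k2 <- dim(W)[2]; Fn <- dim(W)[4]
  s1 <- stride[1]; s2 <- stride[2]
  ph <- same_pad(H, k1, s1); pw <- same_pad(Wd, k2, s2)
  OH <- ph$out; OW <- pw$out
  if (ph$pad > 0 || pw$pad > 0) {
    Xp <- array(0, dim = c(B, H + ph$pad, Wd + pw$pad, Cin))
    Xp[, seq_len(H), seq_len(Wd), ] <- X
  } else {
    Xp <- X
  }
  N <- B * OH * OW
  Ym <- matrix(0, N, Fn)
  for (di in seq_len(k1) - 1L) {
    rows <- seq(1L + di, by = s1, length.out = OH)
    for (dj in seq_len(k2) - 1L) {
      cols <- seq(1L + dj, by = s2, length.out = OW)
      Xs <- Xp[, rows, cols, , drop = FALSE]
      dim(Xs) <- c(N, Cin)
      Ym <- Ym + Xs %*% matrix(W[di + 1L, dj + 1L, , ], Cin, Fn)
    }
  }
  Ym <- bc_add(Ym, b)
  dim(Ym) <- c(B, OH, OW, Fn)
  list(out = Ym,
       cache = list(Xp = Xp, in_dim = d, stride = stride, k = c(k1, k2),
                    OH = OH, OW = OW))
}

conv2d_backward <- function(dY, W, cache) {
  Xp <- cache$Xp
  d <- cache$in_dim; B <- d[1]; H <- d[2]; Wd <- d[3]; Cin <- d[4]
  k1 <- cache$k[1]; k2 <- cache$k[2]
  s1 <- cache$stride[1]; s2 <- cache$stride[2]
  OH <- cache$OH; OW <- cache$OW
  Fn <- dim(W)[4]
  N <- B * OH * OW
  dYm <- dY; dim(dYm) <- c(N, Fn)
  db <- colSums(dYm)
  dW <- array(0, dim = dim(W))
  dXp <- array(0, dim = dim(Xp))
  for (di in seq_len(k1) - 1L) {
    rows <- seq(1L + di, by = s1, length.out = OH)
    for (dj in seq_len(k2) - 1L) {
      cols <- seq(1L + dj, by = s2, length.out = OW)
      Xs <- Xp[, rows, cols, , drop = FALSE]
      dim(Xs) <- c(N, Cin)
      dW[di + 1L, dj + 1L, , ] <- crossprod(Xs, dYm)
      dXs <- dYm %*% t(matrix(W[di + 1L, dj + 1L, , ], Cin, Fn))
      dim(dXs) <- c(B, OH, OW, Cin)
      dXp[, rows, cols, ] <- dXp[, rows, cols, , drop = FALSE] + dXs
    }
  }
  list(dX = dXp[, seq_len(H), seq_len(Wd), , drop = FALSE], dW = dW, db = db)
}

BN_EPS <- 1e-3
BN_MOMENTUM <- 0.99

# x: any array with channels last; flattened to (N, C) internally
batchnorm_forward <- function(x, gamma, beta, run_mean, run_var, training) {
  d <- dim(x)
  C <- d[length(d)]
  xm <- x; dim(xm) <- c(prod(d) / C, C)
  if (training) {
    mu <- colMeans(xm)
    xc <- bc_add(xm, -mu)
    v <- colMeans(xc^2)
    new_rm <- BN_MOMENTUM * run_mean + (1 - BN_MOMENTUM) * mu
    new_rv <- BN_MOMENTUM * run_var + (1 - BN_MOMENTUM) * v
  } else {
    mu <- run_mean; v <- run_var
    xc <- bc_add(xm, -mu)
    new_rm <- run_mean; new_rv <- run_var
  }
  inv_sd <- 1 / sqrt(v + BN_EPS)
  xhat <- bc_mul(xc, inv_sd)
  y <- bc_add(bc_mul(xhat, gamma), beta)
  dim(y) <- d
  list(out = y, run_mean = new_rm, run_var = new_rv,
       cache = list(xhat = xhat, inv_sd = inv_sd, gamma = gamma, d = d))
}

batchnorm_backward <- function(dy, cache) {
  d <- cache$d
  C <- d[length(d)]
  dym <- dy; dim(dym) <- c(prod(d) / C, C)
  xhat <- cache$xhat
  dgamma <- colSums(dym * xhat)
  dbeta <- colSums(dym)
  dxhat <- bc_mul(dym, cache$gamma)
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * xhat)
  dx <- bc_mul(bc_add(dxhat, -m1) - bc_mul(xhat, m2), cache$inv_sd)
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

dropout_forward <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(out = x, mask = NULL))
  mask <- (stats::runif(length(x)) >= rate) / (1 - rate)
  dim(mask) <- dim(x)
  list(out = x * mask, mask = mask)
}

# Single-direction LSTM over X (B, T, D); returns the final hidden state.
# Gate order [input, forget, cell, output] in the 4U-wide weight blocks.
lstm_forward <- function(X, Wx, Wh, b, reverse = FALSE) {
  d <- dim(X); B <- d[1]; Tn <- d[2]
  U <- ncol(Wh) / 4L
  h <- matrix(0, B, U); cs <- matrix(0, B, U)
  order_t <- if (reverse) rev(seq_len(Tn)) else seq_len(Tn)
  caches <- vector("list", Tn)
  iU <- seq_len(U); fU <- U + iU; gU <- 2L * U + iU; oU <- 3L * U + iU
  for (step in seq_len(Tn)) {
    t <- order_t[step]
    Xt <- X[, t, ]
    if (is.null(dim(Xt))) Xt <- matrix(Xt, B)
    a <- bc_add(Xt %*% Wx + h %*% Wh, b)
    ig <- sigmoid(a[, iU, drop = FALSE])
    fg <- sigmoid(a[, fU, drop = FALSE])
    gg <- tanh(a[, gU, drop = FALSE])
    og <- sigmoid(a[, oU, drop = FALSE])
    c_prev <- cs
    cs <- fg * c_prev + ig * gg
    tc <- tanh(cs)
    h_prev <- h
    h <- og * tc
    caches[[step]] <- list(t = t, ig = ig, fg = fg, gg = gg, og = og,
                           c_prev = c_prev, tc = tc, h_prev = h_prev)
  }
  list(h_last = h, caches = caches, order_t = order_t)
}

lstm_backward <- function(dh_last, X, Wx, Wh, fwd) {
  d <- dim(X); B <- d[1]; Tn <- d[2]; D <- d[3]
  U <- ncol(Wh) / 4L
  dWx <- matrix(0, nrow(Wx), ncol(Wx))
  dWh <- matrix(0, U, 4L * U)
  db <- numeric(4L * U)
  dX <- array(0, dim = d)
  dh <- dh_last
  dc <- matrix(0, B, U)
  iU <- seq_len(U); fU <- U + iU; gU <- 2L * U + iU; oU <- 3L * U + iU
  for (step in rev(seq_len(Tn))) {
    cc <- fwd$caches[[step]]
    t <- cc$t
    do_ <- dh * cc$tc
    dc <- dc + dh * cc$og * (1 - cc$tc^2)
    di <- dc * cc$gg
    df <- dc * cc$c_prev
    dg <- dc * cc$ig
    da <- cbind(di * cc$ig * (1 - cc$ig),
                df * cc$fg * (1 - cc$fg),
                dg * (1 - cc$gg^2),
                do_ * cc$og * (1 - cc$og))
    Xt <- X[, t, ]
    if (is.null(dim(Xt))) Xt <- matrix(Xt, B)
    dWx <- dWx + crossprod(Xt, da)
    dWh <- dWh + crossprod(cc$h_prev, da)
    db <- db + colSums(da)
    dX[, t, ] <- da %*% t(Wx)
    dh <- da %*% t(Wh)
    dc <- dc * cc$fg
  }
  list(dX = dX, dWx = dWx, dWh = dWh, db = db)
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# y: integer class indices (1-based); returns loss and dlogits
softmax_xent <- function(Z, y) {
  P <- softmax_rows(Z)
  B <- nrow(Z)
  picked <- P[cbind(seq_len(B), y)]
  loss <- -mean(log(pmax(picked, 1e-12)))
  dZ <- P
  dZ[cbind(seq_len(B), y)] <- dZ[cbind(seq_len(B), y)] - 1
  list(loss = loss, dZ = dZ / B, P = P)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mh <- state$m[[nm]] / bc1
    vh <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}
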