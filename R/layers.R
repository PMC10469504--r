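# Internal neural-network primitives.  Every forward returns list(out, cache)
# and every backward consumes (d_out, cache) and returns list(dx, and any
# parameter gradients).  Matrix layouts are chosen so that the heavy lifting
# is plain BLAS: batches are flattened into the row dimension column-major,
# so an array (n, W, F) and matrix(arr, n * W, F) share memory order.

glorot_uniform <- function(fan_in, fan_out, dims = c(fan_in, fan_out)) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dims)
}

## ---- temporal convolution (shared across channels, 'same' padding) ----
# x: (n, C, T); w: (kt, F1) -> out matrix (n*T*C, F1), rows ordered (n, t, c)
# so the depthwise channel stage can slice without transposes.  The gradient
# with respect to the input is never needed (this is the first layer), so
# the backward pass only returns the kernel gradient.
conv_temporal_fwd <- function(x, w) {
  d <- dim(x); n <- d[1]; C <- d[2]; T <- d[3]
  kt <- nrow(w)
  xt <- aperm(x, c(1, 3, 2))                     # (n, T, C)
  pl <- (kt - 1L) %/% 2L
  xtpad <- array(0, c(n, T + kt - 1L, C))
  xtpad[, (pl + 1L):(pl + T), ] <- xt
  xcol <- im2col_cpp(xtpad, n, T + kt - 1L, C, T, kt)
  out <- xcol %*% w
  list(out = out, cache = list(xcol = xcol, n = n, C = C, T = T))
}

conv_temporal_bwd <- function(d_out, cache) {
  list(dw = crossprod(cache$xcol, d_out))
}

## ---- depthwise channel (spatial) convolution ----
# x: (n, T, C, F1); w: (C, F1, B) -> out matrix (n*T, F2), F2 = F1*B with
# feature index f2 = (f1-1)*B + b; collapses the channel axis.  The (n, T, C)
# layout makes each per-map slice a ready (n*T) x C matrix.
conv_channel_fwd <- function(x, w) {
  d <- dim(x); n <- d[1]; T <- d[2]; C <- d[3]; F1 <- d[4]; B <- dim(w)[3]
  out <- matrix(0, n * T, F1 * B)
  xmats <- vector("list", F1)
  for (f1 in seq_len(F1)) {
    xm <- matrix(x[, , , f1], n * T, C)
    xmats[[f1]] <- xm
    out[, ((f1 - 1L) * B + 1L):(f1 * B)] <- xm %*% matrix(w[, f1, ], C, B)
  }
  list(out = out, cache = list(xmats = xmats, w = w, n = n, C = C, T = T,
                               F1 = F1, B = B))
}

conv_channel_bwd <- function(d_out, cache) {
  n <- cache$n; C <- cache$C; T <- cache$T; F1 <- cache$F1; B <- cache$B
  dw <- array(0, dim(cache$w))
  dx <- array(0, c(n, T, C, F1))
  for (f1 in seq_len(F1)) {
    cols <- ((f1 - 1L) * B + 1L):(f1 * B)
    dcols <- d_out[, cols, drop = FALSE]
    wk <- matrix(cache$w[, f1, ], C, B)
    dw[, f1, ] <- crossprod(cache$xmats[[f1]], dcols)
    dx[, , , f1] <- array(dcols %*% t(wk), c(n, T, C))
  }
  list(dx = dx, dw = dw)
}

## ---- depthwise temporal ('local') convolution, 'same' padding ----
# x: (n, T, F); w: (k, F), one kernel per feature map.
conv_local_fwd <- function(x, w) {
  d <- dim(x); n <- d[1]; T <- d[2]; F <- d[3]
  k <- nrow(w)
  pl <- (k - 1L) %/% 2L; pr <- k - 1L - pl
  xpad <- array(0, c(n, T + k - 1L, F))
  xpad[, (pl + 1L):(pl + T), ] <- x
  out <- array(0, c(n, T, F))
  for (j in seq_len(k)) {
    out <- out + xpad[, j:(j + T - 1L), , drop = FALSE] *
      rep(w[j, ], each = n * T)
  }
  list(out = out, cache = list(xpad = xpad, w = w, n = n, T = T, F = F,
                               k = k, pl = pl))
}

conv_local_bwd <- function(d_out, cache) {
  n <- cache$n; T <- cache$T; F <- cache$F; k <- cache$k; pl <- cache$pl
  dw <- matrix(0, k, F)
  dxpad <- array(0, dim(cache$xpad))
  for (j in seq_len(k)) {
    sl <- j:(j + T - 1L)
    dw[j, ] <- colSums(matrix(d_out * cache$xpad[, sl, , drop = FALSE],
                              n * T, F))
    dxpad[, sl, ] <- dxpad[, sl, , drop = FALSE] +
      d_out * rep(cache$w[j, ], each = n * T)
  }
  list(dx = dxpad[, (pl + 1L):(pl + T), , drop = FALSE], dw = dw)
}

# column-wise affine helpers: y[, j] <- x[, j] * a[j] + b[j] without
# materialising broadcast matrices (the large batch-norm tensors make
# rep()/sweep() broadcasting the profile hotspot)
col_affine <- function(x, a, b) {
  for (j in seq_len(ncol(x))) x[, j] <- x[, j] * a[j] + b[j]
  x
}
bcast <- function(v, n, f) rep(v, each = n)

## ---- batch normalisation over matrix columns ----
bn_fwd <- function(x, p, training, momentum, eps) {
  if (training) {
    r <- bn_fwd_train_cpp(x, p$gamma, p$beta, eps)
    p$running_mean <- momentum * p$running_mean + (1 - momentum) * r$mu
    p$running_var <- momentum * p$running_var + (1 - momentum) * r$var
    list(out = r$out, state = p,
         cache = list(xhat = r$xhat, s = r$s, gamma = p$gamma))
  } else {
    s <- sqrt(p$running_var + eps)
    xhat <- col_affine(x, 1 / s, -p$running_mean / s)
    out <- col_affine(xhat, p$gamma, p$beta)
    list(out = out, state = p, cache = NULL)
  }
}

bn_bwd <- function(d_out, cache) {
  bn_bwd_cpp(d_out, cache$xhat, cache$s, cache$gamma)
}

bn_params <- function(F) {
  list(gamma = rep(1, F), beta = rep(0, F),
       running_mean = rep(0, F), running_var = rep(1, F))
}

## ---- layer normalisation over matrix rows ----
LN_EPS <- 1e-5

ln_fwd <- function(x, gamma, beta) {
  n <- nrow(x); f <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu                       # N-vector recycles down columns
  v <- rowMeans(xc * xc)
  s <- sqrt(v + LN_EPS)
  xhat <- xc / s
  out <- col_affine(xhat, gamma, beta)
  list(out = out, cache = list(xhat = xhat, s = s, gamma = gamma))
}

ln_bwd <- function(d_out, cache) {
  xhat <- cache$xhat
  n <- nrow(xhat); f <- ncol(xhat)
  dxhat <- col_affine(d_out, cache$gamma, rep(0, ncol(d_out)))
  rm1 <- rowMeans(dxhat)
  rm2 <- rowMeans(dxhat * xhat)
  dx <- (dxhat - rm1 - xhat * rm2) / cache$s
  list(dx = dx,
       dgamma = colSums(d_out * xhat),
       dbeta = colSums(d_out))
}

## ---- ELU ----
elu_fwd <- function(x) {
  neg <- which(x <= 0)
  y <- x
  y[neg] <- exp(x[neg]) - 1
  list(out = y, cache = list(neg = neg, yneg = y[neg]))
}

elu_bwd <- function(d_out, cache) {
  d <- d_out
  d[cache$neg] <- d[cache$neg] * (cache$yneg + 1)
  d
}

## ---- average pooling along the time axis of (n, T, F) ----
avgpool_fwd <- function(x, P) {
  d <- dim(x); n <- d[1]; T <- d[2]; F <- d[3]
  T1 <- T %/% P
  xt <- x[, seq_len(P * T1), , drop = FALSE]
  dim(xt) <- c(n, P, T1, F)
  out <- array(0, c(n, T1, F))
  for (p in seq_len(P)) {
    out <- out + array(xt[, p, , , drop = FALSE], c(n, T1, F))
  }
  list(out = out / P, cache = list(n = n, T = T, F = F, P = P, T1 = T1))
}

avgpool_bwd <- function(d_out, cache) {
  n <- cache$n; T <- cache$T; F <- cache$F; P <- cache$P; T1 <- cache$T1
  dxt <- array(0, c(n, P, T1, F))
  dpp <- d_out / P
  for (p in seq_len(P)) dxt[, p, , ] <- dpp
  dx <- array(0, c(n, T, F))
  dim(dxt) <- c(n, P * T1, F)
  dx[, seq_len(P * T1), ] <- dxt
  dx
}

## ---- inverted dropout ----
dropout_fwd <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(out = x, cache = NULL))
  mask <- array((stats::runif(length(x)) >= rate) / (1 - rate), dim(x))
  list(out = x * mask, cache = mask)
}

dropout_bwd <- function(d_out, cache) {
  if (is.null(cache)) d_out else d_out * cache
}

## ---- dense ----
dense_fwd <- function(x, w, b) {
  out <- x %*% w
  out <- out + bcast(b, nrow(out), ncol(out))
  list(out = out, cache = list(x = x, w = w))
}

dense_bwd <- function(d_out, cache) {
  list(dx = d_out %*% t(cache$w),
       dw = crossprod(cache$x, d_out),
       db = colSums(d_out))
}

## ---- row softmax and cross-entropy ----
softmax_rows <- function(x) {
  m <- apply(x, 1, max)
  e <- exp(x - m)
  e / rowSums(e)
}

# labels: 0-based integer; returns mean loss and d_logits
softmax_xent <- function(logits, labels) {
  p <- softmax_rows(logits)
  n <- nrow(p)
  idx <- cbind(seq_len(n), labels + 1L)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, probs = p, dlogits = dlogits / n)
}
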