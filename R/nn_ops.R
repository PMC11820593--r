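# Neural-network primitives with manual backpropagation.
#
# Tensor layout: 1-D feature maps are R arrays of dim (B, C, L); 2-D maps
# are (B, C, H, W). Convolutions run as one BLAS GEMM over an im2col patch
# matrix built in C++ with persistent workspace buffers (see
# src/conv_fused.cpp); the 2-D convolutions optionally fuse their ReLU.
# Every *_fwd returns list(out, cache); every *_bwd takes (cache, dout)
# and returns the input gradient plus parameter gradients.

conv_out_len <- function(L, k, stride, pad) (L + 2L * pad - k) %/% stride + 1L

# add a per-column vector to a matrix without sweep() (sweep materializes a
# full-size STATS array, which dominated profiles on wide patch matrices)
addcol <- function(X, b) X + rep(b, each = nrow(X))
mulcol <- function(X, b) X * rep(b, each = nrow(X))
subcol <- function(X, b) X - rep(b, each = nrow(X))

# weights: W is (C_in * k, C_out) with rows ordered channel-fastest (then
# kernel position), matching the im2col column order; b has length C_out.
# 1-D convolutions run through the general fused kernel as the H = 1 case.
conv1d_fwd <- function(x, W, b, stride, pad) {
  d <- dim(x); B <- d[1]; C <- d[2]; L <- d[3]
  k <- nrow(W) / C
  out <- conv_fused_fwd(x, W, b, B, C, 1L, L,
                        1L, k, 1L, stride, 0L, pad, FALSE, 0L)
  dm <- dim(out)
  dim(out) <- c(dm[1], dm[2], dm[4])
  list(out = out, cache = list(x = x, stride = stride, pad = pad, k = k))
}

conv1d_bwd <- function(cache, dout, W) {
  x <- cache$x
  d <- dim(x); B <- d[1]; C <- d[2]; L <- d[3]
  r <- conv_fused_bwd(x, W, dout, dout,
                      B, C, 1L, L, 1L, cache$k, 1L, cache$stride,
                      0L, cache$pad, FALSE, 0L)
  dx <- r$dx
  dim(dx) <- d
  list(dx = dx, dW = r$dW, db = r$db)
}

conv2d_fwd <- function(x, W, b, k, stride, pad, relu = FALSE, slot = 0L) {
  d <- dim(x); B <- d[1]; C <- d[2]; H <- d[3]; Wd <- d[4]
  out <- conv_fused_fwd(x, W, b, B, C, H, Wd,
                        k, k, stride, stride, pad, pad, relu, slot)
  list(out = out,
       cache = list(x = x, out = out, k = k, stride = stride, pad = pad,
                    relu = relu, slot = slot))
}

conv2d_bwd <- function(cache, dout, W) {
  x <- cache$x
  d <- dim(x); B <- d[1]; C <- d[2]; H <- d[3]; Wd <- d[4]
  r <- conv_fused_bwd(x, W, cache$out, dout,
                      B, C, H, Wd, cache$k, cache$k, cache$stride,
                      cache$stride, cache$pad, cache$pad, cache$relu,
                      cache$slot)
  list(dx = r$dx, dW = r$dW, db = r$db)
}

dense_fwd <- function(x, W, b) {
  list(out = addcol(x %*% W, b), cache = list(x = x))
}

dense_bwd <- function(cache, dout, W) {
  list(dx = dout %*% t(W), dW = crossprod(cache$x, dout), db = colSums(dout))
}

relu_fwd <- function(x) list(out = pmax(x, 0), cache = list(pos = x > 0))
relu_bwd <- function(cache, dout) dout * cache$pos

sigmoid <- function(x) 1 / (1 + exp(-x))

# Batch normalization over (B, L) per channel; x is (B, C, L). `state`
# carries running mean/var (momentum 0.1); eval mode uses them.
bn1d_fwd <- function(x, gamma, beta, state, training = TRUE, eps = 1e-5) {
  d <- dim(x); B <- d[1]; C <- d[2]; L <- d[3]
  xm <- aperm(x, c(1, 3, 2)); dim(xm) <- c(B * L, C)
  if (training) {
    mu <- colMeans(xm)
    xc <- subcol(xm, mu)
    va <- colMeans(xc^2)
    state$running_mean <- 0.9 * state$running_mean + 0.1 * mu
    state$running_var <- 0.9 * state$running_var + 0.1 * va
  } else {
    mu <- state$running_mean
    va <- state$running_var
    xc <- subcol(xm, mu)
  }
  inv_std <- 1 / sqrt(va + eps)
  xhat <- mulcol(xc, inv_std)
  ym <- addcol(mulcol(xhat, gamma), beta)
  dim(ym) <- c(B, L, C)
  list(out = aperm(ym, c(1, 3, 2)),
       cache = list(xhat = xhat, inv_std = inv_std, dims = d,
                    training = training),
       state = state)
}

bn1d_bwd <- function(cache, dout, gamma) {
  d <- cache$dims; B <- d[1]; C <- d[2]; L <- d[3]
  dm <- aperm(dout, c(1, 3, 2)); dim(dm) <- c(B * L, C)
  xhat <- cache$xhat
  dgamma <- colSums(dm * xhat)
  dbeta <- colSums(dm)
  dxhat <- mulcol(dm, gamma)
  if (cache$training) {
    t1 <- subcol(dxhat, colMeans(dxhat))
    t2 <- mulcol(xhat, colMeans(dxhat * xhat))
    dxm <- mulcol(t1 - t2, cache$inv_std)
  } else {
    dxm <- mulcol(dxhat, cache$inv_std)
  }
  dim(dxm) <- c(B, L, C)
  list(dx = aperm(dxm, c(1, 3, 2)), dgamma = dgamma, dbeta = dbeta)
}

# Max pooling, 1-D: pads with -Inf (so padding never wins the max), pools
# each channel independently by reusing im2col on a (B*C, 1, L) view.
maxpool1d_fwd <- function(x, k, stride, pad = 0L) {
  d <- dim(x); B <- d[1]; C <- d[2]; L <- d[3]
  Lp <- L + 2L * pad
  if (pad > 0L) {
    xp <- array(-Inf, c(B, C, Lp))
    xp[, , (pad + 1L):(pad + L)] <- x
  } else xp <- x
  dim(xp) <- c(B * C, 1L, Lp)
  Lout <- conv_out_len(L, k, stride, pad)
  M <- im2col_1d(as.numeric(xp), B * C, 1L, Lp, k, stride, 0L, Lout)
  amax <- max.col(M, ties.method = "first")
  val <- M[cbind(seq_len(nrow(M)), amax)]
  dim(val) <- c(B * C, Lout)
  dim(val) <- c(B, C, Lout)
  list(out = val,
       cache = list(amax = amax, dims = d, k = k, stride = stride,
                    pad = pad, Lout = Lout, nrow = B * C * Lout))
}

maxpool1d_bwd <- function(cache, dout) {
  d <- cache$dims; B <- d[1]; C <- d[2]; L <- d[3]
  Lp <- L + 2L * cache$pad
  dM <- matrix(0, cache$nrow, cache$k)
  dM[cbind(seq_len(cache$nrow), cache$amax)] <- as.numeric(dout)
  dxp <- col2im_1d(dM, B * C, 1L, Lp, cache$k, cache$stride, 0L, cache$Lout)
  dim(dxp) <- c(B, C, Lp)
  if (cache$pad > 0L) dxp <- dxp[, , (cache$pad + 1L):(cache$pad + L), drop = FALSE]
  dxp
}

maxpool2d_fwd <- function(x, k, stride) {
  d <- dim(x); B <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  Ho <- conv_out_len(H, k, stride, 0L)
  Wo <- conv_out_len(W, k, stride, 0L)
  r <- maxpool2d_cpp(x, B, C, H, W, k, stride, Ho, Wo)
  list(out = r$val,
       cache = list(arg = r$arg, dims = d, k = k, stride = stride,
                    Ho = Ho, Wo = Wo))
}

maxpool2d_bwd <- function(cache, dout) {
  d <- cache$dims
  maxpool2d_bwd_cpp(dout, cache$arg, d[1], d[2], d[3], d[4],
                    cache$k, cache$stride, cache$Ho, cache$Wo)
}

# Global average pool over L: (B, C, L) -> (B, C)
gap1d_fwd <- function(x) {
  d <- dim(x)
  xm <- x; dim(xm) <- c(d[1] * d[2], d[3])
  out <- rowMeans(xm); dim(out) <- c(d[1], d[2])
  list(out = out, cache = list(dims = d))
}

gap1d_bwd <- function(cache, dout) {
  d <- cache$dims
  array(rep(as.numeric(dout) / d[3], times = d[3]), d)
}

# Adaptive max pool to (out x out), window i spans
# [floor((i-1)*H/out)+1, ceiling(i*H/out)] — overlapping when H % out != 0.
adaptive_maxpool2d_fwd <- function(x, out) {
  d <- dim(x); B <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  y <- array(0, c(B, C, out, out))
  amax <- vector("list", out * out)
  for (j in seq_len(out)) {
    cj <- (floor((j - 1) * W / out) + 1L):ceiling(j * W / out)
    for (i in seq_len(out)) {
      ri <- (floor((i - 1) * H / out) + 1L):ceiling(i * H / out)
      win <- x[, , ri, cj, drop = FALSE]
      dim(win) <- c(B * C, length(ri) * length(cj))
      a <- max.col(win, ties.method = "first")
      y[, , i, j] <- win[cbind(seq_len(B * C), a)]
      amax[[i + (j - 1L) * out]] <- a
    }
  }
  list(out = y, cache = list(dims = d, out = out, amax = amax))
}

adaptive_maxpool2d_bwd <- function(cache, dout) {
  d <- cache$dims; B <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  out <- cache$out
  dx <- array(0, d)
  for (j in seq_len(out)) {
    cj <- (floor((j - 1) * W / out) + 1L):ceiling(j * W / out)
    for (i in seq_len(out)) {
      ri <- (floor((i - 1) * H / out) + 1L):ceiling(i * H / out)
      a <- cache$amax[[i + (j - 1L) * out]]
      dwin <- matrix(0, B * C, length(ri) * length(cj))
      dwin[cbind(seq_len(B * C), a)] <- as.numeric(dout[, , i, j])
      dim(dwin) <- c(B, C, length(ri), length(cj))
      dx[, , ri, cj] <- dx[, , ri, cj, drop = FALSE] + dwin
    }
  }
  dx
}

dropout_fwd <- function(x, p, training = TRUE) {
  if (!training || p <= 0) return(list(out = x, cache = list(mask = NULL)))
  mask <- (matrix(stats::runif(length(x)), nrow(x)) >= p) / (1 - p)
  list(out = x * mask, cache = list(mask = mask))
}

dropout_bwd <- function(cache, dout) {
  if (is.null(cache$mask)) dout else dout * cache$mask
}

# Softmax + cross-entropy on logits (B, K); y is an integer class index
# vector (1-based). Returns loss, probabilities and dlogits.
softmax_ce <- function(logits, y) {
  B <- nrow(logits)
  z <- logits - apply(logits, 1, max)
  ez <- exp(z)
  p <- ez / rowSums(ez)
  idx <- cbind(seq_len(B), y)
  loss <- -mean(log(pmax(p[idx], 1e-300)))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, probs = p, dlogits = dlogits / B)
}

softmax_probs <- function(logits) {
  z <- logits - apply(logits, 1, max)
  ez <- exp(z)
  ez / rowSums(ez)
}
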