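# The dual-channel fusion network: a 1-D residual branch with ICBAM
# attention on the raw slice, a 2-D CNN branch on the stacked image
# encoding, concatenation and a softmax head. Forward passes return
# caches; *_bwd consume them and produce gradient trees shaped like the
# parameter trees, so the optimizer can walk them generically.

#' Fusion network configuration
#'
#' Architecture hyperparameters of the dual-channel classifier. Defaults
#' reproduce the reference layer table: 1-D branch stem 64 channels
#' (kernel 7, stride 2, max-pool 3/2), four ICBAM residual stages with
#' widths 32/64/128/256 (strides 1,2,2,2), global average pool to a
#' 256-vector; 2-D branch convs 64/32/16 (kernels 7/5/3, valid), max-pools
#' 3/3, adaptive max pool 3x3 to a 144-vector; fused 400 -> 200 -> classes.
#'
#' @param input_len 1-D branch input length. Default 1800.
#' @param image_size 2-D branch input side. Default 100.
#' @param stem_channels Stem width. Default 64.
#' @param stage_channels Widths of the four residual stages.
#' @param stage_strides Strides of the four stages.
#' @param reduction Channel-attention bottleneck ratio `r` (FC1: C -> C/r).
#'   Default 4; every stage width must be divisible by it.
#' @param spatial_kernel Spatial-attention conv kernel (odd). Default 7.
#' @param conv2d_channels,conv2d_kernels,pool2d 2-D branch widths, kernel
#'   sizes and pool sizes (pool stride = pool size).
#' @param adaptive2d Adaptive max-pool output side. Default 3.
#' @param hidden_dim Fusion hidden width. Default 200.
#' @param n_classes Number of classes. Default 5.
#' @param dropout Dropout probability on the fused vector. Default 0.5.
#' @return Object of class `fusion_config`.
#' @export
fusion_config <- function(input_len = 1800L, image_size = 100L,
                          stem_channels = 64L,
                          stage_channels = c(32L, 64L, 128L, 256L),
                          stage_strides = c(1L, 2L, 2L, 2L),
                          reduction = 4L, spatial_kernel = 7L,
                          conv2d_channels = c(64L, 32L, 16L),
                          conv2d_kernels = c(7L, 5L, 3L),
                          pool2d = c(3L, 3L), adaptive2d = 3L,
                          hidden_dim = 200L, n_classes = 5L,
                          dropout = 0.5) {
  if (spatial_kernel %% 2L != 1L) stop("spatial_kernel must be odd")
  if (any(stage_channels %% reduction != 0))
    stop("every stage width must be divisible by the reduction ratio")
  feat2 <- conv2d_channels[3] * adaptive2d^2
  structure(list(input_len = as.integer(input_len),
                 image_size = as.integer(image_size),
                 stem_channels = as.integer(stem_channels),
                 stage_channels = as.integer(stage_channels),
                 stage_strides = as.integer(stage_strides),
                 reduction = as.integer(reduction),
                 spatial_kernel = as.integer(spatial_kernel),
                 conv2d_channels = as.integer(conv2d_channels),
                 conv2d_kernels = as.integer(conv2d_kernels),
                 pool2d = as.integer(pool2d),
                 adaptive2d = as.integer(adaptive2d),
                 feat1_dim = as.integer(stage_channels[4]),
                 feat2_dim = as.integer(feat2),
                 fused_dim = as.integer(stage_channels[4] + feat2),
                 hidden_dim = as.integer(hidden_dim),
                 n_classes = as.integer(n_classes),
                 dropout = dropout),
            class = "fusion_config")
}

# ---- initialization ----------------------------------------------------

rand_mat <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)

init_conv <- function(fan_in, n_out, init) {
  if (init == "zeros") list(W = matrix(0, fan_in, n_out), b = numeric(n_out))
  else list(W = rand_mat(fan_in, n_out, sqrt(2 / fan_in)), b = numeric(n_out))
}

init_bn <- function(C, gamma0 = 1) {
  list(gamma = rep(gamma0, C), beta = numeric(C))
}

bn_state <- function(C) list(running_mean = numeric(C), running_var = rep(1, C))

init_icbam <- function(C, r, k, init) {
  list(fc1 = init_conv(C, C %/% r, init),
       fc2 = init_conv(C %/% r, C, init),
       sconv = init_conv(2L * k, 1L, init))
}

init_resblock <- function(C_in, C_out, stride, r, sk, init) {
  p <- list(conv1 = init_conv(C_in * 3L, C_out, init), bn1 = init_bn(C_out),
            icbam = init_icbam(C_out, r, sk, init),
            conv2 = init_conv(C_out * 3L, C_out, init),
            # zero residual scale: a fresh block starts as its shortcut
            bn2 = init_bn(C_out, gamma0 = 0))
  if (C_in != C_out || stride != 1L) {
    p$shortcut <- init_conv(C_in, C_out, init)
    p$bn_sc <- init_bn(C_out)
  }
  p
}

resblock_state <- function(C_in, C_out, stride) {
  s <- list(bn1 = bn_state(C_out), bn2 = bn_state(C_out))
  if (C_in != C_out || stride != 1L) s$bn_sc <- bn_state(C_out)
  s
}

#' Initialize the fusion network parameters
#'
#' Kaiming-style normal initialization for convolutional and dense
#' weights, zero biases, unit batch-norm scale except the residual-closing
#' batch-norm whose scale starts at zero (each block begins as an
#' identity). `init = "zeros"` zeroes everything (used by shape and
#' linearity tests).
#'
#' @param cfg A [fusion_config()].
#' @param seed Integer seed.
#' @param init `"kaiming"` or `"zeros"`.
#' @return List with `params` (trainable tree) and `state` (batch-norm
#'   running statistics).
#' @export
init_fusion_params <- function(cfg, seed = 1L, init = "kaiming") {
  with_seed(derive_seed(seed, "init"), {
    sc <- cfg$stage_channels; st <- cfg$stage_strides
    widths <- c(cfg$stem_channels, sc)
    params <- list(
      branch1 = list(
        stem_conv = init_conv(7L, cfg$stem_channels, init),
        stem_bn = init_bn(cfg$stem_channels),
        stages = lapply(1:4, function(i) {
          init_resblock(widths[i], sc[i], st[i], cfg$reduction,
                        cfg$spatial_kernel, init)
        })),
      branch2 = list(
        conv1 = init_conv(3L * cfg$conv2d_kernels[1]^2, cfg$conv2d_channels[1], init),
        conv2 = init_conv(cfg$conv2d_channels[1] * cfg$conv2d_kernels[2]^2,
                          cfg$conv2d_channels[2], init),
        conv3 = init_conv(cfg$conv2d_channels[2] * cfg$conv2d_kernels[3]^2,
                          cfg$conv2d_channels[3], init)),
      fusion = list(
        fc1 = init_conv(cfg$fused_dim, cfg$hidden_dim, init),
        fc2 = init_conv(cfg$hidden_dim, cfg$n_classes, init)))
    state <- list(
      stem_bn = bn_state(cfg$stem_channels),
      stages = lapply(1:4, function(i) resblock_state(widths[i], sc[i], st[i])))
    list(params = params, state = state)
  })
}

# ---- channel attention (Eq-style: sigmoid(FC2(ReLU(FC1(avg + max))))) --

channel_attention_fwd <- function(x, p, sigmoid_bypass = FALSE) {
  d <- dim(x); B <- d[1]; C <- d[2]; L <- d[3]
  xm <- x; dim(xm) <- c(B * C, L)
  favg <- rowMeans(xm); dim(favg) <- c(B, C)
  amax <- max.col(xm, ties.method = "first")
  fmax <- xm[cbind(seq_len(B * C), amax)]; dim(fmax) <- c(B, C)
  h <- favg + fmax
  f1 <- dense_fwd(h, p$fc1$W, p$fc1$b)
  a1 <- relu_fwd(f1$out)
  f2 <- dense_fwd(a1$out, p$fc2$W, p$fc2$b)
  wc <- if (sigmoid_bypass) matrix(1, B, C) else sigmoid(f2$out)
  wcx <- array(rep(as.numeric(wc), times = L), d)
  out <- x * wcx + x
  list(out = out,
       cache = list(x = x, wc = wc, amax = amax, f1 = f1, a1 = a1, f2 = f2,
                    dims = d, sigmoid_bypass = sigmoid_bypass))
}

channel_attention_bwd <- function(cache, dout, p) {
  d <- cache$dims; B <- d[1]; C <- d[2]; L <- d[3]
  x <- cache$x
  # d(out)/d(wc): sum over L of dout * x
  prod_m <- dout * x; dim(prod_m) <- c(B * C, L)
  dwc <- rowSums(prod_m); dim(dwc) <- c(B, C)
  wcx <- array(rep(as.numeric(cache$wc), times = L), d)
  dx <- dout * (wcx + 1)
  if (cache$sigmoid_bypass) {
    dz2 <- matrix(0, B, C)
  } else {
    dz2 <- dwc * cache$wc * (1 - cache$wc)
  }
  g2 <- dense_bwd(cache$f2$cache, dz2, p$fc2$W)
  dz1 <- relu_bwd(cache$a1$cache, g2$dx)
  g1 <- dense_bwd(cache$f1$cache, dz1, p$fc1$W)
  dh <- g1$dx                               # (B, C): flows to favg and fmax
  # favg path: spread dh/L uniformly; fmax path: scatter to argmax
  dxm <- matrix(rep(as.numeric(dh) / L, times = L), B * C, L)
  dxm[cbind(seq_len(B * C), cache$amax)] <-
    dxm[cbind(seq_len(B * C), cache$amax)] + as.numeric(dh)
  dim(dxm) <- d
  dx <- dx + dxm
  list(dx = dx,
       grads = list(fc1 = list(W = g1$dW, b = g1$db),
                    fc2 = list(W = g2$dW, b = g2$db)))
}

# ---- spatial attention -------------------------------------------------
# max and mean across channels -> (B, 2, L) -> conv(k, pad (k-1)/2) ->
# sigmoid -> scales f1; the block input x0 is re-added (global-feature
# reuse).

spatial_attention_fwd <- function(f1, x0, p, k, sigmoid_bypass = FALSE) {
  d <- dim(f1); B <- d[1]; C <- d[2]; L <- d[3]
  A <- aperm(f1, c(2, 1, 3)); dim(A) <- c(C, B * L)
  tA <- t(A)                                # (B*L, C), rows b-fastest
  amax <- max.col(tA, ties.method = "first")
  smax <- tA[cbind(seq_len(B * L), amax)]
  smean <- rowMeans(tA)
  z <- array(0, c(B, 2L, L))
  z[, 1L, ] <- smax                          # channel 1: max, 2: mean
  z[, 2L, ] <- smean
  cv <- conv1d_fwd(z, p$sconv$W, p$sconv$b, 1L, (k - 1L) %/% 2L)
  a <- if (sigmoid_bypass) array(1, c(B, 1L, L)) else sigmoid(cv$out)
  av <- a[, 1L, ]; dim(av) <- c(B, L)
  sc <- aperm(array(rep(as.numeric(av), times = C), c(B, L, C)), c(1, 3, 2))
  out <- f1 * sc + x0
  list(out = out,
       cache = list(f1 = f1, a = a, sc = sc, amax = amax, cv = cv,
                    dims = d, k = k, sigmoid_bypass = sigmoid_bypass))
}

spatial_attention_bwd <- function(cache, dout, p) {
  d <- cache$dims; B <- d[1]; C <- d[2]; L <- d[3]
  f1 <- cache$f1
  df1 <- dout * cache$sc
  # gradient to the attention map: sum over channels of dout * f1
  pm <- aperm(dout * f1, c(2, 1, 3)); dim(pm) <- c(C, B * L)
  da <- colSums(pm); dim(da) <- c(B, L)     # (B, L)
  if (cache$sigmoid_bypass) {
    dcv <- array(0, c(B, 1L, L))
  } else {
    av <- cache$a[, 1L, ]; dim(av) <- c(B, L)
    dcv <- array(da * av * (1 - av), c(B, 1L, L))
  }
  g <- conv1d_bwd(cache$cv$cache, dcv, p$sconv$W)
  dz <- g$dx                                # (B, 2, L)
  dsmax <- dz[, 1L, ]; dim(dsmax) <- c(B, L)
  dsmean <- dz[, 2L, ]; dim(dsmean) <- c(B, L)
  # mean path: spread across channels; max path: scatter to argmax channel
  dtA <- matrix(rep(as.numeric(dsmean) / C, times = C), B * L, C)
  dtA[cbind(seq_len(B * L), cache$amax)] <-
    dtA[cbind(seq_len(B * L), cache$amax)] + as.numeric(dsmax)
  dA <- t(dtA); dim(dA) <- c(C, B, L)
  df1 <- df1 + aperm(dA, c(2, 1, 3))
  list(df1 = df1, dx0 = dout,
       grads = list(sconv = list(W = g$dW, b = g$db)))
}

icbam_fwd <- function(x, p, k, sigmoid_bypass = FALSE) {
  ca <- channel_attention_fwd(x, p, sigmoid_bypass)
  sa <- spatial_attention_fwd(ca$out, x, p, k, sigmoid_bypass)
  list(out = sa$out, cache = list(ca = ca, sa = sa))
}

icbam_bwd <- function(cache, dout, p) {
  gs <- spatial_attention_bwd(cache$sa$cache, dout, p)
  gc <- channel_attention_bwd(cache$ca$cache, gs$df1, p)
  list(dx = gc$dx + gs$dx0,
       grads = c(gc$grads, gs$grads))
}

# ---- ICBAM residual block ---------------------------------------------
# conv(3, stride, pad 1) -> BN -> ReLU -> ICBAM -> conv(3, 1, pad 1) -> BN
# -> + shortcut -> ReLU

resblock_fwd <- function(x, p, st, stride, k_spatial, training = TRUE,
                         sigmoid_bypass = FALSE) {
  c1 <- conv1d_fwd(x, p$conv1$W, p$conv1$b, stride, 1L)
  b1 <- bn1d_fwd(c1$out, p$bn1$gamma, p$bn1$beta, st$bn1, training)
  r1 <- relu_fwd(b1$out)
  at <- icbam_fwd(r1$out, p$icbam, k_spatial, sigmoid_bypass)
  c2 <- conv1d_fwd(at$out, p$conv2$W, p$conv2$b, 1L, 1L)
  b2 <- bn1d_fwd(c2$out, p$bn2$gamma, p$bn2$beta, st$bn2, training)
  if (!is.null(p$shortcut)) {
    s1 <- conv1d_fwd(x, p$shortcut$W, p$shortcut$b, stride, 0L)
    bs <- bn1d_fwd(s1$out, p$bn_sc$gamma, p$bn_sc$beta, st$bn_sc, training)
    short <- bs$out
  } else {
    s1 <- NULL; bs <- NULL
    short <- x
  }
  r2 <- relu_fwd(b2$out + short)
  st_new <- list(bn1 = b1$state, bn2 = b2$state)
  if (!is.null(bs)) st_new$bn_sc <- bs$state
  list(out = r2$out,
       cache = list(c1 = c1, b1 = b1, r1 = r1, at = at, c2 = c2, b2 = b2,
                    s1 = s1, bs = bs, r2 = r2, has_short = !is.null(p$shortcut)),
       state = st_new)
}

resblock_bwd <- function(cache, dout, p) {
  dsum <- relu_bwd(cache$r2$cache, dout)
  g2 <- bn1d_bwd(cache$b2$cache, dsum, p$bn2$gamma)
  gc2 <- conv1d_bwd(cache$c2$cache, g2$dx, p$conv2$W)
  ga <- icbam_bwd(cache$at$cache, gc2$dx, p$icbam)
  dr1 <- relu_bwd(cache$r1$cache, ga$dx)
  g1 <- bn1d_bwd(cache$b1$cache, dr1, p$bn1$gamma)
  gc1 <- conv1d_bwd(cache$c1$cache, g1$dx, p$conv1$W)
  grads <- list(conv1 = list(W = gc1$dW, b = gc1$db),
                bn1 = list(gamma = g1$dgamma, beta = g1$dbeta),
                icbam = ga$grads,
                conv2 = list(W = gc2$dW, b = gc2$db),
                bn2 = list(gamma = g2$dgamma, beta = g2$dbeta))
  if (cache$has_short) {
    gsb <- bn1d_bwd(cache$bs$cache, dsum, p$bn_sc$gamma)
    gsc <- conv1d_bwd(cache$s1$cache, gsb$dx, p$shortcut$W)
    grads$shortcut <- list(W = gsc$dW, b = gsc$db)
    grads$bn_sc <- list(gamma = gsb$dgamma, beta = gsb$dbeta)
    dx <- gc1$dx + gsc$dx
  } else {
    dx <- gc1$dx + dsum
  }
  list(dx = dx, grads = grads)
}

# ---- branch 1: 1-D ResNet-ICBAM ---------------------------------------

branch1_fwd <- function(x, p, st, cfg, training = TRUE, sigmoid_bypass = FALSE) {
  cs <- conv1d_fwd(x, p$stem_conv$W, p$stem_conv$b, 2L, 3L)
  bs <- bn1d_fwd(cs$out, p$stem_bn$gamma, p$stem_bn$beta, st$stem_bn, training)
  rs <- relu_fwd(bs$out)
  mp <- maxpool1d_fwd(rs$out, 3L, 2L, 1L)
  h <- mp$out
  stage_caches <- vector("list", 4L)
  st_new <- list(stem_bn = bs$state, stages = vector("list", 4L))
  shapes <- list(stem = dim(cs$out), pool = dim(h))
  for (i in 1:4) {
    sb <- resblock_fwd(h, p$stages[[i]], st$stages[[i]],
                       cfg$stage_strides[i], cfg$spatial_kernel,
                       training, sigmoid_bypass)
    h <- sb$out
    stage_caches[[i]] <- sb$cache
    st_new$stages[[i]] <- sb$state
    shapes[[paste0("stage", i)]] <- dim(h)
  }
  gp <- gap1d_fwd(h)
  list(out = gp$out,                        # (B, 256)
       cache = list(cs = cs, bs = bs, rs = rs, mp = mp,
                    stages = stage_caches, gp = gp, shapes = shapes),
       state = st_new)
}

branch1_bwd <- function(cache, dout, p, cfg) {
  dh <- gap1d_bwd(cache$gp$cache, dout)
  sgrads <- vector("list", 4L)
  for (i in 4:1) {
    g <- resblock_bwd(cache$stages[[i]], dh, p$stages[[i]])
    dh <- g$dx
    sgrads[[i]] <- g$grads
  }
  dmp <- maxpool1d_bwd(cache$mp$cache, dh)
  drs <- relu_bwd(cache$rs$cache, dmp)
  gb <- bn1d_bwd(cache$bs$cache, drs, p$stem_bn$gamma)
  gc <- conv1d_bwd(cache$cs$cache, gb$dx, p$stem_conv$W)
  list(dx = gc$dx,
       grads = list(stem_conv = list(W = gc$dW, b = gc$db),
                    stem_bn = list(gamma = gb$dgamma, beta = gb$dbeta),
                    stages = sgrads))
}

# ---- branch 2: 2-D CNN -------------------------------------------------

branch2_fwd <- function(x, p, cfg) {
  k <- cfg$conv2d_kernels
  c1 <- conv2d_fwd(x, p$conv1$W, p$conv1$b, k[1], 1L, 0L, relu = TRUE,
                   slot = 1L)
  m1 <- maxpool2d_fwd(c1$out, cfg$pool2d[1], cfg$pool2d[1])
  c2 <- conv2d_fwd(m1$out, p$conv2$W, p$conv2$b, k[2], 1L, 0L, relu = TRUE,
                   slot = 2L)
  m2 <- maxpool2d_fwd(c2$out, cfg$pool2d[2], cfg$pool2d[2])
  c3 <- conv2d_fwd(m2$out, p$conv3$W, p$conv3$b, k[3], 1L, 0L, relu = TRUE,
                   slot = 3L)
  ap <- adaptive_maxpool2d_fwd(c3$out, cfg$adaptive2d)
  B <- dim(x)[1]
  flat <- ap$out; dim(flat) <- c(B, length(flat) / B)
  shapes <- list(conv1 = dim(c1$out), pool1 = dim(m1$out),
                 conv2 = dim(c2$out), pool2 = dim(m2$out),
                 conv3 = dim(c3$out), adaptive = dim(ap$out))
  list(out = flat,                          # (B, 144)
       cache = list(c1 = c1, m1 = m1, c2 = c2, m2 = m2,
                    c3 = c3, ap = ap, shapes = shapes))
}

branch2_bwd <- function(cache, dout, p, cfg) {
  dap <- dout; dim(dap) <- dim(cache$ap$out)
  dr3 <- adaptive_maxpool2d_bwd(cache$ap$cache, dap)
  g3 <- conv2d_bwd(cache$c3$cache, dr3, p$conv3$W)
  dm2 <- maxpool2d_bwd(cache$m2$cache, g3$dx)
  g2 <- conv2d_bwd(cache$c2$cache, dm2, p$conv2$W)
  dm1 <- maxpool2d_bwd(cache$m1$cache, g2$dx)
  g1 <- conv2d_bwd(cache$c1$cache, dm1, p$conv1$W)
  list(dx = g1$dx,
       grads = list(conv1 = list(W = g1$dW, b = g1$db),
                    conv2 = list(W = g2$dW, b = g2$db),
                    conv3 = list(W = g3$dW, b = g3$db)))
}

# ---- fusion head -------------------------------------------------------

fusion_head_fwd <- function(x1, x2, p, cfg, training = TRUE) {
  fused <- cbind(x1, x2)                    # (B, 400)
  dp <- dropout_fwd(fused, cfg$dropout, training)
  f1 <- dense_fwd(dp$out, p$fc1$W, p$fc1$b)
  a1 <- relu_fwd(f1$out)
  f2 <- dense_fwd(a1$out, p$fc2$W, p$fc2$b)
  list(out = f2$out,                        # logits (B, n_classes)
       cache = list(dp = dp, f1 = f1, a1 = a1, f2 = f2,
                    d1 = ncol(x1), d2 = ncol(x2)))
}

fusion_head_bwd <- function(cache, dout, p) {
  g2 <- dense_bwd(cache$f2$cache, dout, p$fc2$W)
  da1 <- relu_bwd(cache$a1$cache, g2$dx)
  g1 <- dense_bwd(cache$f1$cache, da1, p$fc1$W)
  dfused <- dropout_bwd(cache$dp$cache, g1$dx)
  list(dx1 = dfused[, seq_len(cache$d1), drop = FALSE],
       dx2 = dfused[, cache$d1 + seq_len(cache$d2), drop = FALSE],
       grads = list(fc1 = list(W = g1$dW, b = g1$db),
                    fc2 = list(W = g2$dW, b = g2$db)))
}

# ---- full model --------------------------------------------------------

# x1: (B, 1, input_len); x2: (B, 3, image_size, image_size)
fusion_fwd <- function(x1, x2, params, state, cfg, training = TRUE,
                       sigmoid_bypass = FALSE) {
  b1 <- branch1_fwd(x1, params$branch1, state, cfg, training, sigmoid_bypass)
  b2 <- branch2_fwd(x2, params$branch2, cfg)
  hd <- fusion_head_fwd(b1$out, b2$out, params$fusion, cfg, training)
  list(logits = hd$out,
       cache = list(b1 = b1, b2 = b2, hd = hd),
       state = b1$state)
}

fusion_bwd <- function(cache, dlogits, params, cfg) {
  gh <- fusion_head_bwd(cache$hd$cache, dlogits, params$fusion)
  g1 <- branch1_bwd(cache$b1$cache, gh$dx1, params$branch1, cfg)
  g2 <- branch2_bwd(cache$b2$cache, gh$dx2, params$branch2, cfg)
  list(grads = list(branch1 = g1$grads, branch2 = g2$grads,
                    fusion = gh$grads))
}
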