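# Minimal deterministic neural-network primitives for batch-size-1 training.
# Feature maps are arrays (H, W, D, C) with D the 3-bin depth axis. 3x3x3
# convolutions are computed as im2col gathers followed by one BLAS matrix
# multiply; backward passes scatter-add with rowsum(). Everything is plain
# double arithmetic driven by R's RNG, so runs are bit-reproducible per seed.

.idx_cache <- new.env(parent = emptyenv())

# linear indices into a zero-padded (H+2, W+2, D+2) volume for all 27 kernel
# offsets of every output position; offset order matches the column-major
# flattening of a (3, 3, 3, ...) weight array (kh fastest, then kw, then kd)
.conv3_idx <- function(H, W, D) {
  key <- paste(H, W, D, sep = "x")
  if (!is.null(.idx_cache[[key]])) return(.idx_cache[[key]])
  Hp <- H + 2L; Wp <- W + 2L; Dp <- D + 2L
  h <- rep_len(seq_len(H), H * W * D)
  w <- rep(rep(seq_len(W), each = H), D)
  d <- rep(seq_len(D), each = H * W)
  npos <- H * W * D
  idx <- integer(npos * 27L)
  o <- 0L
  for (dk in -1:1) for (dj in -1:1) for (di in -1:1) {
    idx[o * npos + seq_len(npos)] <-
      (h + di + 1L) + Hp * (w + dj) + Hp * Wp * (d + dk)
    o <- o + 1L
  }
  .idx_cache[[key]] <- idx
  idx
}

# note the index arithmetic above: padded coordinate is (h+di+1, w+dj+1,
# d+dk+1); column-major linear index = ph + Hp*(pw-1) + Hp*Wp*(pd-1)
# = (h+di+1) + Hp*(w+dj) + Hp*Wp*(d+dk).

.pad3 <- function(x) {
  d <- dim(x)
  xp <- array(0, c(d[1] + 2L, d[2] + 2L, d[3] + 2L, d[4]))
  xp[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1), ] <- x
  xp
}

nn_conv3_forward <- function(x, w, b) {
  d <- dim(x); H <- d[1]; W <- d[2]; D <- d[3]; Cin <- d[4]
  Cout <- dim(w)[5]
  idx <- .conv3_idx(H, W, D)
  xp <- .pad3(x)
  dim(xp) <- c(length(xp) / Cin, Cin)
  X <- xp[idx, , drop = FALSE]
  dim(X) <- c(H * W * D, 27L * Cin)
  Wm <- w; dim(Wm) <- c(27L * Cin, Cout)
  Y <- X %*% Wm
  Y <- Y + rep(b, each = nrow(Y))
  dim(Y) <- c(H, W, D, Cout)
  list(y = Y, cache = list(X = X, idx = idx, dims = d, Wm = Wm))
}

nn_conv3_backward <- function(dy, cache) {
  d <- cache$dims; H <- d[1]; W <- d[2]; D <- d[3]; Cin <- d[4]
  Cout <- ncol(cache$Wm)
  dYm <- dy; dim(dYm) <- c(H * W * D, Cout)
  dW <- crossprod(cache$X, dYm)
  dim(dW) <- c(3L, 3L, 3L, Cin, Cout)
  db <- colSums(dYm)
  dXcol <- dYm %*% t(cache$Wm)
  dim(dXcol) <- c(H * W * D * 27L, Cin)
  g <- rowsum(dXcol, group = cache$idx, reorder = TRUE)
  dMp <- matrix(0, (H + 2L) * (W + 2L) * (D + 2L), Cin)
  dMp[as.integer(rownames(g)), ] <- g
  dim(dMp) <- c(H + 2L, W + 2L, D + 2L, Cin)
  dx <- dMp[2:(H + 1), 2:(W + 1), 2:(D + 1), , drop = FALSE]
  list(dx = dx, dw = dW, db = db)
}

nn_bn_forward <- function(x, gamma, beta, state, train, momentum = 0.1,
                          eps = 1e-5) {
  d <- dim(x); C <- d[4]; N <- prod(d[1:3])
  xm <- x; dim(xm) <- c(N, C)
  if (train) {
    mu <- colMeans(xm)
    xc <- xm - rep(mu, each = N)
    va <- colMeans(xc * xc)
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var  <- (1 - momentum) * state$var + momentum * va
  } else {
    mu <- state$mean
    xc <- xm - rep(mu, each = N)
    va <- state$var
  }
  invstd <- 1 / sqrt(va + eps)
  xhat <- xc * rep(invstd, each = N)
  y <- xhat * rep(gamma, each = N) + rep(beta, each = N)
  dim(y) <- d
  list(y = y, state = state,
       cache = list(xhat = xhat, invstd = invstd, gamma = gamma, dims = d,
                    train = train))
}

nn_bn_backward <- function(dy, cache) {
  d <- cache$dims; C <- d[4]; N <- prod(d[1:3])
  dym <- dy; dim(dym) <- c(N, C)
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  dxhat <- dym * rep(cache$gamma, each = N)
  if (cache$train) {
    m1 <- colMeans(dxhat)
    m2 <- colMeans(dxhat * cache$xhat)
    dx <- (dxhat - rep(m1, each = N) - cache$xhat * rep(m2, each = N)) *
      rep(cache$invstd, each = N)
  } else {
    dx <- dxhat * rep(cache$invstd, each = N)
  }
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

nn_relu_forward <- function(x) list(y = pmax(x, 0), cache = x > 0)

nn_relu_backward <- function(dy, cache) dy * cache

# spatial-only 2x2 max pooling (the bin depth axis is never collapsed)
nn_pool_forward <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]
  stopifnot(H %% 2 == 0, W %% 2 == 0)
  io <- seq(1L, H, 2L); jo <- seq(1L, W, 2L)
  s1 <- x[io, jo, , , drop = FALSE];     s2 <- x[io + 1L, jo, , , drop = FALSE]
  s3 <- x[io, jo + 1L, , , drop = FALSE]; s4 <- x[io + 1L, jo + 1L, , , drop = FALSE]
  y <- pmax(s1, s2, s3, s4)
  dim(y) <- dim(s1)
  # deterministic tie-break: first of (s1, s2, s3, s4) attaining the max
  t1 <- s1 == y
  t2 <- (s2 == y) & !t1
  t3 <- (s3 == y) & !t1 & !t2
  t4 <- !(t1 | t2 | t3)
  list(y = y, cache = list(t = list(t1, t2, t3, t4), dims = d))
}

nn_pool_backward <- function(dy, cache) {
  d <- cache$dims
  dx <- array(0, d)
  io <- seq(1L, d[1], 2L); jo <- seq(1L, d[2], 2L)
  t <- cache$t
  dx[io, jo, , ]           <- dy * t[[1]]
  dx[io + 1L, jo, , ]      <- dy * t[[2]]
  dx[io, jo + 1L, , ]      <- dy * t[[3]]
  dx[io + 1L, jo + 1L, , ] <- dy * t[[4]]
  dx
}

# spatial 2x2 up-convolution (transposed conv, stride 2), depth preserved
nn_upconv_forward <- function(x, w, b) {
  d <- dim(x); H <- d[1]; W <- d[2]; D <- d[3]; Cin <- d[4]
  Cout <- dim(w)[4]
  xm <- x; dim(xm) <- c(H * W * D, Cin)
  y <- array(0, c(2L * H, 2L * W, D, Cout))
  for (a in 1:2) for (bb in 1:2) {
    Yab <- xm %*% matrix(w[a, bb, , ], Cin, Cout)
    dim(Yab) <- c(H, W, D, Cout)
    y[seq(a, 2L * H, 2L), seq(bb, 2L * W, 2L), , ] <- Yab
  }
  y <- y + rep(b, each = 4L * H * W * D)
  list(y = y, cache = list(xm = xm, dims = d, w = w))
}

nn_upconv_backward <- function(dy, cache) {
  d <- cache$dims; H <- d[1]; W <- d[2]; D <- d[3]; Cin <- d[4]
  w <- cache$w; Cout <- dim(w)[4]
  dx <- matrix(0, H * W * D, Cin)
  dw <- array(0, dim(w))
  db <- numeric(Cout)
  for (a in 1:2) for (bb in 1:2) {
    dYab <- dy[seq(a, 2L * H, 2L), seq(bb, 2L * W, 2L), , , drop = FALSE]
    dim(dYab) <- c(H * W * D, Cout)
    wa <- matrix(w[a, bb, , ], Cin, Cout)
    dx <- dx + dYab %*% t(wa)
    dw[a, bb, , ] <- crossprod(cache$xm, dYab)
    db <- db + colSums(dYab)
  }
  dim(dx) <- d
  list(dx = dx, dw = dw, db = db)
}

# bin-collapsing output head: 1x1 spatial kernel spanning the full depth D
nn_head_forward <- function(x, w, b) {
  d <- dim(x); H <- d[1]; W <- d[2]; D <- d[3]; Cin <- d[4]
  Cout <- ncol(w)
  xm <- x; dim(xm) <- c(H * W, D * Cin)
  z <- xm %*% w + rep(b, each = H * W)
  list(y = z, cache = list(xm = xm, dims = d, w = w))  # y: (H*W, Cout)
}

nn_head_backward <- function(dz, cache) {
  d <- cache$dims
  dw <- crossprod(cache$xm, dz)
  db <- colSums(dz)
  dxm <- dz %*% t(cache$w)
  dim(dxm) <- d
  list(dx = dxm, dw = dw, db = db)
}

nn_softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# given dL/dp on an (N, K) probability matrix produced by row-softmax,
# return dL/dz through the softmax Jacobian
nn_softmax_backward <- function(dp, p) {
  p * (dp - rowSums(dp * p))
}

# Adam optimizer state & update (per parameter tensor)
adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, skip = character(0)) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    if (nm %in% skip) next
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mh <- state$m[[nm]] / bc1
    vh <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}
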