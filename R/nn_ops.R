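# ---------------------------------------------------------------------------
# Minimal spatiotemporal CNN engine.
#
# Feature tensors are numeric arrays of shape (C, T, H, W, B): channels,
# timeframes, rows, cols, batch. Convolutions are realized as im2col + one
# BLAS matrix product; every layer has a hand-derived backward pass, checked
# against numeric differentiation in the test suite. Only the primitives the
# two architectures need are provided: 3D convolution with "same" padding
# and optional dilation, batch normalization, ReLU/sigmoid/tanh, spatial
# 1x2x2 max pooling, and nearest-neighbor 1x2x2 upsampling.
# ---------------------------------------------------------------------------

# --- padding / im2col ------------------------------------------------------

pad_thw <- function(x, pt, ph, pw) {
  d <- dim(x)
  if (pt == 0 && ph == 0 && pw == 0) return(x)
  out <- array(0, dim = c(d[1], d[2] + 2 * pt, d[3] + 2 * ph, d[4] + 2 * pw, d[5]))
  out[, pt + seq_len(d[2]), ph + seq_len(d[3]), pw + seq_len(d[4]), ] <- x
  out
}

# columns matrix (C*K, T*H*W*B); offset blocks ordered kt-fastest then kh
# then kw, each block holding all C channels
im2col <- function(x, k, dil) {
  d <- dim(x)
  C <- d[1]; Tn <- d[2]; H <- d[3]; W <- d[4]; B <- d[5]
  pt <- dil[1] * (k[1] - 1) / 2
  ph <- dil[2] * (k[2] - 1) / 2
  pw <- dil[3] * (k[3] - 1) / 2
  xp <- pad_thw(x, pt, ph, pw)
  K <- prod(k)
  N <- Tn * H * W * B
  X <- matrix(0, C * K, N)
  blk <- 0L
  for (kk in seq_len(k[3]) - 1L) for (kj in seq_len(k[2]) - 1L) for (ki in seq_len(k[1]) - 1L) {
    piece <- xp[, ki * dil[1] + seq_len(Tn), kj * dil[2] + seq_len(H),
                kk * dil[3] + seq_len(W), , drop = FALSE]
    X[blk * C + seq_len(C), ] <- piece
    blk <- blk + 1L
  }
  X
}

col2im <- function(dX, xdim, k, dil) {
  C <- xdim[1]; Tn <- xdim[2]; H <- xdim[3]; W <- xdim[4]; B <- xdim[5]
  pt <- dil[1] * (k[1] - 1) / 2
  ph <- dil[2] * (k[2] - 1) / 2
  pw <- dil[3] * (k[3] - 1) / 2
  dxp <- array(0, dim = c(C, Tn + 2 * pt, H + 2 * ph, W + 2 * pw, B))
  blk <- 0L
  for (kk in seq_len(k[3]) - 1L) for (kj in seq_len(k[2]) - 1L) for (ki in seq_len(k[1]) - 1L) {
    it <- ki * dil[1] + seq_len(Tn)
    ih <- kj * dil[2] + seq_len(H)
    iw <- kk * dil[3] + seq_len(W)
    piece <- array(dX[blk * C + seq_len(C), ], dim = c(C, Tn, H, W, B))
    dxp[, it, ih, iw, ] <- dxp[, it, ih, iw, , drop = FALSE] + piece
    blk <- blk + 1L
  }
  dxp[, pt + seq_len(Tn), ph + seq_len(H), pw + seq_len(W), , drop = FALSE]
}

# --- layers ----------------------------------------------------------------

# Kaiming fan-in initialization; biases zero. RMSprop state lives with the
# layer (vW, vb) so optimizer updates stay local.
make_conv <- function(cin, cout, k, dil = c(1L, 1L, 1L)) {
  K <- prod(k)
  sdv <- sqrt(2 / (cin * K))
  list(type = "conv",
       W = matrix(rnorm(cout * cin * K, 0, sdv), cout, cin * K),
       b = numeric(cout),
       cin = cin, cout = cout, k = as.integer(k), dil = as.integer(dil),
       vW = NULL, vb = NULL)
}

make_bn <- function(c, eps = 1e-5, momentum = 0.1) {
  list(type = "bn", gamma = rep(1, c), beta = numeric(c),
       run_mean = numeric(c), run_var = rep(1, c),
       eps = eps, momentum = momentum, c = c,
       vgamma = NULL, vbeta = NULL)
}

make_act <- function(kind) list(type = kind)

conv_forward <- function(l, x) {
  d <- dim(x)
  X <- im2col(x, l$k, l$dil)
  Y <- l$W %*% X + l$b
  y <- array(Y, dim = c(l$cout, d[2], d[3], d[4], d[5]))
  list(y = y, cache = list(X = X, xdim = d))
}

conv_backward <- function(l, cache, dy) {
  dY <- matrix(dy, nrow = l$cout)
  dW <- tcrossprod(dY, cache$X)
  db <- rowSums(dY)
  dX <- crossprod(l$W, dY)
  dx <- col2im(dX, cache$xdim, l$k, l$dil)
  list(dx = dx, grads = list(W = dW, b = db))
}

bn_forward <- function(l, x, train) {
  d <- dim(x)
  C <- d[1]; N <- prod(d) / C
  xm <- matrix(x, C, N)
  if (train) {
    mu <- rowMeans(xm)
    v <- rowMeans(xm^2) - mu^2
    l$run_mean <- (1 - l$momentum) * l$run_mean + l$momentum * mu
    l$run_var <- (1 - l$momentum) * l$run_var + l$momentum * v * N / max(N - 1, 1)
  } else {
    mu <- l$run_mean
    v <- l$run_var
  }
  istd <- 1 / sqrt(v + l$eps)
  xhat <- (xm - mu) * istd       # length-C vectors recycle down columns
  y <- array(l$gamma * xhat + l$beta, dim = d)
  list(y = y, cache = list(xhat = xhat, istd = istd, d = d, train = train), layer = l)
}

bn_backward <- function(l, cache, dy) {
  d <- cache$d
  C <- d[1]; N <- prod(d) / C
  dym <- matrix(dy, C, N)
  dgamma <- rowSums(dym * cache$xhat)
  dbeta <- rowSums(dym)
  if (cache$train) {
    dx <- (l$gamma * cache$istd) *
      (dym - dbeta / N - cache$xhat * (dgamma / N))
  } else {
    dx <- (l$gamma * cache$istd) * dym
  }
  list(dx = array(dx, dim = d), grads = list(gamma = dgamma, beta = dbeta))
}

act_forward <- function(l, x) {
  y <- switch(l$type,
              relu = pmax(x, 0),
              sigmoid = 1 / (1 + exp(-x)),
              tanh = tanh(x),
              stop("unknown activation ", l$type))
  if (is.null(dim(y))) dim(y) <- dim(x)
  list(y = y, cache = list(y = y, pos = if (l$type == "relu") (x > 0) else NULL))
}

act_backward <- function(l, cache, dy) {
  dx <- switch(l$type,
               relu = dy * cache$pos,
               sigmoid = dy * cache$y * (1 - cache$y),
               tanh = dy * (1 - cache$y^2))
  list(dx = dx, grads = NULL)
}

layer_forward <- function(l, x, train) {
  switch(l$type,
         conv = c(conv_forward(l, x), list(layer = l)),
         bn = bn_forward(l, x, train),
         {
           r <- act_forward(l, x)
           list(y = r$y, cache = r$cache, layer = l)
         })
}

layer_backward <- function(l, cache, dy) {
  switch(l$type,
         conv = conv_backward(l, cache, dy),
         bn = bn_backward(l, cache, dy),
         act_backward(l, cache, dy))
}

seq_forward <- function(layers, x, train) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- layer_forward(layers[[i]], x, train)
    x <- r$y
    caches[[i]] <- r$cache
    layers[[i]] <- r$layer
  }
  list(y = x, caches = caches, layers = layers)
}

seq_backward <- function(layers, caches, dy) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- layer_backward(layers[[i]], caches[[i]], dy)
    dy <- r$dx
    grads[i] <- list(r$grads)   # NULL-safe: keep list slots aligned with layers
  }
  list(dx = dy, grads = grads)
}

# --- pooling / upsampling / concat ----------------------------------------

pool_slices <- function(x) {
  d <- dim(x)
  x7 <- x
  dim(x7) <- c(d[1], d[2], 2, d[3] / 2, 2, d[4] / 2, d[5])
  lapply(list(c(1, 1), c(2, 1), c(1, 2), c(2, 2)), function(pq) {
    s <- x7[, , pq[1], , pq[2], , , drop = FALSE]
    dim(s) <- c(d[1], d[2], d[3] / 2, d[4] / 2, d[5])
    s
  })
}

maxpool_forward <- function(x) {
  d <- dim(x)
  if (d[3] %% 2 != 0 || d[4] %% 2 != 0)
    stop("maxpool 1x2x2 needs even H and W; got ", d[3], "x", d[4])
  sl <- pool_slices(x)
  y <- pmax(sl[[1]], sl[[2]], sl[[3]], sl[[4]])
  dim(y) <- c(d[1], d[2], d[3] / 2, d[4] / 2, d[5])
  taken <- vector("list", 4)
  left <- array(TRUE, dim = dim(y))
  for (i in 1:4) {
    taken[[i]] <- (sl[[i]] == y) & left     # ties -> earliest slice
    left <- left & !taken[[i]]
  }
  list(y = y, cache = list(taken = taken, d = d))
}

maxpool_backward <- function(cache, dy) {
  d <- cache$d
  dx7 <- array(0, dim = c(d[1], d[2], 2, d[3] / 2, 2, d[4] / 2, d[5]))
  pq <- list(c(1, 1), c(2, 1), c(1, 2), c(2, 2))
  for (i in 1:4) {
    g <- dy * cache$taken[[i]]
    dim(g) <- c(d[1], d[2], 1, d[3] / 2, 1, d[4] / 2, d[5])
    dx7[, , pq[[i]][1], , pq[[i]][2], , ] <- g
  }
  dim(dx7) <- d
  dx7
}

upsample_forward <- function(x) {
  d <- dim(x)
  y7 <- array(0, dim = c(d[1], d[2], 2, d[3], 2, d[4], d[5]))
  xs <- x
  dim(xs) <- c(d[1], d[2], 1, d[3], 1, d[4], d[5])
  for (p in 1:2) for (q in 1:2) y7[, , p, , q, , ] <- xs
  dim(y7) <- c(d[1], d[2], 2 * d[3], 2 * d[4], d[5])
  list(y = y7, cache = list(d = d))
}

upsample_backward <- function(cache, dy) {
  d <- cache$d
  dy7 <- dy
  dim(dy7) <- c(d[1], d[2], 2, d[3], 2, d[4], d[5])
  dx <- array(0, dim = d)
  for (p in 1:2) for (q in 1:2) {
    s <- dy7[, , p, , q, , , drop = FALSE]
    dim(s) <- d
    dx <- dx + s
  }
  dx
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(identical(da[-1], db[-1]))
  out <- array(0, dim = c(da[1] + db[1], da[2], da[3], da[4], da[5]))
  out[seq_len(da[1]), , , , ] <- a
  out[da[1] + seq_len(db[1]), , , , ] <- b
  list(y = out, c1 = da[1])
}

split_channels <- function(dy, c1) {
  d <- dim(dy)
  a <- dy[seq_len(c1), , , , , drop = FALSE]
  b <- dy[c1 + seq_len(d[1] - c1), , , , , drop = FALSE]
  list(da = a, db = b)
}
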