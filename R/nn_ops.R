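# Minimal neural-network primitives (dense + convolutional), BLAS-backed.
# No deep-learning framework is used anywhere in the package: the networks
# are small enough that im2col convolutions and manual backpropagation in
# plain matrix algebra are fast and, crucially, bit-reproducible under R's
# RNG. Tensors are arrays dim (H, W, C, N); dense activations are (n, d).

sigmoid <- function(x) 1 / (1 + exp(-x))

## ---- dense layers -------------------------------------------------------

dense_init <- function(din, dout) {
  # Glorot-uniform
  lim <- sqrt(6 / (din + dout))
  list(W = matrix(stats::runif(din * dout, -lim, lim), din, dout),
       b = rep(0, dout))
}

dense_fw <- function(x, p) sweep(x %*% p$W, 2, p$b, "+")

dense_bw <- function(dy, x, p) {
  list(dx = dy %*% t(p$W), dW = crossprod(x, dy), db = colSums(dy))
}

## ---- Adam optimizer ------------------------------------------------------

adam_new <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  zero_like <- function(x) {
    if (is.list(x)) lapply(x, zero_like) else x * 0
  }
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0,
       m = zero_like(params), v = zero_like(params))
}

# params and grads are parallel (possibly nested) lists of numeric arrays.
adam_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1
  b1 <- opt$beta1; b2 <- opt$beta2
  corr1 <- 1 - b1^opt$t; corr2 <- 1 - b2^opt$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(walk, p, g, m, v)
      list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else {
      m <- b1 * m + (1 - b1) * g
      v <- b2 * v + (1 - b2) * g^2
      p <- p - opt$lr * (m / corr1) / (sqrt(v / corr2) + opt$eps)
      list(p = p, m = m, v = v)
    }
  }
  out <- walk(params, grads, opt$m, opt$v)
  opt$m <- out$m; opt$v <- out$v
  list(opt = opt, params = out$p)
}

## ---- im2col convolution --------------------------------------------------

# Cache of gather-index matrices keyed by geometry (they only depend on
# shapes, not data).
.conv_idx_cache <- new.env(parent = emptyenv())

conv_indices <- function(Hp, Wp, C, k, stride, oh, ow) {
  key <- paste(Hp, Wp, C, k, stride, sep = "_")
  if (!is.null(.conv_idx_cache[[key]])) return(.conv_idx_cache[[key]])
  # rows: output positions (oh*ow, column-major over (r,c));
  # cols: kernel offsets (kr, kc, channel), column-major
  orow <- rep(seq_len(oh), times = ow)
  ocol <- rep(seq_len(ow), each = oh)
  base_r <- (orow - 1) * stride            # 0-based top of receptive field
  base_c <- (ocol - 1) * stride
  kr <- rep(seq_len(k), times = k * C)
  kc <- rep(rep(seq_len(k), each = k), times = C)
  ch <- rep(seq_len(C), each = k * k)
  idx <- outer(base_r, kr, "+") +                      # rows (1-based)
    Hp * (outer(base_c, kc, "+") - 1) +                # cols
    Hp * Wp * matrix(ch - 1, length(orow), k * k * C, byrow = TRUE)
  .conv_idx_cache[[key]] <- idx
  idx
}

conv_init <- function(k, cin, cout, gain = 2) {
  # He-normal for ReLU-family layers
  sd <- sqrt(gain / (k * k * cin))
  list(W = matrix(stats::rnorm(k * k * cin * cout, sd = sd), k * k * cin, cout),
       b = rep(0, cout))
}

pad_nhwc <- function(x, p) {
  if (p == 0) return(x)
  d <- dim(x)
  xp <- array(0, dim = c(d[1] + 2 * p, d[2] + 2 * p, d[3], d[4]))
  xp[p + seq_len(d[1]), p + seq_len(d[2]), , ] <- x
  xp
}

# x: (H, W, C, N); returns list(y (OH, OW, Cout, N), cache)
conv_fw <- function(x, p, stride = 1, pad = 1) {
  d <- dim(x)
  k <- as.integer(round(sqrt(nrow(p$W) / d[3])))
  xp <- pad_nhwc(x, pad)
  dp <- dim(xp)
  oh <- (dp[1] - k) %/% stride + 1L
  ow <- (dp[2] - k) %/% stride + 1L
  idx <- conv_indices(dp[1], dp[2], d[3], k, stride, oh, ow)
  img_stride <- dp[1] * dp[2] * dp[3]
  # gather all batch images at once
  IDX <- idx[rep(seq_len(nrow(idx)), times = d[4]), , drop = FALSE] +
    rep((seq_len(d[4]) - 1L) * img_stride, each = nrow(idx))
  M <- xp[IDX]
  dim(M) <- dim(IDX)
  Y <- sweep(M %*% p$W, 2, p$b, "+")
  y <- array(Y, dim = c(oh * ow, d[4], ncol(p$W)))
  y <- aperm(y, c(1, 3, 2))
  dim(y) <- c(oh, ow, ncol(p$W), d[4])
  list(y = y, cache = list(M = M, IDX = IDX, xdim = d, pdim = dp, pad = pad,
                           oh = oh, ow = ow, p = p))
}

conv_bw <- function(dy, cache) {
  d <- cache$xdim; dp <- cache$pdim
  n_out <- cache$oh * cache$ow
  cout <- dim(dy)[3]
  dY <- aperm(array(dy, dim = c(n_out, cout, d[4])), c(1, 3, 2))
  dim(dY) <- c(n_out * d[4], cout)
  dW <- crossprod(cache$M, dY)
  db <- colSums(dY)
  dM <- dY %*% t(cache$p$W)
  dxp <- numeric(prod(dp))
  for (kcol in seq_len(ncol(dM)))  # indices within a column are unique
    dxp[cache$IDX[, kcol]] <- dxp[cache$IDX[, kcol]] + dM[, kcol]
  dim(dxp) <- dp
  pad <- cache$pad
  dx <- if (pad > 0)
    dxp[pad + seq_len(d[1]), pad + seq_len(d[2]), , , drop = FALSE]
  else dxp
  dim(dx) <- d
  list(dx = dx, dW = dW, db = db)
}

## ---- activations, upsampling, dropout, instance norm --------------------

lrelu_fw <- function(x, slope = 0.2) list(y = ifelse(x > 0, x, slope * x),
                                          cache = list(x = x, slope = slope))
lrelu_bw <- function(dy, cache) dy * ifelse(cache$x > 0, 1, cache$slope)

relu_fw <- function(x) list(y = pmax(x, 0), cache = x)
relu_bw <- function(dy, cache) dy * (cache > 0)

tanh_fw <- function(x) { y <- tanh(x); list(y = y, cache = y) }
tanh_bw <- function(dy, cache) dy * (1 - cache^2)

upsample_fw <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , , drop = FALSE]
}

upsample_bw <- function(dy) {
  d <- dim(dy)
  r1 <- seq(1, d[1], by = 2); r2 <- r1 + 1
  c1 <- seq(1, d[2], by = 2); c2 <- c1 + 1
  dy[r1, c1, , , drop = FALSE] + dy[r1, c2, , , drop = FALSE] +
    dy[r2, c1, , , drop = FALSE] + dy[r2, c2, , , drop = FALSE]
}

dropout_fw <- function(x, rate, train) {
  if (!train || rate <= 0) return(list(y = x, cache = NULL))
  keep <- array(stats::runif(length(x)) >= rate, dim = dim(x))
  list(y = x * keep / (1 - rate), cache = list(keep = keep, rate = rate))
}
dropout_bw <- function(dy, cache) {
  if (is.null(cache)) dy else dy * cache$keep / (1 - cache$rate)
}

# Instance normalization: per (channel, sample) over spatial dims, with
# per-channel affine parameters.
inorm_init <- function(c) list(gamma = rep(1, c), beta = rep(0, c))

inorm_fw <- function(x, p, eps = 1e-5) {
  d <- dim(x)
  hw <- d[1] * d[2]
  xm <- matrix(x, hw, d[3] * d[4])
  mu <- colMeans(xm)
  xc <- sweep(xm, 2, mu, "-")
  va <- colMeans(xc^2)
  istd <- 1 / sqrt(va + eps)
  xh <- sweep(xc, 2, istd, "*")
  g <- rep(p$gamma, times = d[4])
  y <- sweep(xh, 2, g, "*")
  y <- sweep(y, 2, rep(p$beta, times = d[4]), "+")
  dim(y) <- d
  list(y = y, cache = list(xh = xh, istd = istd, d = d, p = p))
}

inorm_bw <- function(dy, cache) {
  d <- cache$d; hw <- d[1] * d[2]
  dym <- matrix(dy, hw, d[3] * d[4])
  g <- rep(cache$p$gamma, times = d[4])
  dxh <- sweep(dym, 2, g, "*")
  # normalization backward per (channel, sample) column:
  # dx = (dxh - mean(dxh) - xh * mean(dxh * xh)) * istd
  m1 <- colMeans(dxh)
  m2 <- colMeans(dxh * cache$xh)
  dx <- sweep(sweep(dxh, 2, m1, "-") - sweep(cache$xh, 2, m2, "*"),
              2, cache$istd, "*")
  dgamma_full <- colSums(dym * cache$xh)
  dbeta_full <- colSums(dym)
  dgamma <- rowSums(matrix(dgamma_full, d[3], d[4]))
  dbeta <- rowSums(matrix(dbeta_full, d[3], d[4]))
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

## ---- self-attention (gated residual) ------------------------------------

attn_init <- function(c) {
  c8 <- max(1L, c %/% 8L)
  lim <- function(din, dout) sqrt(6 / (din + dout))
  list(Wq = matrix(stats::runif(c * c8, -lim(c, c8), lim(c, c8)), c, c8),
       Wk = matrix(stats::runif(c * c8, -lim(c, c8), lim(c, c8)), c, c8),
       Wv = matrix(stats::runif(c * c, -lim(c, c), lim(c, c)), c, c),
       gamma = 0)
}

softmax_rows <- function(s) {
  e <- exp(s - apply(s, 1, max))
  e / rowSums(e)
}

# x: (H, W, C, N). out = x + gamma * (A V) with A = rowsoftmax(Q K^T).
attn_fw <- function(x, p) {
  d <- dim(x)
  hw <- d[1] * d[2]
  caches <- vector("list", d[4])
  y <- x
  for (n in seq_len(d[4])) {
    X <- matrix(x[, , , n], hw, d[3])
    Q <- X %*% p$Wq; K <- X %*% p$Wk; V <- X %*% p$Wv
    A <- softmax_rows(Q %*% t(K))
    O <- A %*% V
    y[, , , n] <- array(X + p$gamma * O, dim = c(d[1], d[2], d[3]))
    caches[[n]] <- list(X = X, Q = Q, K = K, V = V, A = A, O = O)
  }
  list(y = y, cache = list(per = caches, d = d, p = p))
}

attn_bw <- function(dy, cache) {
  d <- cache$d; hw <- d[1] * d[2]; p <- cache$p
  dx <- dy
  dWq <- p$Wq * 0; dWk <- p$Wk * 0; dWv <- p$Wv * 0; dgamma <- 0
  for (n in seq_len(d[4])) {
    cc <- cache$per[[n]]
    dY <- matrix(dy[, , , n], hw, d[3])
    dgamma <- dgamma + sum(dY * cc$O)
    dO <- p$gamma * dY
    dA <- dO %*% t(cc$V)
    dV <- t(cc$A) %*% dO
    # softmax backward (rows)
    dS <- cc$A * (dA - rowSums(dA * cc$A))
    dQ <- dS %*% cc$K
    dK <- t(dS) %*% cc$Q
    dXn <- dY +                       # residual path
      dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)
    dWq <- dWq + t(cc$X) %*% dQ
    dWk <- dWk + t(cc$X) %*% dK
    dWv <- dWv + t(cc$X) %*% dV
    dx[, , , n] <- array(dXn, dim = c(d[1], d[2], d[3]))
  }
  list(dx = dx, dWq = dWq, dWk = dWk, dWv = dWv, dgamma = dgamma)
}
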