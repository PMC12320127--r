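# ---------------------------------------------------------------------------
# Minimal dense/sparse neural-network primitives.
#
# Feature maps for a batch of N single-subject slices are stored as dense
# matrices with one column per slice. Within a column the layout is
# column-major (row index fastest): pixel index = y + (x-1)*H + (c-1)*H*W.
# Convolutions are implemented as a precomputed sparse patch-gather matrix
# (im2col) followed by one BLAS GEMM against the kernel matrix; pooling is a
# precomputed sparse averaging matrix. Backward passes are the exact
# transposes, so gradients are available for every layer without autodiff.
# ---------------------------------------------------------------------------

# im2col gather index for zero-padded strided 2D convolution.
# Returns an integer vector g of length kh*kw*C*Ho*Wo: entry r gives the
# input pixel index feeding patch position r (patch entries ordered with
# (dy, dx, channel) fastest, then output location column-major); padding
# taps point at the sentinel index npix+1 (a zero row appended at gather
# time). Gathering X[g, ] is the im2col matrix; rowsum() over g is the
# exact transpose (col2im scatter-add).
conv_gather_index <- function(H, W, C, kh, kw, stride = 1L, pad = 0L) {
  Ho <- (H + 2L * pad - kh) %/% stride + 1L
  Wo <- (W + 2L * pad - kw) %/% stride + 1L
  kkc <- kh * kw * C
  dy <- rep(seq_len(kh), times = kw * C)
  dx <- rep(rep(seq_len(kw), each = kh), times = C)
  ch <- rep(seq_len(C), each = kh * kw)
  oy <- rep(seq_len(Ho), times = Wo)
  ox <- rep(seq_len(Wo), each = Ho)
  iy <- outer(dy, (oy - 1L) * stride - pad, "+")          # kkc x HoWo
  ix <- outer(dx, (ox - 1L) * stride - pad, "+")
  cc <- matrix(ch, kkc, Ho * Wo)
  g <- iy + (ix - 1L) * H + (cc - 1L) * (H * W)
  g[iy < 1L | iy > H | ix < 1L | ix > W] <- H * W * C + 1L
  as.integer(g)
}


# Gather index for non-overlapping window average pooling: (win*win) x
# (Ho*Wo) index matrix into the padded pixel vector (sentinel npix+1 for
# out-of-image taps) plus the per-window in-image tap count.
pool_gather_index <- function(H, W, win = 2L, pad = 0L) {
  Ho <- (H + 2L * pad) %/% win
  Wo <- (W + 2L * pad) %/% win
  dy <- rep(seq_len(win), times = win)
  dx <- rep(seq_len(win), each = win)
  oy <- rep(seq_len(Ho), times = Wo)
  ox <- rep(seq_len(Wo), each = Ho)
  iy <- outer(dy, (oy - 1L) * win - pad, "+")
  ix <- outer(dx, (ox - 1L) * win - pad, "+")
  g <- iy + (ix - 1L) * H
  out <- iy < 1L | iy > H | ix < 1L | ix > W
  g[out] <- H * W + 1L
  list(g = matrix(as.integer(g), win * win, Ho * Wo),
       n_in = colSums(!out), Ho = Ho, Wo = Wo)
}

# Grid boundaries for local average pooling: region i along an axis of
# length n with g regions covers indices (floor(n*(i-1)/g)+1) .. floor(n*i/g).
local_pool_bounds <- function(n, g) {
  hi <- floor(n * seq_len(g) / g)
  lo <- c(0L, hi[-g]) + 1L
  cbind(lo = lo, hi = hi)
}

# Sparse matrix mapping (H*W) pixels -> (gh*gw) local-region averages.
local_pool_matrix <- function(H, W, grid = c(2L, 2L)) {
  gh <- grid[1]; gw <- grid[2]
  if (H < gh || W < gw) stop("spatial extent smaller than pooling grid")
  by_ <- local_pool_bounds(H, gh)
  bx_ <- local_pool_bounds(W, gw)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (rx in seq_len(gw)) for (ry in seq_len(gh)) {
    out <- ry + (rx - 1L) * gh
    ys <- seq.int(by_[ry, "lo"], by_[ry, "hi"])
    xs <- seq.int(bx_[rx, "lo"], bx_[rx, "hi"])
    pix <- as.vector(outer(ys, (xs - 1L) * H, "+"))
    ii <- c(ii, rep(out, length(pix)))
    jj <- c(jj, pix)
    xx <- c(xx, rep(1 / length(pix), length(pix)))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(gh * gw, H * W))
}

# --- layer constructors (hold geometry, sparse op and parameters) ----------

he_init <- function(nout, nin, gain = 2) {
  matrix(stats::rnorm(nout * nin, sd = sqrt(gain / nin)), nout, nin)
}

# bias = FALSE for convolutions immediately followed by batch norm (the
# bias is redundant there: BN re-centers per channel).
layer_conv <- function(H, W, C_in, C_out, k = 3L, stride = 1L, pad = 1L,
                       bias = FALSE) {
  g <- conv_gather_index(H, W, C_in, k, k, stride, pad)
  Ho <- (H + 2L * pad - k) %/% stride + 1L
  Wo <- (W + 2L * pad - k) %/% stride + 1L
  params <- list(W = he_init(C_out, k * k * C_in))
  if (bias) params$b <- numeric(C_out)
  list(type = "conv", g = g, npix = H * W * C_in,
       H = H, W = W, C_in = C_in, C_out = C_out,
       kkc = k * k * C_in, Ho = Ho, Wo = Wo, params = params)
}

layer_relu <- function() list(type = "relu", params = list())

# Instance normalization: per channel over spatial positions, separately for
# every slice. Slice-pure (each embedding is a function of its own slice and
# the weights only), so attention localization is not contaminated by
# bag-level statistics. Batch-style normalization over the whole bag was
# rejected for exactly that reason: bag statistics leak bag-level class
# signal into every instance.
layer_inorm <- function(C, eps = 1e-5) {
  list(type = "inorm", C = C, eps = eps,
       params = list(gamma = rep(1, C), beta = numeric(C)))
}

layer_pool <- function(H, W, C, win = 2L, pad = 0L) {
  gi <- pool_gather_index(H, W, win, pad)
  list(type = "pool", gi = gi, H = H, W = W, C = C,
       Ho = gi$Ho, Wo = gi$Wo, params = list())
}

layer_local_pool <- function(H, W, C, grid = c(2L, 2L)) {
  P <- local_pool_matrix(H, W, grid)
  list(type = "spool", P = P, H = H, W = W, C = C,
       Ho = grid[1], Wo = grid[2], params = list())
}

layer_global_pool <- function(H, W, C) {
  P <- Matrix::sparseMatrix(i = rep(1L, H * W), j = seq_len(H * W),
                            x = 1 / (H * W), dims = c(1L, H * W))
  list(type = "spool", P = P, H = H, W = W, C = C, Ho = 1L, Wo = 1L,
       params = list())
}

layer_linear <- function(nin, nout, init_gain = 2) {
  list(type = "linear",
       params = list(W = he_init(nout, nin, init_gain), b = numeric(nout)))
}

# --- forward / backward ----------------------------------------------------

layer_forward <- function(layer, X, keep = FALSE) {
  switch(layer$type,
    conv = {
      N <- ncol(X)
      PP <- im2col_cpp(X, layer$g, layer$kkc)
      Z <- layer$params$W %*% PP
      if (!is.null(layer$params$b)) Z <- Z + layer$params$b
      Z <- chw_to_hwc_cpp(Z, layer$C_out, layer$Ho * layer$Wo)
      list(out = Z, cache = if (keep) list(PP = PP, N = N))
    },
    relu = {
      out <- X * (X > 0)
      list(out = out, cache = if (keep) list(mask = X > 0))
    },
    inorm = {
      C <- layer$C
      N <- ncol(X)
      HW <- nrow(X) %/% C
      dim(X) <- c(HW, C * N)
      ch <- rep(seq_len(C), N)
      m1 <- .colMeans(X, HW, C * N)
      v <- .colMeans(X * X, HW, C * N) - m1^2
      inv <- 1 / sqrt(v + layer$eps)
      sc <- layer$params$gamma[ch] * inv
      sh <- layer$params$beta[ch] - m1 * sc
      out <- sweep(sweep(X, 2, sc, "*"), 2, sh, "+")
      dim(out) <- c(HW * C, N)
      list(out = out,
           cache = if (keep) list(X = X, m1 = m1, inv = inv, ch = ch,
                                  HW = HW, N = N))
    },
    pool = {
      N <- ncol(X)
      dim(X) <- c(layer$H * layer$W, layer$C * N)
      Y <- pool_fwd_cpp(X, layer$gi$g, layer$gi$n_in)
      dim(Y) <- c(layer$Ho * layer$Wo * layer$C, N)
      list(out = Y, cache = if (keep) list(N = N))
    },
    spool = {
      N <- ncol(X)
      dim(X) <- c(layer$H * layer$W, layer$C * N)
      Y <- as.matrix(layer$P %*% X)
      dim(Y) <- c(layer$Ho * layer$Wo * layer$C, N)
      list(out = Y, cache = if (keep) list(N = N))
    },
    linear = {
      list(out = layer$params$W %*% X + layer$params$b,
           cache = if (keep) list(X = X))
    },
    stop("unknown layer type"))
}

layer_backward <- function(layer, dY, cache) {
  switch(layer$type,
    conv = {
      dZ <- hwc_to_chw_cpp(dY, layer$C_out, layer$Ho * layer$Wo)
      dW <- tcrossprod(dZ, cache$PP)
      dPP <- crossprod(layer$params$W, dZ)
      dX <- col2im_cpp(dPP, layer$g, layer$npix)
      grads <- list(W = dW)
      if (!is.null(layer$params$b)) grads$b <- rowSums(dZ)
      list(dX = dX, grads = grads)
    },
    relu = list(dX = dY * cache$mask, grads = list()),
    inorm = {
      C <- layer$C; HW <- cache$HW; N <- cache$N
      ch <- cache$ch
      dim(dY) <- c(HW, C * N)
      xhat <- sweep(sweep(cache$X, 2, cache$m1), 2, cache$inv, "*")
      sum_dy <- .colSums(dY, HW, C * N)
      sum_dyx <- .colSums(dY * xhat, HW, C * N)
      dgamma <- as.vector(rowsum(sum_dyx, ch))
      dbeta <- as.vector(rowsum(sum_dy, ch))
      coef <- (layer$params$gamma[ch] * cache$inv) / HW
      dX <- sweep(dY * HW - sweep(xhat, 2, sum_dyx, "*"), 2, sum_dy) *
        rep(coef, each = HW)
      dim(dX) <- c(HW * C, N)
      list(dX = dX, grads = list(gamma = dgamma, beta = dbeta))
    },
    pool = {
      N <- cache$N
      dim(dY) <- c(layer$Ho * layer$Wo, layer$C * N)
      dX <- pool_bwd_cpp(dY, layer$gi$g, layer$gi$n_in, layer$H * layer$W)
      dim(dX) <- c(layer$H * layer$W * layer$C, N)
      list(dX = dX, grads = list())
    },
    spool = {
      N <- cache$N
      dim(dY) <- c(layer$Ho * layer$Wo, layer$C * N)
      dX <- as.matrix(Matrix::crossprod(layer$P, dY))
      dim(dX) <- c(layer$H * layer$W * layer$C, N)
      list(dX = dX, grads = list())
    },
    linear = {
      list(dX = crossprod(layer$params$W, dY),
           grads = list(W = tcrossprod(dY, cache$X), b = rowSums(dY)))
    },
    stop("unknown layer type"))
}

# --- Adam optimizer on a flat named list of parameter arrays ---------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Run a computation with a temporary RNG seed, restoring the caller's RNG.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
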