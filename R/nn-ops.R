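# Differentiable 3D network primitives on CPU.
#
# Feature maps are stored as nvox x C matrices (voxels in array order for a
# given spatial shape). Convolutions use im2col gathers with cached index
# tables plus BLAS matrix multiplies; gradients are written out explicitly
# (no autodiff dependency exists in this stack). Adequate for the desk-scale
# volumes (24^3 - 32^3) this package trains on.

.nn_cache <- new.env(parent = emptyenv())

# Index table mapping each (output voxel, kernel offset, input channel) to a
# linear index into the zero-padded input vector; plus the indices of the
# unpadded voxels inside the padded vector.
conv3_index <- function(shape, cin, stride) {
  key <- paste(c(shape, cin, stride), collapse = "_")
  hit <- .nn_cache[[key]]
  if (!is.null(hit)) return(hit)
  pd <- shape + 2L
  od <- (shape - 1L) %/% stride + 1L
  ox <- (seq_len(od[1]) - 1L) * stride  # 0-based start in padded
  oy <- (seq_len(od[2]) - 1L) * stride
  oz <- (seq_len(od[3]) - 1L) * stride
  base <- as.vector(outer(outer(ox, oy * pd[1], `+`), oz * pd[1] * pd[2], `+`))
  nvox_out <- length(base)
  cols <- vector("list", 27L * cin)
  ci <- 0L
  voxels_per_ch <- prod(pd)
  for (c in seq_len(cin)) {
    choff <- (c - 1L) * voxels_per_ch
    for (dz in 0:2) for (dy in 0:2) for (dx in 0:2) {
      ci <- ci + 1L
      cols[[ci]] <- base + (dx + dy * pd[1] + dz * pd[1] * pd[2]) + choff + 1L
    }
  }
  idx <- matrix(unlist(cols), nrow = nvox_out)
  ix <- seq_len(shape[1]) + 1L; iy <- seq_len(shape[2]) + 1L; iz <- seq_len(shape[3]) + 1L
  inner1 <- as.vector(outer(outer(ix, (iy - 1L) * pd[1], `+`),
                            (iz - 1L) * pd[1] * pd[2], `+`))
  inner <- as.vector(outer(inner1, (seq_len(cin) - 1L) * voxels_per_ch, `+`))
  out <- list(idx = idx, inner = inner, out_shape = od, pad_len = prod(pd) * cin)
  .nn_cache[[key]] <- out
  out
}

# 3^3 convolution, zero padding 1, stride 1 or 2.
conv3_forward <- function(x, shape, W, b, stride = 1L) {
  cin <- ncol(x)
  ci <- conv3_index(shape, cin, stride)
  xp <- numeric(ci$pad_len)
  xp[ci$inner] <- x
  M <- matrix(xp[ci$idx], nrow = nrow(ci$idx))
  y <- M %*% W
  y <- sweep(y, 2, b, `+`)
  list(y = y, shape = ci$out_shape, cache = list(M = M, ci = ci, cin = cin,
                                                W = W, in_n = nrow(x)))
}

conv3_backward <- function(dy, cache) {
  M <- cache$M; ci <- cache$ci
  dW <- crossprod(M, dy)
  db <- colSums(dy)
  dM <- dy %*% t(cache$W)
  dxp <- numeric(ci$pad_len)
  for (j in seq_len(ncol(dM))) {
    id <- ci$idx[, j]
    dxp[id] <- dxp[id] + dM[, j]
  }
  dx <- matrix(dxp[ci$inner], nrow = cache$in_n)
  list(dx = dx, dW = dW, db = db)
}

# 1x1x1 convolution: pure channel mixing.
conv1_forward <- function(x, W, b) {
  y <- x %*% W
  y <- sweep(y, 2, b, `+`)
  list(y = y, cache = list(x = x, W = W))
}

conv1_backward <- function(dy, cache) {
  list(dx = dy %*% t(cache$W), dW = crossprod(cache$x, dy), db = colSums(dy))
}

# Instance normalization (batch of one): per-channel spatial statistics.
instnorm_forward <- function(x, gamma, beta, eps = 1e-5) {
  n <- nrow(x)
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  v <- colSums(xc^2) / n
  istd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, istd, `*`)
  y <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  list(y = y, cache = list(xhat = xhat, istd = istd, gamma = gamma, n = n))
}

instnorm_backward <- function(dy, cache) {
  xhat <- cache$xhat; n <- cache$n
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2, cache$gamma, `*`)
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * xhat)
  dx <- sweep(sweep(dxhat, 2, m1) - sweep(xhat, 2, m2, `*`), 2, cache$istd, `*`)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

relu_forward <- function(x) {
  mask <- x > 0
  list(y = x * mask, cache = mask)
}

relu_backward <- function(dy, mask) dy * mask

# Sparse trilinear interpolation operator from one cubic-ish shape onto
# another (both covering the same physical extent; half-voxel alignment).
upsample_operator <- function(from_shape, to_shape) {
  key <- paste(c("up", from_shape, to_shape), collapse = "_")
  hit <- .nn_cache[[key]]
  if (!is.null(hit)) return(hit)
  axes <- lapply(1:3, function(a) {
    f <- (seq_len(to_shape[a]) - 0.5) * (from_shape[a] / to_shape[a]) + 0.5
    i0 <- pmin(pmax(floor(f), 1), max(from_shape[a] - 1L, 1L))
    fr <- pmin(pmax(f - i0, 0), 1)
    list(i0 = i0, i1 = pmin(i0 + 1L, from_shape[a]), w1 = fr, w0 = 1 - fr)
  })
  nvo <- prod(to_shape)
  gx <- rep(seq_len(to_shape[1]), times = to_shape[2] * to_shape[3])
  gy <- rep(rep(seq_len(to_shape[2]), each = to_shape[1]), times = to_shape[3])
  gz <- rep(seq_len(to_shape[3]), each = to_shape[1] * to_shape[2])
  ii <- jj <- xx <- vector("list", 8L)
  k <- 0L
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    k <- k + 1L
    sx <- if (cx == 0) axes[[1]]$i0 else axes[[1]]$i1
    sy <- if (cy == 0) axes[[2]]$i0 else axes[[2]]$i1
    sz <- if (cz == 0) axes[[3]]$i0 else axes[[3]]$i1
    wx <- if (cx == 0) axes[[1]]$w0 else axes[[1]]$w1
    wy <- if (cy == 0) axes[[2]]$w0 else axes[[2]]$w1
    wz <- if (cz == 0) axes[[3]]$w0 else axes[[3]]$w1
    ii[[k]] <- seq_len(nvo)
    jj[[k]] <- sx[gx] + (sy[gy] - 1L) * from_shape[1] +
      (sz[gz] - 1L) * from_shape[1] * from_shape[2]
    xx[[k]] <- wx[gx] * wy[gy] * wz[gz]
  }
  S <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(nvo, prod(from_shape)))
  .nn_cache[[key]] <- S
  S
}

upsample_forward <- function(x, from_shape, to_shape) {
  if (all(from_shape == to_shape)) return(list(y = x, cache = NULL))
  S <- upsample_operator(from_shape, to_shape)
  list(y = as.matrix(S %*% x), cache = S)
}

upsample_backward <- function(dy, cache) {
  if (is.null(cache)) return(dy)
  as.matrix(Matrix::crossprod(cache, dy))
}

# Combined L1 + mean-squared-error objective and its gradient.
l1_mse_loss <- function(pred, ref) {
  d <- pred - ref
  n <- length(d)
  list(loss = mean(abs(d)) + mean(d^2),
       grad = sign(d) / n + 2 * d / n)
}

adam_init <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
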