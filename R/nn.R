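# Minimal layer zoo for the volumetric encoder: 3-D convolution (C++ im2col
# + GEMM), instance normalisation, ReLU, global average pooling, dense
# layers, and Adam. Everything operates on single samples in channel-first
# (C, X, Y, Z) layout; batching is a plain gradient average, which instance
# normalisation keeps exact.

conv_fw <- function(x, W, b, ksize, stride = 1L, pad = (ksize - 1L) %/% 2L) {
  cpp_conv3d_fw(x, dim(x), W, b, as.integer(ksize), as.integer(stride),
                as.integer(pad))
}

conv_bw <- function(x, W, dy, ksize, stride = 1L, pad = (ksize - 1L) %/% 2L,
                    need_dx = TRUE) {
  cpp_conv3d_bw(x, dim(x), W, dy, as.integer(ksize), as.integer(stride),
                as.integer(pad), isTRUE(need_dx))
}

# Instance norm: per-channel standardisation over the spatial voxels of one
# sample, followed by a learnable affine (gamma, beta). With a single
# spatial voxel standardisation would annihilate the signal (the mean equals
# the value), so the layer degrades to the plain affine map there.
inorm_fw <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x)
  M <- matrix(x, nrow = d[1])
  if (ncol(M) == 1L) {
    y <- M * gamma + beta
    dim(y) <- d
    return(list(y = y, xhat = M, inv = NULL, dims = d))
  }
  mu <- rowMeans(M)
  v <- rowMeans(M * M) - mu * mu
  inv <- 1 / sqrt(pmax(v, 0) + eps)
  xhat <- (M - mu) * inv
  y <- xhat * gamma + beta
  dim(y) <- d
  list(y = y, xhat = xhat, inv = inv, dims = d)
}

inorm_bw <- function(cache, gamma, dy) {
  d <- cache$dims
  dY <- matrix(dy, nrow = d[1])
  dgamma <- rowSums(dY * cache$xhat)
  dbeta <- rowSums(dY)
  dxhat <- dY * gamma
  if (is.null(cache$inv)) {  # single-voxel affine branch
    dx <- dxhat
    dim(dx) <- d
    return(list(dx = dx, dgamma = dgamma, dbeta = dbeta))
  }
  dx <- cache$inv *
    (dxhat - rowMeans(dxhat) - cache$xhat * rowMeans(dxhat * cache$xhat))
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

relu_fw <- function(x) x * (x > 0)

relu_bw <- function(y, dy) dy * (y > 0)

pool_fw <- function(x) {
  d <- dim(x)
  rowMeans(matrix(x, nrow = d[1]))
}

pool_bw <- function(dims, dvec) {
  n <- prod(dims[2:4])
  dx <- matrix(dvec / n, nrow = dims[1], ncol = n)
  dim(dx) <- dims
  dx
}

# Layer norm (no affine) on a plain vector: z-scores the pooled feature so
# embeddings are not dominated by the input-independent component that
# average pooling of rectified maps produces.
lnorm_fw <- function(x, eps = 1e-5) {
  mu <- mean(x)
  v <- mean(x * x) - mu * mu
  inv <- 1 / sqrt(max(v, 0) + eps)
  xhat <- (x - mu) * inv
  list(y = xhat, xhat = xhat, inv = inv)
}

lnorm_bw <- function(cache, dy) {
  cache$inv * (dy - mean(dy) - cache$xhat * mean(dy * cache$xhat))
}

dense_fw <- function(x, W, b) as.vector(W %*% x + b)

dense_bw <- function(x, W, dy) {
  list(dx = as.vector(crossprod(W, dy)), dW = tcrossprod(dy, x), db = dy)
}

softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

# He (fan-in) initialisation; draws come from the ambient RNG stream so the
# caller controls seeding.
he_weights <- function(nout, nin) {
  matrix(rnorm(nout * nin, sd = sqrt(2 / nin)), nrow = nout, ncol = nin)
}

# ---- Adam -------------------------------------------------------------

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# elementwise sum of two same-shaped gradient lists
acc_grads <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) a[[nm]] <- a[[nm]] + b[[nm]]
  a
}

scale_grads <- function(g, f) lapply(g, function(x) x * f)
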