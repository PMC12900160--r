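# Minimal neural-network engine for the multi-branch 1D-CNN.
#
# Convolutions are expressed as im2col patch matrices multiplied through
# BLAS, so everything runs in vectorised base R. Activations of a batch of
# B windows of length L are kept in "flat" (B*L, C) matrices whose row
# index is r = (t-1)*B + b; a time shift of o samples is then a plain
# vector shift by o*B positions, which keeps patch extraction cheap.
# Only the pieces this architecture needs are implemented: same-padding
# stride-1 1D convolution, batch normalization, ReLU, inverted dropout,
# global average pooling, dense layers, sigmoid head, and Adam.

# column-wise helpers (faster than sweep for tall matrices)
add_cols <- function(z, v) z + rep(v, each = nrow(z))
mul_cols <- function(z, v) z * rep(v, each = nrow(z))

# im2col for same-padding stride-1 1D convolution on the flat layout.
# x: (B*L, C). Returns (B*L, K*C); column (c-1)*K + k holds the input
# shifted by o = k - 1 - (K-1)/2 time steps (zero padded).
im2col <- function(x, B, L, K) {
  n <- B * L
  C <- ncol(x)
  half <- (K - 1L) %/% 2L
  M <- matrix(0, n, K * C)
  for (c in seq_len(C)) {
    xc <- x[, c]
    for (k in seq_len(K)) {
      o <- (k - 1L - half) * B
      col <- (c - 1L) * K + k
      if (o == 0L) M[, col] <- xc
      else if (o > 0L) M[seq_len(n - o), col] <- xc[(o + 1L):n]
      else M[(-o + 1L):n, col] <- xc[seq_len(n + o)]
    }
  }
  M
}

# Scatter-add the im2col gradient back onto the flat input.
col2im <- function(dM, B, L, C, K) {
  n <- B * L
  half <- (K - 1L) %/% 2L
  dx <- matrix(0, n, C)
  for (c in seq_len(C)) {
    acc <- numeric(n)
    for (k in seq_len(K)) {
      o <- (k - 1L - half) * B
      g <- dM[, (c - 1L) * K + k]
      if (o == 0L) acc <- acc + g
      else if (o > 0L) acc[(o + 1L):n] <- acc[(o + 1L):n] + g[seq_len(n - o)]
      else acc[seq_len(n + o)] <- acc[seq_len(n + o)] + g[(-o + 1L):n]
    }
    dx[, c] <- acc
  }
  dx
}

nn_init_dense <- function(n_in, n_out) {
  list(W = matrix(stats::rnorm(n_in * n_out, 0, sqrt(2 / n_in)), n_in, n_out),
       b = rep(0, n_out))
}

nn_init_conv <- function(K, C_in, F_out) nn_init_dense(K * C_in, F_out)

bn_forward <- function(z, bn, gamma, beta, training, momentum = 0.9,
                       eps = 1e-5) {
  if (training) {
    mu <- colMeans(z)
    v <- colMeans(z^2) - mu^2
    bn$run_mean <- momentum * bn$run_mean + (1 - momentum) * mu
    bn$run_var <- momentum * bn$run_var + (1 - momentum) * v
  } else {
    mu <- bn$run_mean
    v <- bn$run_var
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- mul_cols(add_cols(z, -mu), inv)
  out <- add_cols(mul_cols(xhat, gamma), beta)
  list(out = out, cache = list(xhat = xhat, inv = inv), bn = bn)
}

bn_backward <- function(dout, cache, gamma) {
  xhat <- cache$xhat
  dgamma <- colSums(dout * xhat)
  dbeta <- colSums(dout)
  dxhat <- mul_cols(dout, gamma)
  dz <- mul_cols(
    add_cols(dxhat - mul_cols(xhat, colMeans(dxhat * xhat)),
             -colMeans(dxhat)),
    cache$inv
  )
  list(dz = dz, dgamma = dgamma, dbeta = dbeta)
}

dropout_mask <- function(dim_, rate) {
  if (rate <= 0) return(NULL)
  matrix((stats::runif(prod(dim_)) >= rate) / (1 - rate), dim_[1], dim_[2])
}

# Adam optimizer state and update over a flat named list of arrays.
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Average-pool the time axis of a flat (B*L, C) activation by factor p
# (trailing remainder of the time axis dropped).
avg_pool_flat <- function(x, B, L, p) {
  Lp <- L %/% p
  out <- matrix(0, B * Lp, ncol(x))
  for (c in seq_len(ncol(x))) {
    xm <- matrix(x[, c], B, L)
    acc <- matrix(0, B, Lp)
    for (j in seq_len(p)) acc <- acc + xm[, seq(j, Lp * p, by = p), drop = FALSE]
    out[, c] <- as.vector(acc) / p
  }
  out
}

avg_unpool_flat <- function(d, B, Lp, p, L) {
  out <- matrix(0, B * L, ncol(d))
  for (c in seq_len(ncol(d))) {
    g <- matrix(d[, c], B, Lp) / p
    m <- matrix(0, B, L)
    for (j in seq_len(p)) m[, seq(j, Lp * p, by = p)] <- g
    out[, c] <- as.vector(m)
  }
  out
}

# --- one convolutional branch -------------------------------------------

branch_forward <- function(x_mat, layers, K, dropout, training, batchnorm,
                           pool = 1L) {
  B <- nrow(x_mat); L0 <- ncol(x_mat)
  L <- L0
  x <- matrix(as.vector(x_mat), B * L, 1L)    # flat layout, C = 1
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    C <- ncol(x)
    M <- im2col(x, B, L, K)
    z <- add_cols(M %*% layers[[i]]$conv$W, layers[[i]]$conv$b)
    if (batchnorm) {
      bnres <- bn_forward(z, layers[[i]]$bn_stats, layers[[i]]$bn_gamma,
                          layers[[i]]$bn_beta, training)
      layers[[i]]$bn_stats <- bnres$bn
      a_pre <- bnres$out
      bn_cache <- bnres$cache
    } else {
      a_pre <- z
      bn_cache <- NULL
    }
    relu_mask <- a_pre > 0
    a <- a_pre * relu_mask
    dmask <- if (training) dropout_mask(dim(a), dropout) else NULL
    if (!is.null(dmask)) a <- a * dmask
    caches[[i]] <- list(M = M, C = C, L_in = L, bn_cache = bn_cache,
                        relu_mask = relu_mask, dmask = dmask)
    if (pool > 1L && i < length(layers)) {
      a <- avg_pool_flat(a, B, L, pool)
      L <- L %/% pool
    }
    x <- a
  }
  Fo <- ncol(x)
  # GAP: mean over the L time rows of each sample; the flat layout makes
  # each feature map a contiguous (B, L) block after a dim reshape
  gap <- matrix(0, B, Fo)
  for (f in seq_len(Fo)) gap[, f] <- rowMeans(matrix(x[, f], B, L))
  list(gap = gap, caches = caches, B = B, L = L, layers = layers,
       pool = pool)
}

branch_backward <- function(dgap, fwd, layers, K, batchnorm) {
  B <- fwd$B; L <- fwd$L
  pool <- fwd$pool %||% 1L
  grads <- list()
  # GAP backward: spread the gradient uniformly over time
  da <- dgap[rep(seq_len(B), times = L), , drop = FALSE] / L
  for (i in rev(seq_along(layers))) {
    cache <- fwd$caches[[i]]
    if (pool > 1L && i < length(layers)) {
      da <- avg_unpool_flat(da, B, L, pool, cache$L_in)
      L <- cache$L_in
    }
    if (!is.null(cache$dmask)) da <- da * cache$dmask
    da <- da * cache$relu_mask
    if (batchnorm) {
      bb <- bn_backward(da, cache$bn_cache, layers[[i]]$bn_gamma)
      dz <- bb$dz
      grads[[paste0("bn_gamma_", i)]] <- bb$dgamma
      grads[[paste0("bn_beta_", i)]] <- bb$dbeta
    } else {
      dz <- da
    }
    grads[[paste0("conv_W_", i)]] <- crossprod(cache$M, dz)
    grads[[paste0("conv_b_", i)]] <- colSums(dz)
    if (i > 1L) {
      dM <- tcrossprod(dz, layers[[i]]$conv$W)
      da <- col2im(dM, B, L, cache$C, K)
    }
  }
  grads
}
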