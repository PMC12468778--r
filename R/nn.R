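# Convolutional network primitives with explicit backpropagation.
#
# Feature maps are stored as plain matrices of dim (H*W*N) x C with row order
# (i fastest, then j, then image index n); spatial dims travel alongside.
# Convolutions are same-padded (zero padding, stride 1, odd kernel) and run
# as im2col + BLAS matmul. The gradient w.r.t. the input of a convolution is
# itself a same-padded convolution with the spatially flipped,
# channel-transposed kernel, so a single conv routine serves both directions.

# Gather k x k patches: returns (H*W*N) x (k*k*C), columns ordered
# (ki fastest, kj, c) to match the column-major flattening of a
# (k, k, Cin, Cout) weight array.
im2col <- function(Fm, H, W, N, k) {
  C <- ncol(Fm)
  p <- (k - 1L) %/% 2L
  Hp <- H + 2L * p; Wp <- W + 2L * p
  xa <- array(Fm, dim = c(H, W, N, C))
  xp <- array(0, dim = c(Hp, Wp, N, C))
  xp[p + seq_len(H), p + seq_len(W), , ] <- xa
  cols <- matrix(0, H * W * N, k * k * C)
  q <- 0L
  for (cc in seq_len(C)) {
    for (kj in seq_len(k)) {
      for (ki in seq_len(k)) {
        q <- q + 1L
        cols[, q] <- xp[ki:(ki + H - 1L), kj:(kj + W - 1L), , cc]
      }
    }
  }
  cols
}

conv_fwd <- function(Fm, H, W, N, Warr, b = NULL, keep_cols = FALSE) {
  k <- dim(Warr)[1L]
  cols <- im2col(Fm, H, W, N, k)
  out <- cols %*% matrix(Warr, ncol = dim(Warr)[4L])
  if (!is.null(b)) out <- sweep(out, 2L, b, "+")
  list(out = out, cols = if (keep_cols) cols else NULL)
}

# dY: (H*W*N) x Cout. Returns input gradient and (optionally) weight grads.
conv_bwd <- function(dY, H, W, N, Warr, cols = NULL, need_input = TRUE) {
  k <- dim(Warr)[1L]
  dW <- db <- NULL
  if (!is.null(cols)) {
    dW <- array(crossprod(cols, dY), dim = dim(Warr))
    db <- colSums(dY)
  }
  dX <- NULL
  if (need_input) {
    Wf <- aperm(Warr[k:1, k:1, , , drop = FALSE], c(1L, 2L, 4L, 3L))
    dX <- conv_fwd(dY, H, W, N, Wf)$out
  }
  list(dX = dX, dW = dW, db = db)
}

relu_fwd <- function(x) {
  mask <- x > 0
  list(out = x * mask, mask = mask)
}

# Batch normalization over (H, W, N) per channel; biased batch variance.
bn_fwd <- function(x, gamma, beta, training, rm, rv, eps = 1e-5, momentum = 0.1) {
  if (training) {
    mu <- colMeans(x)
    xc <- sweep(x, 2L, mu)
    v <- colMeans(xc^2)
    rm <- (1 - momentum) * rm + momentum * mu
    rv <- (1 - momentum) * rv + momentum * v
  } else {
    mu <- rm; v <- rv
    xc <- sweep(x, 2L, mu)
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2L, istd, "*")
  out <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  list(out = out, cache = list(xhat = xhat, istd = istd, gamma = gamma),
       rm = rm, rv = rv)
}

bn_bwd <- function(dY, cache) {
  M <- nrow(dY)
  xhat <- cache$xhat
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dxhat <- sweep(dY, 2L, cache$gamma, "*")
  # dx = istd * (dxhat - mean(dxhat) - xhat * mean(dxhat * xhat))
  dx <- dxhat
  dx <- sweep(dx, 2L, colMeans(dxhat))
  dx <- dx - sweep(xhat, 2L, colMeans(dxhat * xhat), "*")
  dx <- sweep(dx, 2L, cache$istd, "*")
  list(dX = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- nested-parameter utilities (Adam) --------------------------------------

nl_map <- function(f, a) {
  if (is.list(a)) lapply(a, function(el) nl_map(f, el)) else f(a)
}

nl_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- nl_map2(f, a[[i]], b[[i]])
    out
  } else {
    f(a, b)
  }
}

nl_zeros_like <- function(a) nl_map(function(x) x * 0, a)

adam_init <- function(params) {
  list(m = nl_zeros_like(params), v = nl_zeros_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- nl_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- nl_map2(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- nl_map2(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                 state$m, state$v)
  params <- nl_map2(`-`, params, upd)
  list(params = params, state = state)
}
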