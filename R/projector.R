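# DnCNN projector: the trainable stand-in for the projection onto the set of
# plausible images. Architecture: input conv (kernel x kernel x 1 -> width)
# + ReLU, then L intermediate blocks (conv width -> width, batch norm, ReLU),
# then an output conv (width -> 1). Same-padding throughout, so one set of
# weights serves any image side >= kernel.

#' DnCNN projector configuration
#'
#' @param L number of intermediate conv+BN+ReLU blocks (>= 0).
#' @param width channels of the hidden layers (default 64).
#' @param residual if `TRUE`, the projection step returns `x + P(x)` instead
#'   of `P(x)`.
#' @param kernel spatial kernel size (odd, default 3).
#' @param batchnorm batch-normalize the intermediate blocks (default `TRUE`;
#'   when on, intermediate convs carry no bias since BN's shift absorbs it).
#' @param final_bias include a bias in the output conv (default `TRUE`).
#' @return A `dncnn_config` object.
#' @export
dncnn_config <- function(L = 5L, width = 64L, residual = TRUE, kernel = 3L,
                         batchnorm = TRUE, final_bias = TRUE) {
  check_scalar(L, "L"); check_scalar(width, "width"); check_scalar(kernel, "kernel")
  if (L < 0) stop_config("L must be >= 0")
  if (width < 1) stop_config("width must be >= 1")
  if (kernel %% 2 != 1) stop_config("kernel must be odd")
  structure(list(L = as.integer(L), width = as.integer(width),
                 residual = isTRUE(residual), kernel = as.integer(kernel),
                 batchnorm = isTRUE(batchnorm), final_bias = isTRUE(final_bias)),
            class = "dncnn_config")
}

#' Trainable parameter count of a DnCNN configuration
#'
#' Input conv: `k^2 * width + width`. Each intermediate block:
#' `k^2 * width^2 + 2 * width` with batch norm (gamma and beta; conv bias
#' absorbed), or `k^2 * width^2 + width` without. Output conv:
#' `k^2 * width (+ 1)`.
#'
#' @param config a `dncnn_config`.
#' @return Integer parameter count.
#' @export
dncnn_param_count <- function(config) {
  k2 <- config$kernel^2
  w <- config$width
  per_block <- if (config$batchnorm) k2 * w * w + 2 * w else k2 * w * w + w
  (k2 * w + w) + config$L * per_block + (k2 * w + as.integer(config$final_bias))
}

he_init <- function(k, cin, cout) {
  array(stats::rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
        dim = c(k, k, cin, cout))
}

#' Build a DnCNN projector with seeded random weights
#'
#' Weights use fan-in-scaled (He) normal initialization; BN scale/shift start
#' at 1/0. The same seed reproduces identical weights and hence identical
#' forward outputs.
#'
#' @param config a `dncnn_config`.
#' @param seed integer seed for the weight draw.
#' @return A `dncnn` object with elements `config`, `params` (nested trainable
#'   parameters) and `state` (BN running statistics).
#' @export
build_dncnn <- function(config, seed = 1L) {
  stopifnot(inherits(config, "dncnn_config"))
  k <- config$kernel; w <- config$width
  with_seed(seed, {
    params <- list(
      input = list(W = he_init(k, 1L, w), b = numeric(w)),
      mid = lapply(seq_len(config$L), function(l) {
        blk <- list(W = he_init(k, w, w))
        if (config$batchnorm) {
          blk$gamma <- rep(1, w); blk$beta <- numeric(w)
        } else {
          blk$b <- numeric(w)
        }
        blk
      }),
      output = list(W = he_init(k, w, 1L))
    )
    if (config$final_bias) params$output$b <- 0
    state <- list(mid = lapply(seq_len(config$L), function(l) {
      list(rm = numeric(w), rv = rep(1, w))
    }))
    structure(list(config = config, params = params, state = state),
              class = "dncnn")
  })
}

#' @export
print.dncnn <- function(x, ...) {
  cat(sprintf("<dncnn: L=%d, width=%d, kernel=%d, batchnorm=%s, %d parameters>\n",
              x$config$L, x$config$width, x$config$kernel,
              x$config$batchnorm, dncnn_param_count(x$config)))
  invisible(x)
}

# Forward pass on a side x side x N batch. Returns the output batch plus,
# when keep_cache, everything backprop needs, and updated BN running stats
# when training.
dncnn_fwd <- function(net, arr, training = FALSE, keep_cache = FALSE) {
  cfg <- net$config
  d <- dim(arr)
  H <- d[1L]; W <- d[2L]; N <- d[3L]
  Fm <- matrix(as.vector(arr), ncol = 1L)
  cache <- list(H = H, W = W, N = N)

  cv <- conv_fwd(Fm, H, W, N, net$params$input$W, net$params$input$b, keep_cols = keep_cache)
  rl <- relu_fwd(cv$out)
  cache$input <- list(cols = cv$cols, mask = rl$mask)
  h <- rl$out

  cache$mid <- vector("list", cfg$L)
  for (l in seq_len(cfg$L)) {
    blk <- net$params$mid[[l]]
    cv <- conv_fwd(h, H, W, N, blk$W, blk$b, keep_cols = keep_cache)
    z <- cv$out
    mc <- list(cols = cv$cols)
    if (cfg$batchnorm) {
      st <- net$state$mid[[l]]
      bn <- bn_fwd(z, blk$gamma, blk$beta, training, st$rm, st$rv)
      z <- bn$out
      mc$bn <- bn$cache
      if (training) net$state$mid[[l]] <- list(rm = bn$rm, rv = bn$rv)
    }
    rl <- relu_fwd(z)
    mc$mask <- rl$mask
    cache$mid[[l]] <- mc
    h <- rl$out
  }
  cache$pre_out <- if (keep_cache) h else NULL

  cv <- conv_fwd(h, H, W, N, net$params$output$W, net$params$output$b, keep_cols = keep_cache)
  cache$output <- list(cols = cv$cols)
  list(out = array(cv$out, dim = d), cache = cache, state = net$state)
}

# Backprop: dOut is side x side x N. Returns nested grads (same shape as
# params) and the gradient w.r.t. the input batch.
dncnn_bwd <- function(net, cache, dOut) {
  cfg <- net$config
  H <- cache$H; W <- cache$W; N <- cache$N
  dY <- matrix(as.vector(dOut), ncol = 1L)

  cb <- conv_bwd(dY, H, W, N, net$params$output$W, cache$output$cols)
  grads <- list(output = list(W = cb$dW))
  if (cfg$final_bias) grads$output$b <- cb$db
  dh <- cb$dX

  grads$mid <- vector("list", cfg$L)
  for (l in rev(seq_len(cfg$L))) {
    mc <- cache$mid[[l]]
    dz <- dh * mc$mask
    g <- list()
    if (cfg$batchnorm) {
      bb <- bn_bwd(dz, mc$bn)
      g$gamma <- bb$dgamma; g$beta <- bb$dbeta
      dz <- bb$dX
    }
    cb <- conv_bwd(dz, H, W, N, net$params$mid[[l]]$W, mc$cols)
    g <- c(list(W = cb$dW), g)
    if (!cfg$batchnorm) g$b <- cb$db
    grads$mid[[l]] <- g[names(net$params$mid[[l]])]
    dh <- cb$dX
  }

  dz <- dh * cache$input$mask
  cb <- conv_bwd(dz, H, W, N, net$params$input$W, cache$input$cols)
  grads$input <- list(W = cb$dW, b = cb$db)
  list(grads = grads[names(net$params)],
       dInput = array(cb$dX, dim = c(H, W, N)))
}

#' Run a DnCNN on an image or batch
#'
#' @param net a `dncnn`.
#' @param x `side x side` matrix or `side x side x N` batch.
#' @param training use batch statistics for BN (`TRUE`) or running statistics
#'   (`FALSE`, the default inference behaviour).
#' @return Output of the same shape as `x`.
#' @export
dncnn_forward <- function(net, x, training = FALSE) {
  stopifnot(inherits(net, "dncnn"))
  single <- is.matrix(x)
  arr <- if (single) array(x, dim = c(dim(x), 1L)) else x
  out <- dncnn_fwd(net, arr, training = training)$out
  if (single) out[, , 1L] else out
}

#' Apply one projection step
#'
#' Non-residual form returns `P(x)`; residual form returns `x + P(x)`, which
#' lets the network learn only the correction toward the image set.
#'
#' @param net a `dncnn`.
#' @param x pre-projection estimate (matrix or batch).
#' @param residual override the flag in the projector's config.
#' @param training BN mode, see [dncnn_forward()].
#' @return Next estimate, same shape as `x`.
#' @export
project <- function(net, x, residual = net$config$residual, training = FALSE) {
  p <- dncnn_forward(net, x, training = training)
  if (residual) x + p else p
}
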