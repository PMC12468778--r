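# Linear measurement operators y = A x + w.
#
# Two operator families are supported:
#   * gaussian — dense A with entries i.i.d. N(0, 1/m),
#   * dct      — A = S F, where F is the orthonormal 2D type-II DCT on
#                side x side images and S keeps m coefficient rows.
# Images are vectorized row-major (see img_to_vec); forward and adjoint use
# the identical ordering, so <A x, r> == <x, A' r> holds exactly up to float
# rounding for both kinds.

#' Construct a dense Gaussian measurement operator
#'
#' Entries are drawn i.i.d. `N(0, 1/m)` with `m = round(rate * side^2)`, the
#' standard compressed-sensing ensemble in which every column of A has unit
#' expected squared norm.
#'
#' @param side image side length (images are `side x side`, so `n = side^2`).
#' @param sampling_rate m/n, in (0, 1].
#' @param seed integer seed; the same seed reproduces the matrix bit-exactly.
#' @return A `measurement_model` object.
#' @export
#' @examples
#' m <- make_gaussian_model(side = 8, sampling_rate = 0.25, seed = 1)
#' dim(model_dense(m))
make_gaussian_model <- function(side, sampling_rate, seed = 1L) {
  check_scalar(side, "side"); check_scalar(sampling_rate, "sampling_rate")
  if (side < 2) stop_config("side must be >= 2")
  if (sampling_rate <= 0 || sampling_rate > 1) {
    stop_config("sampling_rate must be in (0, 1], got ", sampling_rate)
  }
  n <- as.integer(side)^2
  m <- as.integer(round(sampling_rate * n))
  if (m < 1L) stop_config("sampling_rate too small: no measurements")
  A <- with_seed(seed, matrix(stats::rnorm(m * n, sd = sqrt(1 / m)), nrow = m, ncol = n))
  structure(
    list(kind = "gaussian", side = as.integer(side), m = m, n = n,
         sampling_rate = sampling_rate, A = A, seed = as.integer(seed)),
    class = "measurement_model"
  )
}

# Orthonormal 1D type-II DCT matrix (N x N): row k (0-based) is
# c_k cos(pi (2 i + 1) k / (2 N)), c_0 = sqrt(1/N), c_k = sqrt(2/N).
dct_matrix <- function(N) {
  k <- 0:(N - 1)
  i <- 0:(N - 1)
  D <- sqrt(2 / N) * cos(outer(k, 2 * i + 1) * pi / (2 * N))
  D[1, ] <- sqrt(1 / N)
  D
}

# Row-selection order for the DCT operator. Coefficient (k1, k2) (0-based
# frequency pair) sits at row-major index (k1)*side + k2 + 1.
dct_row_order <- function(side, pattern, seed) {
  n <- side * side
  if (pattern == "uniform-random-rows") {
    with_seed(seed, sample.int(n))
  } else if (pattern == "low-frequency-first") {
    k1 <- rep(0:(side - 1), each = side)
    k2 <- rep(0:(side - 1), times = side)
    order(k1 + k2, pmax(k1, k2), k1)
  } else {
    stop_config("unknown undersampling pattern: ", pattern)
  }
}

#' Construct an undersampled 2D-DCT measurement operator
#'
#' Builds `A = S F` where `F` is the orthonormal 2D type-II DCT and `S` keeps
#' `m` coefficient rows, either uniformly at random (seeded) or
#' low-frequency-first (rows ordered by increasing `k1 + k2`). Because the
#' kept rows come from an orthonormal transform, `A A' = I` at every sampling
#' rate. Forward and adjoint are applied matrix-free (two small matrix
#' products plus a gather/scatter); `model_dense()` materializes A for audits.
#'
#' @inheritParams make_gaussian_model
#' @param pattern `"uniform-random-rows"` (default) or `"low-frequency-first"`.
#' @return A `measurement_model` object.
#' @export
make_dct_model <- function(side, sampling_rate,
                           pattern = c("uniform-random-rows", "low-frequency-first"),
                           seed = 1L) {
  pattern <- match.arg(pattern)
  check_scalar(side, "side"); check_scalar(sampling_rate, "sampling_rate")
  if (side < 2) stop_config("side must be >= 2")
  if (sampling_rate <= 0 || sampling_rate > 1) {
    stop_config("sampling_rate must be in (0, 1], got ", sampling_rate)
  }
  n <- as.integer(side)^2
  m <- as.integer(round(sampling_rate * n))
  if (m < 1L) stop_config("sampling_rate too small: no measurements")
  if (m > n) stop_config("m > n is not a valid undersampling")
  rows <- dct_row_order(as.integer(side), pattern, seed)[seq_len(m)]
  structure(
    list(kind = "dct", side = as.integer(side), m = m, n = n,
         sampling_rate = sampling_rate, pattern = pattern, rows = rows,
         D = dct_matrix(as.integer(side)), seed = as.integer(seed)),
    class = "measurement_model"
  )
}

#' @export
print.measurement_model <- function(x, ...) {
  cat(sprintf("<measurement_model: %s, %d x %d (side %d, rate %.3f%s, seed %d)>\n",
              x$kind, x$m, x$n, x$side, x$sampling_rate,
              if (x$kind == "dct") paste0(", ", x$pattern) else "", x$seed))
  invisible(x)
}

# 2D DCT / inverse DCT of a side x side x N batch.
dct2_batch <- function(arr, D) {
  d <- dim(arr)
  tmp <- D %*% matrix(arr, d[1L])                 # over rows
  tmp <- array(tmp, d)
  tmp <- aperm(tmp, c(2L, 1L, 3L))
  tmp <- D %*% matrix(tmp, d[2L])                 # over columns
  aperm(array(tmp, d[c(2L, 1L, 3L)]), c(2L, 1L, 3L))
}

idct2_batch <- function(arr, D) {
  d <- dim(arr)
  tmp <- crossprod(D, matrix(arr, d[1L]))
  tmp <- array(tmp, d)
  tmp <- aperm(tmp, c(2L, 1L, 3L))
  tmp <- crossprod(D, matrix(tmp, d[2L]))
  aperm(array(tmp, d[c(2L, 1L, 3L)]), c(2L, 1L, 3L))
}

#' Apply the forward operator
#'
#' @param model a `measurement_model`.
#' @param x an image (`side x side` matrix), a length-n vector in row-major
#'   order, or a `side x side x N` batch.
#' @return Measurement matrix `m x N` (a plain vector for a single image
#'   given as a vector or matrix is returned as `m x 1`).
#' @export
forward <- function(model, x) UseMethod("forward")

#' @export
forward.measurement_model <- function(model, x) {
  arr <- as_image_batch(x, model$side)
  if (model$kind == "gaussian") {
    model$A %*% imgs_to_vecs(arr)
  } else {
    coef <- imgs_to_vecs(dct2_batch(arr, model$D))
    coef[model$rows, , drop = FALSE]
  }
}

#' Apply the adjoint operator
#'
#' @param model a `measurement_model`.
#' @param r residual vector of length `m`, or an `m x N` batch.
#' @return `side x side x N` array of back-projected images.
#' @export
adjoint <- function(model, r) UseMethod("adjoint")

#' @export
adjoint.measurement_model <- function(model, r) {
  r <- if (is.matrix(r)) r else matrix(r, ncol = 1L)
  if (nrow(r) != model$m) stop_shape("residual", model$m, nrow(r))
  if (model$kind == "gaussian") {
    vecs_to_imgs(crossprod(model$A, r), model$side)
  } else {
    coef <- matrix(0, model$n, ncol(r))
    coef[model$rows, ] <- r
    idct2_batch(vecs_to_imgs(coef, model$side), model$D)
  }
}

#' Materialize the dense measurement matrix
#'
#' For the Gaussian kind this returns the stored matrix; for the DCT kind the
#' selected rows of the 2D transform are assembled explicitly (kron of the 1D
#' basis, reordered to the row-major pixel convention). Intended for audits
#' and tests.
#'
#' @param model a `measurement_model`.
#' @return An `m x n` matrix.
#' @export
model_dense <- function(model) {
  if (model$kind == "gaussian") return(model$A)
  # Row-major vec: pixel (i, j) -> (i-1)*side + j; coefficient (k1, k2) row
  # index (k1)*side + k2 + 1. F[(k1,k2),(i,j)] = D[k1+1,i+1] * D[k2+1,j+1],
  # which is kronecker(D, D) in the row-major ordering.
  Ffull <- kronecker(model$D, model$D)
  Ffull[model$rows, , drop = FALSE]
}

#' Squared spectral norm of the measurement operator
#'
#' `sigma_max(A)^2`, computed by deterministic power iteration on `A'A`
#' (matrix-free). For the DCT kind the rows are orthonormal, so the value is
#' exactly 1. The classical stable gradient step size is its reciprocal, see
#' [stable_step_size()].
#'
#' @param model a `measurement_model`.
#' @param iters power-iteration count.
#' @return Scalar `sigma_max^2`.
#' @export
operator_norm_sq <- function(model, iters = 50L) {
  if (model$kind == "dct") return(1)
  v <- with_seed(model$seed + 424243L, stats::rnorm(model$n))
  v <- v / sqrt(sum(v^2))
  lam <- 1
  for (i in seq_len(iters)) {
    w <- img_to_vec(adjoint(model, forward(model, vec_to_img(v, model$side)))[, , 1L])
    lam <- sqrt(sum(w^2))
    v <- w / lam
  }
  lam
}

#' Largest stable gradient step size
#'
#' `1 / sigma_max(A)^2`: the largest step for which the gradient-descent map
#' on `||y - A x||^2` is non-expansive, used to initialize the trainable
#' step-size and memory coefficients at a known-convergent algorithm.
#'
#' @param model a `measurement_model`.
#' @return Scalar step size.
#' @export
stable_step_size <- function(model) 1 / operator_norm_sq(model)

#' Specify additive measurement noise
#'
#' @param sigma noise standard deviation (intensity units, >= 0).
#' @param seed integer seed for the noise stream.
#' @return A `noise_spec` object.
#' @export
noise_spec <- function(sigma, seed = 1L) {
  check_scalar(sigma, "sigma")
  if (sigma < 0) stop_config("sigma must be >= 0, got ", sigma)
  structure(list(sigma = sigma, seed = as.integer(seed)), class = "noise_spec")
}

#' Add i.i.d. Gaussian noise to measurements
#'
#' `sigma = 0` returns `y` bit-exactly (no RNG draw is consumed).
#'
#' @param y measurement vector or `m x N` matrix.
#' @param noise a `noise_spec`.
#' @return `y + w` with `w ~ N(0, sigma^2 I)`, seeded and reproducible.
#' @export
add_noise <- function(y, noise) {
  stopifnot(inherits(noise, "noise_spec"))
  if (noise$sigma == 0) return(y)
  w <- with_seed(noise$seed, stats::rnorm(length(y), sd = noise$sigma))
  y + if (is.matrix(y)) matrix(w, nrow(y)) else w
}

#' Input signal-to-noise ratio in decibels
#'
#' Defined as `10 log10( mean ||A x||^2 / (m sigma^2) )`, the ratio of the
#' average measurement signal energy to the expected noise energy over a test
#' set. Doubling `sigma` lowers the value by exactly `20 log10(2) ~ 6.02` dB.
#'
#' @param model a `measurement_model`.
#' @param images `side x side x N` array (or single image).
#' @param noise a `noise_spec` with `sigma > 0`.
#' @return SNR in dB.
#' @export
input_snr_db <- function(model, images, noise) {
  stopifnot(inherits(noise, "noise_spec"))
  if (noise$sigma <= 0) {
    stop(errorCondition("input SNR is undefined at sigma = 0",
                        class = c("demun_undefined_snr", "error")))
  }
  arr <- as_image_batch(images, model$side)
  if (dim(arr)[3L] < 1L) stop_config("image set is empty")
  y <- forward(model, arr)
  10 * log10(mean(colSums(y^2)) / (model$m * noise$sigma^2))
}
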