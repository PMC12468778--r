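# Seeded synthetic grayscale image sets.
#
# Three families, chosen to probe different aspects of reconstruction:
#   * cartoons   — piecewise-constant ellipses/rectangles/triangles on a flat
#                  background: sharp edges, the regime SSIM is sensitive to;
#   * grf        — band-limited Gaussian random fields with power-law spectrum
#                  ~ (1 + |f|)^(-gamma), mimicking 1/f natural-image statistics;
#   * dct_sparse — exactly k nonzero 2D-DCT coefficients, the sanity tier for
#                  DCT operators (recovery is nearly trivial).
# All values land in [0, 1]; output depends only on (kind, count, side, seed).

#' Generate a synthetic image set
#'
#' @param kind one of `"cartoons"`, `"grf"`, `"dct_sparse"`.
#' @param count number of images (> 0).
#' @param side image side length.
#' @param seed integer seed; same seed gives a bit-identical set.
#' @param k sparsity for `dct_sparse` (number of nonzero coefficients).
#' @param exponent spectral exponent gamma for `grf` (0 = white noise).
#' @param rescale rescale each image to `[0, 1]` (min-max, affine; the
#'   default). Disable to obtain the raw fields — e.g. exact DCT sparsity
#'   before rescaling — which may then leave `[0, 1]`.
#' @return An `image_set`: list with `images` (`side x side x count` array),
#'   `side`, `count`, `kind`, `seed`, `split`.
#' @export
#' @examples
#' s <- generate_images("cartoons", count = 4, side = 16, seed = 7)
#' range(s$images)
generate_images <- function(kind = c("cartoons", "grf", "dct_sparse"),
                            count, side, seed = 1L, k = 4L, exponent = 2,
                            rescale = TRUE) {
  kind <- match.arg(kind)
  check_scalar(count, "count"); check_scalar(side, "side")
  if (count <= 0) stop_config("count must be > 0")
  if (side < 2) stop_config("side must be >= 2")
  side <- as.integer(side); count <- as.integer(count)
  imgs <- with_seed(seed, {
    arr <- array(0, dim = c(side, side, count))
    for (t in seq_len(count)) {
      arr[, , t] <- switch(kind,
        cartoons   = gen_cartoon(side),
        grf        = gen_grf(side, exponent),
        dct_sparse = gen_dct_sparse(side, k))
    }
    arr
  })
  if (rescale) {
    for (t in seq_len(count)) imgs[, , t] <- rescale01(imgs[, , t])
  }
  structure(list(images = imgs, side = side, count = count, kind = kind,
                 seed = as.integer(seed), split = "all"),
            class = "image_set")
}

rescale01 <- function(img) {
  rng <- range(img)
  if (rng[2] > rng[1]) (img - rng[1]) / (rng[2] - rng[1]) else img * 0 + 0.5
}

gen_cartoon <- function(side) {
  xg <- matrix(rep(seq(0, 1, length.out = side), each = side), side, byrow = FALSE)
  yg <- t(xg)
  img <- matrix(stats::runif(1, 0, 0.3), side, side)
  nshape <- sample(3:8, 1)
  for (s in seq_len(nshape)) {
    val <- stats::runif(1)
    type <- sample(c("ellipse", "rect", "triangle"), 1)
    if (type == "ellipse") {
      cx <- stats::runif(1); cy <- stats::runif(1)
      a <- stats::runif(1, 0.08, 0.35); b <- stats::runif(1, 0.08, 0.35)
      th <- stats::runif(1, 0, pi)
      u <- (xg - cx) * cos(th) + (yg - cy) * sin(th)
      v <- -(xg - cx) * sin(th) + (yg - cy) * cos(th)
      mask <- (u / a)^2 + (v / b)^2 <= 1
    } else if (type == "rect") {
      x0 <- stats::runif(1, 0, 0.8); y0 <- stats::runif(1, 0, 0.8)
      mask <- xg >= x0 & xg <= x0 + stats::runif(1, 0.1, 0.5) &
              yg >= y0 & yg <= y0 + stats::runif(1, 0.1, 0.5)
    } else {
      px <- stats::runif(3); py <- stats::runif(3)
      # barycentric sign test
      d1 <- (xg - px[2]) * (py[1] - py[2]) - (px[1] - px[2]) * (yg - py[2])
      d2 <- (xg - px[3]) * (py[2] - py[3]) - (px[2] - px[3]) * (yg - py[3])
      d3 <- (xg - px[1]) * (py[3] - py[1]) - (px[3] - px[1]) * (yg - py[1])
      mask <- (d1 >= 0 & d2 >= 0 & d3 >= 0) | (d1 <= 0 & d2 <= 0 & d3 <= 0)
    }
    img[mask] <- val
  }
  img
}

gen_grf <- function(side, exponent) {
  white <- matrix(stats::rnorm(side * side), side, side)
  if (exponent == 0) return(white)
  # shape the spectrum in the DCT basis: filter (1 + |f|)^(-exponent/2)
  D <- dct_matrix(side)
  k1 <- matrix(rep(0:(side - 1), each = side), side, byrow = TRUE)
  k2 <- t(k1)
  filt <- (1 + sqrt(k1^2 + k2^2))^(-exponent / 2)
  crossprod(D, (filt * (D %*% white %*% t(D)))) %*% D
}

gen_dct_sparse <- function(side, k) {
  if (k < 1 || k > side * side) stop_config("k must be in [1, side^2]")
  coef <- matrix(0, side, side)
  pos <- sample.int(side * side, k)
  coef[pos] <- stats::rnorm(k)
  D <- dct_matrix(side)
  crossprod(D, coef) %*% D
}

#' Split an image set into train and test subsets
#'
#' Seeded shuffle; the two subsets are disjoint and exhaustive.
#'
#' @param set an `image_set`.
#' @param fraction train fraction in (0, 1).
#' @param seed integer seed for the shuffle.
#' @return List with elements `train` and `test` (both `image_set`s).
#' @export
split_images <- function(set, fraction, seed = 1L) {
  stopifnot(inherits(set, "image_set"))
  check_scalar(fraction, "fraction")
  if (fraction <= 0 || fraction >= 1) stop_config("fraction must be in (0, 1)")
  ntr <- round(fraction * set$count)
  if (ntr < 1 || ntr >= set$count) stop_config("degenerate split sizes")
  idx <- with_seed(seed, sample.int(set$count))
  take <- function(ii, tag) {
    structure(list(images = set$images[, , ii, drop = FALSE], side = set$side,
                   count = length(ii), kind = set$kind, seed = set$seed,
                   split = tag), class = "image_set")
  }
  list(train = take(sort(idx[seq_len(ntr)]), "train"),
       test  = take(sort(idx[(ntr + 1):set$count]), "test"))
}

#' @export
print.image_set <- function(x, ...) {
  cat(sprintf("<image_set: %d x (%d x %d), kind=%s, split=%s, seed=%d>\n",
              x$count, x$side, x$side, x$kind, x$split, x$seed))
  invisible(x)
}
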