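# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so library calls never perturb a caller's stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("demun_config_error", "error")))
}

stop_shape <- function(what, expected, actual) {
  stop(errorCondition(
    sprintf("%s: expected size %s, got %s", what,
            paste(expected, collapse = "x"), paste(actual, collapse = "x")),
    class = c("demun_shape_error", "error")
  ))
}

check_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_config(name, " must be a finite numeric scalar")
  }
  x
}

# Images travel as side x side matrices (or side x side x N arrays for
# batches). Measurement vectors use row-major pixel order: pixel (i, j) of the
# image maps to entry (i - 1) * side + j of the vector. The same permutation
# is used by forward and adjoint, so the adjoint contract is unaffected.

img_to_vec <- function(img) {
  as.vector(t(img))
}

vec_to_img <- function(v, side) {
  matrix(v, nrow = side, ncol = side, byrow = TRUE)
}

# Batch versions: arr is side x side x N, vecs is n x N (row-major columns).
imgs_to_vecs <- function(arr) {
  d <- dim(arr)
  matrix(aperm(arr, c(2L, 1L, 3L)), nrow = d[1L] * d[2L], ncol = d[3L])
}

vecs_to_imgs <- function(v, side) {
  n <- nrow(v)
  if (n != side * side) stop_shape("image vector", side * side, n)
  aperm(array(v, dim = c(side, side, ncol(v))), c(2L, 1L, 3L))
}

as_image_batch <- function(x, side) {
  if (is.matrix(x) && nrow(x) == side && ncol(x) == side) {
    array(x, dim = c(side, side, 1L))
  } else if (is.array(x) && length(dim(x)) == 3L) {
    if (dim(x)[1L] != side || dim(x)[2L] != side) {
      stop_shape("image batch", c(side, side, NA), dim(x))
    }
    x
  } else if (is.numeric(x) && length(x) == side * side) {
    array(vec_to_img(x, side), dim = c(side, side, 1L))
  } else {
    stop_shape("image", c(side, side), if (is.null(dim(x))) length(x) else dim(x))
  }
}
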