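# Reconstruction quality metrics and summary tables.

#' Peak signal-to-noise ratio
#'
#' `10 log10(peak^2 / MSE)` with MSE the mean squared pixel error. A zero-MSE
#' pair returns the documented sentinel of 100 dB (the cap also applies to
#' any value above it) rather than infinity.
#'
#' @param xhat,xstar images of identical shape.
#' @param peak peak intensity (1.0 for images normalized to `[0, 1]`).
#' @return PSNR in dB.
#' @export
psnr <- function(xhat, xstar, peak = 1.0) {
  if (!identical(dim(xhat), dim(xstar))) stop_shape("psnr input", dim(xstar), dim(xhat))
  if (peak <= 0) stop_config("peak must be > 0")
  mse <- mean((xhat - xstar)^2)
  if (mse == 0) return(100)
  min(10 * log10(peak^2 / mse), 100)
}

# 2D Gaussian window, normalized to sum 1.
gaussian_window <- function(size = 11L, sigma = 1.5) {
  r <- (size - 1) / 2
  g <- exp(-((-r):r)^2 / (2 * sigma^2))
  w <- outer(g, g)
  w / sum(w)
}

# 'valid' correlation of img with an s x s window.
filter_valid <- function(img, w) {
  s <- nrow(w)
  H <- nrow(img) - s + 1L
  W <- ncol(img) - s + 1L
  out <- matrix(0, H, W)
  for (a in seq_len(s)) {
    for (b in seq_len(s)) {
      out <- out + w[a, b] * img[a:(a + H - 1L), b:(b + W - 1L)]
    }
  }
  out
}

#' Structural similarity index
#'
#' Mean local SSIM over an 11 x 11 Gaussian window (sigma 1.5), constants
#' `K1 = 0.01`, `K2 = 0.03`, data range 1.0 — the standard configuration of
#' the original index. Only windows fully inside the image contribute.
#'
#' @param xhat,xstar images of identical shape, side >= window size.
#' @param data_range dynamic range of the data (1.0 for `[0, 1]` images).
#' @return SSIM score in `[-1, 1]`.
#' @export
ssim <- function(xhat, xstar, data_range = 1.0) {
  if (!identical(dim(xhat), dim(xstar))) stop_shape("ssim input", dim(xstar), dim(xhat))
  w <- gaussian_window()
  if (nrow(xhat) < nrow(w) || ncol(xhat) < ncol(w)) {
    stop(errorCondition(
      sprintf("image (%d x %d) smaller than SSIM window (%d)",
              nrow(xhat), ncol(xhat), nrow(w)),
      class = c("demun_input_error", "error")))
  }
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  mu1 <- filter_valid(xhat, w)
  mu2 <- filter_valid(xstar, w)
  s11 <- filter_valid(xhat * xhat, w) - mu1^2
  s22 <- filter_valid(xstar * xstar, w) - mu2^2
  s12 <- filter_valid(xhat * xstar, w) - mu1 * mu2
  num <- (2 * mu1 * mu2 + C1) * (2 * s12 + C2)
  den <- (mu1^2 + mu2^2 + C1) * (s11 + s22 + C2)
  mean(num / den)
}

#' PSNR after each unrolled step
#'
#' @param trace list of per-step estimates `x_1 ... x_T`.
#' @param xstar ground-truth image.
#' @param peak peak intensity.
#' @return Numeric vector of length `T`.
#' @export
per_step_psnr <- function(trace, xstar, peak = 1.0) {
  vapply(trace, function(x) psnr(x, xstar, peak), 0)
}

#' Summarize evaluation records as mean +/- sd tables
#'
#' Groups per-image records by the given columns and reduces each metric to
#' its mean and sample standard deviation (ddof = 1). Cells with fewer than
#' two records are dropped with a warning.
#'
#' @param records data.frame with one row per evaluated image; metric columns
#'   given in `metrics`, grouping columns in `by`.
#' @param by character vector of grouping column names.
#' @param metrics character vector of metric column names.
#' @return data.frame with one row per group and `<metric>_mean`,
#'   `<metric>_sd` and `n_images` columns.
#' @export
summarize_records <- function(records, by = "config",
                              metrics = c("psnr", "ssim")) {
  stopifnot(is.data.frame(records), all(by %in% names(records)),
            all(metrics %in% names(records)))
  key <- interaction(records[by], drop = TRUE, sep = " | ")
  out <- lapply(levels(key), function(lv) {
    sub <- records[key == lv, , drop = FALSE]
    if (nrow(sub) < 2L) {
      warning("dropping summary cell with a single record: ", lv)
      return(NULL)
    }
    row <- sub[1L, by, drop = FALSE]
    for (mcol in metrics) {
      row[[paste0(mcol, "_mean")]] <- mean(sub[[mcol]])
      row[[paste0(mcol, "_sd")]] <- stats::sd(sub[[mcol]])
    }
    row$n_images <- nrow(sub)
    row
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out)) out <- records[0, by, drop = FALSE]
  rownames(out) <- NULL
  out
}
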