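# Image stack I/O: PNG files (one image per file) and plain CSV stacks
# (count*side rows of side columns, images stacked vertically).

# ITU-R BT.601 luma weights for RGB -> grayscale.
LUMA_601 <- c(0.299, 0.587, 0.114)

to_gray <- function(img) {
  if (length(dim(img)) == 2L) return(img)
  ch <- dim(img)[3L]
  if (ch == 1L) return(img[, , 1L])
  # drop alpha if present, combine with BT.601 luma weights
  img[, , 1L] * LUMA_601[1] + img[, , 2L] * LUMA_601[2] + img[, , 3L] * LUMA_601[3]
}

center_crop <- function(img, side) {
  h <- nrow(img); w <- ncol(img)
  s <- min(h, w)
  r0 <- floor((h - s) / 2); c0 <- floor((w - s) / 2)
  img[(r0 + 1):(r0 + s), (c0 + 1):(c0 + s)]
}

# Bilinear resample of a square image to side x side.
resize_bilinear <- function(img, side) {
  s <- nrow(img)
  if (s == side) return(img)
  pos <- (seq_len(side) - 0.5) * s / side + 0.5 # sample centers in src coords
  i0 <- pmin(pmax(floor(pos), 1), s); i1 <- pmin(i0 + 1, s)
  fr <- pmin(pmax(pos - i0, 0), 1)
  rows <- img[i0, , drop = FALSE] * (1 - fr) + img[i1, , drop = FALSE] * fr
  t(t(rows[, i0, drop = FALSE]) * (1 - fr) + t(rows[, i1, drop = FALSE]) * fr)
}

#' Load an image set from PNG files or a CSV stack
#'
#' PNG inputs are converted to grayscale with BT.601 luma weights
#' (0.299, 0.587, 0.114), center-cropped to square, and bilinearly resized to
#' `side`; 8-bit code 255 maps to exactly 1.0. A `.csv` path is read as a
#' vertical stack of `side x side` blocks written by [save_images()].
#'
#' @param path a directory of `.png` files, a single `.png`, or a `.csv` stack.
#' @param side target side length.
#' @return An `image_set`.
#' @export
load_images <- function(path, side) {
  check_scalar(side, "side")
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE, ignore.case = TRUE))
    if (length(files) == 0L) stop("no PNG files found in ", path)
  } else if (file.exists(path)) {
    files <- path
  } else {
    stop("cannot read ", path)
  }
  if (length(files) == 1L && grepl("\\.csv$", files, ignore.case = TRUE)) {
    mat <- as.matrix(utils::read.csv(files, header = FALSE))
    if (ncol(mat) != side || nrow(mat) %% side != 0L) {
      stop_shape("CSV image stack", c(NA, side), dim(mat))
    }
    count <- nrow(mat) %/% side
    arr <- array(0, dim = c(side, side, count))
    for (t in seq_len(count)) arr[, , t] <- mat[((t - 1) * side + 1):(t * side), ]
  } else {
    arr <- array(0, dim = c(side, side, length(files)))
    for (t in seq_along(files)) {
      img <- tryCatch(png::readPNG(files[t]),
                      error = function(e) stop("unreadable PNG: ", files[t]))
      arr[, , t] <- resize_bilinear(center_crop(to_gray(img), side), side)
    }
    count <- length(files)
  }
  arr[arr < 0] <- 0; arr[arr > 1] <- 1
  structure(list(images = arr, side = as.integer(side), count = count,
                 kind = "loaded", seed = NA_integer_, split = "all"),
            class = "image_set")
}

#' Save an image set
#'
#' A `.csv` path writes the full-precision stack (lossless round trip with
#' [load_images()]); a directory writes one 16-bit PNG per image.
#'
#' @param set an `image_set`.
#' @param path `.csv` file or output directory.
#' @return `path`, invisibly.
#' @export
save_images <- function(set, path) {
  stopifnot(inherits(set, "image_set"))
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    mat <- do.call(rbind, lapply(seq_len(set$count), function(t) set$images[, , t]))
    utils::write.table(mat, path, sep = ",", row.names = FALSE, col.names = FALSE)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (t in seq_len(set$count)) {
      png::writePNG(set$images[, , t],
                    file.path(path, sprintf("img_%04d.png", t)))
    }
  }
  invisible(path)
}
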