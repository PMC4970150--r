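# Image containers and low-level raster operations.
#
# Conventions used throughout the package:
#   * A grayscale image is a numeric matrix [height x width] with values in
#     [0, 255]; an RGB image is a numeric array [height x width x 3], channel
#     order R, G, B regardless of the file format's native order.
#   * Pixel coordinates are 0-based: x grows rightwards (columns), y grows
#     downwards (rows). Pixel (x, y) is matrix element [y + 1, x + 1].
#   * Rectangles are half-open: a box (x, y, w, h) covers columns
#     [x, x + w) and rows [y, y + h).

#' Validate a grayscale image
#'
#' @param img numeric matrix, values in \[0, 255\].
#' @return the input, invisibly.
#' @export
assert_gray <- function(img) {
  assert(is.matrix(img) && is.numeric(img), "grayscale image must be a numeric matrix")
  assert(nrow(img) >= 1 && ncol(img) >= 1, "image must be at least 1x1")
  assert(all(is.finite(img)), "image values must be finite")
  assert(min(img) >= 0 && max(img) <= 255, "image values must lie in [0, 255]")
  invisible(img)
}

#' Validate an RGB image
#'
#' @param img numeric array \[h, w, 3\], values in \[0, 255\], channels R,G,B.
#' @return the input, invisibly.
#' @export
assert_rgb <- function(img) {
  assert(is.array(img) && length(dim(img)) == 3 && dim(img)[3] == 3,
         "RGB image must be an [h, w, 3] array")
  assert(all(is.finite(img)), "image values must be finite")
  assert(min(img) >= 0 && max(img) <= 255, "image values must lie in [0, 255]")
  invisible(img)
}

#' Convert an RGB image to grayscale
#'
#' Standard luma conversion with ITU-R BT.601 weights
#' (0.299 R + 0.587 G + 0.114 B), rounded to integers in \[0, 255\].
#'
#' @param img RGB image array \[h, w, 3\].
#' @return grayscale matrix \[h, w\].
#' @export
to_gray <- function(img) {
  assert_rgb(img)
  g <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  matrix(clamp(round(g), 0, 255), dim(img)[1], dim(img)[2])
}

#' Read an image file as an RGB array
#'
#' PNG is read with the png package; JPEG with the jpeg package when
#' installed. Grayscale files are expanded to three identical channels and
#' any alpha channel is dropped. Values are rescaled to \[0, 255\].
#'
#' @param path file path; format chosen by extension (.png, .jpg/.jpeg).
#' @return RGB image array \[h, w, 3\].
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = {
      assert(requireNamespace("jpeg", quietly = TRUE),
             "reading JPEG requires the 'jpeg' package")
      jpeg::readJPEG(path)
    },
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  if (length(dim(raw)) == 2) raw <- array(raw, c(dim(raw), 1))
  nc <- dim(raw)[3]
  img <- if (nc >= 3) raw[, , 1:3, drop = FALSE] else
    array(raw[, , 1], c(dim(raw)[1:2], 3))
  img * 255
}

#' Write an image to a PNG file
#'
#' Grayscale matrices are written as single-channel PNG, RGB arrays as
#' three-channel PNG.
#'
#' @param img grayscale matrix or RGB array, values in \[0, 255\].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  png::writePNG(img / 255, target = path)
  invisible(path)
}

# --- separable convolution -------------------------------------------------

# 1-D convolution along rows (axis = "y") or columns (axis = "x") with an
# odd-length kernel; boundary "zero" pads with 0, "replicate" repeats edges.
#' @noRd
conv1 <- function(m, k, axis = c("y", "x"), boundary = c("zero", "replicate")) {
  axis <- match.arg(axis)
  boundary <- match.arg(boundary)
  n <- length(k)
  if (n == 1L) return(m * k)
  assert(n %% 2 == 1, "kernel length must be odd")
  p <- (n - 1L) %/% 2L
  if (axis == "x") return(t(conv1(t(m), k, "y", boundary)))
  h <- nrow(m)
  pad_top <- if (boundary == "zero") matrix(0, p, ncol(m)) else
    m[rep(1L, p), , drop = FALSE]
  pad_bot <- if (boundary == "zero") matrix(0, p, ncol(m)) else
    m[rep(h, p), , drop = FALSE]
  mp <- rbind(pad_top, m, pad_bot)
  out <- matrix(0, h, ncol(m))
  for (j in seq_len(n)) out <- out + k[j] * mp[j:(j + h - 1L), , drop = FALSE]
  out
}

# truncated, unit-sum 1-D Gaussian kernel (3 sigma support)
#' @noRd
gaussian_kernel1 <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian blur of a grayscale image
#'
#' Separable convolution with a unit-sum Gaussian truncated at 3 sigma.
#' Edge rows/columns are replicated so borders are not darkened.
#'
#' @param img grayscale matrix.
#' @param sigma standard deviation in pixels; `sigma <= 0` is the identity.
#' @param boundary `"replicate"` (default) or `"zero"`.
#' @return blurred matrix, same size.
#' @export
gaussian_blur <- function(img, sigma, boundary = "replicate") {
  k <- gaussian_kernel1(sigma)
  conv1(conv1(img, k, "y", boundary), k, "x", boundary)
}

# Sobel derivatives; borders zeroed (the 3x3 stencil is undefined there).
# sobel_x responds to vertical edges (d/dx), sobel_y to horizontal edges.
#' @noRd
sobel_pair <- function(img) {
  h <- nrow(img); w <- ncol(img)
  assert(h >= 3 && w >= 3, "image must be at least 3x3 for Sobel derivatives")
  gx <- conv1(conv1(img, c(1, 2, 1), "y", "zero"), c(-1, 0, 1), "x", "zero")
  gy <- conv1(conv1(img, c(1, 2, 1), "x", "zero"), c(-1, 0, 1), "y", "zero")
  gx[c(1, h), ] <- 0; gx[, c(1, w)] <- 0
  gy[c(1, h), ] <- 0; gy[, c(1, w)] <- 0
  list(gx = gx, gy = gy)
}
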