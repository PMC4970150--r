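# Face-proportion geometry: face box cropping, eye search band, and
# eyebrow-row estimation from the vertical intensity projection.

#' Face bounding box
#'
#' A rectangle in 0-based, half-open pixel coordinates, typically produced
#' by an external face detector and supplied as input.
#'
#' @param x,y top-left corner (pixels, 0-based).
#' @param w,h width and height (pixels, > 0).
#' @return object of class `face_box`.
#' @export
face_box <- function(x, y, w, h) {
  assert(w > 0 && h > 0, "face box must have positive size")
  structure(list(x = x, y = y, w = w, h = h), class = "face_box")
}

#' Crop a face box horizontally
#'
#' Shrinks the box to `fraction` of its width, centered: with the default
#' 0.70, 15\% of the width is removed on each side so that background and
#' hair are excluded before eye search. The left offset is floored and the
#' new width rounded to integers.
#'
#' @param face `face_box`.
#' @param fraction ratio in (0, 1\].
#' @return cropped `face_box` with the same vertical extent.
#' @export
crop_face_width <- function(face, fraction = 0.70) {
  assert(fraction > 0 && fraction <= 1, "fraction must be in (0, 1]")
  off <- floor(fp_tidy(face$w * (1 - fraction) / 2))
  w2 <- round(fp_tidy(face$w * fraction))
  assert(w2 >= 1, "cropped face width is below 1 pixel")
  face_box(face$x + off, face$y, w2, face$h)
}

#' Vertical image projection
#'
#' Row-wise sums of intensity; row `j` (0-based) of the image maps to
#' element `j + 1`. Valleys of the projection mark dark horizontal bands
#' (eyebrows, eyes).
#'
#' @param img grayscale matrix.
#' @return numeric vector of per-row sums, length `nrow(img)`.
#' @export
vertical_projection <- function(img) {
  assert_gray(img)
  rowSums(img)
}

#' Estimate the eyebrow row from a vertical projection
#'
#' The projection is smoothed with a centered moving average (edges
#' replicated) and scanned top-down; the first strict local minimum is
#' returned (the rough eyebrow band). On a plateau the topmost index wins;
#' if no interior local minimum exists the global minimum row is returned.
#'
#' @param proj per-row projection vector (length >= 3).
#' @param smoothing moving-average window length in rows (odd; default 5).
#' @return 0-based row index.
#' @export
estimate_eyebrow_row <- function(proj, smoothing = 5) {
  n <- length(proj)
  assert(n >= 3, "projection must have length >= 3")
  smoothing <- max(1L, as.integer(smoothing))
  if (smoothing %% 2 == 0) smoothing <- smoothing + 1L
  if (smoothing > 1) {
    p <- (smoothing - 1L) %/% 2L
    padded <- c(rep(proj[1], p), proj, rep(proj[n], p))
    s <- vapply(seq_len(n), function(i) mean(padded[i:(i + smoothing - 1L)]),
                numeric(1))
  } else s <- proj
  for (j in 2:(n - 1)) {
    if (s[j] < s[j - 1] && s[j] <= s[j + 1]) return(j - 1L)
  }
  which.min(s) - 1L
}

#' Eye search region of a face box
#'
#' Returns the horizontal band of the (cropped) face in which the eyes are
#' searched, from facial-proportion priors, together with the estimated
#' eyebrow row when a grayscale image is supplied.
#'
#' @param face `face_box` (already width-cropped).
#' @param band_frac fractions of the face height delimiting the band
#'   (default rows `[0.20 h, 0.55 h)`).
#' @param gray optional full grayscale image in the same coordinate frame;
#'   when given, the eyebrow row is estimated inside the band.
#' @param smoothing projection smoothing window (rows).
#' @return list with `box` (`face_box` of the band) and `eyebrow_row`
#'   (absolute 0-based row index, or `NA` if `gray` missing).
#' @export
eye_search_region <- function(face, band_frac = c(0.20, 0.55), gray = NULL,
                              smoothing = 5) {
  assert(length(band_frac) == 2 && band_frac[1] >= 0 && band_frac[2] <= 1 &&
           band_frac[1] < band_frac[2], "invalid band fractions")
  y0 <- floor(fp_tidy(face$y + band_frac[1] * face$h))
  y1 <- floor(fp_tidy(face$y + band_frac[2] * face$h))
  assert(y1 - y0 >= 3, "degenerate eye search band")
  box <- face_box(face$x, y0, face$w, y1 - y0)
  eyebrow <- NA_integer_
  if (!is.null(gray)) {
    sub <- crop_image(gray, box)
    eyebrow <- y0 + estimate_eyebrow_row(vertical_projection(sub), smoothing)
  }
  list(box = box, eyebrow_row = eyebrow)
}

#' Crop an image to a box
#'
#' @param img grayscale matrix or RGB array.
#' @param box `face_box`-like rectangle (0-based, half-open), clipped to the
#'   image.
#' @return sub-image of the same kind.
#' @export
crop_image <- function(img, box) {
  h <- dim(img)[1]; w <- dim(img)[2]
  x0 <- max(0L, floor(box$x)); y0 <- max(0L, floor(box$y))
  x1 <- min(w, ceiling(box$x + box$w)); y1 <- min(h, ceiling(box$y + box$h))
  assert(x1 > x0 && y1 > y0, "crop box does not intersect the image")
  if (length(dim(img)) == 3) img[(y0 + 1):y1, (x0 + 1):x1, , drop = FALSE]
  else img[(y0 + 1):y1, (x0 + 1):x1, drop = FALSE]
}
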