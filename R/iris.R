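# Iris center selection and iris radius estimation.
#
# Candidate centers are local minima of the dark-mode FRST image; they are
# scored by circularity (the FRST response), darkness of the blurred
# intensity, and geometric priors (left/right half separation, eyebrow
# penalty, inter-pupillary distance). The radius is then refined by a
# radial projection of the vertical-edge Sobel response around the center.

#' Iris radius search range from the face width
#'
#' Anthropometric prior: the eye width is approximately 1/5 of the face
#' width, and the iris-to-eye width ratio about 0.42, giving a nominal
#' radius `R0 = 0.5 * 0.42 * face_width / 5`. The returned range is
#' `[ceiling(R0 (1 - tol)), floor(R0 (1 + tol))]`.
#'
#' @param face_width face box width in pixels.
#' @param tolerance relative half-width of the range (default 0.3).
#' @return list with `r_min`, `r_max`, `r_nominal` (pixels).
#' @export
radius_range <- function(face_width, tolerance = 0.3) {
  assert(face_width > 0, "face width must be positive")
  r0 <- fp_tidy(0.5 * 0.42 * face_width / 5)
  assert(r0 >= 2, "face too small: nominal iris radius below the 2 px floor")
  r_min <- ceiling(fp_tidy(r0 * (1 - tolerance)))
  r_max <- floor(fp_tidy(r0 * (1 + tolerance)))
  assert(r_min >= 2, "face too small: minimum iris radius below 2 px")
  assert(r_max >= r_min, "empty radius range")
  list(r_min = as.integer(r_min), r_max = as.integer(r_max), r_nominal = r0)
}

#' Scan a symmetry image for candidate minima
#'
#' The image is tiled with windows of size `2 r_min`; the minimum position
#' of each non-flat tile is retained, then minima closer than `r_min` to a
#' stronger (lower-valued) minimum are merged away.
#'
#' @param S symmetry image (matrix).
#' @param r_min minimum search radius (pixels).
#' @return data.frame with columns `x`, `y` (0-based) and `s` (value of `S`);
#'   zero rows when `S` is flat.
#' @export
scan_minima <- function(S, r_min) {
  h <- nrow(S); w <- ncol(S)
  win <- max(2L, as.integer(2 * r_min))
  xs <- ys <- vs <- numeric(0)
  for (ty in seq(1L, h, by = win)) {
    for (tx in seq(1L, w, by = win)) {
      tile <- S[ty:min(h, ty + win - 1L), tx:min(w, tx + win - 1L), drop = FALSE]
      if (max(tile) == min(tile)) next  # flat tile: no evidence
      k <- which.min(tile)
      ys <- c(ys, ty + (k - 1L) %% nrow(tile) - 1L)
      xs <- c(xs, tx + (k - 1L) %/% nrow(tile) - 1L)
      vs <- c(vs, tile[k])
    }
  }
  if (length(vs) == 0) return(data.frame(x = numeric(0), y = numeric(0), s = numeric(0)))
  ord <- order(vs)
  keep <- integer(0)
  for (i in ord) {
    if (length(keep) == 0 ||
        all(sqrt((xs[keep] - xs[i])^2 + (ys[keep] - ys[i])^2) >= r_min))
      keep <- c(keep, i)
  }
  keep <- sort(keep)
  data.frame(x = xs[keep], y = ys[keep], s = vs[keep])
}

#' Score iris center candidates
#'
#' The symmetry response is weighted by the inverted, blurred gray-scale
#' intensity (the pupil must be dark), and candidates above the eyebrow row
#' are penalized:
#' `score = (-S(c)) * (255 - blur(gray)(c)) / 255 * penalty`.
#'
#' @param cands data.frame from [scan_minima()] (columns `x`, `y`, `s`).
#' @param S symmetry image.
#' @param gray grayscale image, same frame as `S`.
#' @param eyebrow_row 0-based row index; candidates with `y < eyebrow_row`
#'   are penalized. `NA` disables the penalty.
#' @param penalty multiplicative penalty factor (default 0.5).
#' @param blur_sigma Gaussian sigma for the darkness weighting (default 2).
#' @return `cands` with an added `score` column, sorted by decreasing score.
#' @export
score_candidates <- function(cands, S, gray, eyebrow_row = NA, penalty = 0.5,
                             blur_sigma = 2) {
  if (nrow(cands) == 0) return(cbind(cands, score = numeric(0)))
  bg <- gaussian_blur(gray, blur_sigma)
  idx <- cbind(cands$y + 1L, cands$x + 1L)
  dark <- (255 - bg[idx]) / 255
  dark[abs(dark) < 1e-10] <- 0   # kernel-normalization dust on saturated pixels
  score <- (-cands$s) * dark
  if (!is.na(eyebrow_row)) score <- score * ifelse(cands$y < eyebrow_row, penalty, 1)
  out <- cands
  out$score <- score
  out[order(-out$score), , drop = FALSE]
}

#' Select the left/right iris pair
#'
#' The left and right centers must lie in the left and right halves of the
#' face box; over all cross-half pairs the product of the candidate scores,
#' weighted by a Gaussian prior on the inter-pupillary distance normalized
#' by the face width, is maximized.
#'
#' @param scored scored candidates (columns `x`, `y`, `score`), coordinates
#'   in the same frame as `face`.
#' @param face `face_box` delimiting the search frame.
#' @param ipd_mean,ipd_sigma mean and sigma of the IPD / face-width ratio
#'   prior (defaults 0.4 and 0.1).
#' @return list with `left` and `right`, each `list(x, y, score)`, plus
#'   `pair_score`.
#' @export
select_pair <- function(scored, face, ipd_mean = 0.4, ipd_sigma = 0.1) {
  mid <- face$x + face$w / 2
  li <- which(scored$x < mid)
  ri <- which(scored$x >= mid)
  if (length(li) == 0) stop("iris detection failed: no candidate in the left half", call. = FALSE)
  if (length(ri) == 0) stop("iris detection failed: no candidate in the right half", call. = FALSE)
  eps <- 1e-12
  best <- NULL; best_w <- -Inf
  for (i in li) for (j in ri) {
    d <- sqrt((scored$x[i] - scored$x[j])^2 + (scored$y[i] - scored$y[j])^2)
    g <- exp(-((d / face$w - ipd_mean)^2) / (2 * ipd_sigma^2))
    wgt <- (max(scored$score[i], 0) + eps) * (max(scored$score[j], 0) + eps) * g
    if (wgt > best_w) { best_w <- wgt; best <- c(i, j) }
  }
  list(left = list(x = scored$x[best[1]], y = scored$y[best[1]],
                   score = scored$score[best[1]]),
       right = list(x = scored$x[best[2]], y = scored$y[best[2]],
                    score = scored$score[best[2]]),
       pair_score = best_w)
}

#' Refine an iris center to the pupil minimum
#'
#' Searches a small `(r_min/2) x (r_min/2)` neighborhood of the estimate on
#' the blurred intensity image and moves the center to the darkest pixel
#' (the pupil). Ties are broken by proximity to the unrefined center.
#'
#' @param gray grayscale image.
#' @param center `c(x, y)` (0-based).
#' @param r_min minimum iris radius (pixels).
#' @param blur_sigma Gaussian blur sigma (default 2).
#' @return refined `c(x, y)`.
#' @export
refine_center <- function(gray, center, r_min, blur_sigma = 2) {
  h <- nrow(gray); w <- ncol(gray)
  half <- max(1L, floor(r_min / 4))
  x0 <- max(0L, round(center[1]) - half); x1 <- min(w - 1L, round(center[1]) + half)
  y0 <- max(0L, round(center[2]) - half); y1 <- min(h - 1L, round(center[2]) + half)
  # blur on a padded crop so the window sees the same values as a global blur
  pad <- ceiling(3 * blur_sigma)
  cx0 <- max(0L, x0 - pad); cy0 <- max(0L, y0 - pad)
  cx1 <- min(w - 1L, x1 + pad); cy1 <- min(h - 1L, y1 + pad)
  sub <- gaussian_blur(gray[(cy0 + 1):(cy1 + 1), (cx0 + 1):(cx1 + 1), drop = FALSE],
                       blur_sigma)
  win <- sub[(y0 - cy0 + 1):(y1 - cy0 + 1), (x0 - cx0 + 1):(x1 - cx0 + 1), drop = FALSE]
  mn <- min(win)
  k <- which(win == mn)
  wy <- y0 + (k - 1L) %% nrow(win)
  wx <- x0 + (k - 1L) %/% nrow(win)
  d2 <- (wx - center[1])^2 + (wy - center[2])^2
  b <- which.min(d2)
  c(wx[b], wy[b])
}

#' Radial gradient projection around an iris center
#'
#' The ROI is blurred and a vertical-edge Sobel derivative taken (absolute
#' value); magnitudes at or below the k-th percentile of the nonzero
#' responses are zeroed to suppress noise. For each radius `r`, the
#' projection sums the responses at polar samples `(cx +/- r cos t,
#' cy +/- r sin t)` for `t` stepped at 1 degree over `theta_deg`, i.e. over
#' both the left and right iris-sclera transitions. Nearest-pixel lookup;
#' samples outside the image contribute 0.
#'
#' @param gray_roi grayscale ROI containing the eye.
#' @param center `c(x, y)` iris center in ROI coordinates (0-based).
#' @param r_min,r_max radius range (pixels).
#' @param k percentile of gradients to ignore (default 20).
#' @param theta_deg angular window in degrees (default `c(-45, 45)`).
#' @param blur_sigma Gaussian blur sigma applied before Sobel (default 2).
#' @return list with `radii` and `proj` vectors; a warning is attached in
#'   attribute `clipped` when `r_max` exceeds the ROI.
#' @export
radial_projection <- function(gray_roi, center, r_min, r_max, k = 20,
                              theta_deg = c(-45, 45), blur_sigma = 2) {
  h <- nrow(gray_roi); w <- ncol(gray_roi)
  assert(center[1] >= 0 && center[1] < w && center[2] >= 0 && center[2] < h,
         "center must lie inside the ROI")
  a <- abs(sobel_pair(gaussian_blur(gray_roi, blur_sigma))$gx)
  if (k > 0) {
    nz <- a[a > 0]
    if (length(nz) > 0) {
      q <- stats::quantile(nz, min(k, 100) / 100, names = FALSE)
      a[a <= q] <- 0
    }
  }
  radii <- seq.int(r_min, r_max)
  th <- seq(theta_deg[1], theta_deg[2], by = 1) * pi / 180
  cs <- cos(th); sn <- sin(th)
  clipped <- FALSE
  proj <- vapply(radii, function(r) {
    xs <- c(center[1] + r * cs, center[1] - r * cs)
    ys <- c(center[2] + r * sn, center[2] - r * sn)
    xi <- round(xs); yi <- round(ys)
    ok <- xi >= 0 & xi < w & yi >= 0 & yi < h
    if (!all(ok)) clipped <<- TRUE
    if (!any(ok)) return(0)
    sum(a[cbind(yi[ok] + 1, xi[ok] + 1)])
  }, numeric(1))
  out <- list(radii = radii, proj = proj)
  attr(out, "clipped") <- clipped
  out
}

#' Select the iris radius from a radial projection
#'
#' The most prominent projection peak is the iris boundary:
#' `radius = argmax_r proj(r)`, ties broken toward the smaller radius.
#'
#' @param proj list from [radial_projection()] (or a numeric vector with a
#'   `radii` attribute-like companion).
#' @return selected radius (integer pixels).
#' @export
select_radius <- function(proj) {
  p <- proj$proj; r <- proj$radii
  assert(length(p) > 0, "empty projection")
  if (all(p == 0)) stop("no edge evidence: radial projection is all zero", call. = FALSE)
  r[which.max(p)]
}
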