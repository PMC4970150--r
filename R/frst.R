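# Fast Radial Symmetry Transform (FRST).
#
# A gradient-based operator that accumulates, for each radius r, the
# orientation and magnitude contributions of every gradient element at the
# pixel it points to (positively-affected) and away from (negatively-
# affected). Dark radially-symmetric blobs -- such as the iris/pupil against
# skin and sclera -- produce strong negative responses at their centers when
# only negatively-affected pixels are accumulated ("dark" mode).

#' FRST parameters
#'
#' @param radii integer vector of radii (pixels, >= 1) to accumulate over.
#' @param alpha radial strictness exponent (> 0); higher values suppress the
#'   response of straight edges relative to true circular symmetry.
#'   Default 2, the common choice for this transform.
#' @param mode `"dark"` (negatively-affected pixels only -- dark blobs),
#'   `"bright"`, or `"both"`.
#' @param gaussian_sigma_factor sigma of the spreading Gaussian `A_r` as a
#'   fraction of the radius (default 0.25); the kernel is truncated at
#'   3 sigma and normalized to unit sum.
#' @param normalization how the orientation/magnitude maps are normalized
#'   before combination: `"max_abs"` (per-radius maximum absolute value,
#'   the default) or `"kappa"` (clamp counts at `kappa` as in the original
#'   transform formulation).
#' @param kappa clamp value used when `normalization = "kappa"`.
#' @return object of class `frst_params`.
#' @export
frst_params <- function(radii, alpha = 2, mode = c("dark", "bright", "both"),
                        gaussian_sigma_factor = 0.25,
                        normalization = c("max_abs", "kappa"), kappa = 9.9) {
  assert(length(radii) >= 1 && all(radii >= 1), "radii must be >= 1")
  assert(alpha > 0, "alpha must be > 0")
  structure(list(radii = as.integer(round(radii)), alpha = alpha,
                 mode = match.arg(mode),
                 gaussian_sigma_factor = gaussian_sigma_factor,
                 normalization = match.arg(normalization), kappa = kappa),
            class = "frst_params")
}

#' Image gradient field
#'
#' 3x3 Sobel derivatives in x and y; border pixels are zeroed.
#'
#' @param img grayscale matrix (at least 3x3).
#' @return list with matrices `gx`, `gy`, and `magnitude`.
#' @export
gradient_field <- function(img) {
  g <- sobel_pair(img)
  list(gx = g$gx, gy = g$gy, magnitude = sqrt(g$gx^2 + g$gy^2))
}

#' Positively- and negatively-affected pixels of one gradient element
#'
#' The affected pixels lie at distance `r` from `p` along the gradient
#' direction: `p +/- round(g / ||g|| * r)`, rounding half away from zero
#' component-wise.
#'
#' @param p pixel coordinates `c(x, y)` (0-based).
#' @param g gradient vector `c(gx, gy)` with nonzero norm.
#' @param r radius in pixels.
#' @return list with `p_plus` and `p_minus`, each `c(x, y)`.
#' @export
affected_pixels <- function(p, g, r) {
  nrm <- sqrt(sum(g^2))
  assert(nrm > 0, "zero gradient has no affected pixels")
  off <- round_away(g / nrm * r)
  list(p_plus = p + off, p_minus = p - off)
}

#' Accumulate orientation and magnitude projection images
#'
#' For each pixel with a nonzero gradient, the orientation image gains
#' +/- 1 and the magnitude image +/- the gradient norm at the positively /
#' negatively affected pixel. In `"dark"` mode only the negatively-affected
#' updates are applied, in `"bright"` mode only the positive ones. Affected
#' pixels falling outside the image are discarded.
#'
#' @param grad gradient field from [gradient_field()].
#' @param r radius in pixels.
#' @param mode `"dark"`, `"bright"` or `"both"`.
#' @return list with matrices `O` and `M` (same size as the image).
#' @export
frst_accumulate <- function(grad, r, mode = "dark") {
  h <- nrow(grad$gx); w <- ncol(grad$gx)
  O <- matrix(0, h, w); M <- matrix(0, h, w)
  mag <- grad$magnitude
  sel <- which(mag > 0)
  if (length(sel) == 0) return(list(O = O, M = M))
  x <- (sel - 1L) %/% h   # 0-based column
  y <- (sel - 1L) %% h    # 0-based row
  m <- mag[sel]
  dx <- round_away(grad$gx[sel] / m * r)
  dy <- round_away(grad$gy[sel] / m * r)
  add_side <- function(sgn) {
    tx <- x + sgn * dx; ty <- y + sgn * dy
    ok <- tx >= 0 & tx < w & ty >= 0 & ty < h
    if (!any(ok)) return()
    idx <- tx[ok] * h + ty[ok] + 1L
    sums <- rowsum(cbind(1, m[ok]), group = idx)
    at <- as.integer(rownames(sums))
    O[at] <<- O[at] + sgn * sums[, 1]
    M[at] <<- M[at] + sgn * sums[, 2]
  }
  if (mode %in% c("bright", "both")) add_side(1)
  if (mode %in% c("dark", "both")) add_side(-1)
  list(O = O, M = M)
}

#' Single-radius symmetry image
#'
#' Combines the normalized orientation and magnitude projections,
#' `F_r = |O~|^alpha * |M~| * sign(O~)`, and spreads the contribution with a
#' unit-sum 2-D Gaussian of sigma `gaussian_sigma_factor * r` truncated at
#' 3 sigma (zero boundary). The sign is carried through so that dark
#' symmetric regions yield negative responses.
#'
#' @param O,M projection images from [frst_accumulate()].
#' @param r radius (pixels).
#' @param params `frst_params`.
#' @return matrix `S_r`.
#' @export
frst_symmetry_single <- function(O, M, r, params) {
  if (params$normalization == "kappa") {
    On <- clamp(O, -params$kappa, params$kappa) / params$kappa
    mm <- max(abs(M))
    Mn <- if (mm > 0) M / mm else M
  } else {
    om <- max(abs(O)); mm <- max(abs(M))
    On <- if (om > 0) O / om else O
    Mn <- if (mm > 0) M / mm else M
  }
  Fr <- abs(On)^params$alpha * abs(Mn) * sign(On)
  sigma <- params$gaussian_sigma_factor * r
  k <- gaussian_kernel1(sigma)
  conv1(conv1(Fr, k, "y", "zero"), k, "x", "zero")
}

#' Fast radial symmetry transform
#'
#' Full transform: the sum of the single-radius symmetry images over all
#' configured radii. In dark mode, minima of the result mark centers of
#' dark circular structures.
#'
#' @param img grayscale matrix.
#' @param params `frst_params`.
#' @return matrix `S`, same size as `img`.
#' @export
frst <- function(img, params) {
  assert_gray(img)
  grad <- gradient_field(img)
  S <- matrix(0, nrow(img), ncol(img))
  for (r in params$radii) {
    acc <- frst_accumulate(grad, r, params$mode)
    S <- S + frst_symmetry_single(acc$O, acc$M, r, params)
  }
  S
}
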