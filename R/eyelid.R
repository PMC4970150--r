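# Two-parabola eye shape model and Monte Carlo eyelid fitting.
#
# The external eye shape is a 12-value control-point vector: the iris
# center (cx, cy) plus, relative to it, the top/bottom eyelid mid-points
# (tx, ty), (bx, by), two outer control points of the top eyelid
# (tlx, tly), (trx, try), and the y-offsets bly, bry that place the bottom
# parabola's outer control points below the top ones (same x). Each eyelid
# is the unique parabola y = a x^2 + b x + c through its three control
# points. Candidate shapes are scored against the sclera probability map by
# comparing band means just inside vs just outside each eyelid curve, and
# the solution is the fitness-weighted average of the best hypotheses.

SHAPE_NAMES <- c("cx", "cy", "tx", "ty", "bx", "by",
                 "tlx", "tly", "trx", "try", "bly", "bry")

#' Construct an eye shape vector
#'
#' @param cx,cy iris center (absolute pixels).
#' @param tx,ty top-eyelid mid-point, relative to the center (y grows
#'   downwards, so `ty` is negative for an open eye).
#' @param bx,by bottom-eyelid mid-point (relative).
#' @param tlx,tly,trx,try_y left/right outer control points of the top
#'   eyelid (relative); must satisfy `tlx < tx < trx`.
#' @param bly,bry y-offsets added to `tly`/`try_y` to form the bottom
#'   parabola's outer control points.
#' @return named numeric vector of class `eye_shape` (12 values).
#' @export
eye_shape <- function(cx, cy, tx, ty, bx, by, tlx, tly, trx, try_y, bly, bry) {
  v <- c(cx, cy, tx, ty, bx, by, tlx, tly, trx, try_y, bly, bry)
  names(v) <- SHAPE_NAMES
  assert(all(is.finite(v)), "shape values must be finite")
  assert(v["tlx"] < v["tx"] && v["tx"] < v["trx"],
         "control points must satisfy tlx < tx < trx")
  structure(v, class = "eye_shape")
}

#' @noRd
as_eye_shape <- function(v) {
  names(v) <- SHAPE_NAMES
  structure(v, class = "eye_shape")
}

#' Parabola through three points
#'
#' Coefficients of the unique `y = a x^2 + b x + c` interpolating three
#' points with distinct x coordinates (`a` may be 0 for collinear points).
#'
#' @param p1,p2,p3 points `c(x, y)`.
#' @return named vector `c(a, b, c)`.
#' @export
parabola_from_points <- function(p1, p2, p3) {
  xs <- c(p1[1], p2[1], p3[1]); ys <- c(p1[2], p2[2], p3[2])
  assert(length(unique(xs)) == 3, "points must have distinct x coordinates")
  co <- as.numeric(solve(cbind(xs^2, xs, 1), ys))
  c(a = co[1], b = co[2], c = co[3])
}

#' Evaluate a parabola
#' @param par coefficients `c(a, b, c)`.
#' @param x x coordinates.
#' @return y values.
#' @export
parabola_y <- function(par, x) par[1] * x^2 + par[2] * x + par[3]

#' Top and bottom eyelid parabolas of an eye shape
#'
#' The top parabola passes through the three top control points, the bottom
#' parabola through the bottom mid-point and the two offset outer points;
#' all in absolute image coordinates.
#'
#' @param shape `eye_shape`.
#' @return list with `top` and `bottom` coefficient vectors.
#' @export
shape_to_parabolas <- function(shape) {
  s <- unclass(shape)
  cx <- s["cx"]; cy <- s["cy"]
  top <- parabola_from_points(
    c(cx + s["tlx"], cy + s["tly"]),
    c(cx + s["tx"],  cy + s["ty"]),
    c(cx + s["trx"], cy + s["try"]))
  bottom <- parabola_from_points(
    c(cx + s["tlx"], cy + s["tly"] + s["bly"]),
    c(cx + s["bx"],  cy + s["by"]),
    c(cx + s["trx"], cy + s["try"] + s["bry"]))
  list(top = top, bottom = bottom)
}

#' Band pixels alongside an eyelid parabola
#'
#' For each integer x in `x_range` and each offset `d` in `1..delta`, the
#' pixel `(x, round(f(x)) +/- d)`: the inner band points toward the eye
#' interior (downwards for the top eyelid, upwards for the bottom one), the
#' outer band away from it. Pixels outside the image are dropped.
#'
#' @param par parabola coefficients.
#' @param side `"inner"` or `"outer"`.
#' @param eyelid `"top"` or `"bottom"`.
#' @param delta band width in pixels (>= 1).
#' @param x_range `c(x_lo, x_hi)` inclusive integer range.
#' @param dims optional image dims `c(h, w)` for clipping.
#' @return matrix with columns `x`, `y` (0-based).
#' @export
band_pixels <- function(par, side = c("inner", "outer"),
                        eyelid = c("top", "bottom"), delta, x_range,
                        dims = NULL) {
  side <- match.arg(side); eyelid <- match.arg(eyelid)
  assert(delta >= 1, "delta must be >= 1")
  xs <- seq.int(ceiling(x_range[1]), floor(x_range[2]))
  assert(length(xs) > 0, "empty x range")
  sgn <- if (eyelid == "top") (if (side == "inner") 1 else -1) else
    (if (side == "inner") -1 else 1)
  y0 <- round(parabola_y(par, xs))
  d <- rep(seq_len(delta), each = length(xs))
  x <- rep(xs, times = delta)
  y <- rep(y0, times = delta) + sgn * d
  if (!is.null(dims)) {
    ok <- x >= 0 & x < dims[2] & y >= 0 & y < dims[1]
    x <- x[ok]; y <- y[ok]
  }
  assert(length(x) > 0, "band lies entirely outside the image")
  cbind(x = x, y = y)
}

#' Monte Carlo matching parameters
#'
#' @param alpha,beta weights of the inner (sclera) and outer (non-sclera)
#'   band means; must sum to 1 (defaults 0.5 / 0.5).
#' @param delta band width in pixels (default 5, proportional to a typical
#'   iris radius).
#' @param n_hypotheses number of uniformly sampled shapes (default 200).
#' @param top_fraction fraction of fittest hypotheses that vote
#'   (default 0.3).
#' @param seed optional RNG seed for reproducible sampling.
#' @return object of class `mc_params`.
#' @export
mc_params <- function(alpha = 0.5, beta = 0.5, delta = 5, n_hypotheses = 200,
                      top_fraction = 0.3, seed = NULL) {
  assert(abs(alpha + beta - 1) < 1e-9, "alpha + beta must equal 1")
  assert(delta >= 1, "delta must be >= 1")
  assert(n_hypotheses >= 1, "need at least one hypothesis")
  structure(list(alpha = alpha, beta = beta, delta = delta,
                 n_hypotheses = as.integer(n_hypotheses),
                 top_fraction = top_fraction, seed = seed),
            class = "mc_params")
}

# scoring interval: fixed around the center (the hypothesis corners are
# only known after voting), clipped to the map
#' @noRd
hypothesis_x_range <- function(shape, prob_dims, halfwidth) {
  rng <- shape["cx"] + c(-1, 1) * halfwidth
  c(max(0, rng[1]), min(prob_dims[2] - 1, rng[2]))
}

#' Fitness of an eye-shape hypothesis on a probability map
#'
#' `omega = (alpha * mean(p+) - beta * mean(p-)) / (alpha + beta)`, where
#' `p+` pools the sclera probabilities of the inner bands of both eyelid
#' parabolas (expected bright) and `p-` the outer bands (expected dark).
#' With probabilities in \[0, 1\] and `alpha + beta = 1`, omega lies in
#' \[-1, 1\]; a hypothesis sitting exactly on the sclera boundary of an
#' ideal binary map scores `alpha`.
#'
#' @param prob_map sclera probability matrix in \[0, 1\].
#' @param shape `eye_shape` (coordinates in the map's frame).
#' @param params `mc_params`.
#' @param x_range optional explicit x interval; by default a fixed window
#'   of `halfwidth` pixels either side of the center (clipped to the map),
#'   so scores are comparable across hypotheses.
#' @param halfwidth half-width of the default scoring interval;
#'   `segment_eye()` passes `3 * iris_radius`.
#' @return scalar omega.
#' @export
score_hypothesis <- function(prob_map, shape, params, x_range = NULL,
                             halfwidth = NULL) {
  dims <- dim(prob_map)
  if (is.null(halfwidth))
    halfwidth <- 3 * max(params$delta, (shape["trx"] - shape["tlx"]) / 4)
  if (is.null(x_range))
    x_range <- hypothesis_x_range(shape, dims, halfwidth)
  assert(x_range[2] > x_range[1], "hypothesis does not intersect the ROI")
  pb <- shape_to_parabolas(shape)
  grab <- function(par, side, lid) {
    px <- tryCatch(band_pixels(par, side, lid, params$delta, x_range, dims),
                   error = function(e) NULL)
    if (is.null(px)) numeric(0) else prob_map[cbind(px[, "y"] + 1, px[, "x"] + 1)]
  }
  inner <- c(grab(pb$top, "inner", "top"), grab(pb$bottom, "inner", "bottom"))
  outer <- c(grab(pb$top, "outer", "top"), grab(pb$bottom, "outer", "bottom"))
  assert(length(inner) > 0 && length(outer) > 0, "empty scoring bands")
  (params$alpha * mean(inner) - params$beta * mean(outer)) /
    (params$alpha + params$beta)
}

#' Default sampling bounds of the hypothesis domain
#'
#' Uniform bounds for each shape value, proportional to the iris radius R
#' (from eye anthropometry): mid-points near the vertical through the
#' center, outer control points at 1.2-3 R laterally. The center itself is
#' fixed (degenerate bounds) at the detected iris center.
#'
#' @param center iris center `c(x, y)`.
#' @param iris_radius radius R in pixels.
#' @return named list of `c(lo, hi)` bounds for all 12 shape values.
#' @export
default_shape_bounds <- function(center, iris_radius) {
  R <- iris_radius
  list(cx = c(center[1], center[1]), cy = c(center[2], center[2]),
       tx = c(-0.5, 0.5) * R, ty = c(-2.2, -0.8) * R,
       bx = c(-0.5, 0.5) * R, by = c(0.8, 2.2) * R,
       tlx = c(-3, -1.2) * R, tly = c(-1.2, 0.6) * R,
       trx = c(1.2, 3) * R, try = c(-1.2, 0.6) * R,
       bly = c(0.2, 2.5) * R, bry = c(0.2, 2.5) * R)
}

#' Uniformly sample eye-shape hypotheses
#'
#' Each of the 12 shape values is drawn independently and uniformly from
#' its bounds; rows violating `tlx < tx < trx` are resampled. Deterministic
#' for a given `params$seed`.
#'
#' @param center iris center `c(x, y)`.
#' @param iris_radius iris radius R (pixels).
#' @param params `mc_params`.
#' @param bounds bounds list as from [default_shape_bounds()].
#' @return matrix `n_hypotheses x 12` (columns named as the shape vector).
#' @export
generate_hypotheses <- function(center, iris_radius, params,
                                bounds = default_shape_bounds(center, iris_radius)) {
  assert(all(SHAPE_NAMES %in% names(bounds)), "bounds must cover all 12 shape values")
  for (nm in SHAPE_NAMES)
    assert(bounds[[nm]][2] >= bounds[[nm]][1], paste("invalid bounds for", nm))
  if (!is.null(params$seed)) set.seed(params$seed)
  n <- params$n_hypotheses
  draw <- function(m) {
    vapply(SHAPE_NAMES, function(nm) {
      lo <- bounds[[nm]][1]; hi <- bounds[[nm]][2]
      if (hi > lo) stats::runif(m, lo, hi) else rep(lo, m)
    }, numeric(m))
  }
  H <- matrix(draw(n), nrow = n, dimnames = list(NULL, SHAPE_NAMES))
  for (it in 1:100) {
    bad <- which(!(H[, "tlx"] < H[, "tx"] & H[, "tx"] < H[, "trx"]))
    if (length(bad) == 0) break
    H[bad, ] <- matrix(draw(length(bad)), nrow = length(bad))
  }
  H
}

#' Vote the solution shape from scored hypotheses
#'
#' The fittest `ceiling(top_fraction * N)` hypotheses contribute; weights
#' are the fitness values shifted by the minimum selected fitness (floored
#' at a small epsilon so they are nonnegative), and the solution control
#' points are the weighted per-coordinate average -- a convex combination
#' of the selected shapes.
#'
#' @param hypotheses matrix `n x 12` of shapes.
#' @param omegas fitness of each hypothesis.
#' @param params `mc_params`.
#' @param eps weight floor keeping every selected vote strictly positive.
#' @return voted `eye_shape`.
#' @export
vote_shape <- function(hypotheses, omegas, params, eps = 1e-6) {
  n <- nrow(hypotheses)
  assert(n >= 1 && length(omegas) == n, "need one omega per hypothesis")
  m <- min(n, max(1L, ceiling(params$top_fraction * n)))
  sel <- order(-omegas)[seq_len(m)]
  w <- pmax(omegas[sel] - min(omegas[sel]), eps)
  if (sum(w) <= 0) return(as_eye_shape(hypotheses[sel[1], ]))
  as_eye_shape(drop(w %*% hypotheses[sel, , drop = FALSE]) / sum(w))
}

#' Eye corners as the parabola intersections
#'
#' Solves `a1 x^2 + b1 x + c1 = a2 x^2 + b2 x + c2`; two distinct real
#' roots are required. The left corner is the smaller root.
#'
#' @param top,bottom parabola coefficient vectors.
#' @return list with `left` and `right` corners `c(x, y)`.
#' @export
eye_corners <- function(top, bottom) {
  da <- top[1] - bottom[1]; db <- top[2] - bottom[2]; dc <- top[3] - bottom[3]
  if (abs(da) < 1e-12) {
    assert(abs(db) >= 1e-12, "identical parabolas have no corners")
    stop("parabolas intersect in fewer than two points", call. = FALSE)
  }
  disc <- db^2 - 4 * da * dc
  assert(disc > 0, "parabolas intersect in fewer than two points")
  roots <- sort((-db + c(-1, 1) * sqrt(disc)) / (2 * da))
  list(left = c(roots[1], unname(parabola_y(top, roots[1]))),
       right = c(roots[2], unname(parabola_y(top, roots[2]))))
}

#' @noRd
eye_region_mask <- function(dims, top, bottom, x_lo, x_hi) {
  mask <- matrix(FALSE, dims[1], dims[2])
  xs <- seq.int(max(0, ceiling(x_lo)), min(dims[2] - 1, floor(x_hi)))
  for (x in xs) {
    yt <- parabola_y(top, x); yb <- parabola_y(bottom, x)
    if (yb < yt) next
    y0 <- max(0, ceiling(yt)); y1 <- min(dims[1] - 1, floor(yb))
    if (y1 >= y0) mask[(y0 + 1):(y1 + 1), x + 1] <- TRUE
  }
  mask
}

#' Segment the eye shape by Monte Carlo sampling
#'
#' Generates `n_hypotheses` shapes around the iris center, scores each on
#' the sclera probability map, votes the solution from the fittest
#' fraction, and extracts the eye corners and a binary mask of the region
#' between the two parabolas.
#'
#' @param prob_map sclera probability matrix.
#' @param center iris center `c(x, y)` in map coordinates.
#' @param iris_radius iris radius (pixels).
#' @param params `mc_params`.
#' @param bounds optional sampling bounds.
#' @return list with `shape` (`eye_shape`), `corners`, `mask` (logical
#'   matrix), `omega` (fitness of the voted shape) and `omegas` (all
#'   hypothesis scores).
#' @export
segment_eye <- function(prob_map, center, iris_radius, params = mc_params(),
                        bounds = NULL) {
  dims <- dim(prob_map)
  if (is.null(bounds)) bounds <- default_shape_bounds(center, iris_radius)
  H <- generate_hypotheses(center, iris_radius, params, bounds)
  fb <- 3 * iris_radius
  omegas <- vapply(seq_len(nrow(H)), function(i) {
    tryCatch(score_hypothesis(prob_map, as_eye_shape(H[i, ]), params,
                              halfwidth = fb),
             error = function(e) -Inf)
  }, numeric(1))
  assert(any(is.finite(omegas)), "no hypothesis could be scored on this map")
  H <- H[is.finite(omegas), , drop = FALSE]
  omegas <- omegas[is.finite(omegas)]
  shape <- vote_shape(H, omegas, params)
  pb <- shape_to_parabolas(shape)
  corners <- tryCatch(eye_corners(pb$top, pb$bottom), error = function(e) {
    xr <- c(max(0, center[1] - fb), min(dims[2] - 1, center[1] + fb))
    list(left = c(xr[1], unname(parabola_y(pb$top, xr[1]))),
         right = c(xr[2], unname(parabola_y(pb$top, xr[2]))))
  })
  mask <- eye_region_mask(dims, pb$top, pb$bottom, corners$left[1], corners$right[1])
  omega <- tryCatch(score_hypothesis(prob_map, shape, params,
                                     halfwidth = fb),
                    error = function(e) NA_real_)
  list(shape = shape, corners = corners, mask = mask,
       omega = omega, omegas = omegas)
}
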