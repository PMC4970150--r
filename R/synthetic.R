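# Parametric renderer of frontal eye and face images with exact ground
# truth: skin background, off-white sclera bounded by the two eyelid
# parabolas, dark iris disk with darker pupil, dark eyebrow bands, additive
# Gaussian noise and an optional specular highlight. Masks and annotations
# are exact by construction (no anti-aliasing by default), so parameter-
# recovery tests against the renderer are well-posed.

#' Default synthetic palette
#'
#' Region mean colors (R, G, B in 0..255) chosen to mimic the contrast of
#' typical sclera / skin training patches.
#'
#' @return named list of RGB triplets.
#' @export
synthetic_colors <- function() {
  list(skin = c(205, 170, 140), sclera = c(235, 230, 225),
       iris = c(60, 80, 40), pupil = c(15, 15, 15),
       eyebrow = c(90, 60, 45), highlight = c(250, 250, 250))
}

#' Canonical open-eye shape for rendering
#'
#' A symmetric two-parabola shape scaled by the iris radius R: eyelid
#' apices at -/+ `openness * R` vertically, outer control points at
#' +/- 2.15 R, giving corners near +/- 2.38 R so that the iris-to-eye
#' width ratio is about 0.42.
#'
#' @param center `c(x, y)` iris center (absolute pixels).
#' @param iris_radius R in pixels.
#' @param openness vertical apex offset in units of R (default 1.6; values
#'   below 1 occlude the top of the iris).
#' @return `eye_shape`.
#' @export
synthetic_eye_shape <- function(center, iris_radius, openness = 1.6) {
  R <- iris_radius
  eye_shape(center[1], center[2],
            tx = 0, ty = -openness * R, bx = 0, by = 1.6 * R,
            tlx = -2.15 * R, tly = -0.3 * R, trx = 2.15 * R, try_y = -0.3 * R,
            bly = 0.6 * R, bry = 0.6 * R)
}

#' Eye render specification
#'
#' @param shape ground-truth `eye_shape` (absolute coordinates on the
#'   target canvas).
#' @param iris_radius,pupil_radius disk radii in pixels
#'   (`pupil_radius < iris_radius`).
#' @param colors palette list as [synthetic_colors()].
#' @param noise_sigma additive Gaussian noise sd in intensity units
#'   (default 0).
#' @param highlight optional specular disk `list(dx, dy, radius)` relative
#'   to the iris center.
#' @param seed optional RNG seed for the noise.
#' @return object of class `eye_render_spec`.
#' @export
eye_render_spec <- function(shape, iris_radius, pupil_radius,
                            colors = synthetic_colors(), noise_sigma = 0,
                            highlight = NULL, seed = NULL) {
  assert(pupil_radius < iris_radius, "pupil radius must be below the iris radius")
  structure(list(shape = shape, iris_radius = iris_radius,
                 pupil_radius = pupil_radius, colors = colors,
                 noise_sigma = noise_sigma, highlight = highlight, seed = seed),
            class = "eye_render_spec")
}

# paint one eye onto channel matrices (in place value-wise); returns masks
#' @noRd
paint_eye <- function(chan, spec) {
  s <- unclass(spec$shape)
  dims <- dim(chan[[1]])
  pb <- shape_to_parabolas(spec$shape)
  corners <- eye_corners(pb$top, pb$bottom)
  eye <- eye_region_mask(dims, pb$top, pb$bottom, corners$left[1], corners$right[1])
  X <- matrix(rep(0:(dims[2] - 1), each = dims[1]), dims[1])
  Y <- matrix(rep(0:(dims[1] - 1), times = dims[2]), dims[1])
  d2 <- (X - s["cx"])^2 + (Y - s["cy"])^2
  iris <- eye & d2 <= spec$iris_radius^2
  pupil <- eye & d2 <= spec$pupil_radius^2
  sclera <- eye & !iris
  for (k in 1:3) {
    chan[[k]][sclera] <- spec$colors$sclera[k]
    chan[[k]][iris] <- spec$colors$iris[k]
    chan[[k]][pupil] <- spec$colors$pupil[k]
  }
  if (!is.null(spec$highlight)) {
    hl <- spec$highlight
    hd2 <- (X - s["cx"] - hl$dx)^2 + (Y - s["cy"] - hl$dy)^2
    hm <- eye & hd2 <= hl$radius^2
    for (k in 1:3) chan[[k]][hm] <- spec$colors$highlight[k]
  }
  list(chan = chan, masks = list(eye = eye, sclera = sclera, iris = iris),
       corners = corners)
}

#' @noRd
eye_annotation_from_spec <- function(spec, corners) {
  s <- unclass(spec$shape)
  list(pupil_center = unname(c(s["cx"], s["cy"])),
       iris_radius = spec$iris_radius,
       left_corner = unname(corners$left), right_corner = unname(corners$right),
       top_eyelid_mid = unname(c(s["cx"] + s["tx"], s["cy"] + s["ty"])),
       bottom_eyelid_mid = unname(c(s["cx"] + s["bx"], s["cy"] + s["by"])),
       shape = unname(unclass(spec$shape)))
}

#' @noRd
add_noise <- function(chan, sigma, seed = NULL) {
  if (sigma > 0) {
    if (!is.null(seed)) set.seed(seed)
    for (k in 1:3)
      chan[[k]] <- clamp(round(chan[[k]] +
                                 matrix(stats::rnorm(length(chan[[k]]), 0, sigma),
                                        nrow(chan[[k]]))), 0, 255)
  }
  chan
}

#' @noRd
chan_to_rgb <- function(chan) {
  img <- array(0, c(dim(chan[[1]]), 3))
  for (k in 1:3) img[, , k] <- chan[[k]]
  img
}

#' Render a single synthetic eye
#'
#' @param spec `eye_render_spec`.
#' @param width,height canvas size; defaults fit the eye with a margin.
#' @return list with `image` (RGB array), `annotation` (ground truth) and
#'   `masks` (logical matrices `eye`, `sclera`, `iris`).
#' @export
render_eye <- function(spec, width = NULL, height = NULL) {
  s <- unclass(spec$shape)
  if (is.null(width)) width <- ceiling(s["cx"] + abs(s["trx"]) * 1.4)
  if (is.null(height)) height <- ceiling(s["cy"] + s["by"] * 1.8)
  assert(s["cx"] + s["tlx"] > 0 && s["cx"] + s["trx"] < width &&
           s["cy"] + s["ty"] > 0 && s["cy"] + s["by"] < height,
         "eye shape does not fit the canvas")
  chan <- lapply(1:3, function(k) matrix(spec$colors$skin[k], height, width))
  p <- paint_eye(chan, spec)
  chan <- add_noise(p$chan, spec$noise_sigma, spec$seed)
  list(image = chan_to_rgb(chan),
       annotation = eye_annotation_from_spec(spec, p$corners),
       masks = p$masks)
}

#' Face render specification
#'
#' Anthropometric placement: eye centers at `0.5 +/- ipd_ratio/2` of the
#' face width and `eye_y_ratio` of the face height; nominal iris radius
#' `0.5 * 0.42 * face_w / 5` (eye width one fifth of the face, iris 0.42 of
#' the eye width); eyebrow bands above each eye.
#'
#' @param face_w face width in pixels (default 400).
#' @param face_h face height (default `1.3 * face_w`).
#' @param ipd_ratio inter-pupillary distance / face width (default 0.4).
#' @param eye_y_ratio eye row / face height (default 0.42).
#' @param iris_radius one or two radii (left, right); default the nominal
#'   anthropometric radius.
#' @param openness eyelid openness passed to [synthetic_eye_shape()]; one
#'   or two values.
#' @param colors palette list.
#' @param noise_sigma additive noise sd (default 2).
#' @param highlight optional specular disk spec applied to both eyes.
#' @param margin skin margin around the face box (default `0.04 * face_w`).
#' @param seed optional RNG seed for the noise.
#' @return object of class `face_render_spec`.
#' @export
face_render_spec <- function(face_w = 400, face_h = round(1.3 * face_w),
                             ipd_ratio = 0.4, eye_y_ratio = 0.42,
                             iris_radius = NULL, openness = 1.6,
                             colors = synthetic_colors(), noise_sigma = 2,
                             highlight = NULL, margin = round(0.04 * face_w),
                             seed = NULL) {
  r0 <- fp_tidy(0.5 * 0.42 * face_w / 5)
  if (is.null(iris_radius)) iris_radius <- r0
  iris_radius <- rep_len(iris_radius, 2)
  openness <- rep_len(openness, 2)
  assert(ipd_ratio > 0 && ipd_ratio < 1, "ipd_ratio must be in (0, 1)")
  structure(list(face_w = face_w, face_h = face_h, ipd_ratio = ipd_ratio,
                 eye_y_ratio = eye_y_ratio, iris_radius = iris_radius,
                 openness = openness, colors = colors,
                 noise_sigma = noise_sigma, highlight = highlight,
                 margin = margin, seed = seed),
            class = "face_render_spec")
}

#' Render a synthetic frontal face
#'
#' Composites two eyes and two eyebrow bands onto a skin canvas and
#' returns exact annotations for both eyes together with the face box.
#'
#' @param spec `face_render_spec`.
#' @return list with `image`, `face` (`face_box`), `left`, `right`
#'   (annotations), and `masks` (per-eye mask lists).
#' @export
render_face <- function(spec) {
  m <- spec$margin
  W <- spec$face_w + 2 * m; H <- spec$face_h + 2 * m
  chan <- lapply(1:3, function(k) matrix(spec$colors$skin[k], H, W))
  eye_y <- m + spec$eye_y_ratio * spec$face_h
  ex <- m + (0.5 + c(-0.5, 0.5) * spec$ipd_ratio) * spec$face_w
  masks <- list(); anns <- list()
  for (i in 1:2) {
    R <- spec$iris_radius[i]
    shp <- synthetic_eye_shape(c(ex[i], eye_y), R, spec$openness[i])
    es <- eye_render_spec(shp, R, pupil_radius = max(2, round(0.45 * R)),
                          colors = spec$colors, highlight = spec$highlight)
    p <- paint_eye(chan, es)
    chan <- p$chan
    masks[[i]] <- p$masks
    anns[[i]] <- eye_annotation_from_spec(es, p$corners)
    # eyebrow band above this eye
    bw <- 2.8 * R
    by0 <- round(eye_y - 0.125 * spec$face_h)
    by1 <- round(eye_y - 0.095 * spec$face_h)
    bx0 <- max(0, round(ex[i] - bw)); bx1 <- min(W - 1, round(ex[i] + bw))
    for (k in 1:3)
      chan[[k]][(by0 + 1):(by1 + 1), (bx0 + 1):(bx1 + 1)] <- spec$colors$eyebrow[k]
  }
  chan <- add_noise(chan, spec$noise_sigma, spec$seed)
  list(image = chan_to_rgb(chan),
       face = face_box(m, m, spec$face_w, spec$face_h),
       left = anns[[1]], right = anns[[2]],
       masks = list(left = masks[[1]], right = masks[[2]]))
}

#' Generate a reproducible synthetic dataset
#'
#' Renders `n` faces with randomized anthropometry and writes, per image, a
#' PNG, a ground-truth annotation JSON and eye-region mask PNGs. The
#' `difficulty` presets are: `"clean"` (mild noise, fully visible irises),
#' `"noisy"` (strong noise plus a specular highlight) and `"occluded"`
#' (top eyelids lowered over the iris, emulating semi-closed eyes).
#'
#' @param dir output directory (created if missing).
#' @param n number of images (>= 1).
#' @param difficulty `"clean"`, `"noisy"` or `"occluded"`.
#' @param seed RNG seed making the corpus reproducible.
#' @return data.frame manifest with file paths and ground-truth columns.
#' @export
generate_dataset <- function(dir, n, difficulty = c("clean", "noisy", "occluded"),
                             seed = 1) {
  difficulty <- match.arg(difficulty)
  assert(n >= 1, "n must be >= 1")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    spec <- sample_face_spec(difficulty, seed = seed + i - 1)
    fr <- render_face(spec)
    img_path <- file.path(dir, sprintf("face_%03d.png", i))
    ann_path <- file.path(dir, sprintf("face_%03d.json", i))
    mask_path <- file.path(dir, sprintf("face_%03d_eyemask.png", i))
    write_image(fr$image, img_path)
    write_annotations(list(image = basename(img_path), left = fr$left,
                           right = fr$right), ann_path)
    write_image((fr$masks$left$eye | fr$masks$right$eye) * 255, mask_path)
    rows[[i]] <- data.frame(
      image = img_path, annotation = ann_path, mask = mask_path,
      face_x = fr$face$x, face_y = fr$face$y, face_w = fr$face$w,
      face_h = fr$face$h,
      left_x = fr$left$pupil_center[1], left_y = fr$left$pupil_center[2],
      right_x = fr$right$pupil_center[1], right_y = fr$right$pupil_center[2],
      left_r = fr$left$iris_radius, right_r = fr$right$iris_radius)
  }
  do.call(rbind, rows)
}

#' Sample a randomized face render spec
#'
#' Draws anthropometric parameters from narrow uniform ranges around the
#' defaults (face width 360-440 px, IPD ratio 0.38-0.42, eye row
#' 0.40-0.44, iris radius within 10\% of nominal, mild color jitter) for
#' the given difficulty preset.
#'
#' @param difficulty `"clean"`, `"noisy"` or `"occluded"`.
#' @param seed RNG seed.
#' @return `face_render_spec`.
#' @export
sample_face_spec <- function(difficulty = "clean", seed = 1) {
  set.seed(seed)
  face_w <- round(stats::runif(1, 360, 440))
  r0 <- 0.5 * 0.42 * face_w / 5
  cols <- synthetic_colors()
  jit <- function(col) clamp(col + round(stats::runif(3, -8, 8)), 0, 255)
  cols$skin <- jit(cols$skin); cols$sclera <- jit(cols$sclera)
  noise <- switch(difficulty, clean = 2, noisy = 12, occluded = 4)
  openness <- if (difficulty == "occluded") stats::runif(2, 0.55, 0.8) else
    stats::runif(2, 1.4, 1.8)
  hl <- if (difficulty == "noisy")
    list(dx = -0.3 * r0, dy = -0.3 * r0, radius = max(1, 0.2 * r0)) else NULL
  face_render_spec(
    face_w = face_w,
    ipd_ratio = stats::runif(1, 0.38, 0.42),
    eye_y_ratio = stats::runif(1, 0.40, 0.44),
    iris_radius = r0 * stats::runif(2, 0.9, 1.1),
    openness = openness, colors = cols, noise_sigma = noise,
    highlight = hl, seed = seed + 10000L)
}
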