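# Shared fixtures, built lazily and cached for the whole test run.

.fixtures <- new.env(parent = emptyenv())

clip255 <- function(x) pmin(pmax(x, 0), 255)

# Gaussian color cloud around a palette mean
color_cloud <- function(mu, n, sd = 6) {
  clip255(matrix(rep(mu, each = n), n) + matrix(stats::rnorm(3 * n, 0, sd), n))
}

# sclera / non-sclera training pixels emulating 25 + 30 patches of 10x10
sclera_training_pixels <- function(seed = 42, sd = 6) {
  set.seed(seed)
  cols <- synthetic_colors()
  list(pos = color_cloud(cols$sclera, 25 * 100, sd),
       neg = rbind(color_cloud(cols$skin, 18 * 100, sd),
                   color_cloud(cols$eyebrow, 6 * 100, sd),
                   color_cloud(cols$iris, 6 * 100, sd)))
}

get_sclera_model <- function() {
  if (is.null(.fixtures$model)) {
    px <- sclera_training_pixels()
    .fixtures$model <- train_sclera_classifier(px$pos, px$neg)
  }
  .fixtures$model
}

get_sclera_lut <- function() {
  if (is.null(.fixtures$lut))
    .fixtures$lut <- build_sclera_lut(get_sclera_model())
  .fixtures$lut
}

# ground-truth shape at the center of the hypothesis sampling domain (the
# only truth whose full control-point decomposition is identified by a
# binary probability map; see the methods vignette)
domain_mid_shape <- function(center, iris_radius) {
  b <- default_shape_bounds(center, iris_radius)
  m <- vapply(b, mean, numeric(1))
  eye_shape(m["cx"], m["cy"], m["tx"], m["ty"], m["bx"], m["by"],
            m["tlx"], m["tly"], m["trx"], m["try"], m["bly"], m["bry"])
}

# binary probability map (1 inside the eye region) for a truth shape
binary_map_for <- function(shape, dims) {
  pb <- shape_to_parabolas(shape)
  crn <- eye_corners(pb$top, pb$bottom)
  mask_between_parabolas(dims, pb$top, pb$bottom,
                         crn$left[1], crn$right[1]) * 1
}

# independent point-in-region rasterizer (per-pixel test, no shared code
# with the package's column-wise filler)
mask_between_parabolas <- function(dims, top, bottom, x_lo, x_hi) {
  m <- matrix(FALSE, dims[1], dims[2])
  for (y in 0:(dims[1] - 1)) for (x in 0:(dims[2] - 1)) {
    if (x < x_lo || x > x_hi) next
    yt <- top[1] * x^2 + top[2] * x + top[3]
    yb <- bottom[1] * x^2 + bottom[2] * x + bottom[3]
    m[y + 1, x + 1] <- (y >= yt && y <= yb)
  }
  m
}
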