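test_that("parabola interpolation through three points is exact", {
  expect_equal(parabola_from_points(c(-1, 1), c(0, 0), c(1, 1)),
               c(a = 1, b = 0, c = 0))
  expect_equal(parabola_from_points(c(0, 0), c(1, 1), c(2, 2)),
               c(a = 0, b = 1, c = 0))
  p <- parabola_from_points(c(0, 2), c(3, 0), c(5, 4))
  for (pt in list(c(0, 2), c(3, 0), c(5, 4)))
    expect_equal(parabola_y(p, pt[1]), pt[2], tolerance = 1e-9,
                 ignore_attr = TRUE)
  expect_error(parabola_from_points(c(1, 0), c(1, 2), c(3, 1)), "distinct")
})

test_that("shape-to-parabola construction honours the control points", {
  sym <- eye_shape(50, 40, 0, -15, 0, 15, -20, -3, 20, -3, 6, 6)
  pb <- shape_to_parabolas(sym)
  expect_equal(unname(pb$top["b"] + 2 * pb$top["a"] * 50), 0, tolerance = 1e-9)
  expect_equal(unname(pb$bottom["b"] + 2 * pb$bottom["a"] * 50), 0,
               tolerance = 1e-9)

  flat <- eye_shape(50, 40, 0, -3, 0, -3, -20, -3, 20, -3, 0, 0)
  pbf <- shape_to_parabolas(flat)
  expect_equal(pbf$top, pbf$bottom, tolerance = 1e-9)

  set.seed(12)
  for (i in 1:5) {
    s <- eye_shape(50 + runif(1, -5, 5), 40, runif(1, -4, 4), runif(1, -20, -10),
                   runif(1, -4, 4), runif(1, 10, 20), runif(1, -30, -18),
                   runif(1, -6, 4), runif(1, 18, 30), runif(1, -6, 4),
                   runif(1, 3, 15), runif(1, 3, 15))
    pb <- shape_to_parabolas(s)
    v <- unclass(s)
    expect_equal(parabola_y(pb$top, v["cx"] + v["tx"]), v["cy"] + v["ty"],
                 tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(parabola_y(pb$bottom, v["cx"] + v["tlx"]),
                 v["cy"] + v["tly"] + v["bly"],
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("band pixels enumerate the offsets next to the curve", {
  par <- c(a = 0.02, b = -1, c = 30)
  b1 <- band_pixels(par, "inner", "top", delta = 1, x_range = c(5, 15))
  expect_equal(nrow(b1), 11)
  inner <- band_pixels(par, "inner", "top", 4, c(5, 15))
  outer <- band_pixels(par, "outer", "top", 4, c(5, 15))
  expect_equal(nrow(inner), nrow(outer))
  # literal enumeration oracle
  want <- do.call(rbind, lapply(5:15, function(x) {
    y0 <- round(0.02 * x^2 - x + 30)
    cbind(x = rep(x, 4), y = y0 + 1:4)   # inner of top eyelid points down
  }))
  expect_equal(inner[order(inner[, "x"], inner[, "y"]), ],
               want[order(want[, "x"], want[, "y"]), ])
  # bottom-eyelid inner band points up
  binner <- band_pixels(par, "inner", "bottom", 2, c(5, 6))
  expect_true(all(binner[, "y"] < round(parabola_y(par, binner[, "x"]))))
})

test_that("hypothesis scoring realizes the band-mean closed forms", {
  params <- mc_params()
  shape <- domain_mid_shape(c(60, 50), 12)
  uni <- matrix(0.37, 110, 130)
  expect_equal(score_hypothesis(uni, shape, params), 0, tolerance = 1e-12)

  pm <- binary_map_for(shape, c(110, 130))
  # central interval where the region is thicker than delta on both sides
  omega <- score_hypothesis(pm, shape, params, x_range = c(45, 75))
  expect_equal(omega, 0.5, tolerance = 1e-12)

  off <- unclass(shape)
  moved <- eye_shape(off["cx"], off["cy"] + 60, off["tx"], off["ty"], off["bx"],
                     off["by"], off["tlx"], off["tly"], off["trx"], off["try"],
                     off["bly"], off["bry"])
  expect_lte(score_hypothesis(pm, moved, params, x_range = c(45, 75)), 0)
})

test_that("hypothesis sampling is uniform inside the bounds and ordered", {
  center <- c(60, 50)
  bounds <- default_shape_bounds(center, 12)
  degen <- lapply(bounds, function(b) c(mean(b), mean(b)))
  p1 <- mc_params(n_hypotheses = 1, seed = 5)
  H1 <- generate_hypotheses(center, 12, p1, degen)
  expect_equal(unname(H1[1, ]), unname(vapply(degen, mean, numeric(1))))

  p <- mc_params(n_hypotheses = 10000, seed = 6)
  H <- generate_hypotheses(center, 12, p)
  expect_true(all(H[, "tlx"] < H[, "tx"] & H[, "tx"] < H[, "trx"]))
  for (nm in colnames(H)) {
    lo <- bounds[[nm]][1]; hi <- bounds[[nm]][2]
    expect_true(all(H[, nm] >= lo & H[, nm] <= hi))
    if (hi > lo) {
      expect_lt(min(H[, nm]) - lo, 0.02 * (hi - lo))
      expect_lt(hi - max(H[, nm]), 0.02 * (hi - lo))
    }
  }
})

test_that("voting averages the fittest hypotheses convexly", {
  params <- mc_params(top_fraction = 0.5)
  s <- unclass(domain_mid_shape(c(60, 50), 12))
  H <- rbind(s, s, s, s)
  expect_equal(unname(unclass(vote_shape(H, c(1, 2, 3, 4), params))),
               unname(s))
  H2 <- rbind(s - 2, s + 2, s + 100, s - 100)
  # equal adjusted weights (after the epsilon floor) -> midpoint of the two
  v <- vote_shape(H2, c(5, 5, 1, 1), params)
  expect_equal(unname(unclass(v)), unname(s), tolerance = 1e-6)
  set.seed(14)
  for (i in 1:5) {
    H3 <- H + matrix(runif(length(H), -3, 3), nrow(H))
    om <- runif(4, -0.2, 0.5)
    v3 <- unclass(vote_shape(H3, om, params))
    m <- max(1, ceiling(params$top_fraction * 4))
    sel <- H3[order(-om)[1:m], , drop = FALSE]
    expect_true(all(v3 >= apply(sel, 2, min) - 1e-9 &
                      v3 <= apply(sel, 2, max) + 1e-9))
  }
})

test_that("eye corners are the parabola intersections", {
  crn <- eye_corners(c(1, 0, 0), c(-1, 0, 2))
  expect_equal(crn$left, c(-1, 1))
  expect_equal(crn$right, c(1, 1))
  expect_error(eye_corners(c(1, 0, 0), c(1, 0, 0)), "corners|fewer")
  shape <- domain_mid_shape(c(60, 50), 12)
  pb <- shape_to_parabolas(shape)
  crn2 <- eye_corners(pb$top, pb$bottom)
  for (c0 in list(crn2$left, crn2$right)) {
    expect_equal(parabola_y(pb$top, c0[1]), c0[2], tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(parabola_y(pb$bottom, c0[1]), c0[2], tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("eye segmentation is deterministic and translation equivariant", {
  center <- c(60, 50); R <- 12
  truth <- domain_mid_shape(center, R)
  pm <- binary_map_for(truth, c(110, 130))
  a <- segment_eye(pm, center, R, mc_params(seed = 77))
  b <- segment_eye(pm, center, R, mc_params(seed = 77))
  expect_identical(a$shape, b$shape)
  expect_identical(a$mask, b$mask)

  # mask sanity: nonempty, bounded by the corner x-range
  expect_gt(sum(a$mask), 0)
  xs <- which(colSums(a$mask) > 0) - 1
  expect_gte(min(xs), floor(a$corners$left[1]))
  expect_lte(max(xs), ceiling(a$corners$right[1]))

  # voted omega at least the median of the scored hypotheses
  expect_gte(a$omega, stats::median(a$omegas))

  # shift map and center together: voted shape shifts along
  dx <- 6; dy <- 4
  pm2 <- matrix(0, 110, 130)
  pm2[(dy + 1):110, (dx + 1):130] <- pm[1:(110 - dy), 1:(130 - dx)]
  s2 <- segment_eye(pm2, center + c(dx, dy), R, mc_params(seed = 77))
  d <- unclass(s2$shape) - unclass(a$shape)
  expect_equal(unname(d[c("cx", "cy")]), c(dx, dy))
  expect_lt(max(abs(d[-(1:2)])), 1.0)
})

test_that("control points are recovered from a clean binary map", {
  center <- c(60, 50); R <- 12
  truth <- domain_mid_shape(center, R)
  pm <- binary_map_for(truth, c(110, 130))
  tp <- shape_points(truth)
  for (seed in 1:3) {
    seg <- segment_eye(pm, center, R, mc_params(seed = seed))
    d <- sqrt(rowSums((shape_points(seg$shape) - tp)^2))
    expect_lt(max(d), 5)
  }
})
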