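test_that("radius range follows the anthropometric prior", {
  rr <- radius_range(500)
  expect_equal(c(rr$r_min, rr$r_max), c(15, 27))  # R0 = 21, tol 0.3
  rr0 <- radius_range(500, tolerance = 0)
  expect_equal(c(rr0$r_min, rr0$r_max), c(21, 21))
  expect_error(radius_range(40), "radius")
})

test_that("minima scanning keeps isolated minima and merges close ones", {
  S <- matrix(0, 30, 30)
  S[11, 21] <- -5
  got <- scan_minima(S, 4)
  expect_equal(nrow(got), 1)
  expect_equal(c(got$x, got$y), c(20, 10))

  # two minima closer than r_min: the lower one survives an exhaustive merge
  S2 <- matrix(0, 30, 30)
  S2[10, 10] <- -5; S2[10, 12] <- -7
  got2 <- scan_minima(S2, 6)
  expect_equal(nrow(got2), 1)
  expect_equal(c(got2$x, got2$y, got2$s), c(11, 9, -7))

  # two equal minima farther than r_min: both retained
  S3 <- matrix(0, 40, 40)
  S3[10, 5] <- -3; S3[30, 35] <- -3
  got3 <- scan_minima(S3, 5)
  expect_equal(nrow(got3), 2)

  # flat map yields no candidates
  expect_equal(nrow(scan_minima(matrix(1, 20, 20), 3)), 0)
})

test_that("candidate scores combine symmetry, darkness and the eyebrow penalty", {
  # saturated-white image: darkness weight kills every score
  S <- matrix(0, 20, 20)
  S[10, 5] <- -4; S[10, 15] <- -4
  white <- matrix(255, 20, 20)
  cands <- data.frame(x = c(4, 14), y = c(9, 9), s = c(-4, -4))
  sc <- score_candidates(cands, S, white, eyebrow_row = NA)
  expect_true(all(sc$score == 0))
  dark <- matrix(0, 20, 20)
  sc1 <- score_candidates(cands, S, dark, eyebrow_row = NA)
  expect_true(all(sc1$score > 0))

  # identical darkness/symmetry, one above the eyebrow row: strictly lower
  gray2 <- matrix(0, 20, 20); S2 <- matrix(0, 20, 20)
  S2[5, 10] <- -4; S2[15, 10] <- -4
  cands2 <- data.frame(x = c(9, 9), y = c(4, 14), s = c(-4, -4))
  sc2 <- score_candidates(cands2, S2, gray2, eyebrow_row = 10)
  expect_lt(sc2$score[sc2$y == 4], sc2$score[sc2$y == 14])
})

test_that("pair selection applies the inter-pupillary distance prior", {
  face <- face_box(0, 0, 100, 100)
  one <- data.frame(x = c(30, 70), y = c(50, 50), score = c(1, 1))
  p <- select_pair(one, face)
  expect_equal(c(p$left$x, p$right$x), c(30, 70))

  # equal scores: candidate at IPD ratio 0.4 beats the one at 0.8
  three <- data.frame(x = c(10, 50, 90), y = c(50, 50, 50), score = c(1, 1, 1))
  p2 <- select_pair(three, face)
  expect_equal(p2$right$x - p2$left$x, 40)

  lonly <- data.frame(x = c(10, 20), y = c(50, 50), score = c(1, 1))
  expect_error(select_pair(lonly, face), "right half")
})

test_that("pair selection is invariant to mirroring (labels swap)", {
  face <- face_box(0, 0, 120, 80)
  set.seed(23)
  cands <- data.frame(x = c(30, 40, 75, 95), y = c(40, 42, 41, 39),
                      score = runif(4, 0.5, 1))
  p <- select_pair(cands, face)
  mir <- cands; mir$x <- 119 - cands$x
  pm <- select_pair(mir, face)
  expect_equal(pm$left$x, 119 - p$right$x)
  expect_equal(pm$right$x, 119 - p$left$x)
})

test_that("center refinement locks onto the dark pupil", {
  g <- matrix(200, 40, 40)
  g[21, 19] <- 0   # pupil minimum at (18, 20), 2 px off the estimate (20, 20)
  ref <- refine_center(g, c(20, 20), r_min = 12, blur_sigma = 0.5)
  expect_equal(ref, c(18, 20))
  # already-darkest center is a fixed point; uniform window keeps the center
  expect_equal(refine_center(g, c(18, 20), 12, 0.5), c(18, 20))
  expect_equal(refine_center(matrix(100, 30, 30), c(15, 15), 8, 0.5), c(15, 15))
})

test_that("radial projection peaks at a circular step edge", {
  flat <- matrix(90, 50, 50)
  pr <- radial_projection(flat, c(25, 25), 5, 15)
  expect_true(all(pr$proj == 0))
  expect_error(select_radius(pr), "no edge evidence")

  img <- matrix(220, 60, 60)
  X <- matrix(rep(0:59, each = 60), 60); Y <- matrix(rep(0:59, 60), 60)
  img[(X - 30)^2 + (Y - 30)^2 <= 64] <- 60
  pr2 <- radial_projection(img, c(30, 30), 4, 14)
  expect_lte(abs(select_radius(pr2) - 8), 1)

  # k = 100 ignores every gradient
  pr3 <- radial_projection(img, c(30, 30), 4, 14, k = 100)
  expect_true(all(pr3$proj == 0))

  # constant intensity offset leaves the projection unchanged
  pr4 <- radial_projection(pmin(img + 30, 255) - 30, c(30, 30), 4, 14)
  expect_equal(pr4$proj, pr2$proj)
})

test_that("radius selection takes the argmax with ties toward smaller radii", {
  expect_equal(select_radius(list(radii = 10:12, proj = c(1, 5, 2))), 11)
  expect_equal(select_radius(list(radii = 10:12, proj = c(5, 1, 5))), 10)
})

test_that("rendered irises are recovered within 10% relative radius error", {
  set.seed(31)
  for (i in 1:5) {
    R <- runif(1, 10, 16)
    shp <- synthetic_eye_shape(c(60, 48), R)
    re <- render_eye(eye_render_spec(shp, R, max(2, round(0.45 * R)),
                                     noise_sigma = 2, seed = i),
                     width = 130, height = 100)
    pr <- radial_projection(to_gray(re$image), c(60, 48), 7, 21)
    expect_lte(abs(select_radius(pr) - R) / R, 0.10)
  }
})
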