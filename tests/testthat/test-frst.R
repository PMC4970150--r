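test_that("gradient field matches a literal Sobel convolution", {
  expect_true(all(gradient_field(matrix(100, 5, 5))$magnitude == 0))
  # vertical step edge: gx fires on the edge columns, gy stays zero
  step <- cbind(matrix(0, 5, 3), matrix(200, 5, 3))
  g <- gradient_field(step)
  expect_true(any(g$gx[2:4, 3:4] != 0))
  expect_true(all(g$gy == 0))
  set.seed(5)
  img <- matrix(sample(0:255, 25, TRUE), 5, 5)
  o <- sobel_oracle(img)
  gi <- gradient_field(img)
  expect_equal(gi$gx, o$gx)
  expect_equal(gi$gy, o$gy)
  expect_equal(gi$magnitude, sqrt(o$gx^2 + o$gy^2))
})

test_that("affected pixels lie at radius r along the gradient, rounded half away from zero", {
  expect_equal(affected_pixels(c(10, 10), c(1, 0), 3),
               list(p_plus = c(13, 10), p_minus = c(7, 10)))
  expect_equal(affected_pixels(c(0, 0), c(3, 4), 5),
               list(p_plus = c(3, 4), p_minus = c(-3, -4)))
  # r / sqrt(2) = 1.414 rounds to 1 per axis
  expect_equal(affected_pixels(c(5, 5), c(1, 1), 2),
               list(p_plus = c(6, 6), p_minus = c(4, 4)))
  expect_error(affected_pixels(c(0, 0), c(0, 0), 3), "zero gradient")
})

test_that("orientation/magnitude accumulation matches the per-pixel oracle", {
  flat <- gradient_field(matrix(50, 6, 6))
  acc <- frst_accumulate(flat, 2)
  expect_true(all(acc$O == 0) && all(acc$M == 0))

  # single gradient pixel in dark mode: exactly one cell of O equals -1
  img <- matrix(100, 9, 9); img[5, 5] <- 101
  grad <- gradient_field(img)
  keep <- which(grad$magnitude == max(grad$magnitude))[1]
  g1 <- list(gx = grad$gx * 0, gy = grad$gy * 0, magnitude = grad$magnitude * 0)
  g1$gx[keep] <- grad$gx[keep]; g1$gy[keep] <- grad$gy[keep]
  g1$magnitude[keep] <- grad$magnitude[keep]
  acc1 <- frst_accumulate(g1, 2, "dark")
  expect_equal(sort(unique(c(acc1$O))), c(-1, 0))
  expect_equal(sum(acc1$O == -1), 1)

  for (seed in 1:3) {
    set.seed(seed)
    img <- matrix(sample(0:255, 256, TRUE), 16, 16)
    for (mode in c("dark", "bright", "both")) {
      got <- frst_accumulate(gradient_field(img), 3, mode)
      want <- accumulate_oracle(img, 3, mode)
      expect_equal(got$O, want$O)
      expect_equal(got$M, want$M)
    }
  }
})

test_that("single-radius symmetry image follows the documented closed form", {
  zero <- matrix(0, 8, 8)
  expect_true(all(frst_symmetry_single(zero, zero, 3, frst_params(3)) == 0))
  # alpha = 1 with a 1x1 kernel (sigma -> 0): S_r = O~ * |M~| elementwise
  set.seed(7)
  O <- matrix(sample(-5:5, 64, TRUE), 8, 8)
  M <- matrix(rnorm(64), 8, 8)
  p <- frst_params(3, alpha = 1, gaussian_sigma_factor = 0)
  got <- frst_symmetry_single(O, M, 3, p)
  expect_equal(got, (O / max(abs(O))) * abs(M / max(abs(M))))
})

test_that("full transform matches the literal per-pixel oracle", {
  for (seed in 1:2) {
    set.seed(seed)
    img <- matrix(sample(0:255, 32 * 32, TRUE), 32, 32)
    S <- frst(img, frst_params(c(3, 5)))
    expect_lt(max(abs(S - frst_oracle(img, c(3, 5)))), 1e-6)
  }
})

test_that("transform is zero on uniform images and equivariant to translation", {
  expect_true(all(frst(matrix(128, 20, 20), frst_params(3)) == 0))
  set.seed(9)
  img <- matrix(128, 40, 40)
  img[10:20, 12:22] <- matrix(sample(0:255, 121, TRUE), 11, 11)
  S1 <- frst(img, frst_params(3))
  shifted <- matrix(128, 40, 40)
  shifted[15:25, 17:27] <- img[10:20, 12:22]
  S2 <- frst(shifted, frst_params(3))
  # compare interiors away from borders
  expect_equal(S2[20:30, 20:30], S1[15:25, 15:25], tolerance = 1e-10)
})

test_that("dark mode on I equals negated bright mode on the inverted image", {
  set.seed(13)
  img <- matrix(sample(0:255, 28 * 28, TRUE), 28, 28)
  Sd <- frst(img, frst_params(c(3, 4), mode = "dark"))
  Sb <- frst(255 - img, frst_params(c(3, 4), mode = "bright"))
  expect_equal(Sd[5:24, 5:24], -Sb[5:24, 5:24], tolerance = 1e-9)
})

test_that("transform is invariant to a constant intensity offset", {
  set.seed(17)
  img <- matrix(sample(0:200, 24 * 24, TRUE), 24, 24)
  expect_equal(frst(img, frst_params(3)), frst(img + 55, frst_params(3)),
               tolerance = 1e-10)
})

test_that("a dark disk produces the most negative response at its center", {
  img <- matrix(220, 48, 48)
  X <- matrix(rep(0:47, each = 48), 48); Y <- matrix(rep(0:47, 48), 48)
  img[(X - 22)^2 + (Y - 26)^2 <= 64] <- 35
  S <- frst(img, frst_params(6:10))
  k <- which.min(S)
  est <- c((k - 1) %/% 48, (k - 1) %% 48)
  expect_lte(sqrt(sum((est - c(22, 26))^2)), 1)
})
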