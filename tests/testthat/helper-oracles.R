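# Independent, literal oracles used to cross-check the vectorized
# implementations. Everything here is written as plain per-pixel loops and
# stays deliberately naive.

# 3x3 Sobel by explicit convolution loops; borders zero
sobel_oracle <- function(img) {
  h <- nrow(img); w <- ncol(img)
  wx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)    # [dy+2, dx+2]
  wy <- t(wx)
  gx <- matrix(0, h, w); gy <- matrix(0, h, w)
  for (y in 2:(h - 1)) for (x in 2:(w - 1)) {
    sx <- 0; sy <- 0
    for (dy in -1:1) for (dx in -1:1) {
      v <- img[y + dy, x + dx]
      sx <- sx + v * wx[dy + 2, dx + 2]
      sy <- sy + v * wy[dy + 2, dx + 2]
    }
    gx[y, x] <- sx; gy[y, x] <- sy
  }
  list(gx = gx, gy = gy)
}

round_away_oracle <- function(x) sign(x) * floor(abs(x) + 0.5)

# literal per-pixel orientation/magnitude accumulation
accumulate_oracle <- function(img, r, mode = "dark") {
  g <- sobel_oracle(img)
  h <- nrow(img); w <- ncol(img)
  O <- matrix(0, h, w); M <- matrix(0, h, w)
  for (y in 0:(h - 1)) for (x in 0:(w - 1)) {
    gx <- g$gx[y + 1, x + 1]; gy <- g$gy[y + 1, x + 1]
    mag <- sqrt(gx^2 + gy^2)
    if (mag == 0) next
    ox <- round_away_oracle(gx / mag * r); oy <- round_away_oracle(gy / mag * r)
    upd <- function(px, py, s) {
      if (px >= 0 && px < w && py >= 0 && py < h) {
        O[py + 1, px + 1] <<- O[py + 1, px + 1] + s
        M[py + 1, px + 1] <<- M[py + 1, px + 1] + s * mag
      }
    }
    if (mode %in% c("bright", "both")) upd(x + ox, y + oy, 1)
    if (mode %in% c("dark", "both")) upd(x - ox, y - oy, -1)
  }
  list(O = O, M = M)
}

# literal full transform: accumulate, normalize, combine, 2-D Gaussian
frst_oracle <- function(img, radii, alpha = 2, mode = "dark",
                        sigma_factor = 0.25) {
  h <- nrow(img); w <- ncol(img)
  S <- matrix(0, h, w)
  for (r in radii) {
    acc <- accumulate_oracle(img, r, mode)
    om <- max(abs(acc$O)); mm <- max(abs(acc$M))
    On <- if (om > 0) acc$O / om else acc$O
    Mn <- if (mm > 0) acc$M / mm else acc$M
    Fr <- abs(On)^alpha * abs(Mn) * sign(On)
    sigma <- sigma_factor * r
    if (sigma <= 0) { S <- S + Fr; next }
    rad <- max(1L, ceiling(3 * sigma))
    xs <- (-rad):rad
    K <- outer(xs, xs, function(a, b) exp(-(a^2 + b^2) / (2 * sigma^2)))
    K <- K / sum(K)
    Sr <- matrix(0, h, w)
    for (y in 1:h) for (x in 1:w) {
      acc2 <- 0
      for (dy in xs) for (dx in xs) {
        yy <- y + dy; xx <- x + dx
        if (yy >= 1 && yy <= h && xx >= 1 && xx <= w)
          acc2 <- acc2 + K[dy + rad + 1, dx + rad + 1] * Fr[yy, xx]
      }
      Sr[y, x] <- acc2
    }
    S <- S + Sr
  }
  S
}

# the 7 control points of a shape as absolute (x, y) rows
shape_points <- function(s) {
  s <- unclass(s)
  cx <- s["cx"]; cy <- s["cy"]
  rbind(center = c(cx, cy),
        top_mid = c(cx + s["tx"], cy + s["ty"]),
        bottom_mid = c(cx + s["bx"], cy + s["by"]),
        top_left = c(cx + s["tlx"], cy + s["tly"]),
        top_right = c(cx + s["trx"], cy + s["try"]),
        bottom_left = c(cx + s["tlx"], cy + s["tly"] + s["bly"]),
        bottom_right = c(cx + s["trx"], cy + s["try"] + s["bry"]))
}
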