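# Pixel-wise sclera color model.
#
# Chromatic features (HSV hue plus the chromatic channels of the RGB
# opponent color space) feed a linear max-margin classifier; its decision
# values are calibrated to probabilities with Platt scaling, and the whole
# model is compiled into a 2^24-entry lookup table so a sclera probability
# map is a single array-indexing operation per pixel.

#' RGB opponent color transform
#'
#' `(O1, O2, O3) = ((R - G)/sqrt(2), (R + G - 2B)/sqrt(6), (R + G + B)/sqrt(3))`.
#' O1 and O2 carry the chromatic information; O3 is the intensity axis.
#'
#' @param r,g,b numeric vectors of channel values in \[0, 255\].
#' @return matrix with columns `o1`, `o2`, `o3`.
#' @export
opponent_transform <- function(r, g, b) {
  cbind(o1 = (r - g) / sqrt(2),
        o2 = (r + g - 2 * b) / sqrt(6),
        o3 = (r + g + b) / sqrt(3))
}

#' HSV hue of RGB values
#'
#' Standard hexagonal hue in \[0, 1); achromatic pixels (max = min) get hue
#' 0 by convention.
#'
#' @param r,g,b numeric vectors in \[0, 255\].
#' @return hue vector in \[0, 1).
#' @export
rgb_to_hue <- function(r, g, b) {
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  d <- mx - mn
  h <- numeric(length(mx))
  nz <- d > 0
  rr <- r[nz]; gg <- g[nz]; bb <- b[nz]; dd <- d[nz]; mm <- mx[nz]
  hh <- numeric(sum(nz))
  i <- mm == rr
  hh[i] <- ((gg[i] - bb[i]) / dd[i]) %% 6
  i <- mm == gg & mm != rr
  hh[i] <- (bb[i] - rr[i]) / dd[i] + 2
  i <- mm == bb & mm != rr & mm != gg
  hh[i] <- (rr[i] - gg[i]) / dd[i] + 4
  h[nz] <- hh / 6
  h
}

#' Chromatic feature vector of RGB pixels
#'
#' Default features: hue, O1, O2 (color only). O3, which carries intensity,
#' can be appended with `include_o3 = TRUE`.
#'
#' @param rgb numeric matrix with columns R, G, B in \[0, 255\].
#' @param include_o3 append the intensity channel O3 (default `FALSE`).
#' @return feature matrix (columns `hue`, `o1`, `o2`\[, `o3`\]).
#' @export
extract_features <- function(rgb, include_o3 = FALSE) {
  rgb <- matrix(rgb, ncol = 3)
  opp <- opponent_transform(rgb[, 1], rgb[, 2], rgb[, 3])
  f <- cbind(hue = rgb_to_hue(rgb[, 1], rgb[, 2], rgb[, 3]),
             opp[, c("o1", "o2"), drop = FALSE])
  if (include_o3) f <- cbind(f, o3 = opp[, "o3"])
  f
}

# --- Platt scaling ---------------------------------------------------------

# Regularized maximum-likelihood fit of P(y=1|d) = 1/(1 + exp(A d + B))
# with prior-corrected targets (Platt 1999; Newton iterations following
# Lin, Weng & Keerthi 2007).
#' @noRd
platt_fit <- function(decision, label) {
  n1 <- sum(label); n0 <- sum(!label)
  assert(n1 > 0 && n0 > 0, "Platt calibration needs both classes")
  hi <- (n1 + 1) / (n1 + 2); lo <- 1 / (n0 + 2)
  t <- ifelse(label, hi, lo)
  A <- 0; B <- log((n0 + 1) / (n1 + 1))
  obj <- function(A, B) {
    f <- A * decision + B
    sum(ifelse(f >= 0, t * f + log1p(exp(-f)), (t - 1) * f + log1p(exp(f))))
  }
  val <- obj(A, B)
  for (it in 1:100) {
    f <- A * decision + B
    p <- 1 / (1 + exp(f))
    # gradient and Hessian of the negative log-likelihood
    d1 <- t - p
    d2 <- p * (1 - p)
    g1 <- sum(d1 * decision); g2 <- sum(d1)
    h11 <- sum(d2 * decision^2) + 1e-12
    h22 <- sum(d2) + 1e-12
    h12 <- sum(d2 * decision)
    if (abs(g1) < 1e-10 && abs(g2) < 1e-10) break
    det <- h11 * h22 - h12^2
    dA <- -(h22 * g1 - h12 * g2) / det
    dB <- -(-h12 * g1 + h11 * g2) / det
    step <- 1
    repeat {
      newv <- obj(A + step * dA, B + step * dB)
      if (newv < val + 1e-4 * step * (g1 * dA + g2 * dB) || step < 1e-10) break
      step <- step / 2
    }
    A <- A + step * dA; B <- B + step * dB
    if (abs(val - newv) < 1e-12) { val <- newv; break }
    val <- newv
  }
  c(A = A, B = B)
}

#' @noRd
platt_prob <- function(decision, platt) 1 / (1 + exp(platt["A"] * decision + platt["B"]))

#' Train the sclera color classifier
#'
#' Pools the pixels of the positive (sclera) and negative (skin/eyelash)
#' patches, extracts chromatic features, optionally standardizes them, and
#' fits a linear max-margin classifier. Decision values from a k-fold
#' cross-validation split are then used to fit the Platt sigmoid that maps
#' decisions to sclera probabilities.
#'
#' @param pos_rgb matrix of sclera pixels (columns R, G, B in \[0, 255\]).
#' @param neg_rgb matrix of non-sclera pixels.
#' @param include_o3 include the intensity channel O3 (default `FALSE`).
#' @param standardize center/scale features by training mean and sd
#'   (default `TRUE`).
#' @param cost soft-margin cost parameter (default 1).
#' @param folds cross-validation folds for Platt calibration (default 5).
#' @param seed RNG seed for the fold split (default 1).
#' @return object of class `sclera_model`: linear weights `w`, offset `b`
#'   (decision `d = f(x) . w + b`, positive towards sclera), feature
#'   standardization, and Platt coefficients.
#' @export
train_sclera_classifier <- function(pos_rgb, neg_rgb, include_o3 = FALSE,
                                    standardize = TRUE, cost = 1, folds = 5,
                                    seed = 1) {
  assert(NROW(pos_rgb) >= 1 && NROW(neg_rgb) >= 1,
         "both sclera and non-sclera pixels are required")
  X <- rbind(extract_features(pos_rgb, include_o3),
             extract_features(neg_rgb, include_o3))
  y <- factor(c(rep("sclera", NROW(pos_rgb)), rep("other", NROW(neg_rgb))),
              levels = c("sclera", "other"))
  if (standardize) {
    ctr <- colMeans(X)
    scl <- apply(X, 2, stats::sd)
    scl[scl == 0] <- 1
  } else {
    ctr <- rep(0, ncol(X)); scl <- rep(1, ncol(X))
  }
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")

  fit_linear <- function(idx) {
    m <- e1071::svm(Xs[idx, , drop = FALSE], y[idx], kernel = "linear",
                    cost = cost, scale = FALSE)
    w <- drop(t(m$coefs) %*% m$SV)
    b <- -m$rho
    # orient the decision so sclera pixels get positive values
    if (mean(Xs[idx, , drop = FALSE][y[idx] == "sclera", , drop = FALSE] %*% w + b) <
        mean(Xs[idx, , drop = FALSE][y[idx] == "other", , drop = FALSE] %*% w + b)) {
      w <- -w; b <- -b
    }
    list(w = w, b = b)
  }

  # out-of-fold decision values for calibration
  n <- nrow(Xs)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(max(2, folds)), n))
  dec <- numeric(n)
  for (f in unique(fold)) {
    tr <- which(fold != f); te <- which(fold == f)
    if (length(unique(y[tr])) < 2) { tr <- seq_len(n) }
    fm <- fit_linear(tr)
    dec[te] <- Xs[te, , drop = FALSE] %*% fm$w + fm$b
  }
  platt <- platt_fit(dec, y == "sclera")

  full <- fit_linear(seq_len(n))
  structure(list(w = full$w, b = full$b, center = ctr, scale = scl,
                 platt = platt, include_o3 = include_o3),
            class = "sclera_model")
}

#' Decision values of the sclera classifier
#'
#' @param model `sclera_model`.
#' @param rgb matrix of pixels (columns R, G, B).
#' @return numeric vector of signed decision values (positive = sclera).
#' @export
sclera_decision <- function(model, rgb) {
  X <- extract_features(rgb, model$include_o3)
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  drop(Xs %*% model$w) + model$b
}

#' Sclera probability of RGB pixels (direct model evaluation)
#'
#' @param model `sclera_model`.
#' @param rgb matrix of pixels (columns R, G, B).
#' @return probabilities in \[0, 1\].
#' @export
sclera_probability <- function(model, rgb) {
  unname(platt_prob(sclera_decision(model, rgb), model$platt))
}

# --- lookup table ----------------------------------------------------------

#' Compile the sclera model to a 24-bit lookup table
#'
#' Evaluates `Platt(classifier(features(color)))` for every representable
#' 24-bit RGB color and quantizes the probability to 8 bits (nearest), so
#' probability lookup becomes one array index: `idx = R*65536 + G*256 + B`.
#'
#' @param model `sclera_model`.
#' @param chunk colors evaluated per block (memory/speed trade-off).
#' @return object of class `sclera_lut` with a `probs` raw vector of length
#'   `2^24`.
#' @export
build_sclera_lut <- function(model, chunk = 2^20) {
  n <- 2^24
  probs <- raw(n)
  for (start in seq(0, n - 1, by = chunk)) {
    idx <- start:min(start + chunk - 1, n - 1)
    r <- idx %/% 65536L
    g <- (idx %/% 256L) %% 256L
    b <- idx %% 256L
    p <- sclera_probability(model, cbind(r, g, b))
    probs[idx + 1] <- as.raw(round(p * 255))
  }
  structure(list(probs = probs, include_o3 = model$include_o3, version = 1L),
            class = "sclera_lut")
}

#' Probability lookup in a sclera LUT
#'
#' @param lut `sclera_lut`.
#' @param rgb matrix of pixels (columns R, G, B; integer values 0..255).
#' @return probabilities in \[0, 1\] (8-bit quantized).
#' @export
lut_lookup <- function(lut, rgb) {
  rgb <- matrix(as.integer(round(rgb)), ncol = 3)
  idx <- rgb[, 1] * 65536L + rgb[, 2] * 256L + rgb[, 3] + 1L
  as.integer(lut$probs[idx]) / 255
}

#' Sclera probability map of an image region
#'
#' Per-pixel LUT lookup over the ROI of an RGB image.
#'
#' @param img RGB image array.
#' @param lut `sclera_lut`.
#' @param roi optional `face_box`-like rectangle; default whole image.
#' @return probability matrix in \[0, 1\] the size of the ROI.
#' @export
probability_map <- function(img, lut, roi = NULL) {
  if (!is.null(roi)) img <- crop_image(img, roi)
  h <- dim(img)[1]; w <- dim(img)[2]
  p <- lut_lookup(lut, cbind(c(img[, , 1]), c(img[, , 2]), c(img[, , 3])))
  matrix(p, h, w)
}

# LUT file format: 32-byte header (8-byte magic "SCLRLUT\0", uint32 version,
# uint32 flags [bit 0: O3 included], 16 reserved bytes), then 2^24 bytes of
# 8-bit probabilities, little-endian.

#' Write a sclera LUT to disk
#'
#' @param lut `sclera_lut`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sclera_lut <- function(lut, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("SCLRLUT"), as.raw(0)), con)
  writeBin(as.integer(lut$version), con, size = 4, endian = "little")
  writeBin(as.integer(lut$include_o3), con, size = 4, endian = "little")
  writeBin(raw(16), con)
  writeBin(lut$probs, con)
  invisible(path)
}

#' Read a sclera LUT from disk
#'
#' Refuses files with a wrong magic or an unsupported version.
#'
#' @param path LUT file written by [write_sclera_lut()].
#' @return `sclera_lut`.
#' @export
read_sclera_lut <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 8)
  assert(identical(magic, c(charToRaw("SCLRLUT"), as.raw(0))),
         "not a sclera LUT file")
  version <- readBin(con, "integer", 1, size = 4, endian = "little")
  assert(version == 1L, paste("unsupported LUT version:", version))
  flags <- readBin(con, "integer", 1, size = 4, endian = "little")
  readBin(con, "raw", 16)
  probs <- readBin(con, "raw", 2^24)
  assert(length(probs) == 2^24, "truncated LUT file")
  structure(list(probs = probs, include_o3 = bitwAnd(flags, 1L) == 1L,
                 version = version),
            class = "sclera_lut")
}
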