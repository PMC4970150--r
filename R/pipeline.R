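# Full detection pipeline and annotation file I/O.
#
# Stage order: crop face width -> eye search band + eyebrow row -> dark
# FRST -> candidate minima -> geometric pair selection -> pupil-dark
# refinement -> radial-projection radius -> sclera probability map ->
# Monte Carlo eyelid shape -> corners.

#' Pipeline configuration
#'
#' All stage defaults in one validated object; unknown names are rejected
#' by normal argument matching.
#'
#' @param crop_fraction face width kept before eye search (default 0.70).
#' @param band_frac eye search band as fractions of the face height.
#' @param smoothing projection smoothing window (rows).
#' @param alpha FRST radial strictness.
#' @param gaussian_sigma_factor FRST spreading sigma as a fraction of r.
#' @param max_radii cap on the number of FRST radii (evenly spaced over
#'   the anthropometric range).
#' @param radius_tolerance relative half-width of the radius range.
#' @param k percent of lowest gradients ignored in the radial projection.
#' @param theta_deg angular window of the radial projection (degrees).
#' @param blur_sigma Gaussian sigma for darkness weighting / refinement /
#'   radial projection.
#' @param eyebrow_penalty score factor for candidates above the eyebrow row.
#' @param ipd_mean,ipd_sigma inter-pupillary distance prior (ratio of face
#'   width).
#' @param mc `mc_params` for the eyelid stage.
#' @param seed master seed; per-eye Monte Carlo seeds are derived from it.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(crop_fraction = 0.70, band_frac = c(0.20, 0.55),
                            smoothing = 5, alpha = 2,
                            gaussian_sigma_factor = 0.25, max_radii = 7,
                            radius_tolerance = 0.3, k = 20,
                            theta_deg = c(-45, 45), blur_sigma = 2,
                            eyebrow_penalty = 0.5, ipd_mean = 0.4,
                            ipd_sigma = 0.1, mc = mc_params(), seed = 1) {
  structure(list(crop_fraction = crop_fraction, band_frac = band_frac,
                 smoothing = smoothing, alpha = alpha,
                 gaussian_sigma_factor = gaussian_sigma_factor,
                 max_radii = max_radii, radius_tolerance = radius_tolerance,
                 k = k, theta_deg = theta_deg, blur_sigma = blur_sigma,
                 eyebrow_penalty = eyebrow_penalty, ipd_mean = ipd_mean,
                 ipd_sigma = ipd_sigma, mc = mc, seed = seed),
            class = "pipeline_config")
}

#' Run the full eye-feature detection pipeline
#'
#' @param img RGB image array.
#' @param face `face_box` from an external face detector.
#' @param lut optional `sclera_lut`; when `NULL` the eyelid-shape stage is
#'   skipped and shape fields are `NULL` in the output.
#' @param cfg `pipeline_config`.
#' @return list with `left` and `right` eye annotations (pupil center,
#'   iris radius, confidence, corners, eyelid mid-points, shape vector)
#'   and a `log` list of per-stage diagnostics.
#' @export
detect_pipeline <- function(img, face, lut = NULL, cfg = pipeline_config()) {
  assert_rgb(img)
  gray <- to_gray(img)
  log <- list()

  cface <- crop_face_width(face, cfg$crop_fraction)
  region <- eye_search_region(cface, cfg$band_frac, gray, cfg$smoothing)
  rr <- radius_range(face$w, cfg$radius_tolerance)
  log$radius_range <- c(rr$r_min, rr$r_max)
  log$eyebrow_row <- region$eyebrow_row

  band <- crop_image(gray, region$box)
  radii <- unique(round(seq(rr$r_min, rr$r_max,
                            length.out = min(cfg$max_radii,
                                             rr$r_max - rr$r_min + 1))))
  S <- frst(band, frst_params(radii, alpha = cfg$alpha, mode = "dark",
                              gaussian_sigma_factor = cfg$gaussian_sigma_factor))
  cands <- scan_minima(S, rr$r_min)
  log$n_candidates <- nrow(cands)
  if (nrow(cands) == 0)
    stop("stage scan_minima: no iris candidates found", call. = FALSE)
  scored <- score_candidates(cands, S, band,
                             eyebrow_row = region$eyebrow_row - region$box$y,
                             penalty = cfg$eyebrow_penalty,
                             blur_sigma = cfg$blur_sigma)
  scored$x <- scored$x + region$box$x
  scored$y <- scored$y + region$box$y
  pair <- select_pair(scored, face, cfg$ipd_mean, cfg$ipd_sigma)
  log$pair_score <- pair$pair_score

  one_eye <- function(est, eye_idx) {
    center <- refine_center(gray, c(est$x, est$y), rr$r_min, cfg$blur_sigma)
    half <- rr$r_max + 8L
    rx0 <- max(0L, round(center[1]) - half); ry0 <- max(0L, round(center[2]) - half)
    roi <- face_box(rx0, ry0,
                    min(ncol(gray) - rx0, 2L * half + 1L),
                    min(nrow(gray) - ry0, 2L * half + 1L))
    proj <- radial_projection(crop_image(gray, roi), center - c(rx0, ry0),
                              rr$r_min, rr$r_max, k = cfg$k,
                              theta_deg = cfg$theta_deg,
                              blur_sigma = cfg$blur_sigma)
    radius <- tryCatch(select_radius(proj), error = function(e) rr$r_nominal)
    ann <- list(pupil_center = as.numeric(center), iris_radius = as.numeric(radius),
                confidence = est$score, left_corner = NULL, right_corner = NULL,
                top_eyelid_mid = NULL, bottom_eyelid_mid = NULL, shape = NULL)
    if (!is.null(lut)) {
      sh <- face_box(max(0L, round(center[1] - 3.4 * radius)),
                     max(0L, round(center[2] - 2.8 * radius)),
                     round(6.8 * radius), round(5.6 * radius))
      pm <- probability_map(img, lut, sh)
      mcp <- cfg$mc
      mcp$seed <- cfg$seed * 2L + eye_idx
      off <- c(max(0L, floor(sh$x)), max(0L, floor(sh$y)))
      seg <- segment_eye(pm, center - off, radius, mcp)
      s <- unclass(seg$shape)
      s["cx"] <- s["cx"] + off[1]; s["cy"] <- s["cy"] + off[2]
      ann$shape <- as.numeric(s)
      ann$left_corner <- as.numeric(seg$corners$left + off)
      ann$right_corner <- as.numeric(seg$corners$right + off)
      ann$top_eyelid_mid <- as.numeric(c(s["cx"] + s["tx"], s["cy"] + s["ty"]))
      ann$bottom_eyelid_mid <- as.numeric(c(s["cx"] + s["bx"], s["cy"] + s["by"]))
      ann$shape_omega <- seg$omega
    }
    ann
  }
  left <- one_eye(pair$left, 0L)
  right <- one_eye(pair$right, 1L)
  list(left = left, right = right, log = log)
}

# --- annotation files ------------------------------------------------------

ANNOTATION_SCHEMA_VERSION <- 1L

#' Write eye annotations to JSON
#'
#' The annotation dialect stores, per eye, the six-landmark scheme (pupil
#' center, two corners, top/bottom eyelid mid-points, iris radius or a
#' boundary point) plus the optional 12-value shape vector; coordinates
#' are 0-based floats at pixel centers.
#'
#' @param ann list with at least `left` and `right` eye entries; an
#'   `image` reference string is recommended.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  ann$schema_version <- ANNOTATION_SCHEMA_VERSION
  jsonlite::write_json(ann, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read eye annotations from JSON
#'
#' Validates the schema version and the presence of the required fields,
#' naming the first missing one.
#'
#' @param path annotation file written by [write_annotations()].
#' @return annotation list.
#' @export
read_annotations <- function(path) {
  ann <- jsonlite::read_json(path, simplifyVector = TRUE)
  assert(!is.null(ann$schema_version),
         "annotation validation failed: missing field 'schema_version'")
  assert(ann$schema_version == ANNOTATION_SCHEMA_VERSION,
         paste("unsupported annotation schema version:", ann$schema_version))
  for (eye in c("left", "right")) {
    assert(!is.null(ann[[eye]]),
           paste0("annotation validation failed: missing field '", eye, "'"))
    e <- ann[[eye]]
    assert(!is.null(e$pupil_center),
           paste0("annotation validation failed: missing field '", eye,
                  ".pupil_center'"))
    assert(!is.null(e$iris_radius) || !is.null(e$iris_boundary_point),
           paste0("annotation validation failed: missing field '", eye,
                  ".iris_radius' (or an iris boundary point)"))
  }
  ann
}

#' Export annotations to CSV (one row per eye)
#'
#' @param anns list of annotation lists (as returned by
#'   [read_annotations()] or [detect_pipeline()]).
#' @param path optional output CSV path.
#' @return data.frame with 2 rows per annotation.
#' @export
annotations_to_csv <- function(anns, path = NULL) {
  rows <- list()
  for (i in seq_along(anns)) {
    ann <- anns[[i]]
    for (eye in c("left", "right")) {
      e <- ann[[eye]]
      rows[[length(rows) + 1]] <- data.frame(
        image = ann$image %||% NA_character_, eye = eye,
        pupil_x = e$pupil_center[1], pupil_y = e$pupil_center[2],
        iris_radius = e$iris_radius %||% NA_real_,
        left_corner_x = (e$left_corner %||% c(NA, NA))[1],
        left_corner_y = (e$left_corner %||% c(NA, NA))[2],
        right_corner_x = (e$right_corner %||% c(NA, NA))[1],
        right_corner_y = (e$right_corner %||% c(NA, NA))[2])
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
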