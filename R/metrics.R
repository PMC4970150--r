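# Evaluation measures: normalized eye-center errors, normalized iris
# radius errors, and pixel-classification measures for eye-region masks.

#' Normalized eye-center errors (wec / aec / bec)
#'
#' Left/right center errors normalized by the true inter-center distance:
#' `wec` takes the worst (max) of the two eyes, `bec` the best (min) and
#' `aec` the average. `wec <= 0.25` roughly means the estimate is within
#' the eye, `<= 0.10` within the iris and `<= 0.05` within the pupil.
#'
#' @param cl,cr true left/right iris centers `c(x, y)`.
#' @param cl_hat,cr_hat estimated centers.
#' @return named vector `c(wec, aec, bec)`.
#' @export
center_errors <- function(cl, cr, cl_hat, cr_hat) {
  ipd <- sqrt(sum((cl - cr)^2))
  assert(ipd > 0, "true eye centers coincide")
  el <- sqrt(sum((cl - cl_hat)^2))
  er <- sqrt(sum((cr - cr_hat)^2))
  c(wec = max(el, er) / ipd, aec = mean(c(el, er)) / ipd,
    bec = min(el, er) / ipd)
}

#' Normalized iris-radius errors (aer / wer / ber)
#'
#' Absolute radius errors normalized by the average true radius:
#' `aer = (|rl_hat - rl| + |rr_hat - rr|) / (rl + rr)`, `wer`/`ber` use
#' twice the max/min error over the same denominator, so
#' `aer = (wer + ber) / 2` identically.
#'
#' @param rl,rr true left/right iris radii (pixels, sum > 0).
#' @param rl_hat,rr_hat estimated radii.
#' @return named vector `c(aer, wer, ber)`.
#' @export
radius_errors <- function(rl, rr, rl_hat, rr_hat) {
  assert(rl > 0 && rr > 0, "true radii must be positive")
  el <- abs(rl_hat - rl); er <- abs(rr_hat - rr)
  s <- rl + rr
  c(aer = (el + er) / s, wer = 2 * max(el, er) / s, ber = 2 * min(el, er) / s)
}

#' Pixel confusion counts of two masks
#'
#' "Positive" denotes an eye-region pixel in the prediction; "true"
#' denotes agreement with the ground-truth mask.
#'
#' @param pred,truth logical matrices of the same size.
#' @return list with counts `TP`, `TN`, `FP`, `FN`.
#' @export
pixel_confusion <- function(pred, truth) {
  assert(all(dim(pred) == dim(truth)), "mask sizes differ")
  list(TP = sum(pred & truth), TN = sum(!pred & !truth),
       FP = sum(pred & !truth), FN = sum(!pred & truth))
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' Sensitivity (recall) is the proportion of eye pixels correctly
#' identified, specificity the proportion of non-eye pixels correctly
#' rejected.
#'
#' @param counts list with `TP`, `TN`, `FP`, `FN`.
#' @return named vector `c(sensitivity, specificity, accuracy)`; a zero
#'   denominator raises an error rather than silently returning 0.
#' @export
classification_measures <- function(counts) {
  with(counts, {
    assert(TP + FN > 0, "sensitivity undefined: no positive ground-truth pixels")
    assert(TN + FP > 0, "specificity undefined: no negative ground-truth pixels")
    c(sensitivity = TP / (TP + FN), specificity = TN / (TN + FP),
      accuracy = (TP + TN) / (TP + TN + FP + FN))
  })
}

#' Cumulative accuracy-vs-threshold curve
#'
#' Fraction of cases whose normalized error is at or below each threshold
#' (the curve reported for eye-center localization benchmarks).
#'
#' @param errors vector of per-image normalized errors.
#' @param thresholds threshold grid (default `seq(0, 0.25, 0.01)`).
#' @return data.frame with `threshold` and `fraction`.
#' @export
accuracy_curve <- function(errors, thresholds = seq(0, 0.25, by = 0.01)) {
  data.frame(threshold = thresholds,
             fraction = vapply(thresholds,
                               function(t) mean(errors <= t), numeric(1)))
}
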