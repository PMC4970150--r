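# internal helpers shared across modules

# round half away from zero (round() in R rounds half to even)
#' @noRd
round_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' @noRd
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# drop FP dust before integer rounding ops (e.g. 0.42 * 100 / 5 * 2.5)
#' @noRd
fp_tidy <- function(x) round(x, 9)

#' @noRd
assert <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
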