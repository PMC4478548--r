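#' Kosambi map function and its inverse
#'
#' `kosambi()` converts a recombination fraction r into map distance
#' `d = 25 * ln((1 + 2r) / (1 - 2r))` centimorgans; `kosambi_inv()` is
#' the exact functional inverse `r = tanh(d / 50) / 2`. The transform
#' accounts for partial crossover interference at moderate distances.
#'
#' @param r Recombination fraction(s) in `[0, 0.5)`; values at or above
#'   0.5 are an error (the distance diverges). Values within `cap_eps`
#'   of 0.5 are capped at `cap_cm`.
#' @param cap_cm Ceiling on the returned distance (default 1000 cM).
#' @param cap_eps Numerical guard below 0.5 (default 1e-12).
#' @return Map distance(s) in cM.
#' @export
kosambi <- function(r, cap_cm = 1000, cap_eps = 1e-12) {
  if (any(r < 0 | r >= 0.5, na.rm = TRUE))
    stop_fmt("recombination fraction must lie in [0, 0.5)")
  d <- 25 * log((1 + 2 * r) / (1 - 2 * r))
  pmin(d, cap_cm)
}

#' @rdname kosambi
#' @param d Map distance(s) in cM (non-negative).
#' @export
kosambi_inv <- function(d) {
  if (any(d < 0, na.rm = TRUE)) stop_fmt("map distance must be >= 0")
  tanh(d / 50) / 2
}
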