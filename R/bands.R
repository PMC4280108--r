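#' Canonical seven-band frequency scheme
#'
#' The analysis partitions the 1--100 Hz axis into seven contiguous,
#' non-overlapping bands with inclusive integer bounds: delta/theta (1--7 Hz),
#' alpha (8--12 Hz), beta1 (13--25 Hz), beta2 (26--35 Hz), gamma1 (36--45 Hz),
#' gamma2 (46--70 Hz) and gamma3 (71--100 Hz). Slow delta and theta activity is
#' pooled into a single band because it is confounded by the 4 Hz visual token
#' alternation of the bistable stimulus.
#'
#' @return A tibble with columns `band` (ordered factor), `f_lo`, `f_hi` (Hz,
#'   inclusive integers).
#' @export
#' @examples
#' band_scheme()
band_scheme <- function() {
  tibble::tibble(
    band = factor(band_names(), levels = band_names()),
    f_lo = c(1L, 8L, 13L, 26L, 36L, 46L, 71L),
    f_hi = c(7L, 12L, 25L, 35L, 45L, 70L, 100L)
  )
}

band_names <- function() {
  c("delta_theta", "alpha", "beta1", "beta2", "gamma1", "gamma2", "gamma3")
}

#' Map frequencies to bands
#'
#' Total on the integer grid 1--100 Hz: every frequency belongs to exactly one
#' band.
#'
#' @param freq numeric vector of frequencies in Hz (must lie in \[1, 100\]).
#' @param scheme band scheme tibble, see [band_scheme()].
#' @return factor of band names, same length as `freq`.
#' @export
band_of <- function(freq, scheme = band_scheme()) {
  if (any(freq < min(scheme$f_lo) | freq > max(scheme$f_hi))) {
    stop("frequencies must lie within the band scheme range (1-100 Hz)")
  }
  idx <- findInterval(freq, c(scheme$f_lo, max(scheme$f_hi) + 1L))
  factor(as.character(scheme$band[idx]), levels = levels(scheme$band))
}

#' Bonferroni-corrected per-test alpha
#'
#' @param alpha family-wise alpha (default 0.05).
#' @param n number of comparisons.
#' @return per-test alpha threshold `alpha / n`.
#' @export
#' @examples
#' bonferroni_alpha(0.05, 31) # phase-angle tests over 31 electrodes
#' bonferroni_alpha(0.05, 4)  # four frequency bands
bonferroni_alpha <- function(alpha = 0.05, n) {
  stopifnot(alpha > 0, alpha < 1, n >= 1)
  alpha / n
}

#' Combined stimulation electrode area
#'
#' Area of `n` circular Ag/AgCl stimulation electrodes of a given diameter,
#' in cm^2. With the default ten 12 mm discs the combined area is ~11.3 cm^2.
#'
#' @param n number of electrodes.
#' @param diameter_mm disc diameter in millimetres.
#' @return total area in cm^2.
#' @export
electrode_area_cm2 <- function(n = 10, diameter_mm = 12) {
  stopifnot(n >= 1, diameter_mm > 0)
  n * pi * (diameter_mm / 20)^2  # radius in cm = diameter_mm / 20
}
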