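#' Number of Slepian tapers for a time-bandwidth product
#'
#' Standard multitaper rule `K = floor(2 T W) - 1`, clamped to at least one
#' taper. With the +/-10 Hz half-bandwidth used throughout, 3-second epochs
#' give 59 tapers and 1-second resting-state segments give 19.
#'
#' @param T window length in seconds.
#' @param W half-bandwidth (spectral smoothing) in Hz.
#' @return integer taper count.
#' @export
#' @examples
#' taper_count(3, 10) # 59
#' taper_count(1, 10) # 19
taper_count <- function(T, W) {
  stopifnot(T > 0, W > 0)
  max(1L, as.integer(floor(2 * T * W)) - 1L)
}

#' Two-regime spectral and cross-spectral estimation
#'
#' Estimates per-channel power and per-pair cross-spectra on the integer
#' 1--100 Hz grid with the two-regime scheme: 1--35 Hz from sliding 500 ms
#' Hanning windows (50% overlap, zero-padded to 1 s for the 1 Hz grid) and
#' 36--100 Hz from DPSS multitapers with +/-10 Hz half-bandwidth. By default
#' tapers span the whole epoch (`taper_window = NULL`), which yields 59
#' tapers on 3 s epochs and 19 on 1 s segments; setting `taper_window`
#' (seconds) instead tapers sliding windows of that length. Estimates are
#' averaged over windows, tapers and epochs; power is scaled as one-sided
#' spectral density (microvolts^2 per Hz).
#'
#' @param ep an `epochs` object.
#' @param hann_window Hanning window length in seconds (default 0.5).
#' @param half_bandwidth multitaper half-bandwidth W in Hz (default 10).
#' @param taper_window optional multitaper window length in seconds; `NULL`
#'   tapers whole epochs.
#' @param freqs frequency grid (default 1:100 Hz).
#' @param split_hz regime boundary: frequencies below use the Hanning path
#'   (default 36).
#' @return an object of class `spectral_estimate`: list with `freqs`, `power`
#'   (channels x freqs), `cross` (pairs x freqs, complex), `n_segments`,
#'   `pairs`, `layout`, `labels`, and `method` metadata.
#' @export
estimate_spectra <- function(ep, hann_window = 0.5, half_bandwidth = 10,
                             taper_window = NULL, freqs = 1:100,
                             split_hz = 36) {
  stopifnot(inherits(ep, "epochs"))
  ns <- n_epochs(ep)
  if (ns == 0L) stop("no epochs to estimate from")
  len <- dim(ep$data)[3]
  rate <- ep$rate
  if (len < round(hann_window * rate)) {
    stop("epochs shorter than the Hanning window")
  }
  nch <- dim(ep$data)[2]
  pairs <- ep$layout$pairs

  lo_f <- freqs[freqs < split_hz]
  hi_f <- freqs[freqs >= split_hz]

  power <- matrix(0, nch, length(freqs),
                  dimnames = list(ep$layout$channels$name, freqs))
  cross <- matrix(0 + 0i, nrow(pairs), length(freqs))

  # --- low regime: sliding Hanning windows, zero-padded to 1 s -------------
  wlen <- round(hann_window * rate)
  pad_len <- round(rate)  # 1 s zero-pad -> exact 1 Hz bins
  hop <- max(1L, floor(wlen / 2))
  starts <- seq(1L, len - wlen + 1L, by = hop)
  hann <- 0.5 - 0.5 * cos(2 * pi * (seq_len(wlen) - 1) / (wlen - 1))
  hann <- hann / sqrt(sum(hann^2))
  lo_bins <- lo_f + 1L  # bin 1 is DC on the 1 Hz grid
  n_lo <- 0L
  acc_p_lo <- matrix(0, nch, length(lo_f))
  acc_c_lo <- matrix(0 + 0i, nrow(pairs), length(lo_f))
  for (e in seq_len(ns)) {
    seg <- ep$data[e, , , drop = TRUE]
    if (is.null(dim(seg))) seg <- matrix(seg, nrow = nch)
    for (s0 in starts) {
      w <- seg[, s0:(s0 + wlen - 1L), drop = FALSE] * rep(hann, each = nch)
      wp <- cbind(w, matrix(0, nch, pad_len - wlen))
      W <- t(stats::mvfft(t(wp)))[, lo_bins, drop = FALSE]
      acc_p_lo <- acc_p_lo + (Mod(W)^2)
      acc_c_lo <- acc_c_lo + W[pairs$left, , drop = FALSE] *
        Conj(W[pairs$right, , drop = FALSE])
      n_lo <- n_lo + 1L
    }
  }
  scale <- 2 / rate  # one-sided density for unit-energy windows
  power[, freqs < split_hz] <- acc_p_lo / n_lo * scale
  cross[, freqs < split_hz] <- acc_c_lo / n_lo * scale

  # --- high regime: DPSS multitaper -----------------------------------------
  tlen <- if (is.null(taper_window)) len else round(taper_window * rate)
  if (tlen > len) stop("taper window longer than the epoch")
  T_s <- tlen / rate
  K <- taper_count(T_s, half_bandwidth)
  tapers <- dpss_tapers(tlen, T_s * half_bandwidth, K)
  tstarts <- if (tlen == len) 1L else seq(1L, len - tlen + 1L, by = max(1L, floor(tlen / 2)))
  hi_bins <- round(hi_f * T_s) + 1L
  if (max(abs(hi_f - (hi_bins - 1L) / T_s)) > 0.25) {
    warning("multitaper bin grid misaligned with integer frequencies")
  }
  acc_p_hi <- matrix(0, nch, length(hi_f))
  acc_c_hi <- matrix(0 + 0i, nrow(pairs), length(hi_f))
  n_hi <- 0L
  for (e in seq_len(ns)) {
    seg <- ep$data[e, , , drop = TRUE]
    if (is.null(dim(seg))) seg <- matrix(seg, nrow = nch)
    for (s0 in tstarts) {
      block <- seg[, s0:(s0 + tlen - 1L), drop = FALSE]
      for (k in seq_len(K)) {
        w <- block * rep(tapers[, k], each = nch)
        W <- t(stats::mvfft(t(w)))[, hi_bins, drop = FALSE]
        acc_p_hi <- acc_p_hi + (Mod(W)^2)
        acc_c_hi <- acc_c_hi + W[pairs$left, , drop = FALSE] *
          Conj(W[pairs$right, , drop = FALSE])
        n_hi <- n_hi + 1L
      }
    }
  }
  power[, freqs >= split_hz] <- acc_p_hi / n_hi * scale
  cross[, freqs >= split_hz] <- acc_c_hi / n_hi * scale

  structure(
    list(freqs = freqs, power = power, cross = cross,
         n_segments = ns, pairs = pairs, layout = ep$layout,
         labels = unique(ep$labels[c("session", "condition", "percept")]),
         method = list(
           regime = ifelse(freqs < split_hz, "hanning", "multitaper"),
           hann_window_s = hann_window, half_bandwidth_hz = half_bandwidth,
           taper_window_s = T_s, n_tapers = K)),
    class = "spectral_estimate"
  )
}

#' @export
print.spectral_estimate <- function(x, ...) {
  cat("<spectral_estimate> ", nrow(x$power), " channels, ",
      nrow(x$cross), " pairs, ", length(x$freqs), " frequencies (",
      min(x$freqs), "-", max(x$freqs), " Hz), ", x$n_segments,
      " segments; ", x$method$n_tapers, " tapers\n", sep = "")
  invisible(x)
}

#' Pool a frequency-resolved table over bands
#'
#' Arithmetic mean over each band's integer frequencies. When
#' `exclude_gamma1` is set (stimulation-condition analyses), the gamma1 band
#' (36--45 Hz, containing the 40 Hz artifact) is reported as `NA` and never
#' enters pooled gamma summaries.
#'
#' @param x matrix with columns indexed by integer frequency (colnames), e.g.
#'   `sp$power`, or a numeric vector over `freqs`.
#' @param freqs integer frequencies corresponding to columns.
#' @param scheme a band scheme tibble.
#' @param exclude_gamma1 drop the gamma1 band from the output values.
#' @return matrix rows x bands (or named vector), band-ordered.
#' @export
pool_bands <- function(x, freqs = as.integer(colnames(x)),
                       scheme = band_scheme(), exclude_gamma1 = FALSE) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  bands <- as.character(scheme$band)
  out <- matrix(NA_real_, nrow(x), length(bands),
                dimnames = list(rownames(x), bands))
  for (b in seq_along(bands)) {
    sel <- freqs >= scheme$f_lo[b] & freqs <= scheme$f_hi[b]
    if (any(sel)) out[, b] <- rowMeans(x[, sel, drop = FALSE])
  }
  if (exclude_gamma1) out[, "gamma1"] <- NA_real_
  if (vec) out[1, ] else out
}
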