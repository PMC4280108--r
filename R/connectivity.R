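#' Interhemispheric magnitude-squared coherence
#'
#' Per-frequency coherence `C = |S_xy|^2 / (S_xx S_yy)` for every
#' interhemispheric pair, then pooled over bands (arithmetic mean over the
#' band's 1 Hz steps). Cells with zero power at a frequency are flagged
#' undefined and excluded from pooling; undefined cells propagate as `NA`,
#' never as zero.
#'
#' @param sp a `spectral_estimate`.
#' @param scheme band scheme (default [band_scheme()]).
#' @param exclude_gamma1 drop the gamma1 band (stimulation analyses, 40 Hz
#'   artifact removed by the notch filter).
#' @return tibble of class `band_connectivity`: `pair`, `band`, `coherence`,
#'   `n_segments` plus the label columns of the estimate.
#' @export
msc <- function(sp, scheme = band_scheme(), exclude_gamma1 = FALSE) {
  stopifnot(inherits(sp, "spectral_estimate"))
  p <- sp$pairs
  sxx <- sp$power[p$left, , drop = FALSE]
  syy <- sp$power[p$right, , drop = FALSE]
  denom <- sxx * syy
  coh <- Mod(sp$cross)^2 / denom
  coh[denom <= 0] <- NA_real_
  pooled <- pool_bands(coh, sp$freqs, scheme, exclude_gamma1)
  out <- tibble::tibble(
    pair = rep(p$pair, times = ncol(pooled)),
    band = factor(rep(colnames(pooled), each = nrow(pooled)),
                  levels = levels(scheme$band)),
    coherence = as.vector(pooled),
    n_segments = sp$n_segments
  )
  attach_labels(out, sp$labels, "band_connectivity")
}

attach_labels <- function(out, labels, cls) {
  if (!is.null(labels) && nrow(labels) == 1L) {
    out$session <- labels$session
    out$condition <- labels$condition
    out$percept <- labels$percept
  }
  class(out) <- c(cls, class(out))
  out
}

#' Interhemispheric phase-locking value
#'
#' Band-passes each channel (zero-phase FIR), extracts the analytic-signal
#' phase, and computes `PLV = |mean over time and segments of
#' exp(i (phi_x - phi_y))|` for every interhemispheric pair. Amplitude-free
#' by construction: rescaling a channel leaves the PLV unchanged.
#'
#' @param ep an `epochs` object.
#' @param band numeric `c(lo, hi)` in Hz (default gamma2, 46--70 Hz).
#' @param band_name label stored in the output.
#' @param edge_trim seconds discarded at each epoch edge after filtering.
#' @return tibble of class `band_connectivity`: `pair`, `band`, `plv`,
#'   `n_segments` plus labels.
#' @export
plv <- function(ep, band = c(46, 70), band_name = NULL, edge_trim = 0.1) {
  stopifnot(inherits(ep, "epochs"))
  if (band[2] >= ep$rate / 2) stop("band must lie below Nyquist")
  ns <- n_epochs(ep)
  if (ns == 0L) stop("no epochs")
  p <- ep$layout$pairs
  len <- dim(ep$data)[3]
  trim <- round(edge_trim * ep$rate)
  keep <- (trim + 1L):(len - trim)
  if (length(keep) < 8L) stop("epochs too short for the requested edge trim")
  acc <- complex(real = numeric(nrow(p)), imaginary = numeric(nrow(p)))
  n_acc <- 0L
  nch <- dim(ep$data)[2]
  for (e in seq_len(ns)) {
    seg <- ep$data[e, , , drop = TRUE]
    if (is.null(dim(seg))) seg <- matrix(seg, nrow = nch)
    fb <- fir_bandpass_rows(seg, ep$rate, band[1], band[2])
    ph <- t(apply(fb, 1, instantaneous_phase))[, keep, drop = FALSE]
    dphi <- ph[p$left, , drop = FALSE] - ph[p$right, , drop = FALSE]
    acc <- acc + rowSums(exp(1i * dphi))
    n_acc <- n_acc + length(keep)
  }
  if (is.null(band_name)) band_name <- sprintf("%g-%g Hz", band[1], band[2])
  out <- tibble::tibble(
    pair = p$pair, band = band_name,
    plv = Mod(acc / n_acc), n_segments = ns
  )
  attach_labels(out, unique(ep$labels[c("session", "condition", "percept")]),
                "band_connectivity")
}

#' Percept-related relative connectivity change
#'
#' Relative increase of coherence (or PLV) for horizontal over vertical
#' motion perception, `(C_h - C_v) / C_v`, in percent, per pair and band.
#' The vertical percept serves as the baseline; cells with zero baseline are
#' undefined (`NA`).
#'
#' @param conn_h,conn_v `band_connectivity` tibbles with matched pairs and
#'   bands.
#' @param value column to contrast (default `"coherence"`).
#' @return tibble `pair`, `band`, `<value>_h`, `<value>_v`,
#'   `rel_change_pct`.
#' @export
percept_contrast <- function(conn_h, conn_v, value = "coherence") {
  stopifnot(value %in% names(conn_h), value %in% names(conn_v))
  j <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(conn_h), "pair", "band",
                  h = dplyr::all_of(value)),
    dplyr::select(tibble::as_tibble(conn_v), "pair", "band",
                  v = dplyr::all_of(value)),
    by = c("pair", "band")
  )
  if (nrow(j) != nrow(conn_h)) stop("pairs/bands of the two conditions do not match")
  j$rel_change_pct <- ifelse(j$v > 0, (j$h - j$v) / j$v * 100, NA_real_)
  names(j)[names(j) == "h"] <- paste0(value, "_h")
  names(j)[names(j) == "v"] <- paste0(value, "_v")
  j
}
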