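#' Zero-phase FIR band-pass filter
#'
#' Two-pass (forward-backward) finite impulse response band-pass applied to
#' every channel, with reflection padding to suppress edge transients. The
#' net phase shift is zero and the passband gain is within 1 dB of unity.
#' FIR order defaults to three periods of the low corner frequency.
#'
#' @param rec a `recording`.
#' @param lo,hi corner frequencies in Hz, `0 < lo < hi < rate/2`.
#' @return filtered `recording`.
#' @export
bandpass <- function(rec, lo = 1, hi = 100) {
  stopifnot(inherits(rec, "recording"))
  out <- rec
  out$data <- fir_bandpass_rows(rec$data, rec$rate, lo, hi)
  out
}

#' Zero-phase Butterworth notch (band-stop) filter
#'
#' Order-8 Butterworth band-stop applied forward-backward to remove the
#' stimulation artifact (default 35--45 Hz). Applied identically to sham,
#' stimulation and post data so results stay comparable across conditions;
#' the 40 Hz component is attenuated by more than 40 dB while neighbouring
#' frequencies are preserved.
#'
#' @param rec a `recording`.
#' @param lo,hi stop-band edges in Hz.
#' @param order Butterworth order (design order of each band-stop section).
#' @return filtered `recording`.
#' @export
notch <- function(rec, lo = 35, hi = 45, order = 8) {
  stopifnot(inherits(rec, "recording"))
  nyq <- rec$rate / 2
  if (!(lo > 0 && hi > lo && hi < nyq)) {
    stop("invalid notch corners: need 0 < lo < hi < rate/2")
  }
  # realized as a cascade of two half-order sections: a direct-form
  # transfer function of the full order is numerically unstable for a
  # narrow stop band, while the cascade has the same composite order
  half <- max(2L, ceiling(order / 2))
  bt <- signal::butter(half, c(lo, hi) / nyq, type = "stop")
  out <- rec
  # narrow stop bands ring for ~1/bandwidth seconds; pad generously
  pad <- min(ncol(rec$data) - 1L, ceiling(2 * rec$rate / (hi - lo) * 10))
  out$data <- filtfilt_pad(bt, x = filtfilt_pad(bt, x = rec$data, pad = pad),
                           pad = pad)
  out
}

#' Anti-aliased downsampling
#'
#' Low-pass filters (zero-phase FIR at 80% of the target Nyquist) and then
#' decimates by the integer ratio `rate / target`.
#'
#' @param rec a `recording`.
#' @param target target rate in Hz; must divide the current rate.
#' @return downsampled `recording`.
#' @export
downsample <- function(rec, target = 1000) {
  stopifnot(inherits(rec, "recording"))
  q <- rec$rate / target
  if (abs(q - round(q)) > 1e-9) stop("target must divide the sampling rate")
  q <- round(q)
  if (q == 1L) return(rec)
  cut <- 0.8 * target / 2
  ord <- 2L * ceiling(3 * rec$rate / cut / 2)
  b <- signal::fir1(ord, cut / (rec$rate / 2), type = "low")
  filtered <- filtfilt_pad(b, 1, rec$data)
  out <- rec
  out$data <- filtered[, seq(1, ncol(filtered), by = q), drop = FALSE]
  out$rate <- target
  out
}

#' Epochs container
#'
#' Fixed-length epochs: an array `epochs x channels x samples` with rate and
#' per-epoch labels (session, condition, percept) plus the source window
#' start time.
#'
#' @param data 3D numeric array, epochs x channels x samples.
#' @param rate sampling rate, Hz.
#' @param labels tibble with one row per epoch: columns `session`,
#'   `condition`, `percept`, `start`.
#' @param layout the channel layout.
#' @return an object of class `epochs`.
#' @export
new_epochs <- function(data, rate, labels, layout) {
  stopifnot(length(dim(data)) == 3L, nrow(labels) == dim(data)[1])
  ok_percept <- labels$percept %in% c("horizontal", "vertical", NA)
  if (!all(ok_percept)) stop("percept labels must be horizontal/vertical/NA")
  structure(list(data = data, rate = rate, labels = labels, layout = layout),
            class = "epochs")
}

#' @export
print.epochs <- function(x, ...) {
  d <- dim(x$data)
  cat("<epochs> ", d[1], " epochs x ", d[2], " channels x ", d[3],
      " samples @ ", x$rate, " Hz\n", sep = "")
  invisible(x)
}

n_epochs <- function(ep) dim(ep$data)[1]

#' Epoch a recording around perceptual switches
#'
#' Cuts one 3,000 ms epoch per qualifying perceptual switch, starting 500 ms
#' after the report (window \[t + 0.5 s, t + 3.5 s)), labeled with the newly
#' reported percept. Epochs that would cross the next switch or a trial
#' boundary are dropped, guaranteeing percept purity.
#'
#' @param rec a `recording`.
#' @param ev an `event_stream` with presses and trial markers.
#' @param t_offset,t_length epoch start offset after the switch and epoch
#'   length, seconds.
#' @return an `epochs` object (possibly with zero epochs).
#' @export
epoch_percepts <- function(rec, ev, t_offset = 0.5, t_length = 3.0) {
  stopifnot(inherits(rec, "recording"))
  press <- ev[ev$label %in% c("press_horizontal", "press_vertical"), ]
  trials <- trials_of(ev)
  keep <- list(); labs <- list()
  n <- ncol(rec$data)
  if (nrow(press)) {
    # collapse redundant consecutive same-label presses
    run <- c(TRUE, press$label[-1] != press$label[-nrow(press)])
    press <- press[run, ]
  }
  for (k in seq_len(nrow(press))) {
    t0 <- press$time[k] + t_offset
    t1 <- t0 + t_length
    nxt <- press$time[press$time > press$time[k]]
    if (length(nxt) && t1 > min(nxt)) next
    tr <- trials[trials$start <= press$time[k] & press$time[k] < trials$end, ]
    if (nrow(tr) == 0L || t1 > tr$end[1]) next
    i0 <- floor(t0 * rec$rate) + 1L
    i1 <- i0 + round(t_length * rec$rate) - 1L
    if (i0 < 1L || i1 > n) next
    keep[[length(keep) + 1L]] <- rec$data[, i0:i1, drop = FALSE]
    labs[[length(labs) + 1L]] <- tibble::tibble(
      session = rec$session, condition = rec$condition,
      percept = sub("press_", "", press$label[k]), start = t0)
  }
  stack_epochs(keep, labs, rec, round(t_length * rec$rate))
}

stack_epochs <- function(keep, labs, rec, len) {
  if (!length(keep)) {
    return(new_epochs(array(0, dim = c(0, nrow(rec$data), len)), rec$rate,
                      tibble::tibble(session = character(),
                                     condition = character(),
                                     percept = character(), start = numeric()),
                      rec$layout))
  }
  arr <- array(0, dim = c(length(keep), nrow(rec$data), len))
  for (i in seq_along(keep)) arr[i, , ] <- keep[[i]]
  new_epochs(arr, rec$rate, dplyr::bind_rows(labs), rec$layout)
}

#' Segment resting-state data into 1-second pieces
#'
#' @param rec a `recording` with `condition = "resting"`.
#' @param seg_length segment length in seconds (default 1).
#' @return an `epochs` object with `floor(duration / seg_length)` segments.
#' @export
segment_resting <- function(rec, seg_length = 1) {
  stopifnot(inherits(rec, "recording"))
  if (!is.na(rec$condition) && rec$condition != "resting") {
    stop("segment_resting expects a resting-state recording")
  }
  len <- round(seg_length * rec$rate)
  n_seg <- floor(ncol(rec$data) / len)
  keep <- lapply(seq_len(n_seg), function(k) {
    rec$data[, ((k - 1) * len + 1):(k * len), drop = FALSE]
  })
  labs <- lapply(seq_len(n_seg), function(k) {
    tibble::tibble(session = rec$session, condition = rec$condition,
                   percept = NA_character_, start = (k - 1) * seg_length)
  })
  stack_epochs(keep, labs, rec, len)
}

#' Automated artifact rejection by peak-to-peak amplitude
#'
#' Drops epochs whose peak-to-peak amplitude on any channel exceeds
#' `threshold` microvolts (an automated stand-in for visual inspection).
#'
#' @param ep an `epochs` object.
#' @param threshold peak-to-peak threshold in microvolts (> 0).
#' @return an `epochs` object; attribute `n_dropped` reports drop counts.
#' @export
reject_artifacts <- function(ep, threshold = 150) {
  stopifnot(inherits(ep, "epochs"), threshold > 0)
  ptp <- apply(ep$data, 1, function(m) {
    max(apply(m, 1, function(x) diff(range(x))))
  })
  keep <- ptp <= threshold
  if (!any(keep)) warning("all epochs exceeded the artifact threshold")
  out <- new_epochs(ep$data[keep, , , drop = FALSE], ep$rate,
                    ep$labels[keep, ], ep$layout)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Balance segment counts across condition cells
#'
#' Randomly subsamples epochs without replacement so that every
#' (session, condition, percept) cell has the minimum cell count;
#' deterministic given the seed.
#'
#' @param ep an `epochs` object.
#' @param seed integer seed.
#' @param by label columns defining the cells.
#' @return a balanced `epochs` object.
#' @export
balance_segments <- function(ep, seed, by = c("session", "condition", "percept")) {
  stopifnot(inherits(ep, "epochs"))
  if (n_epochs(ep) == 0L) stop("cannot balance zero epochs")
  cell <- do.call(paste, c(ep$labels[by], sep = "|"))
  counts <- table(cell)
  if (any(counts == 0)) stop("empty cell: ", names(counts)[counts == 0][1])
  m <- min(counts)
  set.seed(seed)
  keep <- unlist(lapply(split(seq_along(cell), cell), function(idx) {
    if (length(idx) > m) sample(idx, m) else idx
  }), use.names = FALSE)
  keep <- sort(keep)
  new_epochs(ep$data[keep, , , drop = FALSE], ep$rate, ep$labels[keep, ],
             ep$layout)
}

#' Subset epochs by a label predicate
#'
#' @param ep an `epochs` object.
#' @param which logical or integer index over epochs.
#' @return subsetted `epochs`.
#' @export
subset_epochs <- function(ep, which) {
  new_epochs(ep$data[which, , , drop = FALSE], ep$rate, ep$labels[which, ],
             ep$layout)
}
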