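# Engbert-style 5-sample moving-difference velocity (deg/s) per axis;
# first/last two samples get zero velocity.
gaze_velocity <- function(x, rate) {
  n <- length(x)
  if (n < 5L) stop("trace shorter than the velocity kernel")
  v <- numeric(n)
  i <- 3:(n - 2)
  v[i] <- rate * (x[i + 2] + x[i + 1] - x[i - 1] - x[i - 2]) / 6
  v
}

robust_sd <- function(v) {
  s2 <- stats::median(v^2) - stats::median(v)^2
  sqrt(max(s2, .Machine$double.eps))
}

#' Prefilter a gaze trace
#'
#' First pass of the two-step procedure: masks blink samples, samples inside
#' out-of-range saccadic excursions (amplitude below `tiny` or above
#' `huge` degrees, found with the velocity-threshold detector), and samples
#' within `press_margin` seconds of a button press. The trace is then cut
#' into epochs of `epoch_length` seconds, and epochs retaining less than 80%
#' unmasked samples are dropped entirely (their samples are masked, never
#' deleted).
#'
#' @param trace tibble with `time`, `x`, `y` (degrees) and optional `blink`.
#' @param rate sampling rate, Hz.
#' @param ev optional `event_stream` with presses.
#' @param tiny,huge excursion bounds in degrees.
#' @param press_margin seconds masked around each press.
#' @param epoch_length epoch length in seconds for the retention rule.
#' @param min_retained minimal fraction of unmasked samples per epoch.
#' @return the trace tibble with logical columns `masked` and `epoch`
#'   (integer id, `NA` for dropped epochs).
#' @export
prefilter_gaze <- function(trace, rate, ev = NULL, tiny = 0.05, huge = 1.6,
                           press_margin = 1, epoch_length = 1,
                           min_retained = 0.8) {
  n <- nrow(trace)
  masked <- if ("blink" %in% names(trace)) trace$blink else rep(FALSE, n)
  # crude saccade pass to find out-of-range excursions
  det <- detect_velocity_runs(trace$x, trace$y, rate, lambda = 8,
                              masked = masked, merge_gap_ms = 20)
  for (k in seq_len(nrow(det))) {
    if (det$amplitude[k] < tiny || det$amplitude[k] > huge) {
      masked[det$i0[k]:det$i1[k]] <- TRUE
    }
  }
  if (!is.null(ev)) {
    press <- ev$time[ev$label %in% c("press_horizontal", "press_vertical")]
    for (tp in press) {
      masked[trace$time >= tp - press_margin & trace$time <= tp + press_margin] <- TRUE
    }
  }
  epoch <- floor(trace$time / epoch_length) + 1L
  keep_ep <- tapply(!masked, epoch, mean) >= min_retained
  dropped <- as.integer(names(keep_ep))[!keep_ep]
  epoch[epoch %in% dropped] <- NA_integer_
  masked[is.na(epoch)] <- TRUE
  out <- trace
  out$masked <- masked
  out$epoch <- epoch
  out
}

# core run detector shared by prefilter and the classifier
detect_velocity_runs <- function(x, y, rate, lambda, masked, merge_gap_ms) {
  vx <- gaze_velocity(x, rate)
  vy <- gaze_velocity(y, rate)
  okv <- !masked
  ex <- lambda * robust_sd(vx[okv])
  ey <- lambda * robust_sd(vy[okv])
  supra <- ((vx / ex)^2 + (vy / ey)^2) > 1 & !masked
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  i0 <- starts[r$values]; i1 <- ends[r$values]
  if (length(i0) > 1L) {
    gap <- (i0[-1] - i1[-length(i1)]) / rate * 1000
    merge <- gap < merge_gap_ms
    keep0 <- c(TRUE, !merge); keep1 <- c(!merge, TRUE)
    i0 <- i0[keep0]; i1 <- i1[keep1]
  }
  if (!length(i0)) {
    return(tibble::tibble(i0 = integer(), i1 = integer(),
                          amplitude = numeric(), peak_velocity = numeric(),
                          direction = numeric()))
  }
  amp <- pv <- dir <- numeric(length(i0))
  for (k in seq_along(i0)) {
    sel <- i0[k]:i1[k]
    ax <- max(x[sel]) - min(x[sel]); ay <- max(y[sel]) - min(y[sel])
    amp[k] <- sqrt(ax^2 + ay^2)
    pv[k] <- max(sqrt(vx[sel]^2 + vy[sel]^2))
    dir[k] <- atan2(y[i1[k]] - y[i0[k]], x[i1[k]] - x[i0[k]])
  }
  tibble::tibble(i0 = i0, i1 = i1, amplitude = amp, peak_velocity = pv,
                 direction = dir)
}

#' Velocity-threshold microsaccade detection
#'
#' Second pass of the two-step procedure, run on a prefiltered trace:
#' 2D velocity from the 5-sample moving-difference kernel; per-axis
#' dispersion from the median-based robust estimator (`robust = FALSE`
#' switches to mean/SD); elliptical threshold at `lambda` (default 8)
#' standard deviations; supra-threshold runs closer than 20 ms are merged;
#' events must last at least 10 ms and have an amplitude between 0.05 and
#' 1 degree.
#'
#' @param trace prefiltered tibble (see [prefilter_gaze()]); columns `time`,
#'   `x`, `y`, optionally `masked`.
#' @param rate sampling rate, Hz.
#' @param lambda velocity threshold multiplier.
#' @param min_dur_ms minimal duration, ms.
#' @param amp_range accepted amplitude range, degrees.
#' @param robust use the median-based dispersion estimator.
#' @param merge_gap_ms merge supra-threshold runs closer than this.
#' @return tibble of class `microsaccade_table`: `onset`, `offset`,
#'   `duration_ms`, `amplitude`, `peak_velocity`, `direction`.
#' @export
detect_microsaccades <- function(trace, rate, lambda = 8, min_dur_ms = 10,
                                 amp_range = c(0.05, 1), robust = TRUE,
                                 merge_gap_ms = 20) {
  masked <- if ("masked" %in% names(trace)) trace$masked else
    rep(FALSE, nrow(trace))
  if (!robust) {
    vx <- gaze_velocity(trace$x, rate); vy <- gaze_velocity(trace$y, rate)
    ex <- lambda * stats::sd(vx[!masked]); ey <- lambda * stats::sd(vy[!masked])
    supra <- ((vx / ex)^2 + (vy / ey)^2) > 1 & !masked
    runs <- detect_velocity_runs(trace$x, trace$y, rate, lambda, masked,
                                 merge_gap_ms)  # geometry from robust path
    # rebuild runs with the mean/SD threshold
    r <- rle(supra); ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    runs <- runs[0, ]
    for (k in which(r$values)) {
      sel <- starts[k]:ends[k]
      ax <- max(trace$x[sel]) - min(trace$x[sel])
      ay <- max(trace$y[sel]) - min(trace$y[sel])
      runs <- dplyr::bind_rows(runs, tibble::tibble(
        i0 = starts[k], i1 = ends[k], amplitude = sqrt(ax^2 + ay^2),
        peak_velocity = max(sqrt(vx[sel]^2 + vy[sel]^2)),
        direction = atan2(trace$y[ends[k]] - trace$y[starts[k]],
                          trace$x[ends[k]] - trace$x[starts[k]])))
    }
  } else {
    runs <- detect_velocity_runs(trace$x, trace$y, rate, lambda, masked,
                                 merge_gap_ms)
  }
  dur <- (runs$i1 - runs$i0 + 1L) / rate * 1000
  keep <- dur >= min_dur_ms & runs$amplitude >= amp_range[1] &
    runs$amplitude <= amp_range[2]
  out <- tibble::tibble(
    onset = trace$time[runs$i0[keep]],
    offset = trace$time[runs$i1[keep]],
    duration_ms = dur[keep],
    amplitude = runs$amplitude[keep],
    peak_velocity = runs$peak_velocity[keep],
    direction = runs$direction[keep]
  )
  class(out) <- c("microsaccade_table", class(out))
  out
}

#' Fixation statistics
#'
#' Mean gaze position and dispersion over unmasked samples, in degrees.
#'
#' @param trace gaze tibble with `x`, `y` and optional `masked`.
#' @return tibble: `mean_x`, `mean_y`, `sd_x`, `sd_y`, `n_samples`.
#' @export
fixation_stats <- function(trace) {
  masked <- if ("masked" %in% names(trace)) trace$masked else
    rep(FALSE, nrow(trace))
  ok <- !masked
  if (!any(ok)) {
    return(tibble::tibble(mean_x = NA_real_, mean_y = NA_real_,
                          sd_x = NA_real_, sd_y = NA_real_, n_samples = 0L))
  }
  tibble::tibble(mean_x = mean(trace$x[ok]), mean_y = mean(trace$y[ok]),
                 sd_x = stats::sd(trace$x[ok]), sd_y = stats::sd(trace$y[ok]),
                 n_samples = sum(ok))
}

#' Convert pixel gaze coordinates to degrees of visual angle
#'
#' Uses the viewing geometry (screen size, resolution, viewing distance
#' 60 cm by default); the fixation point maps to (0, 0).
#'
#' @param x_px,y_px pixel coordinates.
#' @param center_px fixation point in pixels.
#' @param screen_cm physical screen size c(width, height) in cm.
#' @param resolution screen resolution c(width, height) in pixels.
#' @param distance_cm viewing distance in cm.
#' @return tibble with `x`, `y` in degrees.
#' @export
px_to_deg <- function(x_px, y_px, center_px = c(960, 540),
                      screen_cm = c(53.1, 29.9),
                      resolution = c(1920, 1080), distance_cm = 60) {
  cmx <- (x_px - center_px[1]) * screen_cm[1] / resolution[1]
  cmy <- (y_px - center_px[2]) * screen_cm[2] / resolution[2]
  tibble::tibble(x = atan2(cmx, distance_cm) * 180 / pi,
                 y = atan2(cmy, distance_cm) * 180 / pi)
}
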