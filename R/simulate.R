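#' Simulation configuration
#'
#' Parameters of the synthetic EEG/behavior/gaze generator. The generator
#' emulates the statistical structure the analysis assumes: hemisphere-specific
#' narrowband gamma oscillators sharing a common phase process with mixing
#' weight `kappa` (percept-dependent), an interhemispheric phase lag, 1/f
#' background noise, an alpha rhythm whose amplitude is coupled (sign and
#' magnitude `rho`) to the gamma envelope, an optional 40 Hz stimulation
#' artifact with a trigger every 30 cycles, percept streams with
#' gamma-distributed dominance durations in 1-minute trials, and 500 Hz gaze
#' traces with injected microsaccades.
#'
#' @param duration total duration in seconds (default 60, one trial).
#' @param rate EEG sampling rate in Hz (default 5000).
#' @param gamma_freq gamma carrier frequency, Hz (default 40).
#' @param gamma_bw gamma oscillator bandwidth, Hz (default 10): the
#'   "oscillator" is narrowband-filtered noise, so coherence stays below 1
#'   and phase-locking is informative.
#' @param gamma_amp gamma source amplitude, microvolts RMS.
#' @param kappa_h,kappa_v interhemispheric coupling weight in \[0, 1\] while
#'   the horizontal / vertical percept is reported.
#' @param phase_lag interhemispheric phase lag in radians.
#' @param alpha_freq,alpha_amp alpha rhythm frequency (Hz) and amplitude
#'   (microvolts RMS).
#' @param rho correlation in \[-1, 1\] between the alpha amplitude and the
#'   gamma envelope (negative = antagonistic).
#' @param mod_depth depth of the slow amplitude modulation shared between
#'   alpha and gamma (fraction of mean amplitude).
#' @param noise_exponent,noise_scale 1/f background: spectral exponent and
#'   RMS amplitude in microvolts.
#' @param artifact_amp,artifact_freq stimulation artifact amplitude
#'   (microvolts) and frequency (Hz).
#' @param mu_h,mu_v mean dominance duration (s) of the horizontal / vertical
#'   percept; durations are gamma-distributed with shape `dom_shape`.
#' @param dom_shape shape of the dominance-duration gamma distribution.
#' @param trial_length trial length in seconds (1-minute trials by default).
#' @param ms_rate microsaccade rate per second.
#' @param ms_amp_range microsaccade amplitude range, degrees.
#' @param gaze_rate gaze sampling rate, Hz.
#' @param seed mandatory integer seed; all generator output is a
#'   deterministic function of the configuration (base R Mersenne-Twister).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(duration = 60, rate = 5000,
                       gamma_freq = 40, gamma_bw = 10, gamma_amp = 15,
                       kappa_h = 0.6, kappa_v = 0.45, phase_lag = 0,
                       alpha_freq = 10, alpha_amp = 20, rho = -0.5,
                       mod_depth = 0.4,
                       noise_exponent = 1.0, noise_scale = 10,
                       artifact_amp = 200, artifact_freq = 40,
                       mu_h = 10, mu_v = 10, dom_shape = 2,
                       trial_length = 60,
                       ms_rate = 1.5, ms_amp_range = c(0.1, 0.5),
                       gaze_rate = 500,
                       seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(duration > 0, rate > 0, gaze_rate > 0, trial_length > 0)
  if (kappa_h < 0 || kappa_h > 1 || kappa_v < 0 || kappa_v > 1) {
    stop("kappa must lie in [0, 1]")
  }
  if (abs(rho) > 1) stop("|rho| must be <= 1")
  if (mu_h <= 0 || mu_v <= 0) stop("dominance means must be positive")
  structure(as.list(environment()), class = "sim_config")
}

# deterministic sub-seed so that independent generator stages do not share
# random streams; kept below 2^31
sub_seed <- function(seed, k) (as.numeric(seed) * 7 + k * 10007) %% 2147483647

# 1/f^a noise via spectral shaping of white noise, unit RMS
one_over_f <- function(n, rate, exponent) {
  z <- stats::rnorm(n)
  f <- seq(0, rate / 2, by = rate / n)
  shape <- c(0, (f[-1])^(-exponent / 2))
  Z <- stats::fft(z)
  idx <- seq_len(length(shape))
  w <- numeric(n)
  w[idx] <- shape
  if (n %% 2 == 0) w[n:(n / 2 + 2)] <- shape[2:(n / 2)] else
    w[n:((n + 3) / 2)] <- shape[2:((n + 1) / 2)]
  x <- Re(stats::fft(Z * w, inverse = TRUE) / n)
  x / stats::sd(x)
}

# narrowband noise as a complex analytic process centred on f0
narrowband_analytic <- function(n, rate, f0, bw) {
  x <- stats::rnorm(n)
  xb <- fir_bandpass_rows(x, rate, max(f0 - bw / 2, 1), min(f0 + bw / 2, rate / 2 - 1))
  z <- hilbert_analytic(xb)
  z / stats::sd(Re(z))
}

# slow modulator band-limited to lo-hi Hz, standardized and clipped
slow_modulator <- function(n, rate, lo = 1, hi = 2.5) {
  x <- stats::rnorm(n)
  xb <- fir_bandpass_rows(x, rate, lo, hi)
  m <- (xb - mean(xb)) / stats::sd(xb)
  pmin(pmax(m, -2.2), 2.2)
}

#' Generate a percept-report stream
#'
#' Alternating `press_horizontal` / `press_vertical` events with
#' gamma-distributed dominance durations (means `mu_h`, `mu_v`, shape
#' `dom_shape`), organised in trials of `trial_length` seconds with
#' `trial_start` / `trial_end` markers. The first percept of each trial is
#' random. Deterministic given the seed.
#'
#' @param cfg a [sim_config()].
#' @return an `event_stream`.
#' @export
generate_percept_stream <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(sub_seed(cfg$seed, 1))
  n_trials <- max(1L, floor(cfg$duration / cfg$trial_length))
  time <- numeric(); label <- character()
  mu <- c(horizontal = cfg$mu_h, vertical = cfg$mu_v)
  for (tr in seq_len(n_trials)) {
    t0 <- (tr - 1) * cfg$trial_length
    t1 <- t0 + cfg$trial_length
    time <- c(time, t0, t1); label <- c(label, "trial_start", "trial_end")
    percept <- sample(c("horizontal", "vertical"), 1L)
    t <- t0
    while (t < t1) {
      time <- c(time, t)
      label <- c(label, paste0("press_", percept))
      t <- t + stats::rgamma(1, shape = cfg$dom_shape,
                             scale = mu[[percept]] / cfg$dom_shape)
      percept <- if (percept == "horizontal") "vertical" else "horizontal"
    }
  }
  event_stream(time, label)
}

# percept label per sample ("horizontal"/"vertical"/NA) from press events,
# half-open intervals, reset at trial boundaries
percept_per_sample <- function(ev, n, rate) {
  t <- (seq_len(n) - 1L) / rate
  lab <- rep(NA_character_, n)
  press <- ev[ev$label %in% c("press_horizontal", "press_vertical"), ]
  trials <- trials_of(ev)
  for (tr in seq_len(nrow(trials))) {
    p <- press[press$time >= trials$start[tr] & press$time < trials$end[tr], ]
    if (nrow(p) == 0L) next
    bounds <- c(p$time, trials$end[tr])
    for (k in seq_len(nrow(p))) {
      sel <- t >= bounds[k] & t < bounds[k + 1L]
      lab[sel] <- sub("press_", "", p$label[k])
    }
  }
  lab
}

#' Generate a synthetic EEG recording
#'
#' Builds a 31-channel recording at `cfg$rate`: each hemisphere carries a
#' narrowband gamma oscillator mixing a common phase process (weight `kappa`
#' taken from the percept currently reported in `events`; right hemisphere
#' common component delayed by `phase_lag`) with an independent one, spatially
#' projected with posterior Gaussian gain profiles; an alpha rhythm whose
#' amplitude and the gamma envelope share a slow modulator at correlation
#' `rho`; and 1/f background noise. With matched unit spectra the long-run
#' interhemispheric magnitude-squared coherence of the construction is
#' `kappa^4`. Deterministic given the seed.
#'
#' @param cfg a [sim_config()].
#' @param events an `event_stream` with percept intervals covering the
#'   duration (see [generate_percept_stream()]); if `NULL`, the whole
#'   recording uses `kappa_h`.
#' @param layout channel layout (default [default_layout()]).
#' @param condition,session,rs_index metadata stored on the recording.
#' @return a `recording`.
#' @export
generate_recording <- function(cfg, events = NULL, layout = default_layout(),
                               condition = "sham", session = "in_phase",
                               rs_index = NA_integer_) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$duration <= 0) stop("duration must be positive")
  set.seed(sub_seed(cfg$seed, 2))
  n <- round(cfg$duration * cfg$rate)
  rate <- cfg$rate

  # per-sample coupling weight from the percept stream
  kap <- rep(cfg$kappa_h, n)
  if (!is.null(events)) {
    lab <- percept_per_sample(events, n, rate)
    kap[!is.na(lab) & lab == "vertical"] <- cfg$kappa_v
  }

  # gamma sources: common + independent analytic narrowband processes
  zc <- narrowband_analytic(n, rate, cfg$gamma_freq, cfg$gamma_bw)
  zl <- narrowband_analytic(n, rate, cfg$gamma_freq, cfg$gamma_bw)
  zr <- narrowband_analytic(n, rate, cfg$gamma_freq, cfg$gamma_bw)
  mix <- sqrt(pmax(0, 1 - kap^2))
  s_left <- Re(kap * zc + mix * zl)
  s_right <- Re(kap * zc * exp(-1i * cfg$phase_lag) + mix * zr)

  # shared slow (1-4 Hz) modulation linking alpha amplitude and gamma
  # envelope at correlation rho
  m_a <- slow_modulator(n, rate)
  m_i <- slow_modulator(n, rate)
  m_g <- cfg$rho * m_a + sqrt(1 - cfg$rho^2) * m_i
  gain_a <- pmax(0.05, 1 + cfg$mod_depth * m_a)
  gain_g <- pmax(0.05, 1 + cfg$mod_depth * m_g)
  s_left <- s_left * gain_g
  s_right <- s_right * gain_g

  # dedicated gamma2-range oscillator (quasi-sinusoidal carrier, so its
  # envelope carries no intrinsic noise) whose alpha-frequency envelope
  # ripple has depth proportional to gain_g: the envelope-of-envelope chain
  # reads exactly this ripple. Carrier at gamma_freq + 18 keeps both AM
  # sidebands inside the gamma2 band.
  tt <- (seq_len(n) - 1) / rate
  carrier2 <- cos(2 * pi * (cfg$gamma_freq + 18) * tt + stats::runif(1, 0, 2 * pi))
  ripple <- pmax(0.05, 1 + 0.5 * gain_g *
                   cos(2 * pi * cfg$alpha_freq * tt + stats::runif(1, 0, 2 * pi)))
  s_gamma2 <- carrier2 * ripple

  # quasi-sinusoidal alpha rhythm with amplitude gain_a
  alpha_sig <- cos(2 * pi * cfg$alpha_freq * tt + stats::runif(1, 0, 2 * pi)) *
    gain_a

  ch <- layout$channels
  g_gl <- exp(-((ch$x + 0.4)^2 + (ch$y + 0.9)^2) / (2 * 0.35^2))
  g_gr <- exp(-((ch$x - 0.4)^2 + (ch$y + 0.9)^2) / (2 * 0.35^2))
  g_al <- exp(-((ch$y + 0.6)^2) / (2 * 0.5^2))

  data <- matrix(0, nrow(ch), n)
  for (i in seq_len(nrow(ch))) {
    set.seed(sub_seed(cfg$seed, 100 + i))
    data[i, ] <- cfg$gamma_amp * (g_gl[i] * s_left + g_gr[i] * s_right) +
      0.6 * cfg$gamma_amp * g_al[i] * s_gamma2 +
      cfg$alpha_amp * g_al[i] * alpha_sig +
      cfg$noise_scale * one_over_f(n, rate, cfg$noise_exponent)
  }
  new_recording(data, rate, layout, session = session, condition = condition,
                rs_index = rs_index)
}

#' Inject a stimulation artifact and trigger events
#'
#' Adds a sinusoid at `freq` Hz to all channels, weighted by a smooth
#' posterior-midline Gaussian gain profile, and emits a `tacs_trigger` event
#' at every 30th rising zero crossing of the sinusoid (0.75 s cadence at
#' 40 Hz).
#'
#' @param rec a `recording`.
#' @param amplitude artifact amplitude in microvolts (>= 0) at the profile
#'   maximum.
#' @param freq artifact frequency in Hz (must be below Nyquist).
#' @return list with elements `recording` and `events` (the trigger stream).
#' @export
inject_tacs_artifact <- function(rec, amplitude = 200, freq = 40) {
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (freq >= rec$rate / 2) stop("freq must be below Nyquist")
  n <- ncol(rec$data)
  tt <- (seq_len(n) - 1) / rec$rate
  wave <- sin(2 * pi * freq * tt)
  ch <- rec$layout$channels
  gain <- 0.3 + 0.7 * exp(-((ch$x)^2 + (ch$y + 0.7)^2) / (2 * 0.45^2))
  out <- rec
  out$data <- rec$data + amplitude * outer(gain, wave)
  # rising zero crossings of sin(2*pi*f*t) fall at integer multiples of 1/f
  t_trig <- seq(0, (n - 1) / rec$rate, by = 30 / freq)
  list(recording = out,
       events = event_stream(t_trig, rep("tacs_trigger", length(t_trig))))
}

#' Generate a synthetic gaze trace with ground-truth microsaccades
#'
#' Fixational drift (mean-reverting Ornstein-Uhlenbeck walk per axis) plus
#' injected microsaccades with ballistic raised-cosine velocity profiles at
#' Poisson onsets (minimum 120 ms separation), amplitudes uniform in
#' `ms_amp_range` and uniform directions; optional blinks flag samples
#' without deleting them.
#'
#' @param cfg a [sim_config()].
#' @param n_blinks number of blinks to inject (default 0).
#' @return list with `trace` (tibble: `time`, `x`, `y`, `blink`), `truth`
#'   (tibble: `onset`, `duration_ms`, `amplitude`, `direction`,
#'   `peak_velocity`), and `rate`.
#' @export
generate_gaze <- function(cfg, n_blinks = 0) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(sub_seed(cfg$seed, 3))
  rate <- cfg$gaze_rate
  n <- round(cfg$duration * rate)
  dt <- 1 / rate

  # OU drift, stationary SD ~0.08 deg per axis
  theta <- 4; sd_target <- 0.08
  sig <- sd_target * sqrt(2 * theta)
  x <- numeric(n); y <- numeric(n)
  ex <- stats::rnorm(n); ey <- stats::rnorm(n)
  for (i in 2:n) {
    x[i] <- x[i - 1] - theta * x[i - 1] * dt + sig * sqrt(dt) * ex[i]
    y[i] <- y[i - 1] - theta * y[i - 1] * dt + sig * sqrt(dt) * ey[i]
  }

  # candidate Poisson onsets, thinned to a minimum separation
  n_cand <- stats::rpois(1, cfg$ms_rate * cfg$duration)
  onsets <- sort(stats::runif(n_cand, 0.2, cfg$duration - 0.2))
  keep <- c()
  last <- -Inf
  for (o in onsets) {
    if (o - last >= 0.12) { keep <- c(keep, o); last <- o }
  }
  onsets <- keep

  truth <- tibble::tibble(onset = numeric(), duration_ms = numeric(),
                          amplitude = numeric(), direction = numeric(),
                          peak_velocity = numeric())
  for (o in onsets) {
    amp <- stats::runif(1, cfg$ms_amp_range[1], cfg$ms_amp_range[2])
    dur <- stats::runif(1, 0.015, 0.025)
    i0 <- round(o * rate) + 1L
    # gaze-correcting: directions biased back toward fixation, so the
    # saccade sequence is mean-reverting rather than a random walk
    dir <- if (sqrt(x[i0]^2 + y[i0]^2) > 0.05) {
      atan2(-y[i0], -x[i0]) + stats::rnorm(1, 0, 0.6)
    } else {
      stats::runif(1, 0, 2 * pi)
    }
    k <- max(2L, round(dur * rate))
    if (i0 + k > n) next
    # raised-cosine velocity profile integrating to `amp`
    prof <- 1 - cos(2 * pi * (seq_len(k) - 0.5) / k)
    step <- amp * prof / sum(prof)
    dx <- cumsum(step) * cos(dir)
    dy <- cumsum(step) * sin(dir)
    x[(i0 + 1):n] <- x[(i0 + 1):n] + dx[k]
    y[(i0 + 1):n] <- y[(i0 + 1):n] + dy[k]
    x[i0:(i0 + k - 1)] <- x[i0:(i0 + k - 1)] + c(0, dx[-k])
    y[i0:(i0 + k - 1)] <- y[i0:(i0 + k - 1)] + c(0, dy[-k])
    truth <- dplyr::bind_rows(truth, tibble::tibble(
      onset = o, duration_ms = 1000 * k / rate, amplitude = amp,
      direction = dir, peak_velocity = max(step) * rate))
  }

  blink <- rep(FALSE, n)
  if (n_blinks > 0) {
    bl <- stats::runif(n_blinks, 0, cfg$duration - 0.3)
    for (b in bl) {
      i0 <- round(b * rate) + 1L
      blink[i0:min(n, i0 + round(0.2 * rate))] <- TRUE
    }
  }

  list(trace = tibble::tibble(time = (seq_len(n) - 1) * dt, x = x, y = y,
                              blink = blink),
       truth = truth, rate = rate)
}
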