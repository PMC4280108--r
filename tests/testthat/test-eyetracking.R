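test_that("injected microsaccades are recovered with accurate onsets", {
  cfg <- sim_config(duration = 100, ms_rate = 1.0, ms_amp_range = c(0.1, 0.5),
                    seed = 34)
  g <- generate_gaze(cfg)
  tr <- prefilter_gaze(g$trace, g$rate)
  det <- detect_microsaccades(tr, g$rate)
  rec <- event_recall(g$truth$onset, det$onset, tol = 0.02)
  prec <- event_recall(det$onset, g$truth$onset, tol = 0.02)
  expect_gte(rec, 0.9)
  expect_gte(prec, 0.9)
  # onsets within +/-4 ms of ground truth for matched events
  err <- vapply(det$onset, function(o) min(abs(g$truth$onset - o)), numeric(1))
  expect_lt(stats::median(err), 0.004)
  # detected events respect the printed bounds by construction
  expect_true(all(det$duration_ms >= 10))
  expect_true(all(det$amplitude >= 0.05 & det$amplitude <= 1))
})

test_that("events violating the duration or amplitude bounds are rejected", {
  rate <- 500
  set.seed(35)
  n <- 20 * rate
  # smooth fixational drift (AR(1)-filtered noise), very low velocity noise
  x <- as.numeric(stats::filter(rnorm(n, 0, 0.0015), 0.97, "recursive"))
  y <- as.numeric(stats::filter(rnorm(n, 0, 0.0015), 0.97, "recursive"))
  inject <- function(x, t0, amp, dur_s) {
    i0 <- round(t0 * rate); k <- max(2, round(dur_s * rate))
    prof <- 1 - cos(2 * pi * (seq_len(k) - 0.5) / k)
    step <- amp * prof / sum(prof)
    x[(i0 + k):n] <- x[(i0 + k):n] + amp
    x[i0:(i0 + k - 1)] <- x[i0:(i0 + k - 1)] + cumsum(step)
    x
  }
  x <- inject(x, 5, 0.02, 0.02)    # below the 0.05 deg amplitude floor
  x <- inject(x, 10, 0.3, 0.006)   # below the 10 ms duration floor
  x <- inject(x, 15, 0.3, 0.02)    # valid event
  trace <- tibble::tibble(time = (seq_len(n) - 1) / rate, x = x, y = y)
  det <- detect_microsaccades(trace, rate)
  expect_false(any(abs(det$onset - 5) < 0.05))    # amplitude floor
  hits_short <- det[abs(det$onset - 10) < 0.05, ]
  expect_true(nrow(hits_short) == 0 || all(hits_short$duration_ms >= 10))
  expect_true(any(abs(det$onset - 15) < 0.05))    # valid event reported
  expect_true(all(det$duration_ms >= 10))
  expect_true(all(det$amplitude >= 0.05 & det$amplitude <= 1))
})

test_that("prefiltering applies the 80% retention rule and press margins", {
  cfg <- sim_config(duration = 10, ms_rate = 0.5, seed = 36)
  g <- generate_gaze(cfg, n_blinks = 0)
  tr <- g$trace
  # contaminate epoch 3 (seconds 2-3): mask 25% via fake blinks
  blink <- rep(FALSE, nrow(tr))
  blink[tr$time >= 2 & tr$time < 2.25] <- TRUE
  tr$blink <- blink
  out <- prefilter_gaze(tr, g$rate)
  expect_true(all(is.na(out$epoch[out$time >= 2 & out$time < 3])))
  # an epoch with 15% masked survives
  tr2 <- g$trace
  blink2 <- rep(FALSE, nrow(tr2))
  blink2[tr2$time >= 4 & tr2$time < 4.15] <- TRUE
  tr2$blink <- blink2
  out2 <- prefilter_gaze(tr2, g$rate)
  expect_false(anyNA(out2$epoch[out2$time >= 4 & out2$time < 5]))
  # clean trace: nothing masked
  out3 <- prefilter_gaze(g$trace, g$rate)
  expect_true(all(!out3$masked | out3$time > 9))
  # button presses mask +/-1 s
  ev <- press_stream(5, "horizontal", trial_len = 10)
  out4 <- prefilter_gaze(g$trace, g$rate, ev = ev)
  expect_true(all(out4$masked[out4$time >= 4.2 & out4$time <= 5.8]))
})

test_that("fixation statistics summarize unmasked position in degrees", {
  cfg <- sim_config(duration = 60, ms_rate = 0.8, seed = 37)
  g <- generate_gaze(cfg)
  fs <- fixation_stats(g$trace)
  expect_lt(abs(fs$mean_x), 0.1)
  expect_lt(abs(fs$mean_y), 0.1)
  # constant offset shifts the mean exactly
  tr <- g$trace; tr$x <- tr$x + 0.5
  fs2 <- fixation_stats(tr)
  expect_equal(fs2$mean_x, fs$mean_x + 0.5)
  expect_equal(fs2$sd_x, fs$sd_x)
})

test_that("detection is invariant to coordinate rotation and gain-consistent", {
  cfg <- sim_config(duration = 60, ms_rate = 1.2, ms_amp_range = c(0.15, 0.45),
                    seed = 38)
  g <- generate_gaze(cfg)
  det <- detect_microsaccades(g$trace, g$rate)
  # rotate the frame by 30 degrees: same events detected
  th <- pi / 6
  tr_rot <- g$trace
  tr_rot$x <- cos(th) * g$trace$x - sin(th) * g$trace$y
  tr_rot$y <- sin(th) * g$trace$x + cos(th) * g$trace$y
  det_rot <- detect_microsaccades(tr_rot, g$rate)
  expect_equal(nrow(det_rot), nrow(det), tolerance = 0.1)
  expect_gte(event_recall(det$onset, det_rot$onset, tol = 0.004), 0.9)
  # doubling the gain doubles amplitudes; counts change only via the
  # amplitude window, so events away from the boundaries persist
  tr2 <- g$trace; tr2$x <- 2 * tr2$x; tr2$y <- 2 * tr2$y
  det2 <- detect_microsaccades(tr2, g$rate)
  safe <- det[det$amplitude < 0.5, ]
  matched <- vapply(safe$onset, function(o) {
    j <- which.min(abs(det2$onset - o))
    if (abs(det2$onset[j] - o) > 0.004) return(NA_real_)
    det2$amplitude[j] / safe$amplitude[which.min(abs(safe$onset - o))]
  }, numeric(1))
  expect_equal(stats::median(matched, na.rm = TRUE), 2, tolerance = 0.1)
})

test_that("pixel coordinates convert to visual degrees via viewing geometry", {
  d <- px_to_deg(960, 540)
  expect_equal(d$x, 0); expect_equal(d$y, 0)
  # one pixel column ~ screen_width / resolution cm at 60 cm distance
  d2 <- px_to_deg(960 + 100, 540)
  expect_equal(d2$x, atan2(100 * 53.1 / 1920, 60) * 180 / pi)
  expect_gt(d2$x, 0)
})
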