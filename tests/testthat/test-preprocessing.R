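test_that("band-pass preserves in-band tones and suppresses drift", {
  r50 <- bandpass(sine_recording(50, dur = 10), 1, 100)
  amp50 <- sqrt(2 * mean(r50$data[1, ]^2))
  expect_equal(amp50, 1, tolerance = 0.05)
  # slow drift attenuated by >= 20 dB
  rdr <- bandpass(sine_recording(0.2, dur = 10), 1, 100)
  expect_lt(20 * log10(sqrt(2 * mean(rdr$data[1, ]^2))), -20)
  expect_error(bandpass(sine_recording(5), 0, 100), "corner")
  expect_error(bandpass(sine_recording(5), 100, 10), "corner")
})

test_that("two-pass FIR filtering has zero phase (symmetric impulse response)", {
  imp <- rep(0, 4001); imp[2001] <- 1
  y <- gammacoh:::fir_bandpass_rows(imp, 1000, 1, 100)
  expect_equal(y, rev(y))
  expect_equal(which.max(abs(y)), 2001L)
})

test_that("filtering is linear within numerical tolerance", {
  set.seed(8)
  x <- rnorm(4000); y <- rnorm(4000)
  f <- function(s) gammacoh:::fir_bandpass_rows(s, 1000, 1, 100)
  expect_equal(f(2 * x + 3 * y), 2 * f(x) + 3 * f(y), tolerance = 1e-8)
})

test_that("notch removes 40 Hz and spares neighbors, symmetrically by condition", {
  r40 <- notch(sine_recording(40, dur = 20))
  expect_lt(sqrt(mean(r40$data[1, ]^2)) / sqrt(0.5), 0.01)
  r20 <- notch(sine_recording(20, dur = 20))
  expect_equal(sqrt(2 * mean(r20$data[1, ]^2)), 1, tolerance = 0.05)
  # 60 Hz survives a 40+60 mixture
  rate <- 1000; tt <- (0:(20 * rate - 1)) / rate
  mix <- new_recording(matrix(rep(sin(2 * pi * 40 * tt) + sin(2 * pi * 60 * tt),
                                  31), 31, byrow = TRUE), rate, fix_layout())
  y <- notch(mix)$data[1, ]
  amp <- Mod(stats::fft(y)) / length(y) * 2
  expect_equal(amp[60 * 20 + 1], 1, tolerance = 0.05)
  expect_lt(amp[40 * 20 + 1], 0.01)
  expect_error(notch(mix, 45, 35), "corner")
})

test_that("downsampling preserves duration and in-band content, kills aliases", {
  rec <- sine_recording(30, dur = 10, rate = 5000)
  ds <- downsample(rec, 1000)
  expect_identical(ncol(ds$data), 10000L)
  expect_identical(ds$rate, 1000)
  expect_equal(sqrt(2 * mean(ds$data[1, ]^2)), 1, tolerance = 0.05)
  # 900 Hz component absent after decimation to 1000 Hz
  r900 <- downsample(sine_recording(900, dur = 2, rate = 5000), 1000)
  expect_lt(sqrt(2 * mean(r900$data[1, ]^2)), 0.02)
  expect_error(downsample(rec, 1500), "divide")
})

test_that("percept epoching follows the 500 ms offset / 3 s window rule", {
  rec <- sine_recording(10, dur = 60, rate = 500)
  # switch at 10 s, next at 20 s: epoch [10.5, 13.5)
  ev <- press_stream(c(10, 20), c("horizontal", "vertical"))
  ep <- epoch_percepts(rec, ev)
  expect_identical(dim(ep$data)[1], 2L)
  expect_equal(ep$labels$start[1], 10.5)
  expect_identical(dim(ep$data)[3], 1500L)
  expect_identical(ep$labels$percept, c("horizontal", "vertical"))

  # switch at 10, next at 12: dropped (would overlap the next percept)
  ev2 <- press_stream(c(10, 12), c("horizontal", "vertical"))
  ep2 <- epoch_percepts(rec, ev2)
  expect_identical(ep2$labels$percept, "vertical")

  # epochs never cross trial boundaries
  ev3 <- press_stream(c(58), c("horizontal"))
  expect_identical(dim(epoch_percepts(rec, ev3)$data)[1], 0L)

  # no switches, no epochs
  expect_identical(dim(epoch_percepts(rec, press_stream(numeric(),
                                                        character()))$data)[1],
                   0L)

  # redundant same-label presses do not truncate the epoch
  ev4 <- press_stream(c(10, 11, 20), c("horizontal", "horizontal", "vertical"))
  ep4 <- epoch_percepts(rec, ev4)
  expect_true(10.5 %in% ep4$labels$start)
})

test_that("epoching copies samples verbatim from the source recording", {
  set.seed(10)
  rec <- new_recording(matrix(rnorm(31 * 30000), 31), 500, fix_layout())
  ev <- press_stream(c(10), c("horizontal"))
  ep <- epoch_percepts(rec, ev)
  i0 <- floor(10.5 * 500) + 1
  expect_identical(ep$data[1, , ], unname(rec$data[, i0:(i0 + 1499)]))
})

test_that("resting-state segmentation floors to whole seconds", {
  mkrs <- function(dur) {
    new_recording(matrix(0, 31, round(dur * 500)), 500, fix_layout(),
                  condition = "resting")
  }
  expect_identical(dim(segment_resting(mkrs(180))$data)[1], 180L)
  expect_identical(dim(segment_resting(mkrs(1.5))$data)[1], 1L)
  expect_identical(dim(segment_resting(mkrs(0.5))$data)[1], 0L)
  expect_error(segment_resting(sine_recording(10, condition = "sham")),
               "resting")
})

test_that("artifact rejection drops epochs by peak-to-peak threshold", {
  ep <- noise_epochs(n_ep = 6, seed = 2)
  ep$data[3, 5, 100] <- 500  # one spiked epoch
  out <- reject_artifacts(ep, threshold = 200)
  expect_identical(dim(out$data)[1], 5L)
  expect_identical(attr(out, "n_dropped"), 1L)
  # infinite threshold is the identity
  expect_identical(dim(reject_artifacts(ep, Inf)$data)[1], 6L)
  expect_warning(reject_artifacts(ep, threshold = 1e-9), "all epochs")
})

test_that("balancing equalizes cells to the minimum count, reproducibly", {
  ep <- noise_epochs(n_ep = 26, seed = 3)
  ep$labels$percept <- rep(c("horizontal", "vertical"), c(10, 16))
  b1 <- balance_segments(ep, seed = 1)
  expect_identical(as.integer(table(b1$labels$percept)), c(10L, 10L))
  b2 <- balance_segments(ep, seed = 1)
  expect_identical(b1$data, b2$data)
  b3 <- balance_segments(ep, seed = 2)
  expect_identical(as.integer(table(b3$labels$percept)), c(10L, 10L))
  # equal cells: identity up to order
  epq <- noise_epochs(n_ep = 8, seed = 4)
  epq$labels$percept <- rep(c("horizontal", "vertical"), each = 4)
  expect_identical(dim(balance_segments(epq, seed = 9)$data)[1], 8L)
})
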