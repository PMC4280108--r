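test_that("Rao spacing statistic matches its analytic worked values", {
  # all angles identical: spacings are n-1 zeros and one full circle
  expect_equal(rao_spacing_test(rep(1.1, 10))$statistic, 324)
  # perfectly equispaced angles: every spacing equals lambda
  expect_equal(rao_spacing_test(seq(0, 2 * pi * 9 / 10,
                                    length.out = 10))$statistic, 0)
  expect_error(rao_spacing_test(c(1, 2, 3)), "at least 4")
})

test_that("Rao Monte-Carlo p-values are valid and uniform under the null", {
  set.seed(16)
  p_null <- vapply(1:400, function(i) {
    rao_spacing_test(stats::runif(35, 0, 2 * pi), n_mc = 2000)$p.value
  }, numeric(1))
  expect_gte(min(p_null), 1 / 2001)
  ks <- suppressWarnings(stats::ks.test(p_null, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(p_null < 0.05) - 0.05), 0.035)
  # concentration is detected decisively
  set.seed(17)
  p_alt <- vapply(1:20, function(i) {
    rao_spacing_test(rvonmises(100, 0, 2), n_mc = 2000)$p.value
  }, numeric(1))
  expect_true(all(p_alt < 0.001))
})

test_that("Kuiper test is rotation-invariant and detects opposite means", {
  set.seed(18)
  a <- stats::runif(50, 0, 2 * pi); b <- stats::runif(50, 0, 2 * pi)
  v0 <- kuiper_two_sample(a, b)$statistic
  v1 <- kuiper_two_sample(a + 1.3, b + 1.3)$statistic
  expect_equal(v0, v1)
  # identical samples: minimal V, p ~ 1
  same <- kuiper_two_sample(a, a)
  expect_equal(same$p.value, 1)
  expect_lte(same$statistic, 1 / 50 + 1e-12)
  # von Mises means pi apart, n = 200: decisive
  set.seed(19)
  k <- kuiper_two_sample(rvonmises(200, 0, 2), rvonmises(200, pi, 2))
  expect_lt(k$p.value, 0.001)
  expect_error(kuiper_two_sample(a[1:5], b), "n >= 8")
})

test_that("Kuiper null rejections never exceed the nominal rate", {
  set.seed(20)
  p <- vapply(1:300, function(i) {
    kuiper_two_sample(stats::runif(60, 0, 2 * pi),
                      stats::runif(60, 0, 2 * pi))$p.value
  }, numeric(1))
  expect_lt(mean(p < 0.05), 0.075)
  expect_gt(mean(p > 0.5), 0.2)  # p-values spread over the unit interval
})

test_that("the binomial group criterion applies the strict >26/28 rule", {
  expect_true(binomial_group_criterion(27, 28))
  expect_false(binomial_group_criterion(26, 28))
  expect_true(binomial_group_criterion(28, 28))
  expect_error(binomial_group_criterion(29, 28), "exceed")
  expect_error(binomial_group_criterion(-1, 28), "non-negative")
})

test_that("trigger phases concentrate for a 40 Hz tone and covary with shifts", {
  lay <- fix_layout()
  rate <- 1000; dur <- 24
  tt <- (0:(dur * rate - 1)) / rate
  set.seed(21)
  dat <- matrix(rep(sin(2 * pi * 40 * tt), 31), 31, byrow = TRUE) +
    matrix(rnorm(31 * dur * rate, 0, 0.05), 31)
  rec <- new_recording(dat, rate, lay, condition = "stimulation")
  trig <- event_stream(seq(0, dur - 0.01, by = 0.75),
                       rep("tacs_trigger", 32))
  bands <- tibble::tibble(band = "gamma1", f_lo = 36, f_hi = 45)
  ps <- phases_at_triggers(rec, trig, bands = bands, channels = 1)
  a <- ps$angles[[1]]
  circ_sd <- sqrt(-2 * log(Mod(mean(exp(1i * a)))))
  expect_lt(circ_sd, 0.1)
  expect_identical(ps$kind, "real")
  # quarter-period trigger shift rotates the mean angle by pi/2
  trig2 <- event_stream(seq(0, dur - 0.01, by = 0.75) + 1 / 160,
                        rep("tacs_trigger", 32))
  a2 <- phases_at_triggers(rec, trig2, bands = bands, channels = 1)$angles[[1]]
  dmean <- Arg(mean(exp(1i * a2)) / mean(exp(1i * a)))
  expect_equal(dmean, pi / 2, tolerance = 0.1)
  # triggers outside the recording are skipped and counted
  trig3 <- event_stream(c(1, 2, dur + 5), rep("tacs_trigger", 3))
  ps3 <- phases_at_triggers(rec, trig3, bands = bands, channels = 1)
  expect_identical(ps3$n[[1]], 2L)
  expect_identical(ps3$n_skipped[[1]], 1L)
})

test_that("white-noise trigger phases are uniform for most seeds", {
  lay <- fix_layout()
  rate <- 500; dur <- 31
  bands <- tibble::tibble(band = "gamma1", f_lo = 36, f_hi = 45)
  rejections <- vapply(1:10, function(s) {
    set.seed(s)
    rec <- new_recording(matrix(rnorm(31 * dur * rate), 31), rate, lay)
    trig <- dummy_triggers(rec)
    a <- phases_at_triggers(rec, trig, bands = bands, channels = 1)$angles[[1]]
    rao_spacing_test(a, n_mc = 2000)$p.value < 0.05
  }, logical(1))
  expect_lte(mean(rejections), 0.1)
})

test_that("dummy triggers fall at the 0.75 s stimulation cadence", {
  rec <- sine_recording(10, dur = 6, rate = 500)
  dt <- dummy_triggers(rec)
  expect_identical(unique(dt$label), "dummy_trigger")
  expect_equal(unique(diff(dt$time)), 0.75)
  expect_equal(dt$time[1], 0)
})

test_that("spectral entropy attains its analytic extremes", {
  ep <- noise_epochs(n_ep = 3, seed = 22)
  sp <- estimate_spectra(ep)
  # uniform power: H = (B / n_channels) log(n_channels) per band under the
  # per-frequency channel normalization (direct evaluation of the formula)
  sp$power[, ] <- 1
  em <- spectral_entropy(sp)
  bw <- c(delta_theta = 7, alpha = 5, beta = 23, gamma = 55)
  for (b in names(bw)) {
    expect_equal(unique(em$entropy[em$band == b]), bw[[b]] / 31 * log(31),
                 tolerance = 1e-10)
  }
  # the per-channel normalization switch gives log(band width)
  emf <- spectral_entropy(sp, normalize = "frequencies")
  expect_equal(unique(emf$entropy[emf$band == "alpha"]), log(5),
               tolerance = 1e-10)
  # one-hot concentration: zero entropy at that channel/band
  sp$power[, ] <- 0
  sp$power[1, sp$freqs == 10] <- 4
  em1 <- spectral_entropy(sp)
  expect_equal(em1$entropy[em1$band == "alpha" & em1$channel == "L01"], 0)
  # entropy is permutation-invariant over frequencies within a band
  set.seed(23)
  sp$power[, ] <- matrix(runif(31 * 100, 0.5, 2), 31)
  e_orig <- spectral_entropy(sp)
  perm <- sample(which(sp$freqs >= 8 & sp$freqs <= 12))
  sp2 <- sp
  sp2$power[, sp$freqs %in% 8:12] <- sp$power[, perm]
  e_perm <- spectral_entropy(sp2)
  expect_equal(e_perm$entropy[e_perm$band == "alpha"],
               e_orig$entropy[e_orig$band == "alpha"])
})

test_that("a strong stimulation line lowers beta/gamma entropy vs matched noise", {
  lay <- fix_layout()
  mk <- function(with_line, seed) {
    set.seed(seed)
    rate <- 500; dur <- 20
    tt <- (0:(dur * rate - 1)) / rate
    dat <- matrix(rnorm(31 * dur * rate), 31)
    if (with_line) {
      gain <- exp(-((lay$channels$x)^2 + (lay$channels$y + 0.7)^2) / 0.4)
      dat <- dat + 6 * outer(gain, sin(2 * pi * 58 * tt))
    }
    rec <- new_recording(dat, rate, lay, condition = "resting")
    spectral_entropy(estimate_spectra(segment_resting(rec)))
  }
  em_line <- mk(TRUE, 24); em_flat <- mk(FALSE, 24)
  g_line <- em_line$entropy[em_line$band == "gamma"]
  g_flat <- em_flat$entropy[em_flat$band == "gamma"]
  expect_lt(mean(g_line), mean(g_flat))
})
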