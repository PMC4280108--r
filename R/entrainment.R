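#' Four entrainment analysis bands
#'
#' The instantaneous-phase and entropy analyses use four bands: delta/theta
#' (1--7 Hz), alpha (8--12 Hz), pooled beta (13--35 Hz) and pooled gamma
#' (46--100 Hz; gamma1 is excluded because the notch filter removes the
#' stimulation artifact there).
#'
#' @return tibble with `band`, `f_lo`, `f_hi`.
#' @export
entrainment_bands <- function() {
  tibble::tibble(
    band = factor(c("delta_theta", "alpha", "beta", "gamma"),
                  levels = c("delta_theta", "alpha", "beta", "gamma")),
    f_lo = c(1L, 8L, 13L, 46L),
    f_hi = c(7L, 12L, 35L, 100L)
  )
}

#' Dummy triggers at the stimulation cadence
#'
#' For sham and post conditions a dummy marker mimics the stimulation
#' trigger: one event every `cadence` seconds (0.75 s = 30 cycles of 40 Hz),
#' starting at `start`.
#'
#' @param rec a `recording`.
#' @param cadence trigger spacing in seconds.
#' @param start time of the first trigger, seconds.
#' @return an `event_stream` of `dummy_trigger` events.
#' @export
dummy_triggers <- function(rec, cadence = 0.75, start = 0) {
  t <- seq(start, duration(rec) - 1 / rec$rate, by = cadence)
  event_stream(t, rep("dummy_trigger", length(t)))
}

#' Instantaneous phase at stimulation triggers
#'
#' Band-passes each channel (zero-phase FIR), extracts the analytic-signal
#' phase, and samples it at each trigger time. Triggers outside the
#' recording are skipped and counted. Phases are wrapped to (-pi, pi].
#'
#' @param rec a `recording`.
#' @param ev an `event_stream` containing `tacs_trigger` or `dummy_trigger`
#'   events.
#' @param bands band table (default [entrainment_bands()]).
#' @param channels channel indices to analyse (default all).
#' @return tibble of class `phase_samples`: `channel`, `band`, `kind`,
#'   `angles` (list column of radians), `n`, `n_skipped`.
#' @export
phases_at_triggers <- function(rec, ev, bands = entrainment_bands(),
                               channels = seq_len(nrow(rec$data))) {
  stopifnot(inherits(rec, "recording"))
  trig <- ev[ev$label %in% c("tacs_trigger", "dummy_trigger"), ]
  if (nrow(trig) == 0L) stop("no trigger events in the stream")
  kind <- if (any(trig$label == "tacs_trigger")) "real" else "dummy"
  idx <- round(trig$time * rec$rate) + 1L
  inside <- idx >= 1L & idx <= ncol(rec$data)
  n_skipped <- sum(!inside)
  idx <- idx[inside]
  rows <- list()
  for (b in seq_len(nrow(bands))) {
    fb <- fir_bandpass_rows(rec$data[channels, , drop = FALSE], rec$rate,
                            bands$f_lo[b], bands$f_hi[b])
    for (ci in seq_along(channels)) {
      ph <- instantaneous_phase(fb[ci, ])[idx]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        channel = channels[ci], band = as.character(bands$band[b]),
        kind = kind, angles = list(ph), n = length(ph),
        n_skipped = n_skipped)
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("phase_samples", class(out))
  out
}

# null distribution of the Rao spacing statistic, memoised per sample size
.rao_cache <- new.env(parent = emptyenv())

rao_statistic <- function(angles) {
  n <- length(angles)
  a <- sort(((angles %% (2 * pi)) + 2 * pi) %% (2 * pi)) * 180 / pi
  sp <- c(diff(a), 360 - a[n] + a[1])
  lambda <- 360 / n
  0.5 * sum(abs(sp - lambda))
}

#' Rao's spacing test for circular non-uniformity
#'
#' Statistic `U = 1/2 sum |T_i - lambda|` over the sorted circular spacings
#' `T_i` (degrees) with `lambda = 360 / n`; sensitive to multimodal
#' departures from uniformity. The p-value comes from a Monte-Carlo null
#' (uniform circular resampling at matched n), memoised per sample size so
#' that repeated tests at the same n reuse one null distribution.
#'
#' @param angles numeric vector of angles in radians (n >= 4).
#' @param n_mc Monte-Carlo null draws (default 10000).
#' @param mc_seed seed for the null distribution.
#' @return tibble with `statistic` (degrees), `p.value`, `n`, `method`.
#' @export
rao_spacing_test <- function(angles, n_mc = 10000, mc_seed = 20401) {
  n <- length(angles)
  if (n < 4L) stop("Rao spacing test needs at least 4 angles")
  U <- rao_statistic(angles)
  key <- sprintf("n%d_m%d_s%d", n, n_mc, mc_seed)
  null <- get0(key, envir = .rao_cache)
  if (is.null(null)) {
    set.seed(mc_seed)
    null <- vapply(seq_len(n_mc), function(i) {
      rao_statistic(stats::runif(n, 0, 2 * pi))
    }, numeric(1))
    assign(key, null, envir = .rao_cache)
  }
  p <- (1 + sum(null >= U)) / (n_mc + 1)
  tibble::tibble(statistic = U, p.value = p, n = n,
                 method = "Rao spacing test (Monte-Carlo null)")
}

#' Kuiper's two-sample test on the circle
#'
#' `V = D+ + D-` between the two empirical circular CDFs; invariant under a
#' common rotation of both samples. The p-value uses the asymptotic series
#' with the effective-sample-size correction.
#'
#' @param a,b numeric vectors of angles in radians (each n >= 8).
#' @return tibble with `statistic`, `p.value`, `n_a`, `n_b`, `method`.
#' @export
kuiper_two_sample <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 8L || nb < 8L) stop("Kuiper two-sample test needs n >= 8 per sample")
  wrap <- function(x) ((x %% (2 * pi)) + 2 * pi) %% (2 * pi)
  a <- sort(wrap(a)); b <- sort(wrap(b))
  grid <- sort(c(a, b))
  fa <- findInterval(grid, a) / na
  fb <- findInterval(grid, b) / nb
  V <- max(fa - fb) + max(fb - fa)
  ne <- na * nb / (na + nb)
  lam <- (sqrt(ne) + 0.155 + 0.24 / sqrt(ne)) * V
  if (lam < 0.4) {
    p <- 1  # asymptotic series invalid; tail mass is ~1 here
  } else {
    k <- 1:100
    p <- 2 * sum((4 * k^2 * lam^2 - 1) * exp(-2 * k^2 * lam^2))
    p <- min(max(p, 0), 1)
  }
  tibble::tibble(statistic = V, p.value = p, n_a = na, n_b = nb,
                 method = "Kuiper two-sample test (asymptotic)")
}

#' Binomial group-level significance criterion
#'
#' Group-level significance is assumed when more than `threshold` of `n`
#' per-subject-and-session comparisons are individually significant (the
#' fixed rule: >26 of 28 Kuiper tests at the Bonferroni-corrected per-test
#' alpha 0.05/31 = 0.0016).
#'
#' @param k number of significant comparisons.
#' @param n total comparisons (default 28).
#' @param threshold strict lower bound (default 26): pass iff `k > threshold`.
#' @return logical.
#' @export
binomial_group_criterion <- function(k, n = 28, threshold = 26) {
  if (k > n) stop("k cannot exceed n")
  if (k < 0) stop("k must be non-negative")
  k > threshold
}

#' Shannon spectral entropy per channel and band
#'
#' Spectral estimates are normalized and treated like probabilities, then
#' `H = -sum S log S` (natural log) is accumulated over each band's
#' frequencies. Default normalization (`"channels"`) divides, at each
#' frequency, by the sum over channels; the `"frequencies"` switch instead
#' normalizes each channel's spectrum over the band's frequencies (then the
#' uniform maximum is `log` band width). All-zero frequency rows are flagged
#' undefined and excluded.
#'
#' @param sp a `spectral_estimate`.
#' @param bands band table (default [entrainment_bands()]).
#' @param normalize `"channels"` (per frequency, across channels) or
#'   `"frequencies"` (per channel, across the band's frequencies).
#' @return tibble of class `entropy_map`: `channel`, `band`, `entropy`
#'   (nats), `n_freqs`, `normalize`.
#' @export
spectral_entropy <- function(sp, bands = entrainment_bands(),
                             normalize = c("channels", "frequencies")) {
  stopifnot(inherits(sp, "spectral_estimate"))
  normalize <- match.arg(normalize)
  P <- sp$power
  if (any(P < 0)) stop("power must be non-negative")
  plogp <- function(s) ifelse(s > 0, -s * log(s), 0)
  rows <- list()
  for (b in seq_len(nrow(bands))) {
    sel <- sp$freqs >= bands$f_lo[b] & sp$freqs <= bands$f_hi[b]
    Pb <- P[, sel, drop = FALSE]
    if (normalize == "channels") {
      tot <- colSums(Pb)
      ok <- tot > 0
      S <- sweep(Pb[, ok, drop = FALSE], 2, tot[ok], "/")
      H <- rowSums(plogp(S))
      nf <- sum(ok)
    } else {
      tot <- rowSums(Pb)
      S <- sweep(Pb, 1, ifelse(tot > 0, tot, NA_real_), "/")
      H <- rowSums(plogp(S))
      H[tot <= 0] <- NA_real_
      nf <- ncol(Pb)
    }
    rows[[b]] <- tibble::tibble(
      channel = rownames(P), band = as.character(bands$band[b]),
      entropy = unname(H), n_freqs = nf, normalize = normalize)
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("entropy_map", class(out))
  out
}
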