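# Shared fixtures built in code. Small sizes keep the default run fast;
# statistically demanding checks live in test-acceptance.R.

fix_layout <- function() default_layout()

# recording with the same signal on every channel
sine_recording <- function(freq, dur = 10, rate = 1000, amp = 1,
                           noise = 0, seed = 1, condition = NA_character_) {
  set.seed(seed)
  tt <- (0:(dur * rate - 1)) / rate
  sig <- amp * sin(2 * pi * freq * tt)
  data <- matrix(rep(sig, 31), nrow = 31, byrow = TRUE)
  if (noise > 0) data <- data + matrix(rnorm(length(data), 0, noise), 31)
  new_recording(data, rate, fix_layout(), condition = condition)
}

# iid noise epochs
noise_epochs <- function(n_ep = 8, len = 1000, rate = 1000, seed = 1,
                         percept = NA_character_) {
  set.seed(seed)
  arr <- array(rnorm(n_ep * 31 * len), dim = c(n_ep, 31, len))
  new_epochs(arr, rate,
             tibble::tibble(session = NA_character_, condition = NA_character_,
                            percept = rep(percept, n_ep),
                            start = seq_len(n_ep)),
             fix_layout())
}

# one-trial event stream from press times/labels
press_stream <- function(times, labels, trial_len = 60) {
  plab <- if (length(labels)) paste0("press_", labels) else character(0)
  event_stream(c(0, trial_len, times), c("trial_start", "trial_end", plab))
}

# von Mises sample by rejection (test oracle helper)
rvonmises <- function(n, mu, kappa) {
  out <- numeric(0)
  while (length(out) < n) {
    cand <- stats::runif(2 * n, 0, 2 * pi)
    keep <- stats::runif(2 * n) < exp(kappa * (cos(cand - mu) - 1))
    out <- c(out, cand[keep])
  }
  out[seq_len(n)]
}

# match detected events to ground-truth onsets within a tolerance (s)
event_recall <- function(truth_onsets, detected_onsets, tol = 0.02) {
  if (!length(truth_onsets)) return(NA_real_)
  mean(vapply(truth_onsets,
              function(o) any(abs(detected_onsets - o) <= tol), logical(1)))
}
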