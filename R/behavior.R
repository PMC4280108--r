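# Percept-interval accounting shared by motion_ratio and switch_rate.
# Rules: redundant consecutive same-label presses collapse; the first
# `exclude_start` seconds of the trial are excluded (an interval spanning the
# boundary keeps its portion after it); only intervals longer than
# `min_duration` are accepted; the trailing percept runs to trial end.
percept_intervals <- function(ev, trial_row, exclude_start = 3,
                              min_duration = 1, short_mode = c("drop", "reassign")) {
  short_mode <- match.arg(short_mode)
  t0 <- trial_row$start; t1 <- trial_row$end
  press <- ev[ev$label %in% c("press_horizontal", "press_vertical") &
                ev$time >= t0 & ev$time < t1, ]
  n_red <- 0L
  if (nrow(press) > 1L) {
    dup <- c(FALSE, press$label[-1] == press$label[-nrow(press)])
    n_red <- sum(dup)
    press <- press[!dup, ]
  }
  if (nrow(press) == 0L) {
    return(list(intervals = tibble::tibble(percept = character(),
                                           start = numeric(), end = numeric(),
                                           duration = numeric()),
                n_redundant = n_red, excluded = t1 - t0))
  }
  iv <- tibble::tibble(
    percept = sub("press_", "", press$label),
    start = press$time,
    end = c(press$time[-1], t1)
  )
  # trim the start-of-trial exclusion window
  cut <- t0 + exclude_start
  iv$start <- pmax(iv$start, cut)
  iv <- iv[iv$end > iv$start, ]
  iv$duration <- iv$end - iv$start
  short <- iv$duration <= min_duration
  if (short_mode == "reassign" && any(short) && any(!short)) {
    # fold each short interval's time into the nearest preceding accepted
    # interval (or the following one at the trial start)
    acc_idx <- which(!short)
    for (s in which(short)) {
      prev <- acc_idx[acc_idx < s]
      tgt <- if (length(prev)) max(prev) else min(acc_idx)
      iv$duration[tgt] <- iv$duration[tgt] + iv$duration[s]
    }
  }
  accepted <- iv[!short, , drop = FALSE]
  list(intervals = accepted, n_redundant = n_red,
       excluded = (t1 - t0) - sum(accepted$duration))
}

#' Motion ratio per trial
#'
#' Fraction of accepted viewing time spent perceiving horizontal motion,
#' `MR = time_horizontal / time_total`, after the trial's first 3 seconds
#' are excluded, percept durations of 1 second or less are discarded (from
#' numerator and denominator under the default `short_mode = "drop"`;
#' `"reassign"` folds them into the flanking percept), and redundant
#' consecutive same-label presses are collapsed. A trial with no accepted
#' interval yields `NA` and is flagged.
#'
#' @param ev an `event_stream` with presses and trial markers.
#' @param exclude_start seconds excluded at the start of each trial.
#' @param min_duration minimal accepted percept duration, seconds.
#' @param short_mode how sub-threshold intervals are handled.
#' @return tibble: `trial`, `mr`, `accepted_time`, `excluded_time`,
#'   `n_redundant`.
#' @export
motion_ratio <- function(ev, exclude_start = 3, min_duration = 1,
                         short_mode = c("drop", "reassign")) {
  short_mode <- match.arg(short_mode)
  trials <- trials_of(ev)
  purrr::map_dfr(seq_len(nrow(trials)), function(k) {
    pi <- percept_intervals(ev, trials[k, ], exclude_start, min_duration,
                            short_mode)
    tot <- sum(pi$intervals$duration)
    hor <- sum(pi$intervals$duration[pi$intervals$percept == "horizontal"])
    tibble::tibble(trial = k,
                   mr = if (tot > 0) hor / tot else NA_real_,
                   accepted_time = tot,
                   excluded_time = pi$excluded,
                   n_redundant = pi$n_redundant)
  })
}

#' Perceptual switch rate per trial
#'
#' Number of transitions between consecutive accepted percept intervals with
#' differing labels, divided by the accepted trial time in minutes.
#'
#' @inheritParams motion_ratio
#' @return tibble: `trial`, `switch_rate` (per minute), `n_switches`,
#'   `accepted_time`.
#' @export
switch_rate <- function(ev, exclude_start = 3, min_duration = 1,
                        short_mode = c("drop", "reassign")) {
  short_mode <- match.arg(short_mode)
  trials <- trials_of(ev)
  purrr::map_dfr(seq_len(nrow(trials)), function(k) {
    pi <- percept_intervals(ev, trials[k, ], exclude_start, min_duration,
                            short_mode)
    iv <- pi$intervals
    nsw <- if (nrow(iv) > 1L) sum(iv$percept[-1] != iv$percept[-nrow(iv)]) else 0L
    tot <- sum(iv$duration)
    tibble::tibble(trial = k,
                   switch_rate = if (tot > 0) nsw / (tot / 60) else NA_real_,
                   n_switches = nsw, accepted_time = tot)
  })
}

#' Per-session behavioral summary
#'
#' Convenience wrapper joining [motion_ratio()] and [switch_rate()] per
#' trial with overall (time-weighted) aggregates.
#'
#' @inheritParams motion_ratio
#' @return list with `per_trial` tibble and `aggregate` (overall MR and
#'   mean switch rate).
#' @export
behavior_summary <- function(ev, exclude_start = 3, min_duration = 1) {
  mr <- motion_ratio(ev, exclude_start, min_duration)
  sw <- switch_rate(ev, exclude_start, min_duration)
  per_trial <- dplyr::left_join(mr, sw[c("trial", "switch_rate", "n_switches")],
                                by = "trial")
  ok <- !is.na(per_trial$mr)
  agg <- tibble::tibble(
    mr = sum(per_trial$mr[ok] * per_trial$accepted_time[ok]) /
      sum(per_trial$accepted_time[ok]),
    switch_rate = mean(per_trial$switch_rate[ok]),
    n_trials = sum(ok)
  )
  list(per_trial = per_trial, aggregate = agg)
}
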