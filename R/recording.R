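#' Construct a multichannel EEG recording
#'
#' A `recording` holds a channels x samples matrix in microvolts together with
#' its sampling rate, a channel layout, and condition metadata. All samples
#' must be finite and the row count must equal the layout's channel count.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param rate sampling rate in Hz.
#' @param layout a `channel_layout` (default [default_layout()]).
#' @param session `"in_phase"` or `"anti_phase"` (or `NA`).
#' @param condition one of `"sham"`, `"stimulation"`, `"post"`, `"resting"`
#'   (or `NA`).
#' @param rs_index resting-state block index 1--6 when `condition = "resting"`.
#' @return an object of class `recording`.
#' @export
new_recording <- function(data, rate, layout = default_layout(),
                          session = NA_character_, condition = NA_character_,
                          rs_index = NA_integer_) {
  stopifnot(is.matrix(data), is.numeric(data))
  if (!all(is.finite(data))) stop("recording data must be finite")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("rate must be a positive scalar (Hz)")
  }
  validate_layout(layout)
  if (nrow(data) != nrow(layout$channels)) {
    stop("row count (", nrow(data), ") must equal layout channel count (",
         nrow(layout$channels), ")")
  }
  if (!is.na(session) && !session %in% c("in_phase", "anti_phase")) {
    stop("session must be 'in_phase' or 'anti_phase'")
  }
  if (!is.na(condition) &&
      !condition %in% c("sham", "stimulation", "post", "resting")) {
    stop("condition must be one of sham/stimulation/post/resting")
  }
  rownames(data) <- layout$channels$name
  structure(
    list(data = data, rate = rate, layout = layout,
         session = session, condition = condition,
         rs_index = as.integer(rs_index)),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat("<recording> ", nrow(x$data), " channels x ", ncol(x$data),
      " samples @ ", x$rate, " Hz (", ncol(x$data) / x$rate, " s)",
      if (!is.na(x$condition)) paste0(", condition=", x$condition), "\n",
      sep = "")
  invisible(x)
}

#' Recording duration in seconds
#' @param rec a `recording`.
#' @export
duration <- function(rec) ncol(rec$data) / rec$rate

# ---- event streams ----------------------------------------------------------

event_labels <- function() {
  c("tacs_trigger", "dummy_trigger", "press_horizontal", "press_vertical",
    "trial_start", "trial_end", "blink_start", "blink_end")
}

#' Construct an event stream
#'
#' Time-ordered events (stimulation triggers, percept reports, trial
#' boundaries, blinks). Times are in seconds; labels are drawn from a fixed
#' vocabulary. Events are sorted on construction; non-finite times are
#' rejected, and every `trial_start` must be matched by a later `trial_end`.
#'
#' @param time numeric vector of event times (s).
#' @param label character vector of event labels.
#' @return a tibble of class `event_stream` with columns `time`, `label`.
#' @export
event_stream <- function(time = numeric(), label = character()) {
  stopifnot(length(time) == length(label))
  if (length(time) && !all(is.finite(time))) stop("event times must be finite")
  bad <- setdiff(unique(label), event_labels())
  if (length(bad)) {
    stop("unknown event label(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(event_labels(), collapse = ", "))
  }
  ord <- order(time)
  ev <- tibble::tibble(time = as.numeric(time[ord]), label = label[ord])
  ns <- sum(ev$label == "trial_start"); ne <- sum(ev$label == "trial_end")
  if (ns != ne) stop("every trial_start must have a matching trial_end")
  class(ev) <- c("event_stream", class(ev))
  ev
}

#' Trial intervals from an event stream
#'
#' @param ev an `event_stream`.
#' @return tibble with `trial`, `start`, `end` (seconds, half-open
#'   \[start, end)).
#' @export
trials_of <- function(ev) {
  starts <- ev$time[ev$label == "trial_start"]
  ends <- ev$time[ev$label == "trial_end"]
  stopifnot(length(starts) == length(ends), all(ends > starts))
  tibble::tibble(trial = seq_along(starts), start = starts, end = ends)
}
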