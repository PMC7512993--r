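#' Background-activity (spatio-temporal correlation) filter
#'
#' Standard DVS denoiser: uncorrelated low-frequency pixel activity (leak
#' and shot-noise events) is removed by requiring recent support in the
#' spatial neighborhood. An event is kept iff some earlier event occurred at
#' its own pixel or one of its 8 Moore neighbors (radius 1) within the
#' preceding `dt_us` microseconds. The test is causal and polarity-agnostic,
#' and every event — kept or dropped — refreshes the per-pixel
#' last-timestamp map, so a dropped event can still support a later
#' neighbor.
#'
#' The output is a subsequence of the input: order and timestamps are
#' untouched.
#'
#' @param stream A time-sorted [event_stream()].
#' @param dt_us Support window in microseconds (> 0). Default 20000 (20 ms),
#'   a common setting for DVS128 recordings.
#' @return The filtered [event_stream()].
#' @export
filter_background <- function(stream, dt_us = 20000) {
  validate_event_stream(stream)
  stopifnot(dt_us > 0)
  ev <- stream$events
  n <- nrow(ev)
  if (n == 0) return(stream)
  g <- stream$geometry
  # padded last-timestamp map; border avoids bounds checks
  map <- matrix(-Inf, g$height + 2L, g$width + 2L)
  keep <- logical(n)
  t <- ev$t; xi <- ev$x + 2L; yi <- ev$y + 2L  # 1-based + 1 pad
  for (i in seq_len(n)) {
    support <- max(map[(yi[i] - 1L):(yi[i] + 1L), (xi[i] - 1L):(xi[i] + 1L)])
    keep[i] <- (t[i] - support) <= dt_us
    map[yi[i], xi[i]] <- t[i]
  }
  event_stream(ev[keep, , drop = FALSE], g, stream$metadata)
}

#' Hot-pixel filter
#'
#' Removes pathologically active ("hot") pixels: an event is dropped iff the
#' number of events its pixel emitted in the trailing observation window
#' `(t - window_us, t]` of the raw input stream (the event itself included)
#' exceeds `max_events`. A hot pixel is thus suppressed from its first
#' offending event onward and passes again as soon as its raw rate falls
#' back under the limit; all other pixels pass unchanged. The output is a
#' subsequence of the input.
#'
#' @param stream A time-sorted [event_stream()].
#' @param window_us Observation window in microseconds (> 0).
#' @param max_events Maximum events per pixel per window (> 0).
#' @return The filtered [event_stream()].
#' @export
filter_hot_pixels <- function(stream, window_us = 100000, max_events = 200) {
  validate_event_stream(stream)
  stopifnot(window_us > 0, max_events > 0)
  ev <- stream$events
  n <- nrow(ev)
  if (n == 0) return(stream)
  g <- stream$geometry
  pix <- ev$y * g$width + ev$x
  keep <- logical(n)
  idx_by_pix <- split(seq_len(n), pix)
  for (idx in idx_by_pix) {
    tp <- ev$t[idx]
    if (length(idx) <= max_events) {
      keep[idx] <- TRUE
    } else {
      # events in (t_i - W, t_i]: i minus the count of times <= t_i - W
      cnt <- seq_along(tp) - findInterval(tp - window_us, tp)
      keep[idx] <- cnt <= max_events
    }
  }
  event_stream(ev[keep, , drop = FALSE], g, stream$metadata)
}
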