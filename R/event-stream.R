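#' Sensor geometry of an event camera
#'
#' Describes the pixel array of the sensor an event stream was recorded (or
#' synthesized) on. The default is the DVS128 profile used throughout the
#' package: a 128 x 128 pixel Dynamic Vision Sensor.
#'
#' @param width Number of pixel columns (> 0).
#' @param height Number of pixel rows (> 0).
#' @return An object of class `sensor_geometry`: a list with elements
#'   `width` and `height`.
#' @examples
#' sensor_geometry()          # DVS128
#' sensor_geometry(64, 64)
#' @export
sensor_geometry <- function(width = 128L, height = 128L) {
  width <- as.integer(width)
  height <- as.integer(height)
  if (is.na(width) || is.na(height) || width <= 0L || height <= 0L) {
    stop("sensor geometry requires positive integer width and height")
  }
  structure(list(width = width, height = height), class = "sensor_geometry")
}

#' @export
print.sensor_geometry <- function(x, ...) {
  cat(sprintf("<sensor_geometry> %d x %d pixels\n", x$width, x$height))
  invisible(x)
}

#' Polarity levels of a DVS event
#'
#' A DVS pixel emits an OFF event when its log intensity falls by more than
#' the comparator threshold since the memorized value, and an ON event when
#' it rises. `"OFF"` sorts before `"ON"`; this ordering is used wherever
#' events sharing a timestamp need a canonical order.
#' @format Character vector `c("OFF", "ON")`.
#' @export
EVENT_POLARITIES <- c("OFF", "ON")

# Coerce and validate a polarity vector to c("OFF","ON") values.
as_polarity <- function(p) {
  p <- as.character(p)
  bad <- !(p %in% EVENT_POLARITIES)
  if (any(bad)) {
    stop("polarity values must be 'ON' or 'OFF' (got: ",
         paste(utils::head(unique(p[bad]), 3), collapse = ", "), ")")
  }
  p
}

# Events table constructor (internal): plain data.frame with the canonical
# column order. t is kept as double so microsecond timestamps never overflow.
new_events <- function(t = numeric(), x = integer(), y = integer(),
                       polarity = character()) {
  data.frame(
    t = as.numeric(t),
    x = as.integer(x),
    y = as.integer(y),
    polarity = as_polarity(polarity),
    stringsAsFactors = FALSE
  )
}

#' Construct an AER event stream
#'
#' An `event_stream` binds a time-ordered table of address events
#' (timestamp in microseconds, pixel address, polarity) to the geometry of
#' the sensor that produced them. All package functions that consume AER
#' traffic take and return this container.
#'
#' @param events A data.frame with columns `t` (microseconds, numeric,
#'   non-decreasing), `x`, `y` (0-based pixel address, origin at the
#'   lower-left pixel) and `polarity` (`"ON"` or `"OFF"`). Defaults to an
#'   empty table.
#' @param geometry A [sensor_geometry()].
#' @param metadata Optional named list carried along unchanged (stimulus
#'   parameters, phase boundaries, ...).
#' @return An object of class `event_stream`: a list with elements `events`,
#'   `geometry` and `metadata`.
#' @seealso [read_events()], [write_events()], [make_stimulus()]
#' @examples
#' ev <- data.frame(t = c(0, 10), x = 3:4, y = 5L, polarity = "OFF")
#' event_stream(ev)
#' @export
event_stream <- function(events = NULL, geometry = sensor_geometry(),
                         metadata = list()) {
  if (is.null(events)) events <- new_events()
  if (!inherits(geometry, "sensor_geometry")) {
    stop("`geometry` must be a sensor_geometry object")
  }
  req <- c("t", "x", "y", "polarity")
  if (!is.data.frame(events) || !all(req %in% names(events))) {
    stop("`events` must be a data.frame with columns t, x, y, polarity")
  }
  events <- new_events(events$t, events$x, events$y, events$polarity)
  s <- structure(list(events = events, geometry = geometry,
                      metadata = metadata),
                 class = "event_stream")
  validate_event_stream(s)
  s
}

#' Validate an event stream
#'
#' Checks the container invariants: coordinates inside the sensor geometry,
#' non-negative timestamps in non-decreasing order, legal polarity values.
#' Called by the constructor and by the writers; exposed so user code can
#' re-check streams assembled by hand.
#'
#' @param stream An `event_stream`.
#' @return `stream`, invisibly; errors if an invariant is violated.
#' @export
validate_event_stream <- function(stream) {
  if (!inherits(stream, "event_stream")) stop("not an event_stream")
  ev <- stream$events
  g <- stream$geometry
  if (nrow(ev) == 0) return(invisible(stream))
  if (anyNA(ev$t) || any(ev$t < 0)) stop("event timestamps must be >= 0")
  if (is.unsorted(ev$t)) stop("event timestamps must be non-decreasing")
  if (any(ev$x < 0L | ev$x >= g$width)) {
    stop(sprintf("event x address out of range [0, %d)", g$width))
  }
  if (any(ev$y < 0L | ev$y >= g$height)) {
    stop(sprintf("event y address out of range [0, %d)", g$height))
  }
  as_polarity(ev$polarity)
  invisible(stream)
}

#' @export
print.event_stream <- function(x, ...) {
  ev <- x$events
  cat(sprintf("<event_stream> %d events on a %d x %d sensor\n",
              nrow(ev), x$geometry$width, x$geometry$height))
  if (nrow(ev) > 0) {
    cat(sprintf("  time span: %.0f .. %.0f us  (%.1f ms)\n",
                min(ev$t), max(ev$t), (max(ev$t) - min(ev$t)) / 1000))
    cat(sprintf("  polarity:  %d OFF / %d ON\n",
                sum(ev$polarity == "OFF"), sum(ev$polarity == "ON")))
  }
  if (length(x$metadata)) {
    cat("  metadata:  ", paste(names(x$metadata), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of events in a stream
#' @param stream An `event_stream`.
#' @return Integer event count.
#' @export
n_events <- function(stream) {
  stopifnot(inherits(stream, "event_stream"))
  nrow(stream$events)
}

#' Shift all timestamps of a stream
#'
#' @param stream An `event_stream`.
#' @param dt_us Offset in microseconds added to every timestamp (the result
#'   must remain non-negative).
#' @return The shifted `event_stream`.
#' @export
shift_stream <- function(stream, dt_us) {
  stopifnot(inherits(stream, "event_stream"))
  ev <- stream$events
  ev$t <- ev$t + dt_us
  event_stream(ev, stream$geometry, stream$metadata)
}

#' Concatenate event streams in time
#'
#' Streams must share a geometry and already be in global time order
#' (the first event of each stream must not precede the last event of the
#' previous one).
#'
#' @param ... `event_stream` objects.
#' @param metadata Metadata list for the result (default: metadata of the
#'   first stream).
#' @return A single `event_stream`.
#' @export
concat_streams <- function(..., metadata = NULL) {
  streams <- list(...)
  stopifnot(length(streams) > 0,
            all(vapply(streams, inherits, TRUE, "event_stream")))
  g <- streams[[1]]$geometry
  for (s in streams) {
    if (s$geometry$width != g$width || s$geometry$height != g$height) {
      stop("cannot concatenate streams with different geometries")
    }
  }
  ev <- do.call(rbind, lapply(streams, function(s) s$events))
  if (is.null(metadata)) metadata <- streams[[1]]$metadata
  event_stream(ev, g, metadata)
}

#' Tile a stream periodically in time
#'
#' Repeats a recording `n` times, offsetting copy `i` by
#' `(i - 1) * period_us`. This mirrors stimulating a cell with the
#' continuous repetition of a short recording, the protocol used for the
#' response-determinism (entropy) analysis.
#'
#' @param stream An `event_stream`.
#' @param n Number of repetitions (>= 1).
#' @param period_us Repetition period in microseconds; defaults to the
#'   stream's `metadata$period_us`, else the stream duration rounded up to
#'   the next millisecond.
#' @return An `event_stream` with `n * n_events(stream)` events and metadata
#'   fields `period_us` and `n_iterations`.
#' @export
repeat_stream <- function(stream, n, period_us = NULL) {
  stopifnot(inherits(stream, "event_stream"), n >= 1)
  if (is.null(period_us)) period_us <- stream$metadata$period_us
  if (is.null(period_us)) {
    period_us <- 1000 * ceiling((max(stream$events$t) + 1) / 1000)
  }
  if (n_events(stream) > 0 && max(stream$events$t) >= period_us) {
    stop("period_us must exceed the last event timestamp")
  }
  copies <- lapply(seq_len(n) - 1, function(i) {
    ev <- stream$events
    ev$t <- ev$t + i * period_us
    ev
  })
  md <- stream$metadata
  md$period_us <- period_us
  md$n_iterations <- as.integer(n)
  event_stream(do.call(rbind, copies), stream$geometry, md)
}
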