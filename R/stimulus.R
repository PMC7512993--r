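#' Parametric description of a moving / scaling object stimulus
#'
#' Describes a hard-edged two-level stimulus (a disc or a square of uniform
#' intensity on a uniform background) whose center and radius follow
#' piecewise-linear trajectories. A dense frame sequence is rendered from it
#' by [render_frames()] and converted to DVS events by [frames_to_events()].
#'
#' @param shape `"disc"` or `"square"` (the "radius" of a square is its
#'   half-side).
#' @param contrast `"dark-on-light"` (object darker than background, the
#'   configuration that drives the approach cell with OFF events) or
#'   `"light-on-dark"`.
#' @param center_traj data.frame with columns `t_us`, `cx`, `cy`: breakpoints
#'   of the object center, linearly interpolated (time-sorted).
#' @param size_traj data.frame with columns `t_us`, `radius`: breakpoints of
#'   the object radius in pixels (>= 0, time-sorted).
#' @param frame_interval_us Rendering step in microseconds.
#' @param threshold Per-pixel log-intensity event threshold (> 0),
#'   dimensionless (natural-log units).
#' @param background_level,object_level Positive linear intensity levels.
#' @return An object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(shape = c("disc", "square"),
                          contrast = c("dark-on-light", "light-on-dark"),
                          center_traj,
                          size_traj,
                          frame_interval_us = 10000,
                          threshold = 0.35,
                          background_level = 1.0,
                          object_level = 0.5) {
  shape <- match.arg(shape)
  contrast <- match.arg(contrast)
  stopifnot(is.data.frame(center_traj),
            all(c("t_us", "cx", "cy") %in% names(center_traj)),
            is.data.frame(size_traj),
            all(c("t_us", "radius") %in% names(size_traj)))
  if (is.unsorted(center_traj$t_us) || is.unsorted(size_traj$t_us)) {
    stop("trajectory breakpoints must be time-sorted")
  }
  if (any(size_traj$radius < 0)) stop("radius must be >= 0 at all breakpoints")
  if (frame_interval_us <= 0) stop("frame_interval_us must be > 0")
  if (threshold <= 0) stop("threshold must be > 0")
  if (background_level <= 0 || object_level <= 0) {
    stop("intensity levels must be > 0")
  }
  if (contrast == "dark-on-light" && object_level >= background_level) {
    stop("dark-on-light requires object_level < background_level")
  }
  if (contrast == "light-on-dark" && object_level <= background_level) {
    stop("light-on-dark requires object_level > background_level")
  }
  structure(list(shape = shape, contrast = contrast,
                 center_traj = center_traj, size_traj = size_traj,
                 frame_interval_us = frame_interval_us,
                 threshold = threshold,
                 background_level = background_level,
                 object_level = object_level),
            class = "stimulus_spec")
}

# piecewise-linear interpolation of a trajectory column at given times
interp_traj <- function(t_us, v, times) {
  if (length(t_us) == 1) return(rep(v, length(times)))
  stats::approx(t_us, v, xout = times, rule = 2)$y
}

#' Render a stimulus to dense intensity frames
#'
#' One frame is produced per `frame_interval_us` over the union of the
#' trajectory time spans. Pixels whose center (integer coordinates, 0-based,
#' origin lower-left) falls inside the open shape region (distance strictly
#' less than the radius, so a zero radius covers nothing) get
#' `object_level`, all others `background_level` (hard edge, no blur).
#'
#' @param spec A [stimulus_spec()].
#' @param geometry A [sensor_geometry()].
#' @return An object of class `frame_sequence`: list with `times_us`
#'   (numeric vector) and `frames` (list of `height x width` matrices,
#'   row `i` = pixel row `y = i - 1`), plus the geometry.
#' @export
render_frames <- function(spec, geometry = sensor_geometry()) {
  stopifnot(inherits(spec, "stimulus_spec"))
  t0 <- min(spec$center_traj$t_us[1], spec$size_traj$t_us[1])
  t1 <- max(spec$center_traj$t_us[nrow(spec$center_traj)],
            spec$size_traj$t_us[nrow(spec$size_traj)])
  if (t1 <= t0) stop("degenerate stimulus duration")
  times <- seq(t0, t1, by = spec$frame_interval_us)
  cx <- interp_traj(spec$center_traj$t_us, spec$center_traj$cx, times)
  cy <- interp_traj(spec$center_traj$t_us, spec$center_traj$cy, times)
  r <- interp_traj(spec$size_traj$t_us, spec$size_traj$radius, times)
  xs <- matrix(rep(0:(geometry$width - 1), each = geometry$height),
               nrow = geometry$height)
  ys <- matrix(rep(0:(geometry$height - 1), times = geometry$width),
               nrow = geometry$height)
  frames <- vector("list", length(times))
  any_inside <- FALSE
  for (k in seq_along(times)) {
    inside <- if (spec$shape == "disc") {
      (xs - cx[k])^2 + (ys - cy[k])^2 < r[k]^2
    } else {
      pmax(abs(xs - cx[k]), abs(ys - cy[k])) < r[k]
    }
    f <- matrix(spec$background_level, geometry$height, geometry$width)
    f[inside] <- spec$object_level
    frames[[k]] <- f
    any_inside <- any_inside || any(inside)
  }
  if (!any_inside) {
    warning("object never intersects the sensor over the whole trajectory")
  }
  structure(list(times_us = times, frames = frames, geometry = geometry),
            class = "frame_sequence")
}

#' Convert dense intensity frames to DVS events
#'
#' Emulates the DVS pixel principle: each pixel memorizes a log intensity;
#' when the current log intensity differs from the memorized value by at
#' least `threshold`, it emits `floor(|difference| / threshold)` events of
#' the corresponding polarity (OFF for darkening, ON for brightening) and
#' the memorized value moves by that integer number of threshold steps
#' toward the new value, so a large step produces a burst. Pixel memories
#' are initialized from the first frame, which therefore emits nothing.
#'
#' Events within one frame all carry the frame timestamp and are ordered by
#' `(y, x, polarity)` (OFF before ON) for reproducibility. An optional
#' seeded uniform jitter in `[0, jitter_us)` can be added to each event
#' timestamp (events are then re-sorted stably by time).
#'
#' @param frameseq A `frame_sequence` from [render_frames()].
#' @param threshold Log-intensity threshold (> 0).
#' @param jitter_us Upper bound of uniform timestamp jitter (0 = none; keep
#'   it below the frame interval to preserve frame ordering).
#' @return An [event_stream()].
#' @export
frames_to_events <- function(frameseq, threshold, jitter_us = 0) {
  stopifnot(inherits(frameseq, "frame_sequence"), threshold > 0)
  g <- frameseq$geometry
  mem <- log(frameseq$frames[[1]])
  # xs/ys matching the frame matrix layout (row i = y i-1, col j = x j-1)
  ys <- matrix(rep(0:(g$height - 1), times = g$width), nrow = g$height)
  xs <- matrix(rep(0:(g$width - 1), each = g$height), nrow = g$height)
  out <- vector("list", length(frameseq$frames))
  for (k in seq_along(frameseq$frames)[-1]) {
    d <- log(frameseq$frames[[k]]) - mem
    steps <- floor(abs(d) / threshold)
    hit <- which(steps > 0)
    if (length(hit)) {
      sgn <- sign(d[hit])
      mem[hit] <- mem[hit] + sgn * steps[hit] * threshold
      df <- data.frame(
        t = frameseq$times_us[k],
        x = xs[hit], y = ys[hit],
        polarity = ifelse(sgn < 0, "OFF", "ON"),
        n = steps[hit], stringsAsFactors = FALSE)
      df <- df[order(df$y, df$x, df$polarity), ]
      idx <- rep(seq_len(nrow(df)), df$n)
      out[[k]] <- df[idx, c("t", "x", "y", "polarity")]
    }
  }
  ev <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(ev)) ev <- new_events()
  if (jitter_us > 0 && nrow(ev) > 0) {
    ev$t <- ev$t + floor(stats::runif(nrow(ev), 0, jitter_us))
    ev <- ev[order(ev$t), ]
  }
  event_stream(ev, g)
}

#' Synthesize a canonical approach / recede / lateral DVS stimulus
#'
#' Convenience wrapper composing [stimulus_spec()], [render_frames()] and
#' [frames_to_events()] for the three motion archetypes used to probe the
#' approach cell, plus their concatenation:
#'
#' * `"approach"`: a dark disc expanding from `r_start` to `r_end` px over
#'   `duration_us` — the looming stimulus; it emits OFF events along the
#'   expanding contour.
#' * `"recede"`: the time reverse (contracting disc, ON events).
#' * `"lateral"`: a rigid disc translating across the field at an integer
#'   number of pixels per frame, emitting equal OFF (leading edge) and ON
#'   (trailing edge) counts.
#' * `"approach_recede"`: approach, a silent gap of `gap_us`, recede, and a
#'   trailing gap; the metadata records `phase_boundary_us` (start of the
#'   recede phase) and `period_us` (total span) so the stream can be tiled
#'   with [repeat_stream()] for the determinism analysis.
#'
#' @param kind One of `"approach"`, `"recede"`, `"lateral"`,
#'   `"approach_recede"`.
#' @param geometry A [sensor_geometry()].
#' @param duration_us Duration of one motion phase.
#' @param r_start,r_end Disc radius range in pixels (must fit the sensor).
#' @param center `c(cx, cy)` of the (stationary) disc center for
#'   approach/recede; the vertical position of the lateral path.
#' @param px_per_frame Lateral speed, integer pixels per frame.
#' @param gap_us Silent gap after each phase of `approach_recede`.
#' @param frame_interval_us,threshold,background_level,object_level,jitter_us
#'   Passed through to the underlying generator.
#' @return An [event_stream()] with stimulus metadata.
#' @examples
#' s <- make_stimulus("approach", duration_us = 1e5, r_start = 4, r_end = 12)
#' table(s$events$polarity)
#' @export
make_stimulus <- function(kind = c("approach", "recede", "lateral",
                                   "approach_recede"),
                          geometry = sensor_geometry(),
                          duration_us = 400000,
                          r_start = 6, r_end = 48,
                          center = c(63.5, 63.5),
                          px_per_frame = 2L,
                          gap_us = 100000,
                          frame_interval_us = 10000,
                          threshold = 0.35,
                          background_level = 1.0,
                          object_level = 0.5,
                          jitter_us = 0) {
  kind <- match.arg(kind)
  if (duration_us < 2 * frame_interval_us) {
    stop("degenerate duration: need at least two frame intervals")
  }
  if (max(r_start, r_end) > min(geometry$width, geometry$height) / 2) {
    stop("object size range does not fit within the sensor")
  }
  fixed_center <- function() {
    data.frame(t_us = c(0, duration_us), cx = center[1], cy = center[2])
  }
  one <- function(size_traj, center_traj) {
    spec <- stimulus_spec("disc", "dark-on-light",
                          center_traj = center_traj, size_traj = size_traj,
                          frame_interval_us = frame_interval_us,
                          threshold = threshold,
                          background_level = background_level,
                          object_level = object_level)
    frames_to_events(render_frames(spec, geometry), threshold, jitter_us)
  }
  grow <- data.frame(t_us = c(0, duration_us), radius = c(r_start, r_end))
  shrink <- data.frame(t_us = c(0, duration_us), radius = c(r_end, r_start))

  md <- list(kind = kind, duration_us = duration_us,
             r_start = r_start, r_end = r_end,
             frame_interval_us = frame_interval_us, threshold = threshold)
  if (kind == "approach") {
    s <- one(grow, fixed_center())
  } else if (kind == "recede") {
    s <- one(shrink, fixed_center())
  } else if (kind == "lateral") {
    px_per_frame <- as.integer(px_per_frame)
    if (px_per_frame < 1L) stop("px_per_frame must be a positive integer")
    n_frames <- floor(duration_us / frame_interval_us)
    travel <- px_per_frame * n_frames
    x0 <- (geometry$width - 1) / 2 - travel / 2
    ctraj <- data.frame(t_us = c(0, n_frames * frame_interval_us),
                        cx = c(x0, x0 + travel), cy = center[2])
    radius <- min(r_start, r_end)
    if (x0 - radius < 0 || x0 + travel + radius > geometry$width - 1) {
      stop("lateral path does not fit within the sensor")
    }
    s <- one(data.frame(t_us = c(0, n_frames * frame_interval_us),
                        radius = radius), ctraj)
    md$px_per_frame <- px_per_frame
  } else { # approach_recede
    ap <- one(grow, fixed_center())
    re <- one(shrink, fixed_center())
    boundary <- duration_us + gap_us
    re <- shift_stream(re, boundary)
    md$phase_boundary_us <- boundary
    md$gap_us <- gap_us
    md$period_us <- 2 * (duration_us + gap_us)
    s <- concat_streams(ap, re, metadata = md)
    s$metadata <- md
    return(s)
  }
  s$metadata <- md
  s
}
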