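# Time unit for membrane integration: dT in the membrane update is the
# inter-event interval expressed in milliseconds (us / 1000), so that O(1)
# synaptic weights and thresholds in the low thousands are natural scales.
AC_TIME_UNIT_US <- 1000

#' Parameters of the Approach Sensitivity Cell model
#'
#' The AC pools a grid of `n_side x n_side` subunits, each accumulating the
#' ON and OFF events of its `rf_side x rf_side` pixel receptive field into
#' separate potentials. OFF subunits excite the cell (weight `g_off`), ON
#' subunits inhibit it (weight `g_on`); subunit potentials are half
#' rectified, optionally passed through a center-surround subtraction that
#' nulls spatially uniform dimming, summed into a net current, and
#' integrated by a leak-free membrane that fires by threshold crossing (IF)
#' or by comparison against a uniform random draw (Poisson).
#'
#' Defaults are calibrated for the package's canonical DVS128 looming
#' stimuli (see the methods vignette); like the hardware registers they
#' mirror, they are meant to be re-tuned per scenario.
#'
#' @param n_side Subunits per side (`n`); `n_side * rf_side` must equal the
#'   sensor side length (DVS128: 8 * 16 = 128).
#' @param rf_side Pixels per subunit side (`m`).
#' @param g_on Inhibitory (ON) weight, >= 0.
#' @param g_off Excitatory (OFF) weight, >= 0.
#' @param synaptic_weight Potential increment per input event, >= 0.
#' @param if_threshold Membrane firing threshold (strict crossing).
#' @param firing_mode `"IF"` (deterministic) or `"Poisson"` (threshold
#'   replaced by a uniform draw on `[0, if_threshold]`).
#' @param max_firing_rate Maximum output rate in Hz, implemented as an
#'   absolute refractory interval of `1e6 / max_firing_rate` microseconds.
#' @param decay_period_us Period of the shared multiplicative subunit decay.
#' @param decay_factor Multiplicative decay factor in `[0, 1)` applied to
#'   every subunit potential once per elapsed period.
#' @param surround_enabled Apply the center-surround subtraction to the OFF
#'   potentials before pooling.
#' @param polarity_swap Swap ON/OFF roles of incoming events (for scenes
#'   where an approaching object brightens rather than darkens pixels).
#' @param rng_seed Seed for the Poisson-mode draws.
#' @param dt_max_us Saturation bound on the inter-event interval entering
#'   the membrane update (the hardware's inter-event counter is
#'   finite-width); defaults to `decay_period_us`.
#' @return An object of class `ac_params`.
#' @export
ac_params <- function(n_side = 8L, rf_side = 16L,
                      g_on = 1, g_off = 1,
                      synaptic_weight = 1,
                      if_threshold = 1500,
                      firing_mode = c("IF", "Poisson"),
                      max_firing_rate = 60,
                      decay_period_us = 20000,
                      decay_factor = 0.6,
                      surround_enabled = TRUE,
                      polarity_swap = FALSE,
                      rng_seed = 1L,
                      dt_max_us = NULL) {
  firing_mode <- match.arg(firing_mode)
  n_side <- as.integer(n_side); rf_side <- as.integer(rf_side)
  stopifnot(n_side >= 1L, rf_side >= 1L,
            g_on >= 0, g_off >= 0, synaptic_weight >= 0,
            if_threshold > 0, max_firing_rate > 0,
            decay_period_us > 0,
            decay_factor >= 0, decay_factor < 1)
  if (is.null(dt_max_us)) dt_max_us <- decay_period_us
  stopifnot(dt_max_us > 0)
  structure(list(n_side = n_side, rf_side = rf_side,
                 g_on = g_on, g_off = g_off,
                 synaptic_weight = synaptic_weight,
                 if_threshold = if_threshold,
                 firing_mode = firing_mode,
                 max_firing_rate = max_firing_rate,
                 refractory_us = 1e6 / max_firing_rate,
                 decay_period_us = decay_period_us,
                 decay_factor = decay_factor,
                 surround_enabled = isTRUE(surround_enabled),
                 polarity_swap = isTRUE(polarity_swap),
                 rng_seed = as.integer(rng_seed),
                 dt_max_us = dt_max_us),
            class = "ac_params")
}

#' Fresh subunit grid
#'
#' @param n_side Subunits per side.
#' @return List with `v_on` and `v_off` (`n_side x n_side` zero matrices)
#'   and `t_last_decay` (`NA` until the first event arrives).
#' @export
new_subunit_grid <- function(n_side) {
  z <- matrix(0, n_side, n_side)
  list(v_on = z, v_off = z, t_last_decay = NA_real_)
}

#' Fresh AC membrane state
#'
#' @return List with `v_mem` (0), `i_net` (0), `t_last_event` (`NA`),
#'   `t_last_spike` (`-Inf`).
#' @export
new_ac_state <- function() {
  list(v_mem = 0, i_net = 0, t_last_event = NA_real_, t_last_spike = -Inf)
}

#' Map a pixel address to its subunit
#'
#' Each subunit owns an `rf_side x rf_side` block of pixels; pixel `(x, y)`
#' (0-based) belongs to subunit row `floor(y / rf_side) + 1`, column
#' `floor(x / rf_side) + 1` (1-based grid indices, R convention).
#'
#' @param x,y Pixel addresses (vectorized).
#' @param rf_side Pixels per subunit side.
#' @return data.frame with columns `row`, `col` (1-based).
#' @examples
#' subunit_index(0, 0, 16)      # (1, 1)
#' subunit_index(127, 127, 16)  # (8, 8)
#' @export
subunit_index <- function(x, y, rf_side) {
  data.frame(row = as.integer(y) %/% as.integer(rf_side) + 1L,
             col = as.integer(x) %/% as.integer(rf_side) + 1L)
}

#' Half rectification
#'
#' Threshold-linear nonlinearity `max(0, v)` applied to subunit potentials
#' before they are pooled; local strong excitation therefore cannot be
#' cancelled by weak global inhibition.
#'
#' @param v Numeric vector or matrix.
#' @return `pmax(v, 0)`, same shape.
#' @export
rectify <- function(v) pmax(v, 0)

#' Number of von Neumann neighbors of a subunit
#'
#' The center-surround subtraction averages over the 4-connected neighbors
#' that exist: 4 in the grid interior, 3 on an edge, 2 in a corner, and 0
#' for a degenerate 1 x 1 grid.
#'
#' @param row,col 1-based grid position (vectorized).
#' @param n_side Grid side length.
#' @return Integer neighbor count(s).
#' @examples
#' surround_neighbors(1, 1, 8)  # corner: 2
#' surround_neighbors(4, 4, 8)  # interior: 4
#' surround_neighbors(1, 1, 1)  # singleton grid: 0
#' @export
surround_neighbors <- function(row, col, n_side) {
  stopifnot(all(row >= 1), all(col >= 1), all(row <= n_side),
            all(col <= n_side))
  (row > 1) + (row < n_side) + (col > 1) + (col < n_side)
}

#' Center-surround effective potentials
#'
#' For each subunit, subtracts from its (rectified) OFF potential the mean
#' of the rectified OFF potentials of its existing von Neumann neighbors,
#' then rectifies again. A spatially uniform potential field (global
#' dimming of the scene) therefore yields zero everywhere, which is the
#' purpose of the scheme. With no neighbors (1 x 1 grid) the center passes
#' through unchanged.
#'
#' @param v_off `n x n` matrix of OFF potentials.
#' @param row,col Optional 1-based position; if given, the scalar effective
#'   potential of that subunit is returned instead of the full matrix.
#' @return Matrix of effective potentials (or a scalar).
#' @export
center_surround <- function(v_off, row = NULL, col = NULL) {
  stopifnot(is.matrix(v_off), nrow(v_off) == ncol(v_off))
  n <- nrow(v_off)
  r <- rectify(v_off)
  if (n == 1) {
    eff <- r
  } else {
    up <- rbind(r[-1, , drop = FALSE], 0)
    down <- rbind(0, r[-n, , drop = FALSE])
    left <- cbind(0, r[, -n, drop = FALSE])
    right <- cbind(r[, -1, drop = FALSE], 0)
    rows <- matrix(seq_len(n), n, n)
    cols <- matrix(seq_len(n), n, n, byrow = TRUE)
    cnt <- surround_neighbors(rows, cols, n)
    eff <- rectify(r - (up + down + left + right) / cnt)
  }
  if (!is.null(row)) {
    stopifnot(!is.null(col))
    return(eff[row, col])
  }
  eff
}

#' Net synaptic current into the AC
#'
#' `I_net = g_off * sum(effective OFF potentials) - g_on * sum(rectified ON
#' potentials)`, where the effective OFF potentials are the
#' [center_surround()] output when surround suppression is enabled and the
#' plain rectified OFF potentials otherwise. Balanced ON/OFF drive under
#' equal weights (lateral motion) cancels to zero.
#'
#' @param grid A subunit grid (see [new_subunit_grid()]).
#' @param params An [ac_params()].
#' @return Scalar net current.
#' @export
net_input <- function(grid, params) {
  eff_off <- if (params$surround_enabled) {
    center_surround(grid$v_off)
  } else {
    rectify(grid$v_off)
  }
  params$g_off * sum(eff_off) - params$g_on * sum(rectify(grid$v_on))
}

#' Deposit one event into its subunit
#'
#' The event's polarity (after the optional polarity swap) selects the ON or
#' OFF potential of the subunit owning its pixel, which increases by
#' `synaptic_weight`; all other entries are untouched.
#'
#' @param grid A subunit grid.
#' @param x,y,polarity The event's address and polarity.
#' @param params An [ac_params()].
#' @return The updated grid.
#' @export
update_subunit <- function(grid, x, y, polarity, params) {
  su <- subunit_index(x, y, params$rf_side)
  pol <- as_polarity(polarity)
  if (params$polarity_swap) pol <- ifelse(pol == "ON", "OFF", "ON")
  if (pol == "ON") {
    grid$v_on[su$row, su$col] <- grid$v_on[su$row, su$col] +
      params$synaptic_weight
  } else {
    grid$v_off[su$row, su$col] <- grid$v_off[su$row, su$col] +
      params$synaptic_weight
  }
  grid
}

#' Periodic shared decay of the subunit grid
#'
#' For each full `decay_period_us` elapsed since the last decay, every ON
#' and OFF potential is multiplied by `decay_factor` (k elapsed periods
#' apply `decay_factor^k`); `t_last_decay` advances by exactly
#' `k * decay_period_us` so phase is preserved. The decay clock starts at
#' the first event's timestamp.
#'
#' @param grid A subunit grid.
#' @param t_now Current time, microseconds.
#' @param params An [ac_params()].
#' @return The decayed grid.
#' @export
decay_subunits <- function(grid, t_now, params) {
  if (is.na(grid$t_last_decay)) {
    grid$t_last_decay <- t_now
    return(grid)
  }
  k <- floor((t_now - grid$t_last_decay) / params$decay_period_us)
  if (k > 0) {
    f <- params$decay_factor^k
    grid$v_on <- grid$v_on * f
    grid$v_off <- grid$v_off * f
    grid$t_last_decay <- grid$t_last_decay + k * params$decay_period_us
  }
  grid
}

#' Integrate the AC membrane
#'
#' Leak-free integration `v_mem <- max(0, v_mem + i_net * dT)` where `dT`
#' is the interval since the previously processed input event, saturated at
#' `dt_max_us` and expressed in milliseconds (`us / 1000`). The membrane is
#' clamped at zero from below; the first event of a stream integrates over
#' `dT = 0`. During the absolute refractory interval after a spike
#' (`1e6 / max_firing_rate` microseconds) the membrane is held at its reset
#' value, the usual convention for integrate-and-fire models; integration
#' resumes with the first event after the interval elapses.
#'
#' @param state An AC state (see [new_ac_state()]).
#' @param i_net Net synaptic current.
#' @param t_now Current time, microseconds (must not precede
#'   `state$t_last_event`).
#' @param params An [ac_params()].
#' @return The updated state (`v_mem`, `i_net`, `t_last_event`).
#' @export
integrate_membrane <- function(state, i_net, t_now, params) {
  if (!is.na(state$t_last_event) && t_now < state$t_last_event) {
    stop("out-of-order timestamp: events must be processed in time order")
  }
  dt_us <- if (is.na(state$t_last_event)) 0 else t_now - state$t_last_event
  dt <- min(dt_us, params$dt_max_us) / AC_TIME_UNIT_US
  if (t_now - state$t_last_spike < params$refractory_us) {
    state$v_mem <- 0
  } else {
    state$v_mem <- max(0, state$v_mem + i_net * dt)
  }
  state$i_net <- i_net
  state$t_last_event <- t_now
  state
}

#' Threshold comparison and firing
#'
#' IF mode: the cell fires iff `v_mem` strictly exceeds `if_threshold`.
#' Poisson mode: iff `v_mem` strictly exceeds a uniform draw on
#' `[0, if_threshold]` (drawn from R's RNG, so runs are reproducible under
#' a seed). Firing is suppressed while `t_now - t_last_spike` is shorter
#' than the refractory interval `1e6 / max_firing_rate`; the draw is only
#' consumed outside the refractory period. On firing, `v_mem` resets to 0
#' and `t_last_spike` is set to `t_now`.
#'
#' @param state An AC state.
#' @param params An [ac_params()].
#' @param t_now Current time, microseconds.
#' @return List with elements `state` and `fired` (logical).
#' @export
check_fire <- function(state, params, t_now) {
  fired <- FALSE
  if (t_now - state$t_last_spike >= params$refractory_us) {
    thr <- if (params$firing_mode == "Poisson") {
      stats::runif(1, 0, params$if_threshold)
    } else {
      params$if_threshold
    }
    if (state$v_mem > thr) {
      fired <- TRUE
      state$v_mem <- 0
      state$t_last_spike <- t_now
    }
  }
  list(state = state, fired = fired)
}

#' Fresh AC model (parameters + zeroed grid and state)
#'
#' @param params An [ac_params()].
#' @return An object of class `ac_model` with elements `params`, `grid`,
#'   `state`, `fired` (result of the last processed event).
#' @export
ac_model <- function(params = ac_params()) {
  stopifnot(inherits(params, "ac_params"))
  structure(list(params = params,
                 grid = new_subunit_grid(params$n_side),
                 state = new_ac_state(),
                 fired = FALSE),
            class = "ac_model")
}

#' Process one input event through the AC state machine
#'
#' Executes, in the order of the hardware state machine: timestamp-driven
#' subunit decay, subunit potential update (`OnEvent`/`OffEvent`),
#' center-surround input computation, net synaptic current, membrane
#' integration, and threshold comparison. When the cell fires, an output
#' spike at the input event's timestamp is indicated by `fired`.
#'
#' @param model An [ac_model()].
#' @param event A list or one-row data.frame with fields `t`, `x`, `y`,
#'   `polarity`. Events must be presented in non-decreasing time order.
#' @return The updated `ac_model`; inspect `$fired` and `$state`.
#' @export
process_event <- function(model, event) {
  stopifnot(inherits(model, "ac_model"))
  p <- model$params
  t_now <- as.numeric(event$t)
  model$grid <- decay_subunits(model$grid, t_now, p)
  model$grid <- update_subunit(model$grid, event$x, event$y, event$polarity, p)
  i_net <- net_input(model$grid, p)
  model$state <- integrate_membrane(model$state, i_net, t_now, p)
  res <- check_fire(model$state, p, t_now)
  model$state <- res$state
  model$fired <- res$fired
  model
}

#' Run the Approach Sensitivity Cell over an event stream
#'
#' Folds [process_event()] over the stream and collects the output spike
#' train (and, optionally, a per-event trace of net current and membrane
#' potential). Two engines implement identical semantics: `"cpp"` (compiled
#' event loop, the default) and `"r"` (composition of the exported
#' per-operation functions; useful as a readable reference and for
#' cross-checking). In Poisson mode the RNG is seeded from
#' `params$rng_seed`, so runs are reproducible and both engines draw the
#' same numbers.
#'
#' @param params An [ac_params()]; `n_side * rf_side` must equal the sensor
#'   side length of `stream`.
#' @param stream An [event_stream()] with non-decreasing timestamps.
#' @param engine `"cpp"` or `"r"`.
#' @param trace Record `(t_us, i_net, v_mem, fired)` for every input event
#'   (membrane potential after any reset).
#' @return An object of class `ac_output`: list with `spikes` (an
#'   [event_stream()] of output events at the reserved address `(0, 0)`,
#'   polarity `ON`), `trace` (data.frame or `NULL`), `params`, and
#'   `n_input_events`.
#' @examples
#' s <- make_stimulus("approach", duration_us = 2e5, r_start = 6, r_end = 30)
#' out <- ac_run(ac_params(), s)
#' n_events(out$spikes)
#' @export
ac_run <- function(params, stream, engine = c("cpp", "r"), trace = FALSE) {
  stopifnot(inherits(params, "ac_params"))
  validate_event_stream(stream)
  engine <- match.arg(engine)
  g <- stream$geometry
  if (g$width != g$height ||
      params$n_side * params$rf_side != g$width) {
    stop(sprintf(
      "geometry mismatch: n_side * rf_side = %d but sensor side is %d x %d",
      params$n_side * params$rf_side, g$width, g$height))
  }
  ev <- stream$events
  if (params$firing_mode == "Poisson") set.seed(params$rng_seed)
  if (engine == "cpp") {
    res <- ac_run_cpp(ev$t, ev$x, ev$y,
                      as.integer(ev$polarity == "ON"),
                      params$n_side, params$rf_side,
                      params$g_on, params$g_off, params$synaptic_weight,
                      params$if_threshold,
                      params$firing_mode == "Poisson",
                      params$refractory_us,
                      params$decay_period_us, params$decay_factor,
                      params$surround_enabled, params$polarity_swap,
                      AC_TIME_UNIT_US, params$dt_max_us, trace)
    fired <- res$fired
    tr <- if (trace) {
      data.frame(t_us = ev$t, i_net = res$i_net, v_mem = res$v_mem,
                 fired = res$fired)
    }
  } else {
    m <- ac_model(params)
    n <- nrow(ev)
    fired <- logical(n)
    i_net <- v_mem <- numeric(n)
    for (i in seq_len(n)) {
      m <- process_event(m, list(t = ev$t[i], x = ev$x[i], y = ev$y[i],
                                 polarity = ev$polarity[i]))
      fired[i] <- m$fired
      i_net[i] <- m$state$i_net
      v_mem[i] <- m$state$v_mem
    }
    tr <- if (trace) data.frame(t_us = ev$t, i_net = i_net, v_mem = v_mem,
                                fired = fired)
  }
  st <- ev$t[fired]
  spikes <- event_stream(
    data.frame(t = st, x = integer(length(st)), y = integer(length(st)),
               polarity = rep("ON", length(st)), stringsAsFactors = FALSE),
    g, metadata = c(stream$metadata, list(source = "ac_output")))
  structure(list(spikes = spikes, trace = if (trace) tr else NULL,
                 params = params, n_input_events = nrow(ev)),
            class = "ac_output")
}

#' @export
print.ac_output <- function(x, ...) {
  cat(sprintf(
    "<ac_output> %d spikes from %d input events (%s mode, threshold %.3g)\n",
    n_events(x$spikes), x$n_input_events, x$params$firing_mode,
    x$params$if_threshold))
  invisible(x)
}
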