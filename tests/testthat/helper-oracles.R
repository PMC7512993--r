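# Test helpers: fixture generators and independent brute-force oracles.
# Oracles are deliberately written as direct transcriptions of the
# definitions (full-history scans, closed-form decay), sharing no code with
# the implementation paths they check.

rand_stream <- function(n, seed, duration_us = 1e6,
                        geometry = sensor_geometry()) {
  set.seed(seed)
  event_stream(
    data.frame(
      t = sort(floor(runif(n, 0, duration_us))),
      x = sample.int(geometry$width, n, replace = TRUE) - 1L,
      y = sample.int(geometry$height, n, replace = TRUE) - 1L,
      polarity = sample(c("ON", "OFF"), n, replace = TRUE)),
    geometry)
}

# Background filter reference: for each event scan the entire prior history.
bf_filter_background <- function(stream, dt_us) {
  ev <- stream$events
  n <- nrow(ev)
  keep <- logical(n)
  for (i in seq_len(n)) {
    if (i == 1) { keep[i] <- FALSE; next }
    j <- seq_len(i - 1)
    keep[i] <- any(ev$t[i] - ev$t[j] <= dt_us &
                     abs(ev$x[j] - ev$x[i]) <= 1 &
                     abs(ev$y[j] - ev$y[i]) <= 1)
  }
  event_stream(ev[keep, , drop = FALSE], stream$geometry, stream$metadata)
}

# Hot-pixel reference: per event, count that pixel's raw events in the
# trailing window by direct comparison.
bf_filter_hot <- function(stream, window_us, max_events) {
  ev <- stream$events
  n <- nrow(ev)
  keep <- logical(n)
  for (i in seq_len(n)) {
    same <- ev$x == ev$x[i] & ev$y == ev$y[i]
    cnt <- sum(same & ev$t > ev$t[i] - window_us & ev$t <= ev$t[i] &
                 seq_len(n) <= i)
    keep[i] <- cnt <= max_events
  }
  event_stream(ev[keep, , drop = FALSE], stream$geometry, stream$metadata)
}

# Dense AC oracle (IF mode): at every event, re-derive all subunit
# potentials from scratch via the closed-form decay
#   v = sum_j w * f^(D_k - D_j)  over prior same-subunit, same-polarity
# events, where D is the decay-period index since the first event; then
# recompute the center-surround, net current, and fold the membrane.
dense_ac_oracle <- function(stream, params) {
  stopifnot(params$firing_mode == "IF")
  ev <- stream$events
  n <- nrow(ev)
  ns <- params$n_side
  ncell <- ns * ns
  t <- ev$t
  D <- floor((t - t[1]) / params$decay_period_us)
  srow <- ev$y %/% params$rf_side          # 0-based
  scol <- ev$x %/% params$rf_side
  is_on <- ev$polarity == "ON"
  if (params$polarity_swap) is_on <- !is_on
  grp <- srow + ns * scol + ncell * is_on  # 0 .. 2*ncell-1
  ref_us <- 1e6 / params$max_firing_rate

  eff_sum <- function(voff) {
    tot <- 0
    for (r in seq_len(ns)) {
      for (c in seq_len(ns)) {
        center <- max(voff[r, c], 0)
        nb <- c(if (r > 1) voff[r - 1, c], if (r < ns) voff[r + 1, c],
                if (c > 1) voff[r, c - 1], if (c < ns) voff[r, c + 1])
        e <- if (is.null(nb)) center else
          max(center - mean(pmax(nb, 0)), 0)
        tot <- tot + e
      }
    }
    tot
  }

  i_net <- v_mem <- numeric(n)
  fired <- logical(n)
  vm <- 0
  tls <- -Inf
  for (k in seq_len(n)) {
    j <- seq_len(k)
    wts <- params$synaptic_weight * params$decay_factor^(D[k] - D[j])
    sums <- rowsum(wts, grp[j])
    gid <- as.integer(rownames(sums))
    von <- voff <- numeric(ncell)
    off_sel <- gid < ncell
    voff[gid[off_sel] + 1L] <- sums[off_sel]
    von[gid[!off_sel] - ncell + 1L] <- sums[!off_sel]
    voff_m <- matrix(voff, ns, ns)
    se <- if (params$surround_enabled) eff_sum(voff_m) else sum(pmax(voff, 0))
    i_net[k] <- params$g_off * se - params$g_on * sum(pmax(von, 0))
    dt <- if (k == 1) 0 else min(t[k] - t[k - 1], params$dt_max_us) / 1000
    if (t[k] - tls < ref_us) {
      vm <- 0
    } else {
      vm <- max(0, vm + i_net[k] * dt)
    }
    f <- FALSE
    if (t[k] - tls >= ref_us && vm > params$if_threshold) {
      f <- TRUE; vm <- 0; tls <- t[k]
    }
    fired[k] <- f
    v_mem[k] <- vm
  }
  data.frame(t_us = t, i_net = i_net, v_mem = v_mem, fired = fired)
}
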