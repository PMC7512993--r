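test_that("every pixel maps to exactly one subunit of rf_side^2 pixels", {
  px <- expand.grid(x = 0:127, y = 0:127)
  su <- subunit_index(px$x, px$y, 16)
  expect_equal(subunit_index(0, 0, 16), data.frame(row = 1L, col = 1L))
  expect_equal(subunit_index(127, 127, 16), data.frame(row = 8L, col = 8L))
  counts <- table(su$row, su$col)
  expect_equal(dim(counts), c(8, 8))
  expect_true(all(counts == 256))  # each subunit owns 16 x 16 pixels
})

test_that("surround neighbor counts follow the 0/2/3/4 rule", {
  expect_equal(surround_neighbors(1, 1, 8), 2)  # corner
  expect_equal(surround_neighbors(1, 5, 8), 3)  # edge
  expect_equal(surround_neighbors(4, 4, 8), 4)  # interior
  expect_equal(surround_neighbors(1, 1, 1), 0)  # degenerate grid
  # exhaustive tally for the 8x8 grid: 4 corners, 24 edges, 36 interior
  g <- expand.grid(r = 1:8, c = 1:8)
  cnt <- surround_neighbors(g$r, g$c, 8)
  expect_equal(as.integer(table(cnt)), c(4, 24, 36))
})

test_that("rectification and subunit updates behave as defined", {
  expect_equal(rectify(c(-3, 0, 2.5)), c(0, 0, 2.5))
  p <- ac_params()
  g0 <- new_subunit_grid(8)
  g1 <- update_subunit(g0, x = 20, y = 35, polarity = "OFF", p)
  expect_equal(g1$v_off[3, 2], 1)      # y 35 -> row 3, x 20 -> col 2
  expect_equal(sum(g1$v_off), 1)
  expect_equal(sum(g1$v_on), 0)
  # polarity swap routes the same event into the ON potential
  ps <- ac_params(polarity_swap = TRUE)
  g2 <- update_subunit(g0, x = 20, y = 35, polarity = "OFF", ps)
  expect_equal(g2$v_on[3, 2], 1)
  expect_equal(sum(g2$v_off), 0)
})

test_that("random event totals equal per-subunit counts times the weight", {
  s <- rand_stream(1000, seed = 21)
  p <- ac_params(synaptic_weight = 0.5)
  g <- new_subunit_grid(8)
  for (i in seq_len(1000)) {
    g <- update_subunit(g, s$events$x[i], s$events$y[i],
                        s$events$polarity[i], p)
  }
  su <- subunit_index(s$events$x, s$events$y, 16)
  for (pol in c("OFF", "ON")) {
    m <- matrix(0, 8, 8)
    sel <- s$events$polarity == pol
    for (i in which(sel)) m[su$row[i], su$col[i]] <- m[su$row[i], su$col[i]] + 1
    expect_equal(if (pol == "OFF") g$v_off else g$v_on, m * 0.5)
  }
})

test_that("center-surround nulls uniform fields and matches Eq-style arithmetic", {
  # uniform OFF drive (global dimming): zero effective drive everywhere
  u <- matrix(3.7, 8, 8)
  expect_true(all(center_surround(u) == 0))
  # corner with center 4 and the two neighbors at 1: 4 - 2/2 = 3
  m <- matrix(0, 8, 8)
  m[1, 1] <- 4; m[2, 1] <- 1; m[1, 2] <- 1
  expect_equal(center_surround(m, 1, 1), 3)
  # 1x1 grid: no neighbors, center passes through
  expect_equal(center_surround(matrix(5, 1, 1)), matrix(5, 1, 1))
  # random grid: vectorized result equals direct per-cell recomputation
  set.seed(31)
  r <- matrix(runif(64, -2, 5), 8, 8)
  eff <- center_surround(r)
  for (row in 1:8) {
    for (col in 1:8) {
      nb <- c(if (row > 1) r[row - 1, col], if (row < 8) r[row + 1, col],
              if (col > 1) r[row, col - 1], if (col < 8) r[row, col + 1])
      expect_equal(eff[row, col],
                   max(max(r[row, col], 0) - mean(pmax(nb, 0)), 0))
    }
  }
})

test_that("net input is the weighted OFF/ON difference", {
  p <- ac_params(g_on = 1, g_off = 2, surround_enabled = FALSE)
  g <- new_subunit_grid(8)
  g$v_off[1, 1] <- 3
  g$v_on[5, 5] <- 4
  expect_equal(net_input(g, p), 2 * 3 - 1 * 4)
  # balanced drive under equal weights cancels exactly
  pb <- ac_params(g_on = 1, g_off = 1, surround_enabled = FALSE)
  g$v_off <- matrix(runif(64), 8, 8)
  g$v_on <- g$v_off
  expect_equal(net_input(g, pb), 0)
  # surround-off equals the direct summation oracle on random grids
  set.seed(41)
  for (rep in 1:5) {
    g$v_off <- matrix(runif(64, 0, 3), 8, 8)
    g$v_on <- matrix(runif(64, 0, 3), 8, 8)
    expect_equal(net_input(g, pb), sum(g$v_off) - sum(g$v_on))
  }
})

test_that("membrane integration follows dVmem = Inet * dT with clamping", {
  p <- ac_params()
  st <- new_ac_state()
  st$t_last_event <- 0
  st2 <- integrate_membrane(st, i_net = 2, t_now = 5000, p)  # dT = 5 ms
  expect_equal(st2$v_mem, 10)
  st3 <- integrate_membrane(st2, i_net = 0, t_now = 7000, p)
  expect_equal(st3$v_mem, 10)  # zero current leaves the membrane unchanged
  st4 <- integrate_membrane(st3, i_net = -100, t_now = 8000, p)
  expect_equal(st4$v_mem, 0)   # clamp at zero from below
  expect_error(integrate_membrane(st4, 1, t_now = 100, p), "out-of-order")
  # dT saturates at dt_max_us
  st5 <- new_ac_state(); st5$t_last_event <- 0
  st5 <- integrate_membrane(st5, i_net = 1, t_now = 1e8, p)
  expect_equal(st5$v_mem, p$dt_max_us / 1000)
})

test_that("threshold crossing is strict and resets the membrane", {
  p <- ac_params(if_threshold = 10)
  st <- new_ac_state()
  st$v_mem <- 10
  expect_false(check_fire(st, p, 0)$fired)        # boundary: no fire
  st$v_mem <- 10 + 1e-9
  res <- check_fire(st, p, 0)
  expect_true(res$fired)
  expect_equal(res$state$v_mem, 0)
  expect_equal(res$state$t_last_spike, 0)
  # refractory interval suppresses firing
  st2 <- res$state
  st2$v_mem <- 100
  expect_false(check_fire(st2, p, 0 + 100)$fired)
  expect_true(check_fire(st2, p, 0 + p$refractory_us)$fired)
})

test_that("k elapsed periods decay the grid by factor^k", {
  p <- ac_params(decay_period_us = 1000, decay_factor = 0.5)
  g <- new_subunit_grid(8)
  g$v_off[2, 2] <- 8
  g$t_last_decay <- 0
  expect_equal(decay_subunits(g, 999, p)$v_off[2, 2], 8)   # not yet
  expect_equal(decay_subunits(g, 1000, p)$v_off[2, 2], 4)  # one period
  # closed form vs iterated application over k periods
  gk <- decay_subunits(g, 7500, p)
  expect_equal(gk$v_off[2, 2], 8 * 0.5^7)
  expect_equal(gk$t_last_decay, 7000)
  gi <- g
  for (k in 1:7) gi <- decay_subunits(gi, k * 1000, p)
  expect_equal(gi$v_off, gk$v_off)
})

test_that("the event-driven loop matches the hardware state-machine order", {
  p <- ac_params(if_threshold = 50, decay_period_us = 1e6)
  # empty stream: no output, state untouched
  out0 <- ac_run(p, event_stream())
  expect_equal(n_events(out0$spikes), 0)
  # sustained OFF drive into one subunit must eventually fire
  s <- event_stream(data.frame(t = seq(0, 99000, by = 1000), x = 8L, y = 8L,
                               polarity = "OFF"))
  out <- ac_run(p, s, trace = TRUE)
  expect_gt(n_events(out$spikes), 0)
  expect_true(all(out$spikes$events$t %in% s$events$t))
  # ON-leading balanced alternation at one pixel never builds potential
  tt <- rep(seq(0, 49000, by = 1000), each = 2)
  bal <- event_stream(data.frame(t = tt, x = 8L, y = 8L,
                                 polarity = rep(c("ON", "OFF"), 50)))
  outb <- ac_run(p, bal, trace = TRUE)
  expect_equal(n_events(outb$spikes), 0)
  expect_true(all(outb$trace$v_mem == 0))
})

test_that("compiled and pure-R engines agree event for event", {
  s <- rand_stream(400, seed = 51, duration_us = 4e5)
  for (mode in c("IF", "Poisson")) {
    p <- ac_params(if_threshold = 300, firing_mode = mode, rng_seed = 7)
    a <- ac_run(p, s, engine = "cpp", trace = TRUE)
    b <- ac_run(p, s, engine = "r", trace = TRUE)
    expect_equal(a$trace$i_net, b$trace$i_net)
    expect_equal(a$trace$v_mem, b$trace$v_mem)
    expect_identical(a$trace$fired, b$trace$fired)
    expect_equal(a$spikes$events, b$spikes$events, ignore_attr = TRUE)
  }
})

test_that("event-driven state equals the dense from-scratch recomputation", {
  s <- rand_stream(800, seed = 61, duration_us = 3e5)
  for (surround in c(TRUE, FALSE)) {
    p <- ac_params(if_threshold = 500, surround_enabled = surround,
                   decay_period_us = 15000, decay_factor = 0.7)
    got <- ac_run(p, s, trace = TRUE)$trace
    want <- dense_ac_oracle(s, p)
    expect_equal(got$i_net, want$i_net, tolerance = 1e-8)
    expect_equal(got$v_mem, want$v_mem, tolerance = 1e-8)
    expect_identical(got$fired, want$fired)
  }
})

test_that("subunit potentials and the membrane never go negative", {
  s <- rand_stream(2000, seed = 71, duration_us = 2e5)
  p <- ac_params(g_on = 2, if_threshold = 200)
  out <- ac_run(p, s, trace = TRUE)
  expect_true(all(out$trace$v_mem >= 0))
  m <- ac_model(p)
  for (i in seq_len(300)) {
    m <- process_event(m, as.list(s$events[i, ]))
    expect_true(all(m$grid$v_on >= 0) && all(m$grid$v_off >= 0))
  }
  expect_error(
    process_event(m, list(t = 0, x = 0, y = 0, polarity = "OFF")),
    "out-of-order")
})

test_that("Poisson firing is reproducible under a fixed seed", {
  s <- make_stimulus("approach", duration_us = 2e5, r_start = 5, r_end = 30)
  p <- ac_params(firing_mode = "Poisson", rng_seed = 99)
  a <- ac_run(p, s)
  b <- ac_run(p, s)
  expect_identical(a$spikes$events, b$spikes$events)
  expect_gt(n_events(a$spikes), 0)
})

test_that("ac_run validates geometry against the subunit layout", {
  s <- rand_stream(10, seed = 1, geometry = sensor_geometry(64, 64))
  expect_error(ac_run(ac_params(), s), "geometry mismatch")
  out <- ac_run(ac_params(n_side = 4L, rf_side = 16L), s)
  expect_s3_class(out$spikes, "event_stream")
})
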