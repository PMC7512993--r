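#' Split an AC spike train into stimulus iterations
#'
#' For a stimulus that is the continuous repetition of a short
#' approach-then-recede recording, assigns each output spike to iteration
#' `floor(t / iteration_period_us)` and, within the iteration, to the
#' approach or recede window by its offset. Per iteration `i` this yields
#' the total count `ac_e(i)`, the approach-window count `ac_e_ap(i)` and
#' the recede count `ac_e_re(i)`, with `ac_e = ac_e_ap + ac_e_re` by
#' construction.
#'
#' @param spikes An [event_stream()] of AC output spikes (or a numeric
#'   vector of spike times in microseconds).
#' @param iteration_period_us Period of one stimulus iteration (> 0).
#' @param approach_window_us Length-2 numeric `c(start, end)`: offsets
#'   within the period classified as "approach" (half-open interval
#'   `[start, end)`); everything else in the period counts as "recede".
#' @param n_iterations Number of iterations in the recording; spikes at or
#'   beyond `n_iterations * iteration_period_us` are an error.
#' @return An object of class `iteration_counts`: data.frame with columns
#'   `iteration` (1-based), `ac_e`, `ac_e_ap`, `ac_e_re`, one row per
#'   iteration (including silent ones).
#' @export
split_iterations <- function(spikes, iteration_period_us, approach_window_us,
                             n_iterations) {
  t <- if (inherits(spikes, "event_stream")) spikes$events$t else
    as.numeric(spikes)
  stopifnot(iteration_period_us > 0, n_iterations >= 1,
            length(approach_window_us) == 2,
            approach_window_us[1] >= 0,
            approach_window_us[2] <= iteration_period_us,
            approach_window_us[1] < approach_window_us[2])
  iter <- floor(t / iteration_period_us)
  if (any(iter >= n_iterations)) {
    stop("spike timestamps extend beyond n_iterations * iteration_period_us")
  }
  offset <- t - iter * iteration_period_us
  in_ap <- offset >= approach_window_us[1] & offset < approach_window_us[2]
  lev <- seq_len(n_iterations) - 1
  ac_e <- as.integer(table(factor(iter, levels = lev)))
  ac_e_ap <- as.integer(table(factor(iter[in_ap], levels = lev)))
  structure(data.frame(iteration = seq_len(n_iterations),
                       ac_e = ac_e, ac_e_ap = ac_e_ap,
                       ac_e_re = ac_e - ac_e_ap),
            class = c("iteration_counts", "data.frame"),
            iteration_period_us = iteration_period_us,
            approach_window_us = approach_window_us)
}

#' Per-iteration response probabilities
#'
#' Normalizes the approach-window spike counts into a probability
#' distribution over iterations:
#' `p_i = (ac_e(i) - ac_e_re(i)) / sum(ac_e_ap) = ac_e_ap(i) / sum(ac_e_ap)`.
#' A perfectly deterministic cell responds identically in every iteration,
#' giving the uniform distribution (and maximum entropy).
#'
#' @param counts An `iteration_counts` object (or data.frame with columns
#'   `ac_e`, `ac_e_ap`, `ac_e_re`).
#' @return An object of class `response_distribution`: numeric probability
#'   vector summing to 1.
#' @export
response_probabilities <- function(counts) {
  stopifnot(all(c("ac_e", "ac_e_ap", "ac_e_re") %in% names(counts)))
  if (any(counts$ac_e != counts$ac_e_ap + counts$ac_e_re)) {
    stop("invalid counts: ac_e must equal ac_e_ap + ac_e_re")
  }
  total_ap <- sum(counts$ac_e_ap)
  if (total_ap <= 0) {
    stop("undefined distribution: no spikes in any approach window")
  }
  p <- (counts$ac_e - counts$ac_e_re) / total_ap
  stopifnot(abs(sum(p) - 1) < 1e-9, all(p >= 0))
  structure(p, class = "response_distribution")
}

#' Shannon entropy of a response distribution (nats)
#'
#' `H = -sum(p_i * log(p_i))` with the natural logarithm and the convention
#' `0 * log(0) = 0`. For `n` iterations, `H` is bounded by `log(n)`
#' ([max_entropy()]), attained iff the response is identical in every
#' iteration (uniform `p`).
#'
#' @param d A `response_distribution` (or any non-negative numeric vector
#'   summing to 1 within `1e-9`).
#' @return Entropy in nats.
#' @examples
#' response_entropy(rep(1 / 20, 20))  # log(20) = 2.9957
#' @export
response_entropy <- function(d) {
  p <- as.numeric(d)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop("not a probability distribution")
  }
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Maximum attainable response entropy
#'
#' `log(n)` nats for `n` iterations; the entropy of the uniform
#' distribution, representing perfectly deterministic (identical per
#' iteration) behavior of the cell under this normalization.
#'
#' @param n_iterations Number of iterations (>= 1).
#' @return `log(n_iterations)`.
#' @export
max_entropy <- function(n_iterations) {
  stopifnot(n_iterations >= 1)
  log(n_iterations)
}

#' Inter-spike-interval statistics
#'
#' Minimum, maximum and mean of the consecutive timestamp differences of a
#' spike train, reported in milliseconds.
#'
#' @param spikes An [event_stream()] of spikes (or numeric times in
#'   microseconds); at least 2 spikes required.
#' @return List with `min_ms`, `max_ms`, `mean_ms`, `n_spikes`.
#' @export
isi_stats <- function(spikes) {
  t <- if (inherits(spikes, "event_stream")) spikes$events$t else
    as.numeric(spikes)
  if (length(t) < 2) stop("ISI statistics require at least 2 spikes")
  isi <- diff(t) / 1000
  list(min_ms = min(isi), max_ms = max(isi), mean_ms = mean(isi),
       n_spikes = length(t))
}
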