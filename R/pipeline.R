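`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize a run configuration
#'
#' A run configuration drives the end-to-end pipeline. It is a named list
#' (or a YAML file containing one) with fields:
#'
#' * exactly one of `stimulus` (list of [make_stimulus()] arguments,
#'   including `kind`) or `input` (path readable by [read_events()]);
#' * `filter` (optional): `bg_dt_us`, `hot_window_us`, `hot_max_events` —
#'   present entries enable the corresponding filter;
#' * `ac` (optional): [ac_params()] arguments;
#' * `analysis` (optional): `iteration_period_us`, `approach_window_us`
#'   (length 2), `n_iterations`, and optionally `n_repeats` to tile the
#'   stimulus with [repeat_stream()] before the run;
#' * `out_dir` (optional): directory for the manifest, spike file and
#'   report;
#' * `seed` (default 1): seed for every source of randomness in the run.
#'
#' @param config A named list or path to a YAML file.
#' @return The validated configuration list (class `run_config`).
#' @export
read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  has_stim <- !is.null(config$stimulus)
  has_input <- !is.null(config$input)
  if (has_stim == has_input) {
    stop("config must contain exactly one of 'stimulus' or 'input'")
  }
  config$seed <- as.integer(config$seed %||% 1L)
  structure(config, class = c("run_config", "list"))
}

load_or_make_stream <- function(cfg) {
  if (!is.null(cfg$input)) {
    read_events(cfg$input)
  } else {
    do.call(make_stimulus, cfg$stimulus)
  }
}

#' Synthesize a stimulus and write it to disk
#'
#' Runs the stimulus generator for a configuration, writes the stream via
#' [write_events()] and a JSON manifest echoing every parameter (plus the
#' ON/OFF event counts), so the run can be reproduced bit for bit.
#'
#' @param config A run configuration (see [read_run_config()]) with a
#'   `stimulus` block and an `out_dir`.
#' @param format Output stream format, `"aedat"` or `"csv"`.
#' @return Invisibly, a list with `stream_path`, `manifest_path` and the
#'   generated stream.
#' @export
cmd_simulate <- function(config, format = c("aedat", "csv")) {
  cfg <- read_run_config(config)
  format <- match.arg(format)
  if (is.null(cfg$stimulus)) stop("cmd_simulate requires a 'stimulus' block")
  out_dir <- cfg$out_dir %||% stop("cmd_simulate requires 'out_dir'")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  stream <- do.call(make_stimulus, cfg$stimulus)
  ext <- if (format == "csv") "csv" else "aedat"
  stream_path <- file.path(out_dir, paste0("stimulus.", ext))
  write_events(stream, stream_path, format)
  manifest <- list(
    stimulus = cfg$stimulus,
    seed = cfg$seed,
    n_events = n_events(stream),
    n_on = sum(stream$events$polarity == "ON"),
    n_off = sum(stream$events$polarity == "OFF"),
    metadata = stream$metadata,
    stream_file = basename(stream_path))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(stream_path = stream_path, manifest_path = manifest_path,
                 stream = stream))
}

#' Run the full filter -> AC -> metrics pipeline
#'
#' Software analogue of the hardware dataflow: the input stream passes
#' through the background-activity filter (and optionally the hot-pixel
#' filter), then through the AC model; the output spike train is summarized
#' (spike count, ISI statistics when there are at least two spikes, and the
#' repetition-entropy analysis when `analysis` is configured). Any stage
#' failure is re-raised with the stage name. With IF firing the whole
#' pipeline is deterministic; with Poisson firing it is reproducible under
#' the configured seed.
#'
#' @param config A run configuration (see [read_run_config()]).
#' @return A report list: `n_input_events`, `n_after_filter`,
#'   `spike_count`, `spike_times_us`, `isi` (or `NULL`), `entropy` (or
#'   `NULL`), `params`, `config`. Written to `out_dir/report.json` (with a
#'   manifest and the spike stream) when `out_dir` is set.
#' @export
run_pipeline <- function(config) {
  cfg <- read_run_config(config)
  set.seed(cfg$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  stream <- stage("input", load_or_make_stream(cfg))
  if (!is.null(cfg$analysis$n_repeats) && cfg$analysis$n_repeats > 1) {
    stream <- stage("repeat",
                    repeat_stream(stream, cfg$analysis$n_repeats,
                                  cfg$analysis$iteration_period_us %||%
                                    stream$metadata$period_us))
  }
  n_input <- n_events(stream)
  filtered <- stream
  if (!is.null(cfg$filter$bg_dt_us)) {
    filtered <- stage("background-filter",
                      filter_background(filtered, cfg$filter$bg_dt_us))
  }
  if (!is.null(cfg$filter$hot_window_us)) {
    filtered <- stage("hot-pixel-filter",
                      filter_hot_pixels(filtered, cfg$filter$hot_window_us,
                                        cfg$filter$hot_max_events %||% 200))
  }
  ac_args <- cfg$ac %||% list()
  if (is.null(ac_args$rng_seed)) ac_args$rng_seed <- cfg$seed
  params <- stage("ac-params", do.call(ac_params, ac_args))
  out <- stage("ac-model", ac_run(params, filtered))
  spike_t <- out$spikes$events$t

  isi <- if (length(spike_t) >= 2) isi_stats(out$spikes) else NULL
  ent <- NULL
  an <- cfg$analysis
  if (!is.null(an$iteration_period_us) && !is.null(an$n_iterations)) {
    ent <- stage("entropy", {
      counts <- split_iterations(out$spikes, an$iteration_period_us,
                                 unlist(an$approach_window_us),
                                 an$n_iterations)
      if (sum(counts$ac_e_ap) > 0) {
        p <- response_probabilities(counts)
        list(counts = as.data.frame(counts), p = as.numeric(p),
             H = response_entropy(p),
             H_max = max_entropy(an$n_iterations))
      } else {
        list(counts = as.data.frame(counts), p = NULL, H = NULL,
             H_max = max_entropy(an$n_iterations))
      }
    })
  }
  report <- list(n_input_events = n_input,
                 n_after_filter = n_events(filtered),
                 spike_count = length(spike_t),
                 spike_times_us = spike_t,
                 isi = isi, entropy = ent,
                 params = unclass(params),
                 config = unclass(cfg))
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_events(out$spikes, file.path(cfg$out_dir, "ac_spikes.csv"), "csv")
    jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  report
}

#' Space-time view of an event stream with AC spikes overlaid
#'
#' Renders the jAER-style space-time visualization as two panels (x vs t
#' and y vs t), OFF events in blue, ON events in green, and AC output
#' spikes as red stars at mid-field. An empty stream produces blank axes.
#'
#' @param stream Input [event_stream()].
#' @param spikes Optional [event_stream()] of AC output spikes.
#' @param path Output image file (PNG).
#' @param max_points Input events are thinned deterministically (regular
#'   subsampling) to at most this many plotted points per panel.
#' @return Invisibly, list with `n_points_plotted` and `n_spikes`.
#' @export
plot_space_time <- function(stream, spikes = NULL, path, max_points = 20000) {
  validate_event_stream(stream)
  ev <- stream$events
  if (nrow(ev) > max_points) {
    ev <- ev[seq(1, nrow(ev), length.out = max_points), ]
  }
  g <- stream$geometry
  spike_t <- if (!is.null(spikes)) spikes$events$t else numeric()
  grDevices::png(path, width = 900, height = 500)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  cols <- ifelse(ev$polarity == "OFF", "#2040c0", "#20a040")
  tlim <- if (nrow(ev)) range(ev$t) / 1000 else c(0, 1)
  for (dim in c("x", "y")) {
    graphics::plot(ev$t / 1000, ev[[dim]], pch = ".", col = cols,
                   xlim = tlim, ylim = c(0, g[[if (dim == "x") "width"
                                               else "height"]] - 1),
                   xlab = "time (ms)", ylab = paste(dim, "(px)"),
                   main = sprintf("space-time (%s)", dim))
    if (length(spike_t)) {
      graphics::points(spike_t / 1000,
                       rep(g$width / 2, length(spike_t)),
                       pch = 8, col = "red", cex = 1.2)
    }
  }
  invisible(list(n_points_plotted = nrow(ev), n_spikes = length(spike_t)))
}
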