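#' Construct a spike raster
#'
#' An event list of (neuron_id, time_ms) with per-neuron population labels.
#' Rasters are produced by [run_simulation()] and by the fixture generators,
#' and consumed by every rate/synchrony metric.
#'
#' @param neuron_id Integer vector of 1-based neuron ids.
#' @param time_ms Numeric spike times (ms), within `[0, duration_ms]`.
#' @param labels Factor or character of length `n_neurons`: population of
#'   each neuron.
#' @param duration_ms Recording duration (ms).
#' @param refractory_ms Minimal admissible gap between consecutive spikes of
#'   one neuron (0 for fixtures without refractoriness).
#' @param transient_ms Initial window metrics should discard by default.
#' @return A `spike_raster` object.
#' @export
spike_raster <- function(neuron_id, time_ms, labels, duration_ms,
                         refractory_ms = 0, transient_ms = 0) {
  n <- length(labels)
  neuron_id <- as.integer(neuron_id)
  if (length(neuron_id) != length(time_ms))
    stop("'neuron_id' and 'time_ms' must have equal length")
  if (length(time_ms) && (min(time_ms) < 0 || max(time_ms) > duration_ms))
    stop("spike times must lie in [0, duration_ms]")
  if (length(neuron_id) && (min(neuron_id) < 1L || max(neuron_id) > n))
    stop("neuron ids must lie in 1..n_neurons")
  o <- order(neuron_id, time_ms)
  structure(
    list(events = data.frame(neuron_id = neuron_id[o], time_ms = time_ms[o]),
         labels = if (is.factor(labels)) labels else factor(labels),
         n_neurons = n,
         duration_ms = duration_ms,
         refractory_ms = refractory_ms,
         transient_ms = transient_ms),
    class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("<spike_raster> %d spikes from %d neurons over %g ms\n",
              nrow(x$events), x$n_neurons, x$duration_ms))
  invisible(x)
}

#' Total spike count of a raster
#' @param raster A `spike_raster`.
#' @return Integer.
#' @export
n_spikes <- function(raster) nrow(raster$events)

#' Per-neuron spike counts
#' @param raster A `spike_raster`.
#' @param window Optional `c(start, end)` in ms; default full duration.
#' @return Integer vector of length `n_neurons`.
#' @export
spike_counts <- function(raster, window = c(0, raster$duration_ms)) {
  ev <- raster$events
  keep <- ev$time_ms > window[1] & ev$time_ms <= window[2]
  tabulate(ev$neuron_id[keep], nbins = raster$n_neurons)
}

#' Minimal inter-spike interval per neuron
#'
#' Used to assert that no raster violates the refractory period.
#'
#' @param raster A `spike_raster`.
#' @return Named numeric vector (ms) over neurons with >= 2 spikes.
#' @export
min_isi <- function(raster) {
  ev <- raster$events
  spl <- split(ev$time_ms, ev$neuron_id)
  spl <- spl[lengths(spl) >= 2]
  vapply(spl, function(t) min(diff(t)), numeric(1))
}
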