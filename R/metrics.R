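#' Per-neuron firing rates
#'
#' Rate of every neuron (including neurons with no spikes, which get 0 Hz)
#' as spike count in the analysis window divided by window length. By
#' default the window runs from the raster's transient marker to its end,
#' so the settling-in period of a simulation is discarded.
#'
#' @param raster A [spike_raster()].
#' @param window `c(start, end)` in ms, within `[0, duration]`.
#' @return A `rate_table` data.frame (`neuron_id`, `population`,
#'   `rate_hz`) with attributes `summary` (per-population and overall n,
#'   mean, median) and `window`.
#' @export
per_neuron_rates <- function(raster,
                             window = c(raster$transient_ms,
                                        raster$duration_ms)) {
  if (length(window) != 2 || diff(window) <= 0)
    stop("'window' must be c(start, end) with end > start")
  if (window[1] < 0 || window[2] > raster$duration_ms)
    stop("'window' must lie within [0, duration]")
  counts <- spike_counts(raster, window)
  rate_hz <- counts / diff(window) * 1000
  out <- data.frame(neuron_id = seq_len(raster$n_neurons),
                    population = raster$labels,
                    rate_hz = rate_hz)
  by_pop <- split(rate_hz, raster$labels)
  by_pop <- c(by_pop, list(all = rate_hz))
  summ <- data.frame(
    population = names(by_pop),
    n = vapply(by_pop, length, integer(1)),
    mean_hz = vapply(by_pop, mean, numeric(1)),
    median_hz = vapply(by_pop, stats::median, numeric(1)),
    row.names = NULL)
  attr(out, "summary") <- summ
  attr(out, "window") <- window
  class(out) <- c("rate_table", "data.frame")
  out
}

#' Per-population rate summary of a rate table
#' @param rates A `rate_table` from [per_neuron_rates()].
#' @return Data.frame with `population`, `n`, `mean_hz`, `median_hz`.
#' @export
population_rates <- function(rates) attr(rates, "summary")

#' LFP proxy from a stored state history
#'
#' The local field potential proxy is the population average of the
#' instantaneous transmembrane current
#' `(-(V - V0) + ge + gi + dam) / tau_m` (mV/ms). [run_simulation()]
#' accumulates it online; this function recomputes it from a full state
#' history (matrices steps x neurons), which is only feasible for small
#' networks and serves as the equivalence oracle for the online path.
#'
#' @param history List with matrices `v`, `ge`, `gi` (steps x neurons).
#' @param network The `iaf_network` the history came from.
#' @param config The [network_config()] used.
#' @return Data.frame `time_ms`, `lfp`.
#' @export
lfp_trace <- function(history, network, config) {
  cur <- sweep(-sweep(history$v, 2, network$neurons$v0) +
                 history$ge + history$gi,
               2, network$neurons$dam, `+`)
  cur <- sweep(cur, 2, network$neurons$tau_m, `/`)
  data.frame(time_ms = (seq_len(nrow(cur)) - 1) * config$dt,
             lfp = rowMeans(cur))
}

#' Summed membrane potential from a stored state history
#'
#' @inheritParams lfp_trace
#' @return Data.frame `time_ms`, `vm_sum` (mV).
#' @export
vm_sum_trace <- function(history, config) {
  data.frame(time_ms = (seq_len(nrow(history$v)) - 1) * config$dt,
             vm_sum = rowSums(history$v))
}

#' Population synchrony index
#'
#' Bins all spikes of the raster into windows of `bin_ms` and computes the
#' Fano factor of the binned population count,
#' `F = Var(count) / mean(count)`. Independent Poisson trains give F close
#' to 1; N perfectly coincident trains give F close to N. With
#' `normalize = TRUE` (default) the index is rescaled to
#' `(F - 1) / (n_neurons - 1)`, which sits near 0 for asynchronous firing
#' and near 1 for full coincidence. An empty raster returns 0.
#'
#' @param raster A [spike_raster()].
#' @param bin_ms Bin width (ms), default 5 (one refractory period).
#' @param normalize Rescale by network size as described above.
#' @param window Analysis window `c(start, end)` in ms; defaults to the
#'   post-transient span.
#' @return A scalar index.
#' @export
synchrony_index <- function(raster, bin_ms = 5, normalize = TRUE,
                            window = c(raster$transient_ms,
                                       raster$duration_ms)) {
  if (bin_ms <= 0) stop("'bin_ms' must be > 0")
  ev <- raster$events
  t <- ev$time_ms[ev$time_ms > window[1] & ev$time_ms <= window[2]]
  if (!length(t)) return(0)
  n_bins <- max(1L, floor(diff(window) / bin_ms))
  idx <- pmin(floor((t - window[1]) / bin_ms) + 1L, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  f <- stats::var(counts) / mean(counts)
  if (!normalize) return(f)
  if (raster$n_neurons <= 1) return(f)
  (f - 1) / (raster$n_neurons - 1)
}
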