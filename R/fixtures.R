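#' Homogeneous Poisson spike raster
#'
#' Independent Poisson trains of a common rate: a known-statistics stand-in
#' for simulator output, used to validate rate and synchrony metrics
#' (population Fano factor of Poisson counts is 1).
#'
#' @param n_neurons Number of trains.
#' @param rate_hz Rate of every train (>= 0; 0 gives an empty raster).
#' @param duration_ms Duration (ms).
#' @param seed Seed (mandatory for reproducibility).
#' @param labels Optional per-neuron population labels (default
#'   `"excitatory"`).
#' @return A [spike_raster()] with `refractory_ms = 0`.
#' @export
make_poisson_raster <- function(n_neurons, rate_hz, duration_ms, seed,
                                labels = rep("excitatory", n_neurons)) {
  if (rate_hz < 0) stop("'rate_hz' must be >= 0")
  set.seed(derive_seed(seed, "poisson"))
  counts <- stats::rpois(n_neurons, rate_hz * duration_ms / 1000)
  ids <- rep(seq_len(n_neurons), counts)
  times <- stats::runif(sum(counts), 0, duration_ms)
  spike_raster(ids, times, labels, duration_ms, refractory_ms = 0)
}

#' Periodic, fully coincident spike raster
#'
#' Every neuron spikes at the same instants (`phase + k * period`): the
#' maximal-synchrony reference case.
#'
#' @param n_neurons Number of trains.
#' @param period_ms Common inter-spike interval (ms).
#' @param duration_ms Duration (ms).
#' @param phase_ms First spike time (ms).
#' @return A [spike_raster()].
#' @export
make_periodic_raster <- function(n_neurons, period_ms, duration_ms,
                                 phase_ms = period_ms) {
  times1 <- seq(phase_ms, duration_ms, by = period_ms)
  spike_raster(rep(seq_len(n_neurons), each = length(times1)),
               rep(times1, n_neurons),
               rep("excitatory", n_neurons), duration_ms,
               refractory_ms = period_ms)
}

#' Composite sinusoid trace with optional white noise
#'
#' Sum of sinusoids of known frequency and amplitude plus Gaussian white
#' noise, sampled on the simulation time grid: the spectral-analysis
#' fixture with analytically known band content (a pure tone of amplitude A
#' carries power A^2/2, concentrated at its frequency).
#'
#' @param components Data.frame with columns `freq_hz` and `amplitude`
#'   (may have zero rows for pure noise).
#' @param duration_ms Duration (ms).
#' @param dt_ms Sampling step (ms); all frequencies must be below the
#'   Nyquist frequency `500/dt_ms` Hz.
#' @param noise_sd Standard deviation of added white noise (0 for none).
#' @param seed Seed (used only when `noise_sd > 0`).
#' @return Data.frame `time_ms`, `vm_sum` (the default spectral input
#'   column), in the trace dialect the simulator emits.
#' @export
make_sinusoid_trace <- function(components, duration_ms, dt_ms = 1,
                                noise_sd = 0, seed = 1L) {
  nyquist <- 1000 / dt_ms / 2
  if (nrow(components) && any(components$freq_hz >= nyquist))
    stop("component frequency at or above the Nyquist frequency (",
         nyquist, " Hz)")
  t_ms <- seq(0, duration_ms - dt_ms, by = dt_ms)
  x <- numeric(length(t_ms))
  for (i in seq_len(nrow(components)))
    x <- x + components$amplitude[i] *
      sin(2 * pi * components$freq_hz[i] * t_ms / 1000)
  if (noise_sd > 0) {
    set.seed(derive_seed(seed, "trace-noise"))
    x <- x + stats::rnorm(length(x), 0, noise_sd)
  }
  data.frame(time_ms = t_ms, vm_sum = x)
}

#' White-noise trace
#'
#' @inheritParams make_sinusoid_trace
#' @return Data.frame `time_ms`, `vm_sum`.
#' @export
make_noise_trace <- function(duration_ms, dt_ms = 1, noise_sd = 1, seed = 1L) {
  make_sinusoid_trace(data.frame(freq_hz = numeric(0), amplitude = numeric(0)),
                      duration_ms, dt_ms, noise_sd, seed)
}

#' Synthetic sweep records with a known fraction effect
#'
#' Builds a record table shaped like [run_sweep()] output in which the
#' response is `baseline + effect * fraction + N(0, noise_sd)`: the ground
#' truth for validating correlation sign/power and ANOVA calibration
#' without running the simulator.
#'
#' @param grid A [sweep_grid()].
#' @param baseline Response at fraction 0.
#' @param effect Slope of the response in the silenced fraction (may be a
#'   named vector with one slope per target).
#' @param noise_sd SD of the additive Gaussian noise.
#' @param seed Seed.
#' @param response_name Name of the response column (default
#'   `"response"`).
#' @return Data.frame `target`, `fraction`, `rep`, plus the response
#'   column.
#' @export
make_synthetic_runrecords <- function(grid, baseline = 1, effect = 0,
                                      noise_sd = 0, seed = 1L,
                                      response_name = "response") {
  cond <- sweep_conditions(grid)
  slope <- if (is.null(names(effect))) rep(effect, nrow(cond))
           else {
             s <- effect[cond$target]
             s[is.na(s)] <- 0
             s
           }
  set.seed(derive_seed(seed, "runrecords"))
  y <- baseline + slope * cond$fraction +
    if (noise_sd > 0) stats::rnorm(nrow(cond), 0, noise_sd) else 0
  cond[[response_name]] <- as.numeric(y)
  cond
}
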