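# Shared miniature configurations so unit tests stay fast. The full-size
# default configuration is exercised by the acceptance tests.

# three-population network scaled to 1/10 of the default size
small_config <- function(seed = 1L, duration = 2000, n_total = 400, ...) {
  network_config(n_total = n_total, duration = duration, transient = 200,
                 seed = seed, ...)
}

# single homogeneous population with no synapses: isolated-drift dynamics
drift_config <- function(n_total = 10, v0 = -49, vt = -50, vr = -60,
                         tau_m = 20, dt = 1, duration = 2000, seed = 1L,
                         ...) {
  network_config(
    n_total = n_total, dt = dt, duration = duration, transient = 0,
    vt = vt, vr = vr, tau_m = tau_m, seed = seed,
    populations = list(population_spec("excitatory", 1, v0 = v0, pc = 0,
                                       ws = 2, tau_m = tau_m)),
    ...)
}

# spike times of one neuron from a raster
neuron_times <- function(raster, id) {
  raster$events$time_ms[raster$events$neuron_id == id]
}
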