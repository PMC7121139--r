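#' Run an integrate-and-fire network simulation
#'
#' Integrates the current-based model. The membrane drift is
#' `tau_m dV/dt = -(V - V0) + dam` per neuron; synaptic coupling follows
#' `config$synapse`: under `"delta"` (default) a delivered spike perturbs
#' the target's V directly by the presynaptic weight `Ws`, and the
#' perturbation relaxes at the target's membrane constant; under `"cuba"`
#' spikes jump persistent synaptic variables (`dge/dt = -ge/tau_e`,
#' `dgi/dt = -gi/tau_i`) that add to the drift. Spikes are delivered with a
#' one-integration-step delay. A neuron reaching the threshold `vt` fires,
#' resets to `vr` and is clamped there for the refractory period. The
#' constant `dam` term (0 for intact neurons, -30 mV for silenced ones)
#' shifts the attractor of the drift to `v0 + dam`; neurons with nonzero
#' `dam` model synaptically silent cells and never initiate spikes.
#'
#' Per step the simulator records one LFP proxy sample (the mean
#' transmembrane current `(-(V - V0) + ge + gi + dam) / tau_m`, mV/ms) and
#' the summed membrane potential, both from the post-delivery, pre-update
#' snapshot. The run is fully deterministic given `(network, config, seed)`.
#'
#' @param network An [build_network()] result, possibly with damage applied.
#' @param config A [network_config()].
#' @param seed Master seed for the initial-state draw (default
#'   `config$seed`).
#' @param record_state If `TRUE`, also return the full per-step state
#'   history (matrices `n_steps x n`); only sensible for small networks.
#' @return A `sim_result`: `raster` ([spike_raster()]), `traces`
#'   (data.frame `time_ms`, `lfp`, `vm_sum`), `config`, `seed`, and (if
#'   requested) `history` with `v`, `ge`, `gi`.
#' @export
run_simulation <- function(network, config, seed = config$seed,
                           record_state = FALSE) {
  validate_config(config)
  n_steps <- floor(config$duration / config$dt + 1e-9)
  if (abs(n_steps * config$dt - config$duration) > 1e-9)
    warning("'duration' is not a multiple of 'dt'; simulating ",
            n_steps * config$dt, " ms")
  state <- initialize_state(network, config, seed)
  res <- run_sim_cpp(
    n = network$n,
    src_ptr = network$edges$src_ptr,
    targets = network$edges$targets - 1L,
    w_src = network$edges$w_src,
    v0 = network$neurons$v0,
    dam = network$neurons$dam,
    tau_m = network$neurons$tau_m,
    v_init = state$v,
    dt = config$dt,
    n_steps = as.integer(n_steps),
    vt = config$vt, vr = config$vr, refractory = config$refractory,
    tau_e = config$tau_e, tau_i = config$tau_i,
    euler = identical(config$method, "euler"),
    delta_syn = identical(config$synapse, "delta"),
    v_floor = if (is.null(config$v_floor)) -Inf else config$v_floor,
    record_state = record_state)
  raster <- spike_raster(res$neuron_id, res$time_ms,
                         labels = network$neurons$population,
                         duration_ms = n_steps * config$dt,
                         refractory_ms = config$refractory,
                         transient_ms = config$transient)
  out <- structure(
    list(raster = raster,
         traces = data.frame(time_ms = seq_len(n_steps) * config$dt - config$dt,
                             lfp = res$lfp, vm_sum = res$vm_sum),
         config = config,
         seed = seed,
         n_silenced = sum(network$neurons$dam != 0)),
    class = "sim_result")
  if (record_state)
    out$history <- list(v = res$v_hist, ge = res$ge_hist, gi = res$gi_hist)
  out
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %d spikes, %g ms, %d neurons (%d silenced), seed %s\n",
              n_spikes(x$raster), x$raster$duration_ms, x$raster$n_neurons,
              x$n_silenced, format(x$seed)))
  invisible(x)
}

#' Advance the network state by one integration step (reference stepper)
#'
#' A pure-R implementation of the per-step update used by
#' [run_simulation()], kept as an executable statement of the dynamics and
#' as an independent cross-check of the compiled core. Semantics: spikes in
#' `fired_prev` (emitted on the previous step) jump the targets' V
#' (`"delta"` coupling) or `ge`/`gi` (`"cuba"`); the LFP and Vm-sum samples
#' are taken from that snapshot; the membrane then updates (exponential
#' Euler toward `v0 + dam + ge + gi`, or forward Euler), refractory neurons
#' stay clamped at `vr`; undamaged neurons crossing threshold fire and
#' reset; finally `ge`/`gi` decay.
#'
#' @param state A `neuron_state` (see [initialize_state()]).
#' @param network An `iaf_network`.
#' @param config A [network_config()].
#' @param fired_prev Integer ids of neurons that fired on the previous step.
#' @return List: updated `state`, `fired` (ids firing this step), `lfp`
#'   sample and `vm_sum` sample.
#' @export
step_neurons <- function(state, network, config, fired_prev = integer(0)) {
  v <- state$v; ge <- state$ge; gi <- state$gi
  refrac <- state$refractory_remaining
  v0 <- network$neurons$v0
  dam <- network$neurons$dam
  tau <- network$neurons$tau_m
  dt <- config$dt

  delta_syn <- identical(config$synapse, "delta")
  for (i in fired_prev) {
    tg <- out_neighbors(network, i)
    w <- network$edges$w_src[i]
    if (delta_syn) {
      open <- tg[refrac[tg] <= 0]
      v[open] <- v[open] + w
      if (!is.null(config$v_floor))
        v[open] <- pmax(v[open], config$v_floor)
    } else if (w > 0) {
      ge[tg] <- ge[tg] + w
    } else {
      gi[tg] <- gi[tg] + w
    }
  }
  lfp <- mean((-(v - v0) + ge + gi + dam) / tau)
  vm_sum <- sum(v)

  in_refrac <- refrac > 0
  v[in_refrac] <- config$vr
  refrac[in_refrac] <- pmax(refrac[in_refrac] - dt, 0)
  vinf <- v0 + dam + ge + gi
  free <- !in_refrac
  if (identical(config$method, "euler")) {
    v[free] <- v[free] + dt * (vinf[free] - v[free]) / tau[free]
  } else {
    v[free] <- vinf[free] + (v[free] - vinf[free]) * exp(-dt / tau[free])
  }
  if (any(!is.finite(v)))
    stop("non-finite membrane potential: neuron ", which(!is.finite(v))[1])
  fired <- which(free & v >= config$vt & dam == 0)
  v[fired] <- config$vr
  refrac[fired] <- config$refractory
  ge <- ge * exp(-dt / config$tau_e)
  gi <- gi * exp(-dt / config$tau_i)

  list(state = structure(list(v = v, ge = ge, gi = gi,
                              refractory_remaining = refrac),
                         class = "neuron_state"),
       fired = fired, lfp = lfp, vm_sum = vm_sum)
}

#' Reference simulation loop in pure R
#'
#' Drives [step_neurons()] over the configured duration. Orders of magnitude
#' slower than [run_simulation()]; intended for small networks and for
#' validating the compiled core against an independent implementation.
#'
#' @inheritParams run_simulation
#' @return A `sim_result` (without state history).
#' @export
run_simulation_r <- function(network, config, seed = config$seed) {
  n_steps <- floor(config$duration / config$dt + 1e-9)
  state <- initialize_state(network, config, seed)
  fired_prev <- integer(0)
  sp_id <- integer(0); sp_t <- numeric(0)
  lfp <- numeric(n_steps); vm <- numeric(n_steps)
  for (s in seq_len(n_steps)) {
    st <- step_neurons(state, network, config, fired_prev)
    state <- st$state
    fired_prev <- st$fired
    lfp[s] <- st$lfp
    vm[s] <- st$vm_sum
    if (length(st$fired)) {
      sp_id <- c(sp_id, st$fired)
      sp_t <- c(sp_t, rep(s * config$dt, length(st$fired)))
    }
  }
  structure(
    list(raster = spike_raster(sp_id, sp_t, network$neurons$population,
                               duration_ms = n_steps * config$dt,
                               refractory_ms = config$refractory,
                               transient_ms = config$transient),
         traces = data.frame(time_ms = seq_len(n_steps) * config$dt - config$dt,
                             lfp = lfp, vm_sum = vm),
         config = config, seed = seed,
         n_silenced = sum(network$neurons$dam != 0)),
    class = "sim_result")
}

#' Closed-form inter-spike interval of the isolated drift
#'
#' With no synaptic input and `dam = 0`, a suprathreshold neuron
#' (`v0 > vt`) fires periodically with
#' `ISI = refractory + tau_m * log((v0 - vr) / (v0 - vt))`. Returns `Inf`
#' for subthreshold neurons (`v0 <= vt`). Default parameters give
#' approximately 52.96 ms.
#'
#' @param config A [network_config()].
#' @param v0 Resting potential (mV); default the excitatory value.
#' @param tau_m Membrane time constant (ms); default `config$tau_m`.
#' @return ISI in ms.
#' @export
drift_isi <- function(config, v0 = config$populations[[1]]$v0,
                      tau_m = config$tau_m) {
  if (v0 <= config$vt) return(Inf)
  config$refractory + tau_m * log((v0 - config$vr) / (v0 - config$vt))
}
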