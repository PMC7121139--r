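#' Specify a silencing perturbation
#'
#' Models synaptically silent (hyperploid) neurons: a fraction of a target
#' pool receives a constant hyperpolarizing damage term (default -30 mV)
#' that keeps their membrane potential far below threshold, so they never
#' fire. The `"excitatory"` pool excludes the leader subtype, which is
#' silenced as its own condition; `"whole"` draws from all neurons.
#'
#' @param target One of `"none"`, `"whole"`, `"excitatory"`, `"leader"`,
#'   `"interneuron"`.
#' @param fraction Fraction of the pool to silence, in `[0, 1]`. The study
#'   grid uses 0.01, 0.1, 0.2, 0.3, 0.5, 0.8.
#' @param dam_mv Damage term (mV), added as a constant to the membrane
#'   drift.
#' @param seed Seed of the selection draw (independent of wiring and
#'   initialization).
#' @return A `silencing_spec` list.
#' @export
silencing_spec <- function(target = c("none", "whole", "excitatory",
                                      "leader", "interneuron"),
                           fraction = 0, dam_mv = -30, seed = 1L) {
  target <- match.arg(target)
  if (!is.numeric(fraction) || fraction < 0 || fraction > 1)
    stop("invalid 'fraction': must be in [0, 1]")
  structure(list(target = target, fraction = fraction, dam_mv = dam_mv,
                 seed = as.integer(seed)),
            class = "silencing_spec")
}

#' Select the neurons to silence
#'
#' Uniform sample without replacement of `round(fraction * pool size)`
#' neurons (half-up rounding) from the target pool, reproducible from the
#' spec's seed. `target = "none"` or `fraction = 0` selects nothing.
#'
#' @param network An `iaf_network`.
#' @param spec A [silencing_spec()].
#' @return Sorted integer vector of neuron ids.
#' @export
select_silenced <- function(network, spec) {
  if (spec$target == "none" || spec$fraction == 0) return(integer(0))
  pool <- if (spec$target == "whole") network$neurons$id
          else network$neurons$id[network$neurons$population == spec$target]
  if (!length(pool))
    stop("empty pool for silencing target '", spec$target, "'")
  k <- round_half_up(spec$fraction * length(pool))
  set.seed(derive_seed(spec$seed, "silence"))
  sort(sample(pool, k))
}

#' Apply the damage term to a set of neurons
#'
#' Sets `dam` of every listed neuron to `dam_value` and of every other
#' neuron to 0; applying the same set twice is a no-op. The perturbation is
#' static: it is fixed before the run and held for its whole duration.
#' Damaged neurons model cells without the capacity to fire action
#' potentials: besides being hyperpolarized toward `v0 + dam_value`, they
#' never initiate spikes, even if a synchronized volley of excitatory
#' input transiently crosses the threshold.
#'
#' @param network An `iaf_network`.
#' @param ids Neuron ids to damage (may be empty: control condition).
#' @param dam_value Damage term (mV), default -30.
#' @return The modified network.
#' @export
apply_damage <- function(network, ids, dam_value = -30) {
  ids <- as.integer(ids)
  if (length(ids) && (anyNA(ids) || any(ids < 1L | ids > network$n)))
    stop("unknown neuron id in 'ids'")
  network$neurons$dam <- numeric(network$n)
  network$neurons$dam[ids] <- dam_value
  network
}

#' Silence a network in one call
#'
#' Convenience wrapper: [select_silenced()] then [apply_damage()].
#'
#' @inheritParams select_silenced
#' @return The network with damage applied; the selected ids are attached
#'   as attribute `"silenced_ids"`.
#' @export
silence_network <- function(network, spec) {
  ids <- select_silenced(network, spec)
  net <- apply_damage(network, ids, spec$dam_mv)
  attr(net, "silenced_ids") <- ids
  net
}
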