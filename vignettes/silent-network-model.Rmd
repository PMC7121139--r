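---
title: "Modeling synaptically silent neurons in a spiking cortical network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling synaptically silent neurons in a spiking cortical network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

Neurons that re-enter the cell cycle and become hyperploid — a process
documented in Alzheimer's disease — survive inside active circuits while
losing the capacity to fire action potentials. `silentnet` asks the network
question: what does a growing fraction of such *synaptically silent*
neurons do to the firing rates, oscillations and synchrony of the circuit
that contains them?

The vehicle is a current-based integrate-and-fire network of 4,000 neurons
in three populations:

| population  | share | V0 (mV) | tau_m (ms) | Pc  | Ws (mV) |
|-------------|-------|---------|-----------|-----|---------|
| excitatory  | 85%   | -49     | 20        | 0.1 | +2      |
| leader      | 5%    | -46     | 20        | 0.1 | +2      |
| interneuron | 10%   | -49     | 9         | 0.2 | -9      |

Each neuron's membrane potential obeys `tau_m dV/dt = -(V - V0) + dam`,
fires when V reaches Vt = -50 mV, resets to Vr = -60 mV and is clamped
there for a 5 ms refractory period. Every ordered pair of neurons is
connected independently with the source's probability Pc, and a spike
perturbs each postsynaptic target by the source's weight Ws, one
integration step (dt = 1 ms) later. Note that V0 is *above* threshold:
every neuron is intrinsically a pacemaker (isolated period
`refractory + tau_m log((V0-Vr)/(V0-Vt))`, about 53 ms), and the quiet,
irregular activity of the intact network is entirely a product of
recurrent inhibition.

Silent neurons are modeled by a damage term `dam = -30 mV` added to the
membrane equation of a randomly chosen fraction (0.01–0.8) of a target
population (whole network, excitatory, leader, or interneuron), which
anchors their drift at -79 mV. Because they represent cells without the
capacity to fire, damaged neurons additionally never initiate spikes, even
when a synchronized volley of EPSPs transiently crosses threshold; their
membranes still contribute to the field signals.

## The synaptic coupling model

The package implements two compositions of the synaptic rule and makes the
choice explicit in `network_config(synapse = ...)`:

* **`"delta"` (default)** — a spike adds Ws directly to the target's V,
  and the perturbation relaxes at the *target's membrane* constant. Under
  this reading the two printed time constants are population properties:
  tau_e = 20 ms is the excitatory membrane constant and tau_i = 9 ms the
  interneuron membrane constant (the interneurons' "high trigger
  frequency").
* **`"cuba"`** — a spike jumps persistent synaptic variables ge/gi which
  decay with tau_e/tau_i and enter the drift
  (`tau dV/dt = -(V - V0) + ge + gi + dam`), with one shared membrane
  constant.

Only the delta composition yields a usable network, and the reason is
quantitative, not numerical. With persistent synaptic variables, one
presynaptic hertz of excitation lifts a target's time-averaged potential
by `2 mV x 360 inputs x 20 ms = 14.4 mV`, while one hertz of inhibition
depresses it by `9 mV x 80 inputs x 9 ms = 6.5 mV`. Excitation outweighs
inhibition at any common rate, so the CUBA network has a single stable
state: saturation at the refractory-limited rate (~166 Hz for every
neuron, verified by simulation for both the shared and per-population
membrane-constant variants). Under delta coupling the per-hertz drives on
a given target are `2 x 380` (excitatory) versus `9 x 80` (inhibitory)
scaled by the *same* target constant, inhibition wins, and the faster
interneuron membrane gives inhibition the higher gain that stabilizes the
balanced state.

In that state the network reproduces the intended calibration closely:
interneurons fire almost exactly 2 Hz, the excitatory median is far below
1 Hz, and the summed membrane potential shows peaks in all four
conventional bands with a dominant gamma peak near 42 Hz produced by the
interneuron rhythm.

**Known limitation.** Leader neurons — distinguished only by their +3 mV
resting offset — settle at ~0.2–0.3 Hz in the stationary state rather
than the intended 1–5 Hz. They carry the slow 20 ms membrane and so
integrate the full inhibitory load (~29 mV time-averaged
hyperpolarization), which their 3 mV advantage cannot overcome. The 1–5 Hz
range is reached only during the onset epoch (~1.7 Hz over the first
500 ms, before deep suppression develops). We found no stable reading of
the printed parameters that lifts the stationary leader rate into that
range: bounding the inhibitory excursions (the `v_floor` option) or
raising Vr destabilizes the balanced state into saturation. The package
reports the stationary value honestly.

## Measurement pipeline

* **Rates** (`per_neuron_rates`) — spike count over the analysis window
  (default: everything after the 500 ms transient) divided by window
  length; silent neurons are included in population means at 0 Hz, since
  population-level averages are what the sweep figures compare (a flag on
  the summary is unnecessary — filter the returned table to taste).
* **LFP proxy** (`lfp_trace`, recorded online by the simulator) — the
  population mean of the only current-like quantity in the model, the
  full right-hand side of the membrane equation divided by tau_m, in
  mV/ms.
* **Oscillation power** — the per-step *sum of all membrane potentials*
  is the spectral readout. `estimate_psd` is a Welch estimator (1,024 ms
  Hann segments, 50% overlap, per-segment linear detrend) scaled so the
  spectral integral matches the signal variance; `band_power` integrates
  the density over delta 1–4, theta 4–12, beta 12–30 and gamma 30–100 Hz
  (conventional edges; all configurable). `find_band_peaks` reports the
  highest in-band local maximum exceeding 5x the median density.
* **Synchrony** (`synchrony_index`) — the Fano factor of the 5 ms-binned
  population spike count, rescaled as `(F - 1)/(N - 1)` so independent
  Poisson-like firing sits near 0 and full coincidence near 1.

## The silencing sweep and its statistics

`run_sweep` crosses silencing targets with fractions
(0.01, 0.1, 0.2, 0.3, 0.5, 0.8 by default), five repetitions each, plus
unsilenced controls — 125 runs for the full grid. Within a repetition all
conditions share the same realized wiring and initial state (a
matched-control design; the silencing draw has its own stream), so
condition contrasts are not confounded by network realization. Records
are resumable through per-run CSV files keyed by a content fingerprint.

Statistics follow the standard pipeline: Pearson correlation of silenced
fraction against any response over all repetitions of a target
(two-sided t test, n-2 df), and two-way ANOVA (fraction x target) with
Tukey HSD post hoc comparisons — exact F tests for balanced grids,
type-II sums of squares otherwise. Synthetic run records with injected
linear effects (`make_synthetic_runrecords`) validate sign recovery,
type-I calibration (null rejection rate 5%) and power against the
closed-form noncentral-F oracle.

At desk scale (3 fractions x 3 repetitions, 10 s runs) the model
recovers the headline effects: silencing leaders or excitatory neurons
correlates negatively with the excitatory firing rate; silencing across
the whole population correlates *positively* (interneurons are lost too,
so the survivors disinhibit); silencing most interneurons produces an
epileptic-like state whose synchrony index exceeds the control's. One
divergence is documented rather than papered over: whole-population
silencing *raises* gamma-band power here, because in the deeply
suppressed excitatory state the gamma band is carried by the interneuron
rhythm and by burst synchrony, both of which grow as inhibition is
removed; a negative association would require excitatory membranes to
carry coherent gamma, which they do not in this parameter reading.

## What the fixtures do and do not show

`make_poisson_raster`, `make_periodic_raster`, `make_sinusoid_trace`,
`make_noise_trace` and `make_synthetic_runrecords` generate inputs with
known statistics in exactly the raster/trace/record dialects the
simulator emits, so every metric, spectral and statistical stage is
testable against analytic expectations (Poisson rate and Fano factor,
tone power A^2/2 and band concentration, Parseval, exact correlation
signs) without running the network. Passing those tests validates the
*measurement pipeline*; it says nothing about the realism of the network
model itself, which is constrained instead by the calibration targets and
sign recoveries above. None of the fixtures emulate refractoriness,
rate nonstationarity, or cross-train correlations other than full
coincidence.

## Numerical choices

* Exponential-Euler updates (exact for the linear drift between synaptic
  events) rather than forward Euler at the coarse dt = 1 ms; a forward
  Euler mode is kept for comparison. With no synapses the integrator's
  inter-spike interval matches the closed form to the step-quantization
  limit.
* Spike delivery is delayed by one step, and threshold is tested after
  the membrane update, removing within-step event-ordering ambiguity.
* During the refractory window V is clamped at Vr; CUBA synaptic
  variables keep integrating input, while delta-coupling jumps aimed at a
  clamped membrane are lost.
* Vr = -60 mV (the lower bound of the stated initialization range),
  simulation length 10 s and transient 500 ms are package choices, stated
  here because no printed value fixes them; rates are stationary after
  the first few hundred milliseconds, so results are insensitive to the
  transient choice.
* All randomness flows from one master seed through independent derived
  streams (wiring / initialization / silencing / condition), so any run
  or sweep is bit-reproducible and a changed silencing fraction never
  re-wires the network.

## Reproducing the headline numbers

The default test suite exercises every property above at reduced network
sizes (400 neurons, 1–2 s) and runs the full-size calibration and sweeps
(4,000 neurons, 10 s, 5 seeds; 30-run scaled sweep) in its acceptance
suite. `scripts/acceptance.R` recomputes the control-network calibration
(excitatory median, leader mean, interneuron mean rates) from five fresh
10 s simulations and writes them as JSON.
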