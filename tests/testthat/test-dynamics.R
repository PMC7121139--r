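# Dynamics of the integrator against closed-form solutions of the
# linear membrane equation, plus cross-validation of the compiled core
# against the pure-R reference stepper.

test_that("resting potential is a fixed point of the drift", {
  cfg <- drift_config(n_total = 3, v0 = -55, vt = -45)
  net <- build_network(cfg)
  state <- structure(list(v = rep(-55, 3), ge = numeric(3), gi = numeric(3),
                          refractory_remaining = numeric(3)),
                     class = "neuron_state")
  for (k in 1:50) state <- step_neurons(state, net, cfg)$state
  expect_equal(state$v, rep(-55, 3))
})

test_that("isolated suprathreshold neurons fire at the closed-form interval", {
  cfg <- drift_config(n_total = 5, duration = 2000)
  isi_exact <- drift_isi(cfg)        # 5 + 20 log(11/1)
  expect_equal(isi_exact, 5 + 20 * log(11))
  res <- run_simulation(build_network(cfg), cfg)
  isis <- unlist(lapply(1:5, function(i) diff(neuron_times(res$raster, i))))
  expect_true(all(abs(isis - isi_exact) / isi_exact < 0.01))

  # finer steps converge to the exact value, for both integration schemes
  for (m in c("exact", "euler")) {
    cfg_f <- drift_config(n_total = 1, dt = 0.01, duration = 300, method = m)
    res_f <- run_simulation(build_network(cfg_f), cfg_f)
    isis_f <- diff(neuron_times(res_f$raster, 1))
    expect_true(all(abs(isis_f - isi_exact) / isi_exact < 0.005))
  }
})

test_that("a damage term of -30 mV suppresses firing entirely", {
  cfg <- drift_config(n_total = 10, duration = 3000)
  net <- apply_damage(build_network(cfg), 1:10, -30)
  res <- run_simulation(net, cfg)
  expect_equal(n_spikes(res$raster), 0L)
  # the drift attractor moves to v0 + dam = -79 mV
  st <- structure(list(v = rep(-55, 10), ge = numeric(10), gi = numeric(10),
                       refractory_remaining = numeric(10)),
                  class = "neuron_state")
  for (k in 1:400) st <- step_neurons(st, net, cfg)$state
  expect_equal(st$v, rep(-79, 10), tolerance = 1e-6)
})

test_that("compiled core and R reference stepper agree spike-for-spike", {
  for (syn in c("delta", "cuba")) {
    cfg <- small_config(seed = 2L, duration = 400, n_total = 60,
                        synapse = syn)
    net <- build_network(cfg)
    a <- run_simulation(net, cfg)
    b <- run_simulation_r(net, cfg)
    expect_identical(a$raster$events, b$raster$events)
    expect_equal(a$traces$lfp, b$traces$lfp, tolerance = 1e-12)
    expect_equal(a$traces$vm_sum, b$traces$vm_sum, tolerance = 1e-12)
  }
})

test_that("synaptic variables decay exponentially to zero after input stops", {
  cfg <- drift_config(n_total = 2, vt = -30, synapse = "cuba")
  net <- build_network(cfg)
  st <- structure(list(v = rep(-55, 2), ge = c(5, 5), gi = c(-3, -3),
                       refractory_remaining = numeric(2)),
                  class = "neuron_state")
  for (k in 1:40) st <- step_neurons(st, net, cfg)$state
  expect_equal(st$ge, 5 * exp(-40 / cfg$tau_e) * c(1, 1), tolerance = 1e-12)
  expect_equal(st$gi, -3 * exp(-40 / cfg$tau_i) * c(1, 1), tolerance = 1e-12)
  # ten time constants on: relaxed to (numerical) zero
  for (k in 1:200) st <- step_neurons(st, net, cfg)$state
  expect_true(all(abs(st$ge) < 5 * exp(-10)))
  expect_true(all(abs(st$gi) < 3 * exp(-10)))
})

test_that("no raster violates the refractory period", {
  cfg <- small_config(seed = 4L)
  res <- run_simulation(build_network(cfg), cfg)
  expect_gt(n_spikes(res$raster), 0L)
  expect_true(all(min_isi(res$raster) >= cfg$refractory))
})

test_that("identical configuration and seed reproduce the run bit-exactly", {
  cfg <- small_config(seed = 12L, duration = 1000)
  net <- build_network(cfg)
  a <- run_simulation(net, cfg)
  b <- run_simulation(net, cfg)
  expect_identical(a$raster$events, b$raster$events)
  expect_identical(a$traces, b$traces)
  c <- run_simulation(net, cfg, seed = 13L)
  expect_false(identical(a$raster$events, c$raster$events))
})

test_that("the edgeless network shows a rhythmic population signal at the drift frequency", {
  cfg <- drift_config(n_total = 200, duration = 4096)
  res <- run_simulation(build_network(cfg), cfg)
  # every neuron fires periodically
  counts <- spike_counts(res$raster)
  expect_true(all(counts >= floor(4096 / drift_isi(cfg)) - 1))
  # summed membrane potential peaks at the closed-form firing frequency
  psd <- estimate_psd(res, column = "vm_sum")
  f_expect <- 1000 / drift_isi(cfg)
  sel <- psd$freq_hz > 2
  peak <- psd$freq_hz[sel][which.max(psd$power[sel])]
  expect_lt(abs(peak - f_expect), 2 * attr(psd, "df_hz"))
})
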