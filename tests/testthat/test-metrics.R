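test_that("per-neuron rates are count over window, with zero-spike neurons present", {
  r <- spike_raster(rep(1L, 20), seq(500, 10000, length.out = 20),
                    labels = rep("excitatory", 3), duration_ms = 10000)
  rt <- per_neuron_rates(r, window = c(0, 10000))
  expect_equal(nrow(rt), 3)
  expect_equal(rt$rate_hz, c(2, 0, 0))
  summ <- population_rates(rt)
  expect_equal(summ$mean_hz[summ$population == "excitatory"], 2 / 3)

  empty <- make_poisson_raster(5, 0, 1000, seed = 1L)
  expect_equal(per_neuron_rates(empty, c(0, 1000))$rate_hz, rep(0, 5))
  expect_error(per_neuron_rates(r, window = c(100, 100)), "window")
})

test_that("population rates conserve the total spike count", {
  r <- make_poisson_raster(60, 4, 20000, seed = 3L,
                           labels = rep(c("excitatory", "interneuron"), 30))
  rt <- per_neuron_rates(r, window = c(0, 20000))
  summ <- population_rates(rt)
  pops <- summ[summ$population != "all", ]
  total_from_means <- sum(pops$mean_hz * pops$n) * 20
  expect_equal(total_from_means, n_spikes(r))
})

test_that("rates agree between disjoint half-windows of a stationary train", {
  r <- make_poisson_raster(200, 5, 60000, seed = 6L)
  a <- mean(per_neuron_rates(r, c(0, 30000))$rate_hz)
  b <- mean(per_neuron_rates(r, c(30000, 60000))$rate_hz)
  se <- sqrt(5 / (200 * 30)) * sqrt(2)
  expect_lt(abs(a - b), 4 * se)
})

test_that("online field traces equal recomputation from the stored state history", {
  for (syn in c("delta", "cuba")) {
    cfg <- small_config(seed = 5L, duration = 300, n_total = 40, synapse = syn)
    net <- build_network(cfg)
    res <- run_simulation(net, cfg, record_state = TRUE)
    lfp2 <- lfp_trace(res$history, net, cfg)
    vm2 <- vm_sum_trace(res$history, cfg)
    expect_equal(res$traces$lfp, lfp2$lfp, tolerance = 1e-12)
    expect_equal(res$traces$vm_sum, vm2$vm_sum, tolerance = 1e-12)
  }
})

test_that("field traces reproduce direct closed-form cases", {
  cfg <- drift_config(n_total = 1, v0 = -49, tau_m = 20)
  net <- build_network(cfg)
  # one neuron held 20 mV above rest: transmembrane current -20/20 = -1 mV/ms
  hist <- list(v = matrix(-29, 5, 1), ge = matrix(0, 5, 1),
               gi = matrix(0, 5, 1))
  expect_equal(lfp_trace(hist, net, cfg)$lfp, rep(-1, 5))
  # all neurons at rest: zero current
  hist0 <- list(v = matrix(-49, 5, 1), ge = matrix(0, 5, 1),
                gi = matrix(0, 5, 1))
  expect_equal(lfp_trace(hist0, net, cfg)$lfp, rep(0, 5))
  # vm_sum additivity over disjoint groups
  v <- matrix(rnorm(40, -49), 10, 4)
  h <- function(cols) list(v = v[, cols, drop = FALSE])
  expect_equal(vm_sum_trace(h(1:4), cfg)$vm_sum,
               vm_sum_trace(h(1:2), cfg)$vm_sum +
                 vm_sum_trace(h(3:4), cfg)$vm_sum)
  # N neurons at -49 sum to -49 N
  expect_equal(vm_sum_trace(list(v = matrix(-49, 3, 7)), cfg)$vm_sum,
               rep(-49 * 7, 3))
})

test_that("synchrony index sits at the Poisson baseline for independent trains", {
  r <- make_poisson_raster(100, 2, 100000, seed = 11L)
  fano <- synchrony_index(r, bin_ms = 5, normalize = FALSE,
                          window = c(0, 100000))
  expect_lt(abs(fano - 1), 0.1)
  expect_lt(abs(synchrony_index(r, window = c(0, 100000))), 0.005)
})

test_that("perfect coincidence maximizes the synchrony index", {
  r <- make_periodic_raster(50, period_ms = 100, duration_ms = 20000)
  idx <- synchrony_index(r, bin_ms = 5, window = c(0, 20000))
  expect_gt(idx, 0.8)
  empty <- make_poisson_raster(10, 0, 1000, seed = 1L)
  expect_equal(synchrony_index(empty, window = c(0, 1000)), 0)
})
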