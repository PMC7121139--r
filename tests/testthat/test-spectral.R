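test_that("a pure 40 Hz tone concentrates its power in the gamma band", {
  tr <- make_sinusoid_trace(data.frame(freq_hz = 40, amplitude = 1), 10000)
  psd <- estimate_psd(tr)
  peak <- psd$freq_hz[which.max(psd$power)]
  expect_lt(abs(peak - 40), attr(psd, "df_hz"))
  expect_gt(band_power(psd, "gamma") / total_power(psd), 0.95)
  # Parseval: total spectral power matches the signal variance (A^2/2)
  expect_lt(abs(total_power(psd) / stats::var(tr$vm_sum) - 1), 0.02)
})

test_that("white noise gives a flat spectrum satisfying Parseval", {
  tr <- make_noise_trace(60000, noise_sd = 1.5, seed = 7L)
  psd <- estimate_psd(tr)
  expect_lt(abs(total_power(psd) / stats::var(tr$vm_sum) - 1), 0.02)
  # flatness: log-power regressed on frequency has negligible slope
  sel <- psd$freq_hz > 0
  fit <- stats::lm(log(power) ~ freq_hz, data = psd[sel, ])
  # predicted log-power change over the whole axis is small
  expect_lt(abs(coef(fit)[2]) * 500, 0.25)
})

test_that("band powers scale with the square of the signal amplitude", {
  tr <- make_sinusoid_trace(data.frame(freq_hz = c(8, 45),
                                       amplitude = c(1, 0.5)), 8000,
                            noise_sd = 0.2, seed = 2L)
  tr3 <- tr
  tr3$vm_sum <- 3 * tr$vm_sum
  p1 <- estimate_psd(tr)
  p3 <- estimate_psd(tr3)
  for (b in default_bands()$name)
    expect_equal(band_power(p3, b), 9 * band_power(p1, b), tolerance = 1e-9)
})

test_that("band peaks are recovered for a two-tone signal and absent for noise", {
  tr <- make_sinusoid_trace(data.frame(freq_hz = c(6, 45),
                                       amplitude = c(1, 1)), 10000)
  pk <- find_band_peaks(estimate_psd(tr))
  expect_true(pk$detected[pk$band == "theta"])
  expect_true(pk$detected[pk$band == "gamma"])
  df <- attr(estimate_psd(tr), "df_hz")
  expect_lt(abs(pk$freq_hz[pk$band == "theta"] - 6), df)
  expect_lt(abs(pk$freq_hz[pk$band == "gamma"] - 45), df)

  noise <- find_band_peaks(estimate_psd(make_noise_trace(60000, seed = 4L)))
  expect_false(any(noise$detected))
})

test_that("degenerate and invalid spectral inputs are handled", {
  zero <- data.frame(time_ms = 0:4095, vm_sum = numeric(4096))
  psd <- estimate_psd(zero)
  for (b in default_bands()$name) expect_equal(band_power(psd, b), 0)
  expect_error(estimate_psd(make_noise_trace(500, seed = 1L)),
               "shorter than one segment")
  tr <- make_noise_trace(4096, seed = 1L)
  expect_error(band_power(estimate_psd(tr), c(400, 600)), "outside")
  expect_error(band_power(estimate_psd(tr), c(30, 20)), "low < high")
})

test_that("disjoint band powers never exceed the total power", {
  tr <- make_sinusoid_trace(data.frame(freq_hz = c(3, 9, 20, 60),
                                       amplitude = c(1, 1, 1, 1)), 20000,
                            noise_sd = 0.5, seed = 9L)
  psd <- estimate_psd(tr)
  bp <- vapply(default_bands()$name, function(b) band_power(psd, b),
               numeric(1))
  expect_lt(sum(bp), total_power(psd) * (1 + 1e-9))
})

test_that("the estimate is invariant under concatenation of identical segments", {
  # tone with an integer number of cycles per 1024-sample segment
  f <- 40 * 1000 / 1024
  seg <- make_sinusoid_trace(data.frame(freq_hz = f, amplitude = 1), 1024)
  rep8 <- data.frame(time_ms = seq_len(8 * 1024) - 1,
                     vm_sum = rep(seg$vm_sum, 8))
  p1 <- estimate_psd(seg, overlap = 0)
  p8 <- estimate_psd(rep8, overlap = 0)
  expect_equal(p8$power, p1$power, tolerance = 1e-9)
})
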