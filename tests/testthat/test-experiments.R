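test_that("the full study grid enumerates 125 runs", {
  cond <- sweep_conditions(sweep_grid())
  expect_equal(nrow(cond), 4 * 6 * 5 + 5)
  expect_equal(sum(cond$fraction == 0), 5)
  expect_equal(length(unique(paste(cond$target, cond$fraction, cond$rep))),
               nrow(cond))
})

test_that("a miniature sweep runs, resumes, and reproduces bit-identically", {
  cfg <- small_config(seed = 2L, duration = 1200, n_total = 300)
  grid <- sweep_grid(targets = c("whole", "excitatory"),
                     fractions = c(0.3, 0.8), repetitions = 2)
  out_dir <- withr::local_tempdir()
  rec <- run_sweep(cfg, grid, out_dir = out_dir)
  expect_equal(nrow(rec), 2 * 2 * 2 + 2)
  expect_true(all(rec$ok))
  metric_cols <- c("rate_mean_excitatory", "rate_mean_leader",
                   "rate_mean_interneuron", "rate_mean_whole",
                   "power_delta", "power_theta", "power_beta", "power_gamma",
                   "synchrony")
  for (cc in metric_cols) expect_true(all(is.finite(rec[[cc]])))
  # resume: second invocation reads the stored records instead of rerunning
  t0 <- Sys.time()
  rec2 <- run_sweep(cfg, grid, out_dir = out_dir)
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 2)
  expect_equal(rec2[metric_cols], rec[metric_cols], tolerance = 1e-12)
  # fresh recomputation is bit-identical
  rec3 <- run_sweep(cfg, grid)
  expect_identical(rec3[metric_cols], rec[metric_cols])
})

test_that("Pearson correlation recovers exact monotone responses", {
  grid <- sweep_grid(targets = c("whole", "leader"),
                     fractions = c(0.1, 0.3, 0.8), repetitions = 3)
  up <- make_synthetic_runrecords(grid, baseline = 0, effect = 1)
  ct <- correlate_fraction(up, "whole", "response")
  expect_equal(ct$r, 1)
  down <- make_synthetic_runrecords(grid, baseline = 2, effect = -1)
  expect_equal(correlate_fraction(down, "leader", "response")$r, -1)
  flat <- make_synthetic_runrecords(grid, baseline = 1, effect = 0)
  res <- correlate_fraction(flat, "whole", "response")
  expect_true(is.na(res$r))
  expect_match(res$reason, "zero variance")
  expect_error(correlate_fraction(up[up$fraction == 0.1, ], "whole",
                                  "response"), "3 distinct fractions")
})

test_that("identical responses give a null ANOVA with zero Tukey differences", {
  grid <- sweep_grid(targets = c("whole", "excitatory"),
                     fractions = c(0.1, 0.5), repetitions = 3)
  rec <- make_synthetic_runrecords(grid, baseline = 2, effect = 0)
  rep_out <- anova_tukey(rec, "response")
  expect_true(all(rep_out$anova$statistic[1:3] == 0))
  expect_true(all(abs(rep_out$tukey$f_fraction$diff) < 1e-12))
  expect_true(rep_out$balanced)
})

test_that("fraction-effect rejection rate matches the noncentral-F power", {
  grid <- sweep_grid(targets = c("whole", "excitatory"),
                     fractions = c(0.01, 0.1, 0.2, 0.3, 0.5, 0.8),
                     repetitions = 5)
  hits <- vapply(1:200, function(s) {
    rec <- make_synthetic_runrecords(grid, baseline = 1, effect = 2,
                                     noise_sd = 1, seed = s)
    tab <- anova_tukey(rec, "response")$anova
    tab$p_value[tab$term == "f_fraction"] < 0.01
  }, logical(1))
  # independent oracle: closed-form power of the F test. Cell means are
  # effect * fraction, 2 targets x 5 reps per fraction, sigma = 1.
  f <- c(0.01, 0.1, 0.2, 0.3, 0.5, 0.8)
  mu <- 2 * f
  ncp <- 10 * sum((mu - mean(mu))^2)
  power <- 1 - stats::pf(stats::qf(0.99, 5, 48), 5, 48, ncp = ncp)
  se <- sqrt(power * (1 - power) / 200)
  expect_lt(abs(mean(hits) - power), 4 * se)
})

test_that("unbalanced designs fall back to type-II sums of squares", {
  grid <- sweep_grid(targets = c("whole", "excitatory"),
                     fractions = c(0.1, 0.5), repetitions = 3)
  rec <- make_synthetic_runrecords(grid, baseline = 1, effect = 2,
                                   noise_sd = 0.5, seed = 3L)
  rec <- rec[-7, ]   # drop one silenced run
  out <- anova_tukey(rec, "response")
  expect_false(out$balanced)
  expect_true(all(c("f_fraction", "f_target") %in% out$anova$term))
  one_target <- rec[rec$target == "whole", ]
  expect_error(anova_tukey(one_target, "response"), "fewer than 2 levels")
})
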