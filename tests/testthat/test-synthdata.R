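test_that("seed determinism: identical params and seed give bit-identical outputs", {
  a <- simulate_fmd_trace(noise_sd_diameter = 0.002, noise_sd_velocity = 0.8,
                          seed = 42)
  b <- simulate_fmd_trace(noise_sd_diameter = 0.002, noise_sd_velocity = 0.8,
                          seed = 42)
  expect_identical(a, b)

  ra <- simulate_rr_series(noise_sd = 0.02, seed = 7)
  rb <- simulate_rr_series(noise_sd = 0.02, seed = 7)
  expect_identical(ra, rb)

  ca <- simulate_cohort(n_per_group = 4, seed = 3)
  cb <- simulate_cohort(n_per_group = 4, seed = 3)
  expect_identical(ca, cb)
})

test_that("noiseless FMD trace is built to its programmed geometry", {
  tr <- simulate_fmd_trace(baseline_diameter = 0.30, fmd_percent = 10,
                           time_to_peak = 30, noise_sd_diameter = 0,
                           noise_sd_velocity = 0, seed = 1)
  at <- function(t) which.min(abs(tr$time - t))
  expect_equal(max(tr$diameter), 0.33, tolerance = 1e-12)
  expect_equal(tr$diameter[at(30)], 0.33, tolerance = 1e-12)
  # pre-deflation plateau at baseline
  expect_true(all(tr$diameter[tr$time < 0] == 0.30))
  # velocity: peak at release, exponential decay toward baseline
  expect_equal(tr$velocity[at(0)], 60, tolerance = 1e-10)
  expect_lt(tr$velocity[at(120)], 60)
  expect_gt(tr$velocity[at(120)], 11)

  # null effect: constant diameter, %FMD = 0 downstream
  tr0 <- simulate_fmd_trace(fmd_percent = 0, noise_sd_diameter = 0,
                            noise_sd_velocity = 0, seed = 1)
  expect_true(all(tr0$diameter == tr0$diameter[1L]))
  expect_equal(analyze_fmd(tr0)$fmd_percent, 0, tolerance = 1e-12)
})

test_that("Monte-Carlo recovery: noisy traces recover the programmed %FMD", {
  est <- vapply(1:100, function(s) {
    tr <- simulate_fmd_trace(fmd_percent = 10, noise_sd_diameter = 0.002,
                             seed = s)
    analyze_fmd(tr)$fmd_percent
  }, numeric(1))
  expect_lt(abs(mean(est) - 10), 1)        # within 1 percentage point
  expect_lt(sd(est), 1)                    # replicate spread is tight
})

test_that("FMD simulator rejects invalid parameters", {
  expect_error(simulate_fmd_trace(baseline_diameter = -1),
               class = "vasoreact_parameter_error")
  expect_error(simulate_fmd_trace(fmd_percent = -2),
               class = "vasoreact_parameter_error")
  expect_error(simulate_fmd_trace(peak_velocity = 5, baseline_velocity = 11),
               class = "vasoreact_parameter_error")
  expect_error(simulate_fmd_trace(noise_sd_diameter = -0.1),
               class = "vasoreact_parameter_error")
})

test_that("RR generator honours its contract", {
  rr <- simulate_rr_series(mean_rr = 0.9, noise_sd = 0.02, duration = 600,
                           seed = 11)
  expect_true(all(rr$rr > 0))
  expect_gte(rr$duration, 600 - 2 * 0.9)
  # mean of generated RR within 3 SE of mean_rr (modulation averages out)
  se <- sd(rr$rr) / sqrt(length(rr$rr))
  expect_lt(abs(mean(rr$rr) - 0.9), 3 * se + 1e-3)

  expect_error(simulate_rr_series(duration = 200),
               class = "vasoreact_parameter_error")
  expect_error(simulate_rr_series(lf_freq = 0.30),
               class = "vasoreact_parameter_error")
  expect_error(simulate_rr_series(hf_freq = 0.05),
               class = "vasoreact_parameter_error")
})

test_that("cohort generator: shape, programmed effects, smallest cohort", {
  # smallest valid cohort: 2 per group, one variable -> 8 rows
  co <- simulate_cohort(n_per_group = 2, effects = list(MIP = c(48, 5, 1, 1)),
                        within_subject_rho = 0, seed = 1)
  expect_equal(nrow(co), 8L)
  expect_setequal(unique(co$group), c("RMT", "SHAM"))
  expect_setequal(unique(co$time), c("pre", "post"))
  expect_true(all(co$value > 0))
  # each (subject, time, variable) unique; subjects nested in one group
  expect_false(any(duplicated(co[, c("subject", "time", "variable")])))
  expect_true(all(tapply(co$group, co$subject, function(g) length(unique(g))) == 1))

  # programmed MIP effect x1.31 (RMT) with small SD is recovered
  co2 <- simulate_cohort(n_per_group = 12,
                         effects = list(MIP = c(48, 0.5, 1.31, 1.00)),
                         within_subject_rho = 0.9, seed = 5)
  w <- merge(co2[co2$time == "pre", c("subject", "group", "value")],
             co2[co2$time == "post", c("subject", "value")],
             by = "subject", suffixes = c("_pre", "_post"))
  pct_rmt <- mean(percent_change(w$value_pre[w$group == "RMT"],
                                 w$value_post[w$group == "RMT"]))
  pct_sham <- mean(percent_change(w$value_pre[w$group == "SHAM"],
                                  w$value_post[w$group == "SHAM"]))
  expect_lt(abs(pct_rmt - 31), 2)
  expect_lt(abs(pct_sham), 2)

  expect_error(simulate_cohort(n_per_group = 1),
               class = "vasoreact_parameter_error")
  expect_error(simulate_cohort(within_subject_rho = 1.5),
               class = "vasoreact_parameter_error")
})
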