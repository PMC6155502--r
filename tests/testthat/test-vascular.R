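flat_trace <- function(d = 0.30, v = 10, t = seq(-30, 120, by = 0.25)) {
  fmd_trace(t, rep(d, length(t)), rep(v, length(t)))
}

test_that("blood flow and shear rate arithmetic and scaling laws", {
  expect_equal(blood_flow(10, 0.4), 10 * pi * 0.2^2 * 60)
  expect_equal(round(blood_flow(10, 0.4), 2), 75.40)
  expect_equal(round(blood_flow(5, 0.2), 2), 9.42)
  expect_equal(blood_flow(0, 0.3), 0)
  expect_equal(shear_rate(10, 0.4), 200)
  expect_equal(shear_rate(0, 0.5), 0)
  # algebraic inverse: v = SR * d / 8
  sr <- shear_rate(12.3, 0.37)
  expect_equal(sr * 0.37 / 8, 12.3)

  # linear in v_mean; flow ~ d^2; SR ~ 1/d
  v <- 7.3; d <- 0.31
  expect_equal(blood_flow(2 * v, d), 2 * blood_flow(v, d))
  expect_equal(shear_rate(2 * v, d), 2 * shear_rate(v, d))
  expect_equal(blood_flow(v, 2 * d), 4 * blood_flow(v, d))
  expect_equal(shear_rate(v, 2 * d), shear_rate(v, d) / 2)

  expect_error(blood_flow(-1, 0.3), class = "vasoreact_domain_error")
  expect_error(blood_flow(1, 0), class = "vasoreact_domain_error")
  expect_error(shear_rate(1, -0.1), class = "vasoreact_domain_error")
})

test_that("fmd_percent arithmetic", {
  expect_equal(fmd_percent(0.30, 0.33), 10)
  expect_equal(fmd_percent(0.42, 0.42), 0)
  expect_equal(round(fmd_percent(0.29, 0.32), 2), 10.34)
  expect_error(fmd_percent(0, 0.3), class = "vasoreact_domain_error")
})

test_that("baseline diameter averages the pre-deflation window", {
  expect_equal(baseline_diameter(flat_trace(0.30)), 0.30)

  # explicit pre-window values average arithmetically
  t <- seq(-30, 120, by = 1)
  d <- rep(0.30, length(t))
  d[t < 0] <- rep(c(0.29, 0.30, 0.31), length.out = sum(t < 0))
  tr <- fmd_trace(t, d, rep(10, length(t)))
  expect_equal(baseline_diameter(tr), 0.30)

  # noisy baseline within 3 SE of truth
  set.seed(2)
  n_pre <- sum(seq(-30, 120, by = 0.1) < 0)
  tr2 <- simulate_fmd_trace(baseline_diameter = 0.30,
                            noise_sd_diameter = 0.002, seed = 2)
  expect_lt(abs(baseline_diameter(tr2) - 0.30), 3 * 0.002 / sqrt(n_pre))

  # empty pre-window -> insufficient data
  t3 <- seq(0.1, 120, by = 0.1)
  tr3 <- fmd_trace(t3, rep(0.3, length(t3)), rep(10, length(t3)))
  expect_error(baseline_diameter(tr3),
               class = "vasoreact_insufficient_data_error")
})

test_that("peak detection: construction, boundary, and smoothed-scan oracle", {
  tr <- simulate_fmd_trace(baseline_diameter = 0.30, fmd_percent = 10,
                           time_to_peak = 30, noise_sd_diameter = 0,
                           noise_sd_velocity = 0, seed = 1)
  pk <- peak_diameter(tr)
  expect_equal(pk$peak_diameter, 0.33, tolerance = 1e-12)
  expect_equal(pk$time_to_peak, 30)

  # monotone-decreasing post-release diameter -> peak at first post sample
  t <- seq(-30, 120, by = 0.5)
  d <- ifelse(t <= 0, 0.35, 0.35 - 0.0004 * t)
  trd <- fmd_trace(t, d, rep(10, length(t)))
  pkd <- peak_diameter(trd, smooth_window = 0)
  expect_equal(pkd$time_to_peak, 0.5)

  # noisy trace: result identical to a brute-force scan of the
  # independently smoothed series
  set.seed(9)
  tr2 <- simulate_fmd_trace(fmd_percent = 8, noise_sd_diameter = 0.004,
                            seed = 9)
  sm <- smooth_oracle(tr2$diameter, 3, tr2$sample_rate)
  post <- tr2$time > 0
  i <- which.max(sm[post])
  pk2 <- peak_diameter(tr2, smooth_window = 3)
  expect_equal(pk2$peak_diameter, sm[post][i], tolerance = 1e-12)
  expect_equal(pk2$time_to_peak, tr2$time[post][i])

  # no post-deflation samples -> error
  tpre <- seq(-30, -0.5, by = 0.5)
  trp <- fmd_trace(tpre, rep(0.3, length(tpre)), rep(0, length(tpre)))
  expect_error(peak_diameter(trp), class = "vasoreact_insufficient_data_error")
})

test_that("cumulative shear rate equals the trapezoid oracle", {
  # rectangle: constant SR 200 over 30 s -> 6000 (v chosen so 8v/d = 200)
  tr <- flat_trace(d = 0.30, v = 200 * 0.30 / 8)
  expect_equal(cumulative_shear_rate(tr, 0, 30), 6000, tolerance = 1e-9)

  # triangle: linear SR ramp 0 -> 100 over 10 s -> 500, exact for trapezoid
  t <- seq(-30, 120, by = 0.5)
  d <- rep(0.40, length(t))
  v <- ifelse(t >= 0 & t <= 10, (100 * t / 10) * 0.40 / 8, 0)
  trr <- fmd_trace(t, d, v)
  sel <- t >= 0 & t <= 10
  expect_equal(cumulative_shear_rate(trr, 0, 10),
               trapz_oracle(t[sel], 8 * v[sel] / d[sel]))
  expect_equal(cumulative_shear_rate(trr, 0, 10), 500, tolerance = 1e-9)

  # random SR series vs the explicit per-interval oracle, machine precision
  set.seed(4)
  t2 <- sort(c(-5, cumsum(runif(200, 0.05, 0.5))))
  d2 <- runif(length(t2), 0.25, 0.45)
  v2 <- runif(length(t2), 0, 80)
  tr2 <- fmd_trace(t2, d2, v2, pre_deflation_window = 5)
  tp <- t2[length(t2)] - 1
  sel2 <- t2 >= 0 & t2 <= tp
  expect_equal(cumulative_shear_rate(tr2, 0, tp),
               trapz_oracle(t2[sel2], 8 * v2[sel2] / d2[sel2]),
               tolerance = 1e-13)

  expect_error(cumulative_shear_rate(tr, 30, 10),
               class = "vasoreact_ordering_error")
})

test_that("normalized FMD: arithmetic and velocity-scaling law", {
  expect_equal(normalized_fmd(10, 5000), 0.002)
  expect_equal(normalized_fmd(0, 1234), 0)
  expect_error(normalized_fmd(10, 0), class = "vasoreact_domain_error")

  # doubling all velocities (same diameters) halves %FMD/SR at fixed %FMD
  tr <- simulate_fmd_trace(fmd_percent = 8, noise_sd_diameter = 0,
                           noise_sd_velocity = 0, seed = 1)
  tr2 <- fmd_trace(tr$time, tr$diameter, 2 * tr$velocity,
                   sample_rate = tr$sample_rate)
  csr1 <- cumulative_shear_rate(tr, 0, 30)
  csr2 <- cumulative_shear_rate(tr2, 0, 30)
  expect_equal(csr2, 2 * csr1, tolerance = 1e-12)
  expect_equal(normalized_fmd(8, csr2), normalized_fmd(8, csr1) / 2)
})

test_that("vascular conductance reproduces the acute-session values", {
  expect_equal(round(vascular_conductance(47.8, 101), 2), 0.47)
  expect_equal(round(vascular_conductance(116.9, 108), 2), 1.08)
  expect_equal(vascular_conductance(0, 90), 0)
  expect_error(vascular_conductance(50, 0), class = "vasoreact_domain_error")
})

test_that("allometric scaling check: proportionality, bias, and errors", {
  set.seed(3)
  b <- exp(rnorm(12, log(0.30), 0.12))

  # exact proportionality: slope 1, degenerate CI, valid
  chk <- allometric_scaling_check(b, 1.1 * b)
  expect_equal(chk$slope, 1, tolerance = 1e-10)
  expect_equal(chk$ci_low, chk$ci_high, tolerance = 1e-10)
  expect_true(chk$ratio_scaling_valid)

  # peak = baseline^0.8 * noise at n = 200: upper CI below 1
  b2 <- exp(rnorm(200, log(0.30), 0.15))
  p2 <- b2^0.8 * exp(rnorm(200, 0, 0.005))
  chk2 <- allometric_scaling_check(b2, p2)
  expect_lt(chk2$ci_high, 1)
  expect_false(chk2$ratio_scaling_valid)

  expect_error(allometric_scaling_check(b[1:2], 1.1 * b[1:2]),
               class = "vasoreact_insufficient_data_error")
  expect_error(allometric_scaling_check(c(0.3, -0.1, 0.4), c(0.3, 0.2, 0.5)),
               class = "vasoreact_domain_error")
})

test_that("hyperaemic flow curve: rectangle AUC, idempotence, linearity", {
  # constant flow F over [0, 120 s] -> AUC = 2 F (minutes as time unit)
  tr <- flat_trace(d = 0.40, v = 10)
  f <- blood_flow(10, 0.40)
  hc <- hyperaemia_flow_curve(tr, bin_width = 2)
  expect_equal(hc$flow_auc, 2 * f, tolerance = 1e-9)
  expect_true(all(abs(hc$flow - f) < 1e-9))

  # mean of two identical traces equals either input
  hc2 <- hyperaemia_flow_curve(list(tr, tr), bin_width = 2)
  expect_equal(hc2$flow, hc$flow)
  expect_equal(hc2$flow_auc, hc$flow_auc)

  # uniform 0.71x velocity scaling scales the AUC by 0.71
  tr3 <- flat_trace(d = 0.40, v = 10 * 0.71)
  hc3 <- hyperaemia_flow_curve(tr3)
  expect_equal(hc3$flow_auc / hc$flow_auc, 0.71, tolerance = 1e-9)

  expect_error(hyperaemia_flow_curve(list()),
               class = "vasoreact_parameter_error")
})

test_that("windowed hemodynamics averages and derived quantities", {
  t <- seq(0, 60, by = 0.5)
  const <- data.frame(time = t, heart_rate = 70, map = 100, sv = 50)
  w <- windowed_hemodynamics(const)
  expect_equal(w$baseline$heart_rate, 70)
  expect_equal(w$exercise$heart_rate, 70)
  expect_equal(w$baseline$co, 3.5)   # sv 50 x hr 70 -> 3.5 l/min

  # HR 70 at baseline, 83 in the tail -> +18.57% change
  hr <- ifelse(t <= 30, 70, 83)
  d2 <- data.frame(time = t, heart_rate = hr, map = 100, sv = 50)
  w2 <- windowed_hemodynamics(d2)
  expect_equal(w2$baseline$heart_rate, 70)
  expect_equal(w2$exercise$heart_rate, 83)
  expect_equal(percent_change(w2$baseline$heart_rate, w2$exercise$heart_rate),
               18.57, tolerance = 1e-3)

  # velocity/diameter streams yield flow, SR and BVC from averaged primitives
  d3 <- data.frame(time = t, velocity = 10, diameter = 0.4, map = 101)
  w3 <- windowed_hemodynamics(d3)
  expect_equal(w3$baseline$blood_flow, blood_flow(10, 0.4))
  expect_equal(w3$baseline$sr, 200)
  expect_equal(w3$baseline$bvc, blood_flow(10, 0.4) / 101)

  expect_error(windowed_hemodynamics(data.frame(time = 1:10, heart_rate = 70)),
               class = "vasoreact_insufficient_data_error")
})

test_that("analyze_fmd recovers programmed values on noiseless traces", {
  for (fmd in c(4, 8, 12)) {
    for (ttp in c(25, 30, 40)) {
      tr <- simulate_fmd_trace(fmd_percent = fmd, time_to_peak = ttp,
                               noise_sd_diameter = 0, noise_sd_velocity = 0,
                               seed = 1)
      res <- analyze_fmd(tr)
      expect_equal(res$fmd_percent, fmd, tolerance = 1e-9)
      expect_equal(res$time_to_peak, ttp, tolerance = 1e-6)
      expect_gt(res$cumulative_sr, 0)
      expect_equal(res$fmd_per_sr, fmd / res$cumulative_sr)
    }
  }
})
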