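#' Simulate a flow-mediated dilation recording
#'
#' Generates a synthetic brachial-artery diameter/velocity trace with the
#' shape of the standard FMD protocol: the recording starts 30 s before
#' cuff deflation (forearm still occluded, velocity near zero), the cuff
#' releases at `t = 0`, velocity jumps to a hyperaemic peak and decays
#' exponentially back toward resting velocity, while diameter rises from
#' its baseline plateau along a logistic shoulder to a programmed peak at
#' `time_to_peak` and then relaxes. The noiseless peak is held on a short
#' flat plateau (`peak_plateau`, default 3 s) centred at `time_to_peak`,
#' matching the default peak-detection smoother of [peak_diameter()] so
#' that the programmed %FMD and time to peak survive smoothing exactly.
#'
#' @param baseline_diameter resting diameter, cm (default 0.30).
#' @param fmd_percent programmed true %FMD (default 8).
#' @param time_to_peak time of peak dilation, s post-deflation (default 30).
#' @param baseline_velocity resting mean velocity, cm/s (default 11);
#'   this is the asymptote of the hyperaemic decay.
#' @param peak_velocity hyperaemic peak velocity at release, cm/s
#'   (default 60); must be `>= baseline_velocity`.
#' @param velocity_decay_tau exponential decay time constant of the
#'   hyperaemic velocity surge, s (default 25).
#' @param sample_rate sampling rate, Hz (default 10).
#' @param occlusion_duration cuff occlusion duration, s (default 300;
#'   metadata only, the trace starts inside the occlusion).
#' @param pre_deflation_window recorded occluded baseline before
#'   deflation, s (default 30).
#' @param post_window recorded window after deflation, s (default 120).
#' @param peak_plateau width of the flat top at peak dilation, s
#'   (default 3).
#' @param recovery_tau time constant of the post-peak diameter
#'   relaxation, s (default 60).
#' @param noise_sd_diameter Gaussian noise SD on diameter, cm (default 0).
#' @param noise_sd_velocity Gaussian noise SD on velocity, cm/s
#'   (default 0).
#' @param seed integer seed; identical parameters and seed give
#'   bit-identical traces.
#' @return An [fmd_trace()].
#' @examples
#' tr <- simulate_fmd_trace(fmd_percent = 10, seed = 1)
#' analyze_fmd(tr)$fmd_percent
#' @export
simulate_fmd_trace <- function(baseline_diameter = 0.30,
                               fmd_percent = 8,
                               time_to_peak = 30,
                               baseline_velocity = 11,
                               peak_velocity = 60,
                               velocity_decay_tau = 25,
                               sample_rate = 10,
                               occlusion_duration = 300,
                               pre_deflation_window = 30,
                               post_window = 120,
                               peak_plateau = 3,
                               recovery_tau = 60,
                               noise_sd_diameter = 0,
                               noise_sd_velocity = 0,
                               seed = NULL) {
  check_positive(baseline_diameter, "baseline_diameter")
  check_nonneg(fmd_percent, "fmd_percent")
  check_positive(time_to_peak, "time_to_peak")
  check_positive(sample_rate, "sample_rate")
  check_nonneg(noise_sd_diameter, "noise_sd_diameter")
  check_nonneg(noise_sd_velocity, "noise_sd_velocity")
  check_nonneg(baseline_velocity, "baseline_velocity")
  check_positive(velocity_decay_tau, "velocity_decay_tau")
  check_positive(pre_deflation_window, "pre_deflation_window")
  check_nonneg(peak_plateau, "peak_plateau")
  if (peak_velocity < baseline_velocity) {
    vr_stop("peak_velocity must be >= baseline_velocity",
            "vasoreact_parameter_error")
  }
  if (time_to_peak - peak_plateau / 2 <= 0) {
    vr_stop("time_to_peak must exceed half the peak plateau width",
            "vasoreact_parameter_error")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))

  dt <- 1 / sample_rate
  time <- seq(-pre_deflation_window, post_window, by = dt)
  amp <- baseline_diameter * fmd_percent / 100

  # diameter shape s(t) in [0, 1]: 0 before release; logistic rise on
  # (0, ttp - P/2]; flat top of width P centred at ttp; exponential
  # relaxation after. The rescaled logistic hits 0 and 1 exactly at the
  # shoulder ends.
  t_on <- time_to_peak - peak_plateau / 2
  s <- numeric(length(time))
  rise <- time > 0 & time < t_on
  u <- time[rise] / t_on
  L <- function(u) 1 / (1 + exp(-10 * (u - 0.5)))
  s[rise] <- (L(u) - L(0)) / (L(1) - L(0))
  flat <- time >= t_on & time <= time_to_peak + peak_plateau / 2
  s[flat] <- 1
  fall <- time > time_to_peak + peak_plateau / 2
  s[fall] <- exp(-(time[fall] - (time_to_peak + peak_plateau / 2)) /
                   recovery_tau)
  diameter <- baseline_diameter + amp * s

  # velocity: ~0 during occlusion, step to peak at release, exponential
  # decay toward resting velocity
  velocity <- numeric(length(time))
  post <- time >= 0
  velocity[post] <- baseline_velocity +
    (peak_velocity - baseline_velocity) * exp(-time[post] / velocity_decay_tau)

  if (noise_sd_diameter > 0) {
    diameter <- diameter + rnorm(length(time), 0, noise_sd_diameter)
    diameter <- pmax(diameter, baseline_diameter * 0.1)  # keep positive
  }
  if (noise_sd_velocity > 0) {
    velocity <- velocity + rnorm(length(time), 0, noise_sd_velocity)
  }

  fmd_trace(time, diameter, velocity, sample_rate = sample_rate,
            pre_deflation_window = pre_deflation_window)
}

#' Simulate an RR-interval series with programmed spectral content
#'
#' Generates a beat-by-beat RR tachogram as a mean interval plus sinusoidal
#' modulations in the LF (0.04-0.15 Hz) and HF (0.15-0.40 Hz) bands and
#' Gaussian beat-to-beat noise:
#' `RR_i = mean_rr + a_LF sin(2 pi f_LF t_i) + a_HF sin(2 pi f_HF t_i) + e_i`,
#' where `t_i` is the cumulative beat time. Non-positive draws are redrawn
#' (not clipped) to avoid spectral artifacts.
#'
#' @param mean_rr mean RR interval, s (default 0.92, ~65 bpm).
#' @param lf_amplitude LF modulation amplitude, s (default 0.03).
#' @param lf_freq LF modulation frequency, Hz, inside 0.04-0.15
#'   (default 0.10).
#' @param hf_amplitude HF modulation amplitude, s (default 0.03).
#' @param hf_freq HF modulation frequency, Hz, inside 0.15-0.40
#'   (default 0.25).
#' @param noise_sd beat-to-beat Gaussian noise SD, s (default 0.01).
#' @param duration total recording length, s; must be at least 300 s so a
#'   5-min segment can be analysed (default 600, the protocol's 10-min
#'   recording).
#' @param seed integer seed.
#' @return An [rr_series()].
#' @examples
#' rr <- simulate_rr_series(seed = 1)
#' mean_heart_rate(rr)
#' @export
simulate_rr_series <- function(mean_rr = 0.92,
                               lf_amplitude = 0.03, lf_freq = 0.10,
                               hf_amplitude = 0.03, hf_freq = 0.25,
                               noise_sd = 0.01, duration = 600,
                               seed = NULL) {
  check_positive(mean_rr, "mean_rr")
  check_nonneg(lf_amplitude, "lf_amplitude")
  check_nonneg(hf_amplitude, "hf_amplitude")
  check_nonneg(noise_sd, "noise_sd")
  if (duration < 300) {
    vr_stop("duration must be >= 300 s (no analyzable 5-min segment)",
            "vasoreact_parameter_error")
  }
  if (lf_amplitude > 0 && (lf_freq < 0.04 || lf_freq > 0.15)) {
    vr_stop("lf_freq must lie in the LF band (0.04-0.15 Hz)",
            "vasoreact_parameter_error")
  }
  if (hf_amplitude > 0 && (hf_freq < 0.15 || hf_freq > 0.40)) {
    vr_stop("hf_freq must lie in the HF band (0.15-0.40 Hz)",
            "vasoreact_parameter_error")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))

  n_max <- ceiling(duration / mean_rr * 1.5) + 16L
  rr <- numeric(n_max)
  t <- 0
  i <- 0L
  while (t < duration) {
    i <- i + 1L
    base <- mean_rr +
      lf_amplitude * sin(2 * pi * lf_freq * t) +
      hf_amplitude * sin(2 * pi * hf_freq * t)
    repeat {
      val <- base + if (noise_sd > 0) rnorm(1L, 0, noise_sd) else 0
      if (val > 0) break
    }
    rr[i] <- val
    t <- t + val
  }
  rr_series(rr[seq_len(i)])
}

#' Simulate a two-group pre/post cohort of physiological scalars
#'
#' Builds a tidy cohort table (subject, group, time, variable, value) for
#' an RMT-vs-SHAM pre/post design with programmed multiplicative training
#' effects. Values are drawn log-normally so physiological variables stay
#' positive, with a shared within-subject component giving a pre/post
#' correlation `rho` on the log scale; post-training means equal
#' `pre mean * effect multiplier` in expectation.
#'
#' @param n_per_group subjects per group, `>= 2` (default 12, the study's
#'   group size).
#' @param effects named list: for each variable a numeric vector
#'   `c(mean, sd, rmt_mult, sham_mult)` giving the pre-training mean and
#'   between-subject SD and the multiplicative post/pre effect per group.
#'   Defaults to [default_cohort_effects()].
#' @param within_subject_rho pre/post correlation of the log values,
#'   in `[-1, 1]` (default 0.8).
#' @param seed integer seed.
#' @return A data.frame with columns `subject`, `group` (`RMT`/`SHAM`),
#'   `time` (`pre`/`post`), `variable`, `value`.
#' @examples
#' head(simulate_cohort(n_per_group = 3, seed = 1))
#' @export
simulate_cohort <- function(n_per_group = 12,
                            effects = default_cohort_effects(),
                            within_subject_rho = 0.8,
                            seed = NULL) {
  if (!is.numeric(n_per_group) || n_per_group < 2) {
    vr_stop("n_per_group must be >= 2", "vasoreact_parameter_error")
  }
  if (abs(within_subject_rho) > 1) {
    vr_stop("|within_subject_rho| must be <= 1", "vasoreact_parameter_error")
  }
  if (!is.list(effects) || is.null(names(effects))) {
    vr_stop("effects must be a named list of c(mean, sd, rmt_mult, sham_mult)",
            "vasoreact_parameter_error")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- as.integer(n_per_group)
  subjects <- sprintf("S%02d", seq_len(2L * n))
  groups <- rep(c("RMT", "SHAM"), each = n)
  rho <- within_subject_rho

  rows <- lapply(names(effects), function(v) {
    e <- effects[[v]]
    if (length(e) != 4L || any(!is.finite(e)) || e[1] <= 0 || e[2] < 0) {
      vr_stop(sprintf("effects[['%s']] must be c(mean > 0, sd >= 0, rmt_mult, sham_mult)", v),
              "vasoreact_parameter_error")
    }
    m <- e[1]; s <- e[2]
    sdlog <- sqrt(log(1 + (s / m)^2))
    mulog <- log(m) - sdlog^2 / 2
    sd_b <- sdlog * sqrt(max(rho, 0))
    sd_e <- sdlog * sqrt(1 - max(rho, 0))
    b <- rnorm(2L * n, 0, sd_b)
    pre <- exp(mulog + b + rnorm(2L * n, 0, sd_e))
    mult <- ifelse(groups == "RMT", e[3], e[4])
    post <- exp(mulog + log(mult) + b + rnorm(2L * n, 0, sd_e))
    data.frame(
      subject = rep(subjects, 2L),
      group = rep(groups, 2L),
      time = rep(c("pre", "post"), each = 2L * n),
      variable = v,
      value = c(pre, post),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Default programmed cohort effects
#'
#' Pre-training means/SDs and multiplicative post/pre effects for the
#' scalar variables of the synthetic cohort. Means follow the published
#' pre-training group values of the emulated trial (e.g. FVC 4.10 l,
#' MVV 134 l/min, MIP 48 cmH2O, resting HR 65 bpm); between-subject SDs
#' are the SE x sqrt(12) of the same tables. Programmed effects encode
#' the reported training response: MIP x1.31 and MVV x1.16 after RMT with
#' essentially null SHAM effects, and no true change in MAP or SV.
#'
#' @return Named list of `c(mean, sd, rmt_mult, sham_mult)` vectors.
#' @export
default_cohort_effects <- function() {
  list(
    FVC  = c(4.10, 0.48, 1.012, 0.992),
    FEV1 = c(3.37, 0.45, 1.024, 0.997),
    MIP  = c(48,   6.7,  1.31,  1.00),
    MVV  = c(134, 14,    1.16,  1.033),
    RV   = c(0.61, 0.17, 0.967, 1.013),
    HR   = c(65,  10,    0.985, 0.956),
    MAP  = c(88,   7,    1.00,  1.00),
    SV   = c(55,   9,    1.00,  1.00)
  )
}
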