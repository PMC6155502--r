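#' Construct a flow-mediated dilation (FMD) trace
#'
#' Bundles synchronized brachial-artery diameter and mean blood velocity
#' time series around a cuff-deflation event into an `fmd_trace` object,
#' the raw input of the vascular analysis stage. Time is referenced to cuff
#' deflation (`t = 0`); by protocol the recording covers at least 30 s of
#' occluded baseline before deflation and 2 min after.
#'
#' @param time numeric vector of sample times in seconds, strictly
#'   increasing, with `t = 0` at cuff deflation.
#' @param diameter numeric vector of arterial diameters in cm, all positive.
#' @param velocity numeric vector of mean blood velocities in cm/s.
#' @param sample_rate sampling rate in Hz. Defaults to the inverse median
#'   time step.
#' @param pre_deflation_window length of the pre-deflation baseline window
#'   in seconds (default 30).
#' @return An object of class `fmd_trace`: a list with elements `time`,
#'   `diameter`, `velocity`, `sample_rate`, `pre_deflation_window`.
#' @examples
#' t <- seq(-30, 120, by = 0.1)
#' tr <- fmd_trace(t, rep(0.30, length(t)), rep(10, length(t)))
#' baseline_diameter(tr)
#' @export
fmd_trace <- function(time, diameter, velocity, sample_rate = NULL,
                      pre_deflation_window = 30) {
  if (length(time) != length(diameter) || length(time) != length(velocity)) {
    vr_stop("time, diameter and velocity must have equal length",
            "vasoreact_parameter_error")
  }
  if (length(time) < 2L || any(diff(time) <= 0)) {
    vr_stop("time must be strictly increasing with >= 2 samples",
            "vasoreact_parameter_error")
  }
  if (any(!is.finite(diameter)) || any(diameter <= 0)) {
    vr_stop("diameter must be positive at all samples",
            "vasoreact_domain_error")
  }
  check_positive(pre_deflation_window, "pre_deflation_window")
  if (is.null(sample_rate)) sample_rate <- 1 / median(diff(time))
  check_positive(sample_rate, "sample_rate")
  structure(
    list(time = as.numeric(time), diameter = as.numeric(diameter),
         velocity = as.numeric(velocity), sample_rate = sample_rate,
         pre_deflation_window = pre_deflation_window),
    class = "fmd_trace"
  )
}

#' @export
print.fmd_trace <- function(x, ...) {
  cat(sprintf(
    "FMD trace: %d samples, t in [%.1f, %.1f] s (t = 0 at cuff deflation), %.1f Hz\n",
    length(x$time), min(x$time), max(x$time), x$sample_rate))
  cat(sprintf("  diameter %.3f-%.3f cm, velocity %.1f-%.1f cm/s\n",
              min(x$diameter), max(x$diameter),
              min(x$velocity), max(x$velocity)))
  invisible(x)
}

#' @export
plot.fmd_trace <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  plot(x$time, x$diameter, type = "l", xlab = "time since deflation (s)",
       ylab = "diameter (cm)", ...)
  graphics::abline(v = 0, lty = 2, col = "grey50")
  plot(x$time, x$velocity, type = "l", xlab = "time since deflation (s)",
       ylab = "mean velocity (cm/s)", ...)
  graphics::abline(v = 0, lty = 2, col = "grey50")
  invisible(x)
}

#' Baseline arterial diameter
#'
#' Mean diameter over the pre-deflation baseline window `[-w, 0)`, where
#' `w` is the trace's `pre_deflation_window` (30 s by protocol). The full
#' window is averaged for maximal noise suppression.
#'
#' @param trace an [fmd_trace()].
#' @return Baseline diameter in cm.
#' @export
baseline_diameter <- function(trace) {
  stopifnot(inherits(trace, "fmd_trace"))
  sel <- trace$time >= -trace$pre_deflation_window & trace$time < 0
  if (sum(sel) < 5L) {
    vr_stop("fewer than 5 samples in the pre-deflation window",
            "vasoreact_insufficient_data_error")
  }
  mean(trace$diameter[sel])
}

#' Peak arterial diameter and time to peak
#'
#' Maximum of the (optionally smoothed) post-deflation diameter and the
#' time at which it occurs. A centered moving-average smoother of width
#' `smooth_window` seconds (default 3 s; 0 disables smoothing) is applied
#' over the whole trace before the scan; ties are broken by the earliest
#' time.
#'
#' @param trace an [fmd_trace()].
#' @param smooth_window smoothing window width in seconds; 0 for none.
#' @return A list with elements `peak_diameter` (cm) and `time_to_peak`
#'   (s after deflation).
#' @export
peak_diameter <- function(trace, smooth_window = 3) {
  stopifnot(inherits(trace, "fmd_trace"))
  check_nonneg(smooth_window, "smooth_window")
  post <- trace$time > 0
  if (!any(post)) {
    vr_stop("trace has no post-deflation samples",
            "vasoreact_insufficient_data_error")
  }
  d <- smooth_ma(trace$diameter, smooth_window, trace$sample_rate)
  dp <- d[post]
  tp <- trace$time[post]
  i <- which.max(dp)           # which.max returns the first maximum: earliest tie
  list(peak_diameter = dp[i], time_to_peak = tp[i])
}

# centered moving average; window in seconds converted to an odd sample count.
# Edges use the partial window (shrinking), keeping the output length equal.
smooth_ma <- function(x, window_s, sample_rate) {
  if (window_s <= 0) return(x)
  k <- max(1L, round(window_s * sample_rate))
  if (k %% 2L == 0L) k <- k + 1L
  if (k == 1L) return(x)
  h <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  n <- length(x)
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Flow-mediated dilation as a percentage
#'
#' `%FMD = (peak - baseline) / baseline * 100`, the maximal change in
#' arterial diameter after cuff release expressed as a percentage increase
#' above the baseline diameter.
#'
#' @param baseline baseline diameter (cm), positive.
#' @param peak peak diameter (cm).
#' @return Percent dilation.
#' @examples
#' fmd_percent(0.30, 0.33)  # 10
#' @export
fmd_percent <- function(baseline, peak) {
  if (!is.numeric(baseline) || any(baseline <= 0)) {
    vr_stop("baseline diameter must be positive", "vasoreact_domain_error")
  }
  (peak - baseline) / baseline * 100
}

#' Brachial artery blood flow
#'
#' `flow (ml/min) = v_mean * pi * (diameter / 2)^2 * 60`, with `v_mean`
#' in cm/s and diameter in cm (so the product is cm^3/min = ml/min).
#'
#' @param v_mean mean blood velocity (cm/s), non-negative (retrograde flow
#'   is out of scope).
#' @param diameter vessel diameter (cm), positive.
#' @return Blood flow in ml/min.
#' @examples
#' blood_flow(10, 0.4)  # 75.40 ml/min
#' @export
blood_flow <- function(v_mean, diameter) {
  if (any(diameter <= 0)) {
    vr_stop("diameter must be positive", "vasoreact_domain_error")
  }
  if (any(v_mean < 0)) {
    vr_stop("v_mean must be non-negative (flow reversal out of scope)",
            "vasoreact_domain_error")
  }
  v_mean * pi * (diameter / 2)^2 * 60
}

#' Wall shear rate
#'
#' `SR (1/s) = 8 * v_mean / diameter`, the standard Poiseuille estimate of
#' the wall velocity gradient that constitutes the mechanical stimulus for
#' flow-mediated dilation.
#'
#' @inheritParams blood_flow
#' @return Shear rate in 1/s.
#' @examples
#' shear_rate(10, 0.4)  # 200
#' @export
shear_rate <- function(v_mean, diameter) {
  if (any(diameter <= 0)) {
    vr_stop("diameter must be positive", "vasoreact_domain_error")
  }
  8 * v_mean / diameter
}

#' Cumulative shear rate (shear-rate AUC)
#'
#' Trapezoidal integral of the per-sample shear-rate series from cuff
#' release to the time of peak diameter. This area under the SR curve is
#' the dose of mechanical stimulus used to normalize %FMD. Negative
#' instantaneous velocities (retrograde flow) are clipped to zero with a
#' warning before SR is formed.
#'
#' @param trace an [fmd_trace()].
#' @param t_release start of integration, s (default 0 = cuff release).
#' @param t_peak end of integration, s (time of peak diameter).
#' @return Cumulative shear rate (dimensionless: 1/s integrated over s).
#' @export
cumulative_shear_rate <- function(trace, t_release = 0, t_peak) {
  stopifnot(inherits(trace, "fmd_trace"))
  if (t_peak <= t_release) {
    vr_stop("t_peak must be greater than t_release", "vasoreact_ordering_error")
  }
  sel <- trace$time >= t_release & trace$time <= t_peak
  if (sum(sel) < 2L) {
    vr_stop("integration window contains fewer than 2 samples",
            "vasoreact_insufficient_data_error")
  }
  v <- clip_retrograde(trace$velocity[sel])
  sr <- shear_rate(v, trace$diameter[sel])
  trapz(trace$time[sel], sr)
}

# trapezoidal rule: sum over intervals of y_i*dx + 1/2*dy*dx
trapz <- function(x, y) {
  dx <- diff(x)
  sum(y[-length(y)] * dx + 0.5 * diff(y) * dx)
}

clip_retrograde <- function(v) {
  if (any(v < 0)) {
    warning("negative instantaneous velocities clipped to 0 (retrograde flow)",
            call. = FALSE)
    v <- pmax(v, 0)
  }
  v
}

#' Shear-rate-normalized FMD
#'
#' `%FMD / cumulative SR`: the dilation response per unit of shear
#' stimulus, the primary endpoint when hyperaemic stimulus differs between
#' conditions.
#'
#' @param fmd_percent percent dilation.
#' @param cumulative_sr cumulative shear rate, positive.
#' @return The ratio `%FMD / SR_AUC`.
#' @export
normalized_fmd <- function(fmd_percent, cumulative_sr) {
  if (any(cumulative_sr <= 0)) {
    vr_stop("cumulative_sr must be positive", "vasoreact_domain_error")
  }
  fmd_percent / cumulative_sr
}

#' Brachial vascular conductance
#'
#' `BVC (ml/min/mmHg) = blood flow / MAP`.
#'
#' @param blood_flow blood flow in ml/min.
#' @param map mean arterial pressure in mmHg, positive.
#' @return Vascular conductance in ml/min/mmHg.
#' @examples
#' vascular_conductance(47.8, 101)   # 0.47
#' vascular_conductance(116.9, 108)  # 1.08
#' @export
vascular_conductance <- function(blood_flow, map) {
  if (any(map <= 0)) {
    vr_stop("MAP must be positive", "vasoreact_domain_error")
  }
  blood_flow / map
}

#' Allometric scaling check for ratio-normalized FMD
#'
#' Expressing FMD as a percent of baseline diameter presumes peak diameter
#' scales proportionally with baseline diameter. The check regresses
#' `ln(peak)` on `ln(baseline)` by ordinary least squares and accepts the
#' ratio normalization when the upper limit of the two-sided
#' `(1 - alpha)` confidence interval of the slope (t distribution, n - 2
#' df) is greater than or equal to 1.
#'
#' @param baselines vector of baseline diameters (cm), positive.
#' @param peaks vector of peak diameters (cm), positive, same length.
#' @param alpha significance level (default 0.05 for a 95% CI).
#' @return An object of class `scaling_check`: list with `slope`, `ci_low`,
#'   `ci_high`, `ratio_scaling_valid` (`ci_high >= 1`), `n`, `alpha`.
#' @export
allometric_scaling_check <- function(baselines, peaks, alpha = 0.05) {
  if (length(baselines) != length(peaks)) {
    vr_stop("baselines and peaks must have equal length",
            "vasoreact_parameter_error")
  }
  n <- length(baselines)
  if (n < 3L) {
    vr_stop("allometric check needs >= 3 paired observations",
            "vasoreact_insufficient_data_error")
  }
  if (any(baselines <= 0) || any(peaks <= 0)) {
    vr_stop("diameters must be positive", "vasoreact_domain_error")
  }
  x <- log(baselines)
  y <- log(peaks)
  fit <- lm(y ~ x)
  slope <- unname(coef(fit)[2L])
  se <- sqrt(sum(fit$residuals^2) / (n - 2)) / sqrt(sum((x - mean(x))^2))
  tcrit <- qt(1 - alpha / 2, df = n - 2)
  ci_high <- slope + tcrit * se
  structure(
    list(slope = slope, ci_low = slope - tcrit * se,
         ci_high = ci_high,
         # 1e-12 guard so an exact proportional fit (residuals at machine
         # epsilon) cannot flip the boundary decision
         ratio_scaling_valid = ci_high >= 1 - 1e-12,
         n = n, alpha = alpha),
    class = "scaling_check"
  )
}

#' @export
print.scaling_check <- function(x, ...) {
  cat(sprintf(
    "Allometric scaling check (ln peak ~ ln baseline, n = %d):\n", x$n))
  cat(sprintf("  slope %.3f, %d%% CI [%.3f, %.3f] -> ratio scaling %s\n",
              x$slope, round(100 * (1 - x$alpha)), x$ci_low, x$ci_high,
              if (x$ratio_scaling_valid) "VALID (upper CI >= 1)"
              else "NOT supported (upper CI < 1)"))
  invisible(x)
}

#' Group-mean hyperaemic blood flow curve and its AUC
#'
#' Computes per-sample blood flow for each trace, averages across traces,
#' and reports (i) a binned mean flow curve over the 2-min post-release
#' window for display and (ii) the trapezoidal integral (AUC) of the
#' sample-resolution mean curve. Time is converted to minutes for the
#' integral, so with flow in ml/min the AUC is in ml.
#'
#' @param traces a list of [fmd_trace()] objects (a single trace is
#'   wrapped automatically).
#' @param bin_width bin width for the reported curve, seconds (default 2).
#' @param t_max end of the post-release window, s (default 120).
#' @return An object of class `hyperaemia_curve`: list with `time` (bin
#'   centres, s), `flow` (mean binned flow, ml/min), `flow_auc` (ml),
#'   `bin_width`, `n_traces`.
#' @export
hyperaemia_flow_curve <- function(traces, bin_width = 2, t_max = 120) {
  if (inherits(traces, "fmd_trace")) traces <- list(traces)
  if (length(traces) == 0L) {
    vr_stop("at least one trace is required", "vasoreact_parameter_error")
  }
  check_positive(bin_width, "bin_width")
  flows <- lapply(traces, function(tr) {
    stopifnot(inherits(tr, "fmd_trace"))
    sel <- tr$time >= 0 & tr$time <= t_max
    list(t = tr$time[sel],
         f = blood_flow(clip_retrograde(tr$velocity[sel]), tr$diameter[sel]))
  })
  # common grid: the first trace's post-release times; others interpolated
  grid <- flows[[1L]]$t
  fmat <- vapply(flows, function(fl) {
    if (length(fl$t) == length(grid) && all(fl$t == grid)) fl$f
    else stats::approx(fl$t, fl$f, xout = grid, rule = 2)$y
  }, numeric(length(grid)))
  mean_flow <- if (is.matrix(fmat)) rowMeans(fmat) else fmat
  auc <- trapz(grid / 60, pmax(mean_flow, 0))
  bins <- floor(grid / bin_width)
  bt <- tapply(grid, bins, mean)
  bf <- tapply(mean_flow, bins, mean)
  structure(
    list(time = as.numeric(bt), flow = as.numeric(bf), flow_auc = auc,
         bin_width = bin_width, n_traces = length(traces),
         auc_units = "ml (flow ml/min integrated over minutes)"),
    class = "hyperaemia_curve"
  )
}

#' @export
print.hyperaemia_curve <- function(x, ...) {
  cat(sprintf(
    "Hyperaemic flow curve: mean of %d trace(s), %g-s bins; AUC = %.1f ml\n",
    x$n_traces, x$bin_width, x$flow_auc))
  invisible(x)
}

#' @export
plot.hyperaemia_curve <- function(x, ...) {
  plot(x$time, x$flow, type = "b", pch = 16, cex = 0.6,
       xlab = "time since cuff release (s)", ylab = "blood flow (ml/min)", ...)
  invisible(x)
}

#' Windowed hemodynamic averages for an acute exercise bout
#'
#' Averages a time-stamped stream of hemodynamic samples over a baseline
#' window at the start of the recording and over the last `tail_window`
#' seconds, then recomputes the derived quantities (cardiac output
#' `CO = SV * HR / 1000`, blood flow from velocity and diameter, shear
#' rate, and vascular conductance `BVC = flow / MAP`) from the averaged
#' primitives.
#'
#' @param stream a data.frame with column `time` (s) and any of
#'   `heart_rate` (bpm), `map` (mmHg), `sv` (ml), `velocity` (cm/s),
#'   `diameter` (cm), `blood_flow` (ml/min).
#' @param baseline_window seconds averaged from the start (default 30).
#' @param tail_window seconds averaged at the end (default 10).
#' @return A list with elements `baseline` and `exercise`, each a named
#'   list of averaged primitives plus derived `co` (l/min), `blood_flow`
#'   (ml/min), `sr` (1/s) and `bvc` where computable.
#' @export
windowed_hemodynamics <- function(stream, baseline_window = 30,
                                  tail_window = 10) {
  if (!is.data.frame(stream) || !"time" %in% names(stream)) {
    vr_stop("stream must be a data.frame with a `time` column",
            "vasoreact_parameter_error")
  }
  t0 <- min(stream$time)
  t1 <- max(stream$time)
  if (t1 - t0 < baseline_window + tail_window) {
    vr_stop("stream does not cover both averaging windows",
            "vasoreact_insufficient_data_error")
  }
  avg_window <- function(sel) {
    vars <- setdiff(names(stream), "time")
    out <- lapply(stream[sel, vars, drop = FALSE], mean)
    if (!is.null(out$sv) && !is.null(out$heart_rate)) {
      out$co <- out$sv * out$heart_rate / 1000
    }
    if (!is.null(out$velocity) && !is.null(out$diameter)) {
      out$blood_flow <- blood_flow(max(out$velocity, 0), out$diameter)
      out$sr <- shear_rate(max(out$velocity, 0), out$diameter)
    }
    if (!is.null(out$blood_flow) && !is.null(out$map)) {
      out$bvc <- vascular_conductance(out$blood_flow, out$map)
    }
    out
  }
  list(
    baseline = avg_window(stream$time <= t0 + baseline_window),
    exercise = avg_window(stream$time >= t1 - tail_window)
  )
}

#' Full FMD analysis of a single trace
#'
#' Runs the complete single-recording chain: baseline diameter over the
#' pre-deflation window, smoothed peak diameter and time to peak, %FMD,
#' cumulative shear rate from cuff release to peak, shear-normalized FMD,
#' and the hyperaemic flow curve with its AUC.
#'
#' @param trace an [fmd_trace()].
#' @param smooth_window peak-detection smoothing window, s (default 3).
#' @return An object of class `fmd_result`: list with `baseline_diameter`,
#'   `peak_diameter`, `time_to_peak`, `fmd_percent`, `cumulative_sr`,
#'   `fmd_per_sr`, `flow_series` (data.frame time/flow), `flow_auc`.
#' @examples
#' tr <- simulate_fmd_trace(fmd_percent = 10, noise_sd_diameter = 0,
#'                          noise_sd_velocity = 0, seed = 1)
#' analyze_fmd(tr)
#' @export
analyze_fmd <- function(trace, smooth_window = 3) {
  stopifnot(inherits(trace, "fmd_trace"))
  b <- baseline_diameter(trace)
  pk <- peak_diameter(trace, smooth_window = smooth_window)
  fmd <- fmd_percent(b, pk$peak_diameter)
  csr <- cumulative_shear_rate(trace, 0, pk$time_to_peak)
  sel <- trace$time >= 0
  v <- clip_retrograde(trace$velocity[sel])
  flow <- blood_flow(v, trace$diameter[sel])
  auc <- trapz(trace$time[sel] / 60, pmax(flow, 0))
  structure(
    list(baseline_diameter = b,
         peak_diameter = pk$peak_diameter,
         time_to_peak = pk$time_to_peak,
         fmd_percent = fmd,
         cumulative_sr = csr,
         fmd_per_sr = if (csr > 0) fmd / csr else NA_real_,
         flow_series = data.frame(time = trace$time[sel], flow = flow),
         flow_auc = auc,
         smooth_window = smooth_window),
    class = "fmd_result"
  )
}

#' @export
print.fmd_result <- function(x, ...) {
  cat("FMD analysis:\n")
  cat(sprintf("  baseline diameter : %.4f cm\n", x$baseline_diameter))
  cat(sprintf("  peak diameter     : %.4f cm at %.1f s post-release\n",
              x$peak_diameter, x$time_to_peak))
  cat(sprintf("  %%FMD              : %.2f %%\n", x$fmd_percent))
  cat(sprintf("  cumulative SR     : %.0f (release -> peak)\n",
              x$cumulative_sr))
  cat(sprintf("  %%FMD / SR         : %.3e\n", x$fmd_per_sr))
  cat(sprintf("  flow AUC (0-2 min): %.1f ml\n", x$flow_auc))
  invisible(x)
}
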