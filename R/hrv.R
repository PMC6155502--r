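#' Construct an RR-interval series
#'
#' An RR tachogram: successive interbeat intervals and the cumulative beat
#' times they imply. Beat times start at 0 (the first beat) and increase by
#' each interval, so `duration` equals the last beat time.
#'
#' @param rr numeric vector of RR intervals in seconds, all positive.
#' @param beat_time optional numeric vector of cumulative beat times
#'   (seconds, strictly increasing); defaults to `cumsum(rr) - rr[1]` so
#'   the first beat is at `t = 0`.
#' @return An object of class `rr_series`: list with `rr`, `beat_time`,
#'   `duration`.
#' @export
rr_series <- function(rr, beat_time = NULL) {
  if (!is.numeric(rr) || length(rr) < 2L || any(!is.finite(rr)) || any(rr <= 0)) {
    vr_stop("rr must be a numeric vector of positive intervals (>= 2 beats)",
            "vasoreact_parameter_error")
  }
  if (is.null(beat_time)) beat_time <- cumsum(rr) - rr[1L]
  if (length(beat_time) != length(rr) || any(diff(beat_time) <= 0)) {
    vr_stop("beat_time must be strictly increasing and match rr in length",
            "vasoreact_parameter_error")
  }
  structure(
    list(rr = as.numeric(rr), beat_time = as.numeric(beat_time),
         duration = beat_time[length(beat_time)]),
    class = "rr_series"
  )
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("RR series: %d beats over %.1f s, mean RR %.3f s (%.1f bpm)\n",
              length(x$rr), x$duration, mean(x$rr), 60 / mean(x$rr)))
  invisible(x)
}

#' Mean heart rate of an RR series
#'
#' `HR (bpm) = 60 / mean(RR)`.
#'
#' @param series an [rr_series()].
#' @return Mean heart rate in beats per minute.
#' @examples
#' mean_heart_rate(rr_series(rep(1, 100)))  # 60
#' @export
mean_heart_rate <- function(series) {
  stopifnot(inherits(series, "rr_series"))
  60 / mean(series$rr)
}

#' Select the cleanest fixed-length segment of an RR recording
#'
#' Emulates the practice of analysing the "clearest" 5-min stretch of a
#' longer recording: every contiguous window of `segment_length` seconds
#' is scored by its number of artifact-like beats (|change in RR| greater
#' than `artifact_threshold` times the local median RR), ties broken by
#' lower RR variance, then by earliest start.
#'
#' @param series an [rr_series()].
#' @param segment_length window length in seconds (default 300).
#' @param artifact_threshold relative beat-to-beat jump flagged as an
#'   artifact (default 0.20 = 20% of the local median RR).
#' @param median_halfwidth beats on each side used for the local median
#'   (default 5).
#' @return An [rr_series()] restricted to the selected window, with
#'   attribute `segment_start` (s).
#' @export
select_cleanest_segment <- function(series, segment_length = 300,
                                    artifact_threshold = 0.20,
                                    median_halfwidth = 5L) {
  stopifnot(inherits(series, "rr_series"))
  if (series$duration < segment_length) {
    vr_stop("recording shorter than the requested segment",
            "vasoreact_insufficient_data_error")
  }
  rr <- series$rr
  bt <- series$beat_time
  n <- length(rr)

  # local median RR and artifact flags, computed once for the whole series
  locmed <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - median_halfwidth)
    hi <- min(n, i + median_halfwidth)
    median(rr[lo:hi])
  }, numeric(1))
  art <- c(FALSE, abs(diff(rr)) > artifact_threshold * locmed[-1L])

  starts <- which(bt <= series$duration - segment_length)
  best <- NULL
  for (i in starts) {
    j <- which(bt >= bt[i] + segment_length)[1L]  # cover the full window
    idx <- i:j
    score <- sum(art[idx])
    v <- var(rr[idx])
    if (is.null(best) || score < best$score ||
        (score == best$score && v < best$var - 1e-15)) {
      best <- list(i = i, j = j, score = score, var = v)
    }
  }
  out <- rr_series(rr[best$i:best$j], beat_time = bt[best$i:best$j])
  attr(out, "segment_start") <- bt[best$i]
  out
}

# Welch power spectral density with Hann taper.
# x: evenly sampled series; fs: Hz; nperseg: samples per segment;
# overlap: fraction. Returns data.frame(freq, psd) one-sided, in
# units of x^2 per Hz. Segments have their mean removed before tapering.
welch_psd <- function(x, fs, nperseg = NULL, overlap = 0.5) {
  n <- length(x)
  if (is.null(nperseg)) nperseg <- min(n, 480L)
  nperseg <- min(nperseg, n)
  step <- max(1L, floor(nperseg * (1 - overlap)))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  k <- seq_len(nperseg) - 1L
  w <- 0.5 * (1 - cos(2 * pi * k / nperseg))   # periodic Hann
  U <- sum(w^2)
  nf <- nperseg %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- fft(seg)[seq_len(nf)]
    p <- (Mod(X)^2) / (fs * U)
    # one-sided: double everything except DC and (for even nperseg) Nyquist
    dbl <- rep(2, nf)
    dbl[1L] <- 1
    if (nperseg %% 2L == 0L) dbl[nf] <- 1
    acc <- acc + p * dbl
  }
  data.frame(freq = (seq_len(nf) - 1L) * fs / nperseg,
             psd = acc / length(starts))
}

#' Frequency-domain HRV band powers
#'
#' Computes spectral band powers of an RR series. The tachogram (RR in ms)
#' is resampled to an even grid by cubic spline interpolation over beat
#' time, mean-removed, and its power spectral density estimated by Welch's
#' method (120-s Hann-tapered segments, 50% overlap). The PSD is
#' integrated over the VLF (0.01-0.04 Hz), LF (0.04-0.15 Hz) and HF
#' (0.15-0.40 Hz) bands; normalized units are defined on the LF+HF total
#' (`LF n.u. = LF/(LF+HF)*100`), so LF n.u. and HF n.u. sum to 100 by
#' construction, and the sympatho-vagal balance index is `LF/HF`.
#'
#' A constant (zero-variance) series yields zero powers with `NA`
#' normalized units and ratio and `degenerate = TRUE` rather than an error.
#'
#' @param series an [rr_series()], at least 300 s long (use
#'   [select_cleanest_segment()] first for longer recordings).
#' @param bands named list of `c(lo, hi)` Hz ranges for `vlf`, `lf`, `hf`.
#' @param resample_hz even resampling rate, Hz (default 4).
#' @param welch_segment Welch segment length, s (default 120).
#' @param min_duration minimum accepted segment length, s (default 300).
#' @return An object of class `hrv_result`: list with `lf_power`,
#'   `hf_power`, `vlf_power` (ms^2), `lf_nu`, `hf_nu`, `lf_hf_ratio`,
#'   `mean_hr` (bpm), `segment_start` (s), `degenerate`.
#' @examples
#' rr <- simulate_rr_series(lf_amplitude = 0.03, hf_amplitude = 0,
#'                          noise_sd = 0, seed = 1)
#' hrv_band_powers(rr)$lf_nu  # ~100
#' @export
hrv_band_powers <- function(series,
                            bands = list(vlf = c(0.01, 0.04),
                                         lf  = c(0.04, 0.15),
                                         hf  = c(0.15, 0.40)),
                            resample_hz = 4, welch_segment = 120,
                            min_duration = 300) {
  stopifnot(inherits(series, "rr_series"))
  if (series$duration - series$beat_time[1L] < min_duration) {
    vr_stop(sprintf("segment shorter than %g s", min_duration),
            "vasoreact_insufficient_data_error")
  }
  if (!all(c("vlf", "lf", "hf") %in% names(bands)) ||
      any(vapply(bands, function(b) length(b) != 2L || b[1] >= b[2], logical(1)))) {
    vr_stop("bands must name vlf, lf, hf ranges c(lo, hi) with lo < hi",
            "vasoreact_parameter_error")
  }
  seg_start <- attr(series, "segment_start")
  if (is.null(seg_start)) seg_start <- series$beat_time[1L]

  rr_ms <- series$rr * 1000
  if (stats::sd(rr_ms) == 0) {
    return(structure(
      list(lf_power = 0, hf_power = 0, vlf_power = 0,
           lf_nu = NA_real_, hf_nu = NA_real_, lf_hf_ratio = NA_real_,
           mean_hr = mean_heart_rate(series), segment_start = seg_start,
           degenerate = TRUE),
      class = "hrv_result"
    ))
  }

  grid <- seq(series$beat_time[1L], series$beat_time[length(series$beat_time)],
              by = 1 / resample_hz)
  xi <- spline(series$beat_time, rr_ms, xout = grid, method = "fmm")$y
  xi <- xi - mean(xi)
  psd <- welch_psd(xi, fs = resample_hz,
                   nperseg = round(welch_segment * resample_hz))
  df <- psd$freq[2L] - psd$freq[1L]
  band_power <- function(b) {
    sel <- psd$freq >= b[1] & psd$freq < b[2]
    sum(psd$psd[sel]) * df
  }
  vlf <- band_power(bands$vlf)
  lf <- band_power(bands$lf)
  hf <- band_power(c(bands$hf[1], bands$hf[2] + 1e-12))  # hi edge inclusive
  tot <- lf + hf
  structure(
    list(lf_power = lf, hf_power = hf, vlf_power = vlf,
         lf_nu = if (tot > 0) lf / tot * 100 else NA_real_,
         hf_nu = if (tot > 0) hf / tot * 100 else NA_real_,
         lf_hf_ratio = if (hf > 0) lf / hf else NA_real_,
         mean_hr = mean_heart_rate(series), segment_start = seg_start,
         degenerate = tot == 0),
    class = "hrv_result"
  )
}

#' @export
print.hrv_result <- function(x, ...) {
  cat("HRV band powers (Welch):\n")
  if (isTRUE(x$degenerate)) cat("  [degenerate: zero spectral power]\n")
  cat(sprintf("  VLF %.1f ms^2 | LF %.1f ms^2 | HF %.1f ms^2\n",
              x$vlf_power, x$lf_power, x$hf_power))
  cat(sprintf("  LF %.1f n.u. | HF %.1f n.u. | LF/HF %.2f\n",
              x$lf_nu, x$hf_nu, x$lf_hf_ratio))
  cat(sprintf("  mean HR %.1f bpm, segment start %.1f s\n",
              x$mean_hr, x$segment_start))
  invisible(x)
}

#' One-call HRV analysis of a full recording
#'
#' Selects the cleanest 5-min segment and computes its band powers.
#'
#' @param series an [rr_series()] covering at least `segment_length` s.
#' @param segment_length analysed segment length, s (default 300).
#' @param ... passed to [hrv_band_powers()].
#' @return An `hrv_result` (see [hrv_band_powers()]).
#' @export
analyze_hrv <- function(series, segment_length = 300, ...) {
  seg <- select_cleanest_segment(series, segment_length = segment_length)
  hrv_band_powers(seg, ...)
}
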