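#' Write / read an FMD trace as CSV
#'
#' Plain-text persistence of a trace: columns `time_s`, `diameter_cm`,
#' `velocity_cm_s`, with the deflation convention and metadata carried in
#' `#`-prefixed header lines (`deflation_time_s` is always 0: times are
#' stored relative to cuff release).
#'
#' @param trace an [fmd_trace()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_fmd_trace <- function(trace, path) {
  stopifnot(inherits(trace, "fmd_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# deflation_time_s: 0",
               sprintf("# sample_rate_hz: %.10g", trace$sample_rate),
               sprintf("# pre_deflation_window_s: %.10g",
                       trace$pre_deflation_window)), con)
  write.csv(data.frame(time_s = trace$time, diameter_cm = trace$diameter,
                       velocity_cm_s = trace$velocity),
            con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fmd_trace
#' @param path CSV path written by [write_fmd_trace()].
#' @export
read_fmd_trace <- function(path) {
  hdr <- readLines(path, n = 10L)
  hdr <- hdr[startsWith(hdr, "#")]
  get_meta <- function(key, default) {
    m <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (length(m) == 0L) return(default)
    as.numeric(sub(paste0("^# ", key, ": *"), "", m[1L]))
  }
  d <- read.csv(path, comment.char = "#")
  fmd_trace(d$time_s, d$diameter_cm, d$velocity_cm_s,
            sample_rate = get_meta("sample_rate_hz", NULL),
            pre_deflation_window = get_meta("pre_deflation_window_s", 30))
}

#' Write / read an RR series as CSV
#'
#' Columns `beat_time_s`, `rr_s`.
#'
#' @param series an [rr_series()].
#' @param path CSV path.
#' @return `path` invisibly (write); an [rr_series()] (read).
#' @export
write_rr_series <- function(series, path) {
  stopifnot(inherits(series, "rr_series"))
  write.csv(data.frame(beat_time_s = series$beat_time, rr_s = series$rr),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rr_series
#' @export
read_rr_series <- function(path) {
  d <- read.csv(path)
  rr_series(d$rr_s, beat_time = d$beat_time_s)
}

#' Write / read a tidy cohort table as CSV
#'
#' Columns `subject`, `group`, `time`, `variable`, `value`.
#'
#' @param cohort tidy cohort data.frame (see [simulate_cohort()]).
#' @param path CSV path.
#' @return `path` invisibly (write); the cohort data.frame (read).
#' @export
write_cohort <- function(cohort, path) {
  need <- c("subject", "group", "time", "variable", "value")
  if (!all(need %in% names(cohort))) {
    vr_stop("cohort must have columns subject, group, time, variable, value",
            "vasoreact_parameter_error")
  }
  write.csv(cohort[, need], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "group", "time", "variable", "value")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0L) {
    vr_stop(sprintf("cohort file %s lacks column(s): %s", path,
                    paste(miss, collapse = ", ")),
            "vasoreact_validation_error")
  }
  bad <- which(!is.finite(d$value))
  if (length(bad) > 0L) {
    vr_stop(sprintf("cohort file %s has non-numeric value(s) at row(s) %s",
                    path, paste(utils::head(bad, 5L), collapse = ", ")),
            "vasoreact_validation_error")
  }
  d[, need]
}
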