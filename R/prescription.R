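#' Initial isocapnic-hyperpnoea training prescription
#'
#' Starting dose for respiratory muscle training by isocapnic hyperpnoea:
#' tidal volume is set to 50% of forced vital capacity, the target
#' respiratory minute volume to 60% of maximal voluntary ventilation, and
#' the breath frequency follows
#' `f_b = MV / (duty_factor * 0.5 * FVC)` with `duty_factor = 1.3`, a
#' device duty-cycle correction kept as a named parameter. The identity
#' `f_b * (1.3 * 0.5 * FVC) = 0.6 * MVV` holds exactly; note the raw
#' product `Vt * f_b` therefore equals `MV / duty_factor`.
#'
#' @param fvc forced vital capacity, litres, positive.
#' @param mvv maximal voluntary ventilation, l/min, positive.
#' @param vt_fraction fraction of FVC used as tidal volume (default 0.5).
#' @param mv_fraction fraction of MVV used as target minute volume
#'   (default 0.6).
#' @param duty_factor duty-cycle correction in the frequency formula
#'   (default 1.3).
#' @return An object of class `rmt_prescription`: list with `week` (1),
#'   `tidal_volume` (l), `breath_frequency` (breaths/min), `target_mv`
#'   (l/min, = `mv_fraction * mvv`), `minute_ventilation`
#'   (l/min, = `tidal_volume * breath_frequency`), `duty_factor`.
#' @examples
#' initial_prescription(fvc = 4.10, mvv = 134)  # MV 80.4, f_b 30.2
#' @export
initial_prescription <- function(fvc, mvv, vt_fraction = 0.5,
                                 mv_fraction = 0.6, duty_factor = 1.3) {
  check_positive(fvc, "fvc")
  check_positive(mvv, "mvv")
  check_positive(vt_fraction, "vt_fraction")
  check_positive(mv_fraction, "mv_fraction")
  check_positive(duty_factor, "duty_factor")
  vt <- vt_fraction * fvc
  mv <- mv_fraction * mvv
  fb <- mv / (duty_factor * vt)
  structure(
    list(week = 1L, tidal_volume = vt, breath_frequency = fb,
         target_mv = mv, minute_ventilation = vt * fb,
         duty_factor = duty_factor),
    class = "rmt_prescription"
  )
}

#' Weekly progression of an RMT prescription
#'
#' Increases the workload by `increment` (default ~15%) for the next week
#' by alternating which parameter is raised: volume on even weeks,
#' frequency on odd weeks (the alternation starts with volume in week 2).
#' Either way the ventilation product, and hence the target minute volume,
#' grows by the same factor each week.
#'
#' @param p an [initial_prescription()] (or previously progressed) object.
#' @param increment weekly multiplicative increment (default 0.15).
#' @return The week-advanced `rmt_prescription`.
#' @export
progress <- function(p, increment = 0.15) {
  stopifnot(inherits(p, "rmt_prescription"))
  check_nonneg(increment, "increment")
  wk <- p$week + 1L
  if (wk %% 2L == 0L) {
    p$tidal_volume <- p$tidal_volume * (1 + increment)
  } else {
    p$breath_frequency <- p$breath_frequency * (1 + increment)
  }
  p$week <- wk
  p$target_mv <- p$target_mv * (1 + increment)
  p$minute_ventilation <- p$tidal_volume * p$breath_frequency
  p
}

#' Multi-week RMT schedule
#'
#' Builds the full weekly schedule from the initial prescription by
#' repeated [progress()] steps, with optional per-week increment
#' overrides ("small adjustments according to adaptability").
#'
#' @inheritParams initial_prescription
#' @param weeks number of training weeks (default 8).
#' @param increment default weekly increment (default 0.15).
#' @param overrides optional named numeric vector of per-week increments,
#'   names = target week numbers (e.g. `c("3" = 0.10)`).
#' @return A data.frame with one row per week: `week`, `tidal_volume`,
#'   `breath_frequency`, `target_mv`, `minute_ventilation`.
#' @examples
#' rmt_schedule(fvc = 4.10, mvv = 134, weeks = 8)
#' @export
rmt_schedule <- function(fvc, mvv, weeks = 8, increment = 0.15,
                         overrides = NULL, ...) {
  p <- initial_prescription(fvc, mvv, ...)
  rows <- vector("list", weeks)
  rows[[1L]] <- p
  if (weeks > 1L) {
    for (w in 2:weeks) {
      inc <- increment
      if (!is.null(overrides) && as.character(w) %in% names(overrides)) {
        inc <- overrides[[as.character(w)]]
      }
      p <- progress(p, increment = inc)
      rows[[w]] <- p
    }
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    data.frame(week = r$week, tidal_volume = r$tidal_volume,
               breath_frequency = r$breath_frequency,
               target_mv = r$target_mv,
               minute_ventilation = r$minute_ventilation)
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.rmt_prescription <- function(x, ...) {
  cat(sprintf(
    "RMT prescription, week %d: Vt %.2f l x f_b %.1f /min (target MV %.1f l/min)\n",
    x$week, x$tidal_volume, x$breath_frequency, x$target_mv))
  invisible(x)
}
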