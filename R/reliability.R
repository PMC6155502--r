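#' Two-way mixed-model intraclass correlation coefficient
#'
#' Test-retest reliability from a subjects-by-trials matrix. The default is
#' the consistency, single-measures form ICC(3,1),
#' `(MS_subjects - MS_error) / (MS_subjects + (k - 1) MS_error)`,
#' from the two-way ANOVA decomposition with subjects as rows and trials as
#' columns (`k` trials); the trial (column) effect is removed, so ICC is
#' invariant to a constant shift between trials. The absolute-agreement
#' single-measures form ICC(2,1) is available via `type = "agreement"`.
#'
#' A matrix with zero between-subject and zero error variance (all cells
#' equal) returns 1 by convention, with attribute `degenerate = TRUE`.
#'
#' @param m numeric matrix, subjects in rows (>= 2), trials in columns
#'   (>= 2), no missing cells.
#' @param type `"consistency"` (ICC(3,1), default) or `"agreement"`
#'   (ICC(2,1)).
#' @return The ICC (scalar, `<= 1`).
#' @examples
#' m <- cbind(c(10, 20, 30, 40), c(11, 19, 32, 41))
#' icc_two_way_mixed(m)
#' @export
icc_two_way_mixed <- function(m, type = c("consistency", "agreement")) {
  type <- match.arg(type)
  m <- as.matrix(m)
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2L || k < 2L || any(!is.finite(m))) {
    vr_stop("need >= 2 subjects, >= 2 trials, no missing cells",
            "vasoreact_parameter_error")
  }
  grand <- mean(m)
  ss_rows <- k * sum((rowMeans(m) - grand)^2)
  ss_cols <- n * sum((colMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  ms_rows <- ss_rows / (n - 1)
  ms_cols <- ss_cols / (k - 1)
  ms_err <- ss_err / ((n - 1) * (k - 1))
  if (ms_rows <= 0 && ms_err <= 0) {
    out <- 1
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  if (type == "consistency") {
    (ms_rows - ms_err) / (ms_rows + (k - 1) * ms_err)
  } else {
    (ms_rows - ms_err) /
      (ms_rows + (k - 1) * ms_err + k * (ms_cols - ms_err) / n)
  }
}

#' Standard error of measurement as a percentage of the mean
#'
#' `SEM = SD_pooled * sqrt(1 - ICC)`, with `SD_pooled` the sample SD over
#' all cells of the trial matrix, expressed as a percentage of the grand
#' mean. The alternative `sqrt(MS_error)` form is available via
#' `method = "mse"`; both agree to within rounding on typical test-retest
#' tables.
#'
#' @param m the subjects-by-trials matrix the ICC was computed from.
#' @param icc the intraclass correlation (`<= 1`).
#' @param method `"sd"` (default, `SD_pooled * sqrt(1 - ICC)`) or `"mse"`
#'   (`sqrt(MS_error)` from the two-way decomposition).
#' @return SEM as a percentage of the grand mean.
#' @export
sem_percent <- function(m, icc, method = c("sd", "mse")) {
  method <- match.arg(method)
  m <- as.matrix(m)
  if (icc > 1) {
    vr_stop("icc must be <= 1", "vasoreact_parameter_error")
  }
  grand <- mean(m)
  if (grand == 0) {
    vr_stop("grand mean is zero; SEM% undefined", "vasoreact_domain_error")
  }
  sem <- if (method == "sd") {
    sd(as.vector(m)) * sqrt(max(1 - icc, 0))
  } else {
    n <- nrow(m); k <- ncol(m)
    ss_rows <- k * sum((rowMeans(m) - grand)^2)
    ss_cols <- n * sum((colMeans(m) - grand)^2)
    ss_err <- sum((m - grand)^2) - ss_rows - ss_cols
    sqrt(max(ss_err, 0) / ((n - 1) * (k - 1)))
  }
  100 * sem / abs(grand)
}

#' Minimum detectable change at 95% confidence
#'
#' `MDC95 = 1.96 * sqrt(2) * SEM`, here applied on the percent scale:
#' the smallest change exceeding measurement noise with 95% confidence.
#'
#' @param sem_percent SEM as a percentage of the mean, non-negative.
#' @return MDC95 as a percentage.
#' @examples
#' mdc95_percent(3.6)  # 9.98, ~10 at integer rounding
#' @export
mdc95_percent <- function(sem_percent) {
  if (any(sem_percent < 0)) {
    vr_stop("sem_percent must be non-negative", "vasoreact_parameter_error")
  }
  1.96 * sqrt(2) * sem_percent
}

#' Classify an ICC into reliability categories
#'
#' Very high if `> 0.90`, high if in `[0.70, 0.90]`, moderate if in
#' `[0.50, 0.70)`, low below 0.50 (printed band edges treated as inclusive
#' interval boundaries).
#'
#' @param icc intraclass correlation value(s).
#' @return Character vector of classes.
#' @examples
#' classify_icc(c(0.956, 0.85, 0.603, 0.3))
#' @export
classify_icc <- function(icc) {
  ifelse(icc > 0.90, "very high",
         ifelse(icc >= 0.70, "high",
                ifelse(icc >= 0.50, "moderate", "low")))
}

#' Full reliability analysis of a trial matrix
#'
#' Chains [icc_two_way_mixed()], [sem_percent()], [mdc95_percent()] and
#' [classify_icc()] for one variable measured over repeated trials.
#'
#' @param m subjects-by-trials matrix.
#' @param variable_name,units labels carried into the result.
#' @param icc_type,sem_method passed to the underlying functions.
#' @return An object of class `reliability_result`: list with `icc`,
#'   `sem_percent`, `mdc95_percent`, `icc_class`, `trial_means`,
#'   `trial_sds`, `n_subjects`, `n_trials`, labels.
#' @examples
#' m <- cbind(rnorm(10, 100, 10), rnorm(10, 100, 10))
#' reliability_stats(m, "demo")
#' @export
reliability_stats <- function(m, variable_name = "variable", units = "",
                              icc_type = "consistency", sem_method = "sd") {
  m <- as.matrix(m)
  icc <- icc_two_way_mixed(m, type = icc_type)
  sem <- sem_percent(m, as.numeric(icc), method = sem_method)
  structure(
    list(icc = as.numeric(icc), sem_percent = sem,
         mdc95_percent = mdc95_percent(sem),
         icc_class = classify_icc(as.numeric(icc)),
         trial_means = colMeans(m), trial_sds = apply(m, 2L, sd),
         n_subjects = nrow(m), n_trials = ncol(m),
         variable_name = variable_name, units = units,
         degenerate = isTRUE(attr(icc, "degenerate"))),
    class = "reliability_result"
  )
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("Reliability of %s%s (%d subjects x %d trials):\n",
              x$variable_name, if (nzchar(x$units)) paste0(" (", x$units, ")") else "",
              x$n_subjects, x$n_trials))
  cat(sprintf("  trial means %s\n",
              paste(sprintf("%.2f +/- %.2f", x$trial_means, x$trial_sds),
                    collapse = " | ")))
  cat(sprintf("  ICC %.3f (%s), SEM%% %.1f, MDC95%% %.1f\n",
              x$icc, x$icc_class, x$sem_percent, x$mdc95_percent))
  invisible(x)
}

#' Reliability table for several variables
#'
#' Applies [reliability_stats()] to each variable of a list of trial
#' matrices and assembles a test-retest summary table (variable, per-trial
#' mean and SD, ICC, SEM%, MDC95%, class).
#'
#' @param matrices named list of subjects-by-trials matrices.
#' @param ... passed to [reliability_stats()].
#' @return A data.frame, one row per variable.
#' @export
reliability_table <- function(matrices, ...) {
  if (!is.list(matrices) || is.null(names(matrices))) {
    vr_stop("matrices must be a named list", "vasoreact_parameter_error")
  }
  rows <- lapply(names(matrices), function(v) {
    r <- reliability_stats(matrices[[v]], variable_name = v, ...)
    data.frame(variable = v,
               trial1_mean = r$trial_means[1L], trial1_sd = r$trial_sds[1L],
               trial2_mean = r$trial_means[2L], trial2_sd = r$trial_sds[2L],
               icc = r$icc, sem_percent = r$sem_percent,
               mdc95_percent = r$mdc95_percent, icc_class = r$icc_class,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
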