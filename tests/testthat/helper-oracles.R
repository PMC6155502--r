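# Independent oracles used across the suite. These deliberately take a
# different computational route from the package internals.

# explicit per-interval trapezoid sum
trapz_oracle <- function(x, y) {
  s <- 0
  for (i in seq_len(length(x) - 1L)) {
    dx <- x[i + 1L] - x[i]
    s <- s + y[i] * dx + 0.5 * (y[i + 1L] - y[i]) * dx
  }
  s
}

# ICC(3,1) via the two-way ANOVA mean squares from stats::aov
icc_oracle <- function(m) {
  d <- data.frame(
    value = as.vector(m),
    subject = factor(rep(seq_len(nrow(m)), ncol(m))),
    trial = factor(rep(seq_len(ncol(m)), each = nrow(m)))
  )
  tab <- summary(stats::aov(value ~ subject + trial, data = d))[[1L]]
  ms_subj <- tab["subject", "Mean Sq"]
  ms_err <- tab["Residuals", "Mean Sq"]
  k <- ncol(m)
  (ms_subj - ms_err) / (ms_subj + (k - 1) * ms_err)
}

# centered moving average with shrinking edge windows, loop form
smooth_oracle <- function(x, window_s, fs) {
  k <- max(1L, round(window_s * fs))
  if (k %% 2L == 0L) k <- k + 1L
  h <- (k - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - h):min(n, i + h)])
  }, numeric(1))
}

# balanced split-plot (group between, time within) sums of squares by hand;
# d has columns subject, group, time, value
splitplot_oracle <- function(d) {
  grand <- mean(d$value)
  n_t <- length(unique(d$time))
  n_g <- length(unique(d$group))
  n_s <- length(unique(d$subject))
  n_per <- n_s / n_g
  subj_means <- tapply(d$value, d$subject, mean)
  grp_means <- tapply(d$value, d$group, mean)
  time_means <- tapply(d$value, d$time, mean)
  cell_means <- tapply(d$value, list(d$group, d$time), mean)
  ss_between <- n_t * sum((subj_means - grand)^2)
  ss_group <- n_per * n_t * sum((grp_means - grand)^2)
  ss_subj <- ss_between - ss_group
  ss_time <- n_s * sum((time_means - grand)^2)
  ss_cells <- n_per * sum((cell_means - grand)^2)
  ss_int <- ss_cells - ss_group - ss_time
  ss_tot <- sum((d$value - grand)^2)
  ss_err <- ss_tot - ss_between - ss_time - ss_int
  df_subj <- n_s - n_g
  df_err <- (n_s - n_g) * (n_t - 1)
  list(
    F_group = (ss_group / (n_g - 1)) / (ss_subj / df_subj),
    F_time = (ss_time / (n_t - 1)) / (ss_err / df_err),
    F_int = (ss_int / ((n_g - 1) * (n_t - 1))) / (ss_err / df_err)
  )
}

# quick null cohort for ANOVA simulations: balanced 2-group pre/post with
# subject random intercepts and iid noise, no true effects unless shifted
make_null_design <- function(n_per_group, sd_subj = 1, sd_err = 1,
                             rmt_post_shift = 0) {
  n <- 2L * n_per_group
  subj <- sprintf("S%02d", seq_len(n))
  grp <- rep(c("RMT", "SHAM"), each = n_per_group)
  b <- rnorm(n, 0, sd_subj)
  pre <- b + rnorm(n, 0, sd_err)
  post <- b + rnorm(n, 0, sd_err) + ifelse(grp == "RMT", rmt_post_shift, 0)
  data.frame(
    subject = rep(subj, 2L), group = rep(grp, 2L),
    time = rep(c("pre", "post"), each = n),
    variable = "y", value = c(pre, post), stringsAsFactors = FALSE
  )
}
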