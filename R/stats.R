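#' Percent change from pre to post
#'
#' `(post - pre) / pre * 100`; scale-invariant in the sense that
#' `percent_change(c*a, c*b) = percent_change(a, b)` for `c > 0`.
#'
#' @param pre pre-training value(s), non-zero.
#' @param post post-training value(s).
#' @return Percent change.
#' @examples
#' percent_change(48, 63)    # +31.25 (MIP)
#' percent_change(134, 155)  # +15.67 (MVV)
#' @export
percent_change <- function(pre, post) {
  if (any(pre == 0)) {
    vr_stop("pre must be non-zero", "vasoreact_domain_error")
  }
  (post - pre) / pre * 100
}

#' Total lung capacity from residual volume and FVC
#'
#' `TLC = RV + FVC` (litres).
#'
#' @param rv residual volume, l, non-negative.
#' @param fvc forced vital capacity, l, positive.
#' @return Total lung capacity, l.
#' @examples
#' total_lung_capacity(0.61, 4.10)  # 4.71
#' @export
total_lung_capacity <- function(rv, fvc) {
  if (any(rv < 0) || any(fvc <= 0)) {
    vr_stop("rv must be >= 0 and fvc > 0", "vasoreact_domain_error")
  }
  rv + fvc
}

# assemble a comparison_result
comparison_result <- function(effect, statistic, p_value, test_name,
                              adjusted = FALSE, degenerate = FALSE) {
  structure(
    list(effect = effect, statistic = statistic, p_value = p_value,
         test_name = test_name, adjusted = adjusted, degenerate = degenerate),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: effect %.4g, statistic %.3f, p = %.4g%s\n",
              x$test_name, x$effect, x$statistic, x$p_value,
              if (x$adjusted) " (adjusted)" else ""))
  invisible(x)
}

#' Paired Student's t-test on pre/post values
#'
#' Two-sided paired t-test of within-group change. All-zero differences
#' (post identical to pre) return the degenerate `t = 0, p = 1`; constant
#' non-zero differences have no estimable error and raise a
#' degenerate-data error.
#'
#' @param pre,post equal-length numeric vectors paired by subject,
#'   `n >= 2`.
#' @return A `comparison_result` with `effect` = mean difference
#'   (post - pre), `statistic` = t, `p_value`, and additionally
#'   `percent_change` of the means.
#' @export
paired_t <- function(pre, post) {
  if (length(pre) != length(post) || length(pre) < 2L) {
    vr_stop("pre and post must be paired vectors with n >= 2",
            "vasoreact_parameter_error")
  }
  d <- post - pre
  if (sd(d) == 0) {
    if (all(d == 0)) {
      out <- comparison_result(0, 0, 1, "paired t-test", degenerate = TRUE)
      out$percent_change <- 0
      return(out)
    }
    vr_stop("differences have zero variance (non-zero constant shift)",
            "vasoreact_degenerate_data_error")
  }
  tt <- t.test(post, pre, paired = TRUE)
  out <- comparison_result(unname(tt$estimate), unname(tt$statistic),
                           tt$p.value, "paired t-test")
  out$percent_change <- percent_change(mean(pre), mean(post))
  out
}

#' Unpaired Student's t-test between groups
#'
#' Two-sided two-sample t-test with pooled variance (classic Student form).
#'
#' @param x,y numeric vectors for the two groups, each `n >= 2`.
#' @return A `comparison_result` with `effect` = mean(x) - mean(y).
#' @export
unpaired_t <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) {
    vr_stop("both groups need n >= 2", "vasoreact_parameter_error")
  }
  tt <- t.test(x, y, var.equal = TRUE)
  comparison_result(unname(tt$estimate[1L] - tt$estimate[2L]),
                    unname(tt$statistic), tt$p.value,
                    "unpaired t-test (pooled variance)")
}

#' Holm-Sidak step-down adjustment of p-values
#'
#' Sorted raw p-values `p_(1) <= ... <= p_(m)` are adjusted as
#' `1 - (1 - p_(i))^(m - i + 1)` with a running maximum to keep the
#' adjusted values monotone; with `m = 1` the raw p-value is returned
#' unchanged.
#'
#' @param p vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order.
#' @export
holm_sidak <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    vr_stop("p-values must lie in [0, 1]", "vasoreact_parameter_error")
  }
  m <- length(p)
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- cummax(pmin(adj, 1))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Mixed-design (split-plot) two-way repeated-measures ANOVA
#'
#' Group (between subjects) by time (within subjects) ANOVA for one
#' variable of a tidy cohort table, the design used to compare a training
#' and a sham arm before and after an intervention. Implemented as a
#' split-plot `aov` with subject as the error stratum for the within
#' factor. When the interaction is significant at `alpha`, the four
#' pairwise contrasts (pre vs post within each group, paired; group vs
#' group at each time, unpaired) are reported with Holm-Sidak adjusted
#' p-values.
#'
#' @param table tidy cohort data.frame with columns `subject`, `group`,
#'   `time`, `variable`, `value`; the design must be complete (every
#'   subject measured at both times).
#' @param variable which variable to analyse.
#' @param alpha significance level gating the post hocs (default 0.05).
#' @return An object of class `rm_anova_result`: list with `anova` (a
#'   data.frame of F and p for group, time, interaction), `posthoc`
#'   (data.frame of contrasts, or NULL), `variable`, `alpha`.
#' @export
two_way_rm_anova <- function(table, variable, alpha = 0.05) {
  d <- table[table$variable == variable, , drop = FALSE]
  if (nrow(d) == 0L) {
    vr_stop(sprintf("variable '%s' not present", variable),
            "vasoreact_parameter_error")
  }
  tab <- with(d, table(subject, time))
  if (any(tab != 1L)) {
    vr_stop("design must be complete: one value per subject x time",
            "vasoreact_design_error")
  }
  d$subject <- factor(d$subject)
  d$group <- factor(d$group)
  d$time <- factor(d$time, levels = c("pre", "post"))
  fit <- aov(value ~ group * time + Error(subject), data = d)
  s <- summary(fit)
  between <- as.data.frame(s[["Error: subject"]][[1L]])
  within <- as.data.frame(s[["Error: Within"]][[1L]])
  pick <- function(df, term) {
    i <- which(trimws(rownames(df)) == term)
    c(F = df[i, "F value"], p = df[i, "Pr(>F)"])
  }
  res <- rbind(
    group = pick(between, "group"),
    time = pick(within, "time"),
    `group:time` = pick(within, "group:time")
  )
  anova_df <- data.frame(term = rownames(res), F = res[, "F"],
                         p = res[, "p"], row.names = NULL)

  posthoc <- NULL
  if (anova_df$p[anova_df$term == "group:time"] < alpha) {
    wide <- merge(
      d[d$time == "pre", c("subject", "group", "value")],
      d[d$time == "post", c("subject", "value")],
      by = "subject", suffixes = c("_pre", "_post"))
    contrasts <- list(
      `RMT pre vs post` = with(wide[wide$group == "RMT", ],
                               paired_t(value_pre, value_post)),
      `SHAM pre vs post` = with(wide[wide$group == "SHAM", ],
                                paired_t(value_pre, value_post)),
      `RMT vs SHAM (pre)` = unpaired_t(wide$value_pre[wide$group == "RMT"],
                                       wide$value_pre[wide$group == "SHAM"]),
      `RMT vs SHAM (post)` = unpaired_t(wide$value_post[wide$group == "RMT"],
                                        wide$value_post[wide$group == "SHAM"])
    )
    raw <- vapply(contrasts, function(x) x$p_value, numeric(1))
    posthoc <- data.frame(
      contrast = names(contrasts),
      effect = vapply(contrasts, function(x) x$effect, numeric(1)),
      statistic = vapply(contrasts, function(x) x$statistic, numeric(1)),
      p_raw = raw,
      p_holm_sidak = holm_sidak(raw),
      row.names = NULL
    )
  }
  structure(
    list(anova = anova_df, posthoc = posthoc, variable = variable,
         alpha = alpha),
    class = "rm_anova_result"
  )
}

#' @export
print.rm_anova_result <- function(x, ...) {
  cat(sprintf("Mixed-design two-way RM-ANOVA for %s (alpha = %g):\n",
              x$variable, x$alpha))
  print(x$anova, row.names = FALSE, digits = 4)
  if (!is.null(x$posthoc)) {
    cat("Holm-Sidak post hocs (interaction significant):\n")
    print(x$posthoc, row.names = FALSE, digits = 4)
  } else {
    cat("No post hocs (interaction not significant).\n")
  }
  invisible(x)
}

#' Per-variable group comparison table for a cohort
#'
#' For each variable of a tidy cohort table: group means pre/post, percent
#' change of the group means, within-group paired t-tests, the post-values
#' between-group unpaired t-test, and the mixed-design ANOVA interaction
#' p-value. Shapiro-Wilk normality p-values of the within-group changes
#' are reported alongside but never gate the parametric tests.
#'
#' @param table tidy cohort data.frame (see [two_way_rm_anova()]).
#' @param variables variables to analyse (default: all present).
#' @param alpha significance level (default 0.05).
#' @return A data.frame, one row per variable.
#' @export
cohort_compare <- function(table, variables = unique(table$variable),
                           alpha = 0.05) {
  rows <- lapply(variables, function(v) {
    d <- table[table$variable == v, , drop = FALSE]
    wide <- merge(
      d[d$time == "pre", c("subject", "group", "value")],
      d[d$time == "post", c("subject", "value")],
      by = "subject", suffixes = c("_pre", "_post"))
    g <- function(grp) wide[wide$group == grp, , drop = FALSE]
    rmt <- g("RMT"); sham <- g("SHAM")
    t_rmt <- paired_t(rmt$value_pre, rmt$value_post)
    t_sham <- paired_t(sham$value_pre, sham$value_post)
    t_btw <- unpaired_t(rmt$value_post, sham$value_post)
    aovp <- two_way_rm_anova(table, v, alpha = alpha)
    sw <- function(x) if (length(unique(x)) > 2) stats::shapiro.test(x)$p.value else NA_real_
    data.frame(
      variable = v,
      rmt_pre = mean(rmt$value_pre), rmt_post = mean(rmt$value_post),
      rmt_pct_change = percent_change(mean(rmt$value_pre), mean(rmt$value_post)),
      rmt_p_paired = t_rmt$p_value,
      sham_pre = mean(sham$value_pre), sham_post = mean(sham$value_post),
      sham_pct_change = percent_change(mean(sham$value_pre), mean(sham$value_post)),
      sham_p_paired = t_sham$p_value,
      p_between_post = t_btw$p_value,
      p_interaction = aovp$anova$p[aovp$anova$term == "group:time"],
      shapiro_p_rmt = sw(rmt$value_post - rmt$value_pre),
      shapiro_p_sham = sw(sham$value_post - sham$value_pre),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
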