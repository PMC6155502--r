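test_that("percent change arithmetic and scale invariance", {
  expect_equal(percent_change(48, 63), 31.25)
  expect_equal(round(percent_change(134, 155)), 16)
  expect_equal(percent_change(7.3, 7.3), 0)
  # scale invariance
  expect_equal(percent_change(3 * 48, 3 * 63), percent_change(48, 63))
  expect_error(percent_change(0, 5), class = "vasoreact_domain_error")
})

test_that("total lung capacity arithmetic", {
  expect_equal(total_lung_capacity(0.61, 4.10), 4.71)
  expect_equal(total_lung_capacity(0.79, 3.91), 4.70)
  expect_equal(total_lung_capacity(0, 4.2), 4.2)
  expect_error(total_lung_capacity(-0.1, 4), class = "vasoreact_domain_error")
})

test_that("paired t-test: closed-form oracle and degenerate inputs", {
  pre <- c(10, 12, 9, 14)
  post <- pre + c(1, 2, 3, 4)
  r <- paired_t(pre, post)
  d <- c(1, 2, 3, 4)
  t_oracle <- mean(d) / (sd(d) / sqrt(4))
  p_oracle <- 2 * pt(-abs(t_oracle), df = 3)
  expect_equal(r$statistic, t_oracle, tolerance = 1e-12)
  expect_equal(r$p_value, p_oracle, tolerance = 1e-12)
  expect_equal(r$effect, 2.5)

  # post identical to pre: t = 0, p = 1, flagged
  r0 <- paired_t(pre, pre)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  expect_true(r0$degenerate)

  # constant non-zero shift: no estimable error
  expect_error(paired_t(pre, pre + 2),
               class = "vasoreact_degenerate_data_error")
  expect_error(paired_t(1, 2), class = "vasoreact_parameter_error")

  # p -> 0 as n grows for a fixed real shift
  set.seed(61)
  p_small <- paired_t(rnorm(10), rnorm(10) + 1)$p_value
  p_large <- paired_t(rnorm(200), rnorm(200) + 1)$p_value
  expect_lt(p_large, p_small)
})

test_that("Holm-Sidak adjustment: degenerate case, arithmetic, monotonicity", {
  # m = 1 reduces to the unadjusted p
  expect_equal(holm_sidak(0.0321), 0.0321)

  # hand-computed three-test example
  p <- c(0.01, 0.04, 0.03)
  adj <- holm_sidak(p)
  expect_equal(adj[1], 1 - (1 - 0.01)^3, tolerance = 1e-12)
  expect_equal(adj[3], max(1 - (1 - 0.01)^3, 1 - (1 - 0.03)^2),
               tolerance = 1e-12)
  expect_equal(adj[2], max(adj[3], 1 - (1 - 0.04)^1), tolerance = 1e-12)

  # adjusted p-values are monotone in the raw ordering
  set.seed(71)
  praw <- runif(8)
  padj <- holm_sidak(praw)
  expect_true(all(diff(padj[order(praw)]) >= -1e-12))
  expect_true(all(padj >= praw - 1e-12))
  expect_true(all(padj <= 1))

  expect_error(holm_sidak(c(0.5, 1.2)), class = "vasoreact_parameter_error")
})

test_that("mixed-design ANOVA matches the split-plot sums-of-squares oracle", {
  set.seed(81)
  for (r in 1:3) {
    d <- make_null_design(8, rmt_post_shift = runif(1, 0, 2))
    res <- two_way_rm_anova(d, "y")
    ora <- splitplot_oracle(d)
    expect_equal(res$anova$F[res$anova$term == "group"], ora$F_group,
                 tolerance = 1e-8)
    expect_equal(res$anova$F[res$anova$term == "time"], ora$F_time,
                 tolerance = 1e-8)
    expect_equal(res$anova$F[res$anova$term == "group:time"], ora$F_int,
                 tolerance = 1e-8)
  }
})

test_that("mixed-design ANOVA detects a programmed interaction", {
  set.seed(91)
  hits <- vapply(1:100, function(i) {
    d <- make_null_design(12, sd_subj = 1, sd_err = 1, rmt_post_shift = 3)
    res <- two_way_rm_anova(d, "y")
    res$anova$p[res$anova$term == "group:time"] < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.9)

  # significant interaction triggers Holm-Sidak post hocs
  set.seed(92)
  d <- make_null_design(12, rmt_post_shift = 3)
  res <- two_way_rm_anova(d, "y")
  expect_false(is.null(res$posthoc))
  expect_equal(nrow(res$posthoc), 4L)
  expect_true(all(res$posthoc$p_holm_sidak >= res$posthoc$p_raw - 1e-12))
})

test_that("incomplete designs are rejected with a design error", {
  d <- make_null_design(4)
  d <- d[-1, ]  # drop one subject's pre measurement
  expect_error(two_way_rm_anova(d, "y"), class = "vasoreact_design_error")
  expect_error(two_way_rm_anova(d, "nope"),
               class = "vasoreact_parameter_error")
})

test_that("cohort_compare assembles per-variable group statistics", {
  set.seed(101)
  co <- simulate_cohort(n_per_group = 10,
                        effects = list(MIP = c(48, 5, 1.31, 1.0),
                                       MAP = c(88, 7, 1.0, 1.0)),
                        seed = 101)
  tab <- cohort_compare(co)
  expect_equal(sort(tab$variable), c("MAP", "MIP"))
  mip <- tab[tab$variable == "MIP", ]
  expect_lt(mip$rmt_p_paired, 0.05)
  expect_lt(mip$p_interaction, 0.05)
  expect_gt(mip$rmt_pct_change, 20)
  map <- tab[tab$variable == "MAP", ]
  expect_lt(abs(map$rmt_pct_change), 10)
  expect_true(all(tab$rmt_p_paired >= 0 & tab$rmt_p_paired <= 1))
})
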