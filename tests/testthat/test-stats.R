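# Direct simulation of pick-level data from the statistical model (no
# waveform pipeline), for the mixed-model layer.
sim_lmm_data <- function(n_f = 8, n_m = 8, per = 4, gap = 0, icc_sd = 1,
                         res_sd = 1, base = 10) {
  ids <- c(sprintf("F%02d", seq_len(n_f)), sprintf("M%02d", seq_len(n_m)))
  sex <- rep(c("female", "male"), c(n_f, n_m))
  u <- rnorm(n_f + n_m, 0, icc_sd)
  d <- data.frame(
    participant_id = rep(ids, each = per),
    sex = factor(rep(sex, each = per), levels = c("female", "male")),
    stimulus_level = rep(seq(40, by = -2, length.out = per), n_f + n_m)
  )
  d$p1n1_latency <- base + gap * (d$sex == "male") +
    rep(u, each = per) + rnorm(nrow(d), 0, res_sd)
  d
}

test_that("chi-squared upper tail reproduces textbook and printed values", {
  expect_equal(chi2_upper_tail(0, 1), 1)
  expect_equal(chi2_upper_tail(3.84, 1), 0.05, tolerance = 0.002)
  expect_equal(signif(chi2_upper_tail(5.90, 1), 2), 0.015)
  expect_error(chi2_upper_tail(-1, 1), class = "vemp_argument_error")
  expect_error(chi2_upper_tail(1, 0), class = "vemp_argument_error")
})

test_that("Welch test from summaries matches the closed form and raw samples", {
  # identical groups
  w0 <- welch_test(mean_f = 5, sd_f = 1, n_f = 10,
                   mean_m = 5, sd_m = 1, n_m = 10)
  expect_equal(w0$t_statistic, 0)
  expect_equal(w0$p_value, 1)
  # equal variances and n: Welch df is exactly 2n - 2
  expect_equal(w0$df, 18)

  # summary path equals the raw-sample path on identical inputs
  set.seed(4)
  x <- rnorm(12, 10, 2); y <- rnorm(15, 12, 3)
  wr <- welch_test(x = x, y = y)
  ws <- welch_test(mean_f = mean(x), sd_f = sd(x), n_f = 12,
                   mean_m = mean(y), sd_m = sd(y), n_m = 15)
  expect_equal(wr$t_statistic, ws$t_statistic)
  expect_equal(wr$df, ws$df)
  expect_equal(wr$p_value, ws$p_value)
  # and matches stats::t.test on the raw samples
  tt <- t.test(y, x)
  expect_equal(wr$t_statistic, unname(tt$statistic))
  expect_equal(wr$df, unname(tt$parameter))
  expect_equal(wr$p_value, tt$p.value)

  expect_error(welch_test(mean_f = 1, sd_f = 0, n_f = 5,
                          mean_m = 2, sd_m = 1, n_m = 5),
               class = "vemp_argument_error")
})

test_that("Cohen's d conversions behave as published conventions", {
  expect_equal(cohens_d(0, 30), 0)
  expect_equal(cohens_d(4, 16), 2)
  expect_equal(cohens_d(2, 25), 2 * cohens_d(1, 25))
  expect_equal(cohens_d_pooled(9.99, 12.41, 2.74, 2.54), 0.916, tolerance = 1e-3)
  expect_error(cohens_d(1, 0), class = "vemp_argument_error")
})

test_that("participant means average picks irrespective of row order", {
  d <- data.frame(participant_id = c("a", "b", "b"),
                  sex = factor(c("female", "male", "male"),
                               levels = c("female", "male")),
                  p1n1_latency = c(7, 9, 11))
  pm <- participant_means(d)
  expect_equal(pm$mean, c(7, 10))
  pm2 <- participant_means(d[c(3, 1, 2), ])
  expect_equal(pm, pm2)
})

test_that("random-intercept ML fit recovers planted fixed effects", {
  set.seed(11)
  # zero sex effect, no noise: coefficient is numerically zero
  d0 <- sim_lmm_data(gap = 0, icc_sd = 0, res_sd = 0)
  f0 <- suppressWarnings(suppressMessages(fit_lmm(d0, "p1n1_latency")))
  expect_lt(abs(f0$fixed_effects$estimate[f0$fixed_effects$term == "sex_male"]),
            1e-8)
  expect_true(f0$singular)

  # large balanced design: sex gap recovered within its standard error
  set.seed(12)
  d1 <- sim_lmm_data(n_f = 100, n_m = 100, per = 6, gap = 2.42,
                     icc_sd = 2.5, res_sd = 1)
  f1 <- fit_lmm(d1, "p1n1_latency")
  i <- match("sex_male", f1$fixed_effects$term)
  expect_lt(abs(f1$fixed_effects$estimate[i] - 2.42),
            3 * f1$fixed_effects$se[i])

  # known common stimulus slope recovered
  set.seed(13)
  d2 <- sim_lmm_data(n_f = 50, n_m = 50, per = 6, icc_sd = 1, res_sd = 0.5)
  d2$response_level <- 3 + 1.89 * d2$stimulus_level +
    rep(rnorm(100), each = 6) + rnorm(nrow(d2), 0, 0.3)
  f2 <- fit_lmm(d2, "response_level", include_stimulus = TRUE)
  j <- match("stimulus_level", f2$fixed_effects$term)
  expect_equal(f2$fixed_effects$estimate[j], 1.89, tolerance = 0.05)

  expect_error(fit_lmm(d1[d1$sex == "male", ], "p1n1_latency"),
               class = "vemp_argument_error")
})

test_that("likelihood-ratio comparison of nested fits", {
  set.seed(14)
  d <- sim_lmm_data(n_f = 12, n_m = 12, per = 4, gap = 2, icc_sd = 1.5)
  null_fit <- fit_lmm(d, "p1n1_latency", include_sex = FALSE)
  alt_fit <- fit_lmm(d, "p1n1_latency", include_sex = TRUE)
  lrt <- likelihood_ratio_test(null_fit, alt_fit)
  expect_equal(lrt$df, 1)
  expect_equal(lrt$chi2,
               2 * (alt_fit$log_likelihood - null_fit$log_likelihood))
  expect_equal(lrt$p, chi2_upper_tail(lrt$chi2, 1))
  # identical models: chi2 = 0, p = 1
  same <- likelihood_ratio_test(alt_fit, alt_fit)
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  expect_error(likelihood_ratio_test(alt_fit, null_fit),
               class = "vemp_argument_error")
  lrt0 <- likelihood_ratio_test(null_fit, fit_lmm(d, "p1n1_latency",
                                                  include_sex = FALSE,
                                                  include_stimulus = TRUE))
  expect_gte(lrt0$p, 0)
})

test_that("LRT and Welch agree on participant-level data", {
  set.seed(15)
  d <- sim_lmm_data(n_f = 24, n_m = 24, per = 8, gap = 2.4,
                    icc_sd = 2.6, res_sd = 1)
  lrt <- lrt_sex_effect(d, "p1n1_latency")
  pm <- participant_means(d)
  w <- welch_test(x = pm$mean[pm$sex == "female"],
                  y = pm$mean[pm$sex == "male"])
  expect_equal(sign(lrt$sex_effect), sign(w$difference))
  expect_lt(abs(log10(lrt$p / w$p_value)), log10(3)) # p within a factor of 3
})

test_that("LRT type-I error is near nominal alpha on null cohorts", {
  set.seed(16)
  n_rep <- 1000
  rej <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    d <- sim_lmm_data(n_f = 8, n_m = 8, per = 4, gap = 0,
                      icc_sd = 1.5, res_sd = 1)
    rej[i] <- suppressMessages(lrt_sex_effect(d, "p1n1_latency"))$p < 0.05
  }
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.08)
})

test_that("conditional R^2 follows the variance-partition formula", {
  # response exactly linear in sex: R^2 ~ 1
  d <- sim_lmm_data(gap = 3, icc_sd = 0, res_sd = 0)
  f <- suppressWarnings(suppressMessages(fit_lmm(d, "p1n1_latency")))
  expect_equal(conditional_r2(f), 1, tolerance = 1e-6)

  # known variance components
  set.seed(17)
  d2 <- sim_lmm_data(n_f = 150, n_m = 150, per = 6, gap = 2,
                     icc_sd = 2, res_sd = 1)
  f2 <- fit_lmm(d2, "p1n1_latency")
  var_f <- var(c(rep(0, 150 * 6), rep(2, 150 * 6)))
  want <- (var_f + 4) / (var_f + 4 + 1)
  expect_equal(conditional_r2(f2), want, tolerance = 0.05)
})
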