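study_row <- function(label, mean_f, mean_m, sd_f = 2.5, sd_m = 2.5,
                      n_f = 20, n_m = 20, presentations = NA,
                      stimulus_group = "air-conducted") {
  data.frame(study_label = label, n_f = n_f, n_m = n_m,
             mean_f = mean_f, mean_m = mean_m, sd_f = sd_f, sd_m = sd_m,
             presentations = presentations, stimulus_group = stimulus_group,
             stringsAsFactors = FALSE)
}

# Build a study table whose effects and variances are exactly (md, v):
# equal-n groups with sd chosen so sd^2 * 2 / n = v.
studies_from_effects <- function(md, v, n = 20, presentations = NA) {
  do.call(rbind, lapply(seq_along(md), function(i) {
    sdv <- sqrt(v[i] * n / 2)
    study_row(sprintf("S%02d", i), mean_f = 10, mean_m = 10 + md[i],
              sd_f = sdv, sd_m = sdv, n_f = n, n_m = n,
              presentations = if (length(presentations) > 1)
                presentations[i] else presentations)
  }))
}

test_that("study effect and variance follow the summary formulas", {
  same <- study_row("s", 11, 11)
  expect_equal(study_effect(same)$md, 0)
  tab2 <- study_row("full", 9.99, 12.41, 2.74, 2.54, 24, 24)
  e <- study_effect(tab2)
  expect_equal(e$md, 2.42)
  expect_equal(e$variance, 2.74^2 / 24 + 2.54^2 / 24)
  expect_equal(e$variance, 0.582, tolerance = 1e-3)
  dbl <- study_row("dbl", 9.99, 12.41, 2.74, 2.54, 48, 48)
  expect_equal(study_effect(dbl)$variance, e$variance / 2)
  expect_error(study_effect(study_row("bad", 1, 2, sd_f = 0)),
               class = "vemp_argument_error")
})

test_that("DerSimonian-Laird pooling matches hand-worked examples", {
  # md 2.0 and 1.0, both variance 0.5: Q = 1, tau2 = 0, pooled = 1.5
  s <- studies_from_effects(c(2, 1), c(0.5, 0.5))
  m <- pool_random_effects(s)
  expect_equal(m$Q, 1)
  expect_equal(m$tau2, 0)
  expect_equal(m$pooled_md, 1.5)
  expect_equal(m$se, sqrt(1 / 4))

  # md 2.0 and 0.0, both variance 0.5: Q = 4, c = 2, tau2 = 1.5
  s2 <- studies_from_effects(c(2, 0), c(0.5, 0.5))
  m2 <- pool_random_effects(s2)
  expect_equal(m2$Q, 4)
  expect_equal(m2$tau2, 1.5)
  expect_equal(m2$pooled_md, 1)

  # two identical studies
  s3 <- studies_from_effects(c(1.2, 1.2), c(0.4, 0.4))
  m3 <- pool_random_effects(s3)
  expect_equal(m3$Q, 0)
  expect_equal(m3$tau2, 0)
  expect_equal(m3$pooled_md, 1.2)

  # single study: pooled = that study
  s4 <- studies_from_effects(0.8, 0.3)
  m4 <- pool_random_effects(s4)
  expect_equal(m4$pooled_md, 0.8)
  expect_equal(m4$tau2, 0)
})

test_that("pooling is permutation invariant, bounded by study effects, and weights sum to 1", {
  set.seed(51)
  s <- studies_from_effects(rnorm(7, 1.5, 1), runif(7, 0.2, 1.5))
  m <- pool_random_effects(s)
  mp <- pool_random_effects(s[sample(7), ])
  expect_equal(m$pooled_md, mp$pooled_md)
  expect_equal(m$tau2, mp$tau2)
  expect_equal(sum(m$effects$weight), 1)
  expect_gte(m$pooled_md, min(m$effects$md))
  expect_lte(m$pooled_md, max(m$effects$md))
})

test_that("Q is invariant when a constant shifts both group means of every study", {
  s <- studies_from_effects(c(2, 1, 0.5), c(0.5, 0.4, 0.8))
  shifted <- s
  shifted$mean_f <- shifted$mean_f + 7
  shifted$mean_m <- shifted$mean_m + 7
  expect_equal(pool_random_effects(s)$Q, pool_random_effects(shifted)$Q)
  expect_equal(pool_random_effects(s)$pooled_md,
               pool_random_effects(shifted)$pooled_md)
})

test_that("pooling agrees with metafor as an independent cross-check", {
  set.seed(52)
  s <- studies_from_effects(rnorm(9, 2, 1.2), runif(9, 0.2, 2))
  m <- pool_random_effects(s)
  eff <- m$effects
  rma <- metafor::rma(yi = eff$md, vi = eff$vi, method = "DL")
  expect_equal(m$pooled_md, as.numeric(rma$beta), tolerance = 1e-8)
  expect_equal(m$tau2, as.numeric(rma$tau2), tolerance = 1e-8)
  expect_equal(m$Q, as.numeric(rma$QE), tolerance = 1e-8)
  expect_equal(m$se, as.numeric(rma$se), tolerance = 1e-8)
  expect_equal(m$I2, as.numeric(rma$I2) / 100, tolerance = 1e-8)
})

test_that("meta-regression recovers planted moderator slopes", {
  # exact linear relation, equal variances: slope recovered exactly
  pres <- c(100, 200, 300, 500, 1000)
  md <- 3 - 0.002 * pres
  s <- studies_from_effects(md, rep(0.3, 5), presentations = pres)
  mr <- meta_regression(s, "presentations")
  expect_equal(mr$moderator_slope, -0.002, tolerance = 1e-8)
  expect_equal(mr$tau2, 0, tolerance = 1e-8)

  # noisy planted slope: recovered within 3 SE
  set.seed(53)
  pres2 <- round(runif(12, 100, 3000))
  md2 <- 2.5 - 0.0008 * pres2 + rnorm(12, 0, 0.2)
  s2 <- studies_from_effects(md2, runif(12, 0.1, 0.4), presentations = pres2)
  mr2 <- meta_regression(s2, "presentations")
  expect_lt(abs(mr2$moderator_slope - (-0.0008)), 3 * mr2$moderator_se)

  # degenerate designs
  s3 <- studies_from_effects(c(1, 2, 3), rep(0.3, 3), presentations = 200)
  expect_error(meta_regression(s3, "presentations"),
               class = "vemp_argument_error")
  expect_error(meta_regression(s[1:2, ], "presentations"),
               class = "vemp_argument_error")
  expect_error(meta_regression(s, "nope"), class = "vemp_schema_error")
  # studies with missing moderator are excluded
  s4 <- rbind(s2, studies_from_effects(1, 0.3))
  expect_equal(meta_regression(s4, "presentations")$k, 12)
})

test_that("shipped synthetic study table loads and pools", {
  path <- system.file("extdata", "synthetic_studies.csv", package = "cvemp")
  expect_true(nzchar(path))
  studies <- read_studies(path)
  expect_gte(nrow(studies), 8)
  m <- pool_random_effects(studies, subgroup = TRUE)
  expect_true(is.finite(m$pooled_md))
  expect_gte(m$tau2, 0)
  expect_true(all(c("air-conducted", "body-conducted") %in%
                    names(m$subgroups)))
  mr <- meta_regression(studies, "presentations")
  expect_true(is.finite(mr$moderator_p))
})
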