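# Group statistics: random-intercept mixed models with likelihood-ratio
# tests, the Welch-on-participant-means alternative, effect sizes, and
# conditional R^2.

#' Fit a random-intercept mixed model to pick data
#'
#' Maximum-likelihood (not REML) fit of
#' \code{response ~ [stimulus_level] + [sex] + (1 | participant)}, the
#' model family used for the latency and amplitude-growth analyses. ML is
#' required so that nested fixed-effect structures can be compared by
#' likelihood ratio.
#'
#' @param data a [latency_dataset()] (columns \code{participant_id},
#'   \code{sex}, \code{stimulus_level} and the response).
#' @param response one of \code{"p1n1_latency"}, \code{"p1_latency"},
#'   \code{"n1_latency"}, \code{"response_level"}.
#' @param include_sex,include_stimulus include the fixed effect.
#' @return object of class \code{vemp_lmm}: the \pkg{lme4} fit plus
#'   \code{fixed_effects} (estimates and standard errors),
#'   \code{random_intercept_variance}, \code{residual_variance},
#'   \code{log_likelihood}, \code{n_obs}, \code{n_groups}, \code{n_par} and
#'   a \code{singular} flag. Sex is coded 0 = female, 1 = male, so a
#'   positive sex coefficient means a larger response in men.
#' @export
fit_lmm <- function(data, response = "p1n1_latency",
                    include_sex = TRUE, include_stimulus = FALSE) {
  response <- match.arg(response, c("p1n1_latency", "p1_latency",
                                    "n1_latency", "response_level"))
  need <- c("participant_id", "sex", response,
            if (include_stimulus) "stimulus_level")
  miss <- setdiff(need, names(data))
  if (length(miss)) abort_schema(paste("missing columns:", paste(miss, collapse = ", ")))
  if (any(is.na(data[[response]]))) abort_argument("response contains missing values")
  d <- data.frame(
    y = data[[response]],
    sex_male = as.numeric(factor(data$sex, levels = c("female", "male"))) - 1,
    stimulus_level = if (include_stimulus) data$stimulus_level else 0,
    participant_id = data$participant_id
  )
  if (include_sex) {
    per_sex <- table(unique(data.frame(pid = d$participant_id,
                                       sex = d$sex_male))$sex)
    if (length(per_sex) < 2 || min(per_sex) < 2)
      abort_argument("need at least 2 participants per sex")
  }
  terms <- c(if (include_stimulus) "stimulus_level",
             if (include_sex) "sex_male")
  rhs <- paste(c("1", terms, "(1 | participant_id)"), collapse = " + ")
  fml <- stats::as.formula(paste("y ~", rhs))
  fit <- lme4::lmer(fml, data = d, REML = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  fe <- lme4::fixef(fit)
  # degenerate (zero-variance) fits can leave vcov undefined; keep the
  # estimates and flag the fit rather than failing
  se <- tryCatch(sqrt(diag(as.matrix(stats::vcov(fit)))),
                 error = function(e) rep(NA_real_, length(fe)))
  ll <- stats::logLik(fit)
  structure(list(
    formula = paste("y ~", rhs),
    response = response,
    fit = fit,
    fixed_effects = data.frame(term = names(fe), estimate = as.numeric(fe),
                               se = as.numeric(se), stringsAsFactors = FALSE),
    random_intercept_variance = vc$vcov[vc$grp == "participant_id"],
    residual_variance = vc$vcov[vc$grp == "Residual"],
    log_likelihood = as.numeric(ll),
    n_par = attr(ll, "df"),
    n_obs = stats::nobs(fit),
    n_groups = lme4::ngrps(fit)[["participant_id"]],
    singular = lme4::isSingular(fit)
  ), class = "vemp_lmm")
}

#' @export
print.vemp_lmm <- function(x, ...) {
  cat(sprintf("Random-intercept model (ML): %s\n", x$formula))
  print(x$fixed_effects, row.names = FALSE)
  cat(sprintf("  intercept var %.4g, residual var %.4g, logLik %.3f, n = %d obs / %d participants%s\n",
              x$random_intercept_variance, x$residual_variance,
              x$log_likelihood, x$n_obs, x$n_groups,
              if (x$singular) " [singular fit]" else ""))
  invisible(x)
}

#' Upper tail of the chi-squared distribution
#'
#' Survival function used as the likelihood-ratio reference distribution.
#'
#' @param x statistic, >= 0.
#' @param df degrees of freedom, >= 1.
#' @return upper-tail probability.
#' @export
chi2_upper_tail <- function(x, df) {
  if (any(x < 0)) abort_argument("statistic must be >= 0")
  if (any(df < 1)) abort_argument("df must be >= 1")
  stats::pchisq(x, df, lower.tail = FALSE)
}

#' Likelihood-ratio test between nested ML fits
#'
#' \code{chi2 = 2 * (logLik_alt - logLik_null)} referred to a chi-squared
#' distribution with the parameter-count difference as degrees of freedom.
#' Both fits must be maximum-likelihood fits to the same rows.
#'
#' @param null_fit,alt_fit \code{vemp_lmm} objects, null nested in
#'   alternative.
#' @return list with \code{chi2}, \code{df}, \code{p}.
#' @export
likelihood_ratio_test <- function(null_fit, alt_fit) {
  if (null_fit$n_obs != alt_fit$n_obs)
    abort_argument("models were fitted to different numbers of observations")
  df <- alt_fit$n_par - null_fit$n_par
  if (df < 0) abort_argument("alternative model must have at least as many parameters as the null")
  chi2 <- max(0, 2 * (alt_fit$log_likelihood - null_fit$log_likelihood))
  # identical models compare trivially: no evidence against the null
  p <- if (df == 0) 1 else chi2_upper_tail(chi2, df)
  list(chi2 = chi2, df = df, p = p)
}

#' Sex comparison of a response by likelihood ratio
#'
#' Convenience wrapper fitting the nested pair (without / with the sex
#' term) and reporting the likelihood-ratio comparison together with the
#' sex coefficient.
#'
#' @inheritParams fit_lmm
#' @return list: \code{null_fit}, \code{alt_fit}, \code{chi2}, \code{df},
#'   \code{p}, \code{sex_effect} (male minus female) and its \code{se}.
#' @export
lrt_sex_effect <- function(data, response = "p1n1_latency",
                           include_stimulus = FALSE) {
  null_fit <- fit_lmm(data, response, include_sex = FALSE,
                      include_stimulus = include_stimulus)
  alt_fit <- fit_lmm(data, response, include_sex = TRUE,
                     include_stimulus = include_stimulus)
  lrt <- likelihood_ratio_test(null_fit, alt_fit)
  i <- match("sex_male", alt_fit$fixed_effects$term)
  c(list(null_fit = null_fit, alt_fit = alt_fit), lrt,
    list(sex_effect = alt_fit$fixed_effects$estimate[i],
         se = alt_fit$fixed_effects$se[i]))
}

#' Per-participant means of a response
#'
#' Simple mean over each participant's non-null picks. Participants with no
#' usable picks are dropped with a warning.
#'
#' @param data a [latency_dataset()].
#' @param response column to average.
#' @return data frame (\code{participant_id}, \code{sex}, \code{mean}).
#' @export
participant_means <- function(data, response = "p1n1_latency") {
  ok <- !is.na(data[[response]])
  if (!all(ok)) data <- data[ok, , drop = FALSE]
  ids <- unique(data$participant_id)
  if (!length(ids)) abort_argument("no usable picks")
  agg <- stats::aggregate(data[[response]],
                          by = list(participant_id = data$participant_id),
                          FUN = mean)
  names(agg)[2] <- "mean"
  sex <- data$sex[match(agg$participant_id, data$participant_id)]
  out <- data.frame(participant_id = agg$participant_id, sex = sex,
                    mean = agg$mean, stringsAsFactors = FALSE)
  out[order(out$participant_id), , drop = FALSE]
}

#' Welch's unequal-variances t-test
#'
#' Standard Welch statistic with Satterthwaite degrees of freedom (kept
#' fractional), two-tailed p, and 95\% confidence interval on the
#' difference, oriented male minus female. Accepts either raw
#' per-participant means or printed group summaries.
#'
#' @param x,y raw samples for the female and male group; or supply the six
#'   summary arguments instead.
#' @param mean_f,sd_f,n_f,mean_m,sd_m,n_m group summaries.
#' @param conf_level confidence level of the interval.
#' @return object of class \code{vemp_welch}: group summaries,
#'   \code{difference} (male - female), \code{t_statistic}, \code{df},
#'   \code{p_value}, \code{ci_low}, \code{ci_high}.
#' @examples
#' welch_test(mean_f = 9.99, sd_f = 2.74, n_f = 24,
#'            mean_m = 12.41, sd_m = 2.54, n_m = 24)
#' @export
welch_test <- function(x = NULL, y = NULL,
                       mean_f = NULL, sd_f = NULL, n_f = NULL,
                       mean_m = NULL, sd_m = NULL, n_m = NULL,
                       conf_level = 0.95) {
  if (!is.null(x) || !is.null(y)) {
    if (length(x) < 2 || length(y) < 2)
      abort_argument("each group needs at least 2 observations")
    mean_f <- mean(x); sd_f <- stats::sd(x); n_f <- length(x)
    mean_m <- mean(y); sd_m <- stats::sd(y); n_m <- length(y)
  }
  if (is.null(mean_f) || is.null(mean_m))
    abort_argument("supply raw samples or complete group summaries")
  if (n_f < 2 || n_m < 2) abort_argument("each group needs n >= 2")
  if (sd_f <= 0 || sd_m <= 0) abort_argument("group SDs must be > 0")
  v_f <- sd_f^2 / n_f
  v_m <- sd_m^2 / n_m
  se <- sqrt(v_f + v_m)
  diff <- mean_m - mean_f
  t_stat <- diff / se
  df <- (v_f + v_m)^2 / (v_f^2 / (n_f - 1) + v_m^2 / (n_m - 1))
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df)
  structure(list(
    mean_f = mean_f, sd_f = sd_f, n_f = n_f,
    mean_m = mean_m, sd_m = sd_m, n_m = n_m,
    difference = diff, se = se, t_statistic = t_stat, df = df,
    p_value = 2 * stats::pt(-abs(t_stat), df),
    ci_low = diff - tcrit * se, ci_high = diff + tcrit * se
  ), class = "vemp_welch")
}

#' @export
print.vemp_welch <- function(x, ...) {
  cat(sprintf("Welch two-sample comparison (male - female)\n"))
  cat(sprintf("  difference %.3f, t = %.3f, df = %.2f, p = %.4g\n",
              x$difference, x$t_statistic, x$df, x$p_value))
  cat(sprintf("  95%% CI [%.3f, %.3f]; F %.3f +/- %.3f (n=%d), M %.3f +/- %.3f (n=%d)\n",
              x$ci_low, x$ci_high, x$mean_f, x$sd_f, x$n_f,
              x$mean_m, x$sd_m, x$n_m))
  invisible(x)
}

#' Cohen's d from a mixed-model t statistic
#'
#' \code{d = 2 t / sqrt(df)}, the conversion conventionally applied to
#' mixed-model t statistics.
#'
#' @param t t statistic.
#' @param df degrees of freedom, > 0.
#' @return effect size d.
#' @export
cohens_d <- function(t, df) {
  if (any(df <= 0)) abort_argument("df must be > 0")
  2 * t / sqrt(df)
}

#' Pooled-SD Cohen's d from group summaries
#'
#' \code{d = (mean_m - mean_f) / sqrt((sd_f^2 + sd_m^2) / 2)} (equal-n
#' pooling convention).
#'
#' @param mean_f,mean_m,sd_f,sd_m group summaries.
#' @return effect size d (signed, male minus female).
#' @export
cohens_d_pooled <- function(mean_f, mean_m, sd_f, sd_m) {
  (mean_m - mean_f) / sqrt((sd_f^2 + sd_m^2) / 2)
}

#' Conditional R-squared of a random-intercept fit
#'
#' Variance explained by fixed and random effects together:
#' \code{(var_fixed + var_intercept) / (var_fixed + var_intercept +
#' var_residual)}, with \code{var_fixed} the variance of the fixed-effect
#' predictions over the data.
#'
#' @param fit a \code{vemp_lmm}.
#' @return proportion in \[0, 1\].
#' @export
conditional_r2 <- function(fit) {
  X <- stats::model.matrix(fit$fit)
  var_f <- stats::var(as.numeric(X %*% lme4::fixef(fit$fit)))
  tot <- var_f + fit$random_intercept_variance + fit$residual_variance
  if (tot <= 0) vemp_error("vemp_undefined_response_error",
                           "total variance is zero; conditional R^2 undefined")
  (var_f + fit$random_intercept_variance) / tot
}
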