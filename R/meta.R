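# Random-effects meta-analysis of study-level sex differences in p1-n1
# latency, with presentation count as an optional moderator.

#' Study-level mean difference and its variance
#'
#' Mean difference male minus female (positive = longer latency in men) and
#' the variance of that difference from the group SDs and counts:
#' \code{sd_f^2/n_f + sd_m^2/n_m}.
#'
#' @param study one-row data frame (or list) with \code{mean_f},
#'   \code{mean_m}, \code{sd_f}, \code{sd_m}, \code{n_f}, \code{n_m}.
#' @return list with \code{md} and \code{variance}.
#' @export
study_effect <- function(study) {
  if (study$n_f < 2 || study$n_m < 2) abort_argument("group counts must be >= 2")
  if (study$sd_f <= 0 || study$sd_m <= 0) abort_argument("group SDs must be > 0")
  list(md = study$mean_m - study$mean_f,
       variance = study$sd_f^2 / study$n_f + study$sd_m^2 / study$n_m)
}

studies_effects <- function(studies) {
  md <- numeric(nrow(studies)); vi <- numeric(nrow(studies))
  for (i in seq_len(nrow(studies))) {
    e <- study_effect(studies[i, ])
    md[i] <- e$md; vi[i] <- e$variance
  }
  data.frame(study_label = studies$study_label, md = md, vi = vi,
             stringsAsFactors = FALSE)
}

# DerSimonian-Laird pooling of effects yi with variances vi.
dl_pool <- function(yi, vi, conf_level = 0.95) {
  k <- length(yi)
  w <- 1 / vi
  fe <- sum(w * yi) / sum(w)
  Q <- sum(w * (yi - fe)^2)
  df <- k - 1
  tau2 <- if (df > 0) {
    c_dl <- sum(w) - sum(w^2) / sum(w)
    max(0, (Q - df) / c_dl)
  } else 0
  ws <- 1 / (vi + tau2)
  pooled <- sum(ws * yi) / sum(ws)
  se <- sqrt(1 / sum(ws))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(pooled_md = pooled, se = se,
       ci_low = pooled - z * se, ci_high = pooled + z * se,
       tau2 = tau2, Q = Q, df = df,
       I2 = if (Q > 0 && df > 0) max(0, (Q - df) / Q) else 0,
       weights = ws / sum(ws))
}

#' Random-effects pooling of study mean differences
#'
#' DerSimonian--Laird between-study variance with inverse-variance weights
#' \code{1 / (vi + tau2)} and a Wald (normal) confidence interval. With
#' \code{tau2} forced to zero this reduces to fixed-effect
#' inverse-variance pooling. Optionally pools each \code{stimulus_group}
#' subgroup as well.
#'
#' @param studies data frame of study summaries, one row per comparison:
#'   \code{study_label}, \code{n_f}, \code{n_m}, \code{mean_f},
#'   \code{mean_m}, \code{sd_f}, \code{sd_m}, optionally
#'   \code{stimulus_group}.
#' @param subgroup pool each level of \code{stimulus_group} separately as
#'   well.
#' @param conf_level confidence level.
#' @return object of class \code{vemp_meta}: \code{pooled_md}, \code{se},
#'   \code{ci_low}, \code{ci_high}, \code{tau2}, \code{Q}, \code{df},
#'   \code{I2}, per-study \code{effects} (with normalised weights), and
#'   \code{subgroups} when requested.
#' @export
pool_random_effects <- function(studies, subgroup = FALSE,
                                conf_level = 0.95) {
  if (nrow(studies) < 1) abort_argument("need at least one study")
  eff <- studies_effects(studies)
  pooled <- dl_pool(eff$md, eff$vi, conf_level)
  eff$weight <- pooled$weights
  out <- c(pooled[c("pooled_md", "se", "ci_low", "ci_high",
                    "tau2", "Q", "df", "I2")],
           list(effects = eff, k = nrow(eff)))
  if (subgroup && "stimulus_group" %in% names(studies)) {
    out$subgroups <- lapply(split(seq_len(nrow(studies)),
                                  studies$stimulus_group), function(ix) {
      dl_pool(eff$md[ix], eff$vi[ix], conf_level)[
        c("pooled_md", "se", "ci_low", "ci_high", "tau2", "Q", "df", "I2")]
    })
  }
  class(out) <- "vemp_meta"
  out
}

#' @export
print.vemp_meta <- function(x, ...) {
  cat(sprintf("Random-effects meta-analysis (DerSimonian-Laird), k = %d\n", x$k))
  cat(sprintf("  pooled MD (male - female) %.3f ms [%.3f, %.3f], tau2 %.3f, Q %.2f (df %d), I2 %.0f%%\n",
              x$pooled_md, x$ci_low, x$ci_high, x$tau2, x$Q, x$df, 100 * x$I2))
  if (!is.null(x$moderator)) {
    cat(sprintf("  moderator %s: slope %.4g (se %.4g), p = %.4g, residual tau2 %.3f\n",
                x$moderator, x$moderator_slope, x$moderator_se,
                x$moderator_p, x$tau2))
  }
  invisible(x)
}

#' Meta-regression with a continuous study-level moderator
#'
#' Weighted mixed-effects regression of the study mean differences on a
#' moderator (e.g. stimulus presentation count), with the residual
#' between-study variance re-estimated by the method of moments
#' (DerSimonian--Laird type) and a z-based test of the slope. Studies with
#' a missing moderator are excluded. Backed by \pkg{metafor}.
#'
#' @param studies as in [pool_random_effects()]; must contain the moderator
#'   column.
#' @param moderator column name.
#' @return \code{vemp_meta} object with \code{moderator_slope},
#'   \code{moderator_se}, \code{moderator_p}, residual \code{tau2}, and the
#'   underlying \code{rma} fit.
#' @export
meta_regression <- function(studies, moderator = "presentations") {
  if (!moderator %in% names(studies))
    abort_schema(sprintf("moderator column '%s' not found", moderator))
  keep <- !is.na(studies[[moderator]])
  studies <- studies[keep, , drop = FALSE]
  if (nrow(studies) < 3)
    abort_argument("meta-regression needs at least 3 studies with the moderator")
  x <- studies[[moderator]]
  if (length(unique(x)) < 2)
    abort_argument("moderator is constant across studies; slope undefined")
  eff <- studies_effects(studies)
  fit <- metafor::rma(yi = eff$md, vi = eff$vi, mods = ~x, method = "DL",
                      test = "z")
  structure(list(
    pooled_md = NA_real_, se = NA_real_, ci_low = NA_real_,
    ci_high = NA_real_,
    tau2 = as.numeric(fit$tau2), Q = as.numeric(fit$QE),
    df = fit$k - 2L, I2 = NA_real_,
    effects = eff, k = nrow(eff),
    moderator = moderator,
    moderator_slope = as.numeric(fit$beta[2]),
    moderator_se = as.numeric(fit$se[2]),
    moderator_p = as.numeric(fit$pval[2]),
    intercept = as.numeric(fit$beta[1]),
    fit = fit
  ), class = "vemp_meta")
}

#' Read study summaries from CSV
#'
#' @param path CSV with columns \code{study_label}, \code{n_f}, \code{n_m},
#'   \code{mean_f}, \code{mean_m}, \code{sd_f}, \code{sd_m} and optionally
#'   \code{presentations}, \code{stimulus_group}.
#' @return data frame of study summaries.
#' @export
read_studies <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("study_label", "n_f", "n_m", "mean_f", "mean_m", "sd_f", "sd_m")
  miss <- setdiff(need, names(d))
  if (length(miss)) abort_schema(paste("missing columns:", paste(miss, collapse = ", ")))
  d
}
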