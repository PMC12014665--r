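# Power analysis: analytic two-sample noncentral-t power, subsampling of
# presentations/participants, an empirical power grid over simulated
# cohorts, and the ear-canal dial-SPL correction.

#' Analytic power of the two-sample t-test
#'
#' Noncentral-t power with the pooled-SD convention: degrees of freedom
#' \code{2n - 2} and noncentrality \code{d * sqrt(n / 2)} for \code{n} per
#' group, the two-tailed test rejecting when |T| exceeds its critical
#' value.
#'
#' @param d standardized effect size (Cohen's d), >= 0.
#' @param n_per_group participants per group, >= 2.
#' @param alpha significance level.
#' @param two_tailed logical.
#' @return power, in \[alpha-ish, 1\]; equals \code{alpha} at d = 0.
#' @examples
#' power_two_sample_t(0.916, 24) # ~0.87
#' @export
power_two_sample_t <- function(d, n_per_group, alpha = 0.05,
                               two_tailed = TRUE) {
  if (alpha <= 0 || alpha >= 1) abort_argument("alpha must lie in (0, 1)")
  if (any(d < 0)) abort_argument("d must be >= 0")
  if (any(n_per_group < 2)) abort_argument("n_per_group must be >= 2")
  df <- 2 * n_per_group - 2
  ncp <- d * sqrt(n_per_group / 2)
  if (two_tailed) {
    tcrit <- stats::qt(1 - alpha / 2, df)
    stats::pt(-tcrit, df, ncp) + stats::pt(tcrit, df, ncp, lower.tail = FALSE)
  } else {
    tcrit <- stats::qt(1 - alpha, df)
    stats::pt(tcrit, df, ncp, lower.tail = FALSE)
  }
}

#' Retain only the first presentations of a record
#'
#' Models a shorter session by keeping the first
#' \code{floor(n_presentations / epochs_per_sequence)} sequences in
#' acquisition order (the initial maximum-level sequence is always first,
#' so anchoring still works). Requests beyond the recorded count keep
#' everything, with a warning.
#'
#' @param record a \code{vemp_record}.
#' @param n_presentations total stimulus presentations to retain (truncated
#'   to a multiple of \code{epochs_per_sequence}).
#' @param epochs_per_sequence presentations per sequence.
#' @return the trimmed record.
#' @export
subsample_presentations <- function(record, n_presentations,
                                    epochs_per_sequence = 300) {
  k <- floor(n_presentations / epochs_per_sequence)
  if (k < 1) abort_argument("n_presentations must cover at least one sequence")
  ord <- order(vapply(record$sequences, function(s) s$sequence_order, 1L))
  if (k >= length(ord)) {
    if (k > length(ord))
      warning(sprintf("requested %d sequences but only %d recorded; using all",
                      k, length(ord)))
    return(record)
  }
  record$sequences <- record$sequences[ord[seq_len(k)]]
  record
}

# Welch on per-participant mean p1-n1 latency for one simulated cohort.
cohort_welch <- function(records, n_presentations = NULL, n_total = NULL,
                         epochs_per_sequence = 300) {
  if (!is.null(n_total)) {
    sexes <- vapply(records, function(r) as.character(r$sex), "")
    keep <- c(which(sexes == "female")[seq_len(n_total / 2)],
              which(sexes == "male")[seq_len(n_total / 2)])
    records <- records[keep]
  }
  records <- lapply(records, normalize_record)
  if (!is.null(n_presentations)) {
    records <- lapply(records, subsample_presentations, n_presentations,
                      epochs_per_sequence)
  }
  pm <- participant_means(latency_dataset(pick_cohort(records)))
  welch_test(x = pm$mean[pm$sex == "female"], y = pm$mean[pm$sex == "male"])
}

#' Empirical power grid over simulated cohorts
#'
#' For each combination of presentations-per-participant and total
#' participant count (balanced across sexes, first-k by default), simulates
#' cohorts with the generator, runs the full normalisation -> peak-scoring
#' -> participant-means -> Welch pipeline, and reports the mean group
#' difference, mean confidence bounds, median p-value and the fraction of
#' significant cohorts as empirical power.
#'
#' @param config a [vemp_config()].
#' @param presentations vector of presentation counts per participant.
#' @param n_totals vector of total participant counts (even, balanced).
#' @param n_cohorts simulated cohorts per cell.
#' @param alpha significance level for the power count.
#' @param seed integer seed.
#' @return data frame with one row per grid cell:
#'   \code{presentations}, \code{n_total}, group means/SDs,
#'   \code{difference}, \code{ci_low}, \code{ci_high}, \code{p_value}
#'   (median), \code{power}.
#' @export
power_grid <- function(config, presentations, n_totals, n_cohorts = 1000,
                       alpha = 0.05, seed = config$seed) {
  validate_config(config)
  if (any(n_totals %% 2 != 0)) abort_argument("n_totals must be even (balanced)")
  if (any(n_totals > config$n_women + config$n_men))
    abort_argument("n_totals exceed the generated cohort size")
  with_seed(seed)
  grid <- expand.grid(presentations = presentations, n_total = n_totals)
  cells <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    res <- matrix(NA_real_, n_cohorts, 9)
    for (i in seq_len(n_cohorts)) {
      sim <- synth_cohort(config, seed = NULL)
      w <- cohort_welch(sim$records, grid$presentations[g], grid$n_total[g],
                        config$epochs_per_sequence)
      res[i, ] <- c(w$mean_f, w$sd_f, w$mean_m, w$sd_m, w$difference,
                    w$ci_low, w$ci_high, w$p_value, w$p_value < alpha)
    }
    cells[[g]] <- data.frame(
      presentations = grid$presentations[g], n_total = grid$n_total[g],
      mean_f = mean(res[, 1]), sd_f = mean(res[, 2]),
      mean_m = mean(res[, 3]), sd_m = mean(res[, 4]),
      difference = mean(res[, 5]),
      ci_low = mean(res[, 6]), ci_high = mean(res[, 7]),
      p_value = stats::median(res[, 8]),
      power = mean(res[, 9])
    )
  }
  out <- do.call(rbind, cells)
  rownames(out) <- NULL
  out
}

#' Ear-canal dial-SPL correction
#'
#' dB adjustment to the dial SPL for an ear canal differing from the 2 cc
#' calibration coupler: \code{20 * log10(2 / volume_cc)}, from pressure
#' being inversely proportional to volume.
#'
#' @param volume_cc ear-canal volume, cc (> 0).
#' @return correction, dB (positive for canals smaller than 2 cc).
#' @examples
#' ear_canal_correction(0.7) # 9.1 dB
#' @export
ear_canal_correction <- function(volume_cc) {
  if (any(volume_cc <= 0)) abort_argument("volume must be > 0")
  20 * log10(2 / volume_cc)
}
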