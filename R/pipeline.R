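# End-to-end drivers: simulate -> normalise -> pick -> latency dataset,
# per-participant amplitude-growth slopes, and the Monte-Carlo loops behind
# the parameter-recovery and power analyses.

#' Simulate one cohort and run the full pipeline to picks
#'
#' Generates a cohort, computes each participant's background EMG tension,
#' normalises, and scores every sequence.
#'
#' @param config a [vemp_config()].
#' @param seed integer seed; \code{NULL} continues the stream.
#' @param epoch_level simulate raw epochs (with rejection and averaging)
#'   instead of direct sequence averages.
#' @return list: \code{cohort} (truth table), \code{records} (normalised),
#'   \code{picks} (all picks), \code{data} (the non-null
#'   [latency_dataset()]).
#' @export
simulate_pipeline <- function(config, seed = config$seed,
                              epoch_level = FALSE) {
  sim <- synth_cohort(config, epoch_level = epoch_level, seed = seed)
  sim$records <- lapply(sim$records, normalize_record)
  sim$picks <- pick_cohort(sim$records)
  sim$data <- latency_dataset(sim$picks)
  sim
}

#' Per-participant amplitude-growth slopes
#'
#' Ordinary least-squares slope of response level (dB RL) on stimulus level
#' (dB HL) for each participant, the per-participant growth measure whose
#' distribution motivates a fixed-slope mixed model.
#'
#' @param data a [latency_dataset()] with \code{response_level}.
#' @return data frame (\code{participant_id}, \code{sex}, \code{slope},
#'   \code{n_levels}); participants with fewer than two distinct levels get
#'   \code{NA}.
#' @export
participant_slopes <- function(data) {
  ids <- unique(data$participant_id)
  slope <- vapply(ids, function(id) {
    d <- data[data$participant_id == id, ]
    if (length(unique(d$stimulus_level)) < 2) return(NA_real_)
    x <- d$stimulus_level; y <- d$response_level
    sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  }, 0)
  n_levels <- vapply(ids, function(id) {
    length(unique(data$stimulus_level[data$participant_id == id]))
  }, 0L)
  data.frame(participant_id = ids,
             sex = data$sex[match(ids, data$participant_id)],
             slope = slope, n_levels = n_levels,
             stringsAsFactors = FALSE)
}

#' Monte-Carlo cohort recovery
#'
#' Simulates \code{n_cohorts} independent cohorts, runs the full pipeline
#' on each, and summarises per cohort: the men-minus-women difference in
#' per-participant mean p1--n1 latency with its Welch test, and the mean
#' per-participant amplitude-growth slope.
#'
#' @param config a [vemp_config()].
#' @param n_cohorts number of cohorts.
#' @param seed integer seed for the whole run.
#' @param epoch_level simulate raw epochs (slow; intended for small runs).
#' @return data frame with one row per cohort: \code{gap} (ms, male -
#'   female), \code{welch_t}, \code{welch_p}, \code{significant} (p <
#'   0.05), \code{mean_slope}, \code{n_slopes}, \code{n_null_picks}.
#' @export
mc_cohorts <- function(config, n_cohorts, seed = config$seed,
                       epoch_level = FALSE) {
  validate_config(config)
  with_seed(seed)
  rows <- vector("list", n_cohorts)
  for (i in seq_len(n_cohorts)) {
    sim <- simulate_pipeline(config, seed = NULL, epoch_level = epoch_level)
    pm <- participant_means(sim$data)
    w <- welch_test(x = pm$mean[pm$sex == "female"],
                    y = pm$mean[pm$sex == "male"])
    sl <- participant_slopes(sim$data)
    rows[[i]] <- data.frame(
      cohort = i, gap = w$difference, welch_t = w$t_statistic,
      welch_p = w$p_value, significant = w$p_value < 0.05,
      mean_slope = mean(sl$slope, na.rm = TRUE),
      n_slopes = sum(!is.na(sl$slope)),
      n_null_picks = sum(sim$picks$is_null)
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
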