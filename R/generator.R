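# Synthetic cohort and raw-epoch generator emulating the recording design:
# stimulus-locked EMG epochs at 3 kHz with an 18+ ms pre-stimulus span,
# ~50 uV RMS background tension, a biphasic p1/n1 response whose p1-n1
# latency differs by sex, amplitude growth linear in dB RL vs dB HL, two
# descending stimulus series plus a closing 40 dB HL repeat, and occasional
# artifact epochs.

# Draw from N(mean, sd) truncated to [lo, hi] by rejection (deterministic
# under a fixed RNG stream).
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  out <- rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(out < lo | out > hi)
  }
  out
}

# Zero-phase band-limited Gaussian noise, one column per waveform.
# White Gaussian noise is shaped in the frequency domain by a surface-EMG
# spectrum model: a first-order Butterworth high-pass at `highpass_hz`
# (the recording chain's 10 Hz analog high-pass) times a second-order
# Butterworth low-pass at `lowpass_hz` emulating the concentration of
# surface-EMG power below ~500 Hz (the instrument's 1500 Hz anti-alias
# filter passes essentially all of it at 3 kHz sampling). The result is
# rescaled so the expected RMS equals `target_rms`.
band_noise <- function(n_samples, n_cols, sample_rate, target_rms,
                       highpass_hz = 10, lowpass_hz = 500) {
  if (target_rms == 0) return(matrix(0, n_samples, n_cols))
  z <- matrix(rnorm(n_samples * n_cols), n_samples, n_cols)
  k <- seq_len(n_samples) - 1L
  f <- pmin(k, n_samples - k) * sample_rate / n_samples
  r <- f / highpass_hz
  H <- (r / sqrt(1 + r^2)) / sqrt(1 + (f / lowpass_hz)^4)
  shaped <- Re(stats::mvfft(stats::mvfft(z) * H, inverse = TRUE)) / n_samples
  shaped * (target_rms / sqrt(mean(H^2)))
}

# True p1-n1 amplitude (uV) at a stimulus level: response level grows
# linearly at `slope` dB RL per dB HL and crosses 0 dB RL at `threshold`,
# where 0 dB RL corresponds to an amplitude of 10 x background_rms under
# the RL transform 20*log10(amp/background) - 20.
true_amplitude <- function(level, slope, threshold, background_rms) {
  rl <- slope * (level - threshold)
  background_rms * 10^((rl + 20) / 20)
}

#' Simulate a cohort of participants
#'
#' Draws per-participant latent parameters: a true p1--n1 latency from the
#' sex-specific normal distribution (placed symmetrically about the sex's
#' absolute p1/n1 anchor midpoint so that \code{true_n1 - true_p1} equals the
#' drawn latency), an amplitude-growth slope from
#' \code{N(slope_mean, slope_sd^2)}, and the configured response threshold.
#' Latency draws are truncated to \[2, 28\] ms so that p1 stays after the 5 ms
#' candidate floor and n1 inside the 15--37 ms trough window.
#'
#' @param config a [vemp_config()].
#' @param seed integer seed (default: the one stored in \code{config});
#'   \code{NULL} continues the current RNG stream.
#' @return data frame of class \code{vemp_cohort} with one row per
#'   participant: \code{participant_id}, \code{sex} (factor female/male),
#'   \code{true_latency}, \code{true_p1}, \code{true_n1}, \code{true_slope},
#'   \code{true_threshold}.
#' @export
make_cohort <- function(config, seed = config$seed) {
  validate_config(config)
  with_seed(seed)
  draw_sex <- function(n, mean, sd, mid, prefix) {
    lat <- rnorm_trunc(n, mean, sd, 2, 28)
    data.frame(
      participant_id = sprintf("%s%02d", prefix, seq_len(n)),
      sex = factor(rep(if (prefix == "F") "female" else "male", n),
                   levels = c("female", "male")),
      true_latency = lat,
      true_p1 = mid - lat / 2,
      true_n1 = mid + lat / 2,
      true_slope = rnorm_trunc(n, config$slope_mean, config$slope_sd, 0.2, Inf),
      true_threshold = rep(config$threshold_level, n),
      stringsAsFactors = FALSE
    )
  }
  cohort <- rbind(
    draw_sex(config$n_women, config$latency_mean_f, config$latency_sd_f,
             (config$p1_center_f + config$n1_center_f) / 2, "F"),
    draw_sex(config$n_men, config$latency_mean_m, config$latency_sd_m,
             (config$p1_center_m + config$n1_center_m) / 2, "M")
  )
  rownames(cohort) <- NULL
  class(cohort) <- c("vemp_cohort", "data.frame")
  cohort
}

#' Biphasic cVEMP waveform template
#'
#' A smooth biphasic waveform built from two Gaussian lobes: a positive lobe
#' centred at the p1 latency and a negative lobe at the n1 latency. The
#' constructed trace is rescaled on the sample grid so its range (max - min)
#' equals \code{p1n1_amplitude} exactly; its global maximum and minimum fall
#' within one sample of the requested latencies.
#'
#' @param p1_latency,n1_latency peak and trough latencies, ms post-onset;
#'   \code{n1_latency > p1_latency} and both inside \code{duration}.
#' @param p1n1_amplitude peak-to-trough span (max - min), same units as the
#'   returned waveform; 0 gives a flat zero trace.
#' @param sample_rate Hz.
#' @param duration template length, ms from stimulus onset.
#' @param sigma Gaussian lobe SD, ms.
#' @return numeric waveform of \code{round(duration * sample_rate / 1000)}
#'   samples, the first at stimulus onset (t = 0).
#' @examples
#' w <- vemp_template(15, 25, 100, 3000, 50)
#' (which.max(w) - 1) / 3 # ~15 ms
#' @export
vemp_template <- function(p1_latency, n1_latency, p1n1_amplitude,
                          sample_rate, duration, sigma = 3) {
  if (n1_latency <= p1_latency) abort_argument("n1_latency must exceed p1_latency")
  if (p1_latency <= 0 || n1_latency >= duration)
    abort_argument("latencies must lie inside (0, duration)")
  if (p1n1_amplitude < 0) abort_argument("p1n1_amplitude must be >= 0")
  n <- round(duration * sample_rate / 1000)
  t <- (seq_len(n) - 1) * 1000 / sample_rate
  s <- exp(-(t - p1_latency)^2 / (2 * sigma^2)) -
    exp(-(t - n1_latency)^2 / (2 * sigma^2))
  if (p1n1_amplitude == 0) return(numeric(n))
  s * (p1n1_amplitude / (max(s) - min(s)))
}

# Template embedded in a full epoch (zeros before onset).
epoch_template <- function(p1, n1, amp, config) {
  n_pre <- round(config$prestim_duration * config$sample_rate / 1000)
  c(numeric(n_pre),
    vemp_template(p1, n1, amp, config$sample_rate,
                  config$poststim_duration, config$template_sigma))
}

# Per-sequence jittered latencies (zero-mean Gaussian on p1 and n1).
jitter_latencies <- function(truth, config) {
  sd <- config$latency_jitter_sd
  repeat {
    p1 <- truth$true_p1 + rnorm(1, 0, sd)
    n1 <- truth$true_n1 + rnorm(1, 0, sd)
    if (n1 - p1 >= 1 && p1 > 0.5) return(c(p1 = p1, n1 = n1))
  }
}

#' Simulate raw EMG epochs for one participant and stimulus level
#'
#' Each epoch is band-limited Gaussian noise with pre-stimulus RMS equal to
#' the configured background tension plus the participant's biphasic response
#' template, scaled so the response level \code{20*log10(amp/background) - 20}
#' grows with stimulus level at the participant's slope and crosses 0 dB RL
#' at the response threshold. With probability \code{artifact_prob} an epoch
#' is contaminated by a deflection exceeding \code{artifact_amp}. Enough
#' epochs are generated that \code{epochs_per_sequence} accepted epochs
#' always remain after rejection.
#'
#' @param truth one-row slice of a [make_cohort()] data frame.
#' @param level stimulus level, dB HL.
#' @param config a [vemp_config()].
#' @param seed optional integer seed; \code{NULL} continues the stream.
#' @param sequence_order acquisition index recorded on the result.
#' @return An object of class \code{vemp_epochs}: epoch matrix (one row per
#'   epoch) plus sampling and onset metadata.
#' @export
synth_epochs <- function(truth, level, config, seed = NULL,
                         sequence_order = 1L) {
  validate_config(config)
  with_seed(seed)
  lat <- jitter_latencies(truth, config)
  amp <- true_amplitude(level, truth$true_slope, truth$true_threshold,
                        config$background_rms)
  tmpl <- epoch_template(lat[["p1"]], lat[["n1"]], amp, config)
  n_samples <- length(tmpl)
  p <- config$artifact_prob
  n_need <- config$epochs_per_sequence
  n_gen <- ceiling(n_need / (1 - p)) + if (p > 0) 10L else 0L
  repeat {
    contaminated <- stats::rbinom(n_gen, 1, p) == 1
    if (sum(!contaminated) >= n_need) break
    n_gen <- n_gen + 10L
  }
  noise <- band_noise(n_samples, n_gen, config$sample_rate,
                      config$noise_rms, config$highpass_hz,
                      config$lowpass_hz)
  epochs <- t(noise + tmpl)
  for (i in which(contaminated)) {
    centre <- sample.int(n_samples, 1)
    peak <- runif(1, 1.3, 2.0) * config$artifact_amp * sample(c(-1, 1), 1)
    w <- round(config$sample_rate / 1000) # ~1 ms lobe
    spike <- peak * exp(-((seq_len(n_samples) - centre) / w)^2)
    epochs[i, ] <- epochs[i, ] + spike
  }
  structure(list(
    participant_id = truth$participant_id,
    sex = truth$sex,
    stimulus_level = level,
    sample_rate = config$sample_rate,
    onset_index = round(config$prestim_duration * config$sample_rate / 1000) + 1L,
    sequence_order = as.integer(sequence_order),
    epochs = epochs
  ), class = "vemp_epochs")
}

#' @export
print.vemp_epochs <- function(x, ...) {
  cat(sprintf("cVEMP epoch set: %s (%s), %g dB HL, %d epochs x %d samples @ %g Hz\n",
              x$participant_id, as.character(x$sex), x$stimulus_level,
              nrow(x$epochs), ncol(x$epochs), x$sample_rate))
  invisible(x)
}

# Constructor for a sequence average; computes the 18 ms pre-stimulus RMS.
new_sequence <- function(waveform, participant_id, sex, stimulus_level,
                         sample_rate, onset_index, sequence_order,
                         n_epochs, normalized = FALSE) {
  structure(list(
    participant_id = participant_id, sex = sex,
    stimulus_level = stimulus_level, sample_rate = sample_rate,
    onset_index = as.integer(onset_index),
    sequence_order = as.integer(sequence_order),
    n_epochs = as.integer(n_epochs),
    waveform = as.numeric(waveform),
    prestim_rms = rms(waveform[prestim_indices(onset_index, sample_rate)]),
    normalized = normalized
  ), class = "vemp_sequence")
}

#' @export
print.vemp_sequence <- function(x, ...) {
  cat(sprintf("cVEMP sequence: %s, %g dB HL (order %d), %d samples, prestim RMS %.4g%s\n",
              x$participant_id, x$stimulus_level, x$sequence_order,
              length(x$waveform), x$prestim_rms,
              if (x$normalized) " (normalized)" else " uV"))
  invisible(x)
}

# Direct synthesis of a sequence average (no per-epoch loop): the mean of
# `epochs_per_sequence` Gaussian-noise epochs is template + band-limited
# noise with RMS background/sqrt(epochs). Statistically exact for the
# artifact-free Gaussian model because averaging is linear.
synth_sequence <- function(truth, level, config, sequence_order) {
  lat <- jitter_latencies(truth, config)
  amp <- true_amplitude(level, truth$true_slope, truth$true_threshold,
                        config$background_rms)
  tmpl <- epoch_template(lat[["p1"]], lat[["n1"]], amp, config)
  tr <- config$noise_rms / sqrt(config$epochs_per_sequence)
  wav <- tmpl + band_noise(length(tmpl), 1L, config$sample_rate, tr,
                           config$highpass_hz, config$lowpass_hz)[, 1]
  new_sequence(wav, truth$participant_id, truth$sex, level,
               config$sample_rate,
               round(config$prestim_duration * config$sample_rate / 1000) + 1L,
               sequence_order, config$epochs_per_sequence)
}

#' Simulate a participant record across the stimulus schedule
#'
#' Runs the configured stimulus schedule for one participant. With
#' \code{epoch_level = TRUE} raw epochs are synthesised and pushed through
#' artifact rejection and 300-epoch averaging ([reject_epochs()],
#' [average_sequence()]); with the default \code{FALSE} the sequence
#' averages are synthesised directly in the average domain (equivalent for
#' the Gaussian noise model and far cheaper, used by the Monte-Carlo
#' drivers).
#'
#' @inheritParams synth_epochs
#' @param epoch_level simulate individual epochs (see Details).
#' @return An object of class \code{vemp_record} holding the ordered
#'   sequence averages.
#' @export
synth_record <- function(truth, config, epoch_level = FALSE, seed = NULL) {
  validate_config(config)
  with_seed(seed)
  schedule <- level_schedule(config)
  seqs <- vector("list", length(schedule))
  for (i in seq_along(schedule)) {
    seqs[[i]] <- if (epoch_level) {
      es <- synth_epochs(truth, schedule[i], config, sequence_order = i)
      average_sequence(reject_epochs(es, config$artifact_amp),
                       config$epochs_per_sequence)
    } else {
      synth_sequence(truth, schedule[i], config, i)
    }
  }
  structure(list(
    participant_id = truth$participant_id,
    sex = truth$sex,
    truth = truth,
    sequences = seqs,
    background_rms = NULL,
    normalized = FALSE
  ), class = "vemp_record")
}

#' @export
print.vemp_record <- function(x, ...) {
  cat(sprintf("cVEMP record: %s (%s), %d sequences%s%s\n",
              x$participant_id, as.character(x$sex), length(x$sequences),
              if (!is.null(x$background_rms))
                sprintf(", background %.4g uV", x$background_rms) else "",
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Simulate a full cohort of participant records
#'
#' @inheritParams synth_record
#' @param config a [vemp_config()].
#' @param seed integer seed (default: from \code{config}).
#' @return list with elements \code{cohort} (the [make_cohort()] truth table)
#'   and \code{records} (list of [synth_record()] results).
#' @export
synth_cohort <- function(config, epoch_level = FALSE, seed = config$seed) {
  validate_config(config)
  with_seed(seed)
  cohort <- make_cohort(config, seed = NULL)
  records <- lapply(seq_len(nrow(cohort)), function(i) {
    synth_record(cohort[i, ], config, epoch_level = epoch_level, seed = NULL)
  })
  list(cohort = cohort, records = records)
}
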