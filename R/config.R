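#' Generator configuration
#'
#' Builds the configuration that drives the synthetic cVEMP generator. The
#' defaults are the shipped \code{"paper2025"} preset: 24 women and 24 men;
#' per-participant true p1--n1 latency distributions of 9.99 +/- 2.74 ms
#' (women) and 12.41 +/- 2.54 ms (men); absolute p1/n1 latency anchors of
#' 15.3/25.3 ms (women) and 14.6/27.0 ms (men); amplitude growth linear on
#' the dB RL scale with per-participant slope ~ N(1.89, 0.25^2) dB RL per
#' dB HL; 50 uV RMS background sternocleidomastoid tension; 3 kHz sampling;
#' the two descending stimulus series 40->34 and 39->35 dB HL in 2 dB steps
#' plus a closing 40 dB HL repeat; 300 epochs per sequence; and occasional
#' artifact epochs exceeding +/-800 uV.
#'
#' @param n_women,n_men participant counts per sex.
#' @param latency_mean_f,latency_sd_f,latency_mean_m,latency_sd_m mean and SD
#'   (ms) of the per-participant true p1--n1 latency, by sex.
#' @param p1_center_f,n1_center_f,p1_center_m,n1_center_m absolute-latency
#'   anchors (ms post-onset). A participant's true p1/n1 latencies are placed
#'   symmetrically about the sex's anchor midpoint so that n1 - p1 equals the
#'   drawn p1--n1 latency.
#' @param slope_mean,slope_sd dB RL per dB HL amplitude-growth slope
#'   distribution across participants.
#' @param background_rms background EMG tension, uV RMS, which both sets the
#'   noise floor and calibrates the response-amplitude scale (0 dB RL is ten
#'   times this tension).
#' @param noise_rms RMS of the synthesised EMG noise, uV; defaults to
#'   \code{background_rms}. Set 0 for noiseless generation while keeping the
#'   amplitude calibration.
#' @param sample_rate sampling rate, Hz.
#' @param prestim_duration,poststim_duration epoch spans before and after
#'   stimulus onset, ms. The pre-stimulus span must cover the 18 ms RMS window.
#' @param epochs_per_sequence accepted epochs averaged into one sequence.
#' @param level_series ordered stimulus schedule, dB HL.
#' @param artifact_prob per-epoch probability of an artifact deflection.
#' @param artifact_amp artifact rejection bound, uV; contaminated epochs
#'   exceed it in magnitude.
#' @param threshold_level dB HL at which the true p1--n1 amplitude equals
#'   10 x \code{background_rms}, i.e. 0 dB RL under the response-level
#'   transform.
#' @param template_sigma Gaussian lobe width (SD, ms) of the biphasic
#'   waveform template.
#' @param latency_jitter_sd SD (ms) of the zero-mean per-sequence jitter
#'   applied to the true p1 and n1 latencies.
#' @param highpass_hz high-pass corner of the synthesised EMG noise, Hz (the
#'   recording chain's 10 Hz analog high-pass).
#' @param lowpass_hz spectral corner (Hz) of the surface-EMG noise model: a
#'   second-order Butterworth magnitude roll-off emulating the concentration
#'   of surface-EMG power below ~500 Hz. The instrument's 1500 Hz anti-alias
#'   filter passes essentially all of that band at 3 kHz sampling.
#' @param seed integer seed recorded in the configuration and used by
#'   generator entry points unless overridden; \code{NULL} leaves the RNG
#'   stream untouched.
#' @return A validated object of class \code{vemp_config}.
#' @seealso [make_cohort()], [synth_record()], [level_schedule()]
#' @export
vemp_config <- function(n_women = 24, n_men = 24,
                        latency_mean_f = 9.99, latency_sd_f = 2.74,
                        latency_mean_m = 12.41, latency_sd_m = 2.54,
                        p1_center_f = 15.3, n1_center_f = 25.3,
                        p1_center_m = 14.6, n1_center_m = 27.0,
                        slope_mean = 1.89, slope_sd = 0.25,
                        background_rms = 50, sample_rate = 3000,
                        prestim_duration = 20, poststim_duration = 50,
                        epochs_per_sequence = 300,
                        level_series = c(40, 38, 36, 34, 39, 37, 35, 40),
                        artifact_prob = 0.02, artifact_amp = 800,
                        threshold_level = 39,
                        template_sigma = 2, latency_jitter_sd = 0.5,
                        highpass_hz = 10, lowpass_hz = 500,
                        noise_rms = NULL, seed = NULL) {
  cfg <- structure(list(
    n_women = n_women, n_men = n_men,
    latency_mean_f = latency_mean_f, latency_sd_f = latency_sd_f,
    latency_mean_m = latency_mean_m, latency_sd_m = latency_sd_m,
    p1_center_f = p1_center_f, n1_center_f = n1_center_f,
    p1_center_m = p1_center_m, n1_center_m = n1_center_m,
    slope_mean = slope_mean, slope_sd = slope_sd,
    background_rms = background_rms, sample_rate = sample_rate,
    prestim_duration = prestim_duration,
    poststim_duration = poststim_duration,
    epochs_per_sequence = epochs_per_sequence,
    level_series = level_series,
    artifact_prob = artifact_prob, artifact_amp = artifact_amp,
    threshold_level = threshold_level,
    template_sigma = template_sigma,
    latency_jitter_sd = latency_jitter_sd,
    highpass_hz = highpass_hz, lowpass_hz = lowpass_hz,
    noise_rms = if (is.null(noise_rms)) background_rms else noise_rms,
    seed = seed
  ), class = "vemp_config")
  validate_config(cfg)
}

#' @rdname vemp_config
#' @param config object to validate.
#' @export
validate_config <- function(config) {
  if (!inherits(config, "vemp_config")) abort_config("not a vemp_config object")
  with(config, {
    if (n_women < 1 || n_men < 1) abort_config("participant counts must be > 0")
    if (sample_rate <= 0) abort_config("sample_rate must be > 0")
    if (prestim_duration < 18) abort_config("prestim_duration must cover the 18 ms pre-stimulus window")
    if (any(c(latency_sd_f, latency_sd_m, slope_sd, latency_jitter_sd) < 0))
      abort_config("standard deviations must be >= 0")
    if (artifact_prob < 0 || artifact_prob >= 1)
      abort_config("artifact_prob must lie in [0, 1)")
    if (epochs_per_sequence < 1) abort_config("epochs_per_sequence must be > 0")
    if (background_rms < 0) abort_config("background_rms must be >= 0")
    if (length(level_series) < 1) abort_config("level_series must be non-empty")
  })
  invisible(config)
}

#' @export
print.vemp_config <- function(x, ...) {
  cat("cVEMP generator configuration\n")
  cat(sprintf("  cohort: %d women + %d men\n", x$n_women, x$n_men))
  cat(sprintf("  p1-n1 latency (ms): F %.2f +/- %.2f, M %.2f +/- %.2f\n",
              x$latency_mean_f, x$latency_sd_f, x$latency_mean_m, x$latency_sd_m))
  cat(sprintf("  amplitude slope: %.2f +/- %.2f dB RL / dB HL (0 dB RL at %g dB HL)\n",
              x$slope_mean, x$slope_sd, x$threshold_level))
  cat(sprintf("  schedule: %s dB HL, %d epochs/sequence, fs %g Hz\n",
              paste(x$level_series, collapse = " "),
              x$epochs_per_sequence, x$sample_rate))
  invisible(x)
}

#' Read or write a generator configuration as JSON
#'
#' @param path file path.
#' @return `read_config()` returns a `vemp_config`; `write_config()` its
#'   input, invisibly.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(vemp_config))
  extra <- setdiff(names(raw), known)
  if (length(extra)) abort_schema(paste("unknown config fields:", paste(extra, collapse = ", ")))
  do.call(vemp_config, raw)
}

#' @rdname read_config
#' @param config a `vemp_config`.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(config)
}

#' Descending stimulus-level series
#'
#' Arithmetic descent from `start` to `floor` in steps of `step` dB.
#'
#' @param start,floor first and last level, dB HL.
#' @param step decrement, dB.
#' @return numeric vector of levels.
#' @examples
#' descending_series(40, 36) # 40 38 36
#' @export
descending_series <- function(start, floor, step = 2) {
  if (step <= 0) abort_argument("step must be > 0")
  if (floor > start) abort_argument("floor must not exceed start")
  seq(start, floor, by = -step)
}

#' Stimulus schedule of a configuration
#'
#' The default schedule is the two descending series 40->34 and 39->35 dB HL
#' in 2 dB steps followed by a closing repeat at the 40 dB HL maximum:
#' 40, 38, 36, 34, 39, 37, 35, 40.
#'
#' @param config a [vemp_config()].
#' @return ordered numeric vector of dB HL levels.
#' @export
level_schedule <- function(config) {
  validate_config(config)
  config$level_series
}
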