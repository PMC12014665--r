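# Epoch processing: artifact rejection, 300-epoch sequence averaging,
# participant background EMG tension, and normalisation to a dimensionless
# ratio.

#' Reject artifact epochs
#'
#' Drops every epoch containing any sample whose magnitude is strictly
#' larger than the threshold (an extreme sample of exactly the threshold is
#' kept). Order of the surviving epochs is preserved.
#'
#' @param epochs a \code{vemp_epochs} object (see [synth_epochs()] /
#'   [read_epochs()]).
#' @param threshold rejection bound, uV.
#' @return the epoch set containing only accepted epochs.
#' @export
reject_epochs <- function(epochs, threshold = 800) {
  if (threshold <= 0) abort_argument("threshold must be > 0")
  keep <- apply(abs(epochs$epochs) <= threshold, 1, all)
  epochs$epochs <- epochs$epochs[keep, , drop = FALSE]
  epochs
}

#' Average accepted epochs into a sequence
#'
#' Pointwise mean of the first \code{n} accepted epochs in acquisition
#' order, mirroring an online averager that compensates for rejected epochs
#' so that every sequence summarises exactly \code{n} epochs. The 18 ms
#' pre-stimulus RMS of the averaged waveform is computed and stored.
#'
#' @param epochs accepted epochs (after [reject_epochs()]).
#' @param n number of epochs to average.
#' @return a \code{vemp_sequence} object.
#' @export
average_sequence <- function(epochs, n = 300) {
  avail <- nrow(epochs$epochs)
  if (avail < n) {
    abort_insufficient(sprintf(
      "need %d accepted epochs, only %d available (short by %d)",
      n, avail, n - avail))
  }
  wav <- colMeans(epochs$epochs[seq_len(n), , drop = FALSE])
  new_sequence(wav, epochs$participant_id, epochs$sex, epochs$stimulus_level,
               epochs$sample_rate, epochs$onset_index,
               epochs$sequence_order %||% 1L, n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Background EMG tension of a participant
#'
#' RMS of the 18 ms pre-stimulus span of the pointwise mean of the first six
#' sequence averages in acquisition order (i.e. a pre-stimulus mean over the
#' participant's first 1800 presentations under the default 300-epoch
#' sequences). This single value is the participant's background EMG tension
#' used for normalisation.
#'
#' @param record a \code{vemp_record}.
#' @return the record with \code{background_rms} filled in.
#' @export
background_rms <- function(record) {
  seqs <- record$sequences[order(vapply(record$sequences,
                                        function(s) s$sequence_order, 1L))]
  if (length(seqs) < 6)
    abort_insufficient(sprintf("background EMG tension needs 6 sequences, have %d",
                               length(seqs)))
  six <- seqs[1:6]
  wav <- Reduce(`+`, lapply(six, function(s) s$waveform)) / 6
  idx <- prestim_indices(six[[1]]$onset_index, six[[1]]$sample_rate)
  record$background_rms <- rms(wav[idx])
  record
}

#' Normalise a sequence by the background EMG tension
#'
#' Elementwise division of the averaged waveform (uV) by the participant's
#' background EMG tension (uV), giving a dimensionless trace; metadata and
#' the (now dimensionless) pre-stimulus RMS are carried along.
#'
#' @param seq a \code{vemp_sequence}.
#' @param background background EMG tension, uV; must be > 0.
#' @return the normalised \code{vemp_sequence}.
#' @export
normalize_sequence <- function(seq, background) {
  if (!is.numeric(background) || length(background) != 1 || background <= 0)
    abort_argument("background must be a single value > 0")
  seq$waveform <- seq$waveform / background
  seq$prestim_rms <- seq$prestim_rms / background
  seq$normalized <- TRUE
  seq
}

#' Normalise every sequence of a participant record
#'
#' Computes the background EMG tension (unless supplied) and divides each
#' sequence average by it.
#'
#' @param record a \code{vemp_record}.
#' @param background optional background EMG tension, uV; default: computed
#'   with [background_rms()].
#' @return the normalised record.
#' @export
normalize_record <- function(record, background = NULL) {
  if (is.null(background)) {
    record <- background_rms(record)
    background <- record$background_rms
  } else {
    record$background_rms <- background
  }
  record$sequences <- lapply(record$sequences, normalize_sequence,
                             background = background)
  record$normalized <- TRUE
  record
}

#' Response level (dB RL) of a p1--n1 amplitude
#'
#' \code{20 * log10(p1n1_amplitude / background) - 20}. Zero dB RL
#' corresponds to a projected response threshold (an amplitude of ten times
#' the background EMG tension).
#'
#' @param p1n1_amplitude peak-to-trough amplitude, uV (or dimensionless with
#'   \code{background = 1} for already-normalised amplitudes).
#' @param background background EMG tension in the same units.
#' @return response level, dB RL.
#' @examples
#' response_level(500, 50) # 0 dB RL
#' @export
response_level <- function(p1n1_amplitude, background = 1) {
  if (any(background <= 0)) abort_argument("background must be > 0")
  if (any(p1n1_amplitude <= 0))
    vemp_error("vemp_undefined_response_error",
               "response level undefined for non-positive amplitude")
  20 * log10(p1n1_amplitude / background) - 20
}
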