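# p1/n1 identification: topographic prominence of local extrema, the
# three-tier points system for candidate peaks, anchored trough tracking
# across stimulus levels, and the 1.65 x pre-stimulus-RMS null rule.

# Topographic prominence of the sample at `i` (a strict local maximum of
# `x`): extend left and right from the peak until a sample higher than the
# peak is met or the trace ends; the prominence is the peak height minus
# the higher of the two interval minima. Signal boundaries are open: when
# no higher sample exists on a side, the search runs to that end of the
# trace.
peak_prominence <- function(x, i) {
  h <- x[i]
  left <- x[seq_len(i - 1L)]
  hi <- which(left > h)
  lo_l <- if (length(hi)) min(left[(max(hi) + 1L):(i - 1L)]) else min(left)
  right <- x[(i + 1L):length(x)]
  hi <- which(right > h)
  lo_r <- if (length(hi)) min(right[seq_len(min(hi) - 1L)]) else min(right)
  h - max(lo_l, lo_r)
}

strict_maxima <- function(x) {
  n <- length(x)
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1L
}

#' Local extrema with topographic prominence
#'
#' Finds all strict local maxima of a waveform and, by applying the same
#' search to the inverted waveform, all strict local minima, each annotated
#' with its topographic prominence. Latencies are reported in ms relative
#' to stimulus onset and lie exactly on the sample grid (0.33 ms steps at
#' 3 kHz).
#'
#' @param waveform numeric trace (or a \code{vemp_sequence}, from which the
#'   sampling metadata are taken).
#' @param sample_rate Hz; ignored when \code{waveform} is a sequence.
#' @param onset_index 1-based index of the stimulus-onset sample.
#' @param kinds which extrema to return.
#' @param latency_window optional \code{c(lo, hi)} in ms; extrema outside it
#'   are dropped before prominences are computed (prominence itself is
#'   always measured on the full trace).
#' @return data frame with columns \code{kind} ("peak"/"trough"),
#'   \code{index}, \code{latency} (ms), \code{value} (trace value at the
#'   extremum) and \code{prominence}, ordered by index. A flat or monotone
#'   trace yields zero rows.
#' @export
find_extrema <- function(waveform, sample_rate = NULL, onset_index = 1L,
                         kinds = c("peak", "trough"),
                         latency_window = NULL) {
  if (inherits(waveform, "vemp_sequence")) {
    sample_rate <- waveform$sample_rate
    onset_index <- waveform$onset_index
    waveform <- waveform$waveform
  }
  if (length(waveform) < 3) abort_argument("waveform must have at least 3 samples")
  if (is.null(sample_rate)) abort_argument("sample_rate is required")
  out <- list()
  for (kind in kinds) {
    x <- if (kind == "peak") waveform else -waveform
    idx <- strict_maxima(x)
    lat <- (idx - onset_index) * 1000 / sample_rate
    if (!is.null(latency_window)) {
      keep <- lat >= latency_window[1] & lat <= latency_window[2]
      idx <- idx[keep]; lat <- lat[keep]
    }
    if (length(idx)) {
      out[[kind]] <- data.frame(
        kind = kind, index = idx, latency = lat,
        value = waveform[idx],
        prominence = vapply(idx, function(i) peak_prominence(x, i), 0),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(kind = character(), index = integer(),
                      latency = numeric(), value = numeric(),
                      prominence = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$index), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Lean extrema search used on the hot path: vectors only, no data frames.
# Returns list(index, latency, value, prominence) for extrema of `kind`
# with latency inside [lo, hi] ms; prominence is measured on the full trace.
lean_extrema <- function(waveform, sample_rate, onset_index, kind, lo, hi) {
  x <- if (kind == "peak") waveform else -waveform
  idx <- strict_maxima(x)
  lat <- (idx - onset_index) * 1000 / sample_rate
  keep <- lat >= lo & lat <= hi
  idx <- idx[keep]; lat <- lat[keep]
  list(index = idx, latency = lat, value = waveform[idx],
       prominence = vapply(idx, function(i) peak_prominence(x, i), 0))
}

# Shared scoring core over candidate-peak vectors. Returns the component
# and total points in candidate order.
score_points <- function(prominence, latency, n1_latency, proximity_pool) {
  k <- length(prominence)
  prom_pts <- numeric(k); wt_pts <- numeric(k); prox_pts <- numeric(k)
  dist <- abs(latency - n1_latency)
  ord <- order(-prominence, latency)
  top <- ord[seq_len(min(3, k))]
  prom_pts[top] <- (5:3)[seq_along(top)]
  r <- prominence[top] / prominence[ord[1]]
  wt_pts[top] <- ifelse(r >= 2 / 3, 3, ifelse(r > 1 / 3, 2, 1))
  pool <- if (proximity_pool == "prominent") top else seq_len(k)
  near <- pool[order(dist[pool], latency[pool])][seq_len(min(5, length(pool)))]
  prox_pts[near] <- (5:1)[seq_along(near)]
  list(prominence_points = prom_pts, weight_points = wt_pts,
       proximity_points = prox_pts, total = prom_pts + wt_pts + prox_pts,
       n1_distance = dist)
}

# Most prominent trough within [lo, hi] ms; ties broken by earlier latency.
# Returns a one-row data frame, or NULL when the window holds no trough.
most_prominent_trough <- function(seq, lo, hi) {
  tr <- lean_extrema(seq$waveform, seq$sample_rate, seq$onset_index,
                     "trough", lo, hi)
  if (!length(tr$index)) return(NULL)
  i <- order(-tr$prominence, tr$latency)[1]
  data.frame(kind = "trough", index = tr$index[i], latency = tr$latency[i],
             value = tr$value[i], prominence = tr$prominence[i],
             stringsAsFactors = FALSE)
}

#' Identify n1 on the initial maximum-level sequence
#'
#' The n1 trough of the initial 40 dB HL sequence is the most prominent
#' trough with latency between 15 and 37 ms (inclusive).
#'
#' @param seq a normalised \code{vemp_sequence}.
#' @return one-row data frame describing the trough (see [find_extrema()]),
#'   or \code{NULL} when no trough lies in the window (a null response).
#' @export
identify_n1_initial <- function(seq) {
  most_prominent_trough(seq, 15, 37)
}

#' Identify n1 anchored to the initial sequence's trough
#'
#' For sequences after the initial one, trough detection is anchored: the
#' most prominent trough within \code{anchor +/- window_halfwidth} ms,
#' clipped to the 15--37 ms window.
#'
#' @param seq a normalised \code{vemp_sequence}.
#' @param anchor n1 latency (ms) from the participant's initial sequence.
#' @param window_halfwidth half-width of the anchored search window, ms.
#' @return as [identify_n1_initial()].
#' @export
identify_n1_anchored <- function(seq, anchor, window_halfwidth = 5) {
  most_prominent_trough(seq, max(15, anchor - window_halfwidth),
                        min(37, anchor + window_halfwidth))
}

#' Score candidate peaks against n1
#'
#' Implements the three-tier points system over candidate peaks (peaks with
#' latency at or after 5 ms and strictly before n1):
#' \enumerate{
#'   \item the three most prominent peaks receive 5, 4 and 3 points in
#'     order of prominence;
#'   \item those same three receive weight points by their prominence ratio
#'     r to the most prominent peak: 3 if r >= 2/3, 2 if 1/3 < r < 2/3,
#'     1 otherwise;
#'   \item up to five peaks closest in latency to n1 receive 5 down to 1
#'     points, the smallest time difference earning 5.
#' }
#' With fewer than three (or five) candidates, points are awarded down the
#' available list. Prominence and proximity ties are broken in favour of
#' the earlier latency.
#'
#' The pool for the proximity tier is governed by \code{proximity_pool}.
#' The default \code{"prominent"} awards proximity points within the
#' prominence-ranked shortlist (the peaks holding prominence points), which
#' keeps the selection robust on noisy traces: low-prominence ripple peaks
#' adjacent to n1 cannot out-point a dominant p1. \code{"all"} ranks every
#' candidate by distance to n1; on traces whose candidate sets include
#' ripple peaks near the trough this variant can prefer them, so it is
#' provided for sensitivity analysis.
#'
#' @param candidates data frame of candidate peaks ([find_extrema()] rows),
#'   already filtered to the 5 ms--n1 window.
#' @param n1 one-row data frame for the n1 trough.
#' @param proximity_pool \code{"prominent"} (default) or \code{"all"}; see
#'   Details.
#' @return the candidates with \code{prominence_points},
#'   \code{weight_points}, \code{proximity_points}, \code{total} and
#'   \code{n1_distance} columns added.
#' @export
score_peaks <- function(candidates, n1,
                        proximity_pool = c("prominent", "all")) {
  proximity_pool <- match.arg(proximity_pool)
  sc <- candidates
  if (!nrow(sc)) {
    sc$prominence_points <- numeric(0); sc$weight_points <- numeric(0)
    sc$proximity_points <- numeric(0); sc$n1_distance <- numeric(0)
    sc$total <- numeric(0)
    return(sc)
  }
  pts <- score_points(sc$prominence, sc$latency, n1$latency, proximity_pool)
  sc$prominence_points <- pts$prominence_points
  sc$weight_points <- pts$weight_points
  sc$proximity_points <- pts$proximity_points
  sc$n1_distance <- pts$n1_distance
  sc$total <- pts$total
  sc
}

pick_row <- function(seq, p1_latency = NA_real_, n1_latency = NA_real_,
                     p1n1_amplitude = NA_real_, response_level = NA_real_,
                     is_null = TRUE) {
  structure(list(
    participant_id = seq$participant_id, sex = seq$sex,
    stimulus_level = seq$stimulus_level, sequence_order = seq$sequence_order,
    p1_latency = p1_latency, n1_latency = n1_latency,
    p1n1_latency = n1_latency - p1_latency,
    p1n1_amplitude = p1n1_amplitude, response_level = response_level,
    is_null = is_null
  ), class = "data.frame", row.names = 1L)
}

null_pick <- function(seq) pick_row(seq)

#' Pick p1 and n1 on one sequence
#'
#' Composes the full identification: trough selection (initial-style when
#' \code{anchor} is \code{NULL}, anchored otherwise), candidate-peak
#' filtering to latencies in \[5 ms, n1), the points system of
#' [score_peaks()] with ties broken by the smallest time difference from
#' n1, and the null-response rule: the pick is flagged null when the p1--n1
#' amplitude is strictly less than \code{null_factor} times the sequence's
#' own pre-stimulus RMS. Null outcomes are returned as flagged rows, never
#' as errors.
#'
#' @param seq a normalised \code{vemp_sequence} (a raw uV sequence is also
#'   accepted if \code{background} is supplied, in which case the response
#'   level is computed relative to it).
#' @param anchor n1 latency (ms) of the participant's initial sequence, or
#'   \code{NULL} for initial-style trough detection.
#' @param background background EMG tension, uV; only needed for
#'   un-normalised input.
#' @param window_halfwidth anchored-trough half-window, ms.
#' @param null_factor multiplier of the per-sequence pre-stimulus RMS below
#'   which a response is declared null.
#' @return one-row data frame: identifiers, \code{p1_latency},
#'   \code{n1_latency}, \code{p1n1_latency}, \code{p1n1_amplitude} (value
#'   at p1 minus value at n1, in the sequence's units),
#'   \code{response_level} (dB RL) and \code{is_null}.
#' @export
pick_sequence <- function(seq, anchor = NULL, background = NULL,
                          window_halfwidth = 5, null_factor = 1.65,
                          proximity_pool = c("prominent", "all")) {
  proximity_pool <- if (length(proximity_pool) > 1) proximity_pool[1]
                    else proximity_pool
  if (!proximity_pool %in% c("prominent", "all"))
    abort_argument("proximity_pool must be 'prominent' or 'all'")
  # anchored or initial trough window
  lo <- if (is.null(anchor)) 15 else max(15, anchor - window_halfwidth)
  hi <- if (is.null(anchor)) 37 else min(37, anchor + window_halfwidth)
  x <- seq$waveform
  tro <- lean_extrema(x, seq$sample_rate, seq$onset_index, "trough", lo, hi)
  if (!length(tro$index)) return(null_pick(seq))
  i1 <- order(-tro$prominence, tro$latency)[1]
  n1_lat <- tro$latency[i1]; n1_val <- tro$value[i1]
  pk <- lean_extrema(x, seq$sample_rate, seq$onset_index, "peak", 5, n1_lat)
  keep <- pk$latency < n1_lat
  if (!any(keep)) return(null_pick(seq))
  prom <- pk$prominence[keep]; lat <- pk$latency[keep]; val <- pk$value[keep]
  pts <- score_points(prom, lat, n1_lat, proximity_pool)
  best <- order(-pts$total, pts$n1_distance, lat)[1]
  amp <- val[best] - n1_val
  if (amp <= 0) return(null_pick(seq))
  rl <- if (isTRUE(seq$normalized)) {
    response_level(amp)
  } else if (!is.null(background)) {
    response_level(amp, background)
  } else {
    NA_real_
  }
  pick_row(seq, p1_latency = lat[best], n1_latency = n1_lat,
           p1n1_amplitude = amp, response_level = rl,
           is_null = amp < null_factor * seq$prestim_rms)
}

#' Pick p1 and n1 for every sequence of a participant
#'
#' The initial maximum-level sequence (the first acquired) is picked first;
#' its n1 latency anchors trough detection on all remaining sequences. The
#' sequences are processed in acquisition order regardless of list order.
#'
#' @param record a normalised \code{vemp_record}.
#' @inheritParams pick_sequence
#' @return data frame with one [pick_sequence()] row per sequence.
#' @export
pick_participant <- function(record, window_halfwidth = 5,
                             null_factor = 1.65,
                             proximity_pool = c("prominent", "all")) {
  proximity_pool <- match.arg(proximity_pool)
  ord <- order(vapply(record$sequences, function(s) s$sequence_order, 1L))
  seqs <- record$sequences[ord]
  levels <- vapply(seqs, function(s) s$stimulus_level, 0)
  if (levels[1] < max(levels)) {
    abort_protocol(sprintf(
      "initial sequence is at %g dB HL but the maximum recorded level is %g; the anchor must come from the initial maximum-level sequence",
      levels[1], max(levels)))
  }
  first <- pick_sequence(seqs[[1]], anchor = NULL,
                         window_halfwidth = window_halfwidth,
                         null_factor = null_factor,
                         proximity_pool = proximity_pool)
  anchor <- first$n1_latency
  rest <- lapply(seqs[-1], function(s) {
    pick_sequence(s, anchor = if (is.na(anchor)) NULL else anchor,
                  window_halfwidth = window_halfwidth,
                  null_factor = null_factor,
                  proximity_pool = proximity_pool)
  })
  out <- do.call(rbind, c(list(first), rest))
  rownames(out) <- NULL
  out
}

#' Picks for a whole cohort
#'
#' @param records list of normalised \code{vemp_record}s (e.g. from
#'   [synth_cohort()] after [normalize_record()]).
#' @inheritParams pick_sequence
#' @return row-bound [pick_participant()] results.
#' @export
pick_cohort <- function(records, window_halfwidth = 5, null_factor = 1.65,
                        proximity_pool = c("prominent", "all")) {
  proximity_pool <- match.arg(proximity_pool)
  out <- do.call(rbind, lapply(records, pick_participant,
                               window_halfwidth = window_halfwidth,
                               null_factor = null_factor,
                               proximity_pool = proximity_pool))
  rownames(out) <- NULL
  out
}

#' Latency dataset from picks
#'
#' Long-format table feeding the statistics layer: one row per non-null
#' pick.
#'
#' @param picks data frame from [pick_cohort()] / [pick_participant()].
#' @return data frame with the pick columns, nulls removed.
#' @export
latency_dataset <- function(picks) {
  out <- picks[!picks$is_null & !is.na(picks$p1n1_latency), , drop = FALSE]
  rownames(out) <- NULL
  out
}
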