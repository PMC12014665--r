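# Shared fixtures and the independent brute-force oracle for the p1/n1
# identification algorithm. The oracle enumerates extrema and re-derives
# every point award by definition, with explicit loops, so it shares no
# code path with the package implementation.

# Small, fast generator configuration for end-to-end smoke tests.
tiny_config <- function(...) {
  vemp_config(n_women = 2, n_men = 2,
              prestim_duration = 18, poststim_duration = 32,
              epochs_per_sequence = 12,
              level_series = c(40, 38, 36, 34, 39, 37),
              artifact_prob = 0.05, ...)
}

# Wrap a bare waveform in a sequence object (flat zero pre-stimulus span
# unless the waveform provides one).
make_seq <- function(waveform, sample_rate = 3000, onset_index = 55L,
                     level = 40, order = 1L, normalized = TRUE,
                     participant_id = "T01", sex = "female") {
  s <- cvemp:::new_sequence(waveform, participant_id,
                            factor(sex, levels = c("female", "male")),
                            level, sample_rate, onset_index, order,
                            n_epochs = 300L)
  s$normalized <- normalized
  s
}

# Place spike/dip features (value `v` at latency `ms`) on a zero baseline.
feature_wave <- function(features, n = 205, onset_index = 55L,
                         sample_rate = 3000) {
  x <- numeric(n)
  for (f in features) {
    x[onset_index + round(f$ms * sample_rate / 1000)] <- f$v
  }
  x
}

# Smooth-ish random waveforms for oracle-equivalence sweeps: a few random
# sinusoids plus white noise, so candidate sets contain both dominant and
# ripple extrema.
random_wave <- function(n = 205, sample_rate = 3000) {
  t <- seq_len(n) / sample_rate
  x <- numeric(n)
  for (k in seq_len(4)) {
    x <- x + runif(1, 0.5, 3) * sin(2 * pi * runif(1, 20, 300) * t +
                                      runif(1, 0, 2 * pi))
  }
  x + rnorm(n, sd = runif(1, 0.05, 0.6))
}

## ---- brute-force oracle ----------------------------------------------

oracle_prominence <- function(x, i) {
  h <- x[i]
  lmin <- Inf
  j <- i - 1
  while (j >= 1 && x[j] <= h) {
    if (x[j] < lmin) lmin <- x[j]
    j <- j - 1
  }
  if (is.infinite(lmin)) lmin <- h
  rmin <- Inf
  j <- i + 1
  while (j <= length(x) && x[j] <= h) {
    if (x[j] < rmin) rmin <- x[j]
    j <- j + 1
  }
  if (is.infinite(rmin)) rmin <- h
  h - max(lmin, rmin)
}

oracle_extrema <- function(x) {
  out <- data.frame(index = integer(), kind = character())
  for (i in 2:(length(x) - 1)) {
    if (x[i] > x[i - 1] && x[i] > x[i + 1]) {
      out <- rbind(out, data.frame(index = i, kind = "peak"))
    } else if (x[i] < x[i - 1] && x[i] < x[i + 1]) {
      out <- rbind(out, data.frame(index = i, kind = "trough"))
    }
  }
  out
}

# Full re-derivation of one sequence pick. Returns a list mirroring the
# pick_sequence() columns.
oracle_pick <- function(seq, anchor = NULL, window_halfwidth = 5,
                        null_factor = 1.65, proximity_pool = "prominent") {
  x <- seq$waveform
  lat_of <- function(i) (i - seq$onset_index) * 1000 / seq$sample_rate
  ex <- oracle_extrema(x)
  lo <- 15; hi <- 37
  if (!is.null(anchor)) {
    lo <- max(15, anchor - window_halfwidth)
    hi <- min(37, anchor + window_halfwidth)
  }
  troughs <- ex[ex$kind == "trough", ]
  troughs <- troughs[lat_of(troughs$index) >= lo & lat_of(troughs$index) <= hi, ]
  if (!nrow(troughs)) return(list(is_null = TRUE))
  tp <- sapply(troughs$index, function(i) oracle_prominence(-x, i))
  # max prominence, ties to earlier latency
  bestt <- which(tp == max(tp))
  if (length(bestt) > 1) bestt <- bestt[which.min(troughs$index[bestt])]
  n1_i <- troughs$index[bestt]
  n1_lat <- lat_of(n1_i)
  peaks <- ex[ex$kind == "peak", ]
  peaks <- peaks[lat_of(peaks$index) >= 5 & lat_of(peaks$index) < n1_lat, ]
  if (!nrow(peaks)) return(list(is_null = TRUE))
  k <- nrow(peaks)
  prom <- sapply(peaks$index, function(i) oracle_prominence(x, i))
  lat <- lat_of(peaks$index)
  dist <- abs(lat - n1_lat)
  prom_pts <- numeric(k); wt_pts <- numeric(k); prox_pts <- numeric(k)
  # prominence awards 5,4,3 by repeated selection
  remaining <- seq_len(k)
  top <- integer()
  for (award in c(5, 4, 3)) {
    if (!length(remaining)) break
    cand <- remaining[prom[remaining] == max(prom[remaining])]
    if (length(cand) > 1) cand <- cand[which.min(lat[cand])]
    prom_pts[cand] <- award
    top <- c(top, cand)
    remaining <- setdiff(remaining, cand)
  }
  maxprom <- prom[top[1]]
  for (i in top) {
    r <- prom[i] / maxprom
    wt_pts[i] <- if (r >= 2 / 3) 3 else if (r > 1 / 3) 2 else 1
  }
  pool <- if (proximity_pool == "prominent") top else seq_len(k)
  for (award in c(5, 4, 3, 2, 1)) {
    if (!length(pool)) break
    cand <- pool[dist[pool] == min(dist[pool])]
    if (length(cand) > 1) cand <- cand[which.min(lat[cand])]
    prox_pts[cand] <- award
    pool <- setdiff(pool, cand)
  }
  total <- prom_pts + wt_pts + prox_pts
  win <- which(total == max(total))
  if (length(win) > 1) win <- win[dist[win] == min(dist[win])]
  if (length(win) > 1) win <- win[which.min(lat[win])]
  amp <- x[peaks$index[win]] - x[n1_i]
  if (amp <= 0) return(list(is_null = TRUE))
  list(p1_latency = lat[win], n1_latency = n1_lat,
       p1n1_amplitude = amp,
       is_null = amp < null_factor * seq$prestim_rms)
}
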