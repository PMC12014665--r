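test_that("topographic prominence matches hand-worked saddle geometry", {
  # single triangular bump of height 8 on a zero baseline
  x <- c(rep(0, 10), 2, 4, 6, 8, 6, 4, 2, rep(0, 10))
  ex <- find_extrema(x, 3000, 1L)
  pk <- ex[ex$kind == "peak", ]
  expect_equal(nrow(pk), 1)
  expect_equal(pk$prominence, 8)

  # two bumps (10 and 6) separated by a saddle at 2, baseline 0
  x2 <- c(0, 2, 5, 10, 6, 2, 4, 6, 4, 2, 0)
  ex2 <- find_extrema(x2, 3000, 1L)
  pk2 <- ex2[ex2$kind == "peak", ]
  expect_equal(pk2$prominence[pk2$value == 10], 10)
  expect_equal(pk2$prominence[pk2$value == 6], 4)

  # monotone ramp and flat trace: no interior extrema
  expect_equal(nrow(find_extrema(1:50, 3000, 1L)), 0)
  expect_equal(nrow(find_extrema(rep(1, 50), 3000, 1L)), 0)
  expect_error(find_extrema(c(1, 2), 3000, 1L), class = "vemp_argument_error")
})

test_that("extremum latencies sit on the 0.33 ms sample grid", {
  set.seed(3)
  x <- random_wave()
  ex <- find_extrema(x, 3000, 55L)
  steps <- ex$latency * 3 # multiples of 1/3 ms -> integers
  expect_equal(steps, round(steps))
})

test_that("initial n1 selection respects the 15-37 ms window and prominence order", {
  # trough at 14 ms (prominence 9) is outside the window; 20 ms (3) wins
  w <- feature_wave(list(list(ms = 14, v = -9), list(ms = 20, v = -3)))
  s <- make_seq(w)
  n1 <- identify_n1_initial(s)
  expect_equal(n1$latency, 20, tolerance = 1 / 3)
  expect_equal(n1$prominence, 3)

  # 20 ms (3) vs 30 ms (5): larger prominence wins
  w2 <- feature_wave(list(list(ms = 20, v = -3), list(ms = 30, v = -5)))
  expect_equal(identify_n1_initial(make_seq(w2))$latency, 30, tolerance = 1 / 3)

  # no trough in window -> NULL
  w3 <- feature_wave(list(list(ms = 10, v = -5)))
  expect_null(identify_n1_initial(make_seq(w3)))
})

test_that("anchored n1 search clips to anchor +/- halfwidth", {
  w <- feature_wave(list(list(ms = 24, v = -4), list(ms = 33, v = -8)))
  s <- make_seq(w)
  expect_equal(identify_n1_anchored(s, 25)$latency, 24, tolerance = 1 / 3)
  expect_equal(identify_n1_anchored(s, 33)$latency, 33, tolerance = 1 / 3)
  expect_null(identify_n1_anchored(make_seq(feature_wave(list())), 25))
})

test_that("points system awards prominence, weight and proximity tiers", {
  cand <- data.frame(kind = "peak", index = c(115, 106, 85),
                     latency = c(20, 17, 10), value = c(9, 5, 2),
                     prominence = c(9, 5, 2))
  n1 <- data.frame(kind = "trough", index = 127, latency = 24, value = -1,
                   prominence = 5)
  for (pool in c("prominent", "all")) {
    sc <- score_peaks(cand, n1, proximity_pool = pool)
    expect_equal(sc$prominence_points, c(5, 4, 3))
    expect_equal(sc$weight_points, c(3, 2, 1)) # 9/9, 5/9, 2/9
    expect_equal(sc$proximity_points, c(5, 4, 3))
    expect_equal(sc$total, c(13, 10, 7))
  }

  # ratio exactly two thirds earns the full 3 weight points
  cand2 <- cand[1:2, ]
  cand2$prominence <- c(9, 6)
  sc2 <- score_peaks(cand2, n1)
  expect_equal(sc2$weight_points, c(3, 3))

  # single candidate collects 5 + 3 + 5
  sc3 <- score_peaks(cand[1, ], n1)
  expect_equal(sc3$total, 13)
})

test_that("score ties resolve to the peak nearest n1", {
  # two equal-height spike peaks (equal prominence), trough after them
  w <- feature_wave(list(list(ms = 18, v = 5), list(ms = 20, v = 5),
                         list(ms = 22, v = -4)))
  p <- pick_sequence(make_seq(w))
  expect_equal(p$p1_latency, 20, tolerance = 1e-9)
  expect_equal(p$n1_latency, 22, tolerance = 1e-9)
  expect_equal(p$p1n1_amplitude, 9)
})

test_that("null-response rule is strict at 1.65 x the sequence prestim RMS", {
  base_wave <- function(amp) {
    x <- numeric(205)
    x[1:54] <- 1          # prestim RMS = 1
    x[55 + 45] <- amp / 2 # peak at 15 ms
    x[55 + 75] <- -amp / 2 # trough at 25 ms
    x
  }
  exact <- pick_sequence(make_seq(base_wave(1.65)))
  expect_false(exact$is_null) # amplitude equal to the bound is kept
  expect_equal(exact$p1n1_amplitude, 1.65)
  below <- pick_sequence(make_seq(base_wave(1.0)))
  expect_true(below$is_null)
})

test_that("scoring and the null flag are invariant under amplitude scaling", {
  set.seed(8)
  for (i in 1:20) {
    x <- random_wave()
    s1 <- make_seq(x)
    s2 <- make_seq(x * 7.3)
    p1 <- pick_sequence(s1)
    p2 <- pick_sequence(s2)
    expect_equal(p1$is_null, p2$is_null)
    if (!p1$is_null) {
      expect_equal(p1$p1_latency, p2$p1_latency)
      expect_equal(p1$n1_latency, p2$n1_latency)
      expect_equal(p2$p1n1_amplitude, 7.3 * p1$p1n1_amplitude)
    }
  }
})

test_that("pick_sequence agrees with the brute-force oracle on random waveforms", {
  set.seed(2024)
  for (i in 1:250) {
    s <- make_seq(random_wave())
    anchor <- if (i %% 3 == 0) runif(1, 18, 34) else NULL
    pool <- if (i %% 2 == 0) "prominent" else "all"
    got <- pick_sequence(s, anchor = anchor, proximity_pool = pool)
    want <- oracle_pick(s, anchor = anchor, proximity_pool = pool)
    if (is.na(got$p1_latency)) {
      expect_true(want$is_null)
    } else {
      expect_equal(got$p1_latency, want$p1_latency)
      expect_equal(got$n1_latency, want$n1_latency)
      expect_equal(got$p1n1_amplitude, want$p1n1_amplitude)
      expect_equal(got$is_null, want$is_null)
    }
  }
})

test_that("participant picks anchor on the initial maximum-level sequence", {
  cfg <- vemp_config(noise_rms = 0, latency_jitter_sd = 0, artifact_prob = 0)
  co <- make_cohort(cfg, seed = 21)
  rec <- synth_record(co[1, ], cfg, seed = 22)
  rec <- normalize_record(rec, background = 1)
  picks <- pick_participant(rec)
  expect_equal(nrow(picks), 8)
  expect_false(any(picks$is_null))
  expect_lt(max(abs(picks$p1n1_latency - co$true_latency[1])), 2 / 3 + 1e-9)
  expect_equal(length(unique(picks$p1_latency)), 1) # noiseless: identical picks

  # permuting the sequence list leaves the output unchanged
  rec_perm <- rec
  rec_perm$sequences <- rec$sequences[c(5, 2, 8, 1, 4, 7, 3, 6)]
  expect_equal(pick_participant(rec_perm), picks)

  # a record whose first-acquired sequence is not at the maximum level
  rec_bad <- rec
  rec_bad$sequences[[1]]$stimulus_level <- 38
  expect_error(pick_participant(rec_bad), class = "vemp_protocol_error")
})

test_that("noiseless cohort pipeline recovers true latencies within one sample", {
  cfg <- vemp_config(n_women = 4, n_men = 4, noise_rms = 0,
                     latency_jitter_sd = 0, artifact_prob = 0)
  co <- make_cohort(cfg, seed = 31)
  recs <- lapply(seq_len(nrow(co)), function(i) {
    normalize_record(synth_record(co[i, ], cfg, seed = 100 + i), background = 1)
  })
  d <- latency_dataset(pick_cohort(recs))
  err <- d$p1n1_latency - co$true_latency[match(d$participant_id, co$participant_id)]
  # the template contract (extrema at the requested latencies) holds when the
  # two lobes are separated by >= ~2.5 sigma; restrict to that regime
  ok <- co$true_latency[match(d$participant_id, co$participant_id)] >= 5
  expect_lt(max(abs(err[ok])), 2 / 3 + 1e-9) # p1 and n1 each within 1 sample
})
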