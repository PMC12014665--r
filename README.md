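# cvemp

Analysis of cervical vestibular-evoked myogenic potentials (cVEMP) — the
brief stimulus-locked inhibition of tonic sternocleidomastoid EMG used as a
non-invasive probe of vestibular function — from raw EMG epochs through to
group statistics, power analysis and meta-analysis. The package is aimed at
auditory/vestibular electrophysiologists who record sequences of
stimulus-locked EMG epochs under controlled muscle tension and want a
reproducible, scriptable version of the full processing chain, plus a seeded
synthetic-data generator so every stage can be exercised and validated
without access to recordings.

## What it computes

For each participant and stimulus level (dB HL), a *sequence* is the average
of exactly 300 accepted epochs; epochs with any sample beyond ±800 µV are
rejected first. Each sequence is normalised by the participant's background
EMG tension — the RMS of the 18 ms pre-stimulus span of the mean of the first
six sequences — and amplitudes are expressed as response levels:

    dB RL = 20 · log10( p1–n1 amplitude / background ) − 20

The p1 peak and n1 trough are identified by a prominence-based points
system: n1 is the most prominent trough in 15–37 ms on the initial 40 dB HL
sequence (anchoring ±5 ms windows on later sequences); candidate peaks in
[5 ms, n1) collect prominence points (5/4/3), prominence-ratio weights
(3/2/1, with ≥ 2/3 of the leader earning 3) and proximity-to-n1 points
(5…1); the highest total wins, ties resolving to the peak nearest n1. A pick
is null when the p1–n1 amplitude is below 1.65 × the sequence's own
pre-stimulus RMS.

On top of the picks: random-intercept mixed models fitted by ML with
likelihood-ratio tests (`latency ~ sex + (1|participant)`;
`dB RL ~ stimulus_level + sex + (1|participant)`), Welch's unequal-variances
t-test on per-participant means (raw data or printed summaries), Cohen's d,
conditional R², noncentral-t power analysis, an empirical power grid over
reduced presentation/participant counts, DerSimonian–Laird random-effects
meta-analysis of study-level sex differences and meta-regression on stimulus
presentation count. The methods vignette
(`vignettes/cvemp-methods.Rmd`) documents the models, the identification
algorithm and every tunable parameter.

## Worked example

Simulate a 24 + 24 cohort at the standard 8-sequence schedule, run the full
pipeline and compare the sexes:

```r
library(cvemp)

cfg <- vemp_config(seed = 1)          # shipped "paper2025" defaults
sim <- simulate_pipeline(cfg, seed = 1)
head(sim$data[, c("participant_id", "sex", "stimulus_level",
                  "p1n1_latency", "response_level")])

pm <- participant_means(sim$data)
welch_test(x = pm$mean[pm$sex == "female"],
           y = pm$mean[pm$sex == "male"])
#> Welch two-sample comparison (male - female)
#>   difference 2.425, t = 3.232, df = 45.79, p = 0.002283
#>   95% CI [0.914, 3.936]; F 10.602 +/- 2.511 (n=24), M 13.028 +/- 2.686 (n=24)

lrt <- lrt_sex_effect(sim$data, "p1n1_latency")
#> LRT: chi2(1) = 9.82, p = 0.001726; sex effect 2.43 ms (SE 0.73)

mean(participant_slopes(sim$data)$slope)
#> [1] 1.90   # dB RL per dB HL amplitude growth

power_two_sample_t(cohens_d_pooled(9.99, 12.41, 2.74, 2.54), 24)
#> [1] 0.874  # analytic power of the 24+24 design at the default effect size
```

The simulated cohort was generated with a 2.42 ms true sex difference in
p1–n1 latency and amplitude growth of 1.89 dB RL per dB HL; the pipeline
recovers a 2.43 ms gap (p ≈ 0.002 by both the mixed-model likelihood-ratio
test and Welch's test on participant means) and a mean growth slope of 1.90,
and the analytic power of the design at the recovered effect size is 0.87.

A subcommand CLI wraps the same functions
(`inst/cli/vemp simulate | process | pick | stats | power | meta |
earcanal`); e.g. `vemp earcanal 0.7` prints the 9.1 dB dial-SPL correction
for a 0.7 cc ear canal.

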