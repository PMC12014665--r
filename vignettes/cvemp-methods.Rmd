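---
title: "cVEMP analysis: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cVEMP analysis: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvemp)
```

## The measurement and its processing chain

The cervical vestibular-evoked myogenic potential (cVEMP) is a brief,
stimulus-locked inhibition of tonic sternocleidomastoid (SCM) activity,
recorded as a surface-EMG waveform with a characteristic positive peak (p1,
~13–16 ms) and negative trough (n1, ~24–27 ms) after stimulus onset. Because
the potential rides on ongoing muscle activity, single responses are invisible;
the measurement unit is the **sequence** — the average of exactly 300 accepted
stimulus-locked epochs at one stimulus level. `cvemp` implements the full chain
from raw epochs to group statistics:

1. **Artifact rejection** (`reject_epochs()`): epochs with any sample whose
   magnitude is *strictly* larger than ±800 µV are dropped. The bound is read
   literally — a sample of exactly 800 µV survives. Downstream averaging
   compensates, so a sequence always summarises exactly 300 accepted epochs
   (`average_sequence()` errors, naming the shortfall, when fewer are
   available).
2. **Background EMG tension** (`background_rms()`): the RMS of the 18 ms
   pre-stimulus span of the pointwise mean of the participant's first six
   sequences (i.e. a pre-stimulus mean of 1800 presentations). "First six"
   means acquisition order. Note that averaging before taking the RMS cancels
   most of the stochastic EMG, so this quantity is far below the ~50 µV raw
   tension; it is nonetheless the definition used, applied exactly as stated.
   Because it is one constant per participant, any scale it carries cancels
   out of all within-participant contrasts — slopes and latency comparisons
   are unaffected.
3. **Normalisation** (`normalize_sequence()`): each sequence average is
   divided elementwise by the participant's background tension, giving a
   dimensionless trace. The 18 ms window is the half-open interval
   [onset − 18 ms, onset).
4. **Response level**: amplitudes are expressed in dB RL,
   `20·log10(p1n1_amplitude / background) − 20`. Zero dB RL (an amplitude of
   ten times the background tension) is a *projected* response threshold — it
   can lie above the achievable stimulus range.

## The p1/n1 identification algorithm

Peaks are strict local maxima; troughs are found by applying the same search
to the inverted trace. Each extremum carries its **topographic prominence**:
its height minus the higher of the two lowest points separating it from the
nearer higher terrain, with the search running to the ends of the trace when
no higher sample exists on a side (`find_extrema()`). Latencies are quantised
to the 3 kHz sample grid (0.33 ms steps).

Per participant:

* On the initial maximum-level (40 dB HL) sequence, **n1** is the most
  prominent trough between 15 and 37 ms inclusive (`identify_n1_initial()`).
* On every later sequence, trough detection is **anchored**: the most
  prominent trough within ±5 ms of the initial n1, clipped to 15–37 ms
  (`identify_n1_anchored()`). The half-width is configurable.
* Candidate peaks are those at or after 5 ms and strictly before n1. They are
  scored by a three-tier points system (`score_peaks()`): 5/4/3 points to the
  three most prominent; 3/2/1 weight points to those same three by their
  prominence ratio to the leader (3 when the ratio is ≥ 2/3 — the boundary is
  inclusive); and 5…1 proximity points by closeness to n1. The peak with the
  most points is p1; ties go to the peak nearest n1, then to the earlier
  latency. Prominence and proximity ties also resolve to the earlier latency,
  and with fewer than three (or five) candidates the awards simply run down
  the available list.
* A pick is **null** when the p1–n1 amplitude is strictly less than 1.65
  times the *sequence's own* pre-stimulus RMS (the per-sequence quantity, not
  the participant-level background). Nulls are returned as flagged rows,
  never as errors.

### The proximity pool: a deliberate design decision

The proximity tier can be read two ways: rank *all* surviving candidates by
distance to n1, or rank within the prominence shortlist. The all-candidates
reading is structurally fragile on noisy traces: the true p1 typically sits
~10–12 ms before n1, i.e. it is usually the *farthest* candidate, so any five
ripple peaks between p1 and n1 strip it of proximity points while a tiny
ripple peak on the trough's flank collects the maximum five. In simulation
this produced sub-millisecond p1–n1 "latencies" and amplitude-growth slopes
wrong by up to a factor of 2.5 for a quarter of participants — artefacts that
would be glaring on visual inspection of real traces. `cvemp` therefore defaults to
awarding proximity points *within the prominence-ranked shortlist*
(`proximity_pool = "prominent"`); a dominant p1 then always out-points ripple
competitors (its 5 + 3 prominence/weight points exceed any shortlist rival's
4 + 1 + 5). The literal reading remains available as
`proximity_pool = "all"` for sensitivity analysis, and both variants are
verified against an independent brute-force oracle in the test suite.

## Group statistics

The latency analysis fits random-intercept linear mixed models by **maximum
likelihood** (`fit_lmm()`, backed by lme4) — ML rather than REML because
nested fixed-effect structures are compared by likelihood ratio
(`likelihood_ratio_test()`: χ² = 2·ΔlogLik against a χ² reference with the
parameter-count difference as df). Sex is coded 0 = female, 1 = male, so a
positive coefficient means a longer latency in men. The amplitude-growth
model adds stimulus level as a fixed slope:
`dB RL ~ stimulus_level + sex + (1 | participant)`. A fixed (common) slope is
used; the per-participant OLS slopes (`participant_slopes()`) motivate this —
their dispersion is small relative to their mean.

The companion analysis averages picks per participant
(`participant_means()`) and applies Welch's unequal-variances t-test
(`welch_test()`), which accepts either raw samples or printed group
summaries; Satterthwaite degrees of freedom are kept fractional internally
and rounded only for display. Effect sizes: `cohens_d()` converts a
mixed-model t (d = 2t/√df); `cohens_d_pooled()` uses the equal-n pooled-SD
convention. `conditional_r2()` implements the variance-partition form
(fixed + intercept variance over total). No multiple-testing correction is
applied by default; the absolute p1/n1 analyses are exploratory and a
Bonferroni adjustment can be applied to their p-values externally.

**Power**: `power_two_sample_t()` computes noncentral-t power with the
pooled-SD convention (df = 2n − 2, noncentrality d·√(n/2), two-tailed
α = 0.05) — the convention of standard power software, retained even under
unequal variances. `power_grid()` complements it empirically: simulated
cohorts are subsampled in presentations (first-k sequences in acquisition
order, so the anchoring sequence is always retained; normalisation uses the
full record's background before subsampling) and in participants (balanced
across sexes, first-k), then pushed through the complete pick → means →
Welch pipeline; the fraction of significant cohorts is the empirical power.

**Meta-analysis**: `study_effect()` converts study summaries to mean
differences (male − female, so positive = longer in men) with variance
sd²_f/n_f + sd²_m/n_m. `pool_random_effects()` is a direct implementation of
DerSimonian–Laird pooling (method-of-moments τ², inverse-variance weights
1/(v + τ²), Wald intervals), cross-checked in the tests against metafor as
an independent oracle. `meta_regression()` regresses study effects on a
continuous moderator (e.g. stimulus presentation count) with a
DL-type residual τ² and z-based slope test, and is delegated to
`metafor::rma(mods = ~x, method = "DL")` — a weighted moderator fit is
standard methodology, not this package's contribution. Comparisons entering
as multiple rows per study (both ears, several stimuli) are pooled without
correlation adjustment. The shipped `inst/extdata/synthetic_studies.csv` is a
**synthetic** illustration table; no per-study values from the literature are
transcribed in this package.

## The synthetic-data generator

No recordings ship with the package; the generator (`vemp_config()`,
`make_cohort()`, `synth_epochs()`, `synth_record()`) emulates the recording
design so that every stage is testable. The shipped defaults are the study
conditions:

| parameter | default | meaning |
|---|---|---|
| cohort | 24 women + 24 men | balanced design |
| p1–n1 latency | N(9.99, 2.74²) F; N(12.41, 2.54²) M, ms | per-participant truth, truncated to [2, 28] ms |
| p1/n1 anchors | 15.3/25.3 F; 14.6/27.0 M, ms | absolute-latency centring |
| growth slope | N(1.89, 0.25²) dB RL per dB HL | per-participant amplitude growth |
| background | 50 µV RMS | biofeedback tension target |
| sampling | 3 kHz; ≥18 ms pre-stimulus | instrument resolution |
| schedule | 40 38 36 34 39 37 35 40 dB HL | two descending series + closing repeat (2400 presentations) |
| epochs/sequence | 300 | accepted epochs per average |
| artifacts | p = 0.02, >800 µV deflections | rejected upstream |
| threshold_level | 39 dB HL | level at which the true amplitude equals 0 dB RL |
| template lobes | Gaussian, σ = 2 ms | see below |
| per-sequence jitter | 0.5 ms SD on p1 and n1 | sequence-to-sequence variation |
| noise spectrum | 10 Hz HP × 500 Hz LP magnitude | surface-EMG-like band |

A participant's true p1/n1 pair is placed symmetrically about the sex's
anchor midpoint so n1 − p1 equals the drawn latency. Amplitude at level L is
`background · 10^((slope·(L − threshold) + 20)/20)` µV, i.e. linear growth on
the dB RL scale crossing 0 dB RL at the threshold level; with the defaults
this gives ≈620 µV at 40 dB HL and ≈170 µV at 34 dB HL — comfortably inside
the ±800 µV rejection bound and far above the null rule, so the
parameter-recovery suites run at high signal-to-noise. Sessions of this
design typically accumulate ~3,000 presentations per participant once
optional extra low-level sequences are included; the generator's core
schedule is the 8-sequence / 2,400-presentation design, with extra sequences
left as a configuration choice.

Three generator defaults deserve explicit justification; each was settled by
simulation evidence:

* **Noise spectrum.** Shaping the synthetic EMG only by the recording
  filters (10–1500 Hz at 3 kHz sampling) makes the noise white to Nyquist and
  the averaged traces maximally wiggly — unlike surface EMG, whose power
  concentrates below ~500 Hz. The generator shapes white Gaussian noise by a
  first-order 10 Hz high-pass times a second-order 500 Hz low-pass magnitude
  response (zero-phase, applied in the frequency domain) and rescales to the
  target RMS.
* **Template width.** σ = 3 ms lobes overlap at short p1–n1 separations,
  pushing the waveform extrema away from the lobe centres (violating the
  template's contract that extrema land within one sample of the requested
  latencies) and inflating short latencies — asymmetrically by sex, since
  women's latencies are shorter. σ = 2 ms (FWHM ≈ 4.7 ms, a realistic cVEMP
  peak width) keeps the contract for separations ≥ ~5 ms. Below that the
  lobes merge and measured latencies are genuinely inflated; with the default
  distributions ~2% of women fall in that regime, a small residual source of
  downward bias (~0.05–0.1 ms) in the recovered sex gap.
* **Proximity pool.** Discussed above.

What the generator does **not** emulate: real EMG non-stationarity and
fatigue drift, electrode-placement variability, skull vibratory modes, volume
conduction, and genuinely non-Gaussian artifact shapes. Passing the recovery
suites therefore demonstrates that the pipeline's algorithms are correct and
unbiased under the stated statistical model — not that the model captures
every property of real recordings.

## Numerical and procedural choices

* **Average-domain synthesis.** For Monte-Carlo work the sequence average is
  synthesised directly as template + noise with RMS background/√300; because
  averaging is linear and the noise Gaussian, this is distributionally exact
  for the artifact-free case, and ~300× cheaper than per-epoch synthesis. The
  epoch-level path (with artifacts, rejection and averaging) is exercised on
  small cohorts in the unit tests and available via `epoch_level = TRUE`.
* **Problem sizes.** The recovery suites use 200 cohorts of 48 participants
  (the acceptance script and the end-to-end test), 1000 random waveforms for
  oracle equivalence, and 1000 simulated null cohorts for the type-I-error
  check — sizes at which the Monte-Carlo standard errors are a few percent of
  the quantities checked.
* **Monte-Carlo tolerances.** The per-cohort sex-gap estimate has SD
  ≈ 0.76 ms, so a 200-cohort mean carries SE ≈ 0.054 ms; the end-to-end test
  asserts agreement with the configured 2.42 ms gap within 3 SE (0.16 ms)
  rather than demanding a particular rounding, which would fail by chance
  ~30% of the time. Similarly, reading p1/n1 values at argmax-over-noise
  sample positions inflates amplitudes by the expected maximum of the local
  noise — relatively more at low levels — which biases fitted dB RL slopes
  down by ~0.01–0.02 under the default signal-to-noise; the slope check
  allows 0.06 around 1.89 to cover this extraction bias plus Monte-Carlo
  error. Both bands were fixed from this analysis, not fitted to outcomes.
* **Determinism.** Every stochastic entry point takes an explicit seed; a
  fixed seed reproduces cohorts, epoch sets and whole result files
  byte-identically. Rejection sampling implements the truncated normals, so
  determinism holds under a fixed stream.
* **Degenerate inputs.** Flat or monotone traces yield no extrema and a null
  pick; zero-variance mixed-model fits are flagged `singular` rather than
  failing; identical models compare with χ² = 0, p = 1; a meta-regression on
  a constant moderator errors as undefined.

## Limitations

The package provides the *machinery* of the analysis; quantities that can
only come from real recordings (a dataset's conditional R², its absolute
group latencies, reduced-data summary rows) enter only as user inputs or
generator defaults, never as reproduction targets. The
identification algorithm's literal all-candidates proximity variant is
retained for sensitivity work but is not recommended on noisy traces. The
ear-canal correction (`ear_canal_correction()`) applies Boyle's-law pressure
scaling only — it ignores impedance changes with frequency and is intended
for the small corrections (~0–10 dB) discussed for calibration couplers.
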