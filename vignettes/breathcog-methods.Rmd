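---
title: "Respiration-locked cognition: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Respiration-locked cognition: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(breathcog)
```

This vignette documents the scientific model behind `breathcog`, the
parameters that matter, and the choices made where the design was genuinely
open. It states no empirical result beyond what the package's tests and
`scripts/acceptance.R` themselves compute.

## The measurement model

Nasal airflow is a continuous pressure signal around a pre-measured room
baseline. The onset of inspiration (the EI transition) and of expiration
(the IE transition) are defined as the time at which the flow first crosses
the baseline and subsequently deviates from it by more than 2 noise SDs —
the SD gate is a *validity* condition that discards sub-threshold wiggles;
the reported time is the crossing itself, not the later confirmation sample.
Detection runs on a zero-phase 2-Hz low-passed copy of the trace (4th-order
Butterworth, forward–backward), while tidal amplitudes are measured on the
raw waveform.

Two estimation choices are not dictated by the measurement definition:

- **Noise SD.** We estimate it as the SD of the high-frequency residual
  (raw minus low-passed trace). A leading "quiet window" estimate is the
  obvious alternative, but it conflates breathing signal with noise whenever
  the recording starts mid-breath — which synthetic traces, and many real
  ones, do. The residual estimator is available on any trace and converges
  to the injected noise SD on simulated data.
- **Alternation repair.** Valid crossings are forced to strictly alternate
  EI/IE; same-direction repeats and crossings closer than `min_phase_dur`
  (0.2 s) to the last accepted one are discarded. On noiseless traces the
  detector is exact to within two samples: one because the crossing is
  reported at the first sample *past* baseline, and up to one more because
  the 2-Hz filter slightly displaces the slope kink at each onset (the
  inspiratory and expiratory half-waves have different slopes).

The closed-loop trigger path is deliberately different: a 2nd-order
Butterworth applied **forward only**, because a real-time system cannot look
ahead. Its phase delay (≈ 0.1 s at typical breathing frequencies) is part of
the emulated apparatus error, exactly as in the physical system, and comes
on top of the 0.67-s constant trigger delay (0.27 s tubing + 0.4 s
mechanical) and the 0/350/700-ms cue lags. We model the tubing delay inside
the constant, not by shifting the trace; the offline analysis compensates
the recording lag separately via `compensate_lag(trace, 0.27)`.

## Circular phase and block conditions

Event times are projected piecewise-linearly onto the cycle: inspiration
maps onto [0°, 180°), expiration onto [180°, 360°), each stretched by the
actual phase durations of the breath containing the event. The mean
resultant vector of a set of angles summarizes phase concentration; its
length R is 1 only for identical angles and the circular SD is
√(−2 ln R).

A *test block* is the interval from test-cue onset to the button press. Its
condition is decided by the transitions **strictly inside** the open
interval: none → INS or EXP (by the cue's phase), only IE → IE, only EI →
EI, both kinds → Both (excluded from condition analyses, as too rare to
estimate). Strict interiority is a deliberate tie-break: "spanning" a
transition should mean the transition genuinely interrupts the retrieval
interval, and it makes the classification invariant to whether a cue lands
exactly on a crossing sample.

## The synthetic study

The generator's defaults are the study conditions, not tuning knobs:

| parameter | default | meaning |
|---|---|---|
| mean inspiration / expiration | 1.46 s / 2.09 s | group-level phase durations |
| breath-duration CV | 0.10 | within-subject lognormal jitter |
| sigh probability / amplitude | 0.01 / 2.5× | occasional deep breaths |
| sampling rate | 1000 Hz | acquisition rate |
| epochs | 8 A + 8 B | 4 sample + 10 test cues each, delay 10–13 s |
| Epoch A ISI / lags | 6 s / {0, 350, 700} ms | fixed schedule |
| trigger | every 2nd transition + 0.67 s + lag | Epoch B schedule |
| planted EI effects | +150 ms RT, −10 acc. points, −0.4 d′ | retrieval deficit |

Between-subject variability: phase-duration means are drawn around
1.46/2.09 s (SDs 0.25/0.40 s, i.e. the printed group SEs scaled back to the
25-subject sample), and a subject "ability" offset (SD 0.15) shifts d′.

Waveform morphology is not part of the study definition, so flow is a
half-sinusoid per phase — positive in inspiration, negative in expiration —
which guarantees baseline crossings exactly at the ground-truth transitions
and makes the generator its own detection oracle. Sighs multiply one
breath's amplitude by 2.5, safely beyond the 2× detection threshold.
Reaction times are truncated-normal (at zero) around a 1.0-s base — a
typical short-delay DMTS reaction time, chosen so that all four block
conditions are populated in every subject (with a much slower base, blocks
that fit inside a single 1.46-s inspiration all but disappear).

**The planted observer.** The choice model is an equal-variance
signal-detection observer. For each condition we solve the hit and
false-alarm rates that *jointly* produce the target accuracy and target d′
(accuracy = (hit + 1 − fa)/2, d′ = z(hit) − z(fa)). An equal-variance
observer at accuracy *a* cannot have d′ below 2·z(*a*), so the baseline d′
(2.4 at accuracy 0.85) sits above that floor and subject offsets move
accuracy along the unbiased-observer curve acc = Φ(d′/2), keeping every
subject's pair attainable. The generative scheme is two-stage: a provisional
RT (baseline + noise) determines a provisional condition, the condition's RT
shift is added, and the block is re-classified on the final interval —
choices are then keyed to the final, analysis-visible label, so planted
effects and analysis conditions agree by construction.

What the generator does **not** emulate: waveform asymmetries and breathing
artifacts (coughs, swallows), cardiac or motion contamination of the airflow
channel, structured fMRI noise (drift beyond what the DCT basis removes,
physiological aliasing, motion), attention lapses, and learning or fatigue
trends across epochs. Passing the recovery suites therefore shows the
*pipeline* is correct and well-calibrated at study scale — not that real
recordings will be as clean.

## Statistical battery

Assumption routing mirrors standard practice for within-subject designs:
Shapiro–Wilk per condition (α = 0.05; a zero-variance condition counts as a
failure), Mauchly for k ≥ 3. Any normality failure routes the whole family
to Friedman + Wilcoxon post hocs; a sphericity failure alone keeps the
parametric route but applies the Greenhouse–Geisser correction, with ε
computed from the double-centered condition covariance and capped at 1. All
tests are two-sided; Bonferroni multiplies post hoc p-values by the number
of pairs; Wilcoxon drops zero differences and uses average ranks (the
normal approximation with continuity correction); an exactly identical pair
returns p = 1 rather than a degenerate test.

`rmcorr` is the blocked-ANCOVA estimator of the common within-subject
correlation: r_rm = sign(slope)·√(SS_x/(SS_x+SS_e)) with
df = N_obs − n_subjects − 1, p from the t transform, and a Fisher-z CI with
SE = 1/√(df − 3). The omnibus for d′ uses the one-way repeated-measures
design whose df, (2, 48) at 25 subjects × 3 conditions, matches the
reported bookkeeping of such studies.

Under the null (exchangeable normal conditions), the routed battery's
empirical type-I error at α = 0.05 is checked over 2,000 replicates and
must stay in [0.03, 0.07]; the GG correction is applied only when Mauchly
rejects, which keeps the parametric branch from becoming conservative when
sphericity actually holds.

## fMRI design

Each run models 825 scans at TR = 0.8 s, discarding the first ten volumes
(equilibration); regressors are built on the full grid and truncated, so
HRF convolution is unaffected by the discard. Per run the design holds one
sample-block regressor, one delay-block regressor, forty test-block
regressors (cue to response, true RT-length durations), one extra-response
regressor, the signed phase-transition regressor (+1 per IE, −1 per EI, at
scan resolution, HRF-convolved by default but toggleable since raw-impulse
entry is equally defensible), the RVT regressor, a discrete-cosine drift
basis realizing the 1/128-Hz high-pass *inside* the design (the standard
equivalent of filtering data and model identically), and an intercept.

The HRF is the canonical double-gamma (peak 6 s, undershoot 16 s, unit
dispersions, ratio 6, 32-s kernel, unit-sum normalized). RVT is the
Birn-style envelope-difference-over-period, interpolated from breath
midpoints and averaged in each 0.8-s window after shifting by the 5.6-s
hemodynamic delay. Condition contrasts weight each test-block column by
±1/n of its condition group, so IE > EI estimates a per-block mean
difference; "Both" blocks keep weight 0. Fitting is OLS — temporal
autocorrelation modeling is out of scope, and all recovery simulations use
white noise so that OLS is the correct reference model. Rank deficiency is
an error that names the dependent columns rather than a silent pseudo
inverse.

## Problem sizes and tolerances

The test suite runs the oracle comparisons (sums-of-squares, rank formula,
blocked ANCOVA, quantile arithmetic) at 3–5 subjects × 3–4 conditions with
1e-10 tolerances; detection recovery at 100 breaths/250 Hz in the module
test and 500 breaths/1 kHz in the end-to-end suite (recall and precision
≥ 99% within 50 ms at noise SD = 0.1 × amplitude); effect recovery over 100
study replicates of 25 subjects in fast (truth-series) mode, which runs the
identical downstream analysis while skipping trace synthesis; and the GLM
bias check over 200 simulations of the 815-scan single-run design. The
full-fidelity trace mode is exercised on smaller subject counts in the
module tests and on the complete 25-subject study in the acceptance script.

## Known limitations

- The SD gate needs measurable sensor noise; on an ideal noiseless signal
  every crossing validates, which is correct there but means the gate's
  selectivity is only testable with noise present.
- Sextile occupancy and condition frequencies depend on the RT distribution
  relative to the phase durations; condition cells can be empty for extreme
  parameter settings, in which case affected subjects are dropped from the
  balanced repeated-measures analyses (with a warning).
- The Friedman statistic is undefined (0/0 under the tie-corrected form)
  when every subject's row is constant; the package raises an error rather
  than reporting 0.
- `rmcorr` assumes a common within-subject slope; heterogeneous slopes are
  averaged, as in the standard estimator.
- No cardiac regressors, no RETROICOR Fourier terms, no prewhitening, no
  volumetric image handling — the GLM stage is a design-matrix and
  parameter-recovery tool, not an image analysis.
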