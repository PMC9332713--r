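---
title: "EEG-based person verification: models, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EEG-based person verification: models, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

EEG carries stable, individual-specific spectral structure — resting-state
band power profiles and oscillation peak frequencies differ reproducibly
between people — which makes it a candidate biometric. `eegverify`
implements a complete verification study around that idea: a claimed
identity is confirmed or rejected by a small neural network trained
specifically for that person, using spectral features of short EEG
segments.

The package's central scientific question is methodological rather than
neurophysiological: **how much of the reported performance of EEG
biometrics is an artifact of within-session data leakage?** When training
and test segments come from the same recording sessions (scenario 1),
the classifier sees each session's particular state — vigilance,
electrode placement, impedance — on both sides of the split. When test
sessions are held out entirely (scenario 2, the deployment-relevant
protocol), day-to-day variability must be bridged. The package makes the
two protocols directly comparable on data whose generating process is
fully known.

## The verification pipeline

1. **Cohort.** 29 genuine subjects with 20 sessions each (580
   examinations) plus 23 single-session external impostors, 19 scalp
   channels (10–20 montage), 500 Hz, 3 minutes per session. All sizes
   are configurable; the defaults reproduce this design.
2. **Preprocessing.** Common average reference only — no filtering, no
   artifact rejection, imitating a field-deployable system.
3. **Features.** Each recording is cut into 24 non-overlapping 7.5 s
   segments. Per segment, Welch's PSD (1 s Hamming windows, 0.5 s
   overlap, 14 windows, 1 Hz bins) yields, per band and channel:
   the *normalized peak frequency* (argmax frequency / 500 Hz), the
   *peak-to-mean band power ratio*, and the *relative band power*
   (band power / total power over 1–45 Hz). With 19 channels this is 57
   features per band, 285 for all five canonical bands
   (δ 1–4, θ 4–8, α 8–12, β 12–30, γ 30–45 Hz).
4. **Verifier.** One network per verified subject: one hidden tanh
   layer (1–10 neurons), two linear outputs coding genuine = (+1, −1)
   and impostor = (−1, +1), trained by Levenberg–Marquardt on MSE with
   balanced impostor vectors drawn from the other 28 subjects. Ten
   restarts; the restart with the best training accuracy is kept.
5. **Evaluation.** Accuracy, sensitivity, specificity, precision from
   segment-level confusion counts; scenario comparisons by one-way
   ANOVA; band-set comparisons by one-way ANOVA + Tukey HSD; the
   hidden-neuron sweep by two-way ANOVA; an external impostor attack
   (552 foreign segments against every verifier) as the field-realistic
   false-acceptance measure.

## The synthetic cohort generator

Real multi-session recordings of this size are not redistributable, so
the package ships a generator whose *statistical structure* — not
waveform realism — matches what the pipeline needs to be testable:

* **Identity** lives in a per-subject signature: for every (band,
  channel), an oscillation center frequency (uniform within the band,
  up to 85% of the half-width from the midpoint) and amplitude
  (lognormal around 5 µV), plus a 1/f^χ background with χ ∈ [0.8, 1.4].
  `subject_spread` scales both dispersions; distance between subjects'
  mean feature vectors grows monotonically with it (tested).
* **Session drift** is a per-session effect: per-band log-power offsets
  (sd `sigma_session`), per-band peak-frequency jitter (sd
  `sigma_freq`, Hz) and a mild global gain. With both sds at zero the
  effect is exactly the identity.
* **Segment noise** is white (sd `segment_noise`, µV), the only
  within-session variability.

Oscillation phases are random per (band, channel, session): phase
carries no identity information, consistent with power-only features.
External impostors are drawn from the same population distribution as
genuine subjects — the harder, fairer attack condition. Everything is a
pure function of the config seed; recordings are rendered lazily (a
full 603-recording cohort held eagerly would need ~8 GiB) and
bit-identically on every call.

What the generator does **not** model: eye-blink/EMG artifacts,
electrode impedance changes, volume conduction, line noise, or
non-sinusoidal waveform shape. Passing tests therefore show that the
pipeline recovers identity from band-structured spectra under session
drift — not that any particular accuracy will be reached on real EEG.

### Default noise levels

Chosen once as a realistic mid-point: `sigma_session = 0.4` (band power
varies ~±50% day to day), `sigma_freq = 0.3` Hz, `segment_noise = 1`
µV against ~5 µV oscillations, `subject_spread = 0.5`. At desk scale
these defaults make the task nearly but not exactly saturated.

For the leakage-gap checks a *strong drift* condition is used:
`sigma_session = 1.2` (≈3× power shifts), `sigma_freq = 2` Hz — drift
on the order of the between-subject separation, large relative to
segment noise. This is the regime the second scenario is designed to
expose: within-session evaluation stays nearly perfect while
session-disjoint sensitivity drops by several points.

## Numerical and design choices

* **Band bins.** Half-open `[lo, hi)` membership on the 1 Hz grid, so
  the 4, 8, 12 and 30 Hz bins belong to the upper band. Adjacent bands
  never share a bin and the five bands exactly tile 1–45 Hz.
* **Relative-power denominator.** Total power is summed over 1–45 Hz
  (the union of the analysed bands), excluding DC/drift and the
  power-line region; the convention is switchable per call
  (`total_range = c(0, Inf)` for the full-spectrum reading), and the
  five canonical relative powers sum to exactly 1 under the default.
* **Peak frequency.** Bin-center argmax, no interpolation, ties to the
  lowest frequency — the simplest reproducible rule.
* **Welch scaling.** One-sided density (µV²/Hz); all three features are
  ratios, so the convention cancels, but the PSD contract fixes one so
  the Parseval test is meaningful.
* **Scenario 1 clustering** is per session (4 clusters of 6 within each
  session's 24 vectors); a pooled variant (`pool_sessions = TRUE`) is
  available. Impostor draws are refreshed per fold.
* **Scenario 2 split** is chronological: first 75% of sessions train
  (15 of 20 at the default design), the rest test, identical genuine
  sets across the four folds, fresh impostor draws per fold.
* **LM training.** Damping µ starts at 1e-3, ×0.1 on accepted steps,
  ×10 on rejected ones, capped at 1e10; stop at 100 iterations or
  gradient ∞-norm < 1e-7. Inputs are standardized with training-set
  statistics stored in the model (LM on raw ratio features of wildly
  different scales is numerically fragile); initialization is small
  uniform weights scaled by fan-in. A µ overflow without an accepted
  step sets the model's `stalled` flag. No validation-based early
  stopping: every training vector is used for fitting.
* **Prediction.** Genuine iff the genuine output strictly exceeds the
  impostor output; exact ties go to impostor — the conservative choice
  for an access-control system.
* **Aggregation.** Metrics per fold → mean per subject (undefined
  precision cells dropped, since sensitivity already captures the
  degenerate fold) → mean ± sd over subjects.
* **Two-way ANOVA layout.** Subject-level, fold-averaged accuracies
  crossed over band set × hidden count: with 29 subjects and a 10 × 10
  grid this gives the design's error df of 2800.
* **Normality check.** Lilliefors-corrected one-sample KS test —
  the correct calibration when mean and sd are estimated from the data.
* **Seeding.** Every stage derives its seed by hashing the master seed
  with its grid coordinates (`derive_seed()`), so any cell of an
  experiment grid can be recomputed alone and any run replayed exactly
  from its manifest.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run at two scales, chosen as
the package's own desk-scale defaults:

* structural, signal-processing and statistical checks: single
  recordings, toy training sets, simulated ANOVA tables (seconds);
* property checks (leakage gap over 5 master seeds, band-combination,
  easy-regime recovery): 8 subjects × 8 sessions, 1 hidden neuron, 3
  restarts;
* the acceptance script: the full default cohort (29 × 20 + 23
  external), beta-band verifiers with 3 restarts, fold 0 of both
  scenarios, and the complete 16,008-attempt attack.

## Known limitations

* The generator's identity signal is strong; at the default noise
  levels desk-scale verification sits near ceiling, so differences
  between band sets are compressed relative to real data.
* Session drift is band-global (one offset per band shared by all
  channels). Real electrode-placement drift is spatially heterogeneous
  and plausibly harder; the leakage gap measured here is therefore a
  conservative analogue.
* No claim is made about the numerical performance levels of any real
  recording set; only protocol structure, formula fidelity and
  qualitative orderings (scenario gap, band-combination benefit) are
  asserted.
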