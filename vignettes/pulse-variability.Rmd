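---
title: "Beat-wise harmonic variability analysis of arterial pulses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beat-wise harmonic variability analysis of arterial pulses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsevar)
```

## The model

An arterial pulse recording is treated as a train of quasi-periodic beats.
Each beat, cut from foot to foot, is expanded as a truncated Fourier series
on its own period:

$$ s(t) = a_0 + \sum_{n=1}^{10} |a_n| \cos\!\left(\frac{2\pi n t}{T} + \phi_n\right), \qquad
   a_n = \frac{2}{N}\sum_{t=0}^{N-1} s_t\, e^{-i 2\pi n t / N} . $$

Four index families summarize the beats of one recording, ten harmonics
each — the 40 indices:

* **Cₙ** — mean amplitude proportion, $100\,|a_n| / \sum_{k=1}^{10}|a_k|$
  (percent). Describes how pulse power distributes across frequency;
  low harmonics reflect transmission in the large arteries, high harmonics
  the peripheral bed.
* **CVₙ** — beat-to-beat coefficient of variation of the per-beat Cₙ
  (percent, sample SD). A pulse-shape stability index.
* **Pₙ** — mean phase angle (degrees), referenced to the beat foot, cosine
  convention.
* **Pₙ_SD** — beat-to-beat dispersion of the phase (degrees). With CVₙ,
  these "pulse-variability" indices respond to instability of the pulse
  transmission condition, e.g. under vascular perturbation.

HR and HR_CV (percent CV of foot-to-foot intervals, sample SD) complete the
per-recording profile.

### The pulse-variability score

For a subject measured at sessions M0 (pre) and M1 (post), the score is the
product of post/pre ratios of CV₂ and P₁_SD–P₅_SD — the six indices that
respond most strongly to vascular change:

$$ \text{score} = \prod_{j \in \{CV_2, P_{1..5,SD}\}} \frac{x_j^{M1}}{x_j^{M0}} .$$

Each index is already the per-recording aggregate over beats; no further
averaging is applied. The score is multiplicative (M0→M1 composed with
M1→M2 equals M0→M2) and inverts under session swap. Decisions use strict
inequalities — positive iff score > θ — and the two-threshold rule excludes
scores inside [low, high] as ambiguous, trading coverage for accuracy.
Threshold levels of 0.4, 17.1 and 40 are conventional reference points from
the motivating analysis; the package never optimizes thresholds.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `fs` | 500 | Hz | standard for tonometry; ≥ 25 samples per period of the 10th harmonic at 75 bpm. 250 Hz remains adequate (≥ 13 samples) and is used in the scaled-down tests. |
| `duration_s` | 60 | s | one-minute bedside recording, 60–90 beats |
| `rr_cv` | 0.025–0.055 per subject | fraction | reproduces the reported resting HR_CV of ≈ 3.5–4.5% |
| `amp_jitter_cv` | 0.05 | fraction | resting pulse-shape variability; yields CVₙ ≈ 5% |
| `phase_jitter_sd` | 5 | degrees | baseline phase dispersion; yields Pₙ_SD ≈ 5° |
| `noise_sd` | 0.01 | signal units (fundamental = 1) | sensor/quantization noise, 1% of the fundamental |
| `effect_post_phase_sd` | 2.0 | factor | vascular condition: phase dispersion inflated across all ten harmonics at M1 |
| `effect_post_high_harmonics` | 1.3 | factor | vascular condition: amplitudes of harmonics 6–10 raised at M1 (direction reported; magnitude not, 1.3 chosen once as a moderate effect) |
| score ε guard | 1e-9 | — | zero-dispersion synthetic denominators error out rather than clamp |

## What the generator emulates — and what it does not

`simulate_cohort()` produces paired (M0, M1) recordings for groups N (no
side effects), C (cardiac-only) and V (vascular-only). Each subject gets a
mildly perturbed copy of a canonical beat template whose amplitudes decay
monotonically (C₁ ≈ 46%) and whose phases come from a smooth single-upstroke
systolic waveshape; beats are drawn with truncated log-normal intervals
(0.33–1.5 s, i.e. 40–180 bpm), per-beat multiplicative amplitude jitter,
per-beat wrapped-normal phase jitter, and additive white noise. Group V
receives the vascular perturbation at M1; group C only a small
heart-rate-level shift (the reported cardiac-only group showed no harmonic
changes); group N none, so with effect factors at 1 the sessions are
exchangeable and log-scores center at 0.

The generator is a *statistical emulator of the indices*, not a hemodynamic
model: there is no Windkessel or transmission-line physics, no baseline
drift or motion artifacts, no respiratory modulation, no clinical-chemistry
simulation beyond binary labels, and the beat template is stationary within
a recording. A green end-to-end test therefore establishes that the pipeline
recovers known index structure and separates a stated effect size — not that
the score separates real patient groups.

## Numerical choices

* **Beat rendering.** The realized beat period is quantized to the sample
  grid (`N = round(fs·rr)` samples, period `N/fs`), so every rendered beat is
  exactly periodic on its own samples and the harmonic round trip is
  leakage-free by construction.
* **Foot detection.** Runs on a 0.5–40 Hz zero-phase (FFT brick-wall)
  conditioned copy; segmentation always cuts the raw samples so conditioning
  cannot bias Cₙ. Upstrokes are slope maxima at least 0.33 s apart; the foot
  is the intersecting-tangent point, computed with parabolic sub-sample
  refinement. The sub-sample remainder re-references each beat's phases to
  the true foot instant (phase n rotated by 360·n·frac/N degrees), removing
  the ±0.5-sample quantization that would otherwise dominate Pₙ_SD at high
  harmonics. A `method = "minimum"` fallback places the foot at the
  pre-upstroke minimum. Intervals outside 0.33–1.5 s or > 30% from the
  median are rejected (the artifact rule is this package's choice; none is
  prescribed in the field).
* **Cₙ normalization.** By the sum of harmonic amplitudes 1–10 (default),
  making "proportion" literal and Σ Cₙ = 100 exact; an `a₁`-normalized
  dialect is available (`cn_norm = "fundamental"`) since the field's
  normalization is not unique.
* **Phase statistics.** Circular mean and circular SD from the resultant
  length, $\sqrt{-2\ln R}$, which is wrap-safe at ±180° and equals the
  linear SD in the small-dispersion limit; a linear fallback
  (`phase_sd = "linear"`) is provided because "standard deviation of Pₙ"
  does not by itself specify the convention.
* **Sample SD (n−1)** everywhere: recordings hold only ~60–90 beats.
* **Degenerate inputs.** Constant beats (no harmonic content), all-excluded
  decision vectors, sub-3-beat recordings and zero denominators raise typed
  errors (`pulsevar_invalid_beat`, `pulsevar_empty_report`,
  `pulsevar_insufficient_beats`, `pulsevar_degenerate_score`) rather than
  returning NaN.
* **Ties** in the rank AUC count one half (mid-ranks).

## Design decisions taken where the design was open

* **Which session feeds the ML features** is not documented in the
  motivating analysis; both `pulse40` (one session's 40 indices) and
  `delta40` (M1-vs-M0 change features) are provided. In `delta40`, positive
  families (C, CV, P_SD) use log-ratios; phases use wrapped differences in
  degrees, because a circular, sign-indefinite quantity admits no log-ratio.
* **Classifier implementations.** LDA is `MASS::lda`; logistic regression is
  an L2-penalized IRLS fit (an unpenalized fit is unidentified on folds with
  more features than rows and separable classes — the standard library
  implementations this baseline mirrors are also L2-penalized by default).
  GNB, KNN (k = 5), linear SVM (averaged Pegasos), a single-hidden-layer MLP
  (8 units, full-batch gradient descent), CART (gini, depth 4) and a bagged
  forest of CARTs on random feature subspaces are compact in-package
  versions with fixed defaults; everything is deterministic given the seed.
* **Stratified folds** (plain threefold risks single-class folds at
  28-vs-11 imbalance); features are z-scored with training-fold statistics.
* **Single-operating-point AUC** — (sens + spec)/2 — is the reported AUC for
  threshold classifiers, reproducing the arithmetic behind published
  single-cutoff figures; the rank AUC serves continuous scores.
* **Band endpoints are excluded** (ambiguous): "score > θ" phrasing implies
  strict inequality, and exact boundary values have measure zero on a
  continuous score.

## Known limitations

* CVₙ recovery of the configured amplitude jitter is structural only for
  n ≥ 2: because C₁ contributes ≈ 46% of the shared normalization
  denominator, independent per-harmonic amplitude jitter partially cancels
  in C₁ (Var log C₁ ≈ cv²(1 − 2w₁ + Σw²) ≈ (0.6 cv)²). This is a property
  of proportions. The extracted CVₙ agrees with the CVₙ computed from the
  simulator's stored per-beat amplitude draws for all n.
* Amplitude and phase jitter genuinely move the waveform foot relative to
  the rendered beat boundary, so detector accuracy (±2 samples against the
  drawn rr sequence) is asserted under timing jitter and noise only, and
  harmonic round-trip/recovery tests use the simulator's exact segmentation
  (`true_beatset()`); the end-to-end discrimination test runs entirely on
  detected feet.
* Published accuracies of the real-cohort ML baseline depend on an
  unavailable cohort and are out of scope; on synthetic data the baseline is
  validated structurally (separable/null cases, determinism, LDA ranking
  high under a strong phase-dispersion effect).
* Real-data quality problems — drift, movement artifacts, ectopic beats —
  are only covered by the interval outlier rule, not simulated.
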