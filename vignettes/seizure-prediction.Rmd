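---
title: "CSP-based patient-specific seizure prediction: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CSP-based patient-specific seizure prediction: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cspseizure)
```

## The problem and the model

Seizure prediction rests on the hypothesis that a *preictal* brain state —
a transition between the normal interictal state and the seizure itself —
leaves a measurable signature in scalp EEG minutes before onset. This
package implements a patient-specific predictor built entirely on
second-order (spatial covariance) structure:

1. **Segmentation.** The multichannel recording is framed into overlapping
   epochs of length $L = 3$ s slid in 1 s steps (overlap $L - 1$ s). At
   256 Hz a 23-channel epoch is a $23 \times 768$ matrix.
2. **CSP spatial filtering.** Each epoch $D \in \mathbb{R}^{N \times L}$
   contributes a trace-normalized covariance
   $C = DD^\top / \mathrm{trace}(DD^\top)$. Class averages $C_1$ (preictal)
   and $C_2$ (interictal) are composed as $C_c = C_1 + C_2 = F_c \psi
   F_c^\top$, whitened with $P = \psi^{-1/2} F_c^\top$ (so $P C_c P^\top =
   I$), and the whitened class matrices $S_i = P C_i P^\top$ are
   simultaneously diagonalized: $S_i = U \Lambda_i U^\top$ with $\Lambda_1 +
   \Lambda_2 = I$. The projection matrix is $W = U^\top P$, rows sorted by
   descending preictal eigenvalue.
3. **Features.** An epoch is summarized by the natural log of the sample
   variance of each of the $N$ spatially filtered rows of $WX$ — the
   classical CSP log-variance feature, an $N$-vector.
4. **Classification.** A closed-form equal-prior linear discriminant
   ($w = S_p^{-1}(\mu_1 - \mu_0)$, boundary at the projected-mean midpoint)
   is trained on features balanced by random undersampling, and its binary
   output sequence (1 = preictal) is smoothed with a seventh-order median
   filter.
5. **Alarms.** An alarm is raised the first time a run of consecutive
   preictal decisions reaches a patient-specific threshold $\alpha$
   (seconds of run at 1 s steps); the run must break before another alarm
   can fire.
6. **Evaluation.** An alarm within the prediction horizon
   $[\text{onset} - H, \text{onset})$ (with $H$ = 60, 90 or 120 min) is
   positive; alarms inside ictal/postictal intervals or within 10 min of a
   coverage gap are discarded; the rest are false. Same-type alarms within
   one horizon of an earlier alarm count once. Sensitivity is the fraction
   of evaluable seizures with a positive alarm; specificity is
   $1 - \mathrm{fwt}/np$, where the false waiting time is the union of the
   windows opened by false alarms (alarm to end of horizon, clipped to the
   enclosing normal interval) and $np$ is the total normal-interval length;
   FPR is merged false alarms per evaluated hour; prediction time is the
   earliest positive alarm to onset. Periodic and Poisson predictors whose
   period/mean equals the patient's average interictal interval provide the
   chance floor.

### Corrections to the printed derivation

Two printed steps of the classical CSP derivation degenerate as stated:
a whitening $P = \psi^{-1} F_c^\top$ does not make $P C_c P^\top = I$, and
setting both whitened class matrices to $P C_c P^\top$ makes them
identical. This package uses the standard square-root whitening
$P = \psi^{-1/2} F_c^\top$ and $S_i = P C_i P^\top$; these are the only
forms under which the stated property $\Lambda_1 + \Lambda_2 = I$ holds,
and the test suite verifies that property to $10^{-8}$ on random SPD pairs
together with agreement between the fitted eigenvalues and an independent
generalized eigensolve of $(C_1, C_1 + C_2)$.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `window_s` | 3 s | epoch length |
| `step_s` | 1 s | epoch hop (overlap `window_s - step_s`) |
| `preictal_len_s` | 180 s | preictal training interval (180/300/600 s studied) |
| `preictal_offset_s` | 0 s | gap between that interval's end and onset (0/3600/7200 s) |
| `postictal_s` | 600 s | post-seizure exclusion |
| `gap_margin_s` | 600 s | discard margin around missing data |
| `horizon_s` | 3600 s | prediction horizon (3600/5400/7200 s) |
| `alpha` / `alpha_grid` | selected / {3,5,10,20,40,60,90,120} | run-length threshold in seconds |
| `shrinkage` | 1e-3 | LDA pooled-covariance pull toward its diagonal |
| `median_order` | 7 | median filter order |

Choices the source material leaves open, decided here once:

* **Feature log base**: natural log. Any base is a monotone rescaling that
  LDA absorbs; fixing one keeps fits reproducible.
* **LDA regularization**: the pooled covariance of 23-dimensional features
  estimated from a few hundred (undersampled) preictal epochs can be
  ill-conditioned; a 1e-3 diagonal shrinkage is a minimal, documented
  guard. Shrinkage 0 reproduces textbook LDA exactly (and is what the
  hand-solved test fixture uses).
* **Tie at the decision boundary** classifies as interictal — the
  conservative direction for an alarm system.
* **Median filter edges** are reflected (symmetric padding including the
  edge sample); truncation would bias the first and last three seconds
  toward zero.
* **Alarm trigger**: the printed rule ("sum of consecutive ones equals
  alpha with a moving 1 s window") is read as *first crossing of a run of
  length alpha, once per maximal run*; this is the only reading that
  produces a countable alarm series. Runs also break at record boundaries,
  since "consecutive seconds" is undefined across missing time.
* **Alpha selection** (the source states only that it comes from training
  data): highest training sensitivity, ties broken by lowest training FPR,
  then by the largest (most conservative) alpha. Selection happens per
  cross-validation round, inside the training fold.
* **Posthorizon length** for normal intervals is never given a number; it
  is set equal to the 10-minute postictal interval.
* **FPR denominator**: evaluated hours, i.e. coverage minus ictal,
  postictal and discarded-margin time — per-hour rates require a duration
  base, and this is the time during which a false alarm could have been
  scored.
* **Exclusion of seizures without enough preictal history** is interpreted
  as: less recorded coverage before onset than the configured preictal
  interval (plus offset).
* **Boundary normal intervals**: coverage start acts as a posthorizon end
  and coverage end as a horizon start, which is what makes the six-hour
  worked timeline give $np = 4$ h.

## Cross-validation protocol

`loocv_run()` holds out one recording per round. On the $N-1$ training
recordings it averages class covariances (preictal epochs from their
seizures; interictal epochs only from seizure-free recordings), fits CSP
and the discriminant on undersampled features, and — unless `alpha` is
fixed — selects `alpha` by splitting the training recordings into up to 5
inner folds, scoring each candidate on inner-fold alarm performance with
models fit on the remaining inner folds. All parameters are then frozen and
the held-out recording is scored. The held-out recording never enters
covariance averaging, LDA fitting, undersampling or alpha selection (the
report retains each round's training ids, and the tests assert the
separation). Sensitivity and prediction time average only over rounds whose
held-out recording contains an evaluable seizure; specificity and FPR only
where applicable ($np > 0$), mirroring the "not applicable" convention for
records a horizon fully covers.

The wording of the source protocol mixes leave-one-out with "5 folds"; the
reading implemented here uses the inner folds for threshold selection only,
refitting CSP/LDA on all $N-1$ recordings afterwards, because that is the
only arrangement in which all parameters "remain unchanged" during the
held-out evaluation.

## What the synthetic generator emulates — and what it does not

`make_state_covariances()` builds interictal/preictal covariance pairs
sharing a random orthogonal eigenbasis with log-spaced eigenvalues; the
preictal eigenvalues are scaled by $e^{s\,d_k}$, $d_k$ evenly spread over
$[-1, 1]$, so the generalized eigenvalues of the pair are exactly
$\mathrm{plogis}(s\,d_k)$: `separation` $s$ directly controls the contrast
CSP can exploit, and $s = 0$ makes the states identical.
`simulate_record_set()` lays seizures on a timeline, draws stationary
zero-mean Gaussian signal with the state's covariance (preictal within
`preictal_len_s` of each onset, a fixed 5x-variance burst during seizures —
ictal content is excluded from training and evaluation, so it only needs to
exist), splits coverage into recordings, and derives gaps.

The generator is deliberately minimal: no 1/f spectra, no alpha/beta
rhythms, no artifacts, no nonstationary drift, no gradual preictal onset.
CSP with log-variance features uses only stationary second-order spatial
structure, so the generator isolates exactly the signal property the method
depends on. Consequently, passing the synthetic recovery tests shows the
pipeline is *correct* (it recovers a known spatial-covariance contrast and
degrades to chance when none exists); it does not show that real scalp EEG
contains such a contrast, which only clinical corpora such as CHB-MIT can
establish. Reproducing the published per-patient tables requires
downloading that corpus (987.85 h); the CLI supports running on it, but it
is outside the desk-scale test surface.

## Numerical choices

* Covariance eigendecompositions use symmetric-matrix routines; eigenvector
  signs are fixed (first non-negligible coefficient positive) and eigenvalues
  sorted descending, so fits are bit-reproducible across runs.
* `fit_csp()` adds a ridge of $10^{-10}\,\mathrm{trace}(C_c)$ (with a
  message) when $C_c$'s condition number exceeds $10^{12}$.
* A zero-trace epoch, a zero-variance filtered row, an empty class and a
  singular pooled covariance at zero shrinkage are explicit errors, not
  silent NaNs.
* Time is in seconds on a per-patient global clock, intervals are half-open
  `[start, end)`, sample indices 0-based at the API boundary
  (`start_sample`), 1-based inside R matrices.
* All stochastic steps (generator, undersampling, Poisson baseline) draw
  from explicit seeds; cross-validation rounds derive per-round seeds from
  the configured base seed.
* Problem sizes used by the test suite — 6 recordings x 10 min at 8
  channels for end-to-end runs, dimensions 2–16 for eigenvalue properties —
  were chosen as the smallest sets at which the law-of-large-numbers and
  recovery checks are stable.

## Known limitations

* EDF support covers the plain 16-bit EDF used by CHB-MIT (one sampling
  rate across channels); EDF+ annotations, variable rates and resampling
  are out of scope, as are montage re-referencing and artifact rejection.
* Channel harmonization across a patient's recordings keeps the first
  recording's channel set and refuses recordings missing any of it.
* The preictal intervals of seizures clipped by record boundaries lose
  their uncovered epochs (they are dropped and counted, not shortened).
* `specificity` is undefined ($np = 0$) when horizons blanket an entire
  recording — common for 10-minute synthetic records under a 60-minute
  horizon; averages skip such rounds.
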