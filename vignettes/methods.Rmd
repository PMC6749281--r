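---
title: "Channel-selected filter-bank CSP: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Channel-selected filter-bank CSP: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fbcsp)
```

## The model

The package classifies two-class motor-imagery EEG epochs. Its working
assumption is the standard ERD/ERS picture: imagined movement suppresses
(or enhances) the power of band-limited sensorimotor rhythms in a small set
of cortical sources, which volume conduction spreads — linearly and
instantaneously — across scalp channels. Under that assumption the
class-relevant signal is (a) spatially sparse at the source level but
smeared at the sensor level, and (b) expressed as a *variance* change in a
narrow band rather than a mean change. Every stage of the pipeline follows
from those two points.

**Channel scoring.** Each channel's discriminability is summarized by the
Fisher ratio of its three time-domain parameters, the log-variances of the
signal and of its first and second discrete forward differences. These are
the log forms of the Hjorth activity/mobility/complexity descriptors:
cheap, variance-based (point (b)), and computed on 0.5–40 Hz
broadband-filtered epochs so no band choice is needed before any band is
selected. The Fisher ratio sums squared class-mean differences over the
three TDP types and divides by the summed within-class (population)
variances. The argmax channel is the *principle channel*; ties break to
the lowest index for reproducibility.

**Supporting set.** CSP needs more than one channel, and the most useful
companions of the principle channel are those that observe the same
sources. Volume conduction makes exactly those channels correlated, so the
supporting set keeps every channel whose class-mean per-trial Pearson
correlation with the principle channel reaches `rho_thr` in *both*
classes. The comparison is signed, not absolute: strongly anti-correlated
channels are excluded by construction. (Physiologically an
anti-correlated channel could carry the same source with inverted
polarity; admitting it via `|rho|` is a plausible variant, but the signed
rule is the definition implemented, and the threshold grid makes the
practical difference small.) The principle channel always belongs to the
set, since its self-correlation is identically 1. When fewer than two
channels survive, the fit stops with an error advising a lower threshold —
a deliberate hard failure rather than a silent fallback, because a
collapsed set means the threshold is incompatible with the data's
correlation structure.

**Per-band CSP and band selection.** Epochs restricted to the supporting
set pass through a bank of eight 4-Hz fourth-order Butterworth bands
covering 4–36 Hz. Within each band, trial covariances are
trace-normalized (`X Xᵀ / tr(X Xᵀ)`) so trials with different overall
power weigh equally, then averaged by class. One spatial filter pair per
band maximizes/minimizes the class variance ratio
`J(p) = pᵀĒ₁p / pᵀĒ₂p`, solved exactly as the symmetric-definite
generalized eigenproblem via Cholesky whitening. Bands are then ranked by
the mutual information between their two log-variance features and the
class label, and the best two bands' features form the final
4-dimensional vector. Keeping a single filter pair per band and exactly
two bands keeps the feature dimension at 4, which a linear maximum-margin
classifier (C = 1, features standardized by training statistics) handles
without regularization tuning.

**Mutual information estimator.** Band scoring uses Parzen-window
class-conditional densities (Gaussian kernel, Silverman's bandwidth
`1.06 s n^{-1/5}` per class) and estimates `I(f; class)` in bits as the
label entropy minus the mean posterior entropy at the sample points. The
band score is the sum over its two features: selection operates at the
band level, i.e. a band is kept or dropped as a whole, rather than
ranking individual features and pulling in partners. A constant feature
returns 0 bits rather than erroring, since "no information" is the honest
value. The estimator is intentionally simple: it is only ever used to
*rank* eight bands, where its known bias (smoothing slightly deflates MI
for overlapping classes) affects all bands alike.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `window` | 0.5–2.5 | s after cue | standard motor-imagery epoch; avoids cue-locked evoked activity and captures the sustained ERD |
| `broadband` | 0.5–40, order 4 | Hz | TDP/correlation path; wide enough for all three TDP types, excludes drift and line noise |
| `filterbank` | 8 × 4 Hz, 4–36 | Hz | covers theta–low-gamma; 4-Hz resolution separates mu from beta |
| `rho_grid` | 0.60–0.90 step 0.05 | — | spans "loose" to "near-duplicate" correlation regimes |
| `cv_folds`, `cv_repeats` | 5, 5 | — | 5×5 repeated stratified CV; small-sample-friendly |
| `cost` (C) | 1 | — | 4-dim standardized features rarely justify tuning or kernels |
| `erd_depth` (generator) | 0.6 | fraction | strong but not total band-power suppression |

## Numerical choices

- *Variance convention.* All variances are population-normalized
  (`1/n`); the choice cancels in correlations and only shifts log-variance
  features by a constant, but fixing it makes every value reproducible to
  the last bit.
- *Logs.* Natural log throughout; base changes no ordering (Fisher
  argmax, MI ranking) and no classifier decision.
- *Floors.* Variances are floored at `1e-12` before logs so constant or
  linear channels yield finite TDPs/features instead of `-Inf` poisoning
  an argmax. Degenerate channels (zero within-class TDP scatter) are
  excluded from principle-channel contention with a warning; only when
  every channel is degenerate does the fit fail.
- *Zero-phase filtering.* Bandpass is applied forward and backward
  (odd-reflection padding, steady-state initial conditions), because group
  delay would shift energy within a 2-s epoch. Epochs shorter than three
  filter lengths are rejected rather than padded; a padding policy would
  silently change features. Filtering precedes nothing label-dependent,
  so cross-validation precomputes it once per session without leakage.
- *CSP conditioning.* A ridge of `1e-10 · trace` is added to the
  denominator covariance when its condition number exceeds `1e10` — small
  supporting sets estimated from few trials can be near-singular. Filter
  signs are fixed (first nonzero component positive); features are
  sign-invariant, so this is pure determinism.
- *Tie-breaks.* Fisher argmax → lowest channel; band scores → lowest band
  index; inner-CV threshold ties → lowest threshold.

## Cross-validation protocol

Accuracy is estimated by 5 seeded repetitions of stratified 5-fold CV.
Within each outer training fold, `rho_thr` is chosen by an *inner*
stratified 5-fold grid search, so no held-out trial influences channel
selection, spatial filters, band choice, feature scaling or the
classifier. Grid values whose supporting set collapses are skipped; if the
inner winner collapses on the full outer fold, the next-ranked feasible
threshold is used. A constant-threshold mode (one fixed `rho_thr`) is also
exposed; the per-threshold table reported alongside nested results uses
it, mirroring how threshold sensitivity is usually tabulated. The
label-permutation null experiment uses constant-threshold mode
(`rho_thr = 0.7`): the chance-level property does not depend on how the
threshold is chosen, and the nested grid would multiply the cost of an
experiment whose expected answer is 50%.

## What the generator emulates — and what it does not

`simulate_session()` draws two-class sessions from the generative model
the pipeline assumes: each source channel carries 1/f background activity
plus a band-limited stochastic oscillation (filtered white noise, 8–12 Hz
by default); on the designated ERD sources the oscillation variance is
multiplied by `1 − erd_depth` in class-1 trials; sources are mixed by a
row-normalized exponential-falloff matrix `exp(−|a−b|/2)` emulating
volume conduction without electrode geometry; white sensor noise is added
after mixing. Each trial's oscillation is normalized to its exact target
variance, so the realized band power — not merely its expectation —
carries the class effect; ERD is a power modulation, and this keeps the
easy preset's class separation stable across seeds (≥ 3 pooled SDs in log
mu power on the strongest mixed ERD channel). The mu rhythm is given a
weaker amplitude (0.2 vs 1.0) on non-ERD sources, reflecting its focal
sensorimotor topography.

The generator deliberately omits: realistic leadfields and electrode
geometry, artifacts (EMG/EOG/movement), nonstationarity across a session,
multi-subject variability, and any relationship between channel index and
scalp position beyond "nearby indices mix more". Passing the recovery and
accuracy experiments therefore shows the pipeline is *correct* under its
own assumptions — linear mixing, band-limited variance modulation — not
that it attains any particular accuracy on real recordings, where those
assumptions are only approximately true.

## Problem sizes

The validation experiments use the easy preset (18 channels, 100
trials/class, 200 samples at 100 Hz): 100 seeded sessions for
channel/band recovery, one session for the 5×5 nested CV and the
20-permutation null, 50 random covariance pairs (sizes 2–5) against the
Monte-Carlo + quasi-Newton oracle for the CSP solver, and 1000 random
vector pairs for correlation exactness. Unit tests run the same code on
smaller sessions.

## Known limitations

- The broadband (0.5–40 Hz) filter feeds only the TDP/correlation path;
  the filter bank is applied to raw epochs. Cascading the broadband filter
  before the bank would double-filter the shared 4–36 Hz range; the bands
  outside 0.5–40 Hz are empty anyway at typical sampling rates.
- Per-trial correlations are computed on the broadband-filtered epochs —
  the same signals the TDPs see — rather than raw or per-band signals.
- One spatial filter pair per band is fitted, never more; extending to
  2m pairs would change the feature dimension contract.
- The supporting-set rule uses signed correlations (see above).
- With very few trials per class the inner threshold search becomes
  noisy before the outer estimate does; constant-threshold mode is the
  safer choice below roughly 15 trials per class per fold.
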