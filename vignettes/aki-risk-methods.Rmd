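---
title: "Methods: real-time AKI risk prediction on synthetic EHR streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: real-time AKI risk prediction on synthetic EHR streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(akirisk)
```

## The problem

Severe acute kidney injury (AKI, KDIGO stage 2 or 3) is a frequent and
dangerous complication after cardiothoracic surgery. Its two defining
signals -- a doubling of serum creatinine over a pre-operative baseline,
and urine output falling below 0.5 ml/kg/h for at least 12 hours -- arrive
late, irregularly, and buried in a high-dimensional postoperative data
stream. `akirisk` implements a complete, testable pipeline for this
setting: it labels admissions against the KDIGO stage-2/3 criteria,
turns irregular multichannel streams into a regular 15-minute feature
grid, trains a small recurrent model that re-estimates the 7-day AKI risk
every 15 minutes, and evaluates those per-step predictions with
statistics that respect their within-patient correlation. Because real
perioperative EHR data are protected health information, the package
ships a seeded synthetic cohort generator that reproduces the
*statistical structure* the analysis depends on, so every stage is
exercised end-to-end without any data download.

## KDIGO labeling

**Baseline creatinine** is the last value within the 120 h before the
start of surgery; if none exists, the first postoperative value is used
and the fallback is flagged. Admissions with no creatinine and no urine
data, dialysis before the end of surgery, baseline creatinine >= 4.0
mg/dl, or age under 18 are *excluded* -- a distinct outcome from a
negative label, carried with a reason code and never admitted to
training.

**Creatinine criterion.** Onset is the earliest *measurement* at or above
twice baseline within the 7-day study period after surgery end; values
are never interpolated, because a diagnosis exists only when a lab value
does. Stage-3 features (>= 3x baseline or >= 4.0 mg/dl) are recorded as
an informational hint only; the composite stage >= 2 label is the
prediction target.

**Urine criterion.** Flow records (ml/h as charted) are divided by the
admission weight and held as a step function between records, with a
maximum carry of 2 h -- longer charting gaps make a window ineligible
rather than partially evaluated. Onset is the earliest time `t` on the
15-minute grid such that the rate stays below 0.5 ml/kg/h throughout
`[t - 12 h, t]`, the window is fully covered by records, and it lies
entirely within locations where urine charting is reliable (theatre,
recovery room, ICU -- not the normal ward, where incomplete documentation
would manufacture false positives). We deliberately use
*sustained-below* semantics rather than a rolling 12-h mean: under mean
semantics a deep sub-12-h dip (say 11 h at 0.35 ml/kg/h) would fire the
criterion even though oliguria was never sustained for 12 hours, which
contradicts the clinical definition "< 0.5 ml/kg/h for >= 12 h". The
trade-off is sensitivity to a single spuriously high record inside a low
episode; hourly charting with step-carry makes such spikes visible and
rare in practice, and the choice is what makes an 11-hour dip negative
*by definition*. Raising the threshold can never remove an onset and
lowering it can never create one (tested as a property).

**Windows and matching.** The observation window runs from the first
postoperative ICU/recovery transfer to the earliest of discharge, AKI
onset, and 7 days after surgery end; AKI windows end exactly at onset, so
no post-onset information can leak downstream. Controls are matched 1:1
to cases on window length by greedy nearest-neighbour without
replacement, processing cases in descending length (long controls are
the scarce resource) with identifier tie-breaks for determinism.

## The synthetic cohort generator

The generator plants a scenario per admission -- outcome, criterion,
onset offset, hard-negative type -- and then builds trajectories that
satisfy or provably violate the criteria:

* creatinine cases ramp below 1.85x baseline before the planted onset
  and cross 2x exactly at it, with multiplicative noise clamped so the
  crossing time is exact to the measurement;
* urine cases embed an episode at a rate drawn from the configured
  oliguria band that lasts exactly 12 h before the planted onset (the
  labeler recovers it to within one 15-min grid step);
* dual-criterion cases add a creatinine onset lagging the urine onset by
  a lognormal delay with median 14 h (sdlog 1.05, matching an
  interquartile spread of roughly 6-27 h);
* hard negatives include deep oliguric dips shorter than 12 h,
  ward-only oliguria (masked by the reliable-location rule), and
  sub-doubling creatinine rises to 1.45-1.6x baseline.

Defaults are the study conditions: a balanced cohort (planted AKI
fraction 0.5, exact up to rounding), criterion mix 70%
creatinine-only / 12% urine-only / 18% both (so ~30% of cases involve
the urine criterion), onset times lognormal with median 30 h after
surgery, and control discharge offsets drawn from the same distribution
so matching on observation length is feasible. AKI cases additionally
shift the means of a configurable number of informative channels (and of
MAP and lactate) by a configurable effect size from shortly after
surgery, giving the model a learnable signal at desk scale; pure-noise
channels are added alongside. Everything is a pure function of the
configuration seed.

What the generator does *not* emulate -- and what passing tests therefore
do not show about real data: pharmacokinetics (drug administrations are
memoryless Poisson events, as the analysis itself treats them),
physiological feedback between channels, documentation artefacts beyond
location-dependent urine reliability, and distribution shift between
training and deployment. A high AUC on these cohorts demonstrates that
the pipeline recovers a signal it was guaranteed to contain, not that
the clinical problem is this easy.

## Preprocessing

Each admission becomes a 15-minute grid anchored at the window start
(the start point is step 0, so a 24-h window has 97 steps). A channel's
value at a grid point is the last raw observation at or before it;
remaining gaps are forward-filled and leading gaps take a per-channel
clinical default (an editable CSV; synthetic channels default to their
generative mean). Continuous features are scaled as
`(X - median) / IQR`, with median and IQR pooled over all time steps of
all *training* admissions (linear-interpolation quantiles, R type 7);
features with IQR = 0 are flagged and centred only. Operation-type
probabilities, binary drug indicators and sex pass through unscaled.
Drug administrations set a binary channel to 1 at the single grid step
strictly after the dose. The per-step supervised target is the
admission's global label, constant across the sequence: the evaluation
scores every step against that label, and training mirrors the
evaluation.

Surgery descriptions are handled by 17 independent L2-regularised
bag-of-words logistic regressions (one per surgery type) on word-count
features over the training vocabulary; their 17 probabilities -- not
normalised across types -- are broadcast as static features. The ridge
penalty defaults to `3e-5`: weak enough that a genuinely separating
template token drives its type probability above 0.9, strong enough to
keep perfectly separating vocabularies finite. Both the scaler and the
text model record a hash of what they were fitted on, and the pipeline
refuses components whose provenance does not match the training split.

## The risk model

The model is a single-layer recurrent network (GRU by default, tanh cell
as alternative) with a per-step sigmoid readout, written against a
minimal C++ core (full backpropagation through time, Adam at the fixed
learning rate 0.001, gradient-norm clipping at 5, sequence-level
updates). The shipped candidate space -- cell in {gru, rnn}, hidden
width in {8, 16}, depth 1, no convolutional front-end -- is a desk-scale
design choice that keeps the hand-written gradient auditable; the axes,
not these particular values, are what the procedure fixes.
Hyperparameters are selected by five-fold cross-validation at admission
level (folds stratified by label, matched pairs never split), scored by
the AUC of all pooled out-of-fold per-step predictions -- we pool steps
rather than averaging per-patient AUCs, and the out-of-fold predictions
of the winner are reused for threshold calibration. The final predictor
is a uniform ensemble (10 members in the reference design, 3 in the
desk-scale default) of models sharing hyperparameters but differing in
initialisation seed, validation slice and data order.

Two training details matter for honest evaluation. First, the readout
layer initialises at zero, so an untrained model predicts exactly 0.5:
without label signal, training has nothing to move it away from the
constant predictor. Second, the label-shuffle null is trained *without*
early stopping: an early-stopped null model stays near-constant, and the
rank-based AUC then amplifies its residual initialisation noise into
spurious extreme values; trained to convergence, the null model's
predictions genuinely reflect the permuted labels and its held-out AUC
concentrates on chance level. Even so, a single permutation's null AUC
carries a sampling error of several points at desk scale (per-step
predictions are almost perfectly clustered within patients, so the
effective n is the number of test patients); the acceptance suite
therefore compares the learned signal against the *mean* null over five
permutations rather than demanding each permutation land in a narrow
band.

The decision threshold is the largest cut-point whose pooled
out-of-fold sensitivity still reaches the 0.85 target -- equivalently the
`ceiling(0.85 * n_pos)`-th largest positive prediction -- which buys the
best specificity compatible with the sensitivity floor.

## Evaluation

Per-step predictions from one patient are highly correlated, so every
metric's 95% CI uses the design effect: with cluster sizes `m_i`,
intracluster correlation ICC, `DE = (mbar k) / sum_i m_i / (1 + (m_i -
1) ICC)`, `n_eff = n / DE`, `SE = sqrt(X (1 - X) / n_eff)` and `X +/-
1.96 SE` (1.96 verbatim, clipped to [0, 1]). The ICC is the one-way
random-effects ANOVA estimator on the per-step *correctness indicator*
(prediction-at-threshold vs label), reused for all metrics of a report;
the per-step squared error is available as an alternative ICC variable
by argument. Applying the same binomial-style CI to AUC and PR_AUC is a
convention, not a theorem -- AUC is not a proportion of independent
trials -- and the report metadata says so.

The mean per-patient Brier score normalises within each patient first,
making it independent of observation length; a constant 0.5 predictor
scores exactly 0.25. The predictive-quality score is `S = r` for events
and `1 - r` for non-events, compared between predictors by a paired
t-test; the transform `X = -log(-log(S))` (S clipped to `[1e-6, 1 -
1e-6]`, where the transform diverges) is provided for normality-based
planning. Correlated ROC curves are compared with DeLong's test (via
pROC, with a paired bootstrap as the independent oracle in the test
suite). Hosmer-Lemeshow calibration uses equal-frequency decile bins and
reports df = g - 2 = 8 by default -- the convention appropriate when the
probabilities come from a model fitted on the same data, and the one
this package reports; for externally supplied probabilities (validation
samples, simulations with known true risks) the statistic is
approximately chi-square with g degrees of freedom, and
`reference = "validation"` makes the p value uniform under perfect
calibration. Both references are exposed because the difference is not
cosmetic: under a calibrated simulation the development reference
over-rejects threefold.

For the head-to-head harness, one prediction point per test admission is
drawn quasi-randomly: base-2 radical-inverse fractions (0, 1/2, 1/4,
3/4, ...) with a seed-derived rotation, mapped onto each admission's
window and snapped to the grid. Low-discrepancy fractions cannot
concentrate in, say, the first half of every stay, which a uniform
random draw occasionally does. Results are stratified by time to event
into half-open bins [0,2), [2,6), [6,12), [12,24), [24,48), [48,168]
hours (lower bound inclusive; a convention is required because printed
bin edges touch). With one point per patient there is no clustering and
`n_eff = n`. The comparator arm is configurable: a degraded copy of the
model (predictions shrunk toward 0.5 plus noise) by default, or a
reduced model trained on the creatinine channel alone.

## Numerical and design choices

* Quantiles everywhere are linear-interpolation (R type 7).
* IQR = 0 features are centred, not divided.
* Grid step counts include the window start point.
* Ties in matching, fold dealing and candidate selection break by
  identifier or list order -- never by RNG state.
* A 12-h oliguric window may extend back before the study start (into
  theatre time); the onset itself must lie inside the study period. How
  a window straddling the 7-day boundary should count is genuinely
  ambiguous; we require onset <= 168 h.
* Thresholds at the boundary of (0, 1) are shifted inward by 1e-6.
* All seeds derive from a single configuration seed through a hash-based
  stream splitter, so every stage is independently reproducible and no
  seed exceeds 2^31.

## Problem sizes

The test suite runs at sizes chosen to exercise every property while
staying desk-scale: 60-admission fixtures for unit tests, a
500-admission cohort for label-recovery statistics (binomial and
quantile sampling tolerances are derived at that n), a 300-admission
cohort with a 70/30 split, 3-member ensembles and five training seeds
for signal-vs-null model checks, 200 replicates of n = 5000 for
calibration operating characteristics, and 2000 bootstrap replicates for
the DeLong cross-check. The end-to-end experiment default
(`experiment_config()`) is 300 admissions with a 3-member ensemble.

## Known limitations

The recurrent core is intentionally small (no stacking, no attention,
no convolutional front-end, sequence-level updates); it is sized for the
synthetic cohorts it ships with, not for hospital-scale data. The
physician arm of the original comparison cannot be reproduced -- the
harness accepts any second predictor satisfying the comparator
interface, and the shipped comparators are stand-ins that exercise the
statistics, not models of clinician behaviour. The clinical default
table is an editable convention, not expert-elicited values. And all
headline performance numbers in this package's tests are statements
about engineered synthetic cohorts.
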