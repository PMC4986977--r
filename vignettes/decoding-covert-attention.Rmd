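---
title: "Decoding the locus of covert visuospatial attention from lateralized ERPs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding the locus of covert visuospatial attention from lateralized ERPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erpdecode)
```

## The problem

Covert visuospatial attention — attending a peripheral location while the
eyes stay on fixation — leaves a measurable trace in the EEG. When a
stimulus in one hemifield is attended, posterior electrodes contralateral
to it become transiently more negative than their ipsilateral homologues:
an early selection-related negativity (the N2pc, roughly 180--280 ms after
the orienting event) followed by a sustained posterior contralateral
negativity (SPCN, from about 300 ms). Attended stimuli also evoke larger
contralateral positivities (e.g. an enhanced contralateral P1). The
left-minus-right difference wave of a homologous electrode pair (PO7
minus PO8, O1 minus O2, PO3 minus PO4) isolates these lateralized
components from activity common to both hemispheres.

`erpdecode` asks how far such difference waves can localize the focus of
attention beyond a coarse left/right judgement. The task it models is a
modified Posner paradigm: four letter locations arrayed left to right on
the horizontal midline (two per hemifield, adjacent locations 0.88
degrees apart), a 250 ms endogenous grid cue at one of them, a uniform
450--550 ms delay, then each of the four letters flashed twice for 33 ms
(at least 17 ms between a letter's flashes) inside a 200 ms window. Each
location is cued equally often, in random order.

## The decoding model

Each subject contributes one 12-dimensional feature vector per cued
location: mean amplitudes of the three lateralized difference waves over
two cue-locked windows (170--270 ms, within the N2pc range, and 650--840
ms, within the SPCN) and two target-locked windows (0--100 ms and
410--530 ms after the flashes of the letter at the cued location, both
flashes pooled into one average). Windows are half-open
`[onset, offset)`, sharing the epoch convention.

The four locations are decoded with a *dendrogram SVM*: ascending
hierarchical clustering of the class centroids (Ward criterion on
standardized features) yields a binary decision tree with three internal
nodes for four classes; a binary SVM with a quadratic kernel (polynomial
degree 2, `coef0 = 1`, `gamma = 1/12`, `C = 1`) is trained at each node
on the training samples of that node's classes, labelled by side. A test
vector descends the tree, one binary decision per node. On the hemifield
geometry of this task the tree reproducibly splits left-hemifield
locations {1,2} from right-hemifield locations {3,4} at the root, then
separates the members of each pair.

Performance is estimated by leave-one-subject-out cross-validation: the
tree, the node SVMs and the feature standardization are refitted on all
subjects but one, and the held-out subject's four rows are predicted;
with 15 subjects the procedure runs 15 folds and aggregates 60
predictions. Accuracies are displayed truncated to whole percent
(10 of 15 correct displays as 66%) while full precision is retained
internally.

Beyond raw accuracy, the row-normalized confusion matrix
$p_{ij}$ (proportion of actual location $i$ classified as $j$) gives a
spatial error measure,
$$D = \frac{1}{4}\sum_{i,j=1}^{4} p_{ij}\,|i-j|,$$
the mean predicted-vs-actual distance in letter positions, converted to
visual angle by the 0.88-degree horizontal spacing (a uniform matrix
gives $D = 1.25$; $D = 0.62$ corresponds to 0.55 degrees).

Two significance devices accompany the accuracies, because theoretical
chance (25% for four classes, 50% for the binary task) is an unreliable
benchmark at small n: an exact binomial threshold (the smallest $k/n$
with $P(X \ge k) < \alpha$ under $X \sim \mathrm{Bin}(n, 1/4)$; for
$n = 15$ and $\alpha = .05$ this is 8 of 15, 53.3%) and a permutation
test that shuffles location labels *within* subject, re-runs the entire
LOSO pipeline per permutation, and reports the add-one estimator
$p = (1 + \#\{DA_\pi \ge DA_{obs}\})/(B+1)$, which can never return 0.

Two companion analyses complete the evaluation: a binary quadratic SVM
decides whether a flashed letter was at the attended location (attended
means cue location = letter location, 1 of 4 pairings by design, handled
with inverse-frequency class weights), and an ocular-confound control
splits subjects on their lateralized HEOG amplitude 500 ms after cue
onset (the 5 of 15 largest movers vs the remaining 10; `ceiling(n/3)`
otherwise) and repeats the decoding on the low-movement group alone.

## What the synthetic data emulate

No public recordings accompany this paradigm, so the package ships a
generator that renders the study design into continuous multi-channel
EEG with known ground truth:

* **Schedule**: exactly balanced cued locations in random order; all
  cue/delay/flash timing drawn per the task's constraints
  (`generate_schedule()` exposes every onset for testing).
* **Components**: half-cosine-windowed boxcars added to the electrode of
  each pair contralateral to the relevant hemifield — cue-locked early
  (170--270 ms, N2pc-like) and late (400--840 ms, SPCN-like) negativities
  and target-locked early (0--130 ms) and late (400--540 ms) positivities.
  Amplitudes are per-location, eccentricity-graded (outer locations get
  `ecc_factor` times the base amplitude, default 1.5), and sign-mirrored
  across hemifields, so the left-minus-right difference is positive for
  left-hemifield negativity components and negative for right-hemifield
  ones. Letters flashed at uncued locations evoke the same components
  scaled by `unattended_scale` (default 0.2).
* **Noise**: pink (1/f-amplitude) Gaussian noise per channel, default
  10 µV on EEG channels — a spectrum that loads the 0.1 Hz high-pass
  far more realistically than white noise. Mastoids carry near-zero
  reference noise so re-referencing is genuinely exercised.
* **Artifacts**: injectable blink templates (raised-cosine VEOG
  deflection, 200 ms, with 10% leakage into EEG channels) and saccade
  templates (step-like HEOG deflection, 30 ms rise / 400 ms hold), each
  logged with onset and kind so rejection recall can be scored exactly.
* **Determinism**: every function takes one seed; the study driver
  derives subject-level seeds as `seed + 7919*i + {0,1,2}` (schedule,
  noise, artifacts).

What the generator does *not* emulate matters for interpreting green
tests: there is no volume-conducted correlation between channels, no
trial-to-trial latency or amplitude variability beyond additive noise,
no alpha rhythm or slow drifts beyond 1/f, and components are identical
across subjects up to the configured amplitudes. Passing the recovery
suite therefore shows the pipeline is *correct* (it recovers what was
put in, at the SNR put in), not that real recordings would yield any
particular accuracy; the published real-data accuracies (57% four-class,
79% binary) are qualitative reference points that cannot be reproduced
without the original recordings.

## Preprocessing choices

The preprocessing chain follows standard ERP practice; where the
operational definition was open, the package fixes it as follows:

* **Filters**: zero-phase (forward--backward) 4th-order Butterworth
  sections, high-pass then low-pass; EEG band 0.1--30 Hz, EOG band
  0.1--10 Hz. Cut-offs are the -3 dB points of a single pass.
* **Re-referencing** subtracts the averaged mastoids from EEG channels
  only; EOG channels are bipolar derivations and stay untouched.
* **Epochs** are half-open `[-200, 800)` ms windows, `t = 0` at the
  event sample, 512 samples at 512 Hz; the baseline is the mean over
  `[-200, 0)` per channel. Events whose windows overlap a recording
  edge are dropped (never zero-padded), with a warning.
* **"Deflection within a time window"** is implemented as max-minus-min
  (peak-to-peak) over a sliding window of the stated length, stepped one
  sample at a time: > 50 µV on VEOG within 150 ms rejects as a blink,
  > 35 µV on HEOG within 300 ms as an eye movement, and any EEG sample
  beyond ±100 µV as an absolute-limit violation, checked in that order.
  All comparisons are strict (`>`), as printed; the absolute rule applies
  to EEG channels only. Subjects are excluded when their rejection rate
  reaches 30%.

## Classifier choices

* **Linkage/metric**: Ward cost on Euclidean distances between
  class-mean standardized feature vectors. The agglomeration is written
  out in the package (about thirty lines) rather than delegated, because
  degenerate inputs need a defined tie-break: candidate merges are
  scanned in order of their smallest class index and only a strictly
  smaller cost displaces the incumbent, so exact ties (e.g. four
  identical centroids) merge lowest-index-first and still yield a valid
  three-node tree. On tie-free data the topology matches
  `stats::hclust` Ward clustering, which the tests use as an
  independent oracle.
* **"Quadratic" kernel** is read as a degree-2 polynomial kernel
  (`coef0 = 1`), the usual meaning of "quadratic SVM"; an RBF kernel is
  available via `kernel = "rbf"`. Hyperparameters are fixed and logged:
  `C = 1`, `gamma = 1/n_features`.
* **Standardization** (zero mean, unit variance) is fitted on training
  folds only — the held-out subject never influences the scaling, the
  tree, or the node SVMs. The dendrogram is likewise rebuilt inside each
  training fold by default (`rebuild_tree = FALSE` reuses one tree,
  trading a small leakage for stability).
* **Determinism**: training rows are sorted (class, then feature values)
  before fitting, so permuting input order cannot change the model.

## Numerical and statistical choices

* The binomial threshold uses exact tail summation of
  `dbinom`; note that a threshold of 0 correct is unattainable for any
  `alpha < 1` since $P(X \ge 0) = 1$.
* The permutation p-value with few permutations is discrete and, when
  permuted accuracies tie the observed one, conservative; the null
  calibration in the test suite (200 replicate null studies of 8
  subjects, 19 permutations each) shows the p-value distribution is
  mildly conservative but consistent with uniformity at the 1% level,
  and valid in the sense $P(p \le \alpha) \le \alpha$ plus simulation
  tolerance.
* Confusion rows with zero support are reported as undefined (`NaN`) and
  flagged, never silently zero-filled; the distance statistic refuses
  non-normalized matrices.
* The per-subject accounting ambiguity — 15 folds each "correct or
  incorrect" versus a 60-cell confusion matrix — is resolved by emitting
  both: the 60-prediction accuracy (which equals the confusion-matrix
  diagonal mean) and a per-subject majority-correct tally
  (`subject_majority_pct` in the report). Neither is asserted as the
  canonical one.

## Problem sizes in the tests

The test suite and the acceptance script run the full EEG pipeline at
reduced trial counts (8--60 trials per subject instead of the design's
600) and keep the 600-trial default for schedule-level checks; at the
SNRs used, subject-average features stabilize well below 600 trials and
the statistical behaviour under test (recovery, chance levels,
rejection recall, fold structure) is unchanged. Two regimes bracket the
recovery property: a high-SNR condition (1 µV pink noise against 1--3 µV
components) where four-class LOSO accuracy is expected at 90% or above,
and a zero-signal condition (all amplitudes 0) whose accuracy must fall
inside the exact 95% binomial band around 25%.

The eccentricity-ordering property (outer locations classified more
accurately than inner ones, as observed in real data) deserves a note:
with amplitudes graded by the default factor 1.5, a one-axis hemifield
code actually makes the *outer* classes harder (their nearest-neighbour
gap is `0.5a` against `2a` for the inner pair) — that grading instead
reproduces the dendrogram geometry, where {1,2} and {3,4} are the close
pairs. The ordering test therefore grades amplitudes by factor 4,
approximately proportional to the letters' true eccentricities (the four
positions sit at -3, -1, +1, +3 horizontal half-gaps from fixation),
under which inner locations are both lower-amplitude and flanked by two
near neighbours, and the outer-better ordering emerges robustly.

## Worked example

```{r example, eval = FALSE}
library(erpdecode)

study <- simulate_study(
  n_subjects = 15,
  design = task_design(n_blocks = 2, trials_per_block = 30),
  truth = ground_truth(noise_sd_uv = 8, eog_noise_sd_uv = 4),
  seed = 42)

report <- decode_study(study$features, n_permutations = 199, seed = 42,
                       heog = study$heog)
report
```

## Known limitations

* Single-trial decoding is out of scope: features are subject-level
  averages, so the sample size for classification equals the number of
  subjects times four.
* The generator's independence assumptions (no channel covariance, no
  latency jitter) make high-SNR decoding easier than on real data;
  accuracies on synthetic data are diagnostics, not forecasts.
* Oscillatory (spectral-power) features and ROC/AUC-based evaluation
  are deliberately not implemented.
* Recordings and epochs live in memory; on-disk interchange is the
  feature CSV, event-log and rejection-log TSVs.
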