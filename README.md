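# erpdecode

Decoding the locus of covert visuospatial attention from lateralized
event-related potentials (ERPs).

## What this package is for

When attention is covertly directed to a peripheral location, posterior
EEG electrodes contralateral to that location develop characteristic
lateralized components: an early selection negativity (N2pc), a
sustained posterior contralateral negativity (SPCN), and enhanced
contralateral positivities to stimuli flashed at the attended place.
`erpdecode` implements, end to end, a pipeline that asks how precisely
these signals localize the focus of attention among **four** horizontal
locations (two per hemifield) in a modified Posner cueing task — going
beyond the classic left-vs-right dichotomy — and whether they reveal if
a given flashed letter was attended at all.

It is written for cognitive-neuroscience and BCI researchers who want a
reproducible, fully testable reference implementation: because no public
recordings exist for this paradigm, the package includes a synthetic-EEG
generator that renders the exact task design (balanced cues, 250 ms cue,
450–550 ms delay, double 33 ms letter flashes in a 200 ms window, 512 Hz
sampling) with known ground-truth lateralized components, so every
downstream stage is verifiable against what was put in.

## The method in brief

1. **Preprocessing** — averaged-mastoid re-reference; zero-phase
   Butterworth band-pass (EEG 0.1–30 Hz, EOG 0.1–10 Hz); epochs
   [−200, 800) ms, baseline [−200, 0); rejection of blinks (VEOG
   peak-to-peak > 50 µV within 150 ms), eye movements (HEOG > 35 µV
   within 300 ms) and absolute excursions (EEG > ±100 µV); subjects with
   ≥ 30% rejected epochs excluded.
2. **Features** — per subject × cued location, mean amplitudes of the
   left-minus-right difference waves (PO7−PO8, O1−O2, PO3−PO4) over two
   cue-locked windows (170–270, 650–840 ms) and two target-locked
   windows (0–100, 410–530 ms): 2 × 3 × 2 = **12 features**.
3. **Dendrogram SVM (DSVM)** — ascending hierarchical clustering of
   class centroids (Ward) builds a binary decision tree (for this
   geometry: [1,2] vs [3,4], then 1 vs 2 and 3 vs 4); a quadratic-kernel
   binary SVM is trained at each node; prediction descends the tree.
4. **Evaluation** — leave-one-subject-out cross-validation; decoding
   accuracy DA (displayed truncated: 10/15 → 66%); row-normalized
   confusion matrix; mean letter-position distance
   *D* = ¼ Σᵢⱼ pᵢⱼ·|i−j| with conversion to degrees (× 0.88°/position);
   exact binomial significance thresholds; within-subject label
   permutation test; 12 single-feature decodings; binary
   attended-vs-unattended SVM; HEOG ocular-confound subgroup analysis.

## Worked example

```r
library(erpdecode)

study <- simulate_study(
  n_subjects = 15,
  design = task_design(n_blocks = 2, trials_per_block = 30),
  truth = ground_truth(noise_sd_uv = 8, eog_noise_sd_uv = 4),
  seed = 42, heog_drift_uv = seq(0, 7, length.out = 15))

report <- decode_study(study$features, n_permutations = 199, seed = 42,
                       heog = study$heog)
report
```

```
Four-class decoding report (15 subjects, 15 LOSO folds)
  decoding accuracy: 71% (71.67%; chance 25%)
  per-subject majority-correct: 67%
Confusion matrix (rows = actual, row-normalized):
      predicted
actual    1    2    3    4
     1 0.67 0.33 0.00 0.00
     2 0.40 0.60 0.00 0.00
     3 0.00 0.00 0.73 0.27
     4 0.00 0.00 0.13 0.87
mean distance D = 0.28 letter positions (0.25 deg)
  binomial thresholds: 53.3% (p<.05), 60.0% (p<.01)
observed DA = 71.7%, permutation p = 0.005 (B = 199)
  low-HEOG subgroup (n = 10) DA: 57.5%
```

Reading this: at this synthetic signal-to-noise ratio the classifier
assigns 43 of the 60 held-out (subject × location) averages to the
correct one of four locations (71.67%, displayed 71%); errors stay
within the correct hemifield (no cross-midline confusion), so the mean
spatial error is 0.28 letter positions ≈ 0.25° of visual angle; the
accuracy clears the exact binomial p < .01 criterion for 15 subjects
and the within-subject permutation test floors at p = 1/(B+1) = 0.005;
restricting to the ten subjects with the smallest lateralized HEOG
(i.e. the least residual eye movement) still decodes at 57.5%, so the
signal is not an ocular artifact.

The methods vignette
(`vignettes/decoding-covert-attention.Rmd`) documents the model, every
tunable parameter, and what the synthetic generator does and does not
emulate.

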