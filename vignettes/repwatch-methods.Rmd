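---
title: "Recognizing exercises and counting repetitions from smartwatch inertial streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognizing exercises and counting repetitions from smartwatch inertial streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

A person wears two smartwatches — one on the wrist, one on the ankle — while
performing full-body exercises (push-ups, pull-ups, burpees, kettlebell
lifts, box jumps, squats, sit-ups, wall balls; codes `E1`..`E10`). Each watch
records three sensors (accelerometer in m/s², gyroscope in rad/s, and a
software orientation sensor) at roughly 100 Hz with irregular timestamps.
`repwatch` answers two questions from these raw streams alone, with no
feature engineering:

1. **Which exercise is being performed at every point in time?** (including
   a *null* class for sitting, standing and walking between sets), and
2. **How many repetitions were performed in each recognized set?**

Training data come from *constrained* workouts: the wrist watch vibrates at
the start of every repetition, so repetition-start times (and hence set
labels and counts) are recorded automatically without video annotation.

## Pipeline

### From raw streams to the 18-channel matrix

Each sensor stream is resampled by per-axis linear interpolation onto a
uniform 100 Hz grid (the nominal rate of the watches). Linear interpolation
is exact on signals that are linear between raw samples, which the tests
exploit; no low-pass filtering or drift compensation is applied — the
networks consume raw signals. The grid runs from the latest first-timestamp
to the earliest last-timestamp of the selected streams so that no
extrapolation ever occurs. The resampled axes are stacked column-wise in a
fixed canonical order — wrist before ankle; accelerometer, gyroscope,
orientation; axes x, y, z — giving 3 channels per sensor and 18 channels
when both watches are used. The canonical order is a package convention (any
fixed order works); what matters is that the three axes of one sensor stay
contiguous, because the first convolution strides across the channel axis in
steps of 3 and must never mix axes of different sensors.

### Windowing

Recognition operates on windows of `T = 4` s (`W = 400` samples). At test
time consecutive windows overlap by a factor `gamma` (default 0.95); the
stride in samples is `max(1, round(W * (1 - gamma)))`. Trailing samples
shorter than one window are dropped rather than padded. A training window is
labeled with the exercise whose set covers the majority (> 50%) of its
samples, and with *null* otherwise; coverage ties go to the earlier set.

### The network

One convolutional architecture serves both tasks. The default recognition
configuration: five convolutional layers with
100/75/25/25/75 filters, a (15, 3) first kernel applied with vertical stride
3, (15, 1) kernels with stride 1 in deeper layers, valid padding, no
pooling, ReLU activations, dropout 0.5 on the flattened features and dense
activations, one dense hidden layer of 128 units, and a softmax output.
Dense widths, padding and pooling were open details; the defaults here are
the package's choices and are configurable through `model_spec()`. The
commonly tuned counting-model variants — input
standardization, elu activations, two extra dense layers — are exposed as
switches; batch normalization is not implemented. The "stacked W×18 image"
versus "W×3×6 grouped" input formulations are mathematically identical under
the stride-3 first kernel, so the engine implements the grouped form only.

Training is plain stochastic gradient descent on the cross-entropy loss,
batch size 30, learning rate 1e-4 by default, at most 100 epochs, batches
drawn i.i.d. uniformly with replacement from the window pool. When a
validation pool is supplied, training stops after `patience` (default 10)
epochs without validation-loss improvement and the best weights are kept.
Training is deterministic given `train_control(seed = )` on a fixed BLAS.

The engine is written in the package itself: convolutions are evaluated as
direct cache-blocked accumulation loops in C++, with the dense algebra in
BLAS. Gradient correctness is established against central finite differences
in the test suite.

### Recognition over a session

Per-window argmax labels are fused by **majority voting**: every 10 ms time
step takes the most frequent label among the windows covering it (hard
votes; ties go to the lowest class index, and steps covered by no window
inherit the nearest covered step's label). The voted sequence is then
**smoothed**: for every exercise the minimum repetition duration `t_min` is
the shortest vibration interval observed in training; any maximal run of a
non-null label shorter than its `t_min`, flanked on both sides by one
identical label (possibly null), is replaced by that flanking label. The
rule is iterated to a fixpoint, shortest run first, which makes the result
unique and idempotent; runs at the sequence boundaries are left alone, and
null runs are never replaced. Replacing null-flanked short runs by null is
an interpretation choice: it filters out spuriously short predictions next
to transition periods. Maximal
non-null runs of the smoothed sequence become the recognized sets.

### Counting repetitions

Counting uses one binary network per exercise. Its window length is the
exercise's `w = round(t_min * 100)` samples, which guarantees a window never
fully contains two repetition starts. The *start of a repetition* is the
first `floor(w/2)` samples after the vibration; a window is labeled 1 iff it
contains an entire start segment. At test time windows slide at stride
`max(1, round(w/20))` (a package choice — dense enough that every start
segment is fully contained in at least one window), probabilities are
thresholded at 0.5, and the resulting binary sequence is cleaned by
**mode-based run-length smoothing**: with `M1` the most frequent 1-run
length and `M0` the most frequent 0-run length (frequency ties resolve to
the larger length — conservative, it favors confirming runs), 1-runs of
length at least `M1/2` are confirmed starts, shorter runs are candidates,
and a candidate is deleted when a confirmed run starts strictly closer than
`M0/2` positions (start-to-start distance; the reference point was not
specified, run starts are the package's choice). Candidates are judged
against the confirmed set only, in one pass. The count is the number of
remaining 1-runs. Modes are computed per set, since the procedure operates
on one output sequence at a time. If no run reaches `M1/2`, the longest run
is taken as confirmed with a warning.

A repetition that begins exactly at a segment boundary is only containable
by windows that start up to half a counting window *before* the boundary.
Counting therefore slices each segment with a lead-in/out margin: half a
counting window around tightly annotated sets (`count_annotated_sets()`),
and a quarter window around recognized segments (`track_workout()`), whose
boundaries already bleed outward by up to half a recognition window through
voting. Without the margin the first repetition of nearly every set is
structurally undetectable and counts bias low by one.

### Evaluation

All data of one participant land entirely on one side of every split.
`grouped_kfold()` partitions participants into 5 near-equal folds;
`loso_folds()` holds out one participant per fold. Counting quality is
summarized by the mean absolute error, the mean relative error and the
fractions of sets off by 0, 1, 2 or more than 2 repetitions; sets whose
exercise was not recognized are excluded from the error metrics and reported
separately.

## The synthetic workout generator

Real recordings cannot ship with the package, so `generate_dataset()`
produces workouts with the statistical structure the pipeline assumes:

* per-exercise quasi-periodic signatures: sums of `n_harmonics = 3`
  harmonics of the repetition frequency with fixed pseudo-random loadings
  and phases across the 18 channels, drawn once from the master seed —
  distinct loadings and periods make classes separable without
  hand-designing ten biomechanical waveforms;
* an amplitude burst at each repetition onset and a within-repetition
  activity envelope (movement during the first 75% of each constrained
  repetition interval, then a taper while waiting for the next vibration) —
  the cue a start-detection network relies on, as a real accelerometer
  shows a burst at movement onset;
* per-subject variation of amplitude (log-sd 0.15), phase (sd 0.25 rad) and
  period (log-sd 0.05);
* repetition intervals drawn per class from 1.5–4 s; one set of 15
  repetitions per exercise with vibration annotations (the constrained
  protocol), plus a 90–120 s null block and 4–8 s transition gaps;
* ~100 Hz sampling with Gaussian timestamp jitter (sd 1.5 ms), white
  measurement noise (sd 0.3), and a slow mean-reverting baseline wander
  (sd 0.08, mean-reversion 0.05/s) that sits far below the exercise
  frequency band, so null segments show no periodic structure above the
  noise floor;
* unconstrained schemes for testing: `free10` (10 smoothly flowing
  repetitions per exercise, 20% faster, per-repetition period jitter, no
  vibration annotations but hidden true starts) and `one_two_three` (rounds
  of 1, 2 and 3 repetitions).

What the generator does **not** emulate: gravity/orientation physics
consistency between channels, sensor saturation and drift, walking
periodicity inside the null class, form degradation with fatigue, and the
long-tailed inter-person variability of real athletes. Passing the synthetic
benchmark therefore demonstrates that the pipeline's machinery — windowing,
training, voting, smoothing, counting, grouped evaluation — is implemented
correctly and can recover structure it assumes, not that comparable
accuracies hold on real recordings.

## The standing benchmark

`synthetic_benchmark()` is the package's acceptance study, at deliberately
desk-friendly problem sizes: 12 subjects (seed 42), subject-grouped 5-fold
cross-validation of the recognizer, and counting on a grouped holdout of the
last two subjects (20 sets) with counters trained on the remaining ten. To
keep one full run in the ten-minute range on a single core, the benchmark
trains reduced networks (recognition: filters 16/8, one dense layer of 32,
dropout 0.2; counting: filters 12/8, dense 24) with learning rate 0.02 for
at most 15 (recognition) and 8 (counting) epochs of 25 batches — the full
default architecture is exercised by construction and prediction tests but
is not trainable in minutes on one CPU. Thresholds asserted: grouped 5-fold
window accuracy at least 0.95, and at least 90% of held-out sets counted
within ±1 repetition. These thresholds are contracts about the
implementation on this synthetic study, not claims about real data.

## Numerical choices and degenerate inputs

* Stride from the overlap factor is rounded with a floor of one sample.
* `w/2` with odd `w` uses `floor(w/2)`; all containment tests use half-open
  sample intervals.
* Resampling tolerates floating-point roundoff of 1e-9 at grid edges and
  refuses genuine extrapolation.
* Sequences shorter than one window yield zero windows (with a warning) and
  a count of 0.
* An all-zero binary sequence counts 0; a sequence with no confirmed run
  keeps its longest run.
* Argmax ties in prediction and voting resolve to the lowest class index.
* Weights are He-scaled Gaussian; a non-finite loss aborts training with a
  diagnostic rather than returning silently broken weights.
* Session round trips through the JSON + CSV on-disk format preserve values
  to 15 significant digits.

## Known limitations

* Batch normalization is not available in the engine.
* Training the full five-layer/100-filter default architecture is practical
  only for inference-scale experiments on CPU; serious training of that
  configuration calls for a GPU framework.
* Counting assumes the segment routed to a counter truly contains one set of
  the recognized exercise; misrecognition propagates to counts, which is
  inherent to the two-stage design.
* The smoothing fixpoint processes shortest runs first; other orders can
  reach different (rare) fixpoints on adversarial sequences.
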