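---
title: "Sliding shock-advisory analysis during CPR: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sliding shock-advisory analysis during CPR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

During out-of-hospital cardiac arrest, an automated external
defibrillator (AED) must decide from the defibrillation-pad ECG whether
the rhythm is shockable (coarse ventricular fibrillation, VF) or
non-shockable (normal sinus rhythm NSR, other organized non-shockable
rhythms ONR, or asystole ASYS). Chest compressions (CC) contaminate the
ECG with large quasi-periodic artefacts, so conventional AEDs analyze
only during dedicated hands-off pauses. `cprshock` implements the
alternative studied here: a convolutional network that reads the raw,
possibly compression-contaminated ECG and emits a shock probability
*continuously*, at 26 decision times spaced 1 s apart, so that even a
brief insufflation pause inside the analysis window improves the
decision.

The real defi-pad recordings such a study uses are proprietary, so the
package is built around a synthetic generator that reproduces the
*structure* of those data — rhythm classes with machine-checkable
annotation criteria, a 30:2 compression/ventilation protocol, and a
compression-free regular analysis window — and every claim the package
tests is a claim about this synthetic task.

## The period of interest and the sliding grid

Each intervention contributes one period of interest: the 40 s segment
$(-30\,\mathrm{s}; +10\,\mathrm{s}]$ around the start of the regular
AED analysis at $t = 0$. The first 30 s are CPR-contaminated; the final
10 s are hands-off. At 125 Hz that is exactly 5000 samples; sample $i$
carries the time stamp of its right edge, and all intervals are
half-open $[\mathrm{start}, \mathrm{stop})$. This one convention is
used everywhere (generator, window extraction, sHOT), which is what
makes the index arithmetic exact.

Analysis windows of duration $D \in \{5, 10, 15\}$ s slide in 1 s
steps; the decision time $t$ (the last second of the window
$(t - D, t]$) runs over the integer grid $-15, \dots, +10$ — 26
decisions per period for every $D$. The hands-off time (HOT) is any CC
interruption longer than 1 s; the sliding hands-off time sHOT$(t, D)$
is the cumulative overlap of qualifying interruptions with the window,
so $0 \le \mathrm{sHOT} \le D$.

Two boundary readings deserve a note because the defining prose leaves
them open. First, an interruption *qualifies* by its full duration
(strictly $> 1$ s), but *contributes* its clipped overlap with the
window, even when that overlap is under 1 s; the alternative (counting
full episode lengths) can exceed $D$ and was rejected. Second,
interruptions running past the recorded extent of the timeline are
clipped to that extent before qualification, so the package never
claims hands-off time outside the evidence. Tests check the interval
arithmetic against a brute-force per-sample mask on a thousand
randomized timelines.

## The classifier

The network is fully convolutional: three blocks of
Conv1D → ReLU → MaxPool(2) → Dropout(0.3) with kernel sizes
$\{10, 20, 20\}$ and filter counts $\{5, 25, 50\}$, followed by global
average pooling (one feature per filter, 50 features) and a dense unit
with a sigmoid output

$$p_{Sh}(x) = \frac{1}{1 + e^{-x}}, \qquad
  x = \sum_{i=1}^{50} w_i\,\mathrm{GAP}_i + b .$$

Because convolution weights are shared along time and the pooled
features are averages, the parameter count — 27,681 including biases —
is independent of the input length: one weight set evaluates 625, 1250
and 1875-sample windows alike. Convolutions use "same"-style zero
padding (the printed architecture does not state its padding; the
parameter count, which is what the tests pin down, is
padding-independent). Inputs shorter than the stack's receptive field
(131 samples) are rejected rather than silently zero-padded into
meaninglessness.

No deep-learning framework is available to (or wanted by) this
package: forward pass, backpropagation and the Adam optimizer are
implemented here, with the batched convolution kernel in compiled code
(`src/conv1d.cpp`) as an im2col reshape feeding one BLAS matrix product
per layer. The backward pass is verified against central finite
differences in the test suite.

One implementation constant matters: `input_scale = 5e-3`, i.e. the
microvolt input reaches the first convolution in units of 200 µV (the
coarse-VF amplitude criterion). The reference architecture does not state
its input units; with random-uniform ±0.05 initialisation, millivolt
inputs leave early gradients so small that desk-scale epoch budgets
stall near the constant-output optimum, while 200 µV units condition
the first layer well. This is equivalent to rescaling the first-layer
initialisation and does not change what the network can represent.

## Training protocol

Training expands every learning-set period into its 26 sliding windows,
each inheriting the period label — so starts and stops of compressions
fall at arbitrary positions inside the training windows, which is the
point of the sliding strategy. The loss is a prevalence-weighted binary
cross-entropy

$$\mathcal{L} = -\frac{1}{M}\sum_m \delta_m\, w_{Sh} \log P_m +
  (1-\delta_m)\, w_{NSh} \log (1-P_m),$$

with $w_{Sh} = n_{NSh}/n$, $w_{NSh} = n_{Sh}/n$ computed from
period-level counts (the published learning registry gives
$409/6763 \to 0.943/0.057$). Probabilities are clipped at
$\varepsilon = 10^{-7}$ inside the logs. With equal weights the loss is
exactly half the unweighted mean BCE, a closed-form identity the tests
assert. Note a consequence of the weighting: the best *constant*
predictor of the weighted loss outputs $p = 0.5$ regardless of
prevalence, so an untrained or stalled model hovers there.

Optimisation follows the reference protocol: Adam (learning rate 0.001,
$\beta_1 = 0.9$, $\beta_2 = 0.999$), batch size 128, random-uniform
initialisation, a patient-wise 70/30 train/validation partition of the
learning split, early stopping on validation loss with best-weight
restore, several independent runs of which the minimum-validation-loss
run is kept, and finally a decision threshold chosen on the validation
scores by maximising $Se + Sp$ (ties broken toward higher sensitivity;
the decision rule is *shock iff* $p_{Sh} \ge \theta$, the comparison
sense being unstated in the reference design). The defaults in `train_config()`
are the full protocol (750 epochs, patience 150, 5 runs); the package's
own experiments use a reduced budget, below.

Two desk-scale adaptations: the 70/30 partition is patient-wise (the
reference protocol does not say; window-level splitting would leak windows of one
period across subsets), and the partition is re-drawn — deterministically
under the seed — if either side lacks a shock category, which a blind
draw produces easily at a 6% VF prevalence and a few hundred patients.

## The synthetic generator

The generator is the package's definition of the study conditions:

* **Rhythm criteria.** VF: band-limited stochastic oscillator with a
  dominant frequency drifting in 3–8 Hz (a conventional VF range; the
  annotation criterion itself only constrains amplitude), rescaled
  after filtering to a peak-to-peak amplitude in 400–1200 µV
  (criterion: > 200 µV). NSR: P-QRS-T beat templates (sums of Gaussian
  waves) at a rate drawn in 40–100 bpm. ONR: one of four organized
  non-sinus variants (atrial-fibrillation-like irregular RR without P
  waves, wide-QRS idioventricular, bradycardia < 40 bpm, sinus with
  premature beats). ASYS: low-pass noise rescaled to a global
  peak-to-peak of 30–80 µV (criterion: ≤ 100 µV over every 4 s).
  All traces pass a zero-phase 4th-order Butterworth 1–30 Hz bandpass,
  and amplitudes are enforced *after* filtering so the criteria hold on
  the emitted signal.
* **CC artefact.** Harmonic series at the compression rate (drawn
  100–120 min⁻¹) with 2–4 harmonics, per-compression log-normal
  amplitude jitter, slow phase noise, and a 0.15 s raised-cosine taper
  at episode edges; exactly zero outside CC episodes. Peak amplitude is
  drawn log-uniformly in 200–3000 µV per record, spanning weak to
  strong artefacts. These are declared parameters of the simulator, not
  claims about any proprietary recording.
* **Protocol.** Each intervention: cycles of exactly 30 compressions
  followed by an insufflation pause drawn uniformly from 2–8 s (within
  the interquartile span reported for 30:2 CPR pauses), ending in a
  compression-free regular-analysis window. ECG = rhythm + artefact,
  additively, so zero artefact gain reproduces the clean trace
  bit-exactly. The impedance channel is illustrative only and never
  enters the classifier.
* **Dataset.** Default class mix VF 6%, NSR 3%, ONR 28%, ASYS 63%
  (the real-life OHCA proportions), one period per patient by default
  (each simulated intervention ends in exactly one regular analysis;
  multiplicity is a parameter and the patient-wise split is tested with
  several periods per patient), patients split half/half into learning
  and test.

What the generator does *not* emulate: real CC-artefact spectra
(morphology is far more variable in practice), rescuer swaps and rate
drift, electrode motion artefacts and noise transients, rhythm
transitions within a period (the consistency screen exists and is
tested, but the generator emits consistent periods), and shockable
ventricular tachycardia. Passing tests therefore show that the
*pipeline* behaves as specified and that the qualitative findings
(sHOT-dependent performance, post-CC recovery) emerge on data with this
structure — not that the trained weights would transfer to real
defi-pad ECG.

## Evaluation

Per-class performance uses sensitivity for VF and specificity for the
NSh classes, $Se = TP/(TP+FN)$, $Sp = TN/(TN+FP)$; a metric with an
empty denominator is reported as missing, never as 0. Confidence
intervals are two-sided 90% Wilson score intervals ($z = 1.6449$; the
source reports 90% CIs without naming the construction, and Wilson
behaves well at the 0/1 proportions perfect classifiers produce).
Reporting is stratified two ways: by decision time (one decision per
period per time) and by sHOT, pooling all 26 decisions of all periods
into twelve strata — exactly 0 s, (0–1], …, (9–10], > 10 s; strata
above $D$ stay empty for the shorter models and are reported with
$n = 0$. AED performance-goal flags use Se(VF) ≥ 90%, Sp(ASYS) ≥ 95%,
Sp(ONR) ≥ 95%, Sp(NSR) ≥ 99%; the goals are printed with a strict
">" but published tables leave boundary values unflagged, so the
boundary counts as passing here.

ROC curves sweep all observed score thresholds with trapezoidal AUC;
on small sets the tests require exact agreement with the pairwise
concordance statistic and with an established implementation.

## Problem sizes and numerical choices

The package's own experiments (test suite and the acceptance script)
simulate 300 patients at the default mix (three periods each, ~900
periods in all), train the 10 s model with at most 8 epochs, patience
7, batch 128 and 2 independent runs, and evaluate the ~450 held-out
test periods. These sizes are the package's
reproducibility settings — large enough for the qualitative shape
(validation ROC-AUC well above chance, monotone improvement across
sHOT strata, post-CC recovery) while keeping a full run in minutes on
one CPU; the full 750-epoch/5-run protocol remains available through
`train_config()`.

Remaining numerics in one place: layer arithmetic runs in single
precision, as deep-learning frameworks train by default (gradient tests
therefore check directional derivatives, which converge to the analytic
values, rather than per-coordinate quotients that float noise
dominates); probability clipping $10^{-7}$ in the
loss; Adam $\epsilon = 10^{-8}$; early stopping requires improvement
$> 10^{-9}$; operating-point ties resolve to the smallest tied
threshold (highest sensitivity); max-pool ties keep the earlier
position; odd pre-pool lengths drop the trailing position; sHOT
binning tolerates $10^{-9}$ float noise at bin edges; all seeded
generators save and restore the caller's RNG state.

## Known limitations

The trained synthetic model is a demonstration of the method, not a
clinical classifier. Synthetic VF is easier to separate from the
harmonic artefact than real VF is from real artefacts, so absolute
Se/Sp on this task exceed what proprietary-data studies report, and the
sHOT-stratified contrasts are compressed at the top of the scale. The
compiled kernel is single-threaded by design (BLAS threading is the
only parallelism); training time scales linearly in windows × epochs.
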