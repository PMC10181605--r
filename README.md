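# cprshock

Continuous (sliding) shock-advisory analysis of the defibrillation-pad
ECG during cardiopulmonary resuscitation.

During out-of-hospital cardiac arrest an AED must decide, from a single
defi-lead ECG, whether the rhythm is shockable (coarse ventricular
fibrillation, VF) or non-shockable (normal sinus rhythm, other
organized rhythms, asystole). Chest compressions (CC) superimpose
large quasi-periodic artefacts, so conventional devices analyze only in
dedicated hands-off pauses. `cprshock` implements the sliding
alternative: a fully convolutional network reads the raw, possibly
CC-contaminated ECG window (5, 10 or 15 s) and emits a shock
probability at 26 decision times spaced 1 s over the period of interest
(−30 s; +10 s] around the regular AED analysis. The cumulative
hands-off time inside each window — the **sliding hands-off time,
sHOT** — is the covariate the evaluation is stratified by.

The package provides, end to end and without any proprietary data:

* a synthetic OHCA generator — four rhythm classes with
  machine-checkable annotation criteria (VF peak-to-peak > 200 µV;
  NSR 40–100 bpm; ASYS ≤ 100 µV over any 4 s), harmonic CC artefacts at
  100–120 min⁻¹, a 30:2 compression/ventilation protocol with
  insufflation pauses, and a CC-free regular-analysis window;
* the sliding grid, hands-off episode extraction and sHOT
  (interruptions qualify when their full length exceeds 1 s; windows
  accumulate the clipped overlap, so 0 ≤ sHOT ≤ D);
* the classifier itself — Conv1D/ReLU/MaxPool/Dropout blocks with
  kernels {10, 20, 20} and filters {5, 25, 50}, global average pooling
  (50 features) and a sigmoid head, 27,681 parameters shared across all
  window lengths — with backprop, Adam, class-weighted binary
  cross-entropy (w_Sh = 0.943, w_NSh = 0.057 at the published
  409/6763 prevalence), multi-run training with early stopping, and
  ROC operating-point selection by Se + Sp → max;
* the evaluation layer: Se (VF) / Sp (non-shockable classes) per
  decision time and per sHOT stratum with 90% Wilson intervals, ROC
  curves, and AED performance-goal flags
  (Se(VF) ≥ 90%, Sp(ASYS/ONR) ≥ 95%, Sp(NSR) ≥ 99%).

## Worked example

```r
library(cprshock)

# 100 synthetic patients x 3 periods each, default class mix (6% VF /
# 3% NSR / 28% ONR / 63% ASYS), split patient-wise into learning and
# test halves
ds <- make_dataset(100, seed = 42)

# a quick 10 s model (the full protocol is train_config()'s default:
# 750 epochs, patience 150, 5 runs)
fit <- train_cnn(ds, D = 10,
                 config = train_config(epochs = 10, patience = 9,
                                       runs = 1),
                 seed = 1)
glance(fit)
#> # A tibble: 1 × 8
#>       D n_params  runs best_val_loss val_auc threshold val_se val_sp
#>   <dbl>    <dbl> <int>         <dbl>   <dbl>     <dbl>  <dbl>  <dbl>
#> 1    10    27681     1        0.0288   0.968     0.326      1  0.834
```

`n_params` is the architecture's 27,681 shared weights; `val_auc` is
the ROC-AUC on the held-out validation windows; `threshold` is the
operating point maximising Se + Sp on those windows (`val_se`,
`val_sp` are its coordinates). Sliding advice for one test period —
26 rows, one per decision time, with the window's sHOT, the shock
probability and the thresholded decision:

```r
poi <- ds$pois[[ds$manifest$poi_id[ds$manifest$split == "test"][1]]]
predict_sliding(fit, poi)   # an ASYS period: low pSh throughout
#> # A tibble: 26 × 5
#>    poi_id       decision_time  shot    p_sh decision
#>    <chr>                <int> <dbl>   <dbl> <chr>
#>  1 P0001_poi01            -15  2.95 0.00158 NSh
#>  2 P0001_poi01            -14  2.95 0.00158 NSh
#>  3 P0001_poi01            -13  2.95 0.00162 NSh
#>  # …

adv <- evaluate_sliding(fit, ds, split = "test")   # all test periods
performance_by_shot(adv)     # Se/Sp per class and sHOT stratum + CI
performance_by_time(adv)     # Se/Sp per class and decision time + CI
```

`autoplot(poi)` draws the period with CC episodes shaded;
`plot_advice()` and `plot_performance()` plot the advice series and the
stratified performance tables.

A thin CLI over the same functions ships in `inst/cli/cprshock`
(`simulate`, `train`, `evaluate`, `report`).

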