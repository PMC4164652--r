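---
title: "Methods: KS stationarity segmentation and apnea screening from beat-to-beat SBP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: KS stationarity segmentation and apnea screening from beat-to-beat SBP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbpseg)
```

## The problem

Beat-to-beat systolic blood pressure (SBP) during sleep is strongly
nonstationary: the baseline wanders in discrete shifts as autonomic state
changes, and apneic episodes superimpose slow quasi-periodic swings (one
pressure surge per airflow break, a cycle of roughly 50 heartbeats, i.e.
about 0.02 cycles per beat interval).  Conventional spectral tools assume
stationarity, so `sbpseg` first decomposes the record into *stationarity
patches* — maximal stretches within which the distribution of the signal is
statistically constant — and then derives three per-subject screening
quantifiers:

* `mean_L` — the mean patch length (beats).  Healthy blood pressure
  regulation shifts the baseline often, producing short patches; in apneic
  subjects long quiescent stretches survive between event clusters.
* `mean_var` — the mean within-patch variance (mmHg²).  Apneic oscillations
  inflate the local variance.
* `a_max` — the normalized peak of the Welch power spectrum of the
  local-mean-detrended signal in a low-frequency band around 0.02
  cycles/beat (dimensionless).  This measures the strength of the apneic
  oscillation directly.

Each quantifier is screened against apnea status with a ROC analysis, and
`mean_L` and `a_max` are combined into a two-dimensional decision rule.

## Segmentation model

A candidate cut at beat `t` splits a window into left and right samples; the
two-sample Kolmogorov-Smirnov distance `D(t)` is the supremum difference of
their empirical CDFs.  `find_max_cut()` scans every admissible `t` (both
sides must keep at least `l0` beats) and returns the maximizer; ties go to
the smallest `t` for determinism.  `segment_series()` applies the cut when
`D_max` exceeds the chance level `D_crit(N, alpha)` for a window of length
`N`, and recurses depth-first (left first) into both halves until nothing
is splittable.  The result is an ordered, gap-free partition of `[0, N)`;
per-patch means and unbiased variances (`denominator L - 1`, deliberate
because patches can be as short as `l0`) are attached.

Assumptions worth stating: beats are treated as an index, not a time axis
(all frequencies are per beat interval); the record has no missing beats
(artifact/ectopic filtering is upstream of this package); and the test is
distribution-free, so baseline level changes, variance changes, and
oscillation onsets are all detected through the same statistic.

### Significance calibration

The null distribution of `D_max` under "no change" is not the classical
two-sample KS law: the maximum is taken over ~`N` mutually dependent cuts
with the `l0` restriction.  `sbpseg` therefore calibrates `D_crit(N, alpha)`
by Monte Carlo: the empirical `(1 - alpha)` quantile of `D_max` over i.i.d.
standard Gaussian series, scanned with exactly the same code path as real
data.  A pre-calibrated table ships with the package (lengths 66–23170 on a
log grid, 400–3000 null replicates per length, five alpha levels); values
between grid lengths are interpolated linearly in `log N` after a
decreasing isotonic fit, and clamped to the end values outside the grid
(conservative at large `N`).  `calibrate_critical_curve()` regenerates or
extends the table, with optional JSON caching; `critical_curve_fn()` accepts
a user's analytic formula instead.

The null quantile is nearly flat in `N` (≈ 0.39 at `N = 66` down to ≈ 0.29
at `N = 23170` for `alpha = 0.01`): the scan is dominated by edge cuts whose
smaller side stays near `l0` regardless of `N`, so fluctuations do not
shrink with the usual `1/sqrt(N)`.  This is exactly why a matched
Monte-Carlo calibration is used instead of a textbook KS quantile.

Because the test is calibrated against a Gaussian null, heavy-tailed
beat-scale noise would make the nominal `alpha` approximate; the
segmentation itself (a distribution-free statistic) remains valid, only the
type-I rate guarantee is Gaussian-specific.

### Defaults

* `alpha = 0.01`: conservative; one spurious split per ~100 homogeneous
  records.  Exposed everywhere.
* `l0 = 33` beats: the shortest patch the scan may create.  It corresponds
  to the upper edge of the very-low-frequency band of heart-rate regulation
  (0.03 Hz ≈ 33 s ≈ 33 beats at 60 bpm): structure faster than this is
  treated as within-patch variability, not as a regime change.

## Detrending and the spectral quantifier

`detrend_local_mean()` subtracts each patch's mean from its beats.  The
filtered signal has exactly zero mean within every patch (checked to 1e-9 in
the tests) and is far closer to stationary than the raw record, though the
variance may still drift — local-mean removal does not guarantee full
stationarity.

`welch_psd()` estimates the one-sided power spectral density by averaging
tapered, overlapping periodograms: Hamming window of 256 beats, 50%
overlap by default (the common `pwelch` convention; all exposed).  The
normalization is density-scaled, so the integral of the PSD over
`[0, 0.5]` cycles/beat estimates the signal variance (Parseval, tested to
10% on white noise).  With a 256-beat window the resolution is 1/256 ≈
0.0039 cycles/beat, five bins below the 0.02 cycles/beat apneic line —
enough to separate the peak from the band edges without starving the
averaging (a 10800-beat record yields ~83 half-overlapped segments).

`compute_amax()` returns the band maximum of the spectrum divided by the
trapezoidal band integral.  For a flat spectrum over a band of width `W`
this is `1/W` (≈ 10.9 for the default band), which is the practical floor
for oscillation-free records.  Two deliberate choices:

* **"Amplitude" means PSD value** (power), not its square root; a
  `scale = "amplitude"` flag provides the square-root reading, since either
  interpretation of a spectral "amplitude" is defensible.
* **Band `[0.008, 0.1]` cycles/beat.**  The upper edge generously brackets
  the 0.02 peak.  The lower edge excludes the two lowest Welch bins: the
  step edges that local-mean detrending necessarily leaves at patch
  boundaries concentrate spurious power there, and with a lower edge at
  1/512 that residue — not the apneic oscillation — would dominate the band
  maximum for oscillation-free subjects (control-group `a_max` rises from
  ~15 to ~47 on the default cohort and the correlation of `a_max` with AHI
  collapses from ~0.9 to ~0.3).  Both edges are arguments, not constants.

`beat_acf()` and `epoch_autocorr()` provide the supporting autocorrelation
view: apneic fragments of a record show slowly decaying oscillatory
autocorrelation at the event period, quiet fragments of the same record do
not.  `epoch_autocorr()` picks the contiguous 2000-beat fragment with
maximal annotated-apnea coverage and the one with minimal coverage, so the
contrast is within-subject.

## Classification

`roc_curve()` sweeps thresholds at every midpoint between consecutive
distinct feature values (plus sentinels beyond the data range) under
"apneic if value > threshold"; all three quantifiers increase with apnea
severity (a `direction` flag flips this).  The AUC computed by the
trapezoidal rule over this sweep equals the Mann-Whitney statistic
`U/(n1*n0)` exactly, ties counted half — the acceptance tests assert
equality to 1e-12.  `optimal_threshold()` picks the sweep point closest to
the perfect classifier `(FPR 0, TPR 1)`; at equal distance the lower-FPR
point wins (screening favours specificity), then the larger threshold.
Accuracy is apparent accuracy — `(TP + TN) / n` on the same subjects used
to pick the threshold — which is the honest scale for a 33-subject cohort;
no cross-validation is attempted.

`rule2d_evaluate()` combines `mean_L` and `a_max`: a subject is called
non-apneic only when **both** fall at or below their thresholds (the
"low-low" region); exceeding either one triggers an apneic call.  By
default the thresholds are the per-feature ROC optima.  With
`optimize = TRUE` the pair is instead chosen to maximize apparent accuracy
over both sweep grids; since switching one feature off (threshold above its
range) is itself a candidate, the optimized rule can never score below
either single feature.  With the default (ROC) thresholds that dominance is
*not* guaranteed: when one feature is already near-perfect on a given
cohort, adding the second can only import its false positives.  On the
package's default synthetic cohort the combined rule helps or ties at the
documented root seed, and the optimized variant is provided for users who
want the guaranteed-dominant rule.

## The synthetic cohort generator

No clinical recordings ship with the package, so every end-to-end claim is
exercised on synthetic cohorts whose construction mirrors the assumed
physiology:

1. **Piecewise-stationary baseline.** Mean shifts arrive as a Poisson
   process at `seg_rate` shifts per 1000 beats (positions kept ≥ ~90 beats
   apart so patches are resolvable), with jump sizes `N(0, shift_sd)`,
   `shift_sd = 10` mmHg.  Baselines: 120 mmHg (control, normotensive),
   155 mmHg (hypertensive).  Beat-scale noise: Gaussian, SD 4 mmHg.
2. **Apnea epochs.** An apnea-hypopnea index of `AHI` events/hour occupies
   `AHI * 50 / 3600` of the record (each scored event modelled as 50 beats,
   ≈ 50 s at 60 bpm — one full cycle of the 0.02 cycles/beat oscillation),
   capped at 0.9.  Events are placed disjointly, one per equal slot of the
   night, so the realized fraction matches the request to within one event.
   Inside each epoch a sinusoid of period 50 beats is added; the phase
   restarts at each epoch (events are physiologically independent).
3. **Group structure.** Default cohort: 10 hypertensive (AHI 20–50),
   16 normotensive (AHI 15–30, recruitment rule AHI > 15), 7 controls
   (AHI 0–5, no epochs).  `seg_rate = 3 / (1 + AHI/10)`: controls shift
   their baseline often (mean patch ≈ 330 beats), severe apneics rarely.
   This builds the expected ordering of `mean_L` into the cohort by
   construction — it is a modelling choice that encodes "healthy regulation
   is more active", not an empirical claim the pipeline could then verify
   independently.  Per-subject oscillation amplitudes are drawn uniformly
   from 1–14 mmHg: real cohorts contain weak responders whose events barely
   imprint on pressure, and this heterogeneity keeps every single feature
   imperfect (1-D apparent accuracies land in the ~70–97% range), which is
   what makes combining features worthwhile.
4. **Reproducibility.** One root seed; subject `i` uses the derived seed
   `(root + 7919 * i) mod 2^31`, so cohorts are reproducible subject by
   subject and a subject can be regenerated in isolation.

What the generator does **not** emulate: baroreflex or respiratory coupling
(no physiological feedback model), measurement artifacts or ectopic beats
(the pipeline assumes a clean beat series), beat-interval variability (the
beat index is the time axis), non-Gaussian noise, and any distinction
between obstructive and central events.  Passing the end-to-end tests
therefore shows that the pipeline recovers the statistical structure it is
designed to detect when that structure is present — not that clinical
recordings have this structure.

## Problem sizes and runtime choices

The default record length is 10800 beats (a 3 h analysis window at 60 bpm;
pass `n_beats = 21600` for a full 6 h night).  The scan is O(N²) per window
and the recursion can peel segments off one end of a long record, so the
cost grows roughly as N² times the recursion depth; 3 h keeps the full
33-subject cohort analysis under two minutes on one CPU while leaving every
patch-length scale of interest (tens to thousands of beats) inside the
record.  Validation sizes used by the test-suite: 200 exhaustive-oracle
instances at N ≤ 200; 500 null series of 2048 beats for the type-I check;
200 recovery runs with 2-SD jumps and 200-beat blocks; 100 peak-recovery
and 200 amplitude-sweep subjects of 4096 beats.  The spectral criteria use
sustained periodic-breathing bouts (250-beat epochs, five oscillation
cycles each): single 50-beat events carry only one cycle, whose spectral
line is intrinsically one-period wide, so sharp peak localization is only a
meaningful expectation for multi-cycle bouts.

## Numerical and degenerate-input conventions

* Coordinates are 0-based and half-open `[start, end)` everywhere,
  including all CSV output.
* Ties in the KS scan: CDF differences are evaluated only at the last
  element of a run of equal values (realizable points); tied maxima resolve
  to the smallest cut.
* A series shorter than `2 * l0` (or a constant series) is returned as a
  single segment; a single-beat segment reports variance 0.
* Quartiles use linear interpolation of the empirical CDF (R type 7),
  fixed for cross-platform determinism.
* Two-sample KS p-values: exact null distribution (equivalently, the full
  permutation distribution) when there are no ties and `n_a * n_b < 10^4`;
  otherwise the asymptotic Kolmogorov law with effective size
  `n_a * n_b / (n_a + n_b)`.  At cohort sizes (16 vs 7) the exact route is
  the default and agrees with a 10^4-draw permutation estimate to < 0.01.
* Numeric CSVs are written at 17 significant digits and parsed with base
  R's `strtod`-backed reader, so write/read round-trips are bit-exact.

## Known limitations

* The critical curve ships calibrated for `l0 = 33` at five alpha levels;
  other `(alpha, l0)` combinations need a (cached) recalibration run.
* Calibration assumes an i.i.d. Gaussian null; the attained type-I rate
  under strongly non-Gaussian beat noise is not guaranteed.
* Apparent accuracy on 33 subjects is optimistic by construction; the
  package reports it because it is the standard small-cohort metric, not
  because it estimates out-of-sample performance.
* The frequency axis is cycles per beat interval throughout; mapping to Hz
  requires beat timestamps, which the package does not ingest.
* `epoch_autocorr()` needs event annotations; on unannotated clinical data
  the epoch-contrast analysis is unavailable (the cohort-level quantifiers
  are not affected).
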