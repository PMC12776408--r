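---
title: "Detecting quasi-periodic spatiotemporal patterns: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting quasi-periodic spatiotemporal patterns: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatiodyn)
```

## The problem

Resting-state BOLD fMRI carries recurring whole-brain spatiotemporal
motifs: over a window of roughly 20–24 seconds, activity in the default
mode network (DMN) rises and falls in anti-phase with the task-positive
networks (dorsal attention, DAN, and frontoparietal, FPN), with the
pattern propagating through the remaining networks. Two families of
methods extract such structure from a parcellated ROI × time matrix:

* **Quasi-periodic pattern (QPP) detection** — iterative sliding-window
  template matching. A window of the data seeds a template; sliding
  Pearson correlation between the flattened template and every data
  window yields a correlation time course `c(t)`; supra-threshold local
  maxima select windows whose mean becomes the refined template; the loop
  repeats until `c(t)` stabilizes. Occurrences are the maxima of the
  converged `c(t)` (TMX1) and, for the inverted-phase state, its minima
  (TMX2).
* **Complex principal component analysis (cPCA)** — each ROI row is made
  analytic, `Z = I + i·H(I)` with `H` the Hilbert transform; the complex
  correlation matrix `R = Z Z^H / T` encodes synchronization strength in
  its real part and phase lag in its imaginary part; the leading singular
  vectors of `R` are phase-coherent spatial modes, with `arg U` the
  per-ROI phase delay map and `A(t) = U^H Z(t)` the projection time
  courses.

The package implements both, plus the surrounding fidelity protocol: how
do the recovered patterns depend on scan length, on the sampling interval
(TR), and on the band-pass applied before analysis? Because the published
benchmark recordings are restricted-access, every quantitative claim here
is exercised on a synthetic generator that plants a known pattern, so
recovery can be scored against ground truth.

## The synthetic generator

`generate_dataset(synth_config())` produces the standard study
conditions: 246 ROIs split over 8 base networks (DMN 36, DAN 30, FPN 26,
VAN 22, VIS 34, SMN 33, subcortical 39, limbic 26) with the derived
task-positive group TPN = DAN ∪ FPN (56 ROIs); TR 0.72 s; 1200 timepoints
(14.4 min); a planted template of 24 s recurring on average every 45 s
(about one occurrence per 30–60 s of data) at hard minimum spacing of one
window; AR(1) noise per ROI. The limbic count is not part of the
published network tally and was fixed once at 26 so the base networks sum
to 246.

Design choices worth recording:

* **Template rows.** Each ROI row is one period of a Hann-windowed
  cosine, `s · h(θ) (cos(θ − φ) + cos(φ)/2)` with `h(θ) = (1 − cos θ)/2`.
  The `cos(φ)/2` term inside the envelope cancels the envelope–carrier
  cross product, so the row is *exactly* zero-mean at every phase `φ`
  while the window edges stay at zero. Compact support is not cosmetic:
  an untapered single-cycle cosine produces partial-overlap sidelobes in
  the sliding correlation of up to ~0.5, which double-detect events; with
  the taper, sidelobes against the planted template fall below the
  detection threshold even in noiseless data.
* **Phase layout.** Traveling templates space network phases equally over
  `[0, max_phase_lag]` (default π/2) along the fixed propagation ordering
  DMN, FPN, DAN, VAN, SMN, VIS, LIM, SCN. The DMN sits at phase 0 with
  polarity +1, so its mean row attains its minimum at the window centre —
  the same convention the detector aligns to, which is what makes planted
  and detected event indices directly comparable. DAN and FPN carry
  polarity −1, planting the DMN/TPN anti-correlation that defines the
  dominant pattern.
* **Event times** are a jittered regular grid (quasi-periodic recurrence
  without exact periodicity), seeded, with minimum spacing of one window.
* **Noise** is AR(1) per ROI (default lag-1 coefficient 0.3), independent
  across ROIs. Cross-ROI noise correlation, physiological (cardiac or
  respiratory) confounds, scanner drift and motion are *not* emulated, so
  recovery results here bound what clean, well-preprocessed data could
  give; they say nothing about robustness to structured artefacts.
* **SNR** is defined as template RMS over its support divided by the
  noise SD, which makes recovery thresholds statable (the standard
  conditions use SNR 1; the stability experiments use 0.5).

## QPP detection: parameters and numerical choices

* **Window length** is specified in seconds (default 24 s) and converted
  to timepoints with round-half-away-from-zero (33 points at TR 0.72 s,
  11 at 2.25 s); a window of fewer than 2 points is an error.
* **Threshold schedule**: maxima above 0.1 for the first three
  iterations, 0.2 afterwards — the convention of the sliding-template
  literature; both are arguments.
* **Convergence**: successive correlation time courses agreeing at
  Pearson ≥ 0.9999, capped at 20 iterations.
* **Suppression separations.** Within the refinement loop, matched
  maxima closer than a *full* window are suppressed (keeping the larger
  peak): windows closer than W overlap in the data, and admitting them
  double-counts samples in the template mean, which can lock the
  iteration into a smeared multi-offset attractor. Reported event sets
  use the half-window separation `floor(W/2)`, which is enough to
  prevent double-counting a single pass while retaining closely recurring
  patterns.
* **Start points and selection.** Detection runs from 20 seeded random
  starts and keeps the solution whose *own matched events* carry the
  largest total correlation. Scoring on a denser re-extraction would
  favour degenerate templates that match weakly everywhere (many events
  at c ≈ 0.2 can out-sum few events at c ≈ 1).
* **Phase alignment and rebuild.** The winning template is circularly
  shifted so the DMN-mean row attains its minimum at the window centre,
  then rebuilt once as the mean of the full data windows at its aligned
  peaks. A template that converged from a start inside an occurrence
  carries zero or noise columns in its wrap region; the rebuild fills
  them with data. On noiseless planted data this step is what makes
  detected event times match planted ones exactly.
* Optional window expansion during refinement is not implemented; only
  the dominant pattern is extracted (no secondary QPPs, no regression of
  the pattern from the data).

## cPCA: conventions

* The Hilbert transform is computed in the frequency domain on
  mean-removed rows. Edge samples (the first and last ~10%) are excluded
  from phase-based assertions in the tests; the analytic signal is least
  reliable there.
* Rows are normalized to unit RMS before the correlation matrix, so the
  matrix has unit diagonal and is comparable across datasets of different
  amplitude; `normalize = FALSE` restores the raw formulation.
* The SVD phase of each component is arbitrary; it is gauged so the
  largest-modulus entry is real-positive, making decompositions
  reproducible. Gauge invariance (singular values, amplitudes, phase
  *differences*) is asserted in the tests.
* Both phase outputs are exposed: the temporal phase `arg A(t)` of each
  projection and the spatial per-ROI delay map `arg U`. Comparisons and
  figures use the spatial map, which is the standard delay-map reading;
  the temporal phase is a phase *ramp* for narrowband data and is mainly
  useful for tracking cycle progression.
* `component_to_template()` reconstructs one full cycle
  `σ_k · Re(U e^{i 2π m / W})` for side-by-side comparison with QPP
  templates. QPP and cPCA windows are aligned with a best circular shift
  after resampling to a common number of columns.

## Preprocessing contracts

* Band edges: Slow-5 (0.01–0.027 Hz), Slow-4 (0.027–0.073 Hz), Infraslow
  (0.01–0.10 Hz), Infraslow+ (0.01–0.15 Hz). Higher bands are
  deliberately unsupported. A band whose upper edge reaches Nyquist at
  the series' TR is an *error* (for example Infraslow+ at TR 3.6 s, where
  Nyquist is ≈ 0.139 Hz); silently clipping the band would change the
  science.
* The filter is a 2nd-order Butterworth applied forward–backward
  (zero-phase), so filtering cannot displace event timing; gains are
  asserted on the interior 80% of samples to avoid filter transients.
* TR decimation keeps every k-th timepoint starting from the first, with
  no anti-alias filter — the point is to mimic what a slower acquisition
  would have measured. Decimation composes exactly
  (`decimate(a)∘decimate(b) = decimate(ab)`).
* Decimation is applied to the raw series *before* filtering and
  normalization, so filters are designed at the new TR, mimicking
  acquisition at the longer TR. The opposite order is a defensible
  alternative the package does not default to; callers can compose the
  steps themselves for sensitivity checks.
* Global signal regression residualizes each row on `[1, g]` with `g` the
  ROI mean; if the global signal is numerically negligible (input already
  residualized), only the row means are removed, making GSR idempotent.

## Event-set agreement

The modified Jaccard index with cushion counts events shared if they can
be matched one-to-one within ± cushion timepoints (default 8, sensitivity
rerun at 16) and divides by the union size; two empty sets score 1. The
matcher is a greedy two-pointer sweep over the sorted sets, which attains
the maximum matching on 1-D interval constraints — asserted exhaustively
against brute-force enumeration for sets up to size 6. The precursor
time-point analysis reports the mean signed lag (`b − a`) over the same
matching; with no matched pairs the lag is undefined (`NA`), never 0.
Extrema match within type only (maxima to maxima, minima to minima).

## Statistics

Kruskal–Wallis, Wilcoxon signed-rank and Mann–Whitney U delegate to the
standard R implementations with mid-rank ties, dropped zero differences,
and exact small-sample distributions (n ≤ 12 signed-rank, min(n) ≤ 8
rank-sum, both configurable); Dunn's post-hoc z test with tie correction
and Bonferroni adjustment is implemented from the pooled-rank formula.
Exactness is cross-checked in the tests against independent enumeration
over sign patterns and rank splits, and null calibration (type-I rate in
[0.03, 0.07] at α = 0.05 over 2000 seeded replicates) is asserted for the
omnibus and pairwise tests; for Dunn the unadjusted per-comparison p is
calibrated, since the Bonferroni-adjusted value controls the family-wise
rate rather than a per-test level.

## Problem sizes used by the packaged experiments

The experiments shipped in `analysis/` and exercised by the test suite
run at what a single desk CPU handles comfortably: cohorts of 246 ROIs ×
1200 timepoints; five dataset seeds for recovery; five cohorts × five
groups × three durations (120, 360, 864 s) for the stability experiment;
decimation factors up to 5; 2000 replicates for null calibration. These
sizes were chosen as the smallest at which the statistical assertions
are stable across reruns with different seeds.

## Known limitations

* The generator's noise model is unstructured; none of the recovery
  numbers speak to motion, physiological cycles, or spatially correlated
  noise.
* Only the dominant pattern is modelled and extracted; datasets with
  several comparable-strength motifs would violate the single-template
  assumption of both the generator and the detector.
* Sliding-window correlation assumes the pattern recurs at a fixed
  duration; the window is held at 24 s throughout (reconverted to points
  per TR), and no window expansion is attempted.
* The cPCA reconstruction represents a component as a single-frequency
  cycle; harmonic content of the true waveform beyond the first harmonic
  is not reconstructed, which bounds attainable QPP–cPCA template
  agreement below 1 even on clean data (observed ≈ 0.82 under the
  standard conditions).
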