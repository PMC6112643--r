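---
title: "Uterine EHG/tocogram analysis: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Uterine EHG/tocogram analysis: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehgtools)
```

## The signal model and why the bands are where they are

A uterine record couples up to three bipolar abdominal EHG channels (S1
between the top electrodes, S2 between the left electrodes, S3 between the
bottom electrodes) with an external tocogram, all sampled at 20 Hz.  Three
physiological mechanisms dominate below 5 Hz:

* **contraction bursts** — intermittent, below 1 Hz;
* **maternal respiration** — a quasi-sinusoid at 0.2–0.34 Hz;
* **the maternal heart** — a permanent component at the heart rate
  (≈1.2–1.5 Hz at rest during pregnancy) with higher harmonics; the source
  ECG is roughly twenty times stronger than EHG burst activity, so its
  leakage into abdominal recordings is expected, and the uterus also
  transmits it mechanically to the tocograph.

The analysis therefore separates four bands — B0 0.08–1.0, B1 1.0–2.2, B2
2.2–3.5, B3 3.5–5.0 Hz — so that each feature reads a single mechanism: B0
contractions and respiration, B1 the cardiac fundamental, B2/B3 its second
and third harmonics.  B0's lower edge is 0.08 Hz rather than 0.34 Hz on
purpose: keeping respiration inside the analyzed spectrum guarantees at
least one strong low-frequency peak, which anchors the normalization that
the PA feature depends on.

## Filter bank

Each band is realized as a fourth-order digital Butterworth band-pass
(−80 dB/decade roll-off per pass), applied forward and backward so the
composite response is zero-phase with squared magnitude.  Coefficients are
designed at run time per `(band, fs, order)` and cached; nothing is
hard-coded, so resampled synthetic data works unchanged.

**Edge handling.**  Bidirectional filtering needs padding, or start-up
transients corrupt both record ends.  We pad by odd reflection (point
symmetry about the first/last sample) and size the pad from the designed
filter itself: the number of samples an impulse needs to decay below
10^-10, computed from the slowest pole radius.  For B1 this is ≈580
samples; for B0, whose lowest pole sits at radius 0.9916, it is ≈2700
samples.  A fixed short pad (a few dozen samples) would leave B0 transients
at a substantial fraction of their initial size and visibly break the
zero-phase symmetry that downstream tests rely on; the pole-based rule
restores time-reversal symmetry to ~10^-12.  The practical consequence is
that `zero_phase_filter()` requires inputs longer than the pad — whole
records easily satisfy this, and annotated intervals are always sliced
*after* whole-record filtering, never filtered in isolation.

## Spectral features

Power spectra use a Hanning window over the full segment with `M` equal to
the segment length (no zero-padding).  This choice matters for the 0.1 Hz
moving-average smoothing: the smoothing span is converted to bins as
`round(0.1/Δf)` forced odd, so zero-padding would silently change the
number of bins averaged.  The spectrum is scaled so the one-sided sum
equals the windowed energy (Parseval); all features are scale-invariant, so
the scaling only aids interpretability.

Smoothing precedes normalization, and `P_max` is located on the smoothed
spectrum over the whole 0–10 Hz half-axis.  Band-edge bins are computed by
rounding `f·M/f_S`; a shared edge (e.g. 1.0 Hz) is assigned to the lower
band so bands stay disjoint.  The median frequency is the first bin at
which cumulative in-band power reaches half the in-band total; MF and PA
are both read from the smoothed, normalized spectrum for consistency.  The
signal mean is not removed before windowing — the wide-band filter has
already rejected DC, and a second detrending would bias B0.

## Sample entropy

`sample_entropy()` standardizes each segment to zero mean and unit
variance, then counts ordered template pairs within Chebyshev tolerance
`r = 0.15` at pattern lengths `m = 3` and `m − 1`, both anchored at the
same `N − m` starting positions.  This shared-template convention makes
`c_m ≤ c_{m−1}`, hence SE ≥ 0 in the regular branch, and standardization
makes the tolerance a fraction of the segment's own SD — an absolute
tolerance in microvolts would be meaningless across gain settings.  Two
edge cases are defined rather than errors: a zero-variance segment is the
all-match case (SE = 0), and when either count is zero the fallback
`−log((N−m)/(N−m−1))` is returned verbatim.  Note this fallback is
*negative* (its argument exceeds 1); we implement the published form
unchanged and flag it here, since the reciprocal may have been intended.
The counting kernel is C++ (`O(N²m)` with early abort), exercised against
an independent matrix-algebra oracle in the tests; whole-record inputs of
36 000 samples take well under a second.

## Feature assembly

Eleven features per signal: SE in B0–B3 from the time-domain subband
signals sliced to the interval, MF in B0–B3 and PA in B1–B3 from the single
wide-band spectrum of the interval.  These are deliberately two different
data paths: entropy sees the filter bank's time-domain output, the spectral
features see one Hanning spectrum with band windows applied at readout.
PA in B0 is omitted because the global peak nearly always lies in B0, which
would pin that feature at 1.  Columns are ordered signal-major, bands
B0→B3, features SE, MF, PA, so selection histograms are comparable across
runs.  The labor/nonlabor boundary is deliberately early — a recording
within 3 weeks of delivery counts as labor — and configurable.

Whole-record mode applies no transient trimming: records are long relative
to the filter transients and the bidirectional padding already suppresses
edge effects.

## Selection and classification

Separability criteria use Gaussian-moment closed forms (pooled-variance
t-test; Bhattacharyya distance; symmetrized Kullback–Leibler divergence) —
the standard definitions in feature-ranking toolboxes, adopted because only
the criteria's names, not formulas, are conventionally fixed.  SFS always
evaluates the full MCE-versus-k curve and takes its global minimum, because
stopping at the first local minimum is known to quit prematurely.
Candidate enumeration and all tie-breaks follow the Bhattacharyya
pre-ranking, making runs deterministic given their seed.  The 20% holdout
is reporting-only; it does not participate in choosing the subset size.

QDA is implemented as per-class Gaussians with class covariances and
empirical priors; a covariance that fails Cholesky factorization receives a
trace-scaled ridge (`λ·tr(Σ)/d·I`, λ from 10^-6 upward), so constant
columns degrade gracefully.  The implementation is cross-checked against
`MASS::qda` in the test suite.  Cross-validation defaults to balancing
*inside* each training fold, so test rows are never synthetic; the
`balance_upfront` switch reproduces the common protocol of balancing once
before CV (under which balanced class sizes such as 53/53 are quoted).
Confusion counts are pooled across folds within a repetition, AUC is
computed by trapezoidal integration on each repetition's pooled scores, and
means over repetitions are reported in percent.

SMOTE places synthetic minority rows uniformly on segments between a
minority sample and one of its five nearest minority neighbours until
counts are equal; ADASYN allocates synthetic counts per minority sample in
proportion to the fraction of majority points among its neighbours, so the
balanced minority count is approximate rather than exact.  Both are
implemented in-package.

## The synthetic generator

`synth_record()` builds 30-minute, 20 Hz, four-channel records as the sum
of white instrumentation noise (SD 1 µV), a respiration sinusoid
(0.27 Hz, 1.5 µV), a cardiac component, and scheduled contraction activity:

* **cardiac** — a harmonic stack `A(sin φ + 0.5 sin 2φ + 0.25 sin 3φ)` on
  the EHG channels and fundamental-only on TOCO (the tocograph shows the
  rate, not sharp harmonics), with slow sinusoidal FM of ±0.05 Hz so the
  spectral peak has realistic width.  Archetype amplitudes are
  term-nonlabor S1/S2/S3/TOCO = 0.75/0.50/0.60/0.60 µV, preterm-like
  0.25/0.12/0.18/0.08 µV, nonpregnant-like the same as preterm but zero on
  TOCO.  These were chosen once so that the resulting `PA.B1` values land
  in the ranges observed on real recordings (term dummy-interval medians
  of order 0.1, preterm of order 0.02) with `P_max` anchored by
  respiration in B0;
* **contractions** — Gaussian-envelope-modulated 0.1–1.0 Hz noise bursts
  (amplitude 8 µV) at three scheduled 80 s intervals per 30 min, mirrored
  into TOCO as a smooth pressure deflection; dummy intervals of matching
  length are placed in the inter-contraction gaps.

What the generator does **not** emulate: motion artefacts, electrode drift,
non-stationary heart rate beyond the FM jitter, inter-channel propagation
delays, or any electro-mechanical uterus model.  Passing tests on synthetic
cohorts therefore demonstrate that the pipeline recovers injected spectral
structure — not that the classifier's accuracy transfers to clinical data.

One numerical caveat: at cardiac amplitudes near the noise floor the
in-band spectral maximum is not strictly monotone in the injected
amplitude, because the coherent component interferes with the fixed noise
realization (cross terms in the squared spectrum).  Monotonicity checks
therefore use an amplitude grid spanning the measurable range (0 to ≈4×
the term default) rather than steps inside the noise floor.

## Problem sizes and test fixtures

The test and acceptance runs use: 100 random series of ≤300 samples for
the entropy oracle; 100 random spectra for the MF/PA oracles; a
2-informative + 8-noise selection matrix with 100 balanced rows and a
class-mean gap of 4 SD (with weaker gaps the averaged training-CV MCE
curve of QDA at this sample size is so shallow that its argmin drifts
beyond k = 3 — a property of the learner, not of the selection code); and
synthetic cohorts of 30 + 30 records of 30 minutes for the end-to-end
classification check, evaluated with 10-fold, 30-repetition CV.  These
sizes keep the full suite and the acceptance script to a few minutes while
leaving every statistic comfortably away from its decision threshold.

## Known limitations

* The WFDB dialect reader supports format-16 interleaved signal files with
  a single `.dat` per record — sufficient for the uterine databases this
  package targets, not a general WFDB implementation.  Interval annotations
  are read from the plain TSV dialect (`onset`, `offset`, `label`) only.
* The sample-entropy fallback follows the published (negative) form, as
  noted above.
* ADASYN's balanced counts are approximate by construction; code that
  requires exact balance should use SMOTE.
* QDA is the only built-in learner, by design: the point of the package is
  the feature pipeline, and a fixed simple classifier keeps comparisons
  across interval kinds and signal sets interpretable.
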