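---
title: "Methods: multi-domain EEG/EOG features for interpretable sleep staging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-domain EEG/EOG features for interpretable sleep staging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepstager)
```

## The problem and the model

Overnight polysomnography is scored in 30-second epochs into wake (W),
three non-REM depths (N1–N3) and REM. Each stage has a well-known
electrophysiological signature: wake shows posterior alpha (8–12 Hz) and
frequent saccades on the electrooculogram; N1 shows theta and slow rolling
eye movements; N2 carries sleep spindles (12–14 Hz) and K-complexes
(0.5–1.5 Hz); N3 is dominated by high-amplitude delta; REM mixes sawtooth
waves (2–6 Hz) with bursts of rapid eye movements. `sleepstager` encodes
these signatures as 76 explicit features per epoch and classifies them with
a gradient-boosted tree ensemble, so every decision can be traced back to a
named, physiologically meaningful quantity.

The pipeline is: denoise each 30 s epoch → split the EEG into seven rhythm
bands → compute time-domain, spectral and entropy features plus four EOG
features → Fisher-score prefilter → boosted-tree importance ranking →
top-25 XGBoost classification under subject-wise cross-validation.

## Preprocessing choices

**Wavelet denoising.** Each epoch (3000 samples at 100 Hz) is denoised with
a 7-level db4 decomposition and soft thresholding. We use the classic
universal threshold \(\sigma\sqrt{2\ln N}\) with \(\sigma\) estimated
*once* from the finest detail level (median absolute coefficient / 0.6745).
The design alternative — estimating \(\sigma\) per level from that level's
own coefficients — was implemented and rejected: broadband EEG looks
"noise-like" at every scale under a per-level MAD estimate, so per-level
universal thresholds remove essentially all signal energy (in our
measurements an alpha-dominant epoch's SD fell from 23 µV to 0.5 µV and its
alpha power share from 0.67 to 0.01), destroying exactly the spectral
structure the features need. The finest level is where instrument noise
dominates and neural rhythms contribute least, which is the standard
rationale for estimating the noise scale there. The periodised orthogonal
transform needs a length divisible by \(2^7\); epochs are symmetrically
padded to 3072 samples and cropped after reconstruction.

**Filterbank.** Bands are extracted with linear-phase Kaiser-window FIR
bandpass filters targeting 50 dB stopband attenuation and a transition
width of min(1 Hz, half the band width), applied zero-phase by
compensating the (L−1)/2 group delay with reflection padding. Filtering is
per epoch, not per night, matching the per-epoch feature pipeline; the
reflection padding absorbs the edge transients. The band table
deliberately overlaps (a 3 Hz component belongs to both Delta and
Sawtooth); the filterbank is linear and each band output preserves length.

**Why per-epoch denoising?** Nothing downstream uses cross-epoch context,
and per-epoch processing keeps every feature a pure function of its epoch,
which makes the feature matrix reproducible under epoch reordering (a
property the tests assert).

## Feature definitions and parameters

* **Time-domain (7 per signal):** range, mean, population (1/N) variance,
  SD, strict-local-maximum count, zero crossings (sign product over
  consecutive non-zero samples), and the variance of the first-difference
  sequence \(D_n = X_n - X_{n-1}\) — a smoothness measure. Population
  variance is used throughout for consistency with the difference-variance
  definition.
* **Large eye movements (LEM):** adjacent local maximum/minimum pairs of
  the denoised EOG with peak-to-peak amplitude > 120 µV and extrema
  interval ≤ 1.5 s. These thresholds are the accepted operating point for
  saccadic deflections on a horizontal EOG. Extrema are localised on a
  0.5 s moving-average smoothed copy (localisation only, configurable),
  refined to the raw extremum nearby; consecutive same-type extrema
  collapse to the more extreme one, and runs of overlapping qualifying
  pairs merge into one event. The companion feature removes each event
  ± 0.5 s and pools first differences *within* the remaining contiguous
  segments — differences never span a cut, so the feature measures
  background smoothness, not splice artefacts.
* **Spectral:** Yule–Walker AR spectrum, order 16, evaluated on a 0.1 Hz
  grid with trapezoidal band integration. Order 16 resolves the rhythm
  bands of a 100 Hz epoch without the peak-splitting of much higher
  orders; it is configurable. The absolute ratios use P(0.5–35) as "total"
  power — the union of the analysed bands — because a total over the full
  Nyquist range would make the ratios sensitive to out-of-band noise. The
  four relative ratios and the two EOG ratios use their printed band edges
  verbatim (note the β denominator 12–30 Hz differs from the 13–35 Hz
  filterbank beta band; both are kept as-is).
* **Multiscale entropy:** sample entropy (m = 2, Chebyshev distance,
  non-strict ≤ r, self-matches excluded, both counts over the templates
  that admit an (m+1)-extension) of coarse-grained epochs at scales 9–13,
  with r = 0.2·SD of the scale-1 epoch held fixed across scales (the
  standard convention, so that coarse-graining's variance reduction is
  *measured*, not normalised away). Five scales are used because the
  feature inventory requires five entropy columns and scales 9–13 are the
  discriminative range for 100 Hz sleep EEG; an undefined entropy (no
  template matches) is capped at 3.0 and flagged, keeping matrices finite.

The canonical 76-column order is: EEG time features (band-major, 49),
absolute ratios (7), relative ratios (4), entropies by ascending scale
(5), EOG time features (7), LEM count and LEM-excluded difference variance
(2), slow/rapid EOG ratios (2). An EEG-only ablation uses the 65 EEG
columns.

## Selection and classification

Fisher scores \(J = S_B/S_W\) are computed per feature; the components
satisfy the law of total variance (population variance = \(S_W + S_B\)),
which the tests use as an exact internal check. Features with J < 0.1 are
discarded (a score exactly at 0.1 survives); if nothing survives, the top
10 are kept with a warning — a degenerate case real data never hits.
Survivors are ranked by XGBoost mean split gain (the closest standard
single metric to "split improvement weighted by observations"); ties
break by column index, and features the ensemble never uses rank last
with gain 0. The top 25 are kept: the accuracy-versus-k utility
(`accuracy_vs_k_curve()`) shows performance plateauing near that count.

The classifier is XGBoost with softmax output and the tuned operating
point colsample_bytree 0.8, learning rate 0.2, depth 7, 300 rounds,
α 0.1, λ 1, subsample 0.8, single-threaded for bitwise reproducibility.
`grid_search()` implements exhaustive tuning over a documented default
grid (learning rate 0.1/0.2/0.3 × depth 5/7/9 × 100/300 rounds) on the
inner learning/validation split; `run_cv()` accepts `tune = TRUE` but
defaults to the stated operating point, since re-deriving it per fold
multiplies runtime ~18-fold without changing the default behaviour being
validated.

Cross-validation is subject-wise: subjects are partitioned into five test
folds, each training complement splits 2:1 into learning and validation
subjects, and every night of a subject travels with the subject. Feature
selection is re-fit per fold on training data only (Fisher scores on the
whole training fold, importance ranking on its learning split); a
leakage audit asserting disjointness runs on every plan. Both pooled and
per-fold metrics are reported, because pooled confusion counts and
fold-averaged metrics genuinely differ and published tables mix the two.

## Evaluation conventions

Rows of the confusion matrix are expert labels, columns predictions, in
the fixed order W, N1, N2, N3, REM. Accuracy is trace/total (the
multiclass reading of the binary TP/TN formula), precision and recall are
one-vs-rest column/row ratios reported in percent with 0 substituted on
empty denominators, macro-F1 is the unweighted mean of per-class F1, and
\(\kappa = (p_o - p_e)/(1 - p_e)\) with \(p_e\) from the marginals. The
identity "accuracy = class-frequency-weighted mean recall" is asserted in
tests, and the engine is cross-checked against an independent
implementation (caret) on random labelings.

## The synthetic data: what it does and does not show

`simulate_psg()` builds each stage as a sum of band-limited Gaussian noise
components with stage-specific amplitudes, plus planted transients
(spindle bursts, K-complex waves) and EOG events (biphasic deflections
with known peak-to-peak amplitude and extrema spacing, logged as ground
truth). A night follows lead wake 45 min → four N1→N2→N3→N2→REM cycles →
trail wake 45 min (700 epochs), so the 30-minute trim rule is exercised
(exactly 30 epochs removed per side). Subjects differ by a random
amplitude gain (0.85–1.15), which perturbs absolute-amplitude features
across CV folds while leaving ratio features invariant.

Default problem sizes — 5 subjects × one night (~3200 retained epochs) for
the end-to-end checks, 200 epochs per stage for the feature-separability
property — were chosen as the smallest sets at which the statistical
checks are stable.

Passing the end-to-end test (pooled accuracy ≥ 90 %, κ ≥ 0.85) shows the
pipeline's plumbing, leakage controls and feature detectors work; it does
**not** certify real-data performance. The generator omits artefacts,
arousals, stage-transition ambiguity, inter-scorer noise, ECG/EMG bleed
and realistic 1/f background, which is why N1 — the genuinely hard stage
on real recordings — is easy here. Real-data claims require real
polysomnography.

## Numerical and degenerate-input conventions

Zero-variance epochs make the AR fit singular; such epochs are dropped
from the feature matrix with a message. Epochs containing non-finite
samples are dropped at segmentation. EDF output quantises to 16 bits over
the per-channel amplitude range (round-trip error below one quantisation
step, asserted). Band powers use exact trapezoids on the 0.1 Hz grid, so
adjacent bands add exactly. Sample entropy uses non-strict ≤ r matching;
the brute-force oracle in the tests reproduces the compiled implementation
to 1e−12. All RNG-dependent steps take explicit seeds; fold plans,
boosters and simulations are reproducible bit-for-bit given the seed.

## Known limitations

* One EEG + one horizontal EOG channel; no re-referencing or resampling.
* No inter-epoch context features, so stage-transition smoothing that
  sequence models capture is out of scope by design.
* The importance metric is per-fold mean gain; alternative blends
  (gain × cover) would reorder near-ties.
* The LEM detector is tuned for saccade-like biphasic deflections and
  does not discriminate blinks from saccades.
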