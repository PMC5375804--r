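---
title: "Pulse-phase thermography for cotton foreign matter: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pulse-phase thermography for cotton foreign matter: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsetherm)
```

## The measurement and its analysis

In a pulsed-thermography experiment a sample on a reflective steel stage is
heated by lamps for a fixed interval while a thermal camera records
per-pixel temperature. The acquisition protocol is a 1 s resting buffer,
5 s of stimulation, 10 s of cooling and a 1 s rear buffer at 30 frames/s
(510 frames; all of this is configurable through
`acquisition_protocol()`). Frame indexing is 0-based with half-open phase
intervals, so the lamp-off frame is the first cooling frame and — in a
noiseless world — carries the peak temperature.

Two feature families summarize a sample's thermal response:

* **Waveform features**: the mean masked-pixel temperature read at lamp-on,
  lamp-off and the data cutoff gives `peak − rest` (gain after heating) and
  `final − rest` (net gain after cooling). Reads are single frames by
  default; `waveform_features(trace, smooth = w)` averages ±w frames when a
  noisier camera warrants it.
* **Pulse-phase (Fourier) features**: the buffers are trimmed (450 frames
  by default), the mean trace is DFT-ed, and the below-Nyquist half of the
  spectrum is retained — indices `0 .. N/2 − 1`, i.e. 225 amplitudes and
  224 phases for the whole signal, 75/74 for the 150-frame rising part and
  150/149 for the 300-frame falling part. The exact-Nyquist bin is
  discarded with the aliased half; this is the only retention convention
  that yields those three count pairs simultaneously, so the package pins
  it. Amplitudes are raw (unnormalized) phasor moduli:
  no normalization convention is imposed because downstream classifiers
  standardize features per training fold, making the scale immaterial — it
  is fixed only so results are bit-reproducible. Phases lie in (−π, π] and
  the identically-zero 0-Hz phase is dropped. Odd-length traces are
  rejected rather than given a convention: valid protocols at the supported
  frame rates never produce them.

Phases are extracted and stored but excluded from the default
classification feature sets, which use only waveform and amplitude
features; the classification trials are defined on those sets, and keeping
phases out of them preserves that design while leaving the phase data
available for inspection (phasegrams).

## The synthetic-data generator

No thermal videos are distributed with the package, so the generator is a
first-class module that emulates the study design: 12 classes (11 foreign
matter types + cotton lint) × 20 samples, 510-frame videos, i.i.d. Gaussian
camera noise with sd 0.045 °C (the camera's noise-equivalent temperature
difference). Frames default to 80 × 80 rather than the camera's 320 × 240
so a full 240-video replica runs in minutes within ordinary memory;
geometry scales with frame size, and full resolution is a configuration
away.

The thermal model is lumped-capacitance (zero-dimensional): exponential
approach to an equilibrium gain during stimulation, exponential relaxation
toward ambient afterwards,

$$T(t) = T_\mathrm{amb} + g\,(1 - e^{-t'/\tau_h}) \quad\text{(heating)},
\qquad
T(t) = T_\mathrm{amb} + (T_\mathrm{peak} - T_\mathrm{amb})\,
e^{-t'/\tau_c} \quad\text{(cooling)}.$$

A PDE would buy little here: the analysis consumes only mean traces and
low-frequency spectra, and the exponential family already spans the
qualitative waveform families observed across classes (different peaks,
different cooling slopes) at trivial cost. The front buffer rests at
ambient; the rear buffer continues the cooling curve, which is also what
makes the `final` waveform read at the data-cutoff frame exactly equal the
closed form `g(1-e^{-5/\tau_h})e^{-10/\tau_c}` (when the rear buffer is
empty the read falls back to the last cooling frame).

Spatial structure comes from three mechanisms on top of a per-class
geometry mask (broad ellipses for leaves and bract; thin rotated bars for
bark, stems and twine; discs for seeds, seed coats and hulls; centered
rectangles for paper and module cover; the full window for lint):

* per-pixel gain jitter (CV ~0.05–0.10) — absorption inhomogeneity;
* edge cooling: boundary pixels cool with `τ_c / edge_cooling_factor`,
  which is what makes sample rims visible in phasegrams;
* per-sample lognormal multipliers on `g`, `τ_h`, `τ_c` (`sample_cv`).

The last mechanism is a deliberate extension of the per-class parameter
set: camera noise averaged over hundreds of masked pixels is far too small
to produce replicate-to-replicate variation, and without such variation
every class would be trivially separable and leave-one-out accuracy pinned
at 1.0 — no confusion structure, nothing for the statistics to measure.
`sample_cv` plays the role of biological variability among replicates of
one contaminant class.

### Calibration

Only two class temperatures are treated as observations: brown leaves peak
near 75 °C and seed coats near 35 °C above/over a 25 °C ambient. The
`study_classes()` table therefore parameterizes classes by their *peak*
temperature and back-computes the equilibrium gain
`g = (peak − 25)/(1 − e^{−5/τ_h})`. All other class values are plausible
free choices, stated as such, arranged to reproduce the qualitative
structure such experiments report for real contaminants:

* bract, green leaves and brown leaves peak at 70–75 °C with overlapping
  per-sample distributions (`sample_cv = 0.10`) — the confusable triplet
  whose members absorb most identification errors;
* bark (49 °C) and paper (48 °C) overlap — the other reported confusion;
* cotton peaks moderately (69 °C) but cools several times more slowly
  (`τ_c = 8` s vs 2.5–6 s) than everything else, which is what makes
  detection nearly perfect with either feature family;
* module cover gets a strong edge-cooling factor (2.5), making its edges
  stand out in phasegrams.

What passing tests on this generator do **not** show: performance on real
lint (real contaminant geometry, fixed-pattern camera noise, reflections,
convective drafts and sample-stage conduction are all unmodeled), nor the
absolute accuracies of any physical system. What they do show: the
pipeline's bookkeeping is exact (frame/feature counts, closed forms,
container round trips), its statistics are calibrated (null rejection
rates, chance-level LOOCV under permuted labels), and the chain recovers
by classification exactly the separation structure that was built into the
generator.

## Segmentation choices

"The frame of peak temperature" is read as the frame of maximal *spatial
mean* — robust to single hot pixels, and identical to the per-pixel maximum
on noiseless data. Otsu runs on a 256-bin histogram spanning the frame's
min–max range; the threshold sits on a bin edge and maximizes the
between-class variance `w₀w₁(μ₀−μ₁)²`, with ties broken toward the lowest
edge. Foreground is *above* threshold (samples absorb, the stage reflects);
a flag flips this for completeness. Interactive threshold touch-ups common in manual workflows become a
per-sample `manual_threshold` override — no GUI.
Constant frames are rejected as degenerate rather than guessed at. Cotton
uses a fixed 100 × 100 center window (capped at the frame size), paper a
centered rectangle of a quarter of each frame dimension — inside the
rendered paper rectangle by construction.

## Statistical conventions

Pairwise class separation uses the two-sample Hotelling T² with the exact
F transform; for two groups this is the same inference as a one-way
MANOVA, so workflows built on per-pair MANOVA calls get identical numbers. No multiple-testing
correction is applied across the 66 pairs — separation is judged against a
raw 0.001 threshold, and the package follows that convention. The
amplitude-feature test set defaults to the 10 lowest-frequency amplitudes,
matching the count selected by the preliminary sweep. Canonical
discriminant analysis solves the between/within scatter eigenproblem
through a Cholesky factor of the pooled within-class covariance (a
symmetric eigenproblem, numerically stabler than inverting), reports
eigenvalues of `W⁻¹B` on scatter matrices, sphere-scales scores so the
pooled within-class covariance of the scores is the identity, and fixes
each eigenvector's sign by making its first nonzero loading positive so
plots and regression tests are deterministic. Ridge shrinkage of a
singular within-class covariance exists only as a warning-emitting
fallback, never the default path.

Classification is leave-one-out cross-validated. Features are z-scored
with training-fold statistics only (a leakage guard; LDA itself is affine
invariant but the SVM is not). SVM kernels and hyperparameters are a free choice here, so the package
fixes a linear kernel with unit cost and
one-vs-one multiclass voting — all exposed as arguments. LDA uses pooled
covariance with proportional priors; folds with degenerate covariance fall
back to a ridge-shrunk Gaussian discriminant with a warning. Accuracies
are reported as fractions.

## Problem sizes and numerical tolerances

The test suite and acceptance script use: the full 240-video replica at
80 × 80 for the end-to-end classification bands (detection ≥ 0.95,
identification ≥ 0.75, LDA on whole amplitudes, with triplet-concentrated
confusions); 20 000 Monte-Carlo replicates for the Hotelling null
calibration at α = 0.001 (accepting rates in [0.0005, 0.002]); 36-sample
configurations at 10 fps for pipeline bookkeeping; closed-form waveform
agreement to 1e−9 °C; DFT identities (Parseval, conjugate symmetry, pure
cosines) to relative 1e−9 or better; and bit-exact determinism for
container round trips and dataset regeneration (float32 quantization
happens at video construction, so in-memory and on-disk values are
identical). Per-sample RNG streams are derived from the master seed by an
integer Lehmer-step hash of (seed, class index, sample index), so a
sample's video is reproducible regardless of generation order.

## Known limitations

* The lumped model cannot produce within-sample heat diffusion, so
  phasegram structure is limited to the rim/interior contrast injected by
  edge cooling.
* Camera effects beyond i.i.d. Gaussian noise (fixed-pattern noise,
  vignetting, emissivity errors) are not modeled.
* The generator's class calibration is qualitative; synthetic accuracies
  characterize the pipeline, not any physical system.
* Otsu operates on the raw temperature histogram, not an 8-bit rescaled
  image; with 256 bins over the frame range the two differ only in bin
  placement, but the convention is pinned here for reproducibility.
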