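# pulsetherm

Pulse-phase thermography analysis for detecting and identifying foreign
matter in cotton lint — with a physics-based synthetic thermal-video
generator so the whole pipeline runs end to end without any camera data.

## The problem

Cotton grading reports *how much* foreign matter a bale contains but not
*what* it is: bark, bract, leaves, hulls, module cover, paper, seed coats,
seeds, stems and twine all degrade lint differently. Pulsed thermography
offers a cheap imaging route: heat the sample with a timed radiative pulse,
record its temperature with a thermal camera, and exploit the fact that
materials differ in how fast they heat and cool. `pulsetherm` implements
the full analysis chain for such experiments:

1. **Simulation** — a lumped-capacitance model renders per-pixel
   temperature videos: during stimulation the temperature rises as
   `T(t) = T_amb + g (1 − e^{−t/τ_h})`, after lamp-off it relaxes as
   `T_amb + (T_peak − T_amb) e^{−t/τ_c}`, with per-pixel gain jitter,
   accelerated edge cooling, per-sample parameter variation and Gaussian
   camera noise (NETD 0.045 °C).
2. **Video I/O** — a bit-exact binary container (`PTIV`) for float32
   temperature frame stacks with JSON metadata.
3. **Segmentation** — Otsu thresholding of the peak-temperature frame
   (256-bin histogram, foreground above threshold), fixed center
   window/rectangle strategies, and manual threshold overrides.
4. **Features** — the per-frame mean temperature of the sample's pixels is
   trimmed to the heating + cooling window (450 frames at the default
   1/5/10/1 s, 30 fps protocol) and Fourier-transformed; components below
   the Nyquist frequency are retained (225 amplitudes, 224 phases whole;
   75/74 rising; 150/149 falling), alongside two waveform features
   (peak − rest and final − rest temperature). Phasegrams and ampligrams
   render per-pixel spectra as images.
5. **Statistics** — pairwise two-sample Hotelling T² tests over all 66
   class pairs and canonical discriminant analysis (`min(p, k−1)`
   variates, within-class-sphered scores).
6. **Classification** — leave-one-out cross-validated LDA and linear SVM
   on the two-class *detection* task (cotton vs foreign matter) and the
   twelve-class *identification* task, including the cumulative
   amplitude-feature-count sweep (k = 1..15).

## Worked example

```r
library(pulsetherm)

# one synthetic brown-leaf video under the default protocol
spec <- study_classes()$brown_leaves
cfg  <- dataset_config(seed = 1)
out  <- render_video(spec, cfg, sample_seed = 42)

mask  <- segment_video(out$video, "otsu")
trace <- mean_trace(out$video, mask)
waveform_features(trace)
#> # A tibble: 1 × 2
#>   peak_minus_rest final_minus_rest
#>             <dbl>            <dbl>
#> 1            57.2             2.28

spectral_features(trim_buffers(trace), "whole")
#> <spectral_features> mode=whole: 225 amplitudes, 224 phases (0-14.9 Hz)
```

The waveform features say the leaf gained 57.2 °C over its resting
temperature by lamp-off and retained only 2.3 °C of that gain after 10 s of
cooling — brown leaves heat strongly and cool fast. The whole-signal
spectrum keeps the 225 below-Nyquist amplitude values (and 224 phases, the
0-Hz phase being identically zero) that feed the classifiers.

The full study replica — 240 videos, segmentation, features, statistics and
the 16-cell classification grid — is one call:

```r
run <- run_pipeline(dataset_config(seed = 1))
classification_table(run$grid)
#>   feature_set      n_features detection_lda detection_svm identification_lda identification_svm
#> 1 waveform                  2           1         1                   0.75               0.754
#> 2 whole_amp_1_10           10           1         1                   0.842              0.838
#> 3 rising_amp_1_10          10           0.9       0.917               0.738              0.562
#> 4 falling_amp_1_10         10           1         1                   0.729              0.75
```

Detection of foreign matter is essentially perfect on the synthetic
calibration, and twelve-class identification lands near 0.84 with whole
amplitudes and LDA, the errors concentrating in the deliberately confusable
bract / green-leaf / brown-leaf triplet (`autoplot()` on a grid report
draws the confusion matrix).

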