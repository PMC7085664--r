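---
title: "Classifying cognitive stress from interbeat-interval pictures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying cognitive stress from interbeat-interval pictures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibipics)
```

## The problem and the method

Cognitive stress modulates the autonomic nervous system, and with it the
beat-to-beat timing of the heart. `ibipics` classifies a driver's cognitive
stress level — low (LP, rest), normal (NP, ordinary driving) or high (HP,
driving while performing a distracting mental-arithmetic task) — from a
single-channel ECG, using a representation that needs no hand-engineered
features: consecutive interbeat intervals (IBIs) are mapped to binary
"pictures" and classified with a small convolutional network.

The pipeline is:

1. **Preprocess** the ECG: a zero-phase IIR notch removes 50 Hz mains
   interference, and a zero-phase high-pass removes baseline wander.
2. **Detect beats** with a Pan-Tompkins style QRS detector and take
   successive R-peak differences as IBIs.
3. **Filter** IBIs to the physiologically plausible closed range
   [0.6 s, 1.2 s].
4. **Encode**: the band is partitioned into N = 28 cells (widths 0.025 s at
   the band edges, 0.02 s in the middle); each IBI becomes a one-hot N-vector
   and m consecutive vectors are spliced into an N × m binary matrix — one
   picture, labelled by its segment's stress level.
5. **Classify** with an 8-layer CNN (conv 6 → pool → conv 16 → pool →
   conv 120 → dense 120 → 84 → 3, all kernels 5 × 5, pools 2 × 2).
6. **Compare** against the classical baseline: mean IBI, SDNN and RMSSD over
   10 s windows with 8 s overlap, fed to a 3-15-3 feed-forward network.
7. **Select the picture width** m by repeat-training the CNN for each m and
   examining mean accuracy and its relative standard deviation
   (RSD = sd/mean).

The time-domain features are the standard ones: for intervals
$\mathrm{IBI}_1,\dots,\mathrm{IBI}_n$,

$$\overline{\mathrm{IBI}} = \frac{1}{n}\sum_{i=1}^n \mathrm{IBI}_i,\qquad
\mathrm{SDNN} = \sqrt{\frac{\sum_{i=1}^n (\mathrm{IBI}_i-\overline{\mathrm{IBI}})^2}{n-1}},\qquad
\mathrm{RMSSD} = \sqrt{\frac{\sum_{i=1}^{n-1}(\mathrm{IBI}_{i+1}-\mathrm{IBI}_i)^2}{n-1}}.$$

## The synthetic session generator

No public recordings of the driving-simulator protocol exist, so the package
generates sessions with known ground truth. The protocol timeline is fixed:
rest (5 min 30 s, LP), normal driving (5 min 30 s, NP), mental calculations
(3 min, HP), then normal driving, calculations and normal driving again —
1680 s in all. Only the rest phase, the first normal-driving phase and the
two calculation phases enter the analysis data set, each trimmed to its
middle 300 s (150 s for the short phases) to avoid state-transition effects.

What the generator emulates, and the defaults chosen where no empirical
values exist:

* **State-dependent IBIs.** A truncated Gaussian with optional lag-1
  autocorrelation per state. Defaults: means 0.90 / 0.80 / 0.70 s for
  LP / NP / HP, sd 0.04 s, lag-1 correlation 0.3, support (0.55, 1.25) s.
  The ordering (shorter intervals under higher stress) is the physiological
  direction of sympathetic activation; the 0.1 s spacing keeps all three
  states inside the 0.6–1.2 s plausibility band while giving distinct
  histogram modes. The sd of 0.04 s is a typical short-term HRV magnitude
  for a seated adult. These are configurable knobs, not population
  estimates: the source study reports no per-state statistics.
* **Beat morphology.** One PQRST complex per beat as a sum of five Gaussian
  bumps with a dominant R wave normalized to amplitude 1. Real morphology
  (QRS slurring, T-wave asymmetry, respiration-driven amplitude modulation)
  is out of scope; only R-peak timing carries information downstream.
* **Noise.** Additive 50 Hz powerline interference (default amplitude 0.25
  of the R peak), band-limited baseline wander as a sum of eight random
  sinusoids in 0.05–0.5 Hz (peak amplitude 0.4), and white noise
  (sd 0.02). These are the two noise families the preprocessing stage
  exists to remove, plus a broadband floor.
* **Continuity.** The beat train is continuous across phase boundaries (the
  heart does not restart when the task changes); each phase draws its
  intervals from its own state distribution. The session ends with the last
  beat whose waveform fits inside the record.
* **Sampling rate** defaults to 500 Hz, typical of laboratory physiological
  recorders; rates below 100 Hz are rejected as unable to resolve the
  template.

Because all of this is synthetic, a passing pipeline demonstrates *parameter
recovery* — the method separates states that differ in IBI statistics the
way the generator says they do — not performance on real drivers. Real ECG
adds ectopy, motion artifacts, electrode pops, inter-subject morphology
differences and far messier state structure; none of those are modelled.

## Numerical and design choices

* **Notch filter**: second-order IIR biquad (constrained-pole design),
  default quality factor 30 (≈ 1.7 Hz bandwidth at 50 Hz), applied
  forward-backward. Two passes square the magnitude response, so attenuation
  at the notch frequency far exceeds 20 dB while the passband stays within
  a small fraction of a dB.
* **Baseline removal**: second-order Butterworth high-pass at 0.5 Hz, also
  applied forward-backward — a net fourth-order, zero-phase roll-off. A
  single fourth-order section has poles so close to the unit circle at this
  cutoff that linearity degrades to ~1e-8; the cascaded second-order form
  keeps the filter linear to better than 1e-9 relative, which the test suite
  asserts.
* **Edge handling**: both filters use reflective (point-mirror) padding of
  several settling lengths before filtering, so transients die out in the
  padding, not the data.
* **Pan-Tompkins constants**: 5–15 Hz third-order Butterworth band-pass
  (zero-phase), five-point derivative, squaring, 150 ms moving-window
  integration, 200 ms refractory period, dual adaptive thresholds
  initialized from the first 2 s, search-back at 1.66 × the running mean RR.
  Detections are re-localized at the band-passed signal's local maximum
  within ±75 ms, which removes the integrator's group delay; on noise-free
  templated signals recovered peaks sit within one sample of ground truth.
* **Plausibility bounds** are closed at both ends: the bin scheme's final
  cell is printed closed at 1.2 s, and the 0.6 s bound is treated
  symmetrically.
* **Bin boundaries** are built from integer millisecond values divided by
  1000, so boundary IBIs such as 0.7 s fall into their right-hand cell
  without floating-point surprises.
* **Window stride** for picture datasets defaults to 1 (maximal overlap):
  whether the original pictures overlapped is unknown, and stride 1
  maximizes data per session. It is a parameter.
* **Chronological split** is applied per class: each class's earliest 70 %
  of pictures train the model, and the remainder is randomly halved into
  validation and test (odd remainder → validation). Per-class splitting
  guarantees all three classes appear in every split even though the
  protocol's segments are far from interleaved in time.
* **CNN training details** the architecture's source leaves open — loss,
  optimizer, activation, padding, epochs — are set to the standard modern
  defaults: softmax cross-entropy, Adam at 1e-3, batch 32, ReLU,
  zero-padded "same" convolutions, 30 epochs. "Same" padding is the
  load-bearing choice: with strict unpadded convolutions the 5×5/2×2 chain
  collapses for pictures narrower than ~18 columns, and the sweep range
  starts at 16. The third convolution's 7 × ⌊m/4⌋ × 120 output is flattened
  into the 120-unit dense layer.
* **ANN baseline**: 3 inputs (mean IBI, SDNN, RMSSD, standardized on
  training-split statistics), 15 tanh hidden units, 3 linear outputs,
  argmax decision, random 70/15/15 split. The network is trained full-batch
  with Adam; the original's scaled-conjugate-gradient optimizer changes the
  optimization path, not the model class, and any full-batch gradient
  method reaching the same training loss is equivalent for the contract.
  Conflicting descriptions of the hidden transfer ("sigmoid" vs "hyperbolic
  tangent sigmoid") are resolved in favour of the more specific tanh.
* **Repeat training and RSD**: repeat i derives seed `base_seed + i`, which
  re-draws both the validation/test halving and the weight initialization,
  so the RSD reflects both sources of run-to-run variance. The recorded
  accuracy is the test-split accuracy (configurable), and the seed schedule
  is persisted so any repeat can be reproduced in isolation.
* **Neural-network engine**: convolutions are implemented via im2col with
  BLAS matrix products, with gradients verified against finite differences
  in the test suite. Training is single-threaded CPU and deterministic
  given the seed.

## Problem sizes used in the tests

The unit tests run on 30–60 s single-phase sessions and three-segment toy
datasets (~50 intervals per class). The end-to-end checks use full 1680 s
sessions at 500 Hz (~2,100 beats; ~1,000 pictures at m = 28): beat-detector
recovery is asserted at ≥ 99 % sensitivity and positive predictivity, the
CNN at ≥ 0.90 test accuracy within 6 epochs, the ANN at ≥ 0.80, and the
picture-width sweep runs m ∈ {16, 24, 32, 40} with 5 repeats of 2 epochs
each. With the default well-separated state means the CNN typically reaches
perfect test accuracy within one epoch, so short training suffices for the
recovery checks.

## A worked example

```{r example, eval = FALSE}
library(ibipics)

# a full synthetic session with noise, then the full pipeline
syn   <- synthesize_ecg(seed = 1)
noisy <- add_noise(syn$record, noise_spec(), seed = 2)
clean <- preprocess(noisy)$record
ibis  <- beats_to_ibis(detect_beats(clean))

segs <- session_segments(ibis)
ds   <- split_chronological(build_dataset(segs, m = 28), seed = 3)
res  <- train_cnn(ds, cnn_config(epochs = 6, seed = 3))
res$accuracy

# the HRV-feature baseline
ft  <- feature_table(lapply(segs, segment_windows))
ann <- train_ann(ft, ann_config(seed = 3))
ann$accuracy

# picture-width selection at reduced scale
sw <- sweep_m(synthetic_segments(seed = 4), m_values = c(16, 24, 32, 40),
              repeats = 3, config = cnn_config(epochs = 2))
sw$entries
```

## Known limitations

* The generator's IBI distributions are a deliberate simplification; the
  sweep's accuracy-vs-m profile on synthetic data need not peak where it
  would on real recordings, so no particular best m is asserted — only the
  structural behaviour of the sweep.
* The detector assumes upright R peaks of roughly uniform amplitude, which
  the template guarantees; inverted leads or strong amplitude modulation
  would need the thresholds revisited.
* With strongly separated synthetic states most classifier runs saturate at
  accuracy 1.0, making the RSD column nearly degenerate (zero spread);
  narrower state separations exercise it more realistically.
* Pictures discard the IBI ordering information finer than the bin width;
  that is by design (it is the representation under study), not a defect.
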