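---
title: "Transabdominal fetal oximetry: signal model, processing chain, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transabdominal fetal oximetry: signal model, processing chain, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfodetect)
```

## The measurement problem

Transabdominal fetal oximetry (TFO) shines red/near-infrared light into the
maternal abdomen and infers the fetal arterial oxygen saturation from the
light that diffuses back out. A small fraction of the detected photons has
traversed fetal tissue; their intensity is modulated by the fetal cardiac
cycle. The detected photoplethysmogram (PPG) is therefore a *mixed* signal:
maternal cardiac and respiratory pulsations, a large static (DC) component,
noise and motion artifacts, and a fetal pulsatile component that is two to
four orders of magnitude smaller than the DC level.

The chain implemented here turns raw frequency-multiplexed detector
recordings into a continuous, binary decision about instantaneous fetal
hypoxemia — saturation strictly below a clinical threshold, 30% by default —
using a multilayer perceptron that fuses information across five detectors.

## Optical model

The pulsatile absorbance change at wavelength $\lambda$ follows the modified
Beer–Lambert law with oxy- and deoxyhemoglobin as the chromophores:

$$\Delta A^{\lambda} = \left(S\,\varepsilon_{O_2Hb}^{\lambda}
 + (1-S)\,\varepsilon_{RHb}^{\lambda}\right)\Delta C_{THb}\,\langle L\rangle,$$

where $S$ is the arterial oxygen saturation, $\Delta C_{THb}$ the pulsatile
change in total hemoglobin concentration (mM), and $\langle L\rangle$ the
mean photon path length (cm). The ratio of absorbance changes at the two
wavelengths (the *modulation ratio*, or ratio of ratios)

$$\Phi = \frac{\Delta A^{\lambda_1}}{\Delta A^{\lambda_2}}$$

cancels $\Delta C_{THb}$ and $\langle L\rangle$ under the equal-path
assumption, leaving a closed-form, strictly monotone relation between $\Phi$
and $S$ that `saturation_from_phi()` inverts exactly. In practice
$\Phi \approx (AC^{\lambda_1}/DC^{\lambda_1}) / (AC^{\lambda_2}/DC^{\lambda_2})$
because absorbance changes are small.

The wavelengths are 740 and 850 nm — chosen in this field because fetal
saturations of 30–70% are resolved better there than by the conventional
660/940 nm pair. The instrument never reports extinction coefficients, so the
package ships the standard compiled hemoglobin spectra (Prahl) at these two
wavelengths as defaults; every operation accepts a user table
(`extinction_table()`), and the algebra holds for any non-singular table.
Out-of-range saturations are returned unclamped with a flag, so model
violations remain visible.

## Processing chain

1. **Demodulation** (`demodulate()`, `demodulate_recording()`). The two LEDs
   are toggled at 690 and 940 Hz; each color-blind detector samples their sum
   at 8 000 samples/s. Quadrature lock-in against the fundamental of each
   toggle square wave recovers the wavelength-specific envelope, with the
   $2/\pi$ fundamental factor removed analytically. Quadrature detection
   makes the result independent of the toggle phase.
2. **Rate reduction** (`downsample_ppg()`). 8 kHz → 80 Hz through cascaded
   decimate-by-10 stages (order-8 Chebyshev-I, 0.05 dB ripple, cutoff at 0.8
   of the new Nyquist, applied zero-phase). Two cascaded stages are used
   rather than a single order-8 filter at a normalized cutoff of 0.008,
   which is numerically fragile; each stage is additionally normalized to
   exactly unit DC gain (an even-order Chebyshev-I otherwise sits 0.05 dB
   low at DC, and two zero-phase passes would bias all power levels by
   −0.2 dB ≈ −2.3%).
3. **Source normalization** (`source_normalize()`). Detector gain and LED
   drive current are divided out so that rounds recorded at different
   instrument settings are comparable; the radiometric device constant
   defaults to 1 and is exposed.
4. **DC extraction** (`extract_dc()`). The DC is the lower envelope of the
   mixed PPG: strict local minima after a 3-sample median prefilter, thinned
   to a minimum spacing of a quarter maternal cardiac period (default
   0.25/1.3 s) keeping the lower of two close minima, then linear
   interpolation with constant extension at the ends. Fewer than two minima
   (monotone input) falls back to a flagged constant global minimum. Linear
   interpolation is the least-assumption choice; the spacing rule skips
   noise dimples without biasing the floor.
5. **AC extraction** (`build_reference()`, `lockin_ac()`). The fetal AC is
   isolated by lock-in detection referenced to the fetal heart rate measured
   independently (in the animal experiments, a carotid arterial line; in the
   simulator, the ground-truth trace — no PPG-derived FHR estimator is in
   scope). The reference phase is $2\pi\int \mathrm{FHR}(\tau)\,d\tau$
   (trapezoidal, after linear interpolation to the 80 Hz grid); the signal is
   mixed with the quadrature pair, low-passed with a zero-phase 4th-order
   Butterworth at 0.15 Hz, and the amplitude is $2\sqrt{I^2+Q^2}$. The
   0.15 Hz default rejects the maternal cardiac line whenever the FHR–MHR
   separation exceeds ~0.6 Hz (as in these experiments) while following the
   slow drift of the fetal amplitude; both cutoff and order are exposed.
6. **Features** (`compute_features()`). Pulsation ratios AC/DC per detector
   and wavelength (10), modulation ratios per detector (5). Modulation
   ratios outside [0.01, 100] are rejected as outliers — pulsation ratios
   more than two orders of magnitude apart indicate a corrupted measurement
   — and the remainder is averaged in a *centered* 1.5-min window emitted at
   1 sample/s. A centered window keeps features and labels time-aligned; an
   output sample is invalid when its window holds fewer than 10 non-outlier
   points (guards against single-point windows). Pulsation features are the
   same windowed means that form the modulation numerator/denominator, so
   the 15 features of a sample are mutually consistent. Labels come from
   linear interpolation of the sparse arterial-blood-gas (ABG) draws:
   hypoxemic iff strictly below 30%; boundary samples are normoxemic and
   samples outside the draw span are invalid.
7. **Fusion classifier** (`build_network()`, `train_network()`). A two-head
   MLP: a representation head (one 10→16 linear layer + ReLU) digests the
   standardized pulsation ratios — the *signature* of a round's geometry and
   attenuation — and its output is concatenated with the five
   per-round-standardized modulation ratios into a classification head
   128→64→32→16→1 (ReLU after each hidden layer, sigmoid output).
   Concatenation is the minimal combiner consistent with the architecture
   diagram. Training minimizes class-weighted binary cross-entropy
   (weight $N/(2N_c)$ per class) with Adam (lr $10^{-4}$, weight decay
   $10^{-4}$), at most 300 epochs, early stopping with patience 25 on the
   validation loss, restoring the best weights.
8. **Validation harness** (`assign_folds()`, `exclude_overlap()`,
   `run_cross_validation()`). Each round is split into five contiguous
   temporal folds; the validation fold is staggered across rounds (round
   $k$ starts at $20\%\cdot((k-1)\bmod 5)$) and shifted by 20% per
   iteration, so both training and validation see the full range of
   saturations despite the monotone within-round decline. Fold boundaries
   are computed in integer tenths, $\lfloor n l\rfloor < i \le
   \lfloor(n+0.2)l\rfloor$, so floating point cannot move a boundary and
   remainder samples land in the last fold of the cycle. Training samples
   whose 90-s smoothing windows strictly overlap any validation sample's
   window are discarded (windows touching at an endpoint do not overlap).
   Each iteration is evaluated on the pooled validation samples of all
   rounds; the summary is the mean over the five iterations.

### Numerical choices

- All zero-phase filtering uses odd-reflection edge padding (450 samples),
  which passes constants exactly and suppresses IIR start-up transients.
- The across-round (pulsation) standardizer is fitted on training samples
  only and applied to validation, preventing leakage; the per-round
  (modulation) standardizer uses each round's own samples, which is
  within-round normalization rather than leakage. A flag
  (`pulsation_fit = "all"`) switches the pulsation fit to all samples for
  comparison.
- Standardizers use population (divide-by-$n$) moments and refuse
  zero-variance features by name.
- Network weights initialize from a normal distribution scaled per layer as
  $\sqrt{2/\mathrm{fan\_in}}$ (He scaling); a fixed small standard deviation
  makes activations and gradients vanish through six ReLU layers and the
  output never leaves $\sigma(0)=0.5$. Biases start at zero.
- Mini-batches of 128 with seeded shuffling: full-batch training would take
  only 300 Adam steps at lr $10^{-4}$, far too few to move the parameters.
  Every RNG use (initialization, shuffling, bootstrap) is seeded, so runs
  are bit-reproducible.
- ROC curves sweep the unique predicted probabilities; AUC is trapezoidal.
  The AUC confidence interval is a stratified percentile bootstrap (default
  1000 resamples, seeded) — a documented package choice, since no CI method
  is prescribed for this design.
- Single-class validation sets (all-hypoxemic rounds exist by design) report
  the undefined rate as `NaN` with a warning rather than failing.

## The synthetic experiment generator

No public recordings exist for this measurement, so `sim_config()`,
`generate_truth()` and `synthesize_recording()` emulate the controlled
de-saturation experiments end to end, and all system-level tests run on that
emulation:

- five detectors at {1.5, 3, 4.5, 7, 10} cm with exponentially decaying
  received power and a fetal signal fraction that grows with distance
  (defaults 0.02–0.20, set so the fetal AC/DC spans roughly $10^{-3}$ to
  $10^{-2}$ — two to four orders below DC — across the 15–60% saturation
  range);
- a stepwise-declining saturation trajectory (one step per occlusion stage,
  linear drift within steps), ABG draws at the 2.5/5/10-min marks of each
  step with 0.5-point measurement noise, heart rates as bounded random walks
  within 120–174 bpm (fetal) and 75–84 bpm (maternal), and a fixed 0.25 Hz
  ventilator respiration with three harmonics (keeping the respiratory
  comb below ~1 Hz, clear of the fetal band);
- fetal amplitudes tied to the Beer–Lambert forward model, so the
  two-wavelength fetal AC/DC ratio equals $\Phi(S(t))$ by construction —
  the property the end-to-end recovery tests verify;
- LED multiplexing as 50%-duty square waves *band-limited below the raw
  Nyquist rate*. Sampling ideal squares at 8 kHz would fold their unbounded
  harmonic combs onto the 10 Hz intermodulation grid of the 690/940 Hz pair
  (their gcd), producing envelope ripple no real acquisition chain shows —
  a front-end anti-alias filter always precedes the ADC. The truncated
  Fourier series is exactly that filtered square;
- step, ramp and broadband-burst artifacts in configurable windows,
  defaulting to the blood-draw times.

`simulate_feature_cohort()` generates multi-round cohorts directly at the
1 Hz feature level (Beer–Lambert modulation ratios with round- and
detector-specific sensitivity, log-normal noise, pulsation levels growing
with distance), which is the scale at which the classifier and
cross-validation are exercised. Its default composition mirrors the animal
study: three rounds that start normoxemic and descend through the 30%
threshold plus two rounds hypoxemic throughout, 20–40 min each.

What the generator does **not** emulate: photon transport (fetal depth enters
only through the phenomenological fetal fraction), uterine contractions,
fetal movement beyond amplitude drift, pulse-shape harmonics (the lock-in
reads only the FHR-frequency component), and instrument drift. Passing tests
therefore demonstrate that the chain is a faithful, self-consistent
implementation of the method — not that the animal-study performance numbers
transfer, which would require the original recordings.

## Problem sizes used by the test suite

The suite and the acceptance script size their simulations for a desktop
run: unit tests use 1–4 min single-step rounds with two detectors; the
end-to-end saturation-recovery check uses one noise-free 15-min round
(three 5-min steps, 60%→15%, all five detectors); the classifier check uses
the five-round feature-level cohort (~9 600 samples) with three training
seeds; the fold audit runs 100 randomized round lengths between 5 and 5 000.

## Known limitations

- The FHR reference is taken as given; estimating it from the mixed PPG is a
  separate problem.
- Continuous-valued saturation regression is out of scope; the classifier
  answers only the thresholded question.
- The [0.01, 100] range rule is the only signal-quality filter; the `valid`
  flag is the extension point for richer quality indices.
- With a single detector, fetal depth and saturation are confounded; the
  fusion network resolves this only statistically, from the round signature.
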