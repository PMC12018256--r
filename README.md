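# tfodetect

Signal processing and classification for **transabdominal fetal pulse
oximetry (TFO)**: non-invasive, continuous detection of instantaneous fetal
hypoxemia through the maternal abdomen.

## The problem

Standard intrapartum monitoring (cardiotocography) reads fetal heart rate as
a proxy for fetal oxygen status and has a high false-positive rate for birth
asphyxia. TFO measures the quantity of interest directly: dual-wavelength
(740/850 nm) light is shone into the abdomen and five photodetectors at
1.5–10 cm from the source capture *mixed* maternal–fetal photoplethysmograms
(PPG). The fetal pulsatile component is 10²–10⁴ times smaller than the
static (DC) light level, buried under maternal cardiac and respiratory
pulsations.

This package is for researchers building or validating such pipelines. It
implements, end to end:

- **Oximetry algebra.** The modified Beer–Lambert law links the pulsatile
  absorbance change to saturation *S*:
  ΔA^λ = (S·ε_O₂Hb^λ + (1−S)·ε_RHb^λ)·ΔC_THb·⟨L⟩. The ratio of ratios
  Φ = ΔA^λ₁/ΔA^λ₂ ≈ (AC/DC)₇₄₀ ⁄ (AC/DC)₈₅₀ cancels concentration and path
  length; `saturation_from_phi()` inverts it in closed form.
- **Demodulation** of the 690/940 Hz LED-multiplexed 8 kHz detector outputs
  into per-wavelength envelopes, decimation to 80 Hz, and source
  normalization.
- **AC/DC decomposition**: DC as the lower envelope of the mixed PPG; fetal
  AC by quadrature lock-in referenced to the independently measured fetal
  heart rate (variable-frequency reference).
- **Features at 1 Hz**: ten pulsation ratios (AC/DC) and five modulation
  ratios Φ, with [0.01, 100] outlier rejection, 1.5-min smoothing, and
  hypoxemia labels (fSaO₂ < 30%) interpolated from sparse blood-gas draws.
- **Information fusion**: a two-head MLP (10→16 representation head;
  21→128→64→32→16→1 classification head) trained with class-weighted binary
  cross-entropy, Adam (lr 1e-4, weight decay 1e-4), early stopping.
- **Round-based five-fold cross-validation** with staggered validation folds
  and exclusion of training samples whose smoothing windows overlap
  validation windows, plus the full metric suite (confusion matrix,
  accuracy/sensitivity/specificity/precision/F1, ROC/AUC with stratified
  bootstrap CI).
- **A synthetic experiment generator** emulating controlled fetal
  de-saturation rounds (stepwise declining fSaO₂ under progressive aortic
  occlusion, scheduled blood draws, maternal/fetal heart-rate walks,
  ventilator respiration, motion/blood-draw artifacts), so the whole chain
  is testable without animal data.

See `vignettes/tfo-processing.Rmd` for the model, parameter rationale, and
what the simulator does and does not emulate.

## Worked example

Simulate a noise-free 15-minute round whose fetal saturation steps from 60%
to 15%, run the full chain, and read the saturation back from the smoothed
modulation ratio of each detector:

```r
library(tfodetect)

cfg <- sim_config(n_steps = 3, step_duration = 300, fsao2_start = 60,
                  fsao2_end = 15, noise_sd = 0, abg_noise_sd = 0, seed = 7)
truth <- generate_truth(cfg)
#> TFO ground truth: 900 s round, fSaO2 60.0% -> 15.0%, 9 ABG draws, 299/825 hypoxemic s

rec   <- synthesize_recording(cfg, truth)
#> TFO raw recording: 5 detectors, 900.0 s at 8000 sps, LED toggles 690/940 Hz

ppg   <- demodulate_recording(rec)
acdc  <- extract_acdc(ppg, fhr_trace(truth))
feats <- compute_features(acdc, truth$abg)
#> TFO feature samples: 900 rows (825 valid) from 1 round(s), 299 hypoxemic

# true fSaO2 at t = 450 s (mid second step) is 37.5%
mid <- match(450, feats$t)
sapply(1:5, function(d)
  100 * as.numeric(saturation_from_phi(feats[[paste0("phi_d", d)]][mid], cfg$eps)))
#> [1] 37.48 37.49 37.49 37.49 37.56
```

Every detector recovers the mid-step saturation within 0.1 points on clean
data; the 900 rows are the 1 Hz feature samples (825 valid after label-span
trimming), of which 299 are hypoxemic (interpolated fSaO₂ < 30%).

For classification, generate a five-round cohort at the feature level (three
rounds crossing the 30% threshold, two hypoxemic throughout) and run the
round-based cross-validation:

```r
feats <- simulate_feature_cohort(seed = 100)
cv <- run_cross_validation(feats, config = train_config(seed = 0))
cv$summary
#>    accuracy sensitivity specificity   precision          f1         auc
#>       0.899       0.949       0.790       0.902       0.924       0.943
```

`cv$counts` is the per-iteration table (class counts in training/validation,
all metrics), one row per cross-validation shuffle.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/tfo.R simulate --config cfg.yaml --out round.rds
Rscript inst/cli/tfo.R process  --in round.rds --fhr round_fhr.csv --abg round_abg.csv --out features.csv
Rscript inst/cli/tfo.R crossval --features features.csv --seed 1 --out report/
```

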