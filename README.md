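# seizr

Seizure-type detection from higher-order moments of EEG wavelet
distributions.

## What this is for

Electroclinical seizures with motor symptoms — tonic-clonic (TCSZ) and
complex partial (CPSZ) — need different clinical responses than purely
electrographic seizures (EGSZ), which show in the EEG without clinical
manifestations. `seizr` implements an automated three-class detector that
works from only the first 4 seconds of a seizure's onset in a single
scalp-EEG channel sampled at 400 Hz, so a type call can be made early.

The discriminating signal is the *shape* of the EEG's amplitude
distributions, not its power: skewness and kurtosis (third and fourth
standardized moments) are computed over moving windows in three domains —

- **temporal**: the raw samples in each window,
  `SK = E[(x - mu)^3] / sigma^3`, `KU = E[(x - mu)^4] / sigma^4`
  (population estimators, non-excess kurtosis: a Gaussian gives 3);
- **spectral**: moments of frequency weighted by the Hann-tapered STFT
  power spectrum about the spectral centroid `mu1 = sum(f_k s_k)/sum(s_k)`
  with spread `mu2`;
- **wavelet**: moments of each coefficient series of a 6-level
  maximal-overlap discrete wavelet transform (MODWT, Daubechies db4,
  circular boundary), whose series D1..D6, A6 tile 100–200, 50–100,
  25–50, 12.5–25, 6.25–12.5, 3.125–6.25 and 0–3.125 Hz at 400 Hz.

Per-window moments are averaged per channel, giving 2 temporal + 2
spectral + 14 wavelet features. An RBF-kernel SVM
(`k(x,y) = exp(-gamma ||x-y||^2)`, one-vs-one, features z-scored inside
each training fold) classifies the channels; the box constraint `C` and
kernel scale `gamma` are tuned by Gaussian-process Bayesian optimization
(Matern 5/2 surrogate, expected improvement, 30 evaluations over
`[1e-3, 1e3]^2` on a log10 scale) against the 10-fold cross-validated
misclassification rate. Class imbalance is handled by random
undersampling to the minority class; reports include sensitivity,
specificity, precision, accuracy, F1 and the Matthews correlation
coefficient per class and macro-averaged.

Clinical corpora with per-channel seizure-type annotations are
registration-gated, so the package ships a synthetic EEG generator with
three spectrally distinct archetypes (EGSZ low-frequency dominant and
strongly right-skewed; CPSZ rhythmic mid-band; TCSZ broadband with heavy
high-frequency power) that exercises every stage of the pipeline without
any download. Real recordings enter through EDF files or delimited text
plus a label manifest.

## Worked example

```r
library(seizr)

segs <- simulate_dataset(dataset_spec(c(TCSZ = 20, CPSZ = 20, EGSZ = 20),
                                      seed = 1))
ft  <- extract_feature_table(segs, window_config(0.5, 50))
bal <- random_undersample(select_features(ft, "wavelet", "skew"), seed = 2)
report <- cross_validated_report(bal, svm_config(), k = 10, seed = 3)
report
#> <cv_report> 10-fold CV, pooled accuracy 0.9167
#> <metrics_report> overall accuracy 0.9167 (macro MCC 0.8756)
#>  class sensitivity specificity precision     f1    mcc
#>   CPSZ        1.00       0.950    0.9091 0.9524 0.9293
#>   EGSZ        0.90       0.975    0.9474 0.9231 0.8867
#>   TCSZ        0.85       0.950    0.8947 0.8718 0.8107

tn   <- tune_svm(bal, k = 10, cv_seed = 3, budget = 30, seed = 4)
post <- cross_validated_report(bal, tn$best_cfg, k = 10, seed = 3)
post$metrics$overall_accuracy   # 0.95
post$metrics$macro[["mcc"]]     # 0.9263
```

Sixty channels (20 per class) are simulated, 7 per-level wavelet-skewness
features are extracted from 0.5 s windows with 50 % overlap, and a
10-fold cross-validated RBF-SVM reaches 91.7 % pooled accuracy with the
default configuration; Bayesian tuning of `(C, gamma)` lifts it to 95 %
with a macro MCC of 0.93. Larger runs (60 channels/class) land around
96 % — see the acceptance script below.

A command-line interface wrapping the same functions lives at
`inst/cli/seizr.R` (subcommands `simulate`, `extract`, `decompose`,
`train`, `optimize`, `evaluate`); see the header of that file for usage.

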