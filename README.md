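# ramanTBI

Detection of traumatic brain injury (TBI) from Raman spectra of the
neuroretina. The eye shares the brain's metabolic environment, and injury
shifts the lipid/protein balance of the retina in a way Raman spectroscopy
can read out: the C–H stretching bands at 2850 cm⁻¹ (CH₂ symmetric, lipids)
and 2930 cm⁻¹ (CH₃/CH asymmetric, protein-associated) change relative
intensity, and the peak ratio R = I(2930)/I(2850) separates injured from
control tissue. This package implements the complete chemometric pipeline
behind that idea, for spectroscopists and analysts working with retinal (or
other tissue) Raman maps:

- **Preprocessing** — nearest-neighbour cosmic-ray removal across a map,
  fluorescence baseline subtraction (iterative spline with 11 nodes, or
  modified polynomial of order 9 with noise tolerance 1.50), standard normal
  variate (SNV) and unit-area normalization, 1 cm⁻¹ grid resampling, region
  cropping.
- **SKiNET** — a supervised Kohonen self-organizing map (SOM) classifier on
  a hexagonal neuron grid with cosine-similarity matching. Class labels are
  carried as one-hot class weight vectors updated by the same neighbourhood
  rule but excluded from best-matching-unit selection, so supervision never
  distorts the learned topology. The SOM discriminant index (SOMDI) then
  reads off which wavenumbers drive each class's clustering.
- **NNLS decomposition** — non-negative least-squares unmixing of per-sample
  average spectra against a brain-lipid component library (cardiolipin,
  cytochrome C, ganglioside, cholesterol) over 1200–3000 cm⁻¹, with
  group-wise effect statistics.
- **Biomarker statistics** — the six-peak + ratio "barcode", box-plot
  summaries, and a nonparametric ROC whose AUC is computed both by threshold
  sweep and by the Mann–Whitney U statistic (the two agree to 1e-10 by
  construction).
- **Synthetic cohort generator** — labelled TBI/control cohorts with
  realistic band structure, fluorescence baseline, noise and cosmic rays,
  whose per-sample ratio distributions are log-normals calibrated exactly to
  a target median and interquartile range (defaults: median 2.34, IQR 0.63
  for TBI; 0.48, 0.12 for controls; 39 vs 12 samples, 400 spectra/sample).
  Every injected artifact is recorded as ground truth, so the whole pipeline
  is testable without instrument data.

## The model in brief

A SOM is a grid of neurons n with weight vectors **w**ₙ. Each training step
presents a spectrum **x**, finds the best matching unit
b = argmaxₙ cos(**w**ₙ, **x**), and updates every neuron

&nbsp;&nbsp;**w**ₙ ← **w**ₙ + α(t)·h(n, b, t)·(**x** − **w**ₙ),

with learning rate α(t) decaying linearly from 0.3 and a Gaussian
neighbourhood h over hex-centre distance whose radius decays from ⅔ of the
grid edge length to 1. Class weight vectors **c**ₙ receive the same update
driven by the sample's one-hot label, but play no part in matching. After
training, a class's SOMDI profile is the mean of **c**ₙ[class]·**w**ₙ over
the neurons whose class weight argmax is that class, minus the mean weight
of all activated neurons; its peaks name the discriminating wavenumbers.

## Worked example

Simulate a small cohort, classify the high-wavenumber region, and extract
the discriminant features and the biomarker:

```r
library(ramanTBI)

cfg <- cohort_config(n_tbi_samples = 5, n_control_samples = 5,
                     spectra_per_sample = 50, seed = 101)
cohort <- simulate_cohorts(cfg)

# classification branch: crop to the C-H stretching window, SNV-normalize
hw <- snv_normalize(crop_region(
  spectral_map(cohort$wavenumber, cohort$intensities, cohort$meta),
  2800, 3200))
X <- t(hw$intensities); colnames(X) <- hw$wavenumber

split <- stratified_split(cohort$meta$class, 0.2, seed = 101)
model <- skinet(X[split$train, ], cohort$meta$class[split$train], seed = 101)
model
#> SKiNET supervised SOM
#>   grid: 10 x 10 hexagonal neurons
#>   channels: 401; classes: control, TBI
#>   training: 3600 steps (9 epochs over 400 spectra), alpha0 = 0.3,
#>   radius0 = 6.667, cosine metric

confusion_matrix(cohort$meta$class[split$test], predict(model, X[split$test, ]))
#>          predicted
#> true      control TBI
#>   control      50   0
#>   TBI           0  50

somdi(model)
#> SOMDI profiles for 2 classes over 401 channels
#>   control: top peaks at 2852, 3096, 3174 cm^-1
#>   TBI: top peaks at 2928, 2902, 3108 cm^-1
```

The test spectra classify perfectly, and SOMDI localizes the evidence where
the physiology puts it: the TBI profile peaks at ~2930 cm⁻¹ and the control
profile at ~2850 cm⁻¹. The biomarker itself comes from a sample's averaged,
baseline-corrected map:

```r
avg <- average_spectrum(remove_cosmic_rays(cohort_sample_map(cohort, "TBI_01")))
corr <- subtract_baseline(avg, baseline_config("modified_poly"))$corrected
barcode(corr)
#> Barcode features:
#>   I1266   I1452   I1660   I2850   I2880   I2930
#> 0.33905 0.48446 0.58500 0.96155 0.80416 2.12665
#> 2930/2850 ratio: 2.2117
```

against a ground-truth sample ratio of 2.193 — the measured barcode recovers
the injected injury effect within ~1%. `run_pipeline(pipeline_config(seed = 1))`
chains all stages (simulate → despike → split → train → repeated evaluation
→ SOMDI → NNLS decomposition → ratio statistics and ROC) into one
deterministic report; see `format_report()`.

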