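---
title: "Methods: Raman retinal TBI detection with ramanTBI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Raman retinal TBI detection with ramanTBI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramanTBI)
```

## The problem

Traumatic brain injury changes the lipid and protein composition of neural
tissue, and the retina — developmentally part of the central nervous system
— carries that signature. In Raman spectra of retinal tissue the change
concentrates in the high-wavenumber C–H stretching region: the CH₂
symmetric stretch near 2850 cm⁻¹ (lipid-dominated) and the CH₃/CH
asymmetric stretch near 2930 cm⁻¹ (protein-associated) shift in relative
intensity, making the peak ratio R = I(2930)/I(2850) a candidate
diagnostic. ramanTBI implements the full analysis chain around that
biomarker: spectral conditioning, a supervised self-organizing-map
classifier with discriminant feature extraction, component unmixing, and
nonparametric diagnostic statistics — together with a calibrated synthetic
cohort generator that makes each stage testable end to end.

## Preprocessing

**Cosmic rays.** Detector spikes are narrow (1–3 channels), large, and
uncorrelated between map positions. `remove_cosmic_rays()` compares each
spectrum with the median of its k = 2 nearest neighbours (spatial positions
when present, acquisition order otherwise) and replaces channels that
*exceed* the neighbour median by more than 8 robust standard deviations
(MAD of the deviation series). Only positive excursions are flagged:
cosmic rays are additive, and one-sided flagging guarantees a clean
spectrum is never altered by a spiked neighbour — the despiking touches
exactly the corrupted channels and nothing else. For isolated spectra
`despike_spectrum()` provides a within-spectrum fallback (5-channel running
median, threshold floored at 1% of the filtered maximum so band curvature
on quiet spectra is never mistaken for a spike); it is the weaker method
and is only a fallback.

**Baseline.** Tissue autofluorescence produces a broad smooth background.
Two corrections are provided. `modified_poly` iterates a polynomial fit
(default order 9): points above `fit + 1.50 × residual-sd` are treated as
peak regions and clipped out, and the fit repeats until the baseline
changes by less than 1e-4 (relative) or 50 iterations. The noise-tolerance
multiplier 1.50 decides how aggressively shoulders count as peaks. The
`spline` variant emulates instrument-style "intelligent" spline fitting:
the axis is split into 11 segments, a knot is placed at the running-median
minimum of each, a natural cubic spline is drawn through the knots, the
working spectrum is clipped to the spline, and the process repeats to
convergence. Both methods exactly annihilate any baseline inside their
model class (a polynomial of the fitted order reduces to numerical zero),
which the tests assert.

**Normalization.** SNV (`(x − mean)/sd` per spectrum) removes additive and
multiplicative intensity effects and is the default before classification.
Unit-area normalization (trapezoidal integral over the retained axis scaled
to 1) puts spectra from different instruments on one scale and is the
contract checked by the acceptance script. Area normalization is
idempotent; SNV is affine-invariant.

**Grids.** `resample_unit_grid()` linearly interpolates onto integer
wavenumbers (ceil(min)…floor(max), never extrapolating), the common grid
for library fitting; `crop_region()` selects analysis windows — 1200–1700
(fingerprint) and 2800–3200 cm⁻¹ (high-wavenumber) are the ones used here.

## SKiNET: supervised SOM with SOMDI

A self-organizing map places neurons on a hexagonal grid (offset rows,
unit spacing; grid distance = Euclidean distance between hex centres). Each
neuron n holds a spectral weight vector **w**ₙ, initialized uniformly
within the per-channel data range, and a class weight vector **c**ₙ,
initialized uniform over classes. Training draws spectra in shuffled-epoch
order and updates all neurons toward the sample with a Gaussian
neighbourhood kernel centred on the best matching unit (BMU); the class
weights receive the identical update driven by the sample's one-hot label.
The BMU is the cosine-similarity argmax over spectral weights *only* — the
operational meaning of supervision "without influencing the training
process". Cosine matching also makes classification invariant to overall
intensity scale.

Defaults follow the published configuration: 10 × 10 grid (20 × 20
supported), 9 epochs, initial learning rate α₀ = 0.3, initial neighbourhood
radius ⅔ × max(rows, cols). The decay schedules are not published; we use
linear decay to (0.01 α₀, 1) over the step budget — standard Kohonen
practice — with the kernel a Gaussian of hex-centre distance. The step
budget is epochs × n (57,600 steps at nine epochs corresponds to 6,400
training spectra); an explicit `steps` override samples with replacement
when it exceeds epochs × n and truncates the shuffled order otherwise.
Ties in the BMU search break to the lowest neuron index; ties in class
assignment to the first class in sorted order. All stochastic steps are
pure functions of the seed.

**Prediction.** A spectrum's label is the class-weight argmax at its BMU.
A neuron that activated no training data carries no class evidence, so such
BMUs defer to the nearest activated neuron by grid distance — the analogue
of the blank neurons on a map display.

**SOMDI.** For class c, take the activated neurons whose class-weight
argmax is c, average their class-weight-scaled spectral weights, and
subtract the mean spectral weight over all activated neurons. The
subtraction is a design choice that turns "prominent for this class" into a
contrast against the map's shared structure (toggleable via `contrast =
FALSE`); without it, single-class maps would return their mean spectrum
rather than ≈ 0. Profile peaks (local maxima ranked by intensity) name the
discriminating wavenumbers.

**Evaluation.** `stratified_split()` reserves round(20%) of each class;
`kfold_cv()` runs stratified 10-fold cross-validation;
`evaluate_repeated()` retrains from 10 independent initializations and
averages the confusion matrices elementwise, verifying stability rather
than a lucky start.

## NNLS decomposition

Per-sample average spectra (mean over the despiked map, baseline-corrected,
on the integer grid) are fitted over 1200–3000 cm⁻¹ against a four-member
brain-lipid library — cardiolipin, cytochrome C, ganglioside, cholesterol —
by non-negative least squares (Lawson–Hanson active set, via
`pracma::lsqnonneg`). Every fit is checked against the KKT conditions
(gradient ≈ 0 on positive coefficients, ≥ 0 on zero ones, 1e-8 relative).
The shipped library is synthetic — pseudo-Voigt band models encoding the
documented assignments (cardiolipin concentrating amplitude at 2850
relative to 2930; cytochrome C carrying the strong 1660 cm⁻¹ band) — and
is intended for simulation and testing; measured component spectra can be
loaded with `read_spectra()` + `component_library()`. By default the fit is
raw, so a spectrum equal to 2 × a component returns exactly coefficient 2;
`normalize = TRUE` (used by `run_pipeline()`) scales the target and the
components to unit area first so coefficients are comparable across
samples, at the cost of that literal interpretation. Whether the published
decomposition ran on baseline-corrected or raw averages is not stated; the
pipeline corrects first, and `nnls_fit()` itself is agnostic.
`compare_groups()` reports per-component Welch t statistics with
normal-based 95% confidence intervals, flagged at α = 0.05.

## Biomarker statistics

`barcode()` extracts six peak intensities (defaults 1266, 1452, 1660, 2850,
2880, 2930 cm⁻¹; 2955 is a drop-in alternate since the exact published
feature set is read off a figure) as windowed maxima (±10 cm⁻¹; a windowed
integral mode exists) plus the 2930/2850 ratio. Quartiles use the
linear-interpolation (type-7) convention — stated because IQR-based
results change with the convention — and whiskers sit at Q1 − 1.5 IQR and
Q3 + 1.5 IQR clipped to the data extremes. ROC curves sweep the decision
threshold over the observed scores; the AUC is computed both by
trapezoidal integration of that curve and as U/(n₊ n₋) with ties counting
½, and the two are asserted equal to 1e-10 on every call — a built-in
cross-check, additionally validated against an independent ROC
implementation in the tests. Ratios enter the box plots and the ROC per
*sample* (one averaged spectrum per tissue sample), not per spectrum,
matching how the group sizes (39 vs 12) are counted.

## The synthetic cohort generator

The generator emulates the porcine study conditions, which are its
defaults: 39 TBI and 12 control samples, 400 spectra per sample, a
500–3500 cm⁻¹ axis at 1 cm⁻¹. Each sample draws a true ratio from a
group-wise log-normal; the log-normal is parameterized *exactly* from the
printed summaries via μ = log(median), σ = asinh(IQR/(2·median))/z₀.₇₅
(log-normal chosen for positive support and right skew consistent with the
published box plots; medians and IQRs are the only printed constraints).
Defaults: median 2.34 / IQR 0.63 (TBI), 0.48 / 0.12 (control). Each
spectrum is then a pseudo-Voigt band mixture — FWHM 25 cm⁻¹ in the
fingerprint region, 45 cm⁻¹ in the high-wavenumber region, Lorentzian
fraction 0.5, typical condensed-phase widths since only positions are
published — whose 2850/2930 amplitudes are solved from a 2 × 2 cross-talk
system so the summed signal hits the target peak heights exactly at both
band centres, plus fixed companion bands (1266, 1452, 1660, 2880,
2955 cm⁻¹), a broad fluorescence background declining toward high
wavenumber, i.i.d. Gaussian channel noise (sd 0.02 of the 2850 peak
height), Poisson cosmic rays (rate 0.1/spectrum, 1–3 channels wide, 5–50 ×
local signal), and 5% multiplicative log-normal jitter on band amplitudes
and the realized ratio so within-sample spectra vary. Every spike and
every true ratio is recorded as ground truth. The published study also
reports a "510 measurements" total alongside 400 spectra per sample; the
two counts do not reconcile, so the generator simply exposes sample counts
and spectra-per-sample as independent knobs.

What the generator does *not* emulate: instrument response and wavelength
calibration error, detector dark current, spatial correlation across a
map, biological heterogeneity beyond the single ratio effect (companion
bands differ only by jitter between groups), and any optics of the eye.
Passing tests therefore demonstrate that the algorithms recover what the
model injects — band-level discriminants, calibrated ratio distributions,
spike positions — not that real retinal data would behave as cleanly.
The group separation implied by the printed medians is large, so on
calibrated synthetic cohorts the per-sample ratio ROC is essentially
perfect; the published porcine AUC (90.7 ± 0.9%) reflects real-tissue
variability the generator does not model, and no claim of reproducing it
is made.

## Numerical choices and degenerate inputs

- Polynomial baselines fit an orthogonal-polynomial basis on an axis
  rescaled to [−1, 1]; the QR decomposition is computed once per spectrum.
- Convergence: baseline relative change < 1e-4; NNLS KKT tolerance 1e-8
  relative; area normalization verified to 1e-10.
- Zero-norm inputs to the BMU search, constant spectra under SNV,
  nonpositive areas, empty crops, and sub-2 cm⁻¹ spans are explicit
  errors; a metric with a zero denominator is flagged "undefined" rather
  than returning NaN.
- `run_pipeline()` defaults to a reduced profile (8 + 8 samples × 40
  spectra, 8 × 8 grid, 3 repeat initializations) chosen so an interactive
  end-to-end run completes in about a minute; the test suite similarly
  exercises SOMDI recovery at 5 + 5 samples × 50 spectra over ten seeds
  and calibration checks at 10⁴ draws. These sizes are the package's own
  test-design choice; full study scale is a configuration away.
- Per-stage seeds derive deterministically from the global seed and the
  stage name, so every reported number is a function of (config, seed) and
  the full report is byte-reproducible.

## Known limitations

The spline baseline is a faithful-but-chosen reconstruction of a
proprietary instrument routine, and the SOMDI contrast term operationalizes
a qualitative published description; both are documented design choices,
not ports. The component library is synthetic unless the user supplies
measured spectra. The within-spectrum despiker cannot remove spikes wider
than half its window. Cross-validated accuracy and ROC AUC answer
different questions and are both provided; neither is asserted to be the
published evaluation procedure, which is ambiguous on this point.
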