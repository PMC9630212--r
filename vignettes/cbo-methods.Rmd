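---
title: "Measuring collagen bundle orientation by Fourier analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring collagen bundle orientation by Fourier analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbofourier)
```

## The measurement

Collagen bundle orientation (CBO) in scar tissue ranges from strongly
parallel (anisotropic) to random (isotropic), and this architecture matters
mechanically: infarct scars with different bundle alignment behave
differently under load. `cbofourier` implements a semi-automated protocol
that quantifies CBO from a single stained micrograph through its
two-dimensional Fourier power spectrum.

A field of parallel bundles concentrates spectral energy in a narrow band
perpendicular to the bundle direction; a field of randomly oriented bundles
spreads energy isotropically. The protocol turns this into a scalar:

1. **Best-fit contrast** - a percentile-clipped linear stretch to the full
   working range (`best_fit_contrast()`, default clip 0.5% per tail).
2. **Greyscale conversion** - Rec. 601 luminance, 16-bit working depth by
   default (`to_grey()`). The index is invariant to this depth choice
   because the spectrum is renormalized.
3. **Power plot** - center crop to a square, mean subtraction, optional
   Hann window, FFT, `log(1 + |F|)`, and scaling by `gain / max` onto a
   0-255 display range (`compute_power_spectrum()`). The DC bin, zeroed by
   the mean subtraction, is replaced by the maximum of its 8 neighbors.
4. **Pre-filter** - Gaussian smoothing of the scaled plot
   (`prefilter_sigma`, default 1.5 bins). Finite images produce spectral
   speckle; without smoothing, isolated speckle clusters survive
   thresholding far from the center and corrupt the measured shape.
5. **Segmentation** - a threshold on the 0-255 scale selects the central
   frequencies (`segment_spectrum()`), either automatic (Otsu) or manual.
6. **Cleanup** - area filter, hole filling, morphological
   closing/opening, removal of thin radial spikes by an opening
   (`clean_mask()`, `split_spikes()`), and finally the filled convex hull
   of everything that survives.
7. **Axes** - the maximum caliper (Feret) length of the plot and the
   width perpendicular to it (`measure_axes()`).
8. **Index** - width / length, in (0, 1]: near 0 for parallel bundles,
   near 1 for random orientation (`orientation_index()`).

`measure_micrograph()` composes all steps and is deterministic for a fixed
image and `measurement_config()`.

### Why the segmented plot is the union of significant components

After mean subtraction the DC bin is not guaranteed to sit inside a single
connected suprathreshold blob. For broadband micrographs it practically
always is; but for band-limited textures (a grating-like, strongly periodic
bundle field) the plot consists of a pair of conjugate-symmetric lobes that
do not touch the center. The pipeline therefore keeps every thresholded
component that passes the area filter (always including the DC-containing
component when present) and lets the convex hull - which the protocol
applies anyway - merge them into the single measured object. For ordinary
micrographs this is indistinguishable from keeping only the central blob;
for band-limited inputs it recovers the obviously correct elongated plot.

Spike removal runs *before* the hull: an opening cannot undo hull inflation
afterwards, so removing thin leakage spikes (e.g., the axis-aligned cross
produced by the periodic-extension discontinuity at image edges) must
precede it.

### Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `spectrum_gain` | 100 | scales the log-magnitude plot onto 0-255; higher gain lifts faint structure (values clip at 255) |
| `threshold_mode` | auto (Otsu) | reproducible hands-free default; `manual` mirrors the operator's choice |
| `prefilter_sigma` | 1.5 bins | spectral speckle suppression before thresholding |
| `min_area_fraction` | 5e-4 | area filter for satellite components |
| `smoothing_radius_px` | 2 | closing/opening disk radius |
| `spike_removal_radius_px` | 3 | opening disk for thin radial spikes |
| `apply_convex_hull` | TRUE | final homogenization, merges symmetric lobes |
| `window` | none | `hann` suppresses the edge-leakage cross; recommended for synthetic fields and rotation studies |
| `clip_percentile` | 0.5 | contrast-stretch clipping per tail |

Every configuration carries an md5 digest (`config_digest()`) that is
stored with each measurement record, so manual parameter choices remain
auditable.

### Choice of threshold for the synthetic studies

The validation studies (`study_config()`) fix `gain = 100`, `window =
"hann"` and a manual threshold of 70. Otsu's method, applied to a
log-compressed spectrum, tends to place the cut inside the diffuse floor
(the log transform compresses the bright core and inflates the faint tail
into a large class), which keeps the outer fan of weak single-fiber rays
and biases the index upward for strongly aligned fields. A fixed cut at 70%
of the display maximum selects the bright core the way an operator does.
The automatic mode remains the default for hands-free use and is what the
simulated interrater study exercises (Otsu versus Otsu + 10 grey levels).

Band-limited gratings use `grating_config()` (gain 200, manual threshold
128, no pre-filter or spike opening, relaxed area filter): with energy
concentrated in a few small lobes, the operator's response is to raise the
gain until the plot is well defined, and blob-scale cleanup would destroy
lobes only a few pixels across.

## Optimized Masson images

Masson's trichrome stains collagen blue but also stains cellular
structures purple, and those cellular components contribute isotropic
power that pushes the CBO index toward "random". `segment_cellular()`
selects the purple class in HSV space (default hue 260-340 degrees,
saturation >= 0.15, value >= 0.10) and `remove_non_collagen()` replaces
those pixels, producing the digitally "optimized" image.

The default fill (`local_background`) estimates the local background color
by normalized convolution restricted to the bright background class and
feathers the filled pixels at the optical blur scale. Both details matter:
a global mean or plain white fill leaves blob-shaped luminance steps, and
an unblurred fill boundary injects broadband power - either artifact
re-inflates the very index the optimization is meant to correct. Unmasked
pixels are never modified.

## The synthetic model

No real micrographs ship with the package, so validation rests on a
generator with exact ground truth (`generate_fiber_image()`,
`generate_masson_image()`):

* straight, anti-aliased fiber segments; orientations follow an **axial
  von Mises** law (angles doubled onto the circle, concentration `kappa`;
  `kappa = 0` is axial-uniform, `kappa = 8` gives an angular SD of about
  10 degrees);
* **stratified** random centers over a grid - real scar collagen fills the
  field roughly uniformly, and pure Poisson placement adds an isotropic
  low-frequency density noise that swamps the anisotropy signal at small
  field sizes;
* default field 256 px with ~512 fibers of length 120-250 px, width
  3-6 px, Gaussian PSF blur of 1.2 px (sharp vector strokes throw
  unrealistically long spectral rays), background noise SD 6, intensity
  normalized to 235;
* Masson scenes composite opaque blue fibers over a pale background with
  irregular purple blobs painted in the interstitial space (cells are
  molded around bundles); the scene uses ~110 fibers so background and
  blobs remain visible; the ground-truth blob mask is exactly the visible
  purple pixels.

What the generator does **not** emulate: curved or wavy bundles, staining
gradients and batch effects, polarized-light birefringence, confocal PSF
anisotropy, uneven illumination. Passing the synthetic studies shows the
pipeline recovers known orientation structure under realistic speckle and
noise - it does not certify absolute index values on real stains, which
depend on acquisition settings exactly as they do for a human operator.

## Validation studies

The package ships its own validation harness (all under `tests/testthat/`
and re-run by `scripts/acceptance.R`):

* **Grating limit** - pure sinusoidal gratings at 0/30/60/90 degrees
  measure below 0.15 (`grating_study()`).
* **Isotropy / parallel limits and monotonicity** - mean index over 20
  seeds is above 0.80 at `kappa = 0`, below 0.35 at `kappa = 8`, strictly
  decreasing over `kappa` in {0, 1, 2, 4, 8}, and its ranking matches the
  independent spectral second-moment oracle
  (`kappa_study()`, `oracle_spectral_anisotropy()`). The oracle is used
  for ordering only: the index depends on threshold and morphology
  choices, so no closed form predicts its value.
* **Rotation robustness** - rotating the field by 45 degrees changes the
  index by at most 0.10 and shifts the major-axis angle by 45 +- 5 degrees
  (`rotation_study()`).
* **Caliper cross-validation** - `measure_axes()` (exact hull-pairwise
  caliper) agrees with `oracle_feret()` (exhaustive rotation sweep) within
  1.5% on 50 random ellipse masks (`feret_study()`). Ellipses are used
  because random polygons routinely realize the caliper maximum on two
  distant, numerically tied vertex pairs, which makes the perpendicular
  width ill-posed for any implementation pair.
* **ICC** - exact unity for an additive column shift; equality with a
  from-definitions ANOVA oracle to 1e-10; recovery of a known population
  ICC of 0.95 within +-0.02 at n = 500 (`make_reliability_fixture()`).
* **Bland-Altman** - the +-2 SD limits contain 95.45% +- 0.5% of Gaussian
  differences at n = 1e5.
* **Masson inflation and correction** - cellular blobs inflate the raw
  index; after hue segmentation and removal the index returns to within
  0.10 of the blob-free reference (`masson_study()`).
* **Interrater surrogate** - two simulated raters (Otsu vs Otsu + 10 grey
  levels) on 21 samples x 5 fields give a consistency ICC >= 0.90
  (`interrater_study()`).

Problem sizes (256-px fields, 20 seeds per condition, 50 masks, n = 500
fixtures) are chosen so the whole suite completes in minutes on a laptop
while keeping Monte-Carlo error well inside the test margins.

## Reliability statistics

For a samples-by-raters (or samples-by-techniques) matrix of mean indices:

* `icc_consistency_average()` - two-way random-effects, consistency,
  average-measures ICC: `(MS_R - MS_E) / MS_R` from the two-way ANOVA
  without replication, with the one-sided F test (H0: ICC = 0) and the
  F-based confidence interval `[1 - 1/F_L, 1 - 1/F_U]`.
* `bland_altman()` - bias and limits of agreement at exactly +-2 SD of the
  differences (the convention used in the source protocol, not 1.96 SD).
* `coefficient_of_variation()` - `CV% = 100 * SEmeas / mean` with
  `SEmeas = s_pooled * sqrt(1 - ICC)`, the standard error of measurement
  consistent with an ICC-based reliability analysis (the one formula
  reconstructed rather than copied from a printed source).
* `reliability_report()` - one row per column pair: ICC with CI and p,
  Bland-Altman bias and limits, CV% and SEmeas - the layout of an
  interrater or intertechnique agreement table. Pairwise rather than
  omnibus, because each pair of techniques is a separate scientific
  question.

Numerical conventions worth knowing: a residual sum of squares at rounding
noise level is treated as exactly zero, so identical-up-to-a-shift columns
give ICC = 1 exactly, F = Inf and p = 0; fewer than 5 subjects warns
rather than errors (the degrees of freedom permit n >= 2, and small
fixtures must run); histogram bins are half-open on the left, with
edge values assigned to the right bin.

## Design notes and limitations

* The tabular half of the package (measurement records, rater matrices,
  reports) speaks tibbles with `tidy()`/`glance()`/`autoplot()` methods;
  images and spectra are lightweight S3 wrappers around matrices.
* The power plot's conjugate symmetry makes a half-spectrum display and
  the full centered spectrum equivalent for axis measurement; the full
  symmetric plot is used.
* Angles are degrees in [0, 180), counterclockwise from the +x (column)
  axis; the spectral major axis is perpendicular to the dominant fiber
  direction in image space. Caliper ties are broken toward the smallest
  angle; `oracle_feret()` additionally accepts any direction within the
  worst-case grid discretization error of the maximum before applying the
  same rule.
* Non-square images are center-cropped to a square before the FFT so the
  two frequency axes are sampled equally.
* The index is a global, whole-field statistic: local orientation maps,
  fiber tracing, curvature and collagen density are out of scope.
* The DC bin of the displayed spectrum is only guaranteed to be the global
  maximum for broadband images; band-limited inputs peak at their carrier
  frequency instead.
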