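# cbofourier

Semi-automated measurement of **collagen bundle orientation (CBO)** in
histology micrographs by two-dimensional Fourier analysis, with the
reliability statistics used to compare raters and staining/microscopy
techniques.

Scar collagen architecture — from strongly parallel bundles to random
meshwork — shapes the mechanics of healing tissue, most prominently in
myocardial infarct scars. This package quantifies it from a single
micrograph: the 2D FFT power plot of an aligned field concentrates energy
in a band perpendicular to the bundles, while a random field is
isotropic. The **CBO index** is

```
index = minor / major
```

the ratio of the maximum caliper width (minor axis) to the maximum caliper
length (major axis) of the thresholded, cleaned central blob of the
log-scaled power plot — near 0 for parallel bundles, 1 for random
orientation.

The pipeline follows the semi-automated protocol end to end: best-fit
contrast stretch, greyscale conversion, FFT power plot with adjustable
spectrum gain, threshold segmentation of the central frequencies (Otsu or
manual), area filter, hole filling, smoothing, spike exclusion, convex
hull, caliper axis measurement. It is aimed at quantitative histology:
comparing Masson's trichrome, digitally *optimized* Masson (purple
cellular structures removed), Picrosirius red under polarized light, and
H&E-confocal imagery, and at anyone needing a reproducible scalar for
fiber alignment in 2D textures.

It also implements the agreement suite for such comparisons: two-way
random-effects consistency ICC (average measures) with 95% CI and F test,
Bland–Altman bias with ±2 SD limits of agreement, and the coefficient of
variation derived from the standard error of measurement — plus a
synthetic fiber-field generator with exact ground truth for validation.

## Worked example

Measure a strongly aligned and a random synthetic field:

```r
library(cbofourier)

par8 <- generate_fiber_image(fiber_field_params(kappa = 8, seed = 1))
measure_grey(par8$image, study_config())
#> <cbo_orientation> index 0.325 (major 72.6 px, minor 23.6 px, angle 125.9 deg, threshold 70)

rnd <- generate_fiber_image(fiber_field_params(kappa = 0, seed = 1))
measure_grey(rnd$image, study_config())
#> <cbo_orientation> index 0.942 (major 67.2 px, minor 63.3 px, angle 155.0 deg, threshold 70)
```

The aligned field (`kappa = 8`, fiber angles concentrated around 30° with
SD ≈ 10°) yields an elongated spectral blob: 72.6 px long, 23.6 px wide,
index 0.325 — "parallel". Its major axis sits at 125.9°, perpendicular to
the fiber direction, as expected in frequency space. The isotropic field
(`kappa = 0`) gives a nearly round blob and index 0.942 — "random".

Agreement statistics on a simulated 21-sample, 2-rater design with a
population ICC of 0.95:

```r
m <- make_reliability_fixture(21, 2, icc_target = 0.95, seed = 1)
icc_consistency_average(m)
#> ICC (two-way random, consistency, average measures) = 0.954 [0.887, 0.981], F(20, 20) = 21.90, p = 1.62e-09
bland_altman(m[, 1], m[, 2])
#> Bland-Altman: bias 0.0014, SD 0.0659, limits of agreement [-0.1304, 0.1332] (n = 21)
coefficient_of_variation(m)
#> CV = 5.14% (SEmeas = 0.0333, grand mean = 0.6471)
```

`reliability_report()` assembles the pairwise table (ICC, CI, p, bias,
limits, CV%) for every pair of raters or techniques, and
`autoplot()` on a `bland_altman()` result draws the agreement plot.

For real images: `load_micrograph()` reads TIFF/PNG,
`measure_micrograph()` returns the index with its full parameter record,
`segment_cellular()` + `remove_non_collagen()` produce optimized Masson
images, and `measure_micrographs()`/`average_samples()` handle the
five-fields-per-sample design. A thin command-line front end with
`measure`, `optimize-masson`, `reliability` and `simulate` subcommands is
installed at `inst/scripts/cbo`.

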