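---
title: "Measuring grape maturity from depth-camera distance bias"
author: "berrybias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring grape maturity from depth-camera distance bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(berrybias)
```

## The measurement

Time-of-flight and LiDAR depth cameras infer distance from the round
trip of emitted light.  A translucent object like a grape berry lets
part of that light scatter diffusely inside the fruit before it
returns, so the berry registers *farther away* than it is, and its
rounded surface is distorted into a flattened peak.  The peak is
centred on the berry, its tip points toward the camera, and it is
rotationally symmetric about the line from the camera through the
berry — not about the camera's optical axis, which matters as soon as
the berry sits off-axis.

As a harvested berry ages and loses water, its optical properties
change and the distance bias grows, while an opaque-coated reference
scan of the same berry shows that the true surface barely moves.  The
bias is therefore usable as a non-contact maturity proxy.  The package
measures it as

$$ y = s_{\mathrm{coated}} - s_{\mathrm{uncoated}}, $$

the difference between the apex distances of the coated reference scan
and the uncoated scan, so $y$ is negative when the berry appears too
far, and grows in magnitude with age.  Bias series over days $t$ are
summarized by ordinary least-squares fits, linear
($y = a\,t + b$) or quadratic ($y = a\,t^2 + b\,t + c$), via
`fit_maturity()`; a fitted curve can be inverted with `invert_age()` to
read an age off a measured bias.

## Processing chain

`run_pipeline()` applies, per berry:

1. **Isolated-point removal** (`knn_outlier_filter`): a point is kept
   iff its mean distance to its $k$ nearest neighbours is below a
   threshold.  Both an absolute threshold (mm) and the statistical rule
   threshold $= \mathrm{mean} + m\cdot\mathrm{sd}$ over all per-point
   mean neighbour distances are provided; defaults $k = 20$, statistical
   $m = 2$, common practice for depth-sensor clouds.  Neighbour sets
   exclude the point itself, nearest neighbours are exact (clouds are a
   few thousand points), and ties are broken by input order, which makes
   the filter a pure, permutation-equivariant function.  A useful
   property of the statistical rule under speckle contamination is that
   the contaminated standard deviation inflates the cut-off: genuinely
   isolated speckle still sits far above it, while the surface
   population sits well below, so surface erosion is minimal.
2. **Optional crop** (`crop_box`) with closed bounds — deterministic
   membership at the boundary.
3. **Central ray** (`central_ray`) from the camera through the coated
   scan's centroid.  The coated scan carries the undistorted geometry,
   so its centroid is the best available berry location.
4. **Apex detection and bias** (`detect_apex`, `distance_bias`): points
   within an angular window (default $1.2\times$ the coated scan's
   angular radius — wide enough for the whole peak, narrow enough to
   exclude the holder) are projected on the measurement axis, and the
   apex is the mean of the lowest-$q$ quantile of projections (default
   $q = 0.01$, at least 5 points).  A single minimum would be fragile to
   residual noise; a low-quantile mean trades a small, nearly
   day-constant bias for variance reduction — and because the same grid
   geometry is used for coated and uncoated scans, most of that bias
   cancels in the difference $y$.
5. **Fit** (`fit_maturity`) and report.

Two bias conventions are implemented.  `z_axis` measures apex
distances along global $+Z$, matching a plain depth-map reading.
`along_ray` measures them along the central ray, the peak's symmetry
axis.  On-axis the two coincide by construction.  Off-axis, the
`z_axis` reading foreshortens by roughly the cosine of the off-axis
angle (about 5% at 85 mm lateral offset and 255 mm depth, i.e. ~0.5 mm
of a 10 mm bias), while the along-ray reading is invariant to the
angle; this is why the package defaults to `along_ray`.

## The synthetic scene generator

No depth-scan data of this kind is publicly deposited, so the package
ships a generator (`scene_config`, `make_coated_scan`,
`make_uncoated_scan`, `make_scan_series`) that produces scan pairs with
exact ground truth, and every claim the test suite makes is validated
against that truth.

The coated scan ray-casts a regular angular grid (default $48^2$ rays
spanning 1.3 angular radii) against the target sphere and keeps first
intersections — a rounded front surface.  The uncoated scan is a
phenomenological peak model: with the true front surface at range
$s_{\mathrm{surf}}$ along the central ray, base fixed at
$s_{\mathrm{base}} = s_{\mathrm{surf}} + \mathrm{base\_offset}$ and tip
at $s_{\mathrm{tip}} = s_{\mathrm{surf}} - y(t)$, a ray at angle
$\theta$ off the central ray returns range

$$ s(\theta) = s_{\mathrm{base}} - (s_{\mathrm{base}} -
   s_{\mathrm{tip}})\, e^{-\theta^2 / (2 (w\,\theta_{\mathrm{grape}})^2)}. $$

This is the simplest rotationally-symmetric shape with every
qualitative property the real scans show — tip toward the camera, tip
retreating linearly with age, base fixed, symmetry about the
camera–berry line — but it is a test fixture, not a physics model: no
photon transport is simulated, and the true radial profile of real
peaks (Gaussian versus conical, and its width) is not quantified
anywhere we could calibrate against.  Consequences: passing tests
demonstrate that the estimators recover what the generator programmed
under realistic geometry, noise and speckle; they cannot certify
accuracy on real berries, whose peak shape, skin speckle statistics and
holder geometry differ.

Defaults (chosen once, as study conditions):

| parameter | default | why |
|---|---|---|
| `sphere_radius` | 9.525 mm | optical ball-lens control size; grape-like |
| `grape_center` | (0, 0, 369.525) mm | front surface 360 mm on-axis; off-axis berries use (−85, 0, 255) / (93, 0, 255) |
| `bias_slope`, `bias_intercept` | −0.62 mm/day, −8.9 mm | representative measured single-berry schedule |
| `base_offset` | 20 mm | must exceed max \|y(t)\| = 16.34 mm over 12 days |
| `peak_width` | 1.5 | broad flattened peak, wider than the berry, as in real scans |
| `angular_samples` | 48 | ~1000 returns per berry window, typical for a cropped berry |
| `noise_sigma` | 0.5 mm | depth-sensor noise at these ranges |
| `outlier_fraction`, `outlier_range`, `outlier_clearance` | 2%, 30 mm, 10 mm | sparse speckle, kept genuinely isolated from the surface |

Speckle is rejection-sampled to keep at least `outlier_clearance` from
the noiseless surface: injected outliers are supposed to be *isolated*
points, and without the clearance a uniform draw frequently lands
within a millimetre of the surface, where no filter could (or should)
distinguish it from signal.

Per-day seeds are derived as `(seed + 1000003 * t) mod (2^31 - 1)`, so
every scan is a pure function of (config, day), stable across runs and
machines, and generators restore the caller's RNG state.

## Numerical choices

* **Apex estimator error.**  For a quantile-mean apex on a grid of
  angular step $h$, the estimate is biased behind the true tip by
  $\approx C\,\overline{\theta^2}$, where $C$ is the local curvature of
  $s(\theta)$ — $C = d(d-r)/2r$ for the coated sphere and
  $C = (s_\mathrm{base}-s_\mathrm{tip})/2w^2$ for the Gaussian peak.
  At the default geometry and grid this is ~0.01–0.03 mm, and the
  residual after coated/uncoated cancellation is linear in $y(t)$, so a
  noiseless series still fits a line with $R^2 = 1$ to machine
  precision.  These magnitudes set the 0.05 mm (on-axis) and 0.1 mm
  (off-axis) recovery checks in the tests; they were derived from this
  analysis, not fitted to outcomes.
* **Peak base.**  `peak_shape` takes the base as a high quantile
  (default 0.95) of point *range from the camera* — the base is the
  part of the peak whose distance from the camera stays fixed — while
  the tip uses ray projections; the two coincide at the tip.
* **Ties and determinism.**  All order-dependent steps (quantile
  membership, neighbour ranking) break ties by original point index;
  every pipeline stage is deterministic given inputs and config.
* **I/O precision.**  PLY is written with 64-bit float vertex
  properties (ASCII prints 6 decimals of a millimetre): 32-bit floats
  have ~3e-5 mm resolution at 400 mm and could not honour the 1e-6 mm
  round-trip contract.  Readers accept 32-bit files too.
* **Degenerate inputs.**  Empty clouds round-trip through every format;
  crops may be empty; fits refuse designs with too few distinct days;
  quadratic inversion is restricted to the monotone branch at or beyond
  the vertex and reports the attainable range otherwise; a flat linear
  fit refuses inversion.
* **Quadratic inversion branch.**  The quadratic maturity curve is
  non-monotone; `invert_age` uses the branch $t \ge$ vertex (the ageing
  side).  For bias curves that are decreasing lines this never
  triggers; it only matters for quadratic ToF-style fits.

## Problem sizes in the shipped tests

The suite validates the KNN filter against a brute-force oracle on 50
random clouds up to 500 points across a $k \times$ mode grid; apex and
bias recovery on noiseless scenes at all four study geometries; the
full noisy pipeline on 100 seeded 12-day replicates (0.5 mm noise, 2%
speckle), requiring the mean fitted slope within 0.05 mm/day of the
programmed one; and 10,000-point I/O round trips in all formats.  These
sizes were chosen to exercise every code path at desk scale; the
estimator-accuracy conclusions above are insensitive to them.

## Known limitations

* The peak model is a stand-in; nothing here predicts how bias depends
  on refractive index, berry size or camera distance.
* Maturity fits are plain OLS with no uncertainty beyond the residual
  SD, and no cross-variety calibration: a fitted curve belongs to the
  berry (and camera) it was measured on.
* Bias estimation always needs a coated (or otherwise undistorted)
  reference scan of the same berry; estimating bias without a reference
  is out of scope.
* The statistical filter threshold is computed on the contaminated
  cloud; under heavy contamination (far beyond the default 2%) a robust
  scale estimate would be preferable.
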