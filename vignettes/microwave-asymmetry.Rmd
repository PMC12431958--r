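---
title: "Simulating transmission-based microwave breast imaging and contralateral asymmetry analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating transmission-based microwave breast imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mwbreast)
```

## The measurement model

`mwbreast` simulates a planar microwave transmission scanner for breast
imaging and the analysis chain built on it. The instrument holds the breast
between two antenna plates — 247 transmitting and 240 receiving patch
antennas spanning an imaging area of roughly 21 cm × 16 cm — and sweeps an
ultra-wide band from 0.1 to 8 GHz. Each transmitter illuminates the set of
receivers within a lateral pairing radius on the opposite plate, giving more
than 2000 transmitter–receiver paths per scan. Both breasts are imaged in
two mammographic orientations (CC, with horizontal plates, and MLO, with the
plates tilted 45°), at two plate separations D1 and D2 = D1 − 5 mm; the
smaller separation is the one used for imaging.

The physical quantity of interest is the relative permittivity
$\varepsilon_r$ of the tissue, which rises with water content: fat is low,
fibroglandular tissue high, and tumors higher still. Propagation speed in
tissue is $c/\sqrt{\varepsilon_r}$, so a pulse traversing a path of length
$L = \sqrt{d^2 + \mathrm{offset}^2}$ arrives later than through air by
$$\Delta t = \frac{L}{c}\left(\sqrt{\varepsilon_r} - 1\right),
  \qquad\text{inverted as}\qquad
  \varepsilon_r = \left(1 + \frac{c\,\Delta t}{L}\right)^2 .$$
The frequency-domain measurement of each path is transformed to the time
domain with an inverse chirp Z-transform, the envelope peak gives the time
of arrival, and the difference against an equal-length air reference yields
a path-average permittivity. Each path's scalar estimate is painted onto a
small disk footprint at the path midpoint on the plane midway between the
plates; overlapping footprints are averaged. This is deliberately a
single-estimate-per-path, straight-ray picture: no tomographic inversion,
no refraction, no frequency dispersion.

## What the synthetic data emulate — and what they do not

No raw clinical scans are available, so the package ships a first-class
generator for the study conditions:

* **Bilateral, four-view subjects.** Each subject contributes LCC, RCC,
  LMLO and RMLO phantoms on a shared geometry. The breast is a semi-ellipse
  abutting the chest-wall edge of the grid; CC semi-axes are drawn from
  70–100 mm × 55–75 mm, and MLO re-realizations shrink the in-system area
  by a factor 0.8 (the tilted view holds less of the breast between the
  plates; the clinical account gives no number, so 0.8 is a free
  calibration choice).
* **Density categories.** Mammographic categories A–D map to glandular area
  fractions 0.15 / 0.35 / 0.55 / 0.75 (±0.05 subject jitter) and to
  per-category glandular permittivity bands A [8,11], B [10,14], C [13,18],
  D [17,23] over a fat background drawn from [4,7]. The bands were chosen
  so that the dominant threshold region of a segmented image moves from R2
  for density B through R3 (C) to R4 (D), mirroring the clinical pattern.
  Glandular texture is a Gaussian-smoothed white-noise field (15 mm
  correlation length) thresholded to the target fraction.
* **Healthy left–right asymmetry.** A signed draw
  $a \sim N(0, \sigma_a)$ offsets the two glandular fractions to
  $g(1 \pm a/2)$. Clinically, healthy bilateral differences in average
  properties are within about 10%; the default $\sigma_a = 0.2$ keeps the
  median normalized difference near 0.04, and
  `calibrate_asymmetry_scale()` tunes $\sigma_a$ so a seeded cohort's
  ground-truth mean CC contralateral ratio hits a stated target (1.05 by
  default, the reported healthy CC mean).
* **Unilateral tumors.** Cancer subjects carry one elliptical inclusion
  (default in-plane semi-axes 20 mm × 15 mm) on a random side, visible in
  both views of that side by default, or in one view only to mimic lesions
  evident on a single view. The inclusion is *multiplicative*: tissue
  inside the ellipse is scaled by $1 + c$. This keeps $c = 0$ exactly
  identical to a healthy phantom — the property that makes the
  zero-contrast null test meaningful — and makes detection strength
  strictly monotone in $c$. `calibrate_tumor_contrast()` tunes $c$ so the
  cancer cohort's ground-truth mean CC ratio hits its target (1.15 by
  default, the reported cancer CC mean). Note that the calibrated contrast
  (≈1.7, i.e. a 2.7× local elevation over ~11% of the breast area) is much
  larger than the ~10% excised-tissue contrast between tumor and glandular
  tissue: a fractional-area inclusion must carry a large local contrast to
  move a whole-breast average by 10%, which is consistent with the strong
  localized responses visible in clinical reconstructions.

Features of real data that the generator does **not** emulate: anatomically
realistic tissue maps, 3D structure (through-thickness homogeneity is
assumed, so the mid-plane map fully determines the delays), compression
biomechanics linking separation changes to property changes (separations are
carried as metadata only), positioning difficulties with small breasts, and
the clinical tendency for MLO views to hide tumors — synthetic MLO views
detect tumors as well as CC views do, whereas clinically the MLO group
means were similar for healthy and cancer groups. Passing tests therefore
validate the computational chain and its statistical behavior, not clinical
performance.

## Numerical choices

* **Forward model.** Each path's spectrum is
  $S(f) = A(f)\,e^{-2\pi i f \tau}$ with a raised-cosine band window
  $A(f)$ (any smooth window works, provided measurement and reference share
  it, so peak alignment is unbiased) and complex white Gaussian noise at a
  stated SNR relative to mean band power (30 dB in the cohort studies).
  Delays are midpoint-rule line integrals of $\sqrt{\varepsilon_r}$ sampled
  at most half a pixel apart along the path's lateral projection — exact
  for laterally aligned paths.
* **Inverse chirp Z-transform.** The band-limited inverse transform is
  evaluated directly on a zoomed uniform time window (default 0–3 ns, 1024
  samples, chosen so slab delays for $\varepsilon_r \le 30$ at separations
  up to 90 mm stay in-window) as one complex matrix product per scan. On
  degenerate parameters it reduces to the inverse DFT, which the tests
  exploit as an oracle.
* **Arrival picking.** Global envelope maximum with three-point parabolic
  refinement; a peak on the first or last sample flags a window problem.
  Negative measured delay differences (noise) clamp to
  $\varepsilon_r = 1$ rather than propagate.
* **Footprints.** Disks of 6 mm radius at the path midpoint, overlaps
  resolved by unweighted mean; pixels never covered keep the air baseline
  1.0. Pixel centers sit at $(i - 0.5) \cdot \text{pixel}$ with the origin
  at the plate corner.
* **Array layout.** Only the antenna counts and the system extent are
  specified by the hardware description; the 19×13 and 20×12 lattices and
  the 25 mm pairing radius are this package's choices, the radius set so
  the >2000-path property holds with margin (2716 paths).
* **Segmentation.** Breast-area identification is 2-means on
  log-permittivity followed by keeping the largest connected component of
  the higher cluster. The log scale is deliberate: on raw values the
  air-versus-tissue and fat-versus-gland splits have comparable
  within-cluster variance for dense breasts and the "breast" cluster can
  collapse onto the glandular region alone; on log scale the air/tissue
  split dominates for all densities. The two-cluster tissue split inside
  the mask runs on raw values. k-means uses Lloyd's algorithm with ten
  seeded restarts (deterministic given the configuration seed); on any
  instance of twelve or fewer values it attains the exhaustive
  minimum-variance bipartition. Threshold regions are upper-closed exactly
  as defined: R1 = (0,8], R2 = (8,13], R3 = (13,18], R4 > 18.
* **Statistics.** Pooled-variance two-sample t-tests (the clinical report
  does not specify pooled versus Welch; pooled matches the classical ANOVA
  identity $F = t^2$ used as a cross-check). The two-way group × view
  ANOVA uses Type-II sums of squares, the standard choice for testing main
  effects in an unbalanced design (20 versus 14 subjects) without giving
  the interaction priority. Significance is read at 0.05 with no
  multiple-testing correction, as in the clinical analysis. The clinical
  report labels its ratio comparisons "one-way ANOVA" while quoting
  t-values; the package emits both statistics and leaves the labeling
  discrepancy documented rather than resolved.
* **Problem sizes.** The cohort studies run on a 4 mm analysis grid
  (53 × 40 pixels) with 161 frequency points; phantom generation defaults
  to the 2 mm grid. These sizes keep a full 34-subject, 136-scan study in
  the minutes range on one CPU while leaving the slab round-trip error far
  below the 2% acceptance band.

## Design decisions on open points

* The reference signal is air ($\varepsilon_r = 1$); a configurable
  reference permittivity would only shift all estimates and is not exposed
  beyond the inversion formula.
* Each plate separation yields its own image; the smaller separation (D2)
  is the one the cohort pipeline images, matching the clinical choice.
* Breast-area k-means runs on the full image including plate regions
  without tissue (the uncovered-pixel baseline of 1.0 sits inside the air
  cluster), since the clinical description does not restrict the domain.
* The per-subject contralateral ratio is
  $\rho = \max(\bar\varepsilon_L, \bar\varepsilon_R) /
  \min(\bar\varepsilon_L, \bar\varepsilon_R)$ and the normalized
  difference $\delta$ uses the mean of the two breasts in the same view;
  the two are linked by $|\delta| = 2(\rho-1)/(\rho+1)$, which the tests
  assert numerically. For tumor-contrast sweeps the package tracks the
  *cancer-side* ratio (tumor side over contralateral), which is strictly
  monotone in the injected contrast; the max/min ratio is not monotone at
  small contrasts when the tumor sits on the initially lower-permittivity
  side.

## A worked example

```{r example, eval = FALSE}
library(mwbreast)

grid <- grid_spec(pixel_mm = 4)
subject <- generate_subject("S1", "cancer", density = "C", grid = grid,
                            seed = 42L, tumor_contrast = 1.0)
ctx <- scan_context(grid, snr_db = 30)
result <- analyze_subject(subject, ctx, seed = 1L)
result$summary
```

The `analysis/` directory holds the full study as numbered drivers:
`01_simulate_cohort.R` calibrates the generator and writes the ground
truth; `02_reconstruct_segment.R` images and segments all 136 scans;
`03_cohort_stats.R` produces the ratio tables and the ANOVA/t-test battery
under `results/`.

## Known limitations

* 2D phantoms with through-thickness homogeneity; the delay model is exact
  for the model's own physics but not for real 3D anatomy.
* Straight rays: no refraction, diffraction or multipath, which in the
  real instrument blur footprints and bias estimates near strong
  interfaces. The reconstructed breast average consequently sits a few
  percent below the phantom truth (edge pixels mix with air), a bias that
  largely cancels in bilateral ratios — which is exactly why the clinical
  analysis is built on contralateral comparison.
* The generator's MLO views are statistically as informative as CC views;
  clinically they are not, due to positioning.
* Tumor placement avoids the chest wall/axilla question entirely; the
  single-view visibility switch is the only nod to positioning effects.
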