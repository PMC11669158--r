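---
title: "Quantifying bacterial coverage of C. albicans hyphae"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying bacterial coverage of C. albicans hyphae}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measurement problem

Adhesion assays of engineered bacteria to *Candida albicans* hyphae
produce, per sample, one bright-field image in which hyphae appear as
dark curved filaments a few pixels wide, and a fluorescence focal stack
in which the labeled bacteria appear as small bright rods; the stack is
acquired at several focal planes so that every bacterium is visible in
at least one of them. The quantity of interest is the fraction of hyphal
area overlapped by bacteria — a proxy for how densely the bacteria coat
the filaments. Visual scoring of such images is slow and subjective;
`hyphacover` reimplements the automated pipeline for this readout as a
tested, scriptable package, and pairs it with a synthetic micrograph
generator so every stage can be validated against pixel-level ground
truth.

## The pipeline and its parameters

All images are handled at a canonical 8-bit depth (16-bit input is
rescaled by the full nominal range, `round(v * 255 / 65535)`, so a given
physical intensity always maps to the same working value; the fixed
bacteria threshold below is only meaningful on a fixed scale).

**Hyphae channel.** `segment_hyphae()` composes five steps:

1. *Gaussian smoothing*, sigma = `gaussian_radius` (default 3 px): noise
   suppression before differentiation. The parameter is used directly as
   the kernel standard deviation, the convention of the common
   interactive tools; if a different radius convention is intended the
   reinterpretation costs one configuration value.
2. *Sobel gradient magnitude* (`sqrt(gx^2 + gy^2)`, standard 3×3
   kernels, symmetric borders, clamped to [0, 255]): hyphae are detected
   by their contour, which is robust to uneven illumination in
   bright-field.
3. *Directional grayscale closing* with digital lines of `line_length`
   (default 15 px, odd) at 0/45/90/135°, combined by pixel-wise maximum:
   connects gaps in the contour along any of the four orientations. The
   line length is not prescribed by the assay description; 15 px exceeds
   typical noise structures while staying below the curvature scale of
   hyphae, and is deliberately exposed in `pipeline_config()`.
4. *IsoData auto-threshold*: on the 256-bin histogram,
   `t <- round((mean(values <= t) + mean(values > t)) / 2)` iterated
   from the midpoint of the occupied range to its fixed point;
   foreground is strictly above `t` (ties go to background). A constant
   image has no threshold and raises a degenerate-input error, which
   batch processing records as a flagged row.
5. *Directional binary opening* with the same lines, combined by union:
   removes compact noise while keeping structures elongated along any
   orientation.

`fill_holes = FALSE` by default: the assay description thresholds the
closed *contour*, and at hyphal widths the detected contour band already
spans the filament interior (the two edge responses of a filament a few
pixels wide merge under the closing). Filling is available for wide
structures, but on a network of crossing filaments `fillHull` floods the
polygons *between* filaments — on synthetic scenes this inflated the
hyphae area severalfold whenever filaments crossed — so it is opt-in.

**Bacteria channel.** `segment_bacteria()` composes four steps:

1. *Rolling-ball background subtraction*, radius 50 px, per plane. The
   background is the grayscale opening of the image with a spherical
   structuring function ("rolling the ball under the surface"),
   estimated — as in the classic implementations — on a 3×3-mean
   presmoothed and, for large radii, block-averaged copy of the image,
   then interpolated back. Estimating on the raw image would make the
   opening track the minima of the noise rather than the background
   level: the full background offset plus the noise envelope would then
   survive subtraction and defeat the fixed threshold below. The bare
   flat-disk variant (`presmooth = FALSE`), whose contract
   `img - opening(img)` is checked verbatim against a brute-force
   oracle, is retained for testing and comparison.
2. *Percentile contrast enhancement*, `saturated_percent = 0.05`: a
   linear stretch mapping the nearest-rank percentiles (saturation split
   evenly between the tails) to 0 and 255. The cuts are computed once on
   the pooled pixels of the whole stack and applied identically to every
   plane: stretching each plane against its own histogram would amplify
   a strongly defocused (dim) plane until its noise floor crosses the
   threshold, and the projection would inherit that noise.
3. *Maximum-intensity projection* across planes.
4. *Fixed threshold* at intensity 20, inclusive (a pixel at exactly 20
   is foreground).

**Coverage.** `compute_coverage()` intersects the two masks on the
shared pixel grid; `percent_hyphae_covered = 100 * overlap / hyphae
area`. An empty hyphae mask leaves the statistic undefined; such images
are flagged and excluded from group statistics rather than scored zero,
which would bias group means toward the null.

## Group statistics

`run_batch()` processes a manifest (CSV: image paths, strain, biological
replicate, slide position) with per-image error isolation. The standard
acquisition design is 3 positions × 3 replicates = 9 images per strain;
the nine values are treated as independent replicates, as they are
plotted in this assay type. `one_way_anova()` uses the direct
between/within sum-of-squares decomposition and exposes the pooled
within-group mean square, which `holm_sidak_vs_control()` reuses for the
comparisons versus the control strain: pooled-variance t statistics on
the ANOVA's residual degrees of freedom, two-sided p-values, and the
Šidák step-down adjustment `1 - (1 - p_(k))^(m - k + 1)` with running
maxima enforcing monotonicity (and each adjusted p bounded below by its
raw p, which also guards the floating-point identity at exponent one).
The comparison family is strains-versus-control only, not all pairs.
Under a simulated null (6 groups × 9 replicates) the family-wise error
at alpha = 0.05 is calibrated within [0.035, 0.065] in the test suite.

## The synthetic generator

`render_scene()` emulates what the assay puts on the camera, with
geometry in pixels (no physical calibration is standard for this assay
type; the defaults approximate the proportions seen in such micrographs):

* filaments: persistent random walks (unit steps, turning angle bounded
  by `max_turn`, default 0.15 rad) entering the field from a random
  border, dilated to `filament_width` (8 px); rendered as dark ridges
  (contrast 80 below a background of 200) with a slight softening blur,
  plus Gaussian noise;
* bacteria: 7×3 px rods at random orientation, either centered on
  filament pixels (`n_bacteria_on`) or centered farther than the rod's
  major axis from any filament pixel (`n_bacteria_off`) — the clearance
  makes pure off-filament scenes an exact zero-coverage negative
  control. Placement draws are per rod, on-filament rods first, so
  enlarging `n_bacteria_on` extends the same placement prefix and truth
  coverage is monotone in it;
* fluorescence planes: the rod intensity image (peak 180) blurred by a
  per-plane defocus sigma (default 1, 2, 3 — one near-focus plane and
  two progressively defocused ones), plus a background offset (8) and
  Gaussian noise (sd 3).

Scene rendering is fully determined by `seed`; benchmark grids derive
per-scene seeds from a master seed and the scene index.

What the generator does *not* model: physically accurate point-spread
functions and phase-contrast halos, autofluorescence, uneven
illumination, washing dynamics (real negative controls have few residual
bacteria anywhere in the field, not a fixed number placed near the
filaments), yeast-form cells, and depth-dependent focus per bacterium
(each plane blurs the whole rod image with one sigma). Tests passing on
these scenes therefore validate the pipeline's operations and their
composition, not its absolute accuracy on real optics.

## Numerical choices

* Morphology uses the valid-pixel convention (max/min over in-image
  pixels only); with symmetric footprints this is a true adjunction, so
  closings are extensive and idempotent and openings anti-extensive and
  idempotent including at borders — properties the test suite asserts
  against brute-force oracles.
* Convolutions use symmetric (reflective) borders, repeating the
  reflection for kernels wider than the image.
* Intensities are rounded back to integers at every operation boundary
  (8-bit semantics); 16→8-bit conversion rounds half up.
* Percentiles use the nearest-rank rule on the pixel multiset.
* Degenerate rules are explicit: constant images raise errors at the
  auto-threshold, map to all-zero under contrast enhancement, and
  subtract to zero under the rolling ball.
* The four line orientations are closed under 90° rotation and every
  other operator is 90°-equivariant (the ball and disk footprints are
  symmetric, the shrink/upscale grid is reflection-symmetric), so
  end-to-end results are bit-identical under rotation of both channels —
  asserted exactly in the tests, as is invariance to focal-plane order
  and to adding a constant offset to every plane.

## Known limitations

The pipeline's masks are systematically wider than the geometric truth:
the sigma-3 smoothing spreads each filament edge over several pixels, so
the detected contour band is roughly twice the area of an 8 px filament;
and the fixed threshold of 20 (≈8% of a bright bacterium's core after
enhancement) keeps part of each rod's defocus halo, so a 16 px rod
segments as a blob an order of magnitude larger. On fine synthetic
structures the estimated coverage is therefore inflated by a roughly
constant factor (with a small additive noise floor), while strain
*ranking* — the quantity the assay actually uses, binder versus
non-binder against a control — is preserved, as the analysis scripts
and the rank-correlation acceptance test show. On real micrographs,
where hyphae are typically several times wider in pixels, the same
absolute widening is a much smaller relative error. The test suite's
problem sizes (512×512 scenes, 10–20 seeds per property, 2000 null
simulations for the calibration check) were chosen to exercise these
properties at the scale of one field of view.

The rolling-ball background estimate is slightly below a narrow bright
peak (the ball surface curves up under a spike), so isolated spots lose
a fraction of an intensity unit; the flat-disk variant preserves them
exactly and is the one bound by the `img - opening(img)` contract.
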