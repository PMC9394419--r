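---
title: "Deformable-superellipse prostate segmentation and mask-based registration: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deformable-superellipse prostate segmentation and mask-based registration: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 5)
library(trusfit)
```

## The problem

Targeted (fusion) prostate biopsy overlays lesions found on preoperative
MRI onto the live transrectal-ultrasound (TRUS) view. That requires a
segmentation of the gland in both modalities and a registration between
them. TRUS segmentation is the bottleneck: boundaries are blurred by
speckle and shadowing, appearance varies across transducers, and it must
happen in the operating room. `trusfit` implements a semiautomatic
answer: the physician clicks a handful of boundary points on a few axial
slices, a compact deformable shape model is fitted to those points, the
3D gland is interpolated from the per-slice fits, and the resulting mask
is registered to the MRI mask through signed distance maps. Because the
method consumes only points and masks — never image intensities — it
needs no training data and works with any transducer.

## The shape model

A centered superellipse with semi-axes $a_x, a_y > 0$ and squareness
$\epsilon > 0$ is the zero level set of the inside–outside function

$$f(x, y) = \left|\frac{x}{a_x}\right|^\epsilon +
            \left|\frac{y}{a_y}\right|^\epsilon,$$

with $f < 1$ inside and $f > 1$ outside; $\epsilon = 2$ gives an
ellipse, smaller values square the shape off, larger values pinch it.
The boundary is sampled in parametric form
$x = a_x\,|\cos\theta|^{2/\epsilon}\,\mathrm{sign}(\cos\theta)$,
$y = a_y\,|\sin\theta|^{2/\epsilon}\,\mathrm{sign}(\sin\theta)$, which
satisfies the implicit form identically.

Four deformations, applied in a fixed order, turn this into a
prostate-capable model with the 8-parameter vector
$(a_x, a_y, l_x, l_y, r, \epsilon, t, b)$:

1. **rotation** by $r$ radians (counter-clockwise);
2. **linear tapering** along $y$: $x' = (1 + t\,y/a_y)\,x$ — the gland
   narrows toward the apex ($|t| < 1$ keeps the factor positive);
3. **circular bending** along $y$: $x' = x + (1 - \cos(b\,y))/b$, the
   sagitta of an arc of curvature $b$ — the posterior bowing the
   transducer induces ($|b|\,a_y < 1$ keeps it injective on the shape);
4. **translation** by $(l_x, l_y)$ mm.

Each step is a homeomorphism on the shape's extent, so the chain has an
exact closed-form inverse (undo translation, bending, tapering,
rotation, in that order), which the tests verify to $10^{-6}$ mm. All
geometry is computed in physical slice-plane millimetres with the
pixel-center convention, so anisotropic pixels and metric distances are
handled correctly.

```{r shapes, echo = FALSE}
op <- par(mfrow = c(1, 3), mar = c(2, 2, 2, 1))
show <- function(ps, main) {
  plot(NA, xlim = c(-30, 30), ylim = c(-30, 30), asp = 1, main = main,
       xlab = "", ylab = "")
  for (i in seq_along(ps)) {
    v <- superellipse_polygon(ps[[i]], 180)$vertices
    lines(rbind(v, v[1, ]), col = i + 1)
  }
}
show(lapply(c(1, 2, 3.5), function(e) superellipse(25, 18, eps = e)),
     "squareness")
show(lapply(c(-0.4, 0, 0.4), function(t) superellipse(25, 18, t = t)),
     "tapering")
show(lapply(c(0, 0.015, 0.03), function(b) superellipse(25, 18, b = b)),
     "bending")
par(op)
```

## Fitting a slice from sparse points

Given user points $U$ on one axial slice, the fit maximizes a posterior
whose log splits into a Gaussian shape prior and a point likelihood; the
likelihood term is the point-to-polygon energy

$$E(C; U) = \sum_{(x,y) \in U} d\big(C, (x, y)\big)^2,$$

the sum of squared Euclidean distances from each point to the model
boundary polygon $C$. (The squared form is the default; a
`squared = FALSE` flag switches to plain summed distances.) The prior
$\ln \Pr(p_s) = -\sum_j (p_j - m_j)^2 / 2\sigma_j^2$ is implemented but
**disabled by default**: sensible $(m_j, \sigma_j)$ are
population-specific and no defaults are assumed; pose parameters carry
an implicit uniform prior realized as box bounds.

Design choices in the optimizer, where the procedure was genuinely
open:

* **Boundary representation.** The reference procedure rasterizes the
  deformed point set, repairs it by morphological closing and traces
  the mask boundary at every objective evaluation. Both paths are
  implemented; the default evaluates the energy on the exact deformed
  parametric boundary polygon (256 vertices), which is the same curve
  the raster boundary approximates — the deformations are
  homeomorphisms, so the boundary of the deformed region *is* the
  deformed boundary curve — and is smoother and roughly an order of
  magnitude faster. `fit_config(boundary = "raster")` restores the
  rasterizing objective; an equivalence test holds the two to
  Dice ≥ 0.99.
* **Search.** Bounded multistart Nelder–Mead (4 starts: a deterministic
  data-driven initialization plus three seeded jitters) on an
  unconstrained reparametrization that enforces the invariants
  ($a_x, a_y > 0$; $\epsilon \in [0.6, 4]$; $|t| \le 0.6$;
  $|b| a_y \le 0.5$). The objective is non-smooth at polygon-edge
  switches, which rules out derivative-based methods.
* **Initialization.** Centroid for $(l_x, l_y)$, principal axis of the
  point cloud for $r$, extents along the principal frame for
  $(a_x, a_y)$, $\epsilon = 2$, $t = b = 0$. Deterministic and
  scale-aware.
* **Scale equivariance.** Lengths inside the optimizer are expressed
  relative to the annotation extent. Nelder–Mead is comparison-based,
  so rescaling all points rescales the fit exactly ($a_x, a_y, l_x,
  l_y$ by $s$; $b$ by $1/s$; $\epsilon, r, t$ unchanged) — a property
  the tests check at 1%.
* **Degenerate point sets.** With few points (the 4–6 point protocol)
  many parameter vectors explain the data exactly. When a fit already
  matches the points to better than 0.2% of the annotation extent
  (RMS), the search stops rather than wander along the zero-energy
  valley; in particular an initialization that already interpolates the
  points is returned as is. This makes the minimal-point fits
  deterministic and anchored to the simplest consistent shape.

Mid-gland slices with 10–12 points are better served by a closed
B-spline: points are sorted angularly about their centroid (ties by
radius, since users click in arbitrary order), parametrized by chord
length, and one cyclic cubic regression spline per coordinate is fitted
(`mgcv`, `bs = "cc"`), with a smoothing parameter that interpolates at
0. A superellipse is then fitted to dense samples of the spline so the
slice still contributes a parameter vector to the 3D model, while the
refined contour reported for the slice is the spline itself.

### Annotation protocol

At least three slices must be annotated — base, one or more mid-gland
slices, apex — with at least 4 points on base and apex and at least 6
(recommended 10–12, B-spline mode) at mid-gland. The package warns
below the recommended mid-gland count and refuses fewer than 4 points
anywhere.

## From slices to a 3D gland

The fitted parameter vectors are interpolated **linearly in z**
component-wise between annotated slices; the rotation angle is
interpolated along the shortest circular arc, so angles near the
$\pm\pi$ seam average correctly. Every axial plane inside the annotated
range is rasterized from its interpolated vector; the model spans
exactly the annotated z range, with no extrapolated capping beyond the
base and apex slices (the behaviour beyond the extreme slices is
undefined by the procedure, and inventing caps would fabricate
geometry). Interpolation is exact at the annotated slices, and adding a
slice consistent with the interpolant leaves the reconstruction
unchanged — both tested.

For the **second user iteration**, `export_contours()` samples each
model contour at equal arc length (12 points per slice by default) and
writes them as 3D Slicer markups; after manual adjustment the slices
are refitted in B-spline mode. A round-trip without manual edits
reproduces the first-iteration mask to Dice ≥ 0.98.

### Rasterization

Following the reference procedure, a slice mask is built by taking the
lattice points inside the *centered* superellipse, pushing them through
the deformation chain, and binning them into grid pixels; the discrete
forward map leaves nicks and holes where it locally expands, so the
mask is repaired by morphological closing (3×3 box, repeated while
interior holes remain, at most 5 passes, residual holes filled). An
independent oracle — evaluating the inside–outside function at the
*inverse-mapped* pixel centers — agrees with this forward pipeline to
Dice ≥ 0.99 on 128² grids at the package's 0.5 mm reference resolution.
The boundary of a mask is traced along pixel borders (vertices on pixel
corners, counter-clockwise), so a 3×3-pixel mask at 1 mm spacing has
perimeter 12 mm, and contour areas are exact pixel-area sums.

## Mask-based MRI–TRUS registration

Both segmentation masks go through the same preprocessing: crop to the
foreground bounding box plus a 10 mm margin; resample to an isotropic
0.3 mm grid with nearest-neighbor interpolation; smooth with a Gaussian
of σ = 3 voxels (0.9 mm on that grid — σ is interpreted on the
resampled grid because smoothing follows resampling in the pipeline);
and convert to a signed Euclidean distance map, negative inside,
measured in mm to the nearest boundary voxel. The distance transform is
the exact separable lower-envelope algorithm with anisotropic spacing,
verified against brute force to $10^{-6}$.

Initialization is rigid: either the **center initializer** (identity
rotation; translation = vector between the geometric image centers,
computed from origin, dimensions and spacing) or the **landmark
initializer** (closed-form least-squares rigid transform over matched
fiducials — urethra entry at base, verumontanum, urethra entry at apex).
On synthetic pairs the two give nearly identical results, matching the
observation that a simpler center-based initialization suffices.

Refinement optimizes a **full affine transform** (12 parameters, fixed
rotation center) by minimizing the mean squared difference between the
fixed distance map and the moving distance map resampled through the
transform. Two numerical choices matter:

* **Sampling.** The metric is evaluated on a seeded uniform sample
  (default 40 000 voxels) of the fixed grid restricted to a ±6 mm band
  around the gland surface. The near field is where the distance maps
  carry boundary information; far-field values scale with the transform
  under anisotropic scaling and would bias the optimum away from the
  mask-overlap optimum. Sampling is standard practice in intensity
  registration; the band restriction is this package's choice and is
  what makes the affine stage recover anisotropic scale to better
  than 2%.
* **Optimizer.** The gradient of the sampled metric with respect to all
  12 parameters is analytic (chain rule through trilinear
  interpolation). The default optimizer is BFGS on that gradient, which
  converges in a few dozen gradient evaluations; a classical
  regular-step gradient descent (normalized gradient, adaptive step
  halving, parameter scaling so matrix entries and millimetre
  translations take comparable steps) is available as
  `optimizer = "gd"`. It follows the same trajectory but needs many
  hundreds of iterations to traverse the ill-conditioned valley, which
  is why it is not the default. Only improving steps are accepted in
  either mode, so the final metric never exceeds the initial one and
  the reported trace is non-increasing.

By default the MRI-derived map is the fixed image and the TRUS-derived
map the moving image; the CLI flag `--swap` reverses the direction.
Deformable (non-affine) refinement is out of scope.

## Evaluation metrics

For predicted mask $P$ and ground truth $G$ on one grid:
$\mathrm{DSC} = 2|P \cap G| / (|P| + |G|)$,
$\mathrm{VOE} = 1 - |P \cap G| / |P \cup G|$ (one minus Jaccard), and
$\mathrm{RVD} = (|P| - |G|) / |G|$, signed, negative for
under-segmentation. Surface metrics use the boundary-voxel convention:
the surface is the set of foreground voxels with a 6-connected
background neighbor, distances are Euclidean between voxel centers in
physical mm, HD is the full (100th-percentile) Hausdorff distance — no
HD95 variant is reported — and ASSD averages all surface-to-surface
distances symmetrically. A brute-force all-pairs oracle confirms both
on random masks; algebraic identities
($\mathrm{VOE} = 1 - J$, $\mathrm{DSC} = 2J/(1+J)$) hold to $10^{-12}$.

## The synthetic phantom

Because the method consumes only points and masks, a fully synthetic
phantom exercises every stage. The default `phantom_spec()` is a
5-entry parameter stack spanning 40 mm axially (gland ~50 × 42 × 44 mm)
on a TRUS-like grid (0.5 mm in-plane, 2 mm slices): semi-axes grow from
apex (12 × 10 mm) to mid-gland (25 × 21 mm) and shrink to base
(14 × 11 mm), with mid-gland tapering $t = 0.2$ and posterior bending
$b = 0.01\,\mathrm{mm}^{-1}$ — the "tapered, posteriorly warped"
anatomy the deformations exist to model. The **simulated annotator**
picks the base, apex and largest mid-gland slice, samples 4/10/4 points
at equal arc length on the true contours, and jitters them with
isotropic Gaussian noise of σ = 1 mm — a deliberately pessimistic model
of click accuracy. Registration pairs resample the phantom through a
known rigid + anisotropic-scale perturbation (up to 10°, 8 mm,
0.9–1.1) onto a 0.6 mm isotropic grid, a typical T2-weighted MRI
resolution; the stored ground-truth transform scores the recovery.

What the phantom does **not** emulate: speckle, shadowing and
calcification (the method never sees intensities, but a human annotator
misled by them would place worse points than Gaussian jitter); truly
irregular, non-superellipse gland shapes, for which the B-spline path
exists but which the phantom cannot generate by construction; and
deformable (non-affine) MRI–TRUS discrepancy. Passing the synthetic
suite therefore demonstrates correctness of the machinery and
recoverability under the stated noise model, not clinical accuracy.

## Problem sizes and determinism

The shipped tests and the acceptance script run: 1000-draw consistency
checks; 50-shape rasterizer equivalence on 128² grids; 4 noiseless and
20 noisy 2D fits on 160² grids; one 3-slice phantom reconstruction
(144² × 21 voxels); one registration at the full 0.3 mm default
(~10⁷-voxel distance maps, 40 000 metric samples); and 100-pair metric
identities with 16³ brute-force distance oracles. Every stochastic step
(multistart jitter, annotator noise, perturbations, voxel sampling) is
driven by an explicit seed, and all generators are bit-reproducible
given the seed.

## Known limitations

* The fit is underdetermined below ~8 well-spread points; the
  early-stop rule returns the simplest consistent shape rather than an
  arbitrary valley point, but different protocols may prefer the prior
  (Eq. above) with population-calibrated hyperparameters.
* Linear z-interpolation cannot model glands whose cross-section
  changes non-monotonically between annotated slices; the remedy is
  annotating more slices, which the model accepts.
* The registration assumes the masks describe the same anatomy up to an
  affine map; strong probe-induced deformation beyond the bending the
  2D model captures would need a deformable stage.
* NRRD support covers axis-aligned volumes with raw or gzip encodings;
  NIfTI support is axis-aligned RAS.
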