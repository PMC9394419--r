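# trusfit

Semiautomatic prostate segmentation from transrectal ultrasound (TRUS)
by deformable superellipses, 3D gland reconstruction, and mask-based
MRI–TRUS registration — the geometric core of an MRI-targeted (fusion)
prostate biopsy workflow.

TRUS is the live imaging modality during biopsy, but gland boundaries
in it are blurred by speckle and shadowing, and fully automatic
segmenters need transducer-specific training data that is rarely
available. `trusfit` instead asks the physician for a handful of
boundary clicks on a few axial slices and does the rest:

* **Shape model.** Each axial cross-section is a *deformable
  superellipse*: the superellipse
  `|x/ax|^eps + |y/ay|^eps = 1` under rotation *r*, linear tapering *t*
  along y (`x' = (1 + t·y/ay)·x`), circular bending *b* along y
  (`x' = x + (1 − cos(b·y))/b`), and translation `(lx, ly)` — the
  8-parameter vector `p = (ax, ay, lx, ly, r, eps, t, b)`. Tapering and
  bending capture the gland's narrowing toward the apex and the
  posterior bowing induced by the probe.
* **Fitting.** `fit_superellipse()` minimizes the point-to-polygon
  energy `E(C; U) = Σ d(C, u)²` over the user points *U* with a bounded
  multistart Nelder–Mead search (optional Gaussian shape prior,
  disabled by default). Mid-gland slices with 10–12 points can use a
  closed cyclic B-spline (`fit_bspline_contour()`), to which a
  superellipse is then fitted for the 3D model.
* **3D reconstruction.** Annotate at least three slices (base ≥ 4
  points, mid ≥ 6, apex ≥ 4); `prostate_model()` interpolates the
  parameter vectors linearly in z (rotation on the circle) and
  `build_volume()` rasterizes every plane into a binary mask.
  `export_contours()` writes per-slice model points for the second user
  iteration in 3D Slicer.
* **Registration.** `register_masks()` aligns the MRI and TRUS
  segmentation masks: crop to the mask bounding box + 10 mm, resample
  to 0.3 mm isotropic (nearest neighbor), Gaussian-smooth (σ = 3
  voxels), take signed Euclidean distance maps, then refine a full
  affine transform from a rigid initialization (image centers or
  UB/VM/UA fiducial least squares) by minimizing the sampled SSD
  between the distance maps with an analytic gradient.
* **Metrics.** `evaluate_masks()` reports DSC, Jaccard, VOE, signed
  RVD, Hausdorff and average symmetric surface distance in mm.
* **Synthetic phantoms.** `generate_phantom()`,
  `simulate_annotator()` and `make_registration_pair()` build
  prostate-like ground truth, noisy click patterns and perturbed mask
  pairs, so the entire pipeline is testable without patient data.

File formats: NIfTI and NRRD volumes, 3D Slicer markups JSON point
lists (LPS/RAS aware), plain-text 4×4 transforms.

## Worked example

Fit a known deformed shape from 12 noiseless boundary points:

```r
library(trusfit)
truth <- superellipse(25, 18, 40, 38, r = 0.2, eps = 2.4, t = 0.15, b = 0.004)
th  <- seq(0, 2 * pi, length.out = 13)[-13]
pts <- apply_deformations(truth, sample_parametric(truth, th))
fit <- fit_superellipse(pts)
fit
#> Deformable superellipse fit to 12 points
#> Deformable superellipse
#>   semi-axes   ax = 25.127 mm, ay = 18.166 mm
#>   center      lx = 39.967 mm, ly = 37.905 mm
#>   rotation    r  = 0.2016 rad
#>   squareness  eps = 2.293
#>   taper t = 0.1740, bend b = 0.00341 1/mm
#>   energy 0.258227 (initial 32.0814)
```

The recovered semi-axes, center and rotation match the truth to a few
tenths of a millimetre; the residual energy of 0.26 mm² across 12
points corresponds to ~0.15 mm RMS point-to-boundary distance, well
below pixel size.

End-to-end on a synthetic gland — generate the phantom, simulate a
physician clicking 4/10/4 points with 1 mm jitter on three slices, fit,
reconstruct and score:

```r
spec <- phantom_spec(seed = 1, noise_sd = 1)
ph   <- generate_phantom(spec)
ann  <- simulate_annotator(ph$model, spec)
fits <- lapply(ann, fit_slice)
model <- prostate_model(fits, spec$grid, spec$z_spacing)
rec  <- build_volume(model, z_range = range(ph$model$z))
evaluate_masks(rec, ph$mask)
#> Segmentation evaluation
#>   Dice      94.79 %    Jaccard   90.10 %
#>   VOE        9.90 %    RVD       -7.57 %
#>   HD        2.872 mm   ASSD      0.489 mm
```

A Dice of ~95% from 18 noisy clicks on 3 of 21 slices is the intended
operating point: the sub-voxel ASSD says the reconstructed surface
tracks the true gland to about half a millimetre; the negative RVD
reflects mild under-segmentation, typical when noisy points pull the
fitted contour inward.

## Command line

A thin CLI over the same functions is installed with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "trusfit", package = "trusfit"))')
$CLI simulate     --out-dir work --seed 1
$CLI fit-trus     --markups work/annotations.json --volume work/phantom_mask.nrrd --out-dir work/fit
$CLI evaluate     --pred work/fit/trus_mask.nrrd --truth work/phantom_mask.nrrd
$CLI register     --fixed work/reg_fixed.nrrd --moving work/reg_moving.nrrd \
                  --out-transform work/T.txt --out-mask work/warped.nrrd
```

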