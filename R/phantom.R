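#' Specification of a synthetic prostate phantom
#'
#' Defines a prostate-like ground-truth object as a stack of deformable
#' superellipse cross-sections (semi-axes shrinking toward apex and
#' base, mid-gland tapering and posterior bending), the raster grid it
#' is built on, and the behaviour of the simulated annotator. The
#' defaults describe a 40-50 mm gland on a TRUS-like anisotropic grid
#' (0.5 mm in-plane, 2 mm slice thickness) with mid-gland taper t = 0.2
#' and bending b = 0.01 / mm.
#'
#' @param stack List of `list(z, par, region)` entries (`par` a
#'   [superellipse()] or named vector); defaults to the 5-entry gland
#'   described above.
#' @param grid In-plane [slice_grid()].
#' @param z_spacing Slice thickness in mm.
#' @param seed Integer seed driving the simulated annotator.
#' @param noise_sd Annotator jitter standard deviation in mm.
#' @param n_points Named counts of annotated points per region
#'   (`base`, `mid`, `apex`).
#' @return An object of class `"phantom_spec"`.
#' @export
phantom_spec <- function(stack = NULL,
                         grid = slice_grid(144, 144, spacing = c(0.5, 0.5)),
                         z_spacing = 2, seed = 1L, noise_sd = 1,
                         n_points = c(base = 4L, mid = 10L, apex = 4L)) {
  if (is.null(stack)) {
    cx <- grid$origin[1] + (grid$nx - 1) * grid$spacing[1] / 2
    cy <- grid$origin[2] + (grid$ny - 1) * grid$spacing[2] / 2
    stack <- list(
      list(z = 2,  par = superellipse(12, 10, cx, cy, r = 0.05, eps = 2.0),
           region = "apex"),
      list(z = 12, par = superellipse(20, 17, cx, cy + 1, r = 0.08, eps = 2.2,
                                      t = 0.10, b = 0.005), region = "mid"),
      list(z = 22, par = superellipse(25, 21, cx, cy + 2, r = 0.10, eps = 2.4,
                                      t = 0.20, b = 0.010), region = "mid"),
      list(z = 32, par = superellipse(22, 18, cx, cy + 1, r = 0.06, eps = 2.2,
                                      t = 0.12, b = 0.005), region = "mid"),
      list(z = 42, par = superellipse(14, 11, cx, cy, r = 0.03, eps = 2.0),
           region = "base"))
  }
  if (any(!c("base", "mid", "apex") %in% names(n_points)) ||
      n_points["base"] < 4L || n_points["apex"] < 4L || n_points["mid"] < 6L)
    stop("point counts must be named and at least 4 (base/apex) / 6 (mid)",
         call. = FALSE)
  if (noise_sd < 0) stop("annotator noise sd must be nonnegative", call. = FALSE)
  structure(list(stack = stack, grid = grid, z_spacing = z_spacing,
                 seed = as.integer(seed), noise_sd = noise_sd,
                 n_points = n_points),
            class = "phantom_spec")
}

#' Generate the ground-truth phantom
#'
#' Rasterizes the exact parameter stack into a 3D binary mask (every
#' axial plane interpolated densely in z) and returns the mask together
#' with the true [prostate_model()]. Fully deterministic.
#'
#' @param spec A [phantom_spec()].
#' @return List with elements `mask` ([binary_mask3d()]) and `model`
#'   (the ground-truth [prostate_model()]).
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  model <- prostate_model(spec$stack, spec$grid, spec$z_spacing)
  mask <- build_volume(model)
  list(mask = mask, model = model)
}

#' Simulate the annotating physician
#'
#' Selects the base slice, the apex slice and the mid-gland slice of
#' largest cross-section from the ground-truth model, samples the
#' configured number of points at equal arc length on each true contour
#' and jitters them with isotropic Gaussian noise of `spec$noise_sd`
#' mm. Deterministic given `spec$seed`.
#'
#' @param model The ground-truth [prostate_model()].
#' @param spec A [phantom_spec()].
#' @param mid_model Slice model used for the mid-gland slice
#'   annotation (`"bspline"` mirrors the recommended protocol for 10-12
#'   point mid-gland slices).
#' @return A list of [annotated_slice()] objects (base, mid, apex).
#' @export
simulate_annotator <- function(model, spec = phantom_spec(),
                               mid_model = c("bspline", "superellipse")) {
  stopifnot(inherits(model, "prostate_model"))
  mid_model <- match.arg(mid_model)
  idx_base <- which(model$regions == "base")[1]
  idx_apex <- which(model$regions == "apex")[1]
  mids <- which(model$regions == "mid")
  areas <- vapply(mids, function(i)
    contour_area(superellipse_polygon(model$params[[i]], 360L)), numeric(1))
  idx_mid <- mids[which.max(areas)]
  picks <- list(base = idx_base, mid = idx_mid, apex = idx_apex)
  with_seed(spec$seed, {
    lapply(names(picks), function(region) {
      i <- picks[[region]]
      n <- spec$n_points[[region]]
      poly <- superellipse_polygon(model$params[[i]], 720L)
      pts <- contour_arc_points(poly, n)
      pts <- pts + matrix(stats::rnorm(2 * n, 0, spec$noise_sd), n, 2)
      annotated_slice(pts, z_mm = model$z[i], region = region,
                      model = if (region == "mid") mid_model else "superellipse")
    })
  })
}

#' Build a synthetic registration pair
#'
#' Produces a (fixed, moving) mask pair emulating the geometry
#' difference between MRI and TRUS acquisitions: the fixed mask is the
#' input; the moving mask is the same object expressed in a perturbed
#' frame, i.e. resampled through the inverse of the ground-truth
#' transform onto a grid with its own spacing and origin. Registering
#' moving to fixed should recover `true_transform`.
#'
#' @param mask A [binary_mask3d()] (e.g. from [generate_phantom()]).
#' @param perturbation An [affine3d()] ground-truth transform mapping
#'   fixed physical coordinates to moving physical coordinates.
#' @param target_spacing Per-axis voxel size in mm of the moving grid
#'   (default 0.6 mm isotropic, a typical T2-weighted MRI in-plane
#'   resolution).
#' @param pad_mm Extra extent of the moving grid to keep the displaced
#'   object inside.
#' @return List with `fixed`, `moving` ([binary_mask3d()]) and
#'   `true_transform` ([affine3d()]).
#' @export
make_registration_pair <- function(mask, perturbation,
                                   target_spacing = c(0.6, 0.6, 0.6),
                                   pad_mm = 15) {
  mask <- as_mask3d(mask)
  stopifnot(inherits(perturbation, "affine3d"))
  target_spacing <- rep(as.numeric(target_spacing), length.out = 3L)
  ext <- dim(mask$data) * mask$spacing
  newd <- as.integer(ceiling((ext + 2 * pad_mm) / target_spacing))
  ref <- image3d(array(0, newd), spacing = target_spacing,
                 origin = mask$origin - pad_mm)
  moving <- apply_transform(mask, affine_inverse(perturbation), ref)
  if (sum(moving$data) == 0)
    stop("perturbation pushed the object outside the moving grid", call. = FALSE)
  list(fixed = mask, moving = moving, true_transform = perturbation)
}

#' Random rigid + anisotropic-scale perturbation
#'
#' Convenience generator of ground-truth perturbations for registration
#' experiments: rotation of up to `max_rot_deg` about a random axis,
#' translation of up to `max_trans_mm`, and independent per-axis scaling
#' drawn from `scale_range`; centered on `center`.
#'
#' @param seed Integer seed.
#' @param max_rot_deg,max_trans_mm,scale_range Perturbation magnitudes.
#' @param center Length-3 rotation center in mm.
#' @return An [affine3d()].
#' @export
random_perturbation <- function(seed = 1L, max_rot_deg = 10,
                                max_trans_mm = 8, scale_range = c(0.9, 1.1),
                                center = c(0, 0, 0)) {
  with_seed(seed, {
    ax <- stats::rnorm(3)
    ax <- ax / sqrt(sum(ax^2))
    ang <- stats::runif(1, -max_rot_deg, max_rot_deg) * pi / 180
    K <- base::matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
    R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
    S <- diag(stats::runif(3, scale_range[1], scale_range[2]))
    tr <- stats::runif(3, -1, 1)
    tr <- tr / max(sqrt(sum(tr^2)), 1e-12) * stats::runif(1, 0, max_trans_mm)
    affine3d(R %*% S, translation = tr, center = center)
  })
}
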