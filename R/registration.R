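#' Affine transform of 3D physical space
#'
#' Maps a physical point x (mm) to `A (x - c) + c + t`, where `A` is the
#' 3x3 linear part, `t` the translation and `c` the center of rotation.
#' In registration the transform maps fixed-image physical coordinates
#' into moving-image physical coordinates (the resampled moving image is
#' `M(T(x))`).
#'
#' @param matrix 3x3 linear matrix (non-singular).
#' @param translation Length-3 translation in mm.
#' @param center Length-3 rotation center in mm.
#' @return An object of class `"affine3d"`.
#' @export
affine3d <- function(matrix = diag(3), translation = c(0, 0, 0),
                     center = c(0, 0, 0)) {
  matrix <- base::matrix(as.numeric(matrix), 3L, 3L)
  if (abs(det(matrix)) < 1e-12)
    stop("affine matrix must be non-singular", call. = FALSE)
  structure(list(matrix = matrix,
                 translation = rep(as.numeric(translation), length.out = 3L),
                 center = rep(as.numeric(center), length.out = 3L)),
            class = "affine3d")
}

#' @export
print.affine3d <- function(x, ...) {
  cat("Affine 3D transform (fixed -> moving physical mm)\n")
  cat("  linear part:\n")
  print(round(x$matrix, 6))
  cat(sprintf("  translation (%.3f, %.3f, %.3f) mm, center (%.2f, %.2f, %.2f) mm\n",
              x$translation[1], x$translation[2], x$translation[3],
              x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

#' @rdname affine3d
#' @param T An `affine3d`.
#' @param points n x 3 matrix of physical points (mm).
#' @export
transform_points <- function(T, points) {
  pts <- base::matrix(as.numeric(points), ncol = 3L)
  sweep(sweep(pts, 2, T$center) %*% t(T$matrix), 2,
        T$center + T$translation, "+")
}

#' @rdname affine3d
#' @export
affine_inverse <- function(T) {
  Ai <- solve(T$matrix)
  # y = A(x - c) + c + t  =>  x = Ai (y - c - t) + c
  affine3d(Ai, translation = -Ai %*% T$translation, center = T$center)
}

#' @rdname affine3d
#' @param S Second `affine3d`; the composition applies `S` first, then
#'   `T` (`compose(T, S)(x) = T(S(x))`).
#' @export
affine_compose <- function(T, S) {
  M4 <- as_matrix4(T) %*% as_matrix4(S)
  affine3d(M4[1:3, 1:3], translation = M4[1:3, 4], center = c(0, 0, 0))
}

#' @rdname affine3d
#' @export
as_matrix4 <- function(T) {
  M <- diag(4)
  M[1:3, 1:3] <- T$matrix
  M[1:3, 4] <- T$center + T$translation - T$matrix %*% T$center
  M
}

#' Crop a mask to its volume of interest
#'
#' Tight bounding box of the foreground, dilated by `margin_mm` per side
#' and clipped to the input extent. Foreground voxels are preserved.
#'
#' @param mask A [binary_mask3d()].
#' @param margin_mm Margin in mm added on every side (default 10).
#' @return A [binary_mask3d()] on the cropped grid.
#' @export
crop_voi <- function(mask, margin_mm = 10) {
  mask <- as_mask3d(mask)
  if (sum(mask$data) == 0) stop("cannot crop an empty mask", call. = FALSE)
  d <- dim(mask$data)
  idx <- which(mask$data == 1L, arr.ind = TRUE)
  lo <- hi <- integer(3)
  for (ax in 1:3) {
    m <- ceiling(margin_mm / mask$spacing[ax])
    lo[ax] <- max(1L, min(idx[, ax]) - m)
    hi[ax] <- min(d[ax], max(idx[, ax]) + m)
  }
  binary_mask3d(mask$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE],
                spacing = mask$spacing,
                origin = mask$origin + (lo - 1L) * mask$spacing)
}

#' Resample a volume to isotropic resolution
#'
#' Resamples onto an isotropic grid of voxel size `res_mm`, preserving
#' the physical extent within one voxel (output dimension =
#' `round(extent / res_mm)`, same origin, voxel-center convention).
#' Binary masks should use `mode = "nearest"`, which keeps values in
#' \{0, 1\}.
#'
#' @param vol An [image3d()] or [binary_mask3d()].
#' @param res_mm Target isotropic voxel size in mm (default 0.3).
#' @param mode `"nearest"` or `"linear"`.
#' @return Same kind of object as `vol` on the isotropic grid.
#' @export
resample_isotropic <- function(vol, res_mm = 0.3,
                               mode = c("nearest", "linear")) {
  mode <- match.arg(mode)
  if (res_mm <= 0) stop("resolution must be positive", call. = FALSE)
  d <- dim(vol$data)
  newd <- pmax(1L, as.integer(round(d * vol$spacing / res_mm)))
  out <- cpp_resample_affine(as.numeric(vol$data), as.integer(d),
                             vol$spacing, vol$origin,
                             newd, rep(res_mm, 3), vol$origin,
                             as.numeric(diag(3)), c(0, 0, 0), c(0, 0, 0),
                             if (mode == "nearest") 0L else 1L, 0, 1L)
  arr <- array(out, newd)
  if (inherits(vol, "mask3d")) binary_mask3d(arr, rep(res_mm, 3), vol$origin)
  else image3d(arr, rep(res_mm, 3), vol$origin)
}

#' Gaussian smoothing of a mask
#'
#' Separable convolution with a normalized Gaussian kernel, sigma given
#' in voxel units (the registration pipeline applies it after isotropic
#' resampling, so sigma = 3 corresponds to 0.9 mm on the default 0.3 mm
#' grid). Values stay in [0, 1]; total intensity of interior masks is
#' preserved (zero-padded borders).
#'
#' @param mask A [binary_mask3d()] (or any [image3d()]).
#' @param sigma Kernel standard deviation in voxels (> 0).
#' @return An [image3d()] with values in [0, 1].
#' @export
gaussian_smooth <- function(mask, sigma = 3) {
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  rad <- max(1L, ceiling(3 * sigma))
  kern <- stats::dnorm(seq(-rad, rad), sd = sigma)
  kern <- kern / sum(kern)
  sm <- function(a) conv_axis(conv_axis(conv_axis(a, kern, 1L), kern, 2L),
                              kern, 3L)
  arr <- sm(vol_array(mask))
  # renormalize by the smoothed indicator of the domain so that borders
  # see a properly normalized kernel (constant in -> constant out)
  w <- sm(array(1, dim(arr)))
  image3d(pmin(pmax(arr / w, 0), 1), mask$spacing, mask$origin)
}

vol_array <- function(x) {
  a <- if (inherits(x, "image3d")) x$data else as.array(x)
  storage.mode(a) <- "double"
  a
}

# separable 1D convolution along one axis of a 3D array, zero padding
conv_axis <- function(arr, kern, axis) {
  d <- dim(arr)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  a <- aperm(arr, perm)
  da <- dim(a)
  rad <- (length(kern) - 1L) / 2L
  m <- base::matrix(a, da[1], da[2] * da[3])
  mp <- rbind(base::matrix(0, rad, ncol(m)), m, base::matrix(0, rad, ncol(m)))
  f <- stats::filter(mp, kern, method = "convolution", sides = 2L)
  f <- f[(rad + 1L):(rad + da[1]), , drop = FALSE]
  out <- array(as.numeric(f), da)
  aperm(out, order(perm))
}

#' Signed Euclidean distance map of a mask
#'
#' Every voxel holds the exact Euclidean distance in mm from its center
#' to the nearest boundary voxel of the mask (foreground voxels with a
#' 6-connected background neighbor), negative inside the mask, positive
#' outside, zero on the boundary voxels themselves. Equivalent to the
#' Maurer signed distance transform up to the boundary-voxel convention.
#'
#' @param mask A [binary_mask3d()] with both foreground and background,
#'   or an [image3d()] in [0, 1] (thresholded at 0.5).
#' @return An [image3d()] of signed distances in mm.
#' @export
signed_distance_map <- function(mask) {
  arr <- vol_array(mask)
  fg <- arr >= 0.5
  if (!any(fg) || all(fg))
    stop("signed distance needs both foreground and background", call. = FALSE)
  bnd <- boundary_voxels(array(as.integer(fg), dim(arr)))
  dist <- distance_to_sites(bnd, mask$spacing)
  dist[fg] <- -dist[fg]
  image3d(dist, mask$spacing, mask$origin)
}

#' Center-of-image initialization
#'
#' Identity linear part; rotation center at the geometric center of the
#' moving image; translation equal to the vector from the fixed-image
#' center to the moving-image center (all computed from origin,
#' dimensions and spacing, in physical mm).
#'
#' @param fixed,moving [image3d()] volumes.
#' @return An [affine3d()].
#' @export
init_center <- function(fixed, moving) {
  cf <- volume_center(fixed)
  cm <- volume_center(moving)
  affine3d(diag(3), translation = cm - cf, center = cm)
}

#' Landmark (least-squares rigid) initialization
#'
#' Closed-form orthogonal-Procrustes/Kabsch solution of the rigid
#' transform T (rotation + translation) minimizing
#' `sum ||T(fixed_i) - moving_i||^2` over matched landmark pairs, e.g.
#' the urethra-entry (UB, UA) and verumontanum (VM) fiducials.
#'
#' @param fixed_lm,moving_lm n x 3 matrices (n >= 3, non-collinear) of
#'   matched landmarks in physical mm; rows are matched by position (and
#'   by name when both carry row names).
#' @return An [affine3d()] with orthonormal linear part.
#' @export
init_landmarks <- function(fixed_lm, moving_lm) {
  F <- base::matrix(as.numeric(as.matrix(fixed_lm)), ncol = 3L)
  M <- base::matrix(as.numeric(as.matrix(moving_lm)), ncol = 3L)
  if (!is.null(rownames(fixed_lm)) && !is.null(rownames(moving_lm)) &&
      all(sort(rownames(fixed_lm)) == sort(rownames(moving_lm))))
    M <- base::matrix(as.numeric(as.matrix(moving_lm)[rownames(fixed_lm), ]), ncol = 3L)
  if (nrow(F) < 3L || nrow(F) != nrow(M))
    stop("need at least 3 matched landmark pairs", call. = FALSE)
  cf <- colMeans(F); cm <- colMeans(M)
  Fc <- sweep(F, 2, cf); Mc <- sweep(M, 2, cm)
  if (svd(Fc)$d[2] < 1e-9)
    stop("landmarks are collinear", call. = FALSE)
  H <- t(Fc) %*% Mc
  s <- svd(H)
  D <- diag(c(1, 1, sign(det(s$v %*% t(s$u)))))
  R <- s$v %*% D %*% t(s$u)
  affine3d(R, translation = cm - cf, center = cf)
}

#' Sum of squared intensity differences
#'
#' Exact full-grid SSD between two volumes on the same grid; zero iff
#' the volumes are identical.
#'
#' @param a,b [image3d()] volumes on the same grid.
#' @export
ssd <- function(a, b) {
  if (!same_grid(a, b)) stop("volumes must share the same grid", call. = FALSE)
  sum((a$data - b$data)^2)
}

#' Segmentation-based affine registration of two masks
#'
#' The full pipeline of the mask-based MRI-TRUS fusion step: each mask
#' is cropped to its bounding box plus `margin_mm`, resampled to an
#' isotropic `res_mm` grid with nearest-neighbor interpolation, smoothed
#' with a Gaussian of `sigma` voxels, and converted to a signed
#' Euclidean distance map. After rigid initialization (image centers or
#' landmark least squares) a regular-step gradient-descent optimizer
#' refines a full affine transform by minimizing the mean squared
#' difference between the fixed distance map and the resampled moving
#' distance map. Only improving steps are accepted, so the final metric
#' never exceeds the initial one.
#'
#' @param fixed_mask,moving_mask [binary_mask3d()] volumes
#'   (conventionally fixed = MRI, moving = TRUS).
#' @param init `"center"` or `"landmarks"`.
#' @param fixed_landmarks,moving_landmarks n x 3 matrices of matched
#'   fiducials (required for `init = "landmarks"`).
#' @param margin_mm VOI margin (default 10 mm).
#' @param res_mm Isotropic working resolution (default 0.3 mm).
#' @param sigma Gaussian sigma in voxels of the working grid (default 3).
#' @param optimizer `"bfgs"` (default) refines the affine parameters by
#'   quasi-Newton descent on the analytic metric gradient; `"gd"` uses
#'   plain regular-step gradient descent (normalized gradient, adaptive
#'   step halving), the scheme classically used in ITK pipelines.
#' @param max_iter Optimizer iteration cap.
#' @param step_mm Initial step length in mm-equivalent parameter space
#'   (`optimizer = "gd"`).
#' @param min_step_mm Convergence threshold on the step length
#'   (`optimizer = "gd"`).
#' @param sample_band_mm Fixed-grid voxels are sampled within this band
#'   of the gland surface (|signed distance| below the band); aligning
#'   the near field of the distance maps localizes the boundary better
#'   than the far field, whose values are biased under anisotropic
#'   scaling.
#' @param n_samples Number of fixed-grid voxels (seeded uniform sample
#'   within the band) on which the metric and its analytic gradient are
#'   evaluated.
#' @param seed Seed for the voxel sample.
#' @return An object of class `"mask_registration"`: fields `transform`
#'   ([affine3d()]), `metric_initial`, `metric_final`, `trace` (accepted
#'   metric values), `converged`, `iterations`, plus the preprocessed
#'   distance-map grids. Methods: `print`, `summary`.
#' @export
register_masks <- function(fixed_mask, moving_mask,
                           init = c("center", "landmarks"),
                           fixed_landmarks = NULL, moving_landmarks = NULL,
                           margin_mm = 10, res_mm = 0.3, sigma = 3,
                           optimizer = c("bfgs", "gd"),
                           max_iter = 400L, step_mm = 1, min_step_mm = 1e-4,
                           sample_band_mm = 6, n_samples = 40000L, seed = 1L) {
  init <- match.arg(init)
  optimizer <- match.arg(optimizer)
  if (init == "landmarks" && (is.null(fixed_landmarks) || is.null(moving_landmarks)))
    stop("init = 'landmarks' requires both landmark sets", call. = FALSE)

  prep <- function(m) {
    v <- resample_isotropic(crop_voi(as_mask3d(m), margin_mm), res_mm, "nearest")
    signed_distance_map(gaussian_smooth(v, sigma))
  }
  fdm <- prep(fixed_mask)
  mdm <- prep(moving_mask)

  T0 <- if (init == "center") init_center(fdm, mdm)
        else init_landmarks(fixed_landmarks, moving_landmarks)
  cen <- T0$center

  # seeded uniform voxel sample of the fixed grid, restricted to the
  # near-surface band of the fixed distance map
  d <- dim(fdm$data)
  cand_idx <- which(abs(fdm$data) <= sample_band_mm)
  if (length(cand_idx) < 100L) cand_idx <- seq_len(prod(d))
  n_samples <- min(n_samples, length(cand_idx))
  sel <- with_seed(seed, sort(sample(cand_idx, n_samples)))
  ijk <- arrayInd(sel, d)
  pts <- sweep(sweep(ijk - 1, 2, fdm$spacing, "*"), 2, fdm$origin, "+")
  fvals <- fdm$data[sel]

  eval_metric <- function(theta) {
    cpp_ssd_affine_grad(as.numeric(mdm$data), as.integer(dim(mdm$data)),
                        mdm$spacing, mdm$origin, pts, fvals,
                        theta[1:9], theta[10:12], cen)
  }

  theta <- c(as.numeric(t(T0$matrix)), T0$translation)
  # parameter scaling: a unit change in a matrix entry moves points by
  # about the object radius L, translations are already in mm
  L <- max(dim(fdm$data) * fdm$spacing) / 2
  scale <- c(rep(L, 9), rep(1, 3))

  cur <- eval_metric(theta)
  v0 <- cur$value
  if (optimizer == "bfgs") {
    # quasi-Newton on the same analytic gradient; the trace keeps the
    # monotone record of accepted (improving) evaluations
    trace_env <- new.env()
    trace_env$trace <- v0
    fn <- function(th) {
      v <- eval_metric(th)$value
      if (v < trace_env$trace[length(trace_env$trace)])
        trace_env$trace <- c(trace_env$trace, v)
      v
    }
    gr <- function(th) eval_metric(th)$gradient
    opt <- stats::optim(theta, fn, gr, method = "BFGS",
                        control = list(maxit = max_iter, reltol = 1e-10,
                                       parscale = 1 / scale))
    if (opt$value <= v0) theta <- opt$par
    cur <- eval_metric(theta)
    trace <- trace_env$trace
    it <- opt$counts[["gradient"]]
    converged <- opt$convergence == 0L
  } else {
    trace <- v0
    lambda <- step_mm
    it <- 0L
    while (it < max_iter && lambda > min_step_mm) {
      it <- it + 1L
      g <- cur$gradient * scale        # gradient in mm-equivalent space
      gn <- sqrt(sum(g^2))
      if (gn < 1e-14) break
      cand <- theta - lambda * (g / gn) / scale
      nxt <- eval_metric(cand)
      if (nxt$value < cur$value) {
        theta <- cand
        # shrink the step when the direction turns back on itself,
        # otherwise let it grow back toward the initial step length
        if (sum((nxt$gradient * scale) * g) < 0) lambda <- lambda / 2
        else lambda <- min(lambda * 1.5, step_mm)
        cur <- nxt
        trace <- c(trace, cur$value)
      } else {
        lambda <- lambda / 2
      }
    }
    converged <- lambda <= min_step_mm
  }

  Tfin <- affine3d(base::matrix(theta[1:9], 3, 3, byrow = TRUE),
                   translation = theta[10:12], center = cen)
  structure(list(transform = Tfin, initial_transform = T0,
                 metric_initial = v0, metric_final = cur$value,
                 trace = trace, converged = converged,
                 iterations = it, init = init, optimizer = optimizer,
                 fixed_dm = fdm, moving_dm = mdm,
                 res_mm = res_mm, sigma = sigma, margin_mm = margin_mm),
            class = "mask_registration")
}

#' @export
print.mask_registration <- function(x, ...) {
  cat(sprintf("Mask-based affine registration (%s init, %s optimizer)\n",
              x$init, x$optimizer))
  cat(sprintf("  metric (mean squared distance-map difference): %.5g -> %.5g\n",
              x$metric_initial, x$metric_final))
  cat(sprintf("  %d iterations%s\n", x$iterations,
              if (x$converged) ", converged" else " (iteration cap reached)"))
  print(x$transform)
  invisible(x)
}

#' @export
summary.mask_registration <- function(object, ...) {
  structure(list(reg = object,
                 reduction = 1 - object$metric_final /
                   max(object$metric_initial, .Machine$double.eps)),
            class = "summary.mask_registration")
}

#' @export
print.summary.mask_registration <- function(x, ...) {
  print(x$reg)
  cat(sprintf("  metric reduction: %.1f %%\n", 100 * x$reduction))
  invisible(x)
}

#' Resample a mask through an affine transform
#'
#' Resamples `mask` (treated as the moving image) onto `reference`'s
#' grid under `T` with nearest-neighbor interpolation:
#' `out(x) = mask(T(x))`.
#'
#' @param mask A [binary_mask3d()].
#' @param T An [affine3d()].
#' @param reference An [image3d()] providing the output grid (defaults
#'   to the grid of `mask`).
#' @return A [binary_mask3d()] on the reference grid.
#' @export
apply_transform <- function(mask, T, reference = mask) {
  mask <- as_mask3d(mask)
  out <- cpp_resample_affine(as.numeric(mask$data), as.integer(dim(mask$data)),
                             mask$spacing, mask$origin,
                             as.integer(dim(reference$data)), reference$spacing,
                             reference$origin,
                             as.numeric(t(T$matrix)), T$translation, T$center,
                             0L, 0, 0L)
  binary_mask3d(array(out, dim(reference$data)), reference$spacing,
                reference$origin)
}
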