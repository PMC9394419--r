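#' 3D prostate model from fitted axial slices
#'
#' An ordered stack of (z, superellipse parameters) pairs defining the
#' gland between the most superior and most inferior annotated slices.
#' Requires at least three entries with strictly increasing z, covering
#' the base, at least one mid-gland slice and the apex. Between entries,
#' every parameter is interpolated linearly in z; the rotation angle is
#' interpolated along the shortest circular arc.
#'
#' @param fits A list of [fit_slice()] results (class `"slice_fit"`), or
#'   a list of `list(z, par, region)` entries with `par` a
#'   [superellipse()].
#' @param grid Reference [slice_grid()] used when rasterizing
#'   reconstructed slices.
#' @param z_spacing Axial plane spacing in mm of the reconstruction
#'   target.
#' @return An object of class `"prostate_model"` with fields `z`,
#'   `params` (list of [superellipse()]), `regions`, `grid`,
#'   `z_spacing`. Methods: `print`, `predict`, `plot`.
#' @export
prostate_model <- function(fits, grid, z_spacing = 2) {
  entries <- lapply(fits, function(f) {
    if (inherits(f, "slice_fit"))
      list(z = f$slice$z_mm, par = f$par, region = f$slice$region)
    else
      list(z = as.numeric(f$z), par = as_superellipse(f$par),
           region = match.arg(f$region, c("base", "mid", "apex")))
  })
  z <- vapply(entries, `[[`, numeric(1), "z")
  ord <- order(z)
  entries <- entries[ord]
  z <- z[ord]
  if (length(z) < 3L)
    stop("a 3D model needs at least three annotated slices", call. = FALSE)
  if (any(diff(z) <= 0))
    stop("annotated slices must have distinct z positions", call. = FALSE)
  regions <- vapply(entries, `[[`, character(1), "region")
  if (!all(c("base", "mid", "apex") %in% regions))
    stop("annotated slices must cover base, mid-gland and apex", call. = FALSE)
  if (z_spacing <= 0) stop("z_spacing must be positive")
  structure(list(z = z, params = lapply(entries, `[[`, "par"),
                 regions = regions, grid = grid,
                 z_spacing = as.numeric(z_spacing)),
            class = "prostate_model")
}

#' @export
print.prostate_model <- function(x, ...) {
  cat(sprintf("3D prostate model: %d annotated slices, z in [%.2f, %.2f] mm\n",
              length(x$z), min(x$z), max(x$z)))
  for (i in seq_along(x$z))
    cat(sprintf("  z = %7.2f mm  %-5s ax = %.2f, ay = %.2f\n",
                x$z[i], x$regions[i], x$params[[i]]$ax, x$params[[i]]$ay))
  invisible(x)
}

#' Interpolate the parameter vector at an axial position
#'
#' Component-wise linear interpolation between the bracketing annotated
#' slices; at an annotated z the stored parameters are returned exactly.
#' The rotation angle is interpolated along the shortest arc of the
#' circle (so +170 deg and -170 deg average to 180 deg, not 0).
#'
#' @param model A [prostate_model()].
#' @param z Axial position in mm, within the annotated range.
#' @return A [superellipse()].
#' @export
interpolate_params <- function(model, z) {
  stopifnot(inherits(model, "prostate_model"))
  if (z < min(model$z) - 1e-9 || z > max(model$z) + 1e-9)
    stop("z outside the annotated slice range", call. = FALSE)
  z <- min(max(z, min(model$z)), max(model$z))
  mats <- t(vapply(model$params, se_params, numeric(8)))
  colnames(mats) <- c("ax", "ay", "lx", "ly", "r", "eps", "t", "b")
  # unwrap rotation so linear interpolation follows the shortest arc
  r <- mats[, "r"]
  if (length(r) > 1L) {
    d <- diff(r)
    d <- (d + pi) %% (2 * pi) - pi
    mats[, "r"] <- r[1] + c(0, cumsum(d))
  }
  vals <- vapply(colnames(mats), function(nm)
    stats::approx(model$z, mats[, nm], xout = z)$y, numeric(1))
  vals["r"] <- wrap_angle(vals["r"])
  as_superellipse(vals)
}

#' Predict from a 3D prostate model
#'
#' @param object A [prostate_model()].
#' @param z Axial position in mm.
#' @param type `"params"` returns the interpolated [superellipse()],
#'   `"contour"` the boundary polygon at z, `"mask"` the rasterized
#'   slice mask on the model grid.
#' @param n Contour vertices for `type = "contour"`.
#' @param ... Unused.
#' @export
predict.prostate_model <- function(object, z, type = c("params", "contour", "mask"),
                                   n = 256L, ...) {
  type <- match.arg(type)
  p <- interpolate_params(object, z)
  switch(type,
         params = p,
         contour = superellipse_polygon(p, n),
         mask = rasterize(p, object$grid))
}

#' Reconstruct the 3D gland mask from the model
#'
#' Every axial plane of the target volume lying within the annotated z
#' range is rasterized from the interpolated parameter vector; planes
#' outside the range stay empty. The first plane is placed at the most
#' inferior annotated z.
#'
#' @param model A [prostate_model()].
#' @param z_range Length-2 z extent in mm of the output volume (defaults
#'   to the annotated range).
#' @param dz Plane spacing in mm (defaults to `model$z_spacing`).
#' @return A [binary_mask3d()] with in-plane geometry of `model$grid`.
#' @export
build_volume <- function(model, z_range = NULL, dz = NULL) {
  stopifnot(inherits(model, "prostate_model"))
  if (is.null(dz)) dz <- model$z_spacing
  if (is.null(z_range)) z_range <- range(model$z)
  zs <- seq(z_range[1], z_range[2] + 1e-9, by = dz)
  g <- model$grid
  arr <- array(0L, c(g$nx, g$ny, length(zs)))
  for (k in seq_along(zs)) {
    if (zs[k] < min(model$z) - 1e-9 || zs[k] > max(model$z) + 1e-9) next
    arr[, , k] <- rasterize(interpolate_params(model, zs[k]), g)
  }
  if (sum(arr) == 0L) stop("reconstructed volume is empty", call. = FALSE)
  binary_mask3d(arr, spacing = c(g$spacing, dz),
                origin = c(g$origin, zs[1]))
}

#' Export model contour points for the second user iteration
#'
#' Samples `n` points at equal arc length on the model contour of each
#' annotated slice (or of every reconstructed plane), for loading into
#' 3D Slicer, manual adjustment, and refitting in B-spline mode.
#'
#' @param model A [prostate_model()].
#' @param n Points per slice (>= 4).
#' @param slices `"annotated"` exports the annotated planes only,
#'   `"all"` every reconstruction plane.
#' @return A list with one element per slice: `list(z, region, points)`
#'   where `points` is an `n` x 2 matrix on the model contour.
#' @export
export_contours <- function(model, n = 12L, slices = c("annotated", "all")) {
  stopifnot(inherits(model, "prostate_model"))
  slices <- match.arg(slices)
  if (n < 4L) stop("at least 4 exported points per slice", call. = FALSE)
  zs <- if (slices == "annotated") model$z
        else seq(min(model$z), max(model$z) + 1e-9, by = model$z_spacing)
  lapply(seq_along(zs), function(k) {
    z <- zs[k]
    region <- if (slices == "annotated") model$regions[k]
              else model$regions[which.min(abs(model$z - z))]
    poly <- superellipse_polygon(interpolate_params(model, z), 720L)
    list(z = z, region = region, points = contour_arc_points(poly, n))
  })
}

#' @export
plot.prostate_model <- function(x, ...) {
  zs <- seq(min(x$z), max(x$z), length.out = 9L)
  cols <- grDevices::hcl.colors(length(zs), "viridis")
  rng <- NULL
  polys <- lapply(zs, function(z)
    superellipse_polygon(interpolate_params(x, z), 180L)$vertices)
  rng <- apply(do.call(rbind, polys), 2, range)
  graphics::plot(NA, xlim = rng[, 1], ylim = rng[, 2], asp = 1,
                 xlab = "x [mm]", ylab = "y [mm]",
                 main = "Prostate model axial contours", ...)
  for (i in seq_along(polys))
    graphics::lines(rbind(polys[[i]], polys[[i]][1, ]), col = cols[i])
  invisible(x)
}
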