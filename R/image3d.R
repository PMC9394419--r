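#' 3D image volume with physical geometry
#'
#' A scalar 3D grid with voxel spacing and origin in physical mm (RAS
#' axis-aligned frame). Array dimension 1 runs along x, 2 along y, 3
#' along z (superior-inferior); voxel (i, j, k) has physical coordinate
#' `origin + (i-1, j-1, k-1) * spacing` (voxel-center convention).
#'
#' @param data A 3D numeric array.
#' @param spacing Length-3 voxel size in mm (scalar recycled).
#' @param origin Length-3 mm coordinate of the first voxel center.
#' @return An object of class `"image3d"`; [binary_mask3d()] additionally
#'   checks that all values are 0/1 and prepends class `"mask3d"`.
#' @export
image3d <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("data must be a 3D array", call. = FALSE)
  spacing <- rep(as.numeric(spacing), length.out = 3L)
  origin <- rep(as.numeric(origin), length.out = 3L)
  if (any(spacing <= 0) || anyNA(spacing)) stop("spacing must be positive", call. = FALSE)
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "image3d")
}

#' @rdname image3d
#' @export
binary_mask3d <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  vol <- image3d(data, spacing, origin)
  if (!all(vol$data %in% c(0, 1)))
    stop("a binary mask may only contain 0 and 1", call. = FALSE)
  storage.mode(vol$data) <- "integer"
  class(vol) <- c("mask3d", "image3d")
  vol
}

is_mask3d <- function(x) inherits(x, "mask3d") ||
  (inherits(x, "image3d") && all(x$data %in% c(0, 1)))

as_mask3d <- function(x) {
  if (inherits(x, "mask3d")) x
  else binary_mask3d(x$data, x$spacing, x$origin)
}

#' @export
print.image3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("%s: %d x %d x %d voxels, spacing (%.4g, %.4g, %.4g) mm\n",
              if (inherits(x, "mask3d")) "Binary 3D mask" else "3D image volume",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%.4g, %.4g, %.4g) mm; value range [%.4g, %.4g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.image3d <- function(x) dim(x$data)

# physical extent center (mid-point of the voxel-center grid)
volume_center <- function(vol) vol$origin + (dim(vol$data) - 1) * vol$spacing / 2

same_grid <- function(a, b, tol = 1e-6) {
  all(dim(a$data) == dim(b$data)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

# voxel center coordinates along one axis
axis_coords <- function(vol, axis) {
  vol$origin[axis] + (seq_len(dim(vol$data)[axis]) - 1) * vol$spacing[axis]
}
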