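#' Deformable superellipse parameters
#'
#' Constructs and validates the 8-parameter deformable superellipse used to
#' model a prostate cross-section on an axial slice. The base shape is the
#' centered superellipse \eqn{|x/a_x|^\epsilon + |y/a_y|^\epsilon = 1};
#' deformations (applied in the order rotation, tapering, bending,
#' translation) extend it to tilted, tapered and posteriorly bent glands.
#'
#' @param ax,ay Semi-axis lengths along x and y, in mm (> 0).
#' @param lx,ly Translation along x and y, in mm.
#' @param r Rotation angle in radians, positive counter-clockwise.
#' @param eps Squareness exponent (> 0); 2 gives an ordinary ellipse,
#'   smaller values square the shape off, larger values pinch it.
#' @param t Linear tapering coefficient along y (dimensionless, |t| < 1):
#'   the x-extent is scaled by \eqn{1 + t\,y/a_y}, narrowing one end of the
#'   gland and widening the other.
#' @param b Circular bending coefficient along y, in 1/mm (|b| ay < 1):
#'   x is displaced by the sagitta \eqn{(1 - \cos(b\,y))/b} of a circular
#'   arc of curvature b, modelling the posterior warp induced by the
#'   ultrasound transducer.
#' @return An object of class `"superellipse"`.
#' @examples
#' p <- superellipse(ax = 25, ay = 18, lx = 40, ly = 38, r = 0.2,
#'                   eps = 2.4, t = 0.15, b = 0.004)
#' inside_outside(p, cbind(0, 0))
#' @export
superellipse <- function(ax, ay, lx = 0, ly = 0, r = 0, eps = 2, t = 0, b = 0) {
  p <- list(ax = as.numeric(ax), ay = as.numeric(ay),
            lx = as.numeric(lx), ly = as.numeric(ly),
            r = as.numeric(r), eps = as.numeric(eps),
            t = as.numeric(t), b = as.numeric(b))
  class(p) <- "superellipse"
  validate_superellipse(p)
  p
}

validate_superellipse <- function(p) {
  v <- unlist(p[c("ax", "ay", "lx", "ly", "r", "eps", "t", "b")])
  if (length(v) != 8L || anyNA(v) || any(!is.finite(v)))
    stop("superellipse parameters must be 8 finite numbers", call. = FALSE)
  if (p$ax <= 0 || p$ay <= 0) stop("semi-axes ax, ay must be positive", call. = FALSE)
  if (p$eps <= 0) stop("squareness exponent eps must be positive", call. = FALSE)
  if (abs(p$t) >= 1) stop("tapering coefficient must satisfy |t| < 1", call. = FALSE)
  if (abs(p$b) * p$ay >= 1) stop("bending must satisfy |b|*ay < 1", call. = FALSE)
  invisible(p)
}

#' @export
print.superellipse <- function(x, ...) {
  cat("Deformable superellipse\n")
  cat(sprintf("  semi-axes   ax = %.3f mm, ay = %.3f mm\n", x$ax, x$ay))
  cat(sprintf("  center      lx = %.3f mm, ly = %.3f mm\n", x$lx, x$ly))
  cat(sprintf("  rotation    r  = %.4f rad\n", x$r))
  cat(sprintf("  squareness  eps = %.3f\n", x$eps))
  cat(sprintf("  taper t = %.4f, bend b = %.5f 1/mm\n", x$t, x$b))
  invisible(x)
}

#' @export
as.double.superellipse <- function(x, ...) {
  c(ax = x$ax, ay = x$ay, lx = x$lx, ly = x$ly,
    r = x$r, eps = x$eps, t = x$t, b = x$b)
}

se_params <- function(p) {
  c(ax = p$ax, ay = p$ay, lx = p$lx, ly = p$ly,
    r = p$r, eps = p$eps, t = p$t, b = p$b)
}

#' @rdname superellipse
#' @param x A named numeric vector with components
#'   `ax, ay, lx, ly, r, eps, t, b`.
#' @export
as_superellipse <- function(x) {
  if (inherits(x, "superellipse")) return(x)
  x <- unlist(x)
  nm <- c("ax", "ay", "lx", "ly", "r", "eps", "t", "b")
  if (!all(nm %in% names(x))) stop("need named components: ", paste(nm, collapse = ", "))
  do.call(superellipse, as.list(x[nm]))
}

#' Sample the centered superellipse boundary in parametric form
#'
#' Evaluates the parametric boundary
#' \eqn{x = a_x |\cos\theta|^{2/\epsilon}\,\mathrm{sign}(\cos\theta)},
#' \eqn{y = a_y |\sin\theta|^{2/\epsilon}\,\mathrm{sign}(\sin\theta)}.
#' Deformation parameters of `p` are ignored; the points are in the
#' centered, undeformed frame.
#'
#' @param p A [superellipse()].
#' @param thetas Numeric vector of angles in radians.
#' @return An `length(thetas)` x 2 matrix of (x, y) points in mm.
#' @export
sample_parametric <- function(p, thetas) {
  p <- as_superellipse(p)
  if (anyNA(thetas) || any(!is.finite(thetas))) stop("thetas must be finite")
  e <- 2 / p$eps
  ct <- cos(thetas); st <- sin(thetas)
  cbind(x = p$ax * abs(ct)^e * sign(ct),
        y = p$ay * abs(st)^e * sign(st))
}

#' Inside-outside function of the centered superellipse
#'
#' \eqn{f(x,y) = |x/a_x|^\epsilon + |y/a_y|^\epsilon}: equals 1 on the
#' boundary, is below 1 inside and above 1 outside. Deformations of `p`
#' are ignored (points are expected in the centered frame).
#'
#' @inheritParams sample_parametric
#' @param points An n x 2 matrix of (x, y) points in mm.
#' @return Numeric vector of nonnegative values.
#' @export
inside_outside <- function(p, points) {
  p <- as_superellipse(p)
  points <- as_point_matrix(points)
  abs(points[, 1] / p$ax)^p$eps + abs(points[, 2] / p$ay)^p$eps
}

as_point_matrix <- function(points) {
  if (is.null(dim(points))) {
    if (length(points) == 2L) points <- matrix(points, 1L, 2L)
    else stop("points must be an n x 2 matrix")
  }
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("points must be an n x 2 matrix")
  storage.mode(points) <- "double"
  points
}

#' Apply the superellipse deformations to centered points
#'
#' Transforms points from the centered superellipse frame into the slice
#' frame, in the fixed order: rotation by `r`, linear tapering along y,
#' circular bending along y, translation by `(lx, ly)`.
#'
#' @inheritParams inside_outside
#' @return Matrix of deformed points, same shape as `points`.
#' @seealso [invert_deformations()]
#' @export
apply_deformations <- function(p, points) {
  p <- as_superellipse(p)
  pts <- as_point_matrix(points)
  x <- pts[, 1]; y <- pts[, 2]
  # rotation
  cr <- cos(p$r); sr <- sin(p$r)
  x1 <- cr * x - sr * y
  y1 <- sr * x + cr * y
  # linear tapering along y
  x2 <- (p$t * y1 / p$ay + 1) * x1
  # circular bending along y: sagitta of an arc of curvature b at height y
  x3 <- x2 + bend_sagitta(p$b, y1)
  # translation
  cbind(x = x3 + p$lx, y = y1 + p$ly)
}

bend_sagitta <- function(b, y) {
  if (b == 0) return(rep(0, length(y)))
  (1 - cos(b * y)) / b
}

#' Invert the superellipse deformations
#'
#' Maps points from the slice frame back to the centered superellipse
#' frame, undoing translation, bending, tapering and rotation in reverse
#' order. Exact inverse of [apply_deformations()] for parameters within
#' the model invariants.
#'
#' @inheritParams inside_outside
#' @param points An n x 2 matrix of deformed (slice-frame) points in mm.
#' @return Matrix of centered points.
#' @export
invert_deformations <- function(p, points) {
  p <- as_superellipse(p)
  pts <- as_point_matrix(points)
  x <- pts[, 1] - p$lx
  y <- pts[, 2] - p$ly
  x <- x - bend_sagitta(p$b, y)
  fac <- p$t * y / p$ay + 1
  if (any(fac <= 0))
    stop("point outside the invertible range of the tapering map", call. = FALSE)
  x <- x / fac
  cr <- cos(p$r); sr <- sin(p$r)
  cbind(x = cr * x + sr * y, y = -sr * x + cr * y)
}

#' Closed polygon approximation of the deformed superellipse boundary
#'
#' Samples the parametric boundary densely and pushes it through the
#' deformation chain; because every deformation is a homeomorphism within
#' the parameter invariants, the deformed boundary curve is the boundary
#' of the deformed region.
#'
#' @inheritParams inside_outside
#' @param n Number of boundary vertices.
#' @return A [contour2d()] (counter-clockwise, closed).
#' @export
superellipse_polygon <- function(p, n = 256) {
  p <- as_superellipse(p)
  thetas <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  contour2d(apply_deformations(p, sample_parametric(p, thetas)))
}

#' Closed planar contour
#'
#' A closed polygon in slice-plane mm coordinates, stored as an ordered
#' vertex ring (the closing edge from last to first vertex is implicit)
#' and normalized to counter-clockwise orientation.
#'
#' @param vertices An n x 2 matrix (n >= 3) of (x, y) vertices in mm.
#' @return An object of class `"contour2d"` with fields `vertices` and
#'   `closed = TRUE`.
#' @export
contour2d <- function(vertices) {
  v <- as_point_matrix(vertices)
  # drop an explicitly repeated closing vertex
  if (nrow(v) > 1L && all(v[1L, ] == v[nrow(v), ])) v <- v[-nrow(v), , drop = FALSE]
  if (nrow(v) < 3L) stop("a contour needs at least 3 distinct vertices", call. = FALSE)
  if (anyNA(v) || any(!is.finite(v))) stop("contour vertices must be finite", call. = FALSE)
  if (shoelace_area(v) < 0) v <- v[rev(seq_len(nrow(v))), , drop = FALSE]
  structure(list(vertices = v, closed = TRUE), class = "contour2d")
}

#' @export
print.contour2d <- function(x, ...) {
  cat(sprintf("Closed contour: %d vertices, area %.3f mm^2, perimeter %.3f mm\n",
              nrow(x$vertices), contour_area(x), contour_perimeter(x)))
  invisible(x)
}

#' @rdname contour2d
#' @param contour A `contour2d`.
#' @export
contour_area <- function(contour) abs(shoelace_area(contour$vertices))

#' @rdname contour2d
#' @export
contour_perimeter <- function(contour) {
  v <- contour$vertices
  w <- rbind(v[-1L, , drop = FALSE], v[1L, , drop = FALSE])
  sum(sqrt(rowSums((w - v)^2)))
}

shoelace_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  0.5 * sum(x * yn - xn * y)
}

#' Pixel grid of an axial slice
#'
#' Geometry of a 2D raster: `nx` columns along x and `ny` rows along y,
#' pixel sizes in mm, and the mm coordinates of the center of pixel
#' (1, 1). Pixel (i, j) has center `origin + (i - 1, j - 1) * spacing`
#' (pixel-center convention).
#'
#' @param nx,ny Pixel counts along x and y.
#' @param spacing Length-2 pixel size in mm (recycled if scalar).
#' @param origin Length-2 mm coordinates of the first pixel center.
#' @export
slice_grid <- function(nx, ny, spacing = c(1, 1), origin = c(0, 0)) {
  spacing <- rep(as.numeric(spacing), length.out = 2L)
  origin <- rep(as.numeric(origin), length.out = 2L)
  if (any(spacing <= 0)) stop("grid spacing must be positive")
  if (nx < 1 || ny < 1) stop("grid must have at least one pixel per axis")
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 spacing = spacing, origin = origin),
            class = "slice_grid")
}

grid_x <- function(grid) grid$origin[1] + (seq_len(grid$nx) - 1) * grid$spacing[1]
grid_y <- function(grid) grid$origin[2] + (seq_len(grid$ny) - 1) * grid$spacing[2]

#' Rasterize a deformable superellipse onto a slice grid
#'
#' Follows the forward-mapping recipe: lattice points (at the grid
#' resolution) inside the centered superellipse (`inside_outside <= 1`)
#' are pushed through the deformation chain, binned into grid pixels, and
#' the resulting mask is repaired by morphological closing (3x3 box,
#' repeated until no interior hole remains, at most `max_closings`
#' passes; any residual hole is then filled) since the discrete forward
#' map leaves holes where it locally expands.
#'
#' @inheritParams inside_outside
#' @param grid A [slice_grid()].
#' @param max_closings Maximum number of closing passes.
#' @return Integer 0/1 matrix of dimension `c(grid$nx, grid$ny)`
#'   (first index = x/column axis, second = y/row axis).
#' @export
rasterize <- function(p, grid, max_closings = 5L) {
  p <- as_superellipse(p)
  # centered lattice covering the undeformed shape, at grid resolution
  xs <- seq(-p$ax, p$ax, by = grid$spacing[1])
  ys <- seq(-p$ay, p$ay, by = grid$spacing[2])
  pts <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  pts <- pts[inside_outside(p, pts) <= 1, , drop = FALSE]
  if (nrow(pts) == 0L) stop("shape too small for the grid resolution", call. = FALSE)
  fwd <- apply_deformations(p, pts)
  i <- round((fwd[, 1] - grid$origin[1]) / grid$spacing[1]) + 1
  j <- round((fwd[, 2] - grid$origin[2]) / grid$spacing[2]) + 1
  keep <- i >= 1 & i <= grid$nx & j >= 1 & j <= grid$ny
  if (!any(keep)) stop("shape falls entirely outside the grid", call. = FALSE)
  mask <- matrix(0L, grid$nx, grid$ny)
  mask[cbind(i[keep], j[keep])] <- 1L
  mask <- close_until_solid(mask, max_closings)
  mask
}

# Morphological closing with a 3x3 box: always one pass (the discrete
# forward map leaves nicks and holes), repeated while interior holes
# remain (max `iter` passes), then hard-fill any residual hole.
close_until_solid <- function(mask, iter = 5L) {
  kern <- EBImage::makeBrush(3L, "box")
  k <- 0L
  repeat {
    mask <- matrix(as.integer(EBImage::closing(mask, kern) > 0),
                   nrow(mask), ncol(mask))
    k <- k + 1L
    if (count_holes(mask) == 0L || k >= iter) break
  }
  if (count_holes(mask) > 0L) mask <- fill_holes(mask)
  mask
}

# background components not touching the border are holes
count_holes <- function(mask) {
  bg <- EBImage::bwlabel(1L - mask)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  length(setdiff(unique(as.integer(bg)), c(0L, as.integer(border))))
}

fill_holes <- function(mask) {
  bg <- EBImage::bwlabel(1L - mask)
  border <- setdiff(unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)])), 0L)
  matrix(as.integer(mask == 1L | !(bg %in% c(0L, border))), nrow(mask), ncol(mask))
}

n_components <- function(mask) max(EBImage::bwlabel(mask))

#' Trace the boundary polygon of a binary slice mask
#'
#' Extracts the outer boundary of a single-component binary mask as a
#' closed counter-clockwise polygon running along pixel borders
#' (sub-pixel resolution: vertices sit on pixel corners), in mm
#' coordinates of the grid. A 3x3 all-ones mask at 1 mm spacing yields a
#' square of perimeter 12 mm.
#'
#' @param mask 0/1 matrix `[x, y]` as produced by [rasterize()].
#' @param grid The [slice_grid()] the mask lives on; defaults to unit
#'   spacing with origin (0, 0).
#' @return A [contour2d()].
#' @export
contour_of <- function(mask, grid = NULL) {
  if (is.null(grid)) grid <- slice_grid(nrow(mask), ncol(mask))
  if (sum(mask) == 0L) stop("empty mask has no contour", call. = FALSE)
  if (n_components(mask) != 1L)
    stop("mask must have exactly one connected component", call. = FALSE)
  nx <- nrow(mask); ny <- ncol(mask)
  fg <- which(mask == 1L, arr.ind = TRUE)
  i <- fg[, 1]; j <- fg[, 2]
  at <- function(ii, jj) {
    ok <- ii >= 1 & ii <= nx & jj >= 1 & jj <= ny
    out <- rep(0L, length(ii))
    out[ok] <- mask[cbind(ii[ok], jj[ok])]
    out
  }
  # pixel corners on a doubled-integer lattice: center of pixel (i,j) is
  # (2i, 2j); its corners are (2i +/- 1, 2j +/- 1). Directed boundary
  # edges keep the interior on the left (CCW polygon, x right / y up):
  # bottom edge -> +x, right edge -> +y, top edge -> -x, left edge -> -y.
  ed <- list()
  sel <- at(i, j - 1L) == 0L  # bottom
  ed[[1]] <- cbind(2*i[sel] - 1L, 2*j[sel] - 1L, 2*i[sel] + 1L, 2*j[sel] - 1L)
  sel <- at(i + 1L, j) == 0L  # right
  ed[[2]] <- cbind(2*i[sel] + 1L, 2*j[sel] - 1L, 2*i[sel] + 1L, 2*j[sel] + 1L)
  sel <- at(i, j + 1L) == 0L  # top
  ed[[3]] <- cbind(2*i[sel] + 1L, 2*j[sel] + 1L, 2*i[sel] - 1L, 2*j[sel] + 1L)
  sel <- at(i - 1L, j) == 0L  # left
  ed[[4]] <- cbind(2*i[sel] - 1L, 2*j[sel] + 1L, 2*i[sel] - 1L, 2*j[sel] - 1L)
  edges <- do.call(rbind, ed)
  key <- function(a, b) paste(a, b, sep = ",")
  from <- key(edges[, 1], edges[, 2])
  # walk the cycle; at pinch vertices (two outgoing edges) prefer the
  # sharpest left turn so the traced polygon stays simple
  out_idx <- split(seq_len(nrow(edges)), from)
  used <- rep(FALSE, nrow(edges))
  start <- which.min(edges[, 1] * 1e6 + edges[, 2])
  path <- integer(nrow(edges))
  cur <- start; nstep <- 0L
  repeat {
    nstep <- nstep + 1L
    path[nstep] <- cur
    used[cur] <- TRUE
    nxt <- out_idx[[key(edges[cur, 3], edges[cur, 4])]]
    nxt <- nxt[!used[nxt]]
    if (length(nxt) == 0L) break
    if (length(nxt) > 1L) {
      d_in <- edges[cur, 3:4] - edges[cur, 1:2]
      turn <- vapply(nxt, function(e) {
        d_out <- edges[e, 3:4] - edges[e, 1:2]
        atan2(d_in[1] * d_out[2] - d_in[2] * d_out[1],
              d_in[1] * d_out[1] + d_in[2] * d_out[2])
      }, numeric(1))
      nxt <- nxt[which.max(turn)]
    }
    cur <- nxt
  }
  path <- path[seq_len(nstep)]
  v <- edges[path, 1:2, drop = FALSE]
  # drop collinear midpoints to shorten the ring, keep geometry identical
  prv <- rbind(v[nrow(v), ], v[-nrow(v), , drop = FALSE])
  nxtv <- rbind(v[-1L, , drop = FALSE], v[1L, , drop = FALSE])
  collinear <- (prv[, 1] == v[, 1] & v[, 1] == nxtv[, 1]) |
               (prv[, 2] == v[, 2] & v[, 2] == nxtv[, 2])
  v <- v[!collinear, , drop = FALSE]
  mm <- cbind(grid$origin[1] + (v[, 1] / 2 - 1) * grid$spacing[1],
              grid$origin[2] + (v[, 2] / 2 - 1) * grid$spacing[2])
  contour2d(mm)
}
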