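#' Point-to-polygon energy of a contour against user points
#'
#' The data-fidelity term of the point-constrained fit: the sum over user
#' points of the Euclidean distance from the point to the closed polygon
#' boundary, squared by default. Zero exactly when every point lies on
#' the boundary.
#'
#' @param contour A [contour2d()].
#' @param points n x 2 matrix of user points (mm).
#' @param squared Use squared distances (default); `FALSE` sums plain
#'   distances.
#' @return Nonnegative scalar.
#' @export
energy <- function(contour, points, squared = TRUE) {
  d <- point_contour_distance(contour, points)
  if (squared) sum(d^2) else sum(d)
}

#' @rdname energy
#' @return `point_contour_distance()`: the per-point distances to the
#'   polygon boundary.
#' @export
point_contour_distance <- function(contour, points) {
  if (!inherits(contour, "contour2d")) contour <- contour2d(contour)
  pts <- as_point_matrix(points)
  v <- contour$vertices
  w <- rbind(v[-1L, , drop = FALSE], v[1L, , drop = FALSE])
  ex <- w[, 1] - v[, 1]; ey <- w[, 2] - v[, 2]
  len2 <- ex^2 + ey^2
  if (all(len2 < 1e-24)) stop("degenerate polygon", call. = FALSE)
  vapply(seq_len(nrow(pts)), function(s) {
    px <- pts[s, 1] - v[, 1]; py <- pts[s, 2] - v[, 2]
    tt <- pmin(1, pmax(0, ifelse(len2 > 0, (px * ex + py * ey) / len2, 0)))
    sqrt(min((px - tt * ex)^2 + (py - tt * ey)^2))
  }, numeric(1))
}

#' Gaussian log-prior over shape parameters
#'
#' \eqn{\ln \Pr(p_s) = -\sum_j (p_j - m_j)^2 / (2 \sigma_j^2)} over the
#' parameters named in the prior configuration. Nonpositive; zero at the
#' prior mode.
#'
#' @param p A [superellipse()].
#' @param prior A [prior_config()] with `enabled = TRUE`.
#' @export
log_prior <- function(p, prior) {
  if (!isTRUE(prior$enabled)) stop("prior is disabled", call. = FALSE)
  p <- se_params(as_superellipse(p))
  nm <- names(prior$mean)
  -sum((p[nm] - prior$mean)^2 / (2 * prior$sd^2))
}

#' Prior configuration for the shape parameters
#'
#' The paper's experiments never publish prior hyperparameters, so the
#' prior is off by default; when enabled it penalizes departure of the
#' named parameters from their means in units of the stated standard
#' deviations, with overall weight `weight`.
#'
#' @param enabled Logical.
#' @param mean Named numeric vector of prior means (subset of
#'   `ax, ay, lx, ly, r, eps, t, b`; conventionally the shape subset
#'   `ax, ay, eps, t, b`).
#' @param sd Named numeric vector of prior standard deviations (> 0),
#'   same names as `mean`.
#' @param weight Nonnegative multiplier of the prior term in the
#'   objective.
#' @export
prior_config <- function(enabled = FALSE, mean = NULL, sd = NULL, weight = 1) {
  if (enabled) {
    if (is.null(mean) || is.null(sd) || is.null(names(mean)) ||
        !identical(sort(names(mean)), sort(names(sd))))
      stop("an enabled prior needs matching named mean and sd vectors")
    sd <- sd[names(mean)]
    if (any(sd <= 0)) stop("prior standard deviations must be positive")
    bad <- setdiff(names(mean), c("ax", "ay", "lx", "ly", "r", "eps", "t", "b"))
    if (length(bad)) stop("unknown parameters in prior: ", paste(bad, collapse = ", "))
  }
  if (weight < 0) stop("prior weight must be nonnegative")
  structure(list(enabled = enabled, mean = mean, sd = sd, weight = weight),
            class = "prior_config")
}

#' Fit configuration
#'
#' Controls the derivative-free bounded optimization of the superellipse
#' parameters.
#'
#' @param multistarts Number of Nelder-Mead starts (first from the
#'   deterministic data-driven initialization, the rest seeded jitters).
#' @param maxit Iteration cap per start.
#' @param reltol Relative convergence tolerance.
#' @param seed Integer seed making the multistart jitter reproducible.
#' @param squared Use squared point-to-polygon distances in the energy.
#' @param boundary `"parametric"` evaluates the energy on the exact
#'   deformed parametric boundary polygon; `"raster"` reproduces the
#'   rasterize-close-trace loop at every objective evaluation.
#' @param n_theta Boundary vertices for the parametric polygon.
#' @param grid Optional [slice_grid()]; required for `boundary = "raster"`
#'   and used to bound the semi-axes (defaults to twice the annotated
#'   point extent).
#' @param eps_range,t_max Squareness bounds and tapering bound.
#' @param bend_max Bound on |b| * ay, keeping the bending injective.
#' @param early_stop_rel Stop refining once the RMS point-to-boundary
#'   residual falls below this fraction of the annotation extent; with
#'   sparse points the problem is underdetermined near zero energy, and
#'   further search would only wander between equivalent optima (in
#'   particular, an initialization that already explains the points to
#'   sub-resolution accuracy is returned as is).
#' @export
fit_config <- function(multistarts = 4L, maxit = 1000L, reltol = 1e-9,
                       seed = 1L, squared = TRUE,
                       boundary = c("parametric", "raster"),
                       n_theta = 256L, grid = NULL,
                       eps_range = c(0.6, 4), t_max = 0.6, bend_max = 0.5,
                       early_stop_rel = 2e-3) {
  boundary <- match.arg(boundary)
  structure(list(multistarts = as.integer(multistarts), maxit = as.integer(maxit),
                 reltol = reltol, seed = as.integer(seed), squared = squared,
                 boundary = boundary, n_theta = as.integer(n_theta),
                 grid = grid, eps_range = eps_range, t_max = t_max,
                 bend_max = bend_max, early_stop_rel = early_stop_rel),
            class = "fit_config")
}

# run code under a private RNG stream without disturbing the caller's
with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# -- unconstrained reparametrization keeping every iterate inside the
#    model invariants (positivity, |t| bound, injective bending).
#    Lengths are expressed relative to the annotation scale s0, so the
#    Nelder-Mead path (comparison-based, hence invariant to the overall
#    scaling of the energy) is identical for rescaled point sets and
#    the fit is scale-equivariant by construction.
se_from_u <- function(u, cfg, s0 = 1) {
  ay <- s0 * exp(u[2])
  superellipse(ax = s0 * exp(u[1]), ay = ay, lx = s0 * u[3], ly = s0 * u[4],
               r = u[5],
               eps = cfg$eps_range[1] + diff(cfg$eps_range) * stats::plogis(u[6]),
               t = cfg$t_max * tanh(u[7]),
               b = (cfg$bend_max / ay) * tanh(u[8]))
}

u_from_se <- function(p, cfg, s0 = 1) {
  f <- (p$eps - cfg$eps_range[1]) / diff(cfg$eps_range)
  f <- min(max(f, 1e-6), 1 - 1e-6)
  c(log(p$ax / s0), log(p$ay / s0), p$lx / s0, p$ly / s0, p$r, stats::qlogis(f),
    atanh(min(max(p$t / cfg$t_max, -0.999), 0.999)),
    atanh(min(max(p$b * p$ay / cfg$bend_max, -0.999), 0.999)))
}

# deterministic scale-aware initialization: centroid, principal axis,
# extents along the principal frame, eps = 2, no taper/bend
init_superellipse <- function(points) {
  ctr <- colMeans(points)
  cc <- sweep(points, 2, ctr)
  ev <- eigen(stats::cov(cc), symmetric = TRUE)
  ang <- atan2(ev$vectors[2, 1], ev$vectors[1, 1])
  if (ang > pi / 2) ang <- ang - pi
  if (ang <= -pi / 2) ang <- ang + pi
  rot <- cbind(c(cos(ang), -sin(ang)), c(sin(ang), cos(ang)))
  loc <- cc %*% rot  # coordinates in the principal frame
  superellipse(ax = max(abs(loc[, 1])), ay = max(abs(loc[, 2])),
               lx = ctr[1], ly = ctr[2], r = ang, eps = 2, t = 0, b = 0)
}

#' Fit a deformable superellipse to sparse boundary points
#'
#' Minimizes the point-to-polygon energy (squared point-to-boundary
#' distances by default), optionally penalized by the Gaussian shape
#' prior, over the 8 deformable-superellipse parameters with a bounded
#' multistart Nelder-Mead search. Deterministic for a given
#' `config$seed`.
#'
#' @param points n x 2 matrix of annotated boundary points in mm
#'   (n >= 4).
#' @param config A [fit_config()].
#' @param prior A [prior_config()].
#' @return An object of class `"superellipse_fit"`: fields `par` (the
#'   fitted [superellipse()]), `energy`, `initial_energy`, `contour`
#'   (fitted boundary polygon), `points`, `convergence`, `prior`,
#'   `config`. Methods: `print`, `coef`, `summary`, `predict`,
#'   `residuals`, `plot`, `simulate`.
#' @examples
#' truth <- superellipse(25, 18, 40, 38, r = 0.2, eps = 2.4, t = 0.15, b = 0.004)
#' pts <- apply_deformations(truth,
#'                           sample_parametric(truth, seq(0, 2 * pi, length.out = 13)[-13]))
#' fit <- fit_superellipse(pts)
#' coef(fit)
#' @export
fit_superellipse <- function(points, config = fit_config(),
                             prior = prior_config()) {
  pts <- as_point_matrix(points)
  if (nrow(pts) < 4L)
    stop("at least 4 annotated points are required", call. = FALSE)
  if (anyNA(pts) || any(!is.finite(pts))) stop("points must be finite")
  if (anyDuplicated(pts)) stop("duplicated annotated points")
  cfg <- config
  extent <- 2 * max(apply(pts, 2, function(v) diff(range(v)))) + 1e-6
  if (!is.null(cfg$grid))
    extent <- max(extent, max(cfg$grid$nx * cfg$grid$spacing[1],
                              cfg$grid$ny * cfg$grid$spacing[2]))
  s0 <- extent / 2

  objective <- function(u) {
    p <- se_from_u(u, cfg, s0)
    pen <- 0
    if (p$ax > extent) pen <- pen + 1e4 * ((p$ax - extent) / extent)^2
    if (p$ay > extent) pen <- pen + 1e4 * ((p$ay - extent) / extent)^2
    if (abs(p$r) > pi / 2) pen <- pen + 1e4 * (abs(p$r) - pi / 2)^2
    ctr <- if (cfg$boundary == "parametric") {
      superellipse_polygon(p, cfg$n_theta)
    } else {
      g <- cfg$grid
      if (is.null(g)) stop("boundary = 'raster' needs a grid in fit_config")
      m <- tryCatch(rasterize(p, g), error = function(e) NULL)
      if (is.null(m) || n_components(m) != 1L) return(1e8 + pen)
      contour_of(m, g)
    }
    e <- energy(ctr, pts, squared = cfg$squared)
    if (isTRUE(prior$enabled))
      e <- e - prior$weight * log_prior(p, prior)
    e + pen
  }

  p0 <- init_superellipse(pts)
  u0 <- u_from_se(p0, cfg, s0)
  starts <- with_seed(cfg$seed, {
    lapply(seq_len(cfg$multistarts), function(s) {
      if (s == 1L) u0
      else u0 + stats::rnorm(8, 0, c(0.1, 0.1, 0.05, 0.05, 0.15, 0.5, 0.3, 0.3))
    })
  })
  rms_of <- function(u) sqrt(mean(point_contour_distance(
    superellipse_polygon(se_from_u(u, cfg, s0), cfg$n_theta), pts)^2))
  rms_floor <- cfg$early_stop_rel * s0
  e0 <- objective(u0)
  if (rms_of(u0) < rms_floor) {
    best <- list(par = u0, value = e0, convergence = 0L)
  } else {
    best <- NULL
    for (u in starts) {
      opt <- stats::optim(u, objective, method = "Nelder-Mead",
                          control = list(maxit = cfg$maxit, reltol = cfg$reltol))
      if (is.null(best) || opt$value < best$value) best <- opt
      if (rms_of(best$par) < rms_floor) break
    }
  }
  par <- se_from_u(best$par, cfg, s0)
  par$r <- wrap_angle(par$r)
  contour <- superellipse_polygon(par, max(cfg$n_theta, 256L))
  structure(list(par = par,
                 energy = energy(contour, pts, squared = cfg$squared),
                 objective = best$value,
                 initial_energy = e0,
                 contour = contour, points = pts,
                 convergence = best$convergence == 0L,
                 prior = prior, config = cfg),
            class = "superellipse_fit")
}

wrap_angle <- function(r) {
  r <- (r + pi) %% (2 * pi) - pi
  r
}

#' @export
print.superellipse_fit <- function(x, ...) {
  cat("Deformable superellipse fit to", nrow(x$points), "points\n")
  print(x$par)
  cat(sprintf("  energy %.6g (initial %.6g)%s\n", x$energy, x$initial_energy,
              if (x$convergence) "" else " [optimizer iteration cap reached]"))
  invisible(x)
}

#' @export
coef.superellipse_fit <- function(object, ...) se_params(object$par)

#' @export
summary.superellipse_fit <- function(object, ...) {
  res <- residuals(object)
  structure(list(fit = object, residuals = res,
                 rmse = sqrt(mean(res^2)), max_abs = max(res)),
            class = "summary.superellipse_fit")
}

#' @export
print.summary.superellipse_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  point-to-boundary residuals: RMSE %.4f mm, max %.4f mm\n",
              x$rmse, x$max_abs))
  invisible(x)
}

#' @export
residuals.superellipse_fit <- function(object, ...) {
  point_contour_distance(object$contour, object$points)
}

#' Predict boundary points or a mask from a fitted superellipse
#'
#' @param object A `superellipse_fit`.
#' @param type `"contour"` (default) returns the fitted boundary polygon;
#'   `"mask"` rasterizes onto `grid`.
#' @param n Boundary vertices for `type = "contour"`.
#' @param grid [slice_grid()] for `type = "mask"`.
#' @param ... Unused.
#' @export
predict.superellipse_fit <- function(object, type = c("contour", "mask"),
                                     n = 256L, grid = NULL, ...) {
  type <- match.arg(type)
  if (type == "contour") superellipse_polygon(object$par, n)
  else {
    if (is.null(grid)) grid <- object$config$grid
    if (is.null(grid)) stop("type = 'mask' needs a grid")
    rasterize(object$par, grid)
  }
}

#' @export
plot.superellipse_fit <- function(x, ...) {
  v <- x$contour$vertices
  graphics::plot(rbind(v, v[1, ]), type = "l", asp = 1,
                 xlab = "x [mm]", ylab = "y [mm]",
                 main = "Deformable superellipse fit", ...)
  graphics::points(x$points, pch = 19, col = "red")
  invisible(x)
}

#' Simulate noisy annotations from a fitted superellipse
#'
#' Draws `nsim` replicate point sets on the fitted boundary (equal
#' arc-length spacing) with isotropic Gaussian jitter, mirroring how a
#' user would re-annotate the fitted contour.
#'
#' @param object A `superellipse_fit`.
#' @param nsim Number of replicates.
#' @param seed Optional seed.
#' @param n_points Points per replicate.
#' @param sd Jitter standard deviation in mm.
#' @param ... Unused.
#' @return List of `nsim` point matrices.
#' @export
simulate.superellipse_fit <- function(object, nsim = 1, seed = NULL,
                                      n_points = nrow(object$points),
                                      sd = 1, ...) {
  base <- contour_arc_points(superellipse_polygon(object$par, 720L), n_points)
  runner <- function() lapply(seq_len(nsim), function(s)
    base + matrix(stats::rnorm(2 * n_points, 0, sd), n_points, 2))
  if (is.null(seed)) runner() else with_seed(seed, runner())
}

# n points at equal arc length along the contour ring
contour_arc_points <- function(contour, n) {
  v <- contour$vertices
  vc <- rbind(v, v[1L, , drop = FALSE])
  seg <- sqrt(rowSums(diff(vc)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  target <- seq(0, total, length.out = n + 1L)[-(n + 1L)]
  xi <- stats::approx(s, vc[, 1], xout = target)$y
  yi <- stats::approx(s, vc[, 2], xout = target)$y
  cbind(x = xi, y = yi)
}

#' Fit a closed smoothing B-spline contour through annotated points
#'
#' Orders the points angularly about their centroid (ties broken by
#' radius), parametrizes them by chord length and fits one cyclic cubic
#' regression spline per coordinate (periodic smoothing spline). With
#' `smoothing = 0` the curve passes through the points.
#'
#' @param points n x 2 matrix (n >= 6) of annotated points in mm.
#' @param smoothing Nonnegative smoothing parameter (per-coordinate
#'   penalty weight); 0 interpolates.
#' @param n_out Number of contour vertices sampled from the spline
#'   (>= 200 recommended).
#' @return A [contour2d()].
#' @export
fit_bspline_contour <- function(points, smoothing = 0, n_out = 256L) {
  pts <- as_point_matrix(points)
  if (nrow(pts) < 6L) stop("a B-spline contour needs at least 6 points", call. = FALSE)
  if (anyDuplicated(pts)) stop("duplicated annotated points")
  ctr <- colMeans(pts)
  cc <- sweep(pts, 2, ctr)
  sv <- svd(cc)$d
  if (sv[2] < 1e-9 * max(sv[1], 1)) stop("annotated points are collinear", call. = FALSE)
  ang <- atan2(cc[, 2], cc[, 1])
  rad <- sqrt(rowSums(cc^2))
  ord <- order(ang, rad)
  pts <- pts[ord, , drop = FALSE]
  # chord-length parameter over the closed ring, scaled to [0, 1)
  ring <- rbind(pts, pts[1L, , drop = FALSE])
  seg <- sqrt(rowSums(diff(ring)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  tt <- s[-length(s)] / total
  k <- nrow(pts)
  df <- data.frame(tt = tt, x = pts[, 1], y = pts[, 2])
  kn <- list(tt = c(0, 1))
  fx <- mgcv::gam(x ~ s(tt, bs = "cc", k = k), data = df, knots = kn,
                  sp = smoothing)
  fy <- mgcv::gam(y ~ s(tt, bs = "cc", k = k), data = df, knots = kn,
                  sp = smoothing)
  tg <- data.frame(tt = seq(0, 1, length.out = n_out + 1L)[-(n_out + 1L)])
  contour2d(cbind(as.numeric(stats::predict(fx, tg)),
                  as.numeric(stats::predict(fy, tg))))
}

#' Annotated axial slice
#'
#' User point annotations on one axial slice, with the anatomical region
#' and the per-slice model choice. Base and apex slices need at least 4
#' points; mid-gland slices should have at least 6 (a warning is emitted
#' below the recommended count, an error below the hard floor of 4).
#'
#' @param points n x 2 matrix of (x, y) points in slice-plane mm.
#' @param z_mm Axial position of the slice in mm.
#' @param region `"base"`, `"mid"` or `"apex"`.
#' @param model `"superellipse"` or `"bspline"`.
#' @param slice_index Optional integer slice index in the source volume.
#' @export
annotated_slice <- function(points, z_mm, region = c("mid", "base", "apex"),
                            model = c("superellipse", "bspline"),
                            slice_index = NA_integer_) {
  region <- match.arg(region)
  model <- match.arg(model)
  pts <- as_point_matrix(points)
  if (anyNA(pts) || any(!is.finite(pts))) stop("points must be finite")
  if (anyDuplicated(pts)) stop("duplicated points in slice annotation")
  if (nrow(pts) < 4L)
    stop("at least 4 points are required on any slice", call. = FALSE)
  if (region == "mid" && nrow(pts) < 6L)
    warning("mid-gland slices are recommended to have at least 6 points")
  structure(list(points = pts, z_mm = as.numeric(z_mm), region = region,
                 model = model, slice_index = as.integer(slice_index)),
            class = "annotated_slice")
}

#' @export
print.annotated_slice <- function(x, ...) {
  cat(sprintf("Annotated %s slice at z = %.2f mm: %d points (%s model)\n",
              x$region, x$z_mm, nrow(x$points), x$model))
  invisible(x)
}

#' Fit one annotated slice
#'
#' Dispatches on the slice's model: `"superellipse"` fits the deformable
#' superellipse directly to the annotated points; `"bspline"` first fits
#' the closed smoothing B-spline through the points and then fits the
#' superellipse to dense samples of the spline (the refined contour
#' returned is the spline itself, while the parameter vector feeds the
#' 3D model).
#'
#' @param slice An [annotated_slice()].
#' @param config A [fit_config()].
#' @param prior A [prior_config()].
#' @param smoothing Spline smoothing for `"bspline"` slices.
#' @return A list of class `"slice_fit"`: `par` ([superellipse()]),
#'   `contour` ([contour2d()]), `energy`, `slice`, `fit`.
#' @export
fit_slice <- function(slice, config = fit_config(), prior = prior_config(),
                      smoothing = 0) {
  stopifnot(inherits(slice, "annotated_slice"))
  if (slice$model == "superellipse") {
    fit <- fit_superellipse(slice$points, config, prior)
    contour <- fit$contour
  } else {
    spline <- fit_bspline_contour(slice$points, smoothing = smoothing)
    dense <- contour_arc_points(spline, 100L)
    fit <- fit_superellipse(dense, config, prior)
    contour <- spline
  }
  structure(list(par = fit$par, contour = contour, energy = fit$energy,
                 slice = slice, fit = fit),
            class = "slice_fit")
}

#' @export
print.slice_fit <- function(x, ...) {
  print(x$slice)
  print(x$par)
  invisible(x)
}
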