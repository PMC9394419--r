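# shared fixtures: random-but-valid superellipses, reference masks and
# small phantoms built in code

random_superellipse <- function(center = c(40, 40), size = c(10, 30)) {
  ax <- runif(1, size[1], size[2])
  ay <- runif(1, size[1], size[2])
  superellipse(ax = ax, ay = ay,
               lx = center[1] + runif(1, -5, 5),
               ly = center[2] + runif(1, -5, 5),
               r = runif(1, -pi / 3, pi / 3),
               eps = runif(1, 1.2, 3.2),
               t = runif(1, -0.4, 0.4),
               b = runif(1, -0.4, 0.4) / ay)
}

# Dice between two 2D binary matrices
dice2d <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# rasterization oracle: evaluate inside_outside at the inverse-mapped
# grid points (no forward mapping, no closing)
rasterize_oracle <- function(p, grid) {
  xs <- trusfit:::grid_x(grid)
  ys <- trusfit:::grid_y(grid)
  pts <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  ctr <- tryCatch(invert_deformations(p, pts), error = function(e) NULL)
  if (is.null(ctr)) { # fall back: points far outside the taper range
    keep <- rep(FALSE, nrow(pts))
    for (i in seq_len(nrow(pts))) {
      ci <- tryCatch(invert_deformations(p, pts[i, , drop = FALSE]),
                     error = function(e) NULL)
      keep[i] <- !is.null(ci) && inside_outside(p, ci) <= 1
    }
    return(matrix(as.integer(keep), grid$nx, grid$ny))
  }
  matrix(as.integer(inside_outside(p, ctr) <= 1), grid$nx, grid$ny)
}

# small blob mask for 3D metric tests: thresholded smoothed noise
random_blob3d <- function(d = c(12, 12, 12), spacing = c(1, 1, 1),
                          p_fg = 0.45) {
  arr <- array(as.integer(runif(prod(d)) < p_fg), d)
  arr[c(1, d[1]), , ] <- 0L
  arr[, c(1, d[2]), ] <- 0L
  arr[, , c(1, d[3])] <- 0L
  if (sum(arr) == 0) arr[ceiling(d[1] / 2), ceiling(d[2] / 2), ceiling(d[3] / 2)] <- 1L
  binary_mask3d(arr, spacing)
}

small_phantom_spec <- function(seed = 1L, noise_sd = 1) {
  phantom_spec(seed = seed, noise_sd = noise_sd)
}
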