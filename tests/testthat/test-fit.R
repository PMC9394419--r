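test_that("energy matches closed forms and the brute-force edge oracle", {
  sq <- contour2d(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  expect_equal(energy(sq, rbind(c(0, 0), c(1, 1), c(0.5, 0))), 0)
  expect_equal(energy(sq, cbind(2, 0.5), squared = TRUE), 1)
  expect_equal(energy(sq, cbind(2, 0.5), squared = FALSE), 1)
  expect_equal(energy(sq, cbind(3, 0.5), squared = TRUE), 4)
  # brute force over all edges of a triangle
  tri <- contour2d(rbind(c(0, 0), c(4, 0), c(0, 3)))
  set.seed(4)
  pts <- cbind(runif(10, -2, 6), runif(10, -2, 5))
  seg_dist <- function(p, a, b) {
    ab <- b - a
    tt <- max(0, min(1, sum((p - a) * ab) / sum(ab^2)))
    sqrt(sum((a + tt * ab - p)^2))
  }
  verts <- tri$vertices
  brute <- vapply(seq_len(nrow(pts)), function(i) {
    min(vapply(seq_len(nrow(verts)), function(j) {
      k <- if (j == nrow(verts)) 1L else j + 1L
      seg_dist(pts[i, ], verts[j, ], verts[k, ])
    }, numeric(1)))
  }, numeric(1))
  expect_equal(energy(tri, pts, squared = FALSE), sum(brute), tolerance = 1e-12)
  expect_equal(energy(tri, pts, squared = TRUE), sum(brute^2), tolerance = 1e-12)
})

test_that("Gaussian log-prior has its closed-form values", {
  pr <- prior_config(TRUE, mean = c(ax = 20, ay = 15, eps = 2),
                     sd = c(ax = 2, ay = 2, eps = 0.5))
  at_mode <- superellipse(20, 15, eps = 2)
  expect_equal(log_prior(at_mode, pr), 0)
  expect_equal(log_prior(superellipse(22, 15, eps = 2), pr), -0.5)
  expect_equal(log_prior(superellipse(24, 19, eps = 2), pr), -4)
  expect_error(log_prior(at_mode, prior_config(FALSE)), "disabled")
  expect_error(prior_config(TRUE, mean = c(ax = 1), sd = c(ax = -1)), "positive")
  expect_error(prior_config(TRUE, mean = c(zz = 1), sd = c(zz = 1)), "unknown")
})

test_that("noiseless points are recovered to high overlap", {
  shapes <- list(
    superellipse(25, 18, 40, 38, r = 0.2, eps = 2.4, t = 0.15, b = 0.004),
    superellipse(20, 20, 45, 40, eps = 2.0),
    superellipse(28, 16, 38, 42, r = -0.3, eps = 1.8, t = -0.2),
    superellipse(18, 24, 42, 36, r = 0.1, eps = 3.0, b = 0.008))
  g <- slice_grid(160, 160, 0.5)
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  for (truth in shapes) {
    pts <- apply_deformations(truth, sample_parametric(truth, th))
    fit <- fit_superellipse(pts)
    expect_gte(dice2d(rasterize(truth, g), rasterize(fit$par, g)), 0.98)
    expect_lte(fit$objective, fit$initial_energy + 1e-9)
  }
})

test_that("six extreme/diagonal points of an ellipse recover the axes", {
  e <- superellipse(20, 12, 50, 45)
  th6 <- c(0, pi / 4, pi / 2, pi, 5 * pi / 4, 3 * pi / 2)
  f <- fit_superellipse(apply_deformations(e, sample_parametric(e, th6)))
  expect_lt(abs(f$par$ax - 20) / 20, 0.05)
  expect_lt(abs(f$par$ay - 12) / 12, 0.05)
})

test_that("fewer than four points is an error", {
  expect_error(fit_superellipse(cbind(c(0, 1, 2), c(0, 1, 0))), "4")
})

test_that("noisy annotations still recover the shape (mean over seeds)", {
  truth <- superellipse(25, 18, 40, 38, r = 0.2, eps = 2.4, t = 0.15, b = 0.004)
  g <- slice_grid(160, 160, 0.5)
  mt <- rasterize(truth, g)
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  base <- apply_deformations(truth, sample_parametric(truth, th))
  dices <- vapply(1:6, function(s) {
    pts <- trusfit:::with_seed(300 + s,
      base + matrix(rnorm(24, 0, 1), 12, 2))
    dice2d(mt, rasterize(fit_superellipse(pts, fit_config(seed = s))$par, g))
  }, numeric(1))
  expect_gte(mean(dices), 0.95)
})

test_that("a dominant prior pulls the shape parameters to the prior mode", {
  truth <- superellipse(25, 18, 40, 38, eps = 2.4)
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  pts <- apply_deformations(truth, sample_parametric(truth, th))
  pr <- prior_config(TRUE, mean = c(ax = 15, ay = 12, eps = 2),
                     sd = c(ax = 1, ay = 1, eps = 0.2), weight = 1e6)
  f <- fit_superellipse(pts, prior = pr)
  expect_lt(abs(f$par$ax - 15) / 15, 0.02)
  expect_lt(abs(f$par$ay - 12) / 12, 0.02)
  expect_lt(abs(f$par$eps - 2), 0.05)
})

test_that("the fit is scale-equivariant", {
  truth <- superellipse(25, 18, 40, 38, r = 0.2, eps = 2.4, t = 0.15, b = 0.004)
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  pts <- apply_deformations(truth, sample_parametric(truth, th))
  s <- 2.5
  ca <- coef(fit_superellipse(pts))
  cb <- coef(fit_superellipse(pts * s))
  for (nm in c("ax", "ay", "lx", "ly"))
    expect_equal(cb[[nm]] / ca[[nm]], s, tolerance = 0.01)
  for (nm in c("eps", "r", "t"))
    expect_equal(cb[[nm]], ca[[nm]], tolerance = 0.01)
  expect_equal(cb[["b"]] * s, ca[["b"]], tolerance = 0.01)
})

test_that("raster-boundary objective is available and consistent", {
  truth <- superellipse(22, 16, 40, 40, eps = 2.2)
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  pts <- apply_deformations(truth, sample_parametric(truth, th))
  g <- slice_grid(160, 160, 0.5)
  f <- fit_superellipse(pts, fit_config(boundary = "raster", grid = g,
                                        multistarts = 2, maxit = 400))
  expect_gte(dice2d(rasterize(truth, g), rasterize(f$par, g)), 0.97)
})

test_that("fit object methods are coherent", {
  truth <- superellipse(25, 18, 40, 38, eps = 2.4)
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  pts <- apply_deformations(truth, sample_parametric(truth, th))
  f <- fit_superellipse(pts)
  expect_named(coef(f), c("ax", "ay", "lx", "ly", "r", "eps", "t", "b"))
  expect_length(residuals(f), 12)
  expect_lt(summary(f)$rmse, 0.5)
  expect_s3_class(predict(f), "contour2d")
  expect_true(is.matrix(predict(f, type = "mask", grid = slice_grid(160, 160, 0.5))))
  sims <- simulate(f, nsim = 2, seed = 9, sd = 0.5)
  expect_length(sims, 2)
  expect_identical(sims, simulate(f, nsim = 2, seed = 9, sd = 0.5))
  expect_output(print(f), "superellipse")
})

test_that("closed B-spline contours interpolate circles and stay closed", {
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  pts <- cbind(30 + 10 * cos(th), 30 + 10 * sin(th))
  ct <- fit_bspline_contour(pts, smoothing = 0)
  rad <- sqrt(rowSums(sweep(ct$vertices, 2, c(30, 30))^2))
  expect_lt(max(abs(rad - 10)) / 10, 0.01)
  expect_true(ct$closed)
  expect_gte(nrow(ct$vertices), 200)
  expect_error(fit_bspline_contour(pts[1:5, ]), "6")
  line <- cbind(1:8, 2 * (1:8))
  expect_error(fit_bspline_contour(line), "collinear")
})

test_that("slice fitting dispatches on the per-slice model", {
  truth <- superellipse(25, 18, 40, 38, r = 0.2, eps = 2.4, t = 0.15, b = 0.004)
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  pts <- apply_deformations(truth, sample_parametric(truth, th))
  g <- slice_grid(160, 160, 0.5)
  # superellipse mode, minimum base count
  th4 <- c(0, pi / 2, pi, 3 * pi / 2)
  pts4 <- apply_deformations(truth, sample_parametric(truth, th4))
  sb <- fit_slice(annotated_slice(pts4, 10, "base", "superellipse"))
  expect_true(is.finite(sb$energy))
  # bspline mode: two-stage fit recovers the shape
  sm <- fit_slice(annotated_slice(pts, 22, "mid", "bspline"))
  expect_gte(dice2d(rasterize(truth, g), rasterize(sm$par, g)), 0.97)
  expect_s3_class(sm$contour, "contour2d")
  # minimum spline count succeeds
  th6 <- seq(0, 2 * pi, length.out = 7)[-7]
  pts6 <- apply_deformations(truth, sample_parametric(truth, th6))
  s6 <- fit_slice(annotated_slice(pts6, 22, "mid", "bspline"))
  expect_s3_class(s6$par, "superellipse")
})

test_that("annotated slices enforce the point-count protocol", {
  p5 <- cbind(1:5, c(1, 3, 4, 3, 1))
  expect_warning(annotated_slice(p5, 10, "mid"), "6 points")
  expect_silent(annotated_slice(p5, 10, "base"))
  expect_error(annotated_slice(p5[1:3, ], 10, "base"), "4 points")
  expect_error(annotated_slice(rbind(p5, p5[1, ]), 10, "base"), "duplicated")
})
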