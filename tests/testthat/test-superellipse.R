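test_that("parameter validation enforces the model invariants", {
  expect_error(superellipse(-1, 1), "positive")
  expect_error(superellipse(1, 1, eps = 0), "positive")
  expect_error(superellipse(1, 1, t = 1), "\\|t\\|")
  expect_error(superellipse(1, 10, b = 0.2), "bending")
  expect_silent(validate_superellipse <- superellipse(25, 18, t = 0.5, b = 0.05))
})

test_that("parametric form hits the known closed-form points", {
  expect_equal(sample_parametric(superellipse(2, 1, eps = 2), 0),
               cbind(x = 2, y = 0))
  expect_equal(sample_parametric(superellipse(1, 1, eps = 2), pi / 4),
               cbind(x = sqrt(2) / 2, y = sqrt(2) / 2))
  expect_equal(sample_parametric(superellipse(1, 1, eps = 1), pi / 4),
               cbind(x = 0.5, y = 0.5))
})

test_that("inside-outside function is 1 on boundary, <1 inside, >1 outside", {
  expect_equal(inside_outside(superellipse(2, 1, eps = 2.5), cbind(2, 0)), 1)
  expect_equal(inside_outside(superellipse(7, 3, eps = 1.7), cbind(0, 0)), 0)
  expect_equal(inside_outside(superellipse(1, 1, eps = 2), cbind(1, 1)), 2)
})

test_that("parametric and implicit forms are algebraically consistent", {
  set.seed(11)
  worst <- 0
  for (i in 1:200) {
    p <- random_superellipse()
    th <- runif(25, 0, 2 * pi)
    worst <- max(worst, abs(inside_outside(p, sample_parametric(p, th)) - 1))
  }
  expect_lt(worst, 1e-9)
})

test_that("deformations follow the fixed order and known closed forms", {
  # identity when all deformation parameters vanish
  p0 <- superellipse(5, 5)
  expect_equal(apply_deformations(p0, cbind(1, 2)), cbind(x = 1, y = 2))
  # quarter rotation
  pr <- superellipse(5, 5, r = pi / 2)
  expect_equal(apply_deformations(pr, cbind(1, 0)), cbind(x = 0, y = 1))
  # pure translation
  pt <- superellipse(5, 5, lx = 3, ly = -1)
  expect_equal(apply_deformations(pt, cbind(0, 0)), cbind(x = 3, y = -1))
  # tapering: x' = (t * y / ay + 1) * x
  ptt <- superellipse(5, 1, t = 0.5)
  expect_equal(apply_deformations(ptt, cbind(1, 1))[1, 1], c(x = 1.5))
  # bending displaces x by the sagitta of the arc of curvature b
  pb <- superellipse(5, 10, b = 0.04)
  got <- apply_deformations(pb, cbind(0, 5))
  expect_equal(got[1, 1], c(x = (1 - cos(0.04 * 5)) / 0.04))
  expect_equal(got[1, 2], c(y = 5))
})

test_that("inverse deformations invert the forward map exactly", {
  set.seed(7)
  for (i in 1:25) {
    p <- random_superellipse()
    pts <- cbind(runif(100, -p$ax, p$ax), runif(100, -p$ay, p$ay))
    rt <- invert_deformations(p, apply_deformations(p, pts))
    expect_lt(max(abs(rt - pts)), 1e-6)
  }
  # degenerate branches
  p0 <- superellipse(5, 5)
  expect_equal(invert_deformations(p0, cbind(1, 2)), cbind(x = 1, y = 2))
  pt <- superellipse(5, 5, lx = 3, ly = -1)
  expect_equal(invert_deformations(pt, cbind(3, -1)), cbind(x = 0, y = 0))
  # outside the invertible tapering range
  pe <- superellipse(5, 5, t = 0.9)
  expect_error(invert_deformations(pe, cbind(1, -10)), "invertible")
})

test_that("rasterization reproduces areas and stays solid", {
  g <- slice_grid(64, 64, 1)
  m <- rasterize(superellipse(10, 10, 31, 31), g)
  expect_lt(abs(sum(m) - pi * 100) / (pi * 100), 0.03)
  # zero-deformation case agrees with direct inside-outside thresholding
  p <- superellipse(14, 9, 31, 31, eps = 2.6)
  direct <- rasterize_oracle(p, g)
  expect_gte(dice2d(rasterize(p, g), direct), 0.99)
  # bent shape keeps one component and no holes
  gb <- slice_grid(128, 128, 0.5)
  mb <- rasterize(superellipse(25, 20, 32, 32, b = 0.02), gb)
  expect_equal(trusfit:::n_components(mb), 1)
  expect_equal(trusfit:::count_holes(mb), 0)
  expect_error(rasterize(superellipse(10, 10, 500, 500), g), "outside")
})

test_that("forward rasterizer matches the inverse-map oracle on random shapes", {
  set.seed(23)
  g <- slice_grid(128, 128, spacing = 0.5)
  for (i in 1:10) {
    p <- random_superellipse(center = c(32, 32), size = c(12, 28))
    expect_gte(dice2d(rasterize(p, g), rasterize_oracle(p, g)), 0.99)
  }
})

test_that("mask area is nondecreasing in the semi-axes", {
  g <- slice_grid(128, 128, spacing = 0.5)
  base <- list(lx = 32, ly = 32, r = 0.3, eps = 2.2, t = 0.2, b = 0.008)
  areas_ax <- vapply(c(10, 14, 18, 22, 26), function(ax)
    sum(rasterize(do.call(superellipse, c(list(ax = ax, ay = 15), base)), g)),
    numeric(1))
  areas_ay <- vapply(c(10, 14, 18, 22, 26), function(ay)
    sum(rasterize(do.call(superellipse, c(list(ax = 15, ay = ay), base)), g)),
    numeric(1))
  expect_true(all(diff(areas_ax) >= 0))
  expect_true(all(diff(areas_ay) >= 0))
})

test_that("contour tracing follows pixel borders in mm", {
  # 3x3 all-ones at unit spacing: 12 mm perimeter, 9 mm^2 area
  ct <- contour_of(matrix(1L, 3, 3), slice_grid(3, 3, 1))
  expect_equal(contour_perimeter(ct), 12)
  expect_equal(contour_area(ct), 9)
  # single pixel: unit square
  c1 <- contour_of(matrix(1L, 1, 1), slice_grid(1, 1, 1))
  expect_equal(nrow(c1$vertices), 4)
  expect_equal(contour_area(c1), 1)
  # rasterized circle: area within 3% of pi r^2
  g <- slice_grid(64, 64, 1)
  cc <- contour_of(rasterize(superellipse(10, 10, 31, 31), g), g)
  expect_lt(abs(contour_area(cc) - pi * 100) / (pi * 100), 0.03)
  # anisotropic spacing respected
  ca <- contour_of(matrix(1L, 2, 3), slice_grid(2, 3, spacing = c(2, 0.5)))
  expect_equal(contour_area(ca), 2 * 2 * 3 * 0.5)
  expect_error(contour_of(matrix(0L, 4, 4)), "empty")
  two <- matrix(0L, 5, 5); two[1, 1] <- 1L; two[5, 5] <- 1L
  expect_error(contour_of(two), "one connected component")
})

test_that("contours are closed, CCW and orientation-normalized", {
  sq <- contour2d(rbind(c(0, 0), c(0, 1), c(1, 1), c(1, 0)))  # given CW
  expect_gt(trusfit:::shoelace_area(sq$vertices), 0)
  expect_true(sq$closed)
  expect_error(contour2d(rbind(c(0, 0), c(1, 1))), "3 distinct")
})
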