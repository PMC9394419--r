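# unit tests run the registration pipeline at a 0.6 mm working grid to
# keep them quick; the acceptance suite exercises the 0.3 mm default

test_that("VOI cropping keeps the margin and the foreground", {
  arr <- array(0L, c(41, 41, 41)); arr[21, 21, 21] <- 1L
  m <- binary_mask3d(arr)
  cv <- crop_voi(m, 10)
  expect_equal(dim(cv$data), c(21, 21, 21))
  expect_equal(sum(cv$data), 1)
  expect_equal(cv$origin, c(10, 10, 10))
  # clipping at the border invents no padding
  arr2 <- array(0L, c(21, 21, 21)); arr2[1, 11, 11] <- 1L
  cv2 <- crop_voi(binary_mask3d(arr2), 10)
  expect_equal(dim(cv2$data)[1], 11)
  expect_equal(sum(cv2$data), 1)
  expect_error(crop_voi(binary_mask3d(array(0L, c(4, 4, 4)))), "empty")
})

test_that("isotropic resampling preserves extent and binariness", {
  v <- image3d(array(1, c(10, 10, 10)))
  rv <- resample_isotropic(v, 0.3)
  expect_equal(dim(rv$data), c(33, 33, 33))
  expect_true(all(rv$data == 1))
  set.seed(8)
  m <- random_blob3d(c(10, 10, 10))
  rm_ <- resample_isotropic(m, 0.3, "nearest")
  expect_true(all(rm_$data %in% 0:1))
  expect_s3_class(rm_, "mask3d")
  # anisotropic input: per-axis dimension arithmetic
  va <- image3d(array(0, c(10, 12, 5)), spacing = c(0.5, 1, 2))
  ra <- resample_isotropic(va, 0.5)
  expect_equal(dim(ra$data), c(10, 24, 20))
  expect_error(resample_isotropic(v, -1), "positive")
})

test_that("Gaussian smoothing is normalized, symmetric and mass-preserving", {
  ones <- binary_mask3d(array(1L, c(9, 9, 9)))
  expect_equal(max(abs(gaussian_smooth(ones, 2)$data - 1)), 0, tolerance = 1e-9)
  arr <- array(0L, c(21, 21, 21)); arr[9:13, 9:13, 9:13] <- 1L
  sm <- gaussian_smooth(binary_mask3d(arr), 2)
  expect_equal(sum(sm$data), sum(arr), tolerance = sum(arr) * 1e-3)
  expect_equal(sm$data, sm$data[21:1, , ], tolerance = 1e-12)
  expect_true(all(sm$data >= 0 & sm$data <= 1))
  expect_error(gaussian_smooth(ones, 0), "positive")
})

test_that("signed distance maps match boundary geometry and brute force", {
  cube <- array(0L, c(13, 13, 13)); cube[3:11, 3:11, 3:11] <- 1L
  sdc <- signed_distance_map(binary_mask3d(cube))
  expect_equal(sdc$data[7, 7, 7], -4)           # deep interior of a 9^3 cube
  expect_equal(sdc$data[3, 7, 7], 0)            # boundary voxel
  expect_equal(sdc$data[2, 7, 7], 1)            # just outside
  expect_error(signed_distance_map(binary_mask3d(array(1L, c(4, 4, 4)))),
               "foreground and background")
  set.seed(13)
  for (i in 1:5) {
    m <- random_blob3d(c(16, 16, 16), c(1, 1.5, 0.8))
    sd1 <- signed_distance_map(m)
    bnd <- which(trusfit:::boundary_voxels(m$data == 1), arr.ind = TRUE)
    bmm <- sweep(bnd - 1, 2, m$spacing, "*")
    idx <- which(array(TRUE, dim(m$data)), arr.ind = TRUE)
    imm <- sweep(idx - 1, 2, m$spacing, "*")
    bf <- apply(imm, 1, function(p) sqrt(min(colSums((t(bmm) - p)^2))))
    bf <- array(bf, dim(m$data))
    bf[m$data == 1] <- -bf[m$data == 1]
    expect_lt(max(abs(sd1$data - bf)), 1e-6)
  }
})

test_that("center initialization is pure physical-space arithmetic", {
  f <- image3d(array(0, c(11, 11, 11)))
  m <- image3d(array(0, c(11, 11, 11)), origin = c(5, 0, 0))
  T <- init_center(f, m)
  expect_equal(T$matrix, diag(3))
  expect_equal(T$translation, c(5, 0, 0))
  expect_equal(init_center(f, f)$translation, c(0, 0, 0))
  # doubling the spacing doubles the center coordinates
  m2 <- image3d(array(0, c(11, 11, 11)), spacing = c(2, 2, 2))
  expect_equal(trusfit:::volume_center(m2), 2 * trusfit:::volume_center(f))
  expect_equal(init_center(f, m2)$translation, trusfit:::volume_center(f))
})

test_that("landmark initialization solves the orthogonal Procrustes problem", {
  set.seed(5)
  F <- matrix(runif(12, 0, 50), 4, 3)
  expect_equal(init_landmarks(F, F)$matrix, diag(3))
  M <- F + matrix(c(2, 0, 0), 4, 3, byrow = TRUE)
  Tt <- init_landmarks(F, M)
  expect_equal(Tt$matrix, diag(3), tolerance = 1e-9)
  expect_equal(Tt$translation, c(2, 0, 0))
  ang <- 20 * pi / 180
  R <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1), 3, 3)
  Mr <- F %*% t(R) + matrix(c(3, -2, 1), 4, 3, byrow = TRUE)
  Tr <- init_landmarks(F, Mr)
  expect_lt(max(abs(transform_points(Tr, F) - Mr)), 1e-6)
  expect_error(init_landmarks(F[1:2, ], M[1:2, ]), "3")
  coll <- cbind(1:4, 2 * (1:4), 3 * (1:4))
  expect_error(init_landmarks(coll, coll), "collinear")
})

test_that("full-grid SSD matches the naive sum", {
  set.seed(21)
  a <- image3d(array(runif(5 * 5 * 5), c(5, 5, 5)))
  b <- image3d(array(runif(5 * 5 * 5), c(5, 5, 5)))
  expect_equal(ssd(a, a), 0)
  cshift <- image3d(a$data + 0.3)
  expect_equal(ssd(a, cshift), 125 * 0.09, tolerance = 1e-9)
  naive <- 0
  for (i in 1:5) for (j in 1:5) for (k in 1:5)
    naive <- naive + (a$data[i, j, k] - b$data[i, j, k])^2
  expect_equal(ssd(a, b), naive, tolerance = 1e-12)
  expect_error(ssd(a, image3d(array(0, c(4, 5, 5)))), "grid")
})

test_that("affine transforms compose, invert and resample masks exactly", {
  T <- affine3d(matrix(c(1, 0.1, 0, 0, 1, 0, 0, 0, 0.95), 3, 3, byrow = TRUE),
                translation = c(1, -2, 3), center = c(5, 5, 5))
  Ti <- affine_inverse(T)
  pts <- matrix(runif(30, 0, 10), 10, 3)
  expect_lt(max(abs(transform_points(Ti, transform_points(T, pts)) - pts)), 1e-9)
  C <- affine_compose(T, Ti)
  expect_lt(max(abs(as_matrix4(C) - diag(4))), 1e-9)
  expect_error(affine3d(matrix(0, 3, 3)), "singular")
  # identity transform leaves a mask untouched
  m <- random_blob3d(c(10, 10, 10))
  expect_identical(apply_transform(m, affine3d())$data, m$data)
  # pure integer-voxel translation is an exact shift
  shift <- affine3d(translation = c(2, 0, 0))
  sh <- apply_transform(m, shift, m)
  expect_identical(sh$data[1:8, , ], m$data[3:10, , ])
  # round trip through an invertible transform loses little
  spec <- small_phantom_spec()
  ph <- generate_phantom(spec)
  Tp <- random_perturbation(seed = 3, max_rot_deg = 5, max_trans_mm = 3,
                            center = trusfit:::volume_center(ph$mask))
  fine <- resample_isotropic(ph$mask, 1, "nearest")
  fwd <- apply_transform(fine, Tp, fine)
  back <- apply_transform(fwd, affine_inverse(Tp), fine)
  expect_gte(dsc(back, fine), 0.98)
})

test_that("registration recovers synthetic rigid + scale perturbations", {
  spec <- small_phantom_spec()
  ph <- generate_phantom(spec)
  ctr <- trusfit:::volume_center(ph$mask)
  pert <- random_perturbation(seed = 11, max_rot_deg = 10, max_trans_mm = 8,
                              scale_range = c(0.9, 1.1), center = ctr)
  pair <- make_registration_pair(ph$mask, pert)
  reg <- register_masks(pair$fixed, pair$moving, init = "center", res_mm = 0.6)
  expect_lte(reg$metric_final, reg$metric_initial)
  expect_true(all(diff(reg$trace) <= 0))
  fx <- resample_isotropic(crop_voi(pair$fixed, 10), 0.6, "nearest")
  mv <- resample_isotropic(crop_voi(pair$moving, 10), 0.6, "nearest")
  expect_gte(dsc(apply_transform(mv, reg$transform, fx), fx), 0.98)
  comp <- as_matrix4(affine_compose(reg$transform,
                                    affine_inverse(pair$true_transform)))
  resid <- sqrt(sum((comp[1:3, 1:3] %*% ctr + comp[1:3, 4] - ctr)^2))
  expect_lte(resid, 0.5)
  # anisotropic scale is recovered within 2%
  sv <- svd(as_matrix4(reg$transform)[1:3, 1:3] %*%
              solve(as_matrix4(pair$true_transform)[1:3, 1:3]))$d
  expect_lt(max(abs(sv - 1)), 0.02)
})

test_that("self-registration is a fixed point", {
  spec <- small_phantom_spec()
  ph <- generate_phantom(spec)
  reg <- register_masks(ph$mask, ph$mask, res_mm = 0.6)
  fx <- resample_isotropic(crop_voi(ph$mask, 10), 0.6, "nearest")
  expect_gte(dsc(apply_transform(fx, reg$transform, fx), fx), 0.999)
})

test_that("center- and landmark-initialized runs agree on easy pairs", {
  spec <- small_phantom_spec()
  ph <- generate_phantom(spec)
  ctr <- trusfit:::volume_center(ph$mask)
  pert <- random_perturbation(seed = 4, max_rot_deg = 5, max_trans_mm = 4,
                              scale_range = c(1, 1), center = ctr)
  pair <- make_registration_pair(ph$mask, pert)
  lm <- rbind(ctr + c(0, 5, 18), ctr + c(2, -6, 0), ctr + c(-1, 4, -17))
  fx <- resample_isotropic(crop_voi(pair$fixed, 10), 0.6, "nearest")
  mv <- resample_isotropic(crop_voi(pair$moving, 10), 0.6, "nearest")
  d <- vapply(c("center", "landmarks"), function(ini) {
    reg <- register_masks(pair$fixed, pair$moving, init = ini,
                          fixed_landmarks = lm,
                          moving_landmarks = transform_points(pair$true_transform, lm),
                          res_mm = 0.6)
    dsc(apply_transform(mv, reg$transform, fx), fx)
  }, numeric(1))
  expect_lt(abs(d["center"] - d["landmarks"]), 0.5)
  expect_error(register_masks(pair$fixed, pair$moving, init = "landmarks"),
               "landmark")
})

test_that("recovered translation is insensitive to working resolution", {
  spec <- small_phantom_spec()
  ph <- generate_phantom(spec)
  ctr <- trusfit:::volume_center(ph$mask)
  pert <- random_perturbation(seed = 6, max_rot_deg = 4, max_trans_mm = 5,
                              scale_range = c(1, 1), center = ctr)
  pair <- make_registration_pair(ph$mask, pert)
  tr_of <- function(res) {
    reg <- register_masks(pair$fixed, pair$moving, res_mm = res)
    comp <- as_matrix4(affine_compose(reg$transform,
                                      affine_inverse(pair$true_transform)))
    comp[1:3, 1:3] %*% ctr + comp[1:3, 4] - ctr
  }
  expect_lt(sqrt(sum((tr_of(0.6) - tr_of(1.2))^2)), 1.2)  # < 1 coarse voxel
})
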