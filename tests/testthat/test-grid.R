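test_that("warping with a zero field is the identity in both modes", {
  set.seed(1)
  vi <- volume_image(array(rnorm(6^3), c(6, 6, 6)), c(1.5, 1.5, 1.5))
  z <- displacement_field(array(0, c(6, 6, 6, 3)), c(1.5, 1.5, 1.5))
  expect_identical(warp_image(vi, z, "linear")$data, vi$data)
  expect_identical(warp_image(vi, z, "nearest")$data, vi$data)
})

test_that("a one-voxel displacement shifts the volume by exactly one voxel", {
  set.seed(2)
  vi <- volume_image(array(rnorm(8^3), c(8, 8, 8)), c(1.5, 1.5, 1.5))
  u <- array(0, c(8, 8, 8, 3))
  u[, , , 1] <- 1.5                       # +1.5 mm = one voxel along x
  w <- warp_image(vi, displacement_field(u, c(1.5, 1.5, 1.5)))
  expect_equal(w$data[1:7, , ], vi$data[2:8, , ])
  # mask variant preserves volume under the integer shift (interior mask)
  m <- cube_mask(c(8, 8, 8), c(3, 3, 3), c(6, 6, 6))
  wm <- warp_mask(m, displacement_field(u, c(1.5, 1.5, 1.5)))
  expect_equal(sum(wm), sum(m))
  expect_equal(wm[2:5, 3:6, 3:6], m[3:6, 3:6, 3:6])
})

test_that("warp matches a brute-force trilinear oracle on a random smooth field", {
  set.seed(3)
  vi <- volume_image(array(rnorm(8^3), c(8, 8, 8)), c(2, 2, 2))
  ddf <- random_bspline_ddf(vi, 4, 3, seed = 11)
  u_vox <- ddf$vectors / 2
  oracle <- brute_trilinear_warp(vi$data, u_vox)
  expect_lt(max(abs(warp_image(vi, ddf)$data - oracle)), 1e-6)
  expect_lt(max(abs(spatial_transform(vi, ddf)$data - oracle)), 1e-6)
})

test_that("the warp is linear in the image argument", {
  set.seed(4)
  a <- volume_image(array(rnorm(6^3), c(6, 6, 6)), c(2, 2, 2))
  b <- volume_image(array(rnorm(6^3), c(6, 6, 6)), c(2, 2, 2))
  ddf <- random_bspline_ddf(a, 4, 4, seed = 5)
  alpha <- 0.3
  blend <- volume_image(alpha * a$data + (1 - alpha) * b$data, c(2, 2, 2))
  expect_equal(warp_image(blend, ddf)$data,
               alpha * warp_image(a, ddf)$data +
                 (1 - alpha) * warp_image(b, ddf)$data,
               tolerance = 1e-12)
})

test_that("an expanding field grows a warped mask", {
  # backward warp with inward-pointing sample offsets dilates the object
  d <- c(12, 12, 12)
  m <- cube_mask(d, c(5, 5, 5), c(8, 8, 8))
  co <- (0:11) * 1.5
  cen <- co[7]
  u <- array(0, c(d, 3))
  u[, , , 1] <- outer(co - cen, rep(1, 144)) * -0.3
  u[, , , 2] <- array(rep(rep(co - cen, each = 12), 12), d) * -0.3
  u[, , , 3] <- array(rep(co - cen, each = 144), d) * -0.3
  wm <- warp_mask(m, displacement_field(u, c(1.5, 1.5, 1.5)))
  expect_gt(sum(wm), sum(m))
})

test_that("warping by a field and its numerical inverse approximately round-trips", {
  set.seed(6)
  co <- (0:11) * 2
  smooth_img <- outer(sin(co / 5), cos(co / 7)) %o% sin(co / 4 + 1)
  vi <- volume_image(smooth_img, c(2, 2, 2))
  ddf <- random_bspline_ddf(vi, 4, 2, seed = 7)
  # fixed-point inversion of the backward field
  inv <- ddf
  for (it in 1:20) {
    w <- warp_image(volume_image(ddf$vectors[, , , 1], vi$spacing), inv)$data
    w2 <- warp_image(volume_image(ddf$vectors[, , , 2], vi$spacing), inv)$data
    w3 <- warp_image(volume_image(ddf$vectors[, , , 3], vi$spacing), inv)$data
    inv$vectors <- -array(c(w, w2, w3), c(12, 12, 12, 3))
  }
  once <- warp_image(vi, ddf)
  back <- warp_image(once, inv)
  interior <- back$data[3:10, 3:10, 3:10] - vi$data[3:10, 3:10, 3:10]
  expect_lt(mean(abs(interior)), 0.05 * stats::sd(vi$data))
})

test_that("slice resampling follows the stated interpolation recipe", {
  # z-linear ramp: 3.0 mm -> 1.5 mm interpolates the analytic ramp
  d <- c(4, 4, 10)
  ramp <- array(rep(seq(0, 27, by = 3), each = 16), d)
  vi <- volume_image(ramp, c(1.5, 1.5, 3))
  out <- resample_slices(vi, 1.5, "linear")
  expect_equal(dim(out$data)[3], 19)
  expect_equal(out$data[1, 1, ], seq(0, 27, by = 1.5), tolerance = 1e-12)
  # identity at current spacing
  same <- resample_slices(vi, 3, "linear")
  expect_equal(same$data, vi$data, tolerance = 1e-12)
  # nearest mode keeps masks binary
  m <- (ramp > 13) * 1
  outm <- resample_slices(volume_image(m, c(1.5, 1.5, 3)), 1.5, "nearest")
  expect_true(all(outm$data %in% c(0, 1)))
})

test_that("centroid cropping uses round-half-up and border padding", {
  d <- c(20, 20, 20)
  img <- volume_image(array(seq_len(prod(d)), d), c(1.5, 1.5, 1.5))
  ctv <- array(0, d); ctv[10, 10, 10] <- 1
  ss <- structure_set(list(ctv = ctv), c(1.5, 1.5, 1.5))
  cr <- crop_around_centroid(img, ss, "ctv", c(8, 8, 8))
  expect_equal(cr$image$data, img$data[6:13, 6:13, 6:13])
  expect_equal(cr$structures$masks$ctv[5, 5, 5], 1)
  # full-size crop of a centred anchor is the identity
  ctv2 <- array(0, d); ctv2[10:11, 10:11, 10:11] <- 1
  ss2 <- structure_set(list(ctv = ctv2), c(1.5, 1.5, 1.5))
  cr2 <- crop_around_centroid(img, ss2, "ctv", c(20, 20, 20))
  expect_equal(cr2$image$data, img$data)
  # window beyond the border still has the requested shape
  ctv3 <- array(0, d); ctv3[2, 2, 2] <- 1
  ss3 <- structure_set(list(ctv = ctv3), c(1.5, 1.5, 1.5))
  cr3 <- crop_around_centroid(img, ss3, "ctv", c(12, 12, 12))
  expect_equal(dim(cr3$image$data), c(12L, 12L, 12L))
  # empty anchor is refused
  ss4 <- structure_set(list(ctv = array(0, d)), c(1.5, 1.5, 1.5))
  expect_error(crop_around_centroid(img, ss4, "ctv", c(8, 8, 8)), "empty")
})

test_that("random smooth fields respect the amplitude bound and the seed", {
  vi <- volume_image(array(0, c(16, 16, 16)), c(1.5, 1.5, 1.5))
  z <- random_bspline_ddf(vi, 10, 0, seed = 1)
  expect_true(all(z$vectors == 0))
  for (s in 1:3) {
    f <- random_bspline_ddf(vi, 10, 35, seed = s)
    expect_lte(max(abs(f$vectors)), 35)
  }
  f1 <- random_bspline_ddf(vi, 6, 10, seed = 42)
  f2 <- random_bspline_ddf(vi, 6, 10, seed = 42)
  expect_identical(f1$vectors, f2$vectors)
})

test_that("fewer control points give smoother fields (lower bending energy)", {
  vi <- volume_image(array(0, c(16, 16, 16)), c(1.5, 1.5, 1.5))
  be <- function(nc) {
    mean(vapply(1:6, function(s) {
      bending_energy(random_bspline_ddf(vi, nc, 10, seed = s))
    }, 0))
  }
  e <- c(be(4), be(6), be(9))
  expect_true(all(diff(e) > 0))
})
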