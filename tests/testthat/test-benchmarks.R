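test_that("rigid copying transfers masks unchanged on a shared grid", {
  cs <- make_planning_case(anatomy24(seed = 15))
  fc <- sample_fraction_case(cs, variation_params(seed = 4), 1)
  fr <- fc$fractions[[1]]
  copied <- rigid_copy(cs$planning$structures, fr$image)
  expect_identical(copied$masks, cs$planning$structures$masks)
  # identical anatomy gives DSC 1 for every structure
  idf <- sample_fraction_case(cs, variation_params(c(1, 1), c(1, 1), 0, 0), 1)
  for (s in names(copied$masks)) {
    expect_equal(as.numeric(dsc(copied$masks[[s]],
                                idf$fractions[[1]]$structures$masks[[s]])), 1)
  }
  other <- volume_image(array(0, c(16, 16, 16)), c(4, 4, 4))
  expect_error(rigid_copy(cs$planning$structures, other), "grid")
})

test_that("volume change bounds the copied-contour overlap analytically", {
  cs <- make_planning_case(anatomy24(seed = 16))
  fc <- sample_fraction_case(cs, variation_params(c(2, 2), c(1, 1), 0, 0), 1)
  got <- dsc(cs$planning$structures$masks$bladder,
             fc$fractions[[1]]$structures$masks$bladder)
  # concentric ellipsoids with volume ratio 2: DSC = 2*V/(V+2V) = 2/3
  expect_equal(as.numeric(got), 2 / 3, tolerance = 0.05)
  expect_lt(as.numeric(got), 1)
})

test_that("registration recovers a known smooth field on a small phantom", {
  base <- anatomy_params(grid_shape = c(20, 20, 20), spacing_mm = c(4.8, 4.8, 4.8),
                         texture_amplitude = 10, noise_sd = 1)
  cs <- make_planning_case(base)
  gt <- random_bspline_ddf(cs$planning$image, 4, 5, seed = 21)
  fixed <- spatial_transform(cs$planning$image, gt)
  stages <- default_bspline_stages(c(15, 15, 20))
  rec <- bspline_register(fixed, cs$planning$image, stages)
  epe <- mean(sqrt(apply((rec$vectors - gt$vectors)^2, 1:3, sum)))
  epe0 <- mean(sqrt(apply(gt$vectors^2, 1:3, sum)))
  expect_lt(epe, 0.5 * epe0)
  # objective is non-increasing within each stage (monotone line search)
  diag <- attr(rec, "diagnostics")
  for (st in diag) expect_lte(st$final, st$objective[1] + 1e-12)
})

test_that("registering an image to itself yields a near-zero field", {
  base <- anatomy_params(grid_shape = c(16, 16, 16), spacing_mm = c(6, 6, 6),
                         rectum_z_extent = c(20, 70), texture_amplitude = 10)
  cs <- make_planning_case(base)
  rec <- bspline_register(cs$planning$image, cs$planning$image,
                          default_bspline_stages(c(8, 8, 8)))
  expect_lt(mean(abs(rec$vectors)) / 6, 0.1)   # < 0.1 voxel on average
  # determinism: same inputs, same field
  rec2 <- bspline_register(cs$planning$image, cs$planning$image,
                           default_bspline_stages(c(8, 8, 8)))
  expect_identical(rec$vectors, rec2$vectors)
})

test_that("deformable propagation beats rigid copying on smooth small deformations", {
  base <- anatomy_params(grid_shape = c(20, 20, 20), spacing_mm = c(4.8, 4.8, 4.8),
                         texture_amplitude = 10, noise_sd = 1)
  wins <- 0; total <- 0
  for (s in 1:3) {
    cs <- make_planning_case(local({ p <- base; p$seed <- s; p }))
    gt <- random_bspline_ddf(cs$planning$image, 4, 6, seed = 30 + s)
    fixed <- spatial_transform(cs$planning$image, gt)
    truth <- lapply(cs$planning$structures$masks, function(m) {
      (spatial_transform(m * 1, gt) >= 0.5) * 1
    })
    rec <- bspline_register(fixed, cs$planning$image,
                            default_bspline_stages(c(12, 12, 15)))
    prop <- propagate_contours(cs$planning$structures, rec)
    for (nm in c("bladder", "ctv")) {
      total <- total + 1
      d_def <- dsc(prop$masks[[nm]], truth[[nm]])
      d_rig <- dsc(cs$planning$structures$masks[[nm]], truth[[nm]])
      if (d_def >= d_rig) wins <- wins + 1
    }
  }
  expect_gte(wins / total, 0.8)
})

test_that("contour propagation honours the zero field and the rigid-CTV flag", {
  d <- c(10, 10, 10)
  ss <- structure_set(list(bladder = cube_mask(d, c(2, 2, 2), c(4, 4, 4)),
                           ctv = cube_mask(d, c(6, 6, 6), c(8, 8, 8))),
                      c(2, 2, 2))
  z <- displacement_field(array(0, c(d, 3)), c(2, 2, 2))
  expect_identical(propagate_contours(ss, z)$masks, ss$masks)
  u <- array(0, c(d, 3)); u[, , , 1] <- 2
  sh <- displacement_field(u, c(2, 2, 2))
  pr <- propagate_contours(ss, sh, ctv_rigid = TRUE)
  expect_identical(pr$masks$ctv, ss$masks$ctv)          # flag: exact copy
  expect_false(identical(pr$masks$bladder, ss$masks$bladder))
})

test_that("stage configuration is validated", {
  expect_error(bspline_stage(-1), "positive")
  expect_error(bspline_stage(8, 0), "iterations")
  expect_warning(
    bspline_register(
      volume_image(array(rnorm(8^3), c(8, 8, 8)), c(2, 2, 2)),
      volume_image(array(rnorm(8^3), c(8, 8, 8)), c(2, 2, 2)),
      list(bspline_stage(4, 2), bspline_stage(8, 2))),
    "coarse-to-fine")
})
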