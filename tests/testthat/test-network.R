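test_that("forward pass honours shape contracts and deterministic initialization", {
  spec <- network_spec(n_levels = 2, base_channels = 2, head = "segmentation")
  m1 <- build_network(spec, seed = 4)
  m2 <- build_network(spec, seed = 4)
  expect_identical(m1$params, m2$params)
  img <- volume_image(array(rnorm(16^3), c(16, 16, 16)), c(1.5, 1.5, 1.5))
  p <- predict_segmentation(m1, img)
  expect_equal(dim(p$data), c(16L, 16L, 16L))
  expect_true(all(p$data >= 0 & p$data <= 1))
  # indivisible input shape is refused
  bad <- volume_image(array(0, c(15, 15, 15)), c(1.5, 1.5, 1.5))
  expect_error(predict_segmentation(m1, bad), "divisible")
  # wrong head is a usage error
  dspec <- network_spec(2, 2, "displacement")
  dm <- build_network(dspec, seed = 1)
  expect_error(predict_segmentation(dm, img), "segmentation head")
  expect_error(predict_ddf(m1, img, img), "displacement head")
})

test_that("a zero-weight head yields probability 0.5 and a zero field", {
  spec <- network_spec(2, 2, "segmentation")
  m <- build_network(spec, seed = 2)
  m$params$head$w[] <- 0
  m$params$head$b[] <- 0
  img <- volume_image(array(rnorm(8^3), c(8, 8, 8)), c(1.5, 1.5, 1.5))
  expect_true(all(predict_segmentation(m, img)$data == 0.5))
  dspec <- network_spec(2, 2, "displacement")
  dmod <- build_network(dspec, seed = 2)
  dmod$params$head$w[] <- 0
  dmod$params$head$b[] <- 0
  ddf <- predict_ddf(dmod, img, img)
  expect_equal(dim(ddf$vectors), c(8L, 8L, 8L, 3L))
  expect_true(all(ddf$vectors == 0))
  # zero field -> warped planning contours equal rigidly copied contours
  ss <- structure_set(list(ctv = cube_mask(c(8, 8, 8), c(3, 3, 3), c(5, 5, 5))),
                      c(1.5, 1.5, 1.5))
  prop <- propagate_contours(ss, ddf)
  expect_identical(prop$masks$ctv, rigid_copy(ss, img)$masks$ctv)
})

test_that("parameter count scales quadratically with width", {
  n1 <- n_params(build_network(network_spec(3, 2, "segmentation"), 1))
  n2 <- n_params(build_network(network_spec(3, 4, "segmentation"), 1))
  expect_gt(n2 / n1, 3)     # conv weights dominate and scale ~4x
  expect_lt(n2 / n1, 4)     # biases/norms scale linearly, keeping it below 4x
})

test_that("inference is deterministic", {
  spec <- network_spec(2, 2, "segmentation")
  m <- build_network(spec, seed = 9)
  img <- volume_image(array(rnorm(8^3), c(8, 8, 8)), c(1.5, 1.5, 1.5))
  expect_identical(predict_segmentation(m, img)$data,
                   predict_segmentation(m, img)$data)
})

test_that("spatial transformer agrees with the reference warp and is differentiable", {
  set.seed(30)
  vi <- volume_image(array(rnorm(8^3), c(8, 8, 8)), c(2, 2, 2))
  z <- displacement_field(array(0, c(8, 8, 8, 3)), c(2, 2, 2))
  expect_equal(spatial_transform(vi, z)$data, vi$data)
  for (s in 1:3) {
    ddf <- random_bspline_ddf(vi, 4, 4, seed = s)
    expect_lt(max(abs(spatial_transform(vi, ddf)$data -
                        warp_image(vi, ddf)$data)), 1e-5)
  }
  # finite-difference gradient check on a 6^3 toy volume
  mv <- array(rnorm(6^3), c(6, 6, 6))
  dv <- array(rnorm(6^3 * 3, 0, 0.4), c(6, 6, 6, 3))
  ddf <- displacement_field(dv, c(1, 1, 1))
  gout <- array(rnorm(6^3), c(6, 6, 6))
  ga <- contourprop:::spatial_transform_grad_ddf(mv, ddf, gout)
  obj <- function(v) sum(gout * spatial_transform(mv, displacement_field(v, c(1, 1, 1))))
  for (r in 1:6) {
    i <- c(sample(2:5, 3, replace = TRUE), sample(1:3, 1))
    vp <- dv; vp[i[1], i[2], i[3], i[4]] <- vp[i[1], i[2], i[3], i[4]] + 1e-4
    vm <- dv; vm[i[1], i[2], i[3], i[4]] <- vm[i[1], i[2], i[3], i[4]] - 1e-4
    fd <- (obj(vp) - obj(vm)) / 2e-4
    expect_equal(ga[i[1], i[2], i[3], i[4]], fd, tolerance = 1e-3)
  }
})

test_that("the full backward pass matches finite differences", {
  set.seed(31)
  spec <- network_spec(2, 2, "segmentation")
  m <- build_network(spec, seed = 3)
  x <- array(rnorm(8^3), c(8, 8, 8, 1))
  tgt <- (array(rnorm(8^3), c(8, 8, 8)) > 0.5) * 1
  lossfn <- function(model) {
    out <- contourprop:::unet_forward(model, x)$out
    p <- contourprop:::sigmoid(out[, , , 1])
    soft_dice_loss(p, tgt)
  }
  fw <- contourprop:::unet_forward(m, x, want_cache = TRUE)
  p <- contourprop:::sigmoid(fw$out[, , , 1])
  gp <- contourprop:::soft_dice_grad(p, tgt)
  gout <- array(gp * p * (1 - p), dim(fw$out))
  G <- contourprop:::unet_backward(m, fw$cache, gout)
  th <- contourprop:::tree_flatten(m$params)
  gf <- contourprop:::tree_flatten(G)
  idx <- sample(length(th), 8)
  for (i in idx) {
    thp <- th; thp[i] <- thp[i] + 1e-5
    thm <- th; thm[i] <- thm[i] - 1e-5
    mp <- m; mp$params <- contourprop:::tree_unflatten(thp, m$params)
    mm <- m; mm$params <- contourprop:::tree_unflatten(thm, m$params)
    fd <- (lossfn(mp) - lossfn(mm)) / 2e-5
    expect_equal(gf[i], fd, tolerance = 1e-4)
  }
})

test_that("identical inputs give a smaller predicted field than deformed pairs", {
  set.seed(32)
  base <- anatomy16(texture_amplitude = 15, noise_sd = 2)
  cs <- make_planning_case(base)
  # mixed training set (deformed and identity pairs) forces the prediction
  # to depend on the input pair rather than on a memorized mean field
  zero <- displacement_field(array(0, c(16, 16, 16, 3)), c(6, 6, 6))
  pairs <- c(
    lapply(1:10, function(j) list(
      planning = cs$planning$image,
      planning_masks = cs$planning$structures$masks,
      gt_ddf = random_bspline_ddf(cs$planning$image, 4, 10, seed = 200 + j))),
    lapply(1:2, function(j) list(
      planning = cs$planning$image,
      planning_masks = cs$planning$structures$masks, gt_ddf = zero)))
  cfg <- training_config("DDFM", spec = network_spec(3, 4, "displacement"),
                         epochs = 40, learning_rate = 5e-3,
                         ddfm_data_variant = "gt_realistic_ddf",
                         weights = loss_weights(1, 1, 0, 0, 0), seed = 6)
  dm <- train_ddfm(pairs, cfg)
  gt <- random_bspline_ddf(cs$planning$image, 4, 10, seed = 999)
  fr <- spatial_transform(cs$planning$image, gt)
  u_same <- predict_ddf(dm, cs$planning$image, cs$planning$image)
  u_def <- predict_ddf(dm, cs$planning$image, fr)
  expect_lt(mean(abs(u_same$vectors)), mean(abs(u_def$vectors)))
})
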