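test_that("the progressive schedule splits epochs evenly with the remainder last", {
  s <- progressive_schedule(5, 200)
  expect_equal(s$factor, c(16, 8, 4, 2, 1))
  expect_equal(s$epochs, rep(40, 5))
  expect_equal(s$end, c(40, 80, 120, 160, 200))
  s2 <- progressive_schedule(2, 3)
  expect_equal(s2$epochs, c(1, 2))
  expect_true(all(diff(s2$factor) < 0))
  expect_equal(s2$factor[2], 1)
  expect_error(progressive_schedule(5, 4), "total_epochs")
})

test_that("augmentation with zero amplitudes is the identity and is seeded", {
  cs <- make_planning_case(anatomy24(seed = 12))
  part <- list(image = cs$planning$image, structures = cs$planning$structures)
  id <- augment_case(part, augment_params(0, 0, 0, 0, 0, 0), seed = 1)
  expect_equal(id$image$data, part$image$data, tolerance = 1e-12)
  expect_identical(id$structures$masks, part$structures$masks)
  a1 <- augment_case(part, augment_params(), seed = 7)
  a2 <- augment_case(part, augment_params(), seed = 7)
  expect_identical(a1$image$data, a2$image$data)
  expect_identical(a1$structures$masks, a2$structures$masks)
  expect_false(identical(a1$image$data,
                         augment_case(part, augment_params(), seed = 8)$image$data))
})

test_that("rotation-only augmentation preserves mask volume within voxelization error", {
  cs <- make_planning_case(anatomy24(seed = 13))
  part <- list(image = cs$planning$image, structures = cs$planning$structures)
  rot <- augment_case(part, augment_params(rot_deg = 10, trans_mm = 0, scale = 0,
                                           elastic_mm = 0, noise_sd = 0,
                                           intensity = 0), seed = 3)
  v0 <- sum(part$structures$masks$bladder)
  v1 <- sum(rot$structures$masks$bladder)
  expect_lt(abs(v1 - v0) / v0, 0.05)
})

test_that("baseline training reduces the training loss and requires the structure", {
  prior <- list(base = anatomy16(texture_amplitude = 10), axis_jitter = 0.1,
                center_jitter_mm = 2)
  coh <- make_cohort(3, prior, variation_params(), n_fractions = 0, seed = 41)
  cfg <- training_config("BM", spec = network_spec(2, 2, "segmentation"),
                         epochs = 12, learning_rate = 5e-3, seed = 2)
  bm <- train_baseline(coh, "bladder", cfg)
  expect_lt(bm$history$total[nrow(bm$history)], bm$history$total[1])
  expect_equal(nrow(bm$history), 12)
  expect_error(train_baseline(coh[1], "bladder", cfg), "at least 2")
  broken <- coh
  broken[[2]]$planning$structures$masks$bladder <- NULL
  expect_error(train_baseline(broken, "bladder", cfg), "bladder")
})

test_that("fine-tuning memorizes the planning case and keeps the architecture", {
  prior <- list(base = anatomy16(texture_amplitude = 10), axis_jitter = 0.1,
                center_jitter_mm = 2)
  coh <- make_cohort(2, prior, variation_params(), n_fractions = 0, seed = 43)
  cfg <- training_config("BM", spec = network_spec(2, 2, "segmentation"),
                         epochs = 8, learning_rate = 5e-3, seed = 2)
  bm <- train_baseline(coh, "bladder", cfg)
  ft_cfg <- training_config("PSM", spec = bm$spec, epochs = 250,
                            learning_rate = 1e-2,
                            augment = augment_params(0, 0, 0, 0, 0, 0), seed = 3)
  psm <- finetune_patient(bm, coh[[1]], ft_cfg)
  expect_equal(n_params(psm), n_params(bm))
  expect_lt(psm$history$total[nrow(psm$history)], 0.1)   # memorization
  expect_error(finetune_patient(bm, local({
    cs <- coh[[1]]; cs$planning$structures$masks$bladder <- NULL; cs
  }), ft_cfg), "bladder")
})

test_that("supervised field regression reduces the field loss", {
  # lambda_seg = lambda_img = 0 with ground truth reduces the objective to
  # plain supervised regression, whose training loss must decrease
  base <- anatomy16(texture_amplitude = 15, noise_sd = 2)
  prior <- list(base = base, axis_jitter = 0.1, center_jitter_mm = 2)
  coh <- make_cohort(4, prior, variation_params(), n_fractions = 0, seed = 44)
  pairs <- lapply(seq_along(coh), function(i) {
    list(planning = coh[[i]]$planning$image,
         planning_masks = coh[[i]]$planning$structures$masks,
         gt_ddf = random_bspline_ddf(coh[[i]]$planning$image, 4, 8,
                                     seed = 100 + i))
  })
  cfg <- training_config("DDFM", spec = network_spec(3, 4, "displacement"),
                         epochs = 25, learning_rate = 3e-3,
                         ddfm_data_variant = "gt_realistic_ddf",
                         weights = loss_weights(1, 1, 0, 0, 0), seed = 5)
  dm <- train_ddfm(pairs, cfg)
  expect_lt(mean(tail(dm$history$l2, 5)), mean(head(dm$history$l2, 5)))
  # variant/data mismatch is a configuration error
  cfg_tp <- training_config("DDFM", spec = network_spec(3, 4, "displacement"),
                            epochs = 2, ddfm_data_variant = "true_pairs")
  expect_error(train_ddfm(pairs, cfg_tp), "fraction")
})

test_that("true-pair training logs every loss component", {
  base <- anatomy16(texture_amplitude = 10)
  prior <- list(base = base, axis_jitter = 0.1, center_jitter_mm = 2)
  coh <- make_cohort(2, prior, variation_params(c(0.95, 1.1), c(0.95, 1.1), 1, 1),
                     n_fractions = 1, seed = 45)
  pairs <- lapply(coh, function(cs) {
    list(planning = cs$planning$image,
         planning_masks = cs$planning$structures$masks,
         fraction = cs$fractions[[1]]$image,
         fraction_masks = cs$fractions[[1]]$structures$masks)
  })
  cfg <- training_config("DDFM", spec = network_spec(3, 4, "displacement"),
                         epochs = 3, ddfm_data_variant = "true_pairs", seed = 5)
  dm <- train_ddfm(pairs, cfg)
  expect_true(all(c("reg", "seg", "img", "total") %in% names(dm$history)))
  expect_equal(nrow(dm$history), 3)
  expect_true(all(dm$history$l2 == 0))   # no ground-truth term without gt
})
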