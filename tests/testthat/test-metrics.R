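sp15 <- c(1.5, 1.5, 1.5)

test_that("DSC follows voxel counting with a defined degenerate case", {
  d <- c(8, 8, 8)
  a <- cube_mask(d, c(1, 1, 1), c(2, 2, 2))
  expect_equal(dsc(a, a), 1)
  b <- cube_mask(d, c(5, 5, 5), c(6, 6, 6))
  expect_equal(dsc(a, b), 0)
  # 2x2x2 cubes overlapping in 4 voxels: 2*4/(8+8) = 0.5
  c_ <- cube_mask(d, c(1, 1, 2), c(2, 2, 3))
  expect_equal(dsc(a, c_), 0.5)
  e <- array(0, d)
  r <- dsc(e, e)
  expect_equal(as.numeric(r), 1)
  expect_true(attr(r, "degenerate"))
  expect_error(dsc(a, array(0, c(4, 4, 4))), "mismatch")
})

test_that("directed surface distances match arithmetic and a brute-force oracle", {
  d <- c(10, 10, 10)
  a <- array(0, d); a[3, 5, 5] <- 1
  b <- array(0, d); b[6, 5, 5] <- 1          # 3 voxels = 4.5 mm apart
  sd_ <- surface_distances(a, b, sp15)
  expect_equal(sd_$a_to_b, 4.5)
  expect_equal(sd_$b_to_a, 4.5)
  expect_error(surface_distances(a, array(0, d), sp15), "'b'")
  set.seed(20)
  for (r in 1:20) {
    dd <- c(sample(5:12, 1), sample(5:12, 1), sample(5:12, 1))
    sp <- runif(3, 0.8, 2.5)
    m1 <- array(as.numeric(runif(prod(dd)) < 0.3), dd)
    m2 <- array(as.numeric(runif(prod(dd)) < 0.3), dd)
    if (sum(m1) == 0 || sum(m2) == 0) next
    got <- surface_distances(m1, m2, sp)
    oracle <- brute_surface_distances(m1, m2, sp)
    expect_lt(max(abs(sort(got$a_to_b) - sort(oracle$a_to_b))), 1e-9)
    expect_lt(max(abs(sort(got$b_to_a) - sort(oracle$b_to_a))), 1e-9)
  }
})

test_that("hd95 and hd_avg behave on shifted cubes and plates", {
  d <- c(12, 12, 12)
  a <- cube_mask(d, c(3, 3, 3), c(6, 6, 6))
  expect_equal(hd95(a, a, sp15), 0)
  expect_equal(hd_avg(a, a, sp15), 0)
  b <- cube_mask(d, c(5, 3, 3), c(8, 6, 6))   # 2 voxels = 3.0 mm shift
  expect_equal(hd95(a, b, sp15), 3.0)
  # hd95 never exceeds the maximum Hausdorff distance
  sd_ <- surface_distances(a, b, sp15)
  expect_lte(hd95(a, b, sp15), max(c(sd_$a_to_b, sd_$b_to_a)))
  # two parallel 1-voxel plates 3 voxels (4.5 mm) apart
  p1 <- array(0, d); p1[4, , ] <- 1
  p2 <- array(0, d); p2[7, , ] <- 1
  expect_equal(hd_avg(p1, p2, sp15), 4.5)
  expect_equal(hd_avg(p2, p1, sp15), hd_avg(p1, p2, sp15))
})

test_that("surface distances scale linearly with spacing", {
  set.seed(21)
  d <- c(9, 9, 9)
  a <- array(as.numeric(runif(prod(d)) < 0.3), d)
  b <- array(as.numeric(runif(prod(d)) < 0.3), d)
  expect_equal(hd95(a, b, 2 * sp15), 2 * hd95(a, b, sp15))
  expect_equal(hd_avg(a, b, 2 * sp15), 2 * hd_avg(a, b, sp15))
})

test_that("the rectum evaluation region adds round(margin/thickness) slices per side", {
  d <- c(6, 6, 128)
  ptv <- array(0, d); ptv[3:4, 3:4, 40:60] <- 1
  expect_equal(rectum_eval_region(ptv, 1.5, 15), c(30, 70))
  # clamped at the volume boundary
  ptv2 <- array(0, d); ptv2[3, 3, 120:128] <- 1
  expect_equal(rectum_eval_region(ptv2, 1.5, 15), c(110, 128))
  expect_error(rectum_eval_region(array(0, d), 1.5, 15), "empty")
})

test_that("cohort aggregation weights patients, not fractions", {
  rec <- rbind(
    data.frame(patient = "A", fraction = 1:2, structure = "bladder",
               method = "BM", dsc = c(0.8, 0.9), hd95_mm = 1, hdavg_mm = 1,
               degenerate = FALSE),
    data.frame(patient = "B", fraction = 1, structure = "bladder",
               method = "BM", dsc = 0.6, hd95_mm = 1, hdavg_mm = 1,
               degenerate = FALSE))
  st <- aggregate_metrics(rec)
  expect_equal(st$cohort$dsc_mean, 0.725)   # (0.85 + 0.6)/2, not pooled 0.766..
  # duplicating every fraction record changes nothing
  st2 <- aggregate_metrics(rbind(rec, rec))
  expect_equal(st$cohort$dsc_mean, st2$cohort$dsc_mean)
  expect_equal(st$cohort$dsc_sd, st2$cohort$dsc_sd)
  # record order is irrelevant
  st3 <- aggregate_metrics(rec[c(3, 1, 2), ])
  expect_equal(st$cohort$dsc_mean, st3$cohort$dsc_mean)
  # single value per patient: plain mean
  rec1 <- rec[c(1, 3), ]
  expect_equal(aggregate_metrics(rec1)$cohort$dsc_mean, (0.8 + 0.6) / 2)
})

test_that("normality check returns calibrated p-values and flags constants", {
  set.seed(22)
  ok <- 0
  for (s in 1:10) {
    p <- normality_test(rnorm(100))$p
    expect_gte(p, 0); expect_lte(p, 1)
    if (p > 0.05) ok <- ok + 1
  }
  expect_gte(ok, 9)
  r <- normality_test(rep(0.5, 10))
  expect_true(r$degenerate)
  expect_error(normality_test(c(1, 2)), "at least 3")
})

test_that("the paired t-test matches the closed-form statistic", {
  b <- c(0, 0, 0, 0)
  a <- c(1, -1, 2, 0)
  r <- paired_test(a, b)
  expect_equal(r$t, 0.5 / (sqrt(5 / 3) / 2), tolerance = 1e-10)
  expect_equal(r$t, 0.7745967, tolerance = 1e-6)
  expect_equal(r$p, 2 * stats::pt(-abs(r$t), df = 3), tolerance = 1e-10)
  expect_false(r$significant)
  # swapping the arguments negates t and preserves p
  r2 <- paired_test(b, a)
  expect_equal(r2$t, -r$t)
  expect_equal(r2$p, r$p)
  # identical inputs are degenerate and not significant
  r3 <- paired_test(a, a)
  expect_true(r3$degenerate)
  expect_false(r3$significant)
  expect_error(paired_test(setNames(a, letters[1:4]), setNames(b, letters[4:1])),
               "misaligned")
})

test_that("the report table renders one bolded best entry per column", {
  rec <- expand.grid(patient = c("A", "B", "C"), fraction = 1:2,
                     structure = c("bladder"), method = c("BM", "PSM"),
                     stringsAsFactors = FALSE)
  set.seed(23)
  rec$dsc <- ifelse(rec$method == "PSM", 0.9, 0.8) + rnorm(nrow(rec), 0, 0.01)
  rec$hd95_mm <- ifelse(rec$method == "PSM", 3, 5) + rnorm(nrow(rec), 0, 0.1)
  rec$hdavg_mm <- rec$hd95_mm / 3
  rec$degenerate <- FALSE
  st <- aggregate_metrics(rec)
  rp <- report_table(st)
  expect_true(any(grepl("\\*\\*", rp)))
  expect_length(grep("^\\|", rp), 4)   # header, separator, two method rows
  cm <- compare_methods(st, "bladder", "dsc")
  expect_equal(nrow(cm), 1)
  expect_true(cm$significant)
})
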