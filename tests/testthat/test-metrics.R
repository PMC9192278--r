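# Dice family, texture statistics, image quality, detection reports, group
# tests and the bias-variance decomposition.

test_that("dice and new-dice match brute-force set arithmetic", {
  # hand-built fixture: |E| = 6, |F| = 4, overlap 3
  e <- matrix(0, 4, 4); e[1:6] <- 1
  f <- matrix(0, 4, 4); f[4:7] <- 1
  d <- dice_scores(e, f)
  expect_equal(d$dice, 0.6)
  expect_equal(d$new_dice, -0.2)
  expect_equal(d$dice_distance, 1 - d$dice)

  ph <- fixture_phantom()
  expect_equal(dice_scores(ph$mask, ph$mask)$dice, 1)
  expect_equal(dice_scores(ph$mask, ph$mask)$new_dice, 1)

  # disjoint nonempty masks
  a <- matrix(0, 4, 4); a[1] <- 1
  b <- matrix(0, 4, 4); b[16] <- 1
  expect_equal(dice_scores(a, b)$dice, 0)
  expect_equal(dice_scores(a, b)$new_dice, -2)

  expect_error(dice_scores(matrix(0, 4, 4), matrix(0, 4, 4)), "undefined")

  # 100 random pairs against the enumeration oracle, plus invariants
  for (s in 1:100) {
    e <- random_mask(6, 0.4, seed = s)$data
    f <- random_mask(6, 0.4, seed = 1000 + s)$data
    if (sum(e) + sum(f) == 0) next
    d <- dice_scores(e, f)
    o <- oracle_dice(e, f)
    expect_identical(d$dice, o$dice)
    expect_identical(d$new_dice, o$new_dice)
    expect_lte(d$new_dice, d$dice)
    if (d$fp == 0 && d$fn == 0) expect_equal(d$new_dice, d$dice)
    else expect_lt(d$new_dice, d$dice)
    # symmetry under swapping prediction and truth
    ds <- dice_scores(f, e)
    expect_equal(ds$dice, d$dice)
    expect_equal(ds$new_dice, d$new_dice)
  }
})

test_that("soft Dice losses agree with hard scores and penalize FPs harder", {
  for (s in 1:20) {
    e <- random_mask(6, 0.4, seed = 30 + s)$data
    f <- random_mask(6, 0.4, seed = 60 + s)$data
    if (sum(e) + sum(f) == 0) next
    d <- dice_scores(e, f)
    expect_equal(soft_dice_loss(e, f), 1 - d$dice, tolerance = 1e-12)
    expect_equal(soft_new_dice_loss(e, f), 1 - d$new_dice, tolerance = 1e-12)
  }
  f <- random_mask(8, 0.3, seed = 5)$data
  expect_equal(soft_new_dice_loss(f, f), 0)
  expect_error(soft_new_dice_loss(f * 1.5, f), "\\[0, 1\\]")

  # adding pure false-positive mass hurts soft new-dice more than soft dice
  p <- f * 0.9
  bg <- which(f == 0)[1]
  for (delta in c(0.1, 0.3, 0.5)) {
    p2 <- p; p2[bg] <- delta
    drop_dice <- soft_dice_loss(p2, f) - soft_dice_loss(p, f)
    drop_new <- soft_new_dice_loss(p2, f) - soft_new_dice_loss(p, f)
    expect_gt(drop_new, drop_dice)
  }
})

test_that("texture features implement population moments with conventions", {
  tf <- texture_features(c(5, 5, 5))
  expect_true(tf$degenerate)
  expect_equal(tf$mean, 5)
  expect_equal(tf$skewness, 0)
  expect_equal(tf$kurtosis, 0)

  tf2 <- texture_features(c(-1, 0, 1))
  expect_equal(tf2$mean, 0)
  expect_equal(tf2$skewness, 0)
  expect_equal(tf2$kurtosis, (2 / 3) / (2 / 3)^2 - 3)  # = -1.5 by hand
  expect_equal(tf2$kurtosis, -1.5)

  # affine invariance (a > 0)
  x <- rnorm(500)
  a <- texture_features(x); b <- texture_features(3.7 * x + 11)
  expect_equal(a$skewness, b$skewness, tolerance = 1e-9)
  expect_equal(a$kurtosis, b$kurtosis, tolerance = 1e-9)
  expect_error(texture_features(numeric(0)), "empty")
})

test_that("gaussian calibration: skewness ~ 0, excess kurtosis ~ 0", {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(20240901)
  x <- rnorm(1e6)
  tf <- texture_features(x)
  expect_lt(abs(tf$skewness), 0.01)
  expect_lt(abs(tf$kurtosis), 0.02)
})

test_that("image quality metrics match closed forms and track noise", {
  ref <- image_volume(matrix(0, 32, 32), value_range = c(0, 255))
  tst <- image_volume(matrix(10, 32, 32), value_range = c(0, 255))
  q <- image_quality(ref, tst)
  expect_equal(q$rmse, 10)
  expect_equal(q$psnr, 20 * log10(25.5), tolerance = 1e-9)

  qq <- image_quality(ref, ref)
  expect_equal(qq$rmse, 0)
  expect_true(is.infinite(qq$psnr))
  expect_equal(qq$ssim, 1)

  # psnr = 20 log10(MAX / rmse) identity on arbitrary data
  ph <- fixture_phantom()
  np <- add_lowdose_noise(ph$image, noise_model(sigma = 15, seed = 2))
  q2 <- image_quality(ph$image, np$noisy)
  expect_equal(q2$psnr, 20 * log10(q2$max_value / q2$rmse), tolerance = 1e-9)

  # monotone degradation with sigma
  ps <- sapply(c(5, 15, 25), function(sg) {
    image_quality(ph$image,
                  add_lowdose_noise(ph$image, noise_model(sigma = sg, seed = 9))$noisy)$psnr
  })
  expect_true(all(diff(ps) < 0))
})

test_that("detection report computes lesion- and voxel-level rates", {
  ph <- fixture_phantom(seed = 3)
  rep0 <- detection_report(list(ph$mask), list(ph$mask))
  expect_equal(rep0$sensitivity, 100)
  expect_equal(rep0$specificity, 100)
  expect_equal(rep0$accuracy, 100)

  empty <- segmentation_mask(array(0, dim(ph$mask$data)))
  rep1 <- detection_report(list(empty), list(ph$mask))
  expect_equal(rep1$sensitivity, 0)
  expect_equal(rep1$specificity, 100)

  # constructed 2-case fixture with known confusion counts
  t1 <- matrix(0, 8, 8); t1[2:3, 2:3] <- 1           # one 4-voxel lesion
  p1 <- matrix(0, 8, 8); p1[2:3, 2:3] <- 1; p1[6, 6] <- 1  # hit + 1 FP voxel
  t2 <- matrix(0, 8, 8); t2[5:6, 5:6] <- 1
  p2 <- matrix(0, 8, 8)                               # miss
  rep2 <- detection_report(list(p1, p2), list(t1, t2))
  expect_equal(rep2$sensitivity, 50)                  # 1 of 2 lesions
  expect_equal(rep2$lesions_detected$mean, 0.5)
  tn <- (64 - 5) + (64 - 4); fp <- 1; tp <- 4; fn <- 4
  expect_equal(rep2$specificity, 100 * tn / (tn + fp))
  expect_equal(rep2$accuracy, 100 * (tp + tn) / 128)
})

test_that("evaluation reports round-trip through CSV and JSON", {
  t1 <- matrix(0, 8, 8); t1[2:3, 2:3] <- 1
  p1 <- matrix(0, 8, 8); p1[2:3, 2:3] <- 1; p1[6, 6] <- 1
  rep <- detection_report(list(p1), list(t1))
  fc <- tempfile(fileext = ".csv"); fj <- tempfile(fileext = ".json")
  write_eval_report(rep, fc, fj)
  back <- read.csv(fc)
  expect_equal(back$tp, 4)
  expect_equal(back$fp, 1)
  js <- jsonlite::read_json(fj)
  expect_equal(js$sensitivity, 100)
  expect_equal(js$n_cases, 1)
})

test_that("group comparison: identical groups, hand chi-square, type-I rate", {
  ph <- fixture_phantom(seed = 4)
  r <- detection_report(list(ph$mask, ph$mask), list(ph$mask, ph$mask))
  cmp <- compare_groups(r, r)
  expect_equal(unname(cmp$t_test$statistic), 0)
  expect_equal(cmp$t_test$p.value, 1)

  # chi-square on [[10, 90], [50, 50]] without continuity correction:
  # expected counts [[30, 70], [30, 70]], statistic 400(2/30 + 2/70)
  tab <- matrix(c(10, 90, 50, 50), 2, byrow = TRUE)
  cs <- chisq.test(tab, correct = FALSE)
  O <- tab; E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(unname(cs$statistic), sum((O - E)^2 / E), tolerance = 1e-12)
  expect_equal(unname(cs$statistic), 400 * (2 / 30 + 2 / 70),
               tolerance = 1e-9)

  # agreement with the hand statistic on small random 2x2 tables
  set.seed(33)
  for (i in 1:20) {
    tt <- matrix(rpois(4, 6) + 1, 2)
    ee <- outer(rowSums(tt), colSums(tt)) / sum(tt)
    expect_equal(unname(suppressWarnings(
      chisq.test(tt, correct = FALSE))$statistic),
      sum((tt - ee)^2 / ee), tolerance = 1e-10)
  }
})

test_that("bias-variance decomposition holds exactly", {
  ref <- matrix(rnorm(64), 8)
  bv0 <- bias_variance(list(ref, ref), ref)
  expect_equal(c(bv0$bias_sq, bv0$variance, bv0$mse), c(0, 0, 0))

  bv1 <- bias_variance(list(ref + 1, ref - 1), ref)
  expect_equal(bv1$bias_sq, 0)
  expect_equal(bv1$variance, 1)
  expect_equal(bv1$mse, 1)

  bv2 <- bias_variance(list(ref + 3, ref + 3, ref + 3), ref)
  expect_equal(bv2$bias_sq, 9)
  expect_equal(bv2$variance, 0)

  preds <- lapply(1:5, function(i) ref + matrix(rnorm(64, sd = 0.5), 8))
  bv3 <- bias_variance(preds, ref)
  expect_lt(bv3$max_identity_gap, 1e-9)
  expect_error(bias_variance(list(ref), ref), ">= 2")
})
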