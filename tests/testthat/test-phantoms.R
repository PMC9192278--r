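# Phantom generation, noise insertion, and the synthetic perfusion series.

test_that("phantom generation is deterministic and validates lesions", {
  spec <- phantom_spec(shape = c(96, 96),
                       lesions = list(list(center = c(40, 40),
                                           radii = c(7, 7), delta = -15)))
  a <- make_head_phantom(spec)
  b <- make_head_phantom(spec)
  expect_identical(a$image$data, b$image$data)
  expect_identical(a$mask$data, b$mask$data)

  # hyperdense lesion rejected (ischemia is hypodense)
  expect_error(phantom_spec(lesions = list(list(center = c(128, 128),
                                                radii = c(5, 5), delta = 10))),
               "hypodense")
  # lesion outside the brain names the offending index
  expect_error(phantom_spec(shape = c(96, 96),
                            lesions = list(
                              list(center = c(40, 40), radii = c(5, 5), delta = -10),
                              list(center = c(5, 5), radii = c(5, 5), delta = -10))),
               "lesion 2")
})

test_that("zero lesions give an all-zero mask; tissue HUs land as designed", {
  ph <- make_head_phantom(phantom_spec(shape = c(96, 96)))
  expect_true(all(ph$mask$data == 0))
  expect_true(all(ph$image$data[ph$skull_mask$data == 1] == 1000))
  expect_true(min(ph$image$data) == -1000)
})

test_that("ellipsoid lesion voxel count matches analytic volume", {
  # 2D disc
  spec2 <- phantom_spec(shape = c(96, 96),
                        lesions = list(list(center = c(48, 48),
                                            radii = c(8, 8), delta = -15)))
  n2 <- sum(make_head_phantom(spec2)$mask$data)
  expect_lt(abs(n2 - pi * 64) / (pi * 64), 0.10)
  # 3D sphere of radius r: count within 10% of (4/3) pi r^3
  spec3 <- phantom_spec(shape = c(48, 48, 48),
                        lesions = list(list(center = c(24, 24, 24),
                                            radii = c(6, 6, 6), delta = -15)))
  n3 <- sum(make_head_phantom(spec3)$mask$data)
  expect_lt(abs(n3 - 4 / 3 * pi * 216) / (4 / 3 * pi * 216), 0.10)
})

test_that("noise model honours sigma, seed and zero-noise identity", {
  cl <- image_volume(matrix(100, 256, 256))
  expect_identical(add_lowdose_noise(cl, noise_model(sigma = 0))$noisy$data,
                   cl$data)
  np <- add_lowdose_noise(cl, noise_model(sigma = 25, seed = 3))
  v <- var(as.numeric(np$noisy$data - cl$data))
  expect_lt(abs(v - 625) / 625, 0.05)
  expect_lt(abs(mean(np$noisy$data - cl$data)), 1)
  np2 <- add_lowdose_noise(cl, noise_model(sigma = 25, seed = 4))
  expect_false(identical(np$noisy$data, np2$noisy$data))
  expect_identical(np$clean$data, np2$clean$data)
  expect_error(noise_model(sigma = -1), ">= 0")
})

test_that("perfusion series honours the forward model and its invariants", {
  ph <- fixture_phantom(c(64, 64))
  ser <- make_perfusion_series(ph$image, ph$mask)
  expect_equal(length(ser$times), 20)
  expect_equal(dim(ser$frames)[1], length(ser$aif))
  expect_true(all(ser$aif >= 0))
  expect_lt(ser$aif[1], 1e-9)

  # baseline frame equals the phantom; zero-flow voxels never deviate
  expect_equal(ser$frames[1, , ], ph$image$data, tolerance = 1e-10)
  air <- ph$image$data < -500
  for (ti in seq_along(ser$times)) {
    expect_true(all(ser$frames[ti, , ][air] == ph$image$data[air]))
  }

  # central volume identity of the truth maps, exact
  ok <- ser$truth_maps$cbf > 0
  expect_equal(ser$truth_maps$mtt[ok],
               60 * ser$truth_maps$cbv[ok] / ser$truth_maps$cbf[ok],
               tolerance = 1e-12)

  # AUC(tissue) / AUC(AIF) recovers assigned CBV within 5%
  lesion <- ph$mask$data > 0
  normal <- ok & !lesion
  vox_n <- which(normal)[1]; vox_l <- which(lesion & ok)[1]
  nt <- length(ser$times)
  cmat <- matrix(ser$frames, nt)
  for (vox in c(vox_n, vox_l)) {
    enh <- cmat[, vox] - mean(cmat[1:2, vox])
    ratio <- 100 * sum(enh) / sum(ser$aif)
    truth_cbv <- ser$truth_maps$cbv[vox]
    expect_lt(abs(ratio - truth_cbv) / truth_cbv, 0.05)
  }

  # reduced-flow lesion enhances less than normal tissue, all else equal
  ser_eq <- make_perfusion_series(ph$image, ph$mask, lesion_mtt = 4)
  cm <- matrix(ser_eq$frames, length(ser_eq$times))
  peak_l <- max(cm[, vox_l] - cm[1, vox_l])
  peak_n <- max(cm[, vox_n] - cm[1, vox_n])
  expect_lt(peak_l, peak_n)

  expect_error(make_perfusion_series(ph$image, ph$mask, normal_mtt = 0), "MTT")
  expect_error(make_perfusion_series(ph$image, ph$mask, lesion_cbf = -5), "CBF")
})

test_that("NIfTI and PNG round trips preserve the data", {
  ph <- fixture_phantom(c(48, 48))
  tf <- tempfile(fileext = ".nii.gz")
  write_nifti_volume(ph$image, tf)
  back <- read_nifti_volume(tf)
  expect_equal(back$data, ph$image$data, tolerance = 1e-6)
  tp <- tempfile(fileext = ".png")
  write_png_slice(ph$image, tp)
  expect_true(file.exists(tp))
  ser <- make_perfusion_series(ph$image, ph$mask)
  t4 <- tempfile(fileext = ".nii.gz"); ta <- tempfile(fileext = ".csv")
  write_perfusion_series(ser, t4, ta)
  aif_tab <- read.csv(ta)
  expect_equal(aif_tab$aif, ser$aif, tolerance = 1e-6)
})
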