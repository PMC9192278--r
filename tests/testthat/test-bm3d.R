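# Block matching, collaborative filtering, and the two-stage BM3D pipeline.

test_that("bm3d parameter validation enforces the documented constraints", {
  expect_error(bm3d_params(sigma = -1), ">= 0")
  expect_error(bm3d_params(block_size = 16, search_window = 8), "<=")
  expect_error(bm3d_params(max_group_size = 12), "power of two")
  expect_equal(bm3d_params(sigma = 25)$match_threshold, 4 * 625 + 300)
})

test_that("block matching ranks by distance with raster ties, reference first", {
  # flat image: every distance 0; group fills in raster order
  flat <- matrix(5, 32, 32)
  p <- bm3d_params(sigma = 0, block_size = 8, search_window = 17,
                   max_group_size = 8, match_threshold = 10)
  g <- block_match(flat, c(10, 10), p)
  expect_equal(nrow(g$coords), 8)
  expect_equal(g$reference_index, 1)
  expect_equal(g$coords[1, ], c(10, 10))
  others <- g$coords[-1, , drop = FALSE]
  raster_key <- (others[, 1] - 1) * 32 + others[, 2]
  expect_true(all(diff(raster_key) > 0))
  expect_true(all(g$distance == 0))

  # zero threshold on a noisy image: self-match only
  noisy <- matrix(rnorm(1024), 32)
  g0 <- block_match(noisy, c(10, 10),
                    bm3d_params(block_size = 8, search_window = 17,
                                match_threshold = 0))
  expect_equal(nrow(g0$coords), 1)

  # planted identical twin in otherwise dissimilar content, tight threshold
  set.seed(7)
  img <- matrix(rnorm(48 * 48, sd = 50), 48)
  patch <- matrix(rnorm(64, sd = 50), 8)
  img[11:18, 11:18] <- patch
  img[11:18, 25:32] <- patch   # twin inside the 39-px search window
  # brute-force all window distances for the oracle
  ref <- c(11, 11); k <- 8
  halo <- (39 - k) %/% 2
  dists <- c()
  for (r in max(1, ref[1] - halo):min(48 - k + 1, ref[1] + halo)) {
    for (cc in max(1, ref[2] - halo):min(48 - k + 1, ref[2] + halo)) {
      if (r == ref[1] && cc == ref[2]) next
      d <- mean((img[r:(r + k - 1), cc:(cc + k - 1)] - patch)^2)
      dists <- c(dists, d)
    }
  }
  thr <- min(dists[dists > 1e-9]) / 2   # tighter than any non-twin distance
  gt <- block_match(img, ref, bm3d_params(block_size = 8, search_window = 39,
                                          match_threshold = thr))
  expect_equal(nrow(gt$coords), 2)
  expect_equal(gt$coords[2, ], c(11, 25))

  expect_error(block_match(flat, c(30, 30),
                           bm3d_params(block_size = 8, search_window = 17)),
               "border")
})

test_that("hard stage with no shrinkage round-trips, covers every pixel", {
  ph <- fixture_phantom(c(48, 48))
  p0 <- bm3d_params(sigma = 0, lambda3d = 0)
  out <- bm3d_stage(ph$image, params = p0, mode = "hard")
  expect_lt(max(abs(out$data - ph$image$data)), 1e-6)
  expect_true(all(is.finite(out$data)))   # aggregation weights > 0 everywhere
  expect_error(bm3d_stage(ph$image, params = p0, mode = "wiener"), "pilot")
})

test_that("single-block hard stage equals an independent dense DCT oracle", {
  set.seed(21)
  blk <- matrix(rnorm(64, mean = 30, sd = 25), 8)
  p <- bm3d_params(sigma = 25, block_size = 8, search_window = 8,
                   lambda3d = 2.7, step = 1)
  out <- bm3d_stage(blk, params = p, mode = "hard")
  oracle <- oracle_dct_threshold(blk, 2.7 * 25)
  expect_lt(max(abs(out - oracle)), 1e-8)
})

test_that("hard stage strongly suppresses noise on constant content", {
  set.seed(22)
  clean <- matrix(100, 64, 64)
  noisy <- clean + matrix(rnorm(64 * 64, sd = 25), 64)
  out <- bm3d_stage(noisy, params = bm3d_params(sigma = 25), mode = "hard")
  expect_lt(var(as.numeric(out - clean)), 0.1 * 625)
})

test_that("two-stage denoising beats the noisy input and tracks sigma", {
  ph <- fixture_phantom(c(64, 64), seed = 9)
  np <- add_lowdose_noise(ph$image, noise_model(sigma = 25, seed = 31))
  den <- bm3d_denoise(np$noisy, bm3d_params(sigma = 25))
  expect_gt(image_quality(ph$image, den)$psnr,
            image_quality(ph$image, np$noisy)$psnr)

  # clean input, sigma declared 0: output ~ input
  out0 <- bm3d_denoise(ph$image, bm3d_params(sigma = 0, lambda3d = 0))
  expect_lt(max(abs(out0$data - ph$image$data)), 1e-6)

  # residual RMSE non-decreasing in input sigma
  rmse_at <- function(sg) {
    e <- sapply(1:2, function(s) {
      np <- add_lowdose_noise(ph$image, noise_model(sigma = sg, seed = 40 + s))
      sqrt(mean((bm3d_denoise(np$noisy, bm3d_params(sigma = sg))$data -
                   ph$image$data)^2))
    })
    mean(e)
  }
  rr <- sapply(c(5, 15, 25, 50), rmse_at)
  expect_true(all(diff(rr) > 0))
})

test_that("wiener refinement recovers texture the hard threshold removes", {
  img <- textured_image(96)
  g1 <- c(); g2 <- c()
  for (s in 1:3) {
    np <- add_lowdose_noise(img, noise_model(sigma = 25, seed = 50 + s))
    p <- bm3d_params(sigma = 25)
    basic <- bm3d_stage(np$noisy, params = p, mode = "hard")
    den <- bm3d_stage(np$noisy, pilot = basic, params = p, mode = "wiener")
    g1 <- c(g1, image_quality(img, basic)$psnr)
    g2 <- c(g2, image_quality(img, den)$psnr)
  }
  expect_gt(mean(g2), mean(g1))
})

test_that("denoising is shift-covariant away from borders", {
  n <- 192
  base <- matrix(20, n, n)
  bump <- function(m, at) {
    m[(at[1] - 3):(at[1] + 3), (at[2] - 3):(at[2] + 3)] <- 60
    m
  }
  set.seed(23)
  nn <- n - 3
  noise <- matrix(rnorm(nn * nn, sd = 10), nn)
  # same content and noise field, translated by one step-grid period (3 px)
  a <- bump(base, c(n / 2 - 1, n / 2 - 1)); a[1:nn, 1:nn] <- a[1:nn, 1:nn] + noise
  b <- bump(base, c(n / 2 + 2, n / 2 + 2)); b[4:n, 4:n] <- b[4:n, 4:n] + noise
  p <- bm3d_params(sigma = 10)
  da <- bm3d_denoise(a, p)
  db <- bm3d_denoise(b, p)
  # window clipping reaches (halo + shift) for references and a further
  # (halo + block) through group members, chained over the two stages:
  # ~77 px from each border; compare strictly inside that influence zone
  interior <- 79:111
  expect_lt(max(abs(da[interior, interior] - db[interior + 3, interior + 3])),
            1e-4)
})
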