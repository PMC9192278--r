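# Shared fixtures, generated in code at test time.

fixture_phantom <- function(shape = c(64L, 64L), seed = 1L, radius = 6,
                            delta = -15, n_lesions = 1L) {
  make_head_phantom(random_phantom_spec(shape = shape, n_lesions = n_lesions,
                                        radius = radius, delta = delta,
                                        seed = seed))
}

fixture_pair <- function(shape = c(64L, 64L), sigma = 25, seed = 1L) {
  ph <- fixture_phantom(shape, seed = seed)
  list(phantom = ph,
       pair = add_lowdose_noise(ph$image, noise_model(sigma = sigma,
                                                      seed = 100L + seed)))
}

random_mask <- function(n = 8L, p = 0.3, seed = 1L) {
  withr_seed <- function(s, code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(s); code
  }
  withr_seed(seed, segmentation_mask(matrix(rbinom(n * n, 1, p), n)))
}

# textured fixture whose fine structure gives the Wiener stage detail to
# recover; used for BM3D behavioural checks
textured_image <- function(n = 96L) {
  x <- outer(seq_len(n), seq_len(n),
             function(i, j) 60 * sin(i / 9) + 40 * cos(j / 13) + 30 * sin((i + j) / 7))
  x[(n %/% 3):(2 * n %/% 3), (n %/% 3):(2 * n %/% 3)] <-
    x[(n %/% 3):(2 * n %/% 3), (n %/% 3):(2 * n %/% 3)] + 80
  image_volume(x, value_range = range(x) + c(-1, 1))
}

# independent brute-force Dice oracle by explicit set enumeration
oracle_dice <- function(e, f) {
  e_idx <- which(e == 1); f_idx <- which(f == 1)
  tp <- length(intersect(e_idx, f_idx))
  fp <- length(setdiff(e_idx, f_idx))
  fn <- length(setdiff(f_idx, e_idx))
  den <- length(e_idx) + length(f_idx)
  list(dice = 2 * tp / den, new_dice = 2 * (tp - fn - fp) / den)
}

# independent dense DCT-domain oracle for the single-block BM3D case
oracle_dct_threshold <- function(block, lambda_sigma) {
  n <- nrow(block)
  D <- matrix(0, n, n)
  for (i in 0:(n - 1)) for (j in 0:(n - 1)) {
    c0 <- if (i == 0) sqrt(1 / n) else sqrt(2 / n)
    D[i + 1, j + 1] <- c0 * cos(pi * (2 * j + 1) * i / (2 * n))
  }
  co <- D %*% block %*% t(D)
  co[abs(co) < lambda_sigma] <- 0
  t(D) %*% co %*% D
}
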