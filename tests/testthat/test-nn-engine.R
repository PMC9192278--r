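# Layer contracts of the CNN engine: convolution linearity and geometry,
# pooling arithmetic, SE gating, residual identity, and exactness of every
# hand-written backward pass against finite differences.

ns <- asNamespace("strokeseg")

with_test_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

test_that("convolution is linear and maps channel geometry as declared", {
  with_test_seed(11, {
    # worked geometry example: 2x2 kernel, 4 input channels -> 2 output
    W <- array(rnorm(2 * 2 * 4 * 2), c(2, 2, 4, 2))
    x <- array(rnorm(6 * 6 * 4), c(6, 6, 4))
    y <- nn_conv2d(x, W)
    expect_equal(dim(y), c(5, 5, 2))

    # superposition: f(a x1 + b x2) = a f(x1) + b f(x2)
    x2 <- array(rnorm(6 * 6 * 4), c(6, 6, 4))
    lhs <- nn_conv2d(2.5 * x - 1.25 * x2, W)
    rhs <- 2.5 * nn_conv2d(x, W) - 1.25 * nn_conv2d(x2, W)
    expect_equal(lhs, rhs, tolerance = 1e-10)

    # same-size output with symmetric padding and odd kernel
    W3 <- array(rnorm(3 * 3 * 1 * 5), c(3, 3, 1, 5))
    y3 <- nn_conv2d(matrix(rnorm(64), 8), W3, pad = 1)
    expect_equal(dim(y3), c(8, 8, 5))
  })
})

test_that("max pooling divides dims exactly and ignores in-window order", {
  with_test_seed(12, {
    x <- array(rnorm(8 * 12 * 3), c(8, 12, 3))
    pf <- ns$maxpool_fwd(x, 2, 2)
    expect_equal(dim(pf$y), c(4, 6, 3))
    # permute values inside each 2x2 window: pooled output unchanged
    xp <- x
    xp[1:2, 1:2, ] <- x[2:1, 2:1, ]
    expect_equal(ns$maxpool_fwd(xp, 2, 2)$y, pf$y)
    # non-square pool
    expect_equal(dim(ns$maxpool_fwd(x, 2, 3)$y), c(4, 4, 3))
    expect_error(ns$maxpool_fwd(x, 5, 2), "not divisible")
  })
})

test_that("SE block gates channels multiplicatively with logistic gates", {
  with_test_seed(13, {
    x <- array(rnorm(6 * 6 * 16), c(6, 6, 16))
    y <- se_block(x, reduction = 4, seed = 2)
    g <- attr(y, "gates")
    expect_length(g, 16)
    expect_true(all(g > 0 & g < 1))
    expect_equal(nrow(attr(y, "params")$fc1$W), 16)
    expect_equal(ncol(attr(y, "params")$fc1$W), 4)   # bottleneck C/r
    for (c in c(1, 7, 16)) {
      expect_equal(y[, , c], x[, , c] * g[c], tolerance = 1e-12)
    }
    # zero input stays zero; unit gates reproduce the input exactly
    z0 <- se_block(array(0, c(4, 4, 8)), reduction = 4, seed = 2)
    expect_true(all(z0 == 0))
    p1 <- ns$se_params(8, 4)
    p1$fc2$W[] <- 0; p1$fc2$b[] <- 100       # logistic(100) == 1 in doubles
    xi <- array(rnorm(4 * 4 * 8), c(4, 4, 8))
    expect_equal(as.numeric(se_block(xi, 4, params = p1)), as.numeric(xi))
    expect_error(se_block(xi, reduction = 3), "divisible")
  })
})

test_that("residual block is X + F(X), identity at zero branch", {
  with_test_seed(14, {
    x <- array(rnorm(5 * 5 * 3), c(5, 5, 3))
    y0 <- residual_block(x)                 # zero-initialized branch
    expect_equal(as.numeric(y0), as.numeric(x))
    p <- list(conv1 = ns$conv_params(3, 3, 3), conv2 = ns$conv_params(3, 3, 3))
    y <- residual_block(x, params = p)
    expect_equal(y - x, attr(y, "residual"), tolerance = 1e-12,
                 ignore_attr = TRUE)
  })
})

test_that("backward passes match central finite differences", {
  with_test_seed(15, {
    fd_check <- function(fwd, bwd, x, n_probe = 4, tol = 1e-6) {
      out <- fwd(x)
      dy <- array(rnorm(length(out$y)), dim(out$y))
      dx <- bwd(dy, out)
      for (k in seq_len(n_probe)) {
        i <- sample(length(x), 1)
        eps <- 1e-6
        xp <- x; xp[i] <- xp[i] + eps
        xm <- x; xm[i] <- xm[i] - eps
        num <- sum((fwd(xp)$y - fwd(xm)$y) * dy) / (2 * eps)
        expect_equal(dx[i], num, tolerance = tol)
      }
    }
    x <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
    p <- ns$conv_params(3, 2, 4)
    fd_check(function(x) ns$conv_fwd(x, p, 1L),
             function(dy, out) ns$conv_bwd(dy, p, out)$dx, x)
    fd_check(function(x) ns$maxpool_fwd(x, 2, 2),
             function(dy, out) ns$maxpool_bwd(dy, out), x)
    fd_check(function(x) ns$upsample_fwd(x, 2, 2),
             function(dy, out) ns$upsample_bwd(dy, out), x)
    sp <- ns$se_params(2, 2)
    fd_check(function(x) ns$se_fwd(x, sp),
             function(dy, out) ns$se_bwd(dy, sp, out)$dx, x)
  })
})

test_that("full segmentation network gradient is exact (residual + SE path)", {
  with_test_seed(16, {
    cfg <- segnet_config(depth = 2, base_channels = 4, se_reduction = 2)
    net <- build_riseu_net(cfg, seed = 7)
    x <- array(rnorm(16 * 16), c(16, 16, 1))
    f <- matrix(rbinom(256, 1, 0.3), 16)
    lossfun <- function(net) {
      fw <- ns$riseu_fwd(net, x)
      ns$dice_loss_grad(as.numeric(fw$prob), as.numeric(f), "new_dice")$loss
    }
    fw <- ns$riseu_fwd(net, x)
    lg <- ns$dice_loss_grad(as.numeric(fw$prob), as.numeric(f), "new_dice")
    g <- ns$riseu_bwd(net, fw, array(lg$grad, dim(fw$prob)))
    paths <- list(list("enc", 1, "conv1", "W"),
                  list("enc", 2, "se", "fc1", "W"),
                  list("bottleneck", "conv2", "b"),
                  list("up", 1, "W"),
                  list("dec", 2, "proj", "W"),
                  list("head", "W"))
    get_at <- function(tr, p) { for (k in p) tr <- tr[[k]]; tr }
    for (p in paths) {
      pt <- get_at(net$params, p)
      i <- sample(length(pt), 1)
      eps <- 1e-5
      set_at <- function(v) {
        n2 <- net
        expr <- Reduce(function(acc, k) call("[[", acc, k), p,
                       quote(n2$params))
        pt2 <- pt; pt2[i] <- v
        eval(call("<-", expr, pt2))
        n2
      }
      num <- (lossfun(set_at(pt[i] + eps)) - lossfun(set_at(pt[i] - eps))) /
        (2 * eps)
      expect_equal(get_at(g, p)[i], num, tolerance = 1e-5)
    }
  })
})
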