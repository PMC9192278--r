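# Minimal CNN engine in base R: 2D convolution via shift-and-GEMM, ReLU,
# max pooling, nearest-neighbour upsampling, channel concatenation,
# squeeze-excitation gating, dense layers, sigmoid heads, and Adam.
# Feature maps are (H, W, C) arrays; batches are lists of such arrays.
# Every layer has a hand-written backward pass; correctness is locked by
# finite-difference tests.

## ---- parameter initialisation -------------------------------------------

he_init <- function(k, cin, cout) {
  array(stats::rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
        c(k, k, cin, cout))
}

conv_params <- function(k, cin, cout) {
  list(W = he_init(k, cin, cout), b = numeric(cout))
}

dense_params <- function(nin, nout) {
  list(W = matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout),
       b = numeric(nout))
}

se_params <- function(C, r) {
  if (C %% r != 0) stop("channel count ", C, " not divisible by reduction ", r)
  list(fc1 = dense_params(C, C %/% r), fc2 = dense_params(C %/% r, C))
}

## ---- primitives ----------------------------------------------------------

#' Low-level 2D convolution (cross-correlation)
#'
#' Linear map of an (H, W, C_in) feature array by a (k, k, C_in, C_out)
#' weight tensor with symmetric zero padding. Exposed for structural and
#' linearity checks; the training stack uses it internally.
#'
#' @param x numeric array (H, W, C_in); a matrix is treated as one channel.
#' @param W weight array (k, k, C_in, C_out).
#' @param b per-output-channel bias (default zeros).
#' @param pad zero-padding width; `(k-1)/2` gives same-size output for odd k.
#' @return Array (H_out, W_out, C_out) with `H_out = H + 2 pad - k + 1`.
#' @export
nn_conv2d <- function(x, W, b = NULL, pad = 0L) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  if (is.null(b)) b <- numeric(dim(W)[4])
  conv_fwd(x, list(W = W, b = b), pad = pad)$y
}

conv_fwd <- function(x, p, pad) {
  k <- dim(p$W)[1]; cin <- dim(p$W)[3]; cout <- dim(p$W)[4]
  H <- dim(x)[1]; Wd <- dim(x)[2]
  if (dim(x)[3] != cin) stop("input has ", dim(x)[3], " channels, weights expect ", cin)
  Hp <- H + 2 * pad; Wp <- Wd + 2 * pad
  if (pad > 0) {
    xp <- array(0, c(Hp, Wp, cin))
    xp[pad + seq_len(H), pad + seq_len(Wd), ] <- x
  } else xp <- x
  Ho <- Hp - k + 1; Wo <- Wp - k + 1
  if (Ho < 1 || Wo < 1) stop("kernel larger than padded input")
  out <- matrix(rep(p$b, each = Ho * Wo), Ho * Wo, cout)
  for (di in seq_len(k)) for (dj in seq_len(k)) {
    xs <- xp[di:(di + Ho - 1), dj:(dj + Wo - 1), , drop = FALSE]
    Wm <- matrix(p$W[di, dj, , ], cin, cout)
    out <- out + matrix(xs, Ho * Wo, cin) %*% Wm
  }
  list(y = array(out, c(Ho, Wo, cout)), xp = xp, pad = pad, in_dim = dim(x))
}

conv_bwd <- function(dy, p, cache) {
  k <- dim(p$W)[1]; cin <- dim(p$W)[3]; cout <- dim(p$W)[4]
  Ho <- dim(dy)[1]; Wo <- dim(dy)[2]
  Dm <- matrix(dy, Ho * Wo, cout)
  dW <- array(0, dim(p$W))
  dxp <- array(0, dim(cache$xp))
  for (di in seq_len(k)) for (dj in seq_len(k)) {
    xs <- cache$xp[di:(di + Ho - 1), dj:(dj + Wo - 1), , drop = FALSE]
    Xm <- matrix(xs, Ho * Wo, cin)
    dW[di, dj, , ] <- crossprod(Xm, Dm)
    dXm <- Dm %*% t(matrix(p$W[di, dj, , ], cin, cout))
    dxp[di:(di + Ho - 1), dj:(dj + Wo - 1), ] <-
      dxp[di:(di + Ho - 1), dj:(dj + Wo - 1), , drop = FALSE] +
      array(dXm, c(Ho, Wo, cin))
  }
  pad <- cache$pad
  dx <- if (pad > 0) {
    dxp[pad + seq_len(cache$in_dim[1]), pad + seq_len(cache$in_dim[2]), ,
        drop = FALSE]
  } else dxp
  list(dx = dx, dW = dW, db = colSums(Dm))
}

relu_fwd <- function(x) list(y = pmax(x, 0), mask = x > 0)
relu_bwd <- function(dy, cache) dy * cache$mask

sigmoid_ <- function(x) 1 / (1 + exp(-pmin(pmax(x, -40), 40)))

pool_indices <- function(H, W, C, h, w) {
  Hs <- H %/% h; Ws <- W %/% w
  idx <- matrix(0L, Hs * Ws * C, h * w)
  q <- 0L
  for (dj in seq_len(w)) for (di in seq_len(h)) {
    q <- q + 1L
    ri <- seq.int(di, H, by = h); cj <- seq.int(dj, W, by = w)
    idx[, q] <- rep(ri, times = Ws * C) +
      rep(rep(cj - 1L, each = Hs), times = C) * H +
      rep(seq_len(C) - 1L, each = Hs * Ws) * (H * W)
  }
  idx
}

maxpool_fwd <- function(x, h, w) {
  d <- dim(x)
  if (d[1] %% h != 0 || d[2] %% w != 0) {
    stop("spatial dims (", d[1], ", ", d[2], ") not divisible by pool (",
         h, ", ", w, ")")
  }
  idx <- pool_indices(d[1], d[2], d[3], h, w)
  cand <- matrix(x[idx], nrow(idx), ncol(idx))
  best <- max.col(cand, ties.method = "first")
  sel <- idx[cbind(seq_len(nrow(idx)), best)]
  list(y = array(x[sel], c(d[1] %/% h, d[2] %/% w, d[3])),
       sel = sel, in_dim = d)
}

maxpool_bwd <- function(dy, cache) {
  dx <- array(0, cache$in_dim)
  dx[cache$sel] <- dy
  dx
}

upsample_fwd <- function(x, h, w) {
  d <- dim(x)
  list(y = x[rep(seq_len(d[1]), each = h), rep(seq_len(d[2]), each = w), ,
             drop = FALSE],
       in_dim = d, h = h, w = w)
}

upsample_bwd <- function(dy, cache) {
  d <- cache$in_dim; h <- cache$h; w <- cache$w
  dx <- array(0, d)
  for (di in seq_len(h)) for (dj in seq_len(w)) {
    dx <- dx + dy[seq.int(di, d[1] * h, by = h),
                  seq.int(dj, d[2] * w, by = w), , drop = FALSE]
  }
  dx
}

concat_fwd <- function(a, b) {
  da <- dim(a); db <- dim(b)
  if (!identical(da[1:2], db[1:2])) stop("concat: spatial shapes differ")
  y <- array(0, c(da[1], da[2], da[3] + db[3]))
  y[, , seq_len(da[3])] <- a
  y[, , da[3] + seq_len(db[3])] <- b
  list(y = y, ca = da[3])
}

concat_bwd <- function(dy, cache) {
  ca <- cache$ca
  list(da = dy[, , seq_len(ca), drop = FALSE],
       db = dy[, , -seq_len(ca), drop = FALSE])
}

se_fwd <- function(x, p) {
  d <- dim(x); HW <- d[1] * d[2]; C <- d[3]
  Xm <- matrix(x, HW, C)
  z <- matrix(colMeans(Xm), 1, C)
  a1 <- z %*% p$fc1$W + matrix(p$fc1$b, 1)
  h1 <- pmax(a1, 0)
  a2 <- h1 %*% p$fc2$W + matrix(p$fc2$b, 1)
  g <- sigmoid_(a2)
  y <- array(Xm * rep(as.numeric(g), each = HW), d)
  list(y = y, x = x, z = z, a1 = a1, h1 = h1, g = g)
}

se_bwd <- function(dy, p, cache) {
  d <- dim(cache$x); HW <- d[1] * d[2]; C <- d[3]
  Dm <- matrix(dy, HW, C)
  Xm <- matrix(cache$x, HW, C)
  g <- as.numeric(cache$g)
  dXm <- Dm * rep(g, each = HW)
  dg <- matrix(colSums(Dm * Xm), 1, C)
  da2 <- dg * g * (1 - g)
  dW2 <- crossprod(cache$h1, da2)
  db2 <- as.numeric(da2)
  dh1 <- da2 %*% t(p$fc2$W)
  da1 <- dh1 * (cache$a1 > 0)
  dW1 <- crossprod(cache$z, da1)
  db1 <- as.numeric(da1)
  dz <- da1 %*% t(p$fc1$W)
  dXm <- dXm + matrix(rep(as.numeric(dz) / HW, each = HW), HW, C)
  list(dx = array(dXm, d),
       grads = list(fc1 = list(W = dW1, b = db1),
                    fc2 = list(W = dW2, b = db2)))
}

## ---- standalone blocks (exported surface) --------------------------------

#' Squeeze-excitation channel gate
#'
#' Global-average-pools each channel, passes the channel descriptor through a
#' bottleneck of width `C / reduction` with ReLU, expands back, and applies a
#' logistic gate `s_c` in (0, 1) multiplicatively to each channel.
#'
#' @param x feature array (H, W, C).
#' @param reduction bottleneck ratio r; C must be divisible by r.
#' @param params optional parameter list (as from the internal initializer);
#'   fresh seeded parameters are drawn when omitted.
#' @param seed seed used when `params` is NULL.
#' @return Gated features, with the gate vector attached as attribute
#'   `"gates"` and parameters as `"params"`.
#' @export
se_block <- function(x, reduction = 4, params = NULL, seed = 1L) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  C <- dim(x)[3]
  if (C %% reduction != 0) {
    stop("channels (", C, ") not divisible by reduction (", reduction, ")")
  }
  if (is.null(params)) params <- with_seed(seed, se_params(C, reduction))
  fw <- se_fwd(x, params)
  structure(fw$y, gates = as.numeric(fw$g), params = params)
}

#' Residual block: output = X + F(X)
#'
#' The branch F is a conv-ReLU-conv stack on equal channel counts, so a
#' zero-initialized branch makes the block an exact identity map.
#'
#' @param x feature array (H, W, C).
#' @param params optional branch parameters (`conv1`, `conv2`); zero
#'   initialized when omitted (identity block).
#' @param kernel branch kernel size (odd).
#' @return `x + F(x)`, with the branch output attached as attribute
#'   `"residual"` and parameters as `"params"`.
#' @export
residual_block <- function(x, params = NULL, kernel = 3L) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  C <- dim(x)[3]
  if (is.null(params)) {
    params <- list(conv1 = list(W = array(0, c(kernel, kernel, C, C)),
                                b = numeric(C)),
                   conv2 = list(W = array(0, c(kernel, kernel, C, C)),
                                b = numeric(C)))
  }
  pad <- (dim(params$conv1$W)[1] - 1L) %/% 2L
  h <- relu_fwd(conv_fwd(x, params$conv1, pad)$y)$y
  f <- conv_fwd(h, params$conv2, pad)$y
  structure(x + f, residual = f, params = params)
}

## ---- parameter trees and Adam -------------------------------------------

tree_map <- function(f, tree) {
  if (is.list(tree)) lapply(tree, function(t) tree_map(f, t)) else f(tree)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a)); names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    out
  } else f(a, b)
}

tree_zeros <- function(tree) tree_map(function(x) x * 0, tree)

n_params <- function(tree) {
  if (is.list(tree)) sum(vapply(tree, n_params, numeric(1))) else length(tree)
}

adam_init <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       m = tree_zeros(params), v = tree_zeros(params))
}

adam_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  opt$m <- tree_map2(function(m, g) opt$beta1 * m + (1 - opt$beta1) * g,
                     opt$m, grads)
  opt$v <- tree_map2(function(v, g) opt$beta2 * v + (1 - opt$beta2) * g^2,
                     opt$v, grads)
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  step <- tree_map2(function(m, v) {
    opt$lr * (m / bc1) / (sqrt(v / bc2) + opt$eps)
  }, opt$m, opt$v)
  params <- tree_map2(`-`, params, step)
  list(opt = opt, params = params)
}

## ---- losses --------------------------------------------------------------

mse_loss <- function(pred, target) {
  n <- length(pred)
  list(loss = mean((pred - target)^2), grad = 2 * (pred - target) / n)
}

# soft Dice-family losses (linear denominator) with gradient wrt the
# probability map
dice_loss_grad <- function(p, f, variant = c("dice", "new_dice"),
                           eps = 1e-6) {
  variant <- match.arg(variant)
  D <- sum(p) + sum(f) + eps
  if (variant == "dice") {
    N <- 2 * sum(p * f)
    dN <- 2 * f
  } else {
    N <- 2 * (3 * sum(p * f) - sum(p) - sum(f))
    dN <- 2 * (3 * f - 1)
  }
  list(loss = 1 - N / D, grad = -(dN * D - N) / D^2)
}
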