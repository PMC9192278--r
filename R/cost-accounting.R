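# Closed-form cost accounting for network design: fully-connected weight
# counts, convolution parameter counts, and the depthwise-separable
# multiplication ratio.

#' Weight count of a fully-connected layer pair
#'
#' Connecting every input pixel to every hidden unit needs
#' `n_inputs * n_hidden` weights — the count that motivates convolutional
#' weight sharing (a 1000 x 1000 image feeding 1e6 hidden units already
#' needs 1e12 weights).
#'
#' @param n_inputs number of input units (e.g. pixels).
#' @param n_hidden number of hidden units.
#' @param bias include one bias per hidden unit.
#' @return Weight count (double, to avoid integer overflow).
#' @export
fc_weight_count <- function(n_inputs, n_hidden, bias = FALSE) {
  if (n_inputs < 1 || n_hidden < 1) stop("unit counts must be >= 1")
  as.numeric(n_inputs) * as.numeric(n_hidden) +
    if (bias) as.numeric(n_hidden) else 0
}

#' Parameter count of a plain convolution stack
#'
#' Sum over layers of `in_ch * out_ch * k^2` weights plus `out_ch` biases.
#'
#' @param channels integer vector of channel counts, length `n_layers + 1`
#'   (input channels first).
#' @param kernel spatial kernel size (square).
#' @param bias include bias terms.
#' @return Total parameter count.
#' @export
conv_param_count <- function(channels, kernel, bias = TRUE) {
  n <- length(channels) - 1
  if (n < 1) stop("need at least one layer")
  sum(vapply(seq_len(n), function(i) {
    channels[i] * channels[i + 1] * kernel^2 + if (bias) channels[i + 1] else 0
  }, numeric(1)))
}

#' Depthwise-separable convolution cost ratio
#'
#' Multiplication count of a depthwise (`H W D_K^2 M`) plus pointwise
#' (`H W M N`) factorization over a standard convolution
#' (`H W D_K^2 M N`). The counted ratio equals `1/N + 1/D_K^2` exactly.
#'
#' @param H,W feature-map height and width.
#' @param D_K spatial kernel size.
#' @param M,N input and output channel counts.
#' @return A list of class `separable_cost`: `ratio` (counted),
#'   `closed_form` (`1/N + 1/D_K^2`), `standard_mults`, `separable_mults`.
#' @export
separable_cost_ratio <- function(H, W, D_K, M, N) {
  vals <- c(H = H, W = W, D_K = D_K, M = M, N = N)
  if (any(vals < 1) || any(vals != floor(vals))) {
    stop("all dimensions must be strictly positive integers")
  }
  standard <- H * W * D_K^2 * M * N
  separable <- H * W * D_K^2 * M + H * W * M * N
  structure(list(ratio = separable / standard,
                 closed_form = 1 / N + 1 / D_K^2,
                 standard_mults = standard, separable_mults = separable),
            class = "separable_cost")
}

#' @export
print.separable_cost <- function(x, ...) {
  cat(sprintf("separable/standard multiplications: %.6g (closed form 1/N + 1/D_K^2 = %.6g)\n",
              x$ratio, x$closed_form))
  invisible(x)
}
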