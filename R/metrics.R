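# Scoring layer: Dice-family overlap scores and their differentiable
# relaxations, first-order texture statistics, image-quality metrics
# (PSNR/RMSE/SSIM), lesion detection reports, group comparison tests, and the
# bias-variance decomposition of ensemble predictions.

#' Dice-family overlap scores between two binary masks
#'
#' `dice = 2|E∩F| / (|E|+|F|)` for prediction E and truth F. The
#' false-positive-penalizing variant subtracts both error sets in the
#' numerator: `new_dice = 2(|E∩F| - |¬E∩F| - |E∩¬F|) / (|E|+|F|)`, ranging
#' over \[-2, 1\] and equal to `dice` exactly when there are no errors.
#'
#' @param pred,truth `segmentation_mask` objects (or 0/1 arrays) on one grid.
#' @return A list of class `dice_scores`: `dice`, `dice_distance`
#'   (`1 - dice`), `new_dice`, and the confusion counts `tp`, `fp`, `fn`.
#' @export
dice_scores <- function(pred, truth) {
  e <- as_image_data(pred)
  f <- as_image_data(truth)
  if (!identical(dim(e), dim(f))) stop("masks must share a grid")
  if (!all(e %in% c(0, 1)) || !all(f %in% c(0, 1))) {
    stop("masks must be binary")
  }
  tp <- sum(e == 1 & f == 1)
  fp <- sum(e == 1 & f == 0)
  fn <- sum(e == 0 & f == 1)
  denom <- sum(e) + sum(f)
  if (denom == 0) stop("both masks are empty: Dice is undefined (0/0)")
  dice <- 2 * tp / denom
  new_dice <- 2 * (tp - fn - fp) / denom
  structure(list(dice = dice, dice_distance = 1 - dice, new_dice = new_dice,
                 tp = tp, fp = fp, fn = fn),
            class = "dice_scores")
}

#' @export
print.dice_scores <- function(x, ...) {
  cat(sprintf("Dice %.4f (distance %.4f), New Dice %.4f  [TP %d FP %d FN %d]\n",
              x$dice, x$dice_distance, x$new_dice, x$tp, x$fp, x$fn))
  invisible(x)
}

#' Differentiable Dice loss
#'
#' Soft relaxation with probabilities in place of the predicted indicator:
#' `1 - 2 Σ e_i f_i / (Σ e_i + Σ f_i)`. On hard \{0,1\} inputs this equals
#' `1 - dice` from [dice_scores()].
#'
#' @param prob predicted probabilities in \[0, 1\] on the truth grid.
#' @param truth binary mask.
#' @param eps stabilizer added to the denominator (0 for the exact score).
#' @return Scalar loss.
#' @export
soft_dice_loss <- function(prob, truth, eps = 0) {
  p <- as_image_data(prob); f <- as_image_data(truth)
  check_probs(p, f)
  den <- sum(p) + sum(f) + eps
  if (den == 0) stop("empty prediction and truth: loss undefined")
  1 - 2 * sum(p * f) / den
}

#' Differentiable New-Dice loss
#'
#' Relaxation of the false-positive-penalizing score: numerator
#' `2(Σ e f - Σ (1-e) f - Σ e (1-f))`, denominator `Σ e + Σ f`. On hard
#' inputs equals `1 - new_dice` from [dice_scores()]. The linear denominator
#' (rather than a sum of squares) keeps the relaxation well-behaved when the
#' numerator is negative: a squared denominator can be inflated by
#' confident false positives, which rewards over-segmentation — the exact
#' failure mode the score exists to penalize.
#'
#' @inheritParams soft_dice_loss
#' @return Scalar loss.
#' @export
soft_new_dice_loss <- function(prob, truth, eps = 0) {
  p <- as_image_data(prob); f <- as_image_data(truth)
  check_probs(p, f)
  den <- sum(p) + sum(f) + eps
  if (den == 0) stop("empty prediction and truth: loss undefined")
  num <- 2 * (sum(p * f) - sum((1 - p) * f) - sum(p * (1 - f)))
  1 - num / den
}

check_probs <- function(p, f) {
  if (!identical(dim(p), dim(f))) stop("probability and truth grids differ")
  if (min(p) < 0 || max(p) > 1) stop("probabilities must lie in [0, 1]")
  if (!all(f %in% c(0, 1))) stop("truth mask must be binary")
  invisible(TRUE)
}

#' First-order texture statistics of an intensity sample
#'
#' Mean, skewness (third standardized moment) and excess kurtosis (fourth
#' standardized moment minus 3), all with population central moments. A
#' zero-variance sample sets the `degenerate` flag and reports skewness and
#' kurtosis as 0.
#'
#' @param values numeric vector (or image), length >= 1.
#' @return A list of class `texture_features`: `mean`, `skewness`,
#'   `kurtosis`, `degenerate`.
#' @export
texture_features <- function(values) {
  x <- as.numeric(as_image_data(values))
  if (length(x) < 1) stop("empty sample")
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  if (m2 == 0) {
    return(structure(list(mean = mu, skewness = 0, kurtosis = 0,
                          degenerate = TRUE),
                     class = "texture_features"))
  }
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  structure(list(mean = mu, skewness = m3 / m2^1.5, kurtosis = m4 / m2^2 - 3,
                 degenerate = FALSE),
            class = "texture_features")
}

rmse <- function(a, b) sqrt(mean((a - b)^2))

box_mean <- function(m, w) {
  # mean over all fully-contained w x w windows via an integral image
  H <- nrow(m); W <- ncol(m)
  S <- matrix(0, H + 1, W + 1)
  S[-1, -1] <- apply(apply(m, 2, cumsum), 1, cumsum) |> t()
  i <- seq_len(H - w + 1); j <- seq_len(W - w + 1)
  (S[i + w, j + w, drop = FALSE] - S[i, j + w, drop = FALSE] -
     S[i + w, j, drop = FALSE] + S[i, j, drop = FALSE]) / (w * w)
}

#' Structural similarity between two 2D images
#'
#' Mean SSIM over all fully-contained square windows, with the standard
#' stabilizers `C1 = (K1 L)^2`, `C2 = (K2 L)^2`.
#'
#' @param ref,test numeric matrices on one grid.
#' @param max_value dynamic range L.
#' @param window window side in pixels.
#' @param K1,K2 stabilizer constants.
#' @return Mean SSIM in \[-1, 1\].
#' @export
ssim <- function(ref, test, max_value, window = 7, K1 = 0.01, K2 = 0.03) {
  x <- as_image_data(ref); y <- as_image_data(test)
  if (!identical(dim(x), dim(y))) stop("images must share a grid")
  C1 <- (K1 * max_value)^2
  C2 <- (K2 * max_value)^2
  mx <- box_mean(x, window); my <- box_mean(y, window)
  sxx <- box_mean(x * x, window) - mx^2
  syy <- box_mean(y * y, window) - my^2
  sxy <- box_mean(x * y, window) - mx * my
  s <- ((2 * mx * my + C1) * (2 * sxy + C2)) /
    ((mx^2 + my^2 + C1) * (sxx + syy + C2))
  mean(s)
}

#' Image-quality report: PSNR, RMSE, SSIM
#'
#' `psnr = 20 log10(MAX / rmse)`; identical images report an infinite PSNR.
#' MAX is taken from the reference volume's `value_range` unless overridden.
#'
#' @param ref,test `image_volume` objects (or arrays) on one grid and units.
#' @param max_value dynamic range MAX for PSNR/SSIM; defaults to the width of
#'   `ref$value_range`.
#' @return A list of class `quality_report`: `psnr` (dB), `rmse`, `ssim`,
#'   `max_value`.
#' @export
image_quality <- function(ref, test, max_value = NULL) {
  x <- as_image_data(ref); y <- as_image_data(test)
  if (!identical(dim(x), dim(y))) stop("images must share a grid")
  if (inherits(ref, "image_volume") && inherits(test, "image_volume") &&
      ref$intensity_units != test$intensity_units) {
    stop("intensity units differ")
  }
  if (is.null(max_value)) {
    vr <- if (inherits(ref, "image_volume")) ref$value_range else range(x)
    max_value <- vr[2] - vr[1]
  }
  r <- rmse(x, y)
  ps <- if (r > 0) 20 * log10(max_value / r) else Inf
  sm <- if (length(dim(x)) == 2L) ssim(x, y, max_value) else {
    mean(vapply(seq_len(dim(x)[1]),
                function(z) ssim(x[z, , ], y[z, , ], max_value), numeric(1)))
  }
  structure(list(psnr = ps, rmse = r, ssim = sm, max_value = max_value),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("PSNR %.2f dB | RMSE %.4g | SSIM %.4f (MAX %.4g)\n",
              x$psnr, x$rmse, x$ssim, x$max_value))
  invisible(x)
}

label_components <- function(mask) {
  EBImage::bwlabel(as_image_data(mask))
}

#' Lesion detection report over a set of cases
#'
#' A true lesion (connected component of the truth mask) counts as detected
#' when at least one predicted voxel overlaps it. Sensitivity is lesion-level
#' (detected / true lesions, pooled); specificity and accuracy are
#' voxel-level, pooled over cases. `lesions_detected` is the per-case mean
#' and SD of detected counts.
#'
#' @param pred_masks,truth_masks lists of `segmentation_mask` (or 0/1
#'   arrays), one per case, grids matching within each case.
#' @return A list of class `eval_report`: `sensitivity`, `specificity`,
#'   `accuracy` (all percent), `lesions_detected` (`mean`, `sd`), and a
#'   `per_case` data frame.
#' @export
detection_report <- function(pred_masks, truth_masks) {
  if (length(pred_masks) < 1 || length(pred_masks) != length(truth_masks)) {
    stop("need >= 1 case with matching prediction/truth lists")
  }
  rows <- lapply(seq_along(pred_masks), function(i) {
    e <- as_image_data(pred_masks[[i]])
    f <- as_image_data(truth_masks[[i]])
    if (!identical(dim(e), dim(f))) stop("case ", i, ": grid mismatch")
    lab <- label_components(f)
    n_true <- max(lab)
    detected <- if (n_true > 0) {
      sum(vapply(seq_len(n_true), function(k) any(e[lab == k] == 1), logical(1)))
    } else 0L
    data.frame(case = i,
               n_true = n_true, n_detected = detected,
               tp = sum(e == 1 & f == 1), fp = sum(e == 1 & f == 0),
               tn = sum(e == 0 & f == 0), fn = sum(e == 0 & f == 1))
  })
  per_case <- do.call(rbind, rows)
  tot <- colSums(per_case[, c("n_true", "n_detected", "tp", "fp", "tn", "fn")])
  sens <- if (tot["n_true"] > 0) 100 * tot["n_detected"] / tot["n_true"] else NA_real_
  spec <- 100 * tot["tn"] / (tot["tn"] + tot["fp"])
  acc <- 100 * (tot["tp"] + tot["tn"]) / sum(tot[c("tp", "fp", "tn", "fn")])
  per_case$sensitivity <- ifelse(per_case$n_true > 0,
                                 100 * per_case$n_detected / per_case$n_true, NA)
  per_case$specificity <- 100 * per_case$tn / (per_case$tn + per_case$fp)
  per_case$accuracy <- 100 * (per_case$tp + per_case$tn) /
    rowSums(per_case[, c("tp", "fp", "tn", "fn")])
  structure(list(sensitivity = unname(sens), specificity = unname(spec),
                 accuracy = unname(acc),
                 lesions_detected = list(mean = mean(per_case$n_detected),
                                         sd = stats::sd(per_case$n_detected)),
                 per_case = per_case),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  sdtxt <- if (is.na(x$lesions_detected$sd)) "NA"
           else sprintf("%.1f", x$lesions_detected$sd)
  cat(sprintf("Sensitivity %.1f%% | Specificity %.1f%% | Accuracy %.1f%% | lesions detected %.1f +/- %s (n=%d cases)\n",
              x$sensitivity, x$specificity, x$accuracy,
              x$lesions_detected$mean, sdtxt, nrow(x$per_case)))
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' The per-case table goes to CSV; the summary (sensitivity, specificity,
#' accuracy, lesions detected mean and SD, case count) to JSON.
#'
#' @param report an `eval_report` from [detection_report()].
#' @param csv_path per-case CSV path.
#' @param json_path summary JSON path.
#' @return Named vector of the two paths, invisibly.
#' @export
write_eval_report <- function(report, csv_path, json_path) {
  stopifnot(inherits(report, "eval_report"))
  utils::write.csv(report$per_case, csv_path, row.names = FALSE)
  jsonlite::write_json(
    list(sensitivity = report$sensitivity,
         specificity = report$specificity,
         accuracy = report$accuracy,
         lesions_detected_mean = report$lesions_detected$mean,
         lesions_detected_sd = report$lesions_detected$sd,
         n_cases = nrow(report$per_case)),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv_path, json = json_path))
}

#' Compare two evaluation groups
#'
#' Welch t-test on per-case detected lesion counts, and a 2x2 chi-squared
#' test (no continuity correction) on pooled lesion detection proportions.
#'
#' @param a,b `eval_report` objects for the two groups.
#' @return A list of class `group_comparison` with elements `t_test` and
#'   `chisq_test` (both `htest`).
#' @export
compare_groups <- function(a, b) {
  stopifnot(inherits(a, "eval_report"), inherits(b, "eval_report"))
  ca <- a$per_case$n_detected; cb <- b$per_case$n_detected
  if (length(ca) < 2 || length(cb) < 2) stop("t-test needs >= 2 cases per group")
  tt <- if (stats::sd(c(ca, cb)) == 0) {
    # degenerate identical data: t statistic 0 by convention
    structure(list(statistic = c(t = 0), p.value = 1,
                   method = "Welch Two Sample t-test (degenerate)",
                   data.name = "n_detected"), class = "htest")
  } else {
    stats::t.test(ca, cb)
  }
  det_a <- sum(a$per_case$n_detected); miss_a <- sum(a$per_case$n_true) - det_a
  det_b <- sum(b$per_case$n_detected); miss_b <- sum(b$per_case$n_true) - det_b
  tab <- matrix(c(det_a, miss_a, det_b, miss_b), 2, byrow = TRUE)
  cs <- tryCatch(suppressWarnings(stats::chisq.test(tab, correct = FALSE)),
                 error = function(e) NULL)
  structure(list(t_test = tt, chisq_test = cs, table = tab),
            class = "group_comparison")
}

#' Bias-variance decomposition of replicate predictions
#'
#' For predictions of one target across seeds: per-voxel squared bias
#' `(mean - ref)^2`, population variance across replicates, and MSE averaged
#' over replicates, reported as spatial means. `mse = bias_sq + variance`
#' holds exactly per voxel.
#'
#' @param predictions list (>= 2) of arrays/`image_volume`s on one grid.
#' @param reference the reference image on the same grid.
#' @return A list of class `bias_variance_report`: `bias_sq`, `variance`,
#'   `mse`, and `max_identity_gap` (largest per-voxel violation of the
#'   decomposition, numerically ~0).
#' @export
bias_variance <- function(predictions, reference) {
  if (length(predictions) < 2) stop("need >= 2 prediction replicates")
  ref <- as_image_data(reference)
  preds <- lapply(predictions, as_image_data)
  for (p in preds) if (!identical(dim(p), dim(ref))) stop("grid mismatch")
  n <- length(preds)
  mean_pred <- Reduce(`+`, preds) / n
  bias_sq_vox <- (mean_pred - ref)^2
  var_vox <- Reduce(`+`, lapply(preds, function(p) (p - mean_pred)^2)) / n
  mse_vox <- Reduce(`+`, lapply(preds, function(p) (p - ref)^2)) / n
  structure(list(bias_sq = mean(bias_sq_vox), variance = mean(var_vox),
                 mse = mean(mse_vox),
                 max_identity_gap = max(abs(mse_vox - bias_sq_vox - var_vox))),
            class = "bias_variance_report")
}

#' @export
print.bias_variance_report <- function(x, ...) {
  cat(sprintf("bias^2 %.6g + variance %.6g = MSE %.6g\n",
              x$bias_sq, x$variance, x$mse))
  invisible(x)
}
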