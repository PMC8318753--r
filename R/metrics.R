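#' Dice overlap index
#'
#' `2|A intersect B| / (|A| + |B|)`, the standard overlap score in \[0, 1\]
#' between a reference mask A and a predicted mask B. The variant that
#' divides by `|A union B|` instead (twice the Jaccard index, which exceeds
#' 1 for well-overlapping masks) is available via
#' `denominator = "union"`. Two empty masks score 1 by convention.
#'
#' @param A Reference binary mask.
#' @param B Predicted binary mask, same shape.
#' @param denominator `"sum"` (default, standard Dice) or `"union"`.
#' @return Scalar overlap score.
#' @export
dice <- function(A, B, denominator = c("sum", "union")) {
  denominator <- match.arg(denominator)
  check_binary_mask(A, "A"); check_binary_mask(B, "B")
  check_same_shape(A, B, c("A", "B"))
  inter <- sum(A == 1 & B == 1)
  den <- if (denominator == "sum") sum(A) + sum(B) else sum(A == 1 | B == 1)
  if (den == 0) return(1)
  2 * inter / den
}

#' Sensitivity of a segmentation
#'
#' `|A intersect B| / |B|` with A the reference ("gold standard") mask and
#' B the prediction — the fraction of predicted pixels that are truly
#' target (the positive predictive fraction under these roles). The
#' conventional sensitivity `|A intersect B| / |A|` is reported alongside
#' by [evaluate_masks()] as `se_std`.
#'
#' @param A Reference binary mask.
#' @param B Predicted binary mask, same shape.
#' @return Scalar in \[0, 1\], or `NA` when `|B| = 0` (undefined).
#' @export
sensitivity <- function(A, B) {
  check_binary_mask(A, "A"); check_binary_mask(B, "B")
  check_same_shape(A, B, c("A", "B"))
  if (sum(B) == 0) return(NA_real_)
  sum(A == 1 & B == 1) / sum(B)
}

#' Specificity of a segmentation
#'
#' `|A1 intersect B1| / |B1|` where A1, B1 are the complements of the
#' reference and prediction — the fraction of predicted-background pixels
#' that are truly background. The conventional specificity
#' `|A1 intersect B1| / |A1|` is reported alongside by [evaluate_masks()]
#' as `sp_std`.
#'
#' @param A Reference binary mask.
#' @param B Predicted binary mask, same shape.
#' @return Scalar in \[0, 1\], or `NA` when `|B1| = 0` (undefined).
#' @export
specificity <- function(A, B) {
  check_binary_mask(A, "A"); check_binary_mask(B, "B")
  check_same_shape(A, B, c("A", "B"))
  b1 <- sum(B == 0)
  if (b1 == 0) return(NA_real_)
  sum(A == 0 & B == 0) / b1
}

#' Mean squared error between two masks (or images)
#'
#' `(1/MN) * sum (f - g)^2`; for binary masks this is exactly the fraction
#' of disagreeing pixels.
#'
#' @param f,g Numeric matrices of identical shape.
#' @return Non-negative scalar.
#' @export
mse <- function(f, g) {
  if (!is.matrix(f) || !is.matrix(g)) stop_invalid("f", "inputs must be matrices")
  check_same_shape(f, g, c("f", "g"))
  mean((f - g)^2)
}

#' Full segmentation-quality report
#'
#' Dice, sensitivity, specificity (both as-defined and conventional
#' variants) and MSE in one report, plus the underlying pixel counts.
#'
#' @param pred Predicted binary mask.
#' @param ref Reference binary mask, same shape.
#' @return An object of class `svml_metrics`: list with `dice`, `se`, `sp`,
#'   `se_std`, `sp_std`, `mse` and counts `n_ref`, `n_pred`, `n_inter`,
#'   `n_pixels`.
#' @export
evaluate_masks <- function(pred, ref) {
  check_binary_mask(pred, "pred"); check_binary_mask(ref, "ref")
  check_same_shape(ref, pred, c("ref", "pred"))
  inter <- sum(ref == 1 & pred == 1)
  a1 <- sum(ref == 0)
  structure(list(
    dice = dice(ref, pred),
    se = sensitivity(ref, pred),
    sp = specificity(ref, pred),
    se_std = if (sum(ref) == 0) NA_real_ else inter / sum(ref),
    sp_std = if (a1 == 0) NA_real_ else sum(ref == 0 & pred == 0) / a1,
    mse = mse(ref, pred),
    n_ref = sum(ref), n_pred = sum(pred), n_inter = inter,
    n_pixels = length(ref)
  ), class = "svml_metrics")
}

#' @export
print.svml_metrics <- function(x, ...) {
  cat(sprintf("Dice %.4f | SE %.4f | SP %.4f | MSE %.4f  (|A|=%d, |B|=%d, |A&B|=%d, %d px)\n",
              x$dice, x$se, x$sp, x$mse, x$n_ref, x$n_pred, x$n_inter,
              x$n_pixels))
  invisible(x)
}
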