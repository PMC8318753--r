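#' Quantize an image into 1-based integer levels
#'
#' Linear min-max binning of intensities into levels `1..levels`. A constant
#' image maps everywhere to level 1; the maximum value maps to level
#' `levels`. Levels are 1-based so that gradient level `j` can enter the
#' small-gradient advantage weight `1/j^2` without division by zero.
#'
#' @param image Numeric matrix of finite intensities.
#' @param levels Number of quantization levels (>= 2).
#' @return Integer matrix of levels, same shape as `image`.
#' @export
quantize <- function(image, levels = 16L) {
  check_gray_image(image)
  check_scalar_number(levels, "levels")
  if (levels < 2) stop_invalid("levels", "must be at least 2")
  levels <- as.integer(levels)
  lo <- min(image); hi <- max(image)
  if (hi == lo) {
    q <- matrix(1L, nrow(image), ncol(image))
  } else {
    q <- floor((image - lo) / (hi - lo) * levels) + 1L
    q[q > levels] <- levels
    storage.mode(q) <- "integer"
  }
  q
}

#' Sobel gradient magnitude
#'
#' 3x3 Sobel magnitude `sqrt(gx^2 + gy^2)` with symmetric (edge-duplicating)
#' border padding.
#'
#' @param image Numeric matrix, at least 3x3.
#' @return Non-negative numeric matrix, same shape.
#' @export
gradient_magnitude <- function(image) {
  check_gray_image(image, min_dim = 3L)
  p <- pad_symmetric(image, 1L)
  nr <- nrow(image); nc <- ncol(image)
  sh <- function(dr, dc) p[(1L + dr):(nr + dr), (1L + dc):(nc + dc), drop = FALSE]
  # column-direction derivative (gx) and row-direction derivative (gy)
  gx <- (sh(0L, 2L) - sh(0L, 0L)) + 2 * (sh(1L, 2L) - sh(1L, 0L)) +
    (sh(2L, 2L) - sh(2L, 0L))
  gy <- (sh(2L, 0L) - sh(0L, 0L)) + 2 * (sh(2L, 1L) - sh(0L, 1L)) +
    (sh(2L, 2L) - sh(0L, 2L))
  sqrt(gx^2 + gy^2)
}

#' Pair of quantized gray-level and gradient-level grids
#'
#' @param gray_q,grad_q Integer matrices of 1-based levels, same shape.
#' @param Lg,Lv Gray and gradient level counts.
#' @return An object of class `quantized_pair`.
#' @export
quantized_pair <- function(gray_q, grad_q, Lg, Lv) {
  check_same_shape(gray_q, grad_q, c("gray_q", "grad_q"))
  if (any(gray_q < 1L) || any(gray_q > Lg))
    stop_invalid("gray_q", sprintf("levels must lie in [1, %d]", Lg))
  if (any(grad_q < 1L) || any(grad_q > Lv))
    stop_invalid("grad_q", sprintf("levels must lie in [1, %d]", Lv))
  structure(list(gray_q = gray_q, grad_q = grad_q,
                 Lg = as.integer(Lg), Lv = as.integer(Lv)),
            class = "quantized_pair")
}

#' Gray-level gradient co-occurrence matrix of one 5x5 window
#'
#' Counts joint occurrences `H(i, j)` of gray level i and gradient level j
#' over the 25 pixels of the symmetric-padded 5x5 window centered at
#' `(row, col)`, plus the normalized probabilities `P = H / 25`.
#'
#' @param pair A [quantized_pair()].
#' @param row,col 1-based center coordinates, inside the image.
#' @return A `glgc_matrix`: list with integer count matrix `H` (Lg x Lv) and
#'   probability matrix `P`.
#' @export
window_glgcm <- function(pair, row, col) {
  stopifnot(inherits(pair, "quantized_pair"))
  nr <- nrow(pair$gray_q); nc <- ncol(pair$gray_q)
  if (row < 1 || row > nr || col < 1 || col > nc)
    stop("window center out of bounds", call. = FALSE)
  gy <- pad_symmetric(pair$gray_q, 2L)
  gv <- pad_symmetric(pair$grad_q, 2L)
  ri <- row:(row + 4L); ci <- col:(col + 4L)
  wi <- gy[ri, ci]; wj <- gv[ri, ci]
  H <- matrix(0L, pair$Lg, pair$Lv)
  for (t in seq_along(wi)) H[wi[t], wj[t]] <- H[wi[t], wj[t]] + 1L
  glgc_matrix(H)
}

#' Construct a GLGC matrix from counts
#'
#' @param H Non-negative integer count matrix.
#' @return A `glgc_matrix` with `H` and `P = H / sum(H)`.
#' @export
glgc_matrix <- function(H) {
  if (!is.matrix(H) || any(H < 0)) stop_invalid("H", "must be a non-negative count matrix")
  total <- sum(H)
  if (total <= 0) stop_invalid("H", "must contain at least one count")
  structure(list(H = H, P = H / total), class = "glgc_matrix")
}

#' Small-gradient advantage of a GLGC matrix
#'
#' `mu1 = sum_ij H(i,j) / j^2 / sum_ij H(i,j)`; heavily weights small
#' gradient levels, so smooth regions score near 1. Always in (0, 1].
#'
#' @param m A `glgc_matrix` (or a raw count matrix).
#' @return Scalar in (0, 1].
#' @export
small_gradient_advantage <- function(m) {
  if (!inherits(m, "glgc_matrix")) m <- glgc_matrix(m)
  j2 <- matrix(seq_len(ncol(m$H))^2, nrow(m$H), ncol(m$H), byrow = TRUE)
  sum(m$H / j2) / sum(m$H)
}

#' Inverse difference moment of a GLGC matrix
#'
#' `mu2 = -sum_ij P(i,j) / (1 + (i - j)^2)`, with the leading minus sign
#' kept as a fixed sign convention of this feature (it is a constant factor
#' that vanishes after feature standardization). Always in [-1, 0).
#'
#' @param m A `glgc_matrix`.
#' @return Scalar in [-1, 0).
#' @export
inverse_difference_moment <- function(m) {
  if (!inherits(m, "glgc_matrix")) m <- glgc_matrix(m)
  if (abs(sum(m$P) - 1) > 1e-9) stop_invalid("P", "must sum to 1")
  i <- matrix(seq_len(nrow(m$P)), nrow(m$P), ncol(m$P))
  j <- matrix(seq_len(ncol(m$P)), nrow(m$P), ncol(m$P), byrow = TRUE)
  -sum(m$P / (1 + (i - j)^2))
}

#' Per-pixel texture feature maps
#'
#' For every pixel, the 4-component feature vector
#' `[gray_q/Lg, grad_q/Lv, mu1, mu2]` where mu1 (small-gradient advantage)
#' and mu2 (inverse difference moment) are computed from the GLGC matrix of
#' the symmetric-padded 5x5 window centered on the pixel. Because both
#' statistics are means of per-pixel window terms (`1/j^2` and
#' `-1/(1+(i-j)^2)`), the maps are computed with a sliding box filter.
#'
#' @param image Numeric matrix, at least 5x5.
#' @param Lg,Lv Gray and gradient quantization levels.
#' @return Numeric array of dim `c(nrow, ncol, 4)`.
#' @export
feature_stack <- function(image, Lg = 16L, Lv = 16L) {
  check_gray_image(image, min_dim = 5L)
  gray_q <- quantize(image, Lg)
  grad_q <- quantize(gradient_magnitude(image), Lv)
  mu1 <- box_mean(1 / grad_q^2, 2L)
  mu2 <- box_mean(-1 / (1 + (gray_q - grad_q)^2), 2L)
  out <- array(0, dim = c(nrow(image), ncol(image), 4L),
               dimnames = list(NULL, NULL, c("gray", "grad", "mu1", "mu2")))
  out[, , 1L] <- gray_q / Lg
  out[, , 2L] <- grad_q / Lv
  out[, , 3L] <- mu1
  out[, , 4L] <- mu2
  out
}

#' Flatten a feature array into a pixels-by-features matrix
#'
#' Rows follow R's column-major linear pixel order, so `fm[i, ]` is the
#' feature vector of pixel `which == i` in the source image.
#'
#' @param fs A feature array from [feature_stack()].
#' @return Numeric matrix, `n_pixels` x 4.
#' @export
feature_matrix <- function(fs) {
  matrix(fs, nrow = prod(dim(fs)[1:2]), ncol = dim(fs)[3],
         dimnames = list(NULL, dimnames(fs)[[3]]))
}
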