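#' RBF kernel between two feature vectors
#'
#' `K(x, x') = exp(-gamma * ||x - x'||^2)`; symmetric, in (0, 1].
#'
#' @param x,x2 Numeric vectors of equal length.
#' @param gamma Positive kernel width parameter.
#' @return Scalar kernel value.
#' @export
rbf_kernel <- function(x, x2, gamma) {
  if (length(x) != length(x2))
    stop_invalid("x2", "dimension mismatch with x")
  check_scalar_number(gamma, "gamma")
  if (gamma <= 0) stop_invalid("gamma", "must be positive")
  exp(-gamma * sum((x - x2)^2))
}

# Full RBF Gram matrix between rows of X and rows of Y.
rbf_kernel_matrix <- function(X, Y, gamma) {
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

#' Train a weighted soft-margin RBF-kernel SVM
#'
#' Solves the kernelized dual
#' `max_a sum(a) - 1/2 sum_ij a_i a_j y_i y_j K(x_i, x_j)` subject to
#' `sum(a_i y_i) = 0` and the per-sample box `0 <= a_i <= C * v_i`, by
#' two-variable (SMO-style) coordinate ascent with maximal-violating-pair
#' selection. Sample weights `v_i` scale each sample's box cap, the standard
#' weighted-SVM construction; `v_i = 0` removes a sample from the problem.
#' The bias is the mean over free support vectors (`0 < a_i < C v_i`), or
#' the midpoint of the KKT bounds when no support vector is free.
#'
#' Features are z-scored with training statistics by default; the statistics
#' are stored in the model and re-applied at prediction time.
#'
#' @param x Numeric matrix, one sample per row.
#' @param y Labels in \{-1, +1\}.
#' @param v Per-sample weights in \[0, 1\]; default all 1 (plain SVM).
#' @param C Regularization parameter (> 0).
#' @param gamma RBF kernel width (> 0).
#' @param standardize Z-score features with training statistics.
#' @param tol Maximal-violating-pair stopping tolerance on the KKT residual.
#' @param max_passes Iteration cap, in multiples of n two-variable updates.
#' @return A list with `model` (class `svml_model`: support vectors `sv`,
#'   multipliers `beta` > 0, labels `sv_y`, `bias`, `gamma`, `C`,
#'   standardization `center`/`scale`, `n_train`, `Ns`) and `report`
#'   (`iterations`, `dual_objective`, `kkt_violation`, `w_t` the
#'   correct-rate discriminant weight `1 - Ns/n`).
#' @export
train_weighted_svm <- function(x, y, v = NULL, C = 10, gamma = 0.5,
                               standardize = TRUE, tol = 1e-3,
                               max_passes = 10) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (!all(is.finite(x))) stop_invalid("x", "features must be finite")
  n <- nrow(x)
  if (n < 2) stop_invalid("x", "need at least 2 samples")
  if (length(y) != n) stop_invalid("y", "length must match rows of x")
  if (!all(y %in% c(-1, 1))) stop_invalid("y", "labels must be -1 or +1")
  if (is.null(v)) v <- rep(1, n)
  if (length(v) != n || any(v < 0) || any(v > 1))
    stop_invalid("v", "weights must lie in [0, 1], one per sample")
  check_scalar_number(C, "C"); if (C <= 0) stop_invalid("C", "must be positive")
  check_scalar_number(gamma, "gamma")
  if (gamma <= 0) stop_invalid("gamma", "must be positive")

  active <- which(v > 0)
  if (length(unique(y[active])) < 2)
    stop("training requires both classes among samples with positive weight",
         call. = FALSE)

  if (standardize) {
    center <- colMeans(x)
    scl <- apply(x, 2L, stats::sd)
    scl[!is.finite(scl) | scl == 0] <- 1
  } else {
    center <- rep(0, ncol(x)); scl <- rep(1, ncol(x))
  }
  xs <- sweep(sweep(x, 2L, center), 2L, scl, "/")

  xa <- xs[active, , drop = FALSE]
  ya <- y[active]
  ub <- C * v[active]
  na <- length(active)
  K <- rbf_kernel_matrix(xa, xa, gamma)

  alpha <- numeric(na)
  grad <- rep(-1, na)                   # gradient of 1/2 a'Qa - sum(a)
  yg <- -ya * grad                      # -y_i * G_i, the violation score
  max_iter <- max(ceiling(max_passes * na), 5000L)
  eps_b <- 1e-12 * C   # bound-membership tolerance against numerical dust
  iter <- 0L
  repeat {
    up <- (ya > 0 & alpha < ub - eps_b) | (ya < 0 & alpha > eps_b)
    lo <- (ya < 0 & alpha < ub - eps_b) | (ya > 0 & alpha > eps_b)
    if (!any(up) || !any(lo)) { m_up <- 0; m_lo <- 0; break }
    m_up <- max(yg[up]); m_lo <- min(yg[lo])
    if (m_up - m_lo <= tol || iter >= max_iter) break
    i <- which(up)[which.max(yg[up])]
    j <- which(lo)[which.min(yg[lo])]

    s <- ya[i] * ya[j]
    eta <- K[i, i] + K[j, j] - 2 * K[i, j]
    if (eta <= 1e-12) eta <- 1e-12
    # Newton step on alpha_j along the equality constraint
    dj <- -ya[j] * (yg[i] - yg[j]) / eta
    if (s > 0) {
      L <- max(0, alpha[i] + alpha[j] - ub[i]); H <- min(ub[j], alpha[i] + alpha[j])
    } else {
      L <- max(0, alpha[j] - alpha[i]); H <- min(ub[j], ub[i] - alpha[i] + alpha[j])
    }
    aj_new <- min(max(alpha[j] + dj, L), H)
    d <- aj_new - alpha[j]
    if (abs(d) < 1e-14) { iter <- iter + 1L; next }
    ai_new <- alpha[i] - s * d
    # snap to the box to keep bound membership exact
    if (ai_new < eps_b) ai_new <- 0
    if (ai_new > ub[i] - eps_b) ai_new <- ub[i]
    if (aj_new < eps_b) aj_new <- 0
    if (aj_new > ub[j] - eps_b) aj_new <- ub[j]
    d <- aj_new - alpha[j]
    dGi <- ai_new - alpha[i]
    alpha[i] <- ai_new; alpha[j] <- aj_new
    grad <- grad + (ya * K[, i]) * (ya[i] * dGi) + (ya * K[, j]) * (ya[j] * d)
    yg <- -ya * grad
    iter <- iter + 1L
  }
  kkt <- max(0, m_up - m_lo)

  free <- alpha > 1e-8 * C & alpha < ub - 1e-8 * C
  bias <- if (any(free)) mean(yg[free]) else (m_up + m_lo) / 2
  dual_obj <- 0.5 * (sum(alpha) - sum(alpha * grad))

  svi <- which(alpha > 1e-8 * C)
  model <- structure(list(
    sv = xa[svi, , drop = FALSE],
    beta = alpha[svi],
    sv_y = ya[svi],
    bias = bias,
    gamma = gamma, C = C,
    center = center, scale = scl,
    n_train = n, Ns = length(svi),
    standardized_sv = TRUE
  ), class = "svml_model")
  report <- list(iterations = iter, dual_objective = dual_obj,
                 kkt_violation = kkt,
                 alpha = alpha, active = active,
                 w_t = correct_rate_weight(length(svi), n))
  list(model = model, report = report)
}

#' SVM discriminant function
#'
#' `f(x) = sum_{i=1..Ns} y_i beta_i K(x, x_i) + c` over the stored support
#' vectors, with `c` the classification threshold (bias).
#'
#' @param model A trained `svml_model`.
#' @param x Numeric vector or matrix of samples in rows (raw feature scale;
#'   the model's standardization is applied internally).
#' @return Numeric decision value(s).
#' @export
decision_function <- function(model, x) {
  stopifnot(inherits(model, "svml_model"))
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  if (ncol(x) != length(model$center))
    stop_invalid("x", sprintf("expected %d features, got %d",
                              length(model$center), ncol(x)))
  xs <- sweep(sweep(x, 2L, model$center), 2L, model$scale, "/")
  if (model$Ns == 0L) return(rep(model$bias, nrow(x)))
  K <- rbf_kernel_matrix(xs, model$sv, model$gamma)
  drop(K %*% (model$sv_y * model$beta)) + model$bias
}

#' Predict class labels
#'
#' `sign(f(x))`, with the tie `f(x) = 0` assigned to the background class
#' (-1) so segmentations are deterministic.
#'
#' @inheritParams decision_function
#' @return Labels in \{-1, +1\}.
#' @export
predict_label <- function(model, x) {
  f <- decision_function(model, x)
  ifelse(f > 0, 1, -1)
}

#' @export
predict.svml_model <- function(object, newdata, type = c("class", "decision"),
                               ...) {
  type <- match.arg(type)
  if (type == "class") predict_label(object, newdata)
  else decision_function(object, newdata)
}

#' @export
print.svml_model <- function(x, ...) {
  cat(sprintf("Weighted RBF-SVM model: %d support vectors (of %d samples), gamma=%g, C=%g, bias=%.4g\n",
              x$Ns, x$n_train, x$gamma, x$C, x$bias))
  invisible(x)
}

#' Correct-rate discriminant weight
#'
#' `w_t = 1 - E(SV)/n`, with the expected support-vector count estimated by
#' the realized count of the trained model. Derives from the leave-one-out
#' bound `E[P(error)] <= E(SV)/n` on the test error of an SVM.
#'
#' @param Ns Support-vector count (or a trained `svml_model`).
#' @param n Training-set size.
#' @return Scalar in \[0, 1\].
#' @export
correct_rate_weight <- function(Ns, n) {
  if (inherits(Ns, "svml_model")) Ns <- Ns$Ns
  check_scalar_number(Ns, "Ns"); check_scalar_number(n, "n")
  if (n <= 0) stop_invalid("n", "must be positive")
  if (Ns < 0 || Ns > n) stop_invalid("Ns", "must lie in [0, n]")
  1 - Ns / n
}

#' Per-sample hinge losses
#'
#' `L_i = max(0, 1 - y_i f(x_i))`, the training error term of each sample
#' under the current discriminant.
#'
#' @param model A trained `svml_model`.
#' @param x Sample matrix (rows) on the raw feature scale.
#' @param y Labels in \{-1, +1\}.
#' @return Non-negative numeric vector.
#' @export
hinge_losses <- function(model, x, y) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (length(y) != nrow(x)) stop_invalid("y", "length must match rows of x")
  pmax(0, 1 - y * decision_function(model, x))
}

# Squared RKHS norm of the decision function,
# ||w||^2 = sum_ij beta_i beta_j y_i y_j K(x_i, x_j) over support vectors.
rkhs_norm_sq <- function(model) {
  if (model$Ns == 0L) return(0)
  K <- rbf_kernel_matrix(model$sv, model$sv, model$gamma)
  cf <- model$sv_y * model$beta
  drop(t(cf) %*% K %*% cf)
}
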