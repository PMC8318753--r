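# Brute-force reference implementations, deliberately naive and independent
# of the vectorized package code paths.

naive_mask_metrics <- function(A, B) {
  nA <- nB <- nAB <- nA1B1 <- ndis <- 0L
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(ncol(A))) {
      a <- A[i, j]; b <- B[i, j]
      if (a == 1) nA <- nA + 1L
      if (b == 1) nB <- nB + 1L
      if (a == 1 && b == 1) nAB <- nAB + 1L
      if (a == 0 && b == 0) nA1B1 <- nA1B1 + 1L
      if (a != b) ndis <- ndis + 1L
    }
  }
  npx <- length(A)
  list(dice = if (nA + nB == 0) 1 else 2 * nAB / (nA + nB),
       se = if (nB == 0) NA_real_ else nAB / nB,
       sp = if (npx - nB == 0) NA_real_ else nA1B1 / (npx - nB),
       mse = ndis / npx,
       n_ref = nA, n_pred = nB, n_inter = nAB)
}

# Symmetric (edge-duplicating) reflection of an out-of-range index.
reflect_idx <- function(i, n) {
  if (i < 1) 1L - i else if (i > n) 2L * n + 1L - i else i
}

naive_window_glgcm <- function(gray_q, grad_q, row, col, Lg, Lv) {
  H <- matrix(0L, Lg, Lv)
  for (dr in -2:2) {
    for (dc in -2:2) {
      r <- reflect_idx(row + dr, nrow(gray_q))
      cc <- reflect_idx(col + dc, ncol(gray_q))
      H[gray_q[r, cc], grad_q[r, cc]] <- H[gray_q[r, cc], grad_q[r, cc]] + 1L
    }
  }
  H
}

naive_mu1 <- function(H) {
  num <- den <- 0
  for (i in seq_len(nrow(H))) {
    for (j in seq_len(ncol(H))) {
      num <- num + H[i, j] / j^2
      den <- den + H[i, j]
    }
  }
  num / den
}

naive_mu2 <- function(P) {
  s <- 0
  for (i in seq_len(nrow(P))) {
    for (j in seq_len(ncol(P))) s <- s - P[i, j] / (1 + (i - j)^2)
  }
  s
}

# Hand-applied 3x3 Sobel stencil at an interior pixel.
hand_sobel <- function(image, r, c) {
  w <- image[(r - 1):(r + 1), (c - 1):(c + 1)]
  gx <- sum(w * matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3))
  gy <- sum(w * matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3))
  sqrt(gx^2 + gy^2)
}

# Independent dual solution of the unweighted SVM QP via kernlab's
# interior-point solver; returns the dual objective value.
qp_dual_objective <- function(X, y, C, gamma) {
  n <- nrow(X)
  K <- exp(-gamma * as.matrix(dist(X))^2)
  Q <- (y %*% t(y)) * K
  sol <- kernlab::ipop(rep(-1, n), Q + diag(1e-10, n), matrix(y, 1), 0,
                       rep(0, n), rep(C, n), 0, sigf = 9)
  a <- kernlab::primal(sol)
  sum(a) - 0.5 * drop(t(a) %*% Q %*% a)
}

# Brute-force point-in-ellipse rasterization of the phantom lung mask.
bruteforce_lung_mask <- function(spec) {
  a <- spec$width / 5; b <- spec$height / 3
  cx <- c(0.27, 0.73) * spec$width; cy <- spec$height / 2
  ncx <- 0.73 * spec$width; ncy <- 0.40 * spec$height
  m <- matrix(0, spec$height, spec$width)
  for (yy in seq_len(spec$height)) {
    for (xx in seq_len(spec$width)) {
      inside <- ((xx - cx[1]) / a)^2 + ((yy - cy) / b)^2 <= 1 ||
        ((xx - cx[2]) / a)^2 + ((yy - cy) / b)^2 <= 1
      if (!inside && spec$nodule_radius > 0)
        inside <- (xx - ncx)^2 + (yy - ncy)^2 <= spec$nodule_radius^2
      m[yy, xx] <- as.numeric(inside)
    }
  }
  m
}

# Two-Gaussian-blob toy set with a fraction of flipped labels.
make_noisy_toy <- function(seed, n = 80, flip = 0.10, sep = 1.2, sd = 1,
                           n_test = 200) {
  set.seed(seed)
  y <- rep(c(-1, 1), each = n / 2)
  X <- matrix(rnorm(n * 2, sd = sd), n) + cbind(sep * y, 0)
  flipped <- sample(n, round(flip * n))
  y_noisy <- y
  y_noisy[flipped] <- -y_noisy[flipped]
  yt <- rep(c(-1, 1), each = n_test / 2)
  Xt <- matrix(rnorm(n_test * 2, sd = sd), n_test) + cbind(sep * yt, 0)
  list(X = X, y = y_noisy, y_clean = y, flipped = flipped, Xt = Xt, yt = yt)
}

# Small separable 2D toy for solver sanity checks.
make_separable_toy <- function(seed, n = 20, sep = 2.5) {
  set.seed(seed)
  y <- rep(c(-1, 1), each = n / 2)
  X <- matrix(rnorm(n * 2, sd = 0.5), n) + cbind(sep * y, 0)
  list(X = X, y = y)
}
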