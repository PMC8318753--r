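test_that("quantization maps endpoints and constants as specified", {
  expect_true(all(quantize(matrix(5, 8, 8), 16) == 1L))
  img <- matrix(0:255, 16, 16)
  q <- quantize(img, 16)
  expect_equal(q[img == 0], 1L)
  expect_equal(q[img == 255], 16L)
  expect_error(quantize(img, 1), "levels")
})

test_that("quantization agrees with a per-pixel binning loop", {
  set.seed(21)
  img <- matrix(rnorm(64, 100, 30), 8, 8)
  q <- quantize(img, 8)
  breaks <- seq(min(img), max(img), length.out = 9)
  for (i in 1:8) for (j in 1:8) {
    expected <- min(8L, max(1L, findInterval(img[i, j], breaks,
                                             rightmost.closed = TRUE)))
    expect_identical(q[i, j], expected)
  }
})

test_that("Sobel gradient magnitude matches the hand-applied stencil", {
  expect_true(all(gradient_magnitude(matrix(7, 6, 6)) == 0))
  set.seed(22)
  img <- matrix(rnorm(100), 10, 10)
  g <- gradient_magnitude(img)
  expect_true(all(g >= 0))
  for (r in c(3, 5, 8)) for (cc in c(2, 6, 9)) {
    expect_equal(g[r, cc], hand_sobel(img, r, cc))
  }
  # vertical step edge: maximal response on the edge columns
  step <- cbind(matrix(0, 8, 4), matrix(10, 8, 4))
  gs <- gradient_magnitude(step)
  expect_equal(which(gs[4, ] == max(gs)), c(4L, 5L))
  expect_equal(max(gs), 40)  # |gx| = 4 * step height
  expect_error(gradient_magnitude(matrix(1, 2, 2)), "image")
})

test_that("window GLGCM counts match a brute-force double loop", {
  # constant gray + zero gradient: all 25 counts in cell (1,1)
  pair0 <- quantized_pair(matrix(1L, 9, 9), matrix(1L, 9, 9), 16L, 16L)
  m0 <- window_glgcm(pair0, 5, 5)
  expect_equal(m0$H[1, 1], 25L)
  expect_equal(sum(m0$H), 25L)

  set.seed(23)
  for (rep in 1:20) {
    gq <- matrix(sample(1:6, 81, replace = TRUE), 9, 9)
    vq <- matrix(sample(1:5, 81, replace = TRUE), 9, 9)
    pair <- quantized_pair(gq, vq, 6L, 5L)
    r <- sample(9, 1); cc <- sample(9, 1)
    m <- window_glgcm(pair, r, cc)
    expect_identical(m$H, naive_window_glgcm(gq, vq, r, cc, 6L, 5L))
    expect_equal(sum(m$H), 25L)
    expect_equal(sum(m$P), 1, tolerance = 1e-12)
  }
  expect_error(window_glgcm(pair0, 0, 5), "out of bounds")
})

test_that("mu1 and mu2 match brute-force summation and stay in range", {
  all_j1 <- matrix(0L, 4, 4); all_j1[2, 1] <- 10L
  expect_equal(small_gradient_advantage(all_j1), 1)
  all_j2 <- matrix(0L, 4, 4); all_j2[3, 2] <- 7L
  expect_equal(small_gradient_advantage(all_j2), 1 / 4)

  diag_m <- diag(4) * 5
  expect_equal(inverse_difference_moment(glgc_matrix(diag_m)), -1)
  off <- matrix(0L, 4, 4); off[1, 2] <- 3L; off[3, 2] <- 2L
  expect_equal(inverse_difference_moment(glgc_matrix(off)), -1 / 2)

  set.seed(24)
  for (rep in 1:30) {
    H <- matrix(rpois(16, 2), 4, 4)
    if (sum(H) == 0) H[1, 1] <- 1L
    m <- glgc_matrix(H)
    mu1 <- small_gradient_advantage(m)
    mu2 <- inverse_difference_moment(m)
    expect_equal(mu1, naive_mu1(H))
    expect_equal(mu2, naive_mu2(m$P))
    expect_true(mu1 > 0 && mu1 <= 1)
    expect_true(mu2 >= -1 && mu2 < 0)
  }
})

test_that("feature stack composes the degenerate constant case", {
  fs <- feature_stack(matrix(3, 8, 8), 16L, 16L)
  expect_equal(dim(fs), c(8, 8, 4))
  expect_true(all(fs[, , 1] == 1 / 16))
  expect_true(all(fs[, , 2] == 1 / 16))
  expect_true(all(fs[, , 3] == 1))
  expect_true(all(fs[, , 4] == -1))
  expect_error(feature_stack(matrix(1, 4, 4)), "image")
})

test_that("feature stack equals independent per-pixel window recomputation", {
  set.seed(25)
  img <- matrix(rnorm(256, 120, 40), 16, 16)
  fs <- feature_stack(img, 8L, 8L)
  gq <- quantize(img, 8L)
  vq <- quantize(gradient_magnitude(img), 8L)
  for (rep in 1:25) {
    r <- sample(16, 1); cc <- sample(16, 1)
    H <- naive_window_glgcm(gq, vq, r, cc, 8L, 8L)
    expect_equal(unname(fs[r, cc, 1]), gq[r, cc] / 8)
    expect_equal(unname(fs[r, cc, 2]), vq[r, cc] / 8)
    expect_equal(unname(fs[r, cc, 3]), naive_mu1(H), tolerance = 1e-12)
    expect_equal(unname(fs[r, cc, 4]), naive_mu2(H / 25), tolerance = 1e-12)
  }
})

test_that("window features are translation invariant in the interior", {
  set.seed(26)
  gq <- matrix(sample(1:8, 144, replace = TRUE), 12, 12)
  vq <- matrix(sample(1:8, 144, replace = TRUE), 12, 12)
  pair <- quantized_pair(gq, vq, 8L, 8L)
  shifted <- quantized_pair(gq[2:12, 2:12], vq[2:12, 2:12], 8L, 8L)
  for (r in 4:8) for (cc in 4:8) {
    expect_identical(window_glgcm(pair, r, cc)$H,
                     window_glgcm(shifted, r - 1, cc - 1)$H)
  }
})
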