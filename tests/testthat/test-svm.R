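test_that("RBF kernel matches its closed form and componentwise oracle", {
  x <- c(1, 2, 3)
  expect_equal(rbf_kernel(x, x, 0.7), 1)
  expect_equal(rbf_kernel(c(0, 0), c(1, 0), log(2)), 0.5)
  set.seed(31)
  for (rep in 1:10) {
    a <- rnorm(5); b <- rnorm(5); g <- runif(1, 0.1, 2)
    manual <- exp(-g * sum(sapply(1:5, function(k) (a[k] - b[k])^2)))
    expect_equal(rbf_kernel(a, b, g), manual)
    expect_equal(rbf_kernel(a, b, g), rbf_kernel(b, a, g))
    expect_true(rbf_kernel(a, b, g) > 0 && rbf_kernel(a, b, g) <= 1)
  }
  expect_error(rbf_kernel(c(1, 2), c(1, 2, 3), 1), "dimension")
})

test_that("wide-margin 4-point problem is solved to QP-oracle accuracy", {
  X <- rbind(c(-2, 0), c(-2, 1), c(2, 0), c(2, 1))
  y <- c(-1, -1, 1, 1)
  fit <- train_weighted_svm(X, y, C = 10, gamma = 0.5, standardize = FALSE)
  expect_equal(predict_label(fit$model, X), y)
  expect_equal(fit$report$dual_objective, qp_dual_objective(X, y, 10, 0.5),
               tolerance = 1e-4)
})

test_that("v = 1 weighting is the identity and v = 0 removes a sample", {
  toy <- make_separable_toy(32)
  f1 <- train_weighted_svm(toy$X, toy$y, v = rep(1, 20), C = 5, gamma = 0.5)
  f2 <- train_weighted_svm(toy$X, toy$y, C = 5, gamma = 0.5)
  expect_equal(f1$report$alpha, f2$report$alpha, tolerance = 1e-6)

  # standardization off so both runs see identical feature statistics
  v <- rep(1, 20); v[3] <- 0
  fw <- train_weighted_svm(toy$X, toy$y, v = v, C = 5, gamma = 0.5,
                           standardize = FALSE)
  fs <- train_weighted_svm(toy$X[-3, ], toy$y[-3], C = 5, gamma = 0.5,
                           standardize = FALSE)
  grid <- as.matrix(expand.grid(seq(-3, 3, length.out = 5),
                                seq(-2, 2, length.out = 5)))
  expect_equal(decision_function(fw$model, grid),
               decision_function(fs$model, grid), tolerance = 1e-6)
})

test_that("decision function equals an independent support-vector loop", {
  toy <- make_separable_toy(33)
  fit <- train_weighted_svm(toy$X, toy$y, C = 10, gamma = 0.8)
  m <- fit$model
  set.seed(33)
  for (rep in 1:10) {
    x <- rnorm(2)
    xs <- (x - m$center) / m$scale
    f_manual <- m$bias
    for (i in seq_len(m$Ns)) {
      f_manual <- f_manual +
        m$sv_y[i] * m$beta[i] * exp(-m$gamma * sum((xs - m$sv[i, ])^2))
    }
    expect_equal(decision_function(m, x), f_manual, tolerance = 1e-12)
  }
  expect_error(decision_function(m, c(1, 2, 3)), "features")
})

test_that("prediction uses sign with the f = 0 tie broken to background", {
  m <- structure(list(sv = matrix(0, 0, 2), beta = numeric(0),
                      sv_y = numeric(0), bias = 0, gamma = 1, C = 1,
                      center = c(0, 0), scale = c(1, 1), n_train = 2L,
                      Ns = 0L, standardized_sv = TRUE),
                 class = "svml_model")
  expect_equal(decision_function(m, c(5, 5)), 0)  # degenerate: f(x) = bias
  expect_equal(predict_label(m, c(5, 5)), -1)
  m$bias <- 0.3
  expect_equal(predict_label(m, c(5, 5)), 1)
})

test_that("hinge losses equal elementwise recomputation and the KKT margin holds", {
  toy <- make_separable_toy(34)
  fit <- train_weighted_svm(toy$X, toy$y, C = 10, gamma = 0.5)
  L <- hinge_losses(fit$model, toy$X, toy$y)
  f <- decision_function(fit$model, toy$X)
  for (i in seq_along(L)) expect_equal(L[i], max(0, 1 - toy$y[i] * f[i]))
  expect_true(all(L >= 0))
  # non-bound support vectors sit on the margin
  a_full <- numeric(20); a_full[fit$report$active] <- fit$report$alpha
  free <- a_full > 1e-6 & a_full < 10 - 1e-6
  expect_true(all(toy$y[free] * f[free] >= 1 - 1e-3))
})

test_that("correct-rate weight is 1 - Ns/n with validated inputs", {
  expect_equal(correct_rate_weight(3, 10), 0.7)
  expect_equal(correct_rate_weight(0, 10), 1)
  expect_equal(correct_rate_weight(10, 10), 0)
  expect_error(correct_rate_weight(3, 0), "n")
  expect_error(correct_rate_weight(11, 10), "Ns")
})

test_that("dual feasibility and KKT hold on randomized toys", {
  set.seed(35)
  for (rep in 1:8) {
    n <- sample(10:30, 1)
    X <- matrix(rnorm(n * 3), n)
    y <- sample(c(-1, 1), n, replace = TRUE)
    while (length(unique(y)) < 2) y <- sample(c(-1, 1), n, replace = TRUE)
    X[, 1] <- X[, 1] + 1.2 * y
    C <- sample(c(1, 10), 1)
    v <- round(runif(n, 0.5, 1), 2)
    fit <- train_weighted_svm(X, y, v = v, C = C, gamma = 0.5,
                              standardize = FALSE)
    a <- fit$report$alpha
    expect_lte(abs(sum(a * y)), 1e-6 * max(sum(a), 1))
    expect_true(all(a >= -1e-12 & a <= C * v + 1e-9))
    expect_lte(fit$report$kkt_violation, 1e-3)
  }
})

test_that("training hinge loss is non-increasing in C on fixed data", {
  toy <- make_noisy_toy(36, n = 40)
  losses <- sapply(c(0.1, 1, 10, 100), function(C) {
    fit <- train_weighted_svm(toy$X, toy$y, C = C, gamma = 0.5)
    sum(hinge_losses(fit$model, toy$X, toy$y))
  })
  expect_true(all(diff(losses) <= 1e-6))
})

test_that("degenerate training inputs raise typed errors", {
  X <- matrix(rnorm(10), 5)
  expect_error(train_weighted_svm(X, rep(1, 5)), "both classes")
  expect_error(train_weighted_svm(X, c(1, 1, 1, 1, -1), v = c(1, 1, 1, 1, 0)),
               "both classes")
  X[2, 1] <- Inf
  expect_error(train_weighted_svm(X, c(1, 1, -1, -1, 1)), "finite")
})
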