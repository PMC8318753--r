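test_that("weight update is the closed-form loss threshold", {
  L <- c(0.2, 1.5, 0.9)
  expect_equal(update_sample_weights(L, 1.0), c(1, 0, 1))
  expect_equal(update_sample_weights(L, 2.0), c(1, 1, 1))   # lambda > max(L)
  expect_equal(update_sample_weights(L, 0.2), c(0, 0, 0))   # lambda <= min(L)
  expect_error(update_sample_weights(c(-0.1, 1), 1), "losses")
  expect_error(update_sample_weights(L, 0), "lambda")
})

test_that("included set grows monotonically with lambda at fixed losses", {
  set.seed(41)
  L <- rexp(50)
  lams <- sort(runif(10, 0.01, 3))
  counts <- sapply(lams, function(l) sum(update_sample_weights(L, l)))
  expect_true(all(diff(counts) >= 0))
  # nesting, not just counts
  v_prev <- update_sample_weights(L, lams[1])
  for (l in lams[-1]) {
    v <- update_sample_weights(L, l)
    expect_true(all(v >= v_prev))
    v_prev <- v
  }
})

test_that("objective value equals brute-force triple summation", {
  toy <- make_separable_toy(42, n = 12)
  fit <- train_weighted_svm(toy$X, toy$y, C = 2, gamma = 0.5)
  m <- fit$model
  v <- rep(c(1, 0), 6)
  lambda <- 0.7; eta <- 0.25
  L <- hinge_losses(m, toy$X, toy$y)
  wsq <- 0
  for (i in seq_len(m$Ns)) for (j in seq_len(m$Ns)) {
    wsq <- wsq + m$beta[i] * m$beta[j] * m$sv_y[i] * m$sv_y[j] *
      exp(-m$gamma * sum((m$sv[i, ] - m$sv[j, ])^2))
  }
  manual <- sum(v * L) + eta * wsq - lambda * sum(v)
  expect_equal(objective_value(m, toy$X, toy$y, v, lambda, eta), manual,
               tolerance = 1e-10)
  # stated degenerate forms
  expect_equal(objective_value(m, toy$X, toy$y, rep(0, 12), lambda, eta),
               eta * wsq)
  expect_equal(objective_value(m, toy$X, toy$y, rep(1, 12), 0, eta),
               sum(L) + eta * wsq)
})

test_that("a pace threshold above every warm-up loss degenerates to the plain SVM", {
  toy <- make_noisy_toy(43, n = 40)
  plain <- train_weighted_svm(toy$X, toy$y, C = 10, gamma = 0.5)
  cfg <- self_paced_config(lambda0 = 100, max_rounds = 5, C = 10, gamma = 0.5)
  sp <- self_paced_train(toy$X, toy$y, cfg)
  expect_true(all(sp$state$v == 1))
  expect_equal(sp$report$alpha, plain$report$alpha, tolerance = 1e-6)
})

test_that("objective trace does not increase across alternation half-steps", {
  toy <- make_noisy_toy(44, n = 60)
  cfg <- self_paced_config(lambda0 = 0.5, growth = 1.4, max_rounds = 6,
                           C = 10, gamma = 0.5)
  sp <- suppressWarnings(self_paced_train(toy$X, toy$y, cfg))
  tr <- sp$state$objective_trace
  expect_equal(length(tr) %% 2, 0)
  # v-update half-step at fixed model and lambda
  for (k in seq(1, length(tr), by = 2)) {
    expect_lte(tr[k + 1], tr[k] + 1e-8)
  }
  # included-sample count non-decreasing across rounds
  expect_true(all(diff(sp$state$history$n_included) >= 0))
})

test_that("retraining at fixed weights does not increase the objective", {
  toy <- make_noisy_toy(45, n = 50)
  warm <- train_weighted_svm(toy$X, toy$y, C = 10, gamma = 0.5)
  L <- hinge_losses(warm$model, toy$X, toy$y)
  lambda <- as.numeric(quantile(L, 0.7))
  v <- update_sample_weights(L, lambda)
  refit <- train_weighted_svm(toy$X, toy$y, v = v, C = 10, gamma = 0.5)
  before <- objective_value(warm$model, toy$X, toy$y, v, lambda)
  after <- objective_value(refit$model, toy$X, toy$y, v, lambda)
  expect_lte(after, before + 1e-3 * (1 + abs(before)))
})

test_that("curriculum excludes mislabeled points while keeping clean ones", {
  cfg <- self_paced_config(lambda0 = 0.5, growth = 1.3, max_rounds = 5,
                           C = 10, gamma = 0.5)
  for (seed in 1:3) {
    toy <- make_noisy_toy(seed, n = 80, flip = 0.10, sep = 2, sd = 0.8)
    sp <- suppressWarnings(self_paced_train(toy$X, toy$y, cfg))
    expect_gte(mean(sp$state$v[toy$flipped] == 0), 0.5)
    expect_gte(mean(sp$state$v[-toy$flipped] == 1), 0.95)
  }
})

test_that("an all-excluding pace threshold falls back to v = 1 with a warning", {
  toy <- make_noisy_toy(46, n = 30)
  # tiny C keeps every sample inside the margin, so no loss is below lambda0
  cfg <- self_paced_config(lambda0 = 1e-8, growth = 1.01, max_rounds = 1,
                           C = 0.01, gamma = 0.5)
  expect_warning(self_paced_train(toy$X, toy$y, cfg), "degenerate")
})
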