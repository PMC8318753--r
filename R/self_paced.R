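#' Self-paced configuration
#'
#' Parameters of the self-paced curriculum wrapped around the weighted SVM.
#' The regularized objective being alternated is
#' `sum_i v_i L_i + eta * ||w||^2 - lambda * sum_i v_i` over the model and
#' the binary sample weights `v`: the hard self-paced regularizer, whose
#' v-step has the closed form `v_i = 1(L_i < lambda)`.
#'
#' @param lambda0 Initial pace threshold in hinge-loss units; `NULL` (the
#'   default) uses the 60th percentile of the warm-up losses.
#' @param growth Multiplicative lambda growth per outer round (> 1).
#' @param eta Structural-risk weight on `||w||^2`; mapped onto the SVM
#'   trade-off as `C = 1 / (2 * eta * n)` so a single knob controls both.
#'   Ignored when `C` is given explicitly.
#' @param max_rounds Maximum outer rounds.
#' @param C,gamma Inner SVM hyperparameters; `C = NULL` derives C from
#'   `eta`.
#' @param seed Integer seed (reserved for stochastic inner steps; the
#'   curriculum itself is deterministic).
#' @return An object of class `self_paced_config`.
#' @export
self_paced_config <- function(lambda0 = NULL, growth = 1.5, eta = NULL,
                              max_rounds = 10L, C = 10, gamma = 0.5,
                              seed = 1L) {
  if (!is.null(lambda0)) {
    check_scalar_number(lambda0, "lambda0")
    if (lambda0 <= 0) stop_invalid("lambda0", "must be positive")
  }
  check_scalar_number(growth, "growth")
  if (growth <= 1) stop_invalid("growth", "must exceed 1")
  check_scalar_number(max_rounds, "max_rounds")
  if (max_rounds < 1) stop_invalid("max_rounds", "must be at least 1")
  if (is.null(C)) {
    if (is.null(eta)) stop_invalid("C", "give either C or eta")
    check_scalar_number(eta, "eta")
    if (eta <= 0) stop_invalid("eta", "must be positive")
  }
  structure(list(lambda0 = lambda0, growth = growth, eta = eta,
                 max_rounds = as.integer(max_rounds), C = C, gamma = gamma,
                 seed = as.integer(seed)),
            class = "self_paced_config")
}

#' Closed-form self-paced weight update
#'
#' Minimizer of `sum_i v_i L_i - lambda * sum_i v_i` over `v in [0,1]^n`:
#' `v_i = 1` iff `L_i < lambda`, else 0 (samples with loss below the pace
#' threshold are "easy" and admitted).
#'
#' @param losses Non-negative per-sample losses.
#' @param lambda Positive pace threshold.
#' @return 0/1 weight vector.
#' @export
update_sample_weights <- function(losses, lambda) {
  if (any(losses < 0)) stop_invalid("losses", "must be non-negative")
  check_scalar_number(lambda, "lambda")
  if (lambda <= 0) stop_invalid("lambda", "must be positive")
  as.numeric(losses < lambda)
}

#' Self-paced regularized objective
#'
#' `sum_i v_i L_i + eta * ||w||^2 - lambda * sum_i v_i`, where `||w||^2` is
#' the squared RKHS norm of the decision function evaluated on the support
#' vectors and the last term is the hard self-paced regularizer.
#'
#' @param model A trained `svml_model`.
#' @param x,y Training samples and labels.
#' @param v Binary sample weights.
#' @param lambda Pace threshold.
#' @param eta Weight on `||w||^2`; defaults to `1/(2C)` of the model, the
#'   scaling under which SVM retraining at fixed `v` minimizes this
#'   objective.
#' @return Scalar objective value.
#' @export
objective_value <- function(model, x, y, v, lambda, eta = NULL) {
  stopifnot(inherits(model, "svml_model"))
  if (!all(v %in% c(0, 1))) stop_invalid("v", "weights must be binary")
  if (is.null(eta)) eta <- 1 / (2 * model$C)
  L <- hinge_losses(model, x, y)
  if (length(v) != length(L)) stop_invalid("v", "length must match samples")
  sum(v * L) + eta * rkhs_norm_sq(model) - lambda * sum(v)
}

#' Train an SVM under a self-paced curriculum
#'
#' Alternating minimization of the self-paced objective: (i) train the
#' weighted SVM at the current sample weights `v`; (ii) recompute hinge
#' losses; (iii) re-admit samples with loss below the pace threshold
#' `lambda`; (iv) grow `lambda`. Initial weights come from an unweighted
#' warm-up fit thresholded at `lambda0`. Inclusion is monotone: a sample
#' once admitted stays admitted, so the curriculum only ever grows. The
#' loop stops when every sample is included and the weights are stable, or
#' after `max_rounds` rounds. A round whose weight vector is degenerate
#' (all zero, or only one class included) falls back to `v = 1` for that
#' round's fit, with a warning.
#'
#' @param x Sample matrix (rows) of features.
#' @param y Labels in \{-1, +1\}.
#' @param config A [self_paced_config()].
#' @param standardize Passed to [train_weighted_svm()].
#' @return A list with `model` (final `svml_model`), `state` (class
#'   `self_paced_state`: final `v`, `lambda_current`, `round`,
#'   `objective_trace` with one value per completed half-step, and a
#'   per-round `history` data frame), and `report` of the final fit.
#' @export
self_paced_train <- function(x, y, config = self_paced_config(),
                             standardize = TRUE) {
  if (!is.matrix(x)) x <- as.matrix(x)
  n <- nrow(x)
  C <- config$C
  if (is.null(C)) C <- 1 / (2 * config$eta * n)

  warm <- train_weighted_svm(x, y, v = NULL, C = C, gamma = config$gamma,
                             standardize = standardize)
  losses <- hinge_losses(warm$model, x, y)
  lambda <- config$lambda0
  if (is.null(lambda))
    lambda <- max(stats::quantile(losses, 0.6, names = FALSE), 1e-8)

  v <- update_sample_weights(losses, lambda)
  fit <- warm
  trace <- numeric(0)
  history <- NULL
  for (round in seq_len(config$max_rounds)) {
    v_fit <- v
    if (sum(v_fit) == 0 || length(unique(y[v_fit > 0])) < 2) {
      warning(sprintf("round %d: degenerate sample weights; falling back to v = 1",
                      round))
      v_fit <- rep(1, n)
    }
    fit <- train_weighted_svm(x, y, v = v_fit, C = C, gamma = config$gamma,
                              standardize = standardize)
    trace <- c(trace, objective_value(fit$model, x, y, v_fit, lambda))
    losses <- hinge_losses(fit$model, x, y)
    v_new <- pmax(v, update_sample_weights(losses, lambda))  # monotone inclusion
    trace <- c(trace, objective_value(fit$model, x, y, v_new, lambda))
    history <- rbind(history,
                     data.frame(round = round, lambda = lambda,
                                n_included = sum(v_new),
                                objective = trace[length(trace)]))
    if (all(v_new == 1) && all(v_new == v)) { v <- v_new; break }
    v <- v_new
    lambda <- lambda * config$growth
  }
  state <- structure(list(v = v, lambda_current = lambda, round = round,
                          objective_trace = trace, history = history),
                     class = "self_paced_state")
  list(model = fit$model, state = state, report = fit$report)
}
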