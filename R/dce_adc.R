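#' Percent enhancement of a time-signal curve
#'
#' `E(t) = 100 * (S(t) - S_pre) / S_pre` with `S_pre` the mean of the
#' pre-contrast baseline samples.
#'
#' @param curve A `time_signal_curve`.
#' @return Numeric vector of percent enhancement, one value per sample.
#' @export
percent_enhancement <- function(curve) {
  stopifnot(inherits(curve, "time_signal_curve"))
  s_pre <- mean(curve$signal[seq_len(curve$baseline_index_count)])
  if (s_pre <= 0) stop_invalid("curve", "baseline signal must be positive")
  100 * (curve$signal - s_pre) / s_pre
}

#' Steepest slope of an enhancement curve
#'
#' Maximum of the consecutive finite differences `dE/dt` on the
#' percent-enhancement series, in %/s. Invariant to uniform rescaling of
#' the raw signal. Monotonically decreasing curves give a non-positive
#' value.
#'
#' @param curve A `time_signal_curve`.
#' @return Scalar, %/s.
#' @export
steepest_slope <- function(curve) {
  e <- percent_enhancement(curve)
  max(diff(e) / diff(curve$times))
}

#' Washout ratio of an enhancement curve
#'
#' `WR = 100 * (E_peak - E_last) / E_peak` on the percent-enhancement
#' series: the fraction of the peak enhancement lost by the end of the
#' acquisition. Positive for washout curves, near zero for plateaus,
#' negative for persistent enhancement.
#'
#' @param curve A `time_signal_curve`.
#' @return Scalar percentage, or `NA` when the peak enhancement is not
#'   positive (undefined).
#' @export
washout_ratio <- function(curve) {
  e <- percent_enhancement(curve)
  e_peak <- max(e)
  if (e_peak <= 0) return(NA_real_)
  100 * (e_peak - e[length(e)]) / e_peak
}

# Two-segment continuous piecewise-linear fit of enhancement vs time.
# Returns the knee time, fitted enhancement at the knee and at the last
# sample. The knee is chosen by grid search over interior samples.
fit_knee <- function(times, e) {
  n <- length(times)
  best <- NULL; best_rss <- Inf
  for (k in 2:(n - 1)) {
    tau <- times[k]
    hinge <- pmax(times - tau, 0)
    fit <- stats::lm.fit(cbind(1, times, hinge), e)
    rss <- sum(fit$residuals^2)
    if (rss < best_rss) {
      best_rss <- rss
      cf <- fit$coefficients
      best <- list(tau = tau,
                   e_knee = cf[1] + cf[2] * tau,
                   e_last = cf[1] + cf[2] * times[n] +
                     cf[3] * (times[n] - tau))
    }
  }
  best
}

#' Classify an enhancement curve by its late-phase behavior
#'
#' Schaefer-style three-way typing on the relative late change
#' `r = (E_last - E_peak) / E_peak`: `r > +tol/100` is persistent,
#' `|r| <= tol/100` plateau, `r < -tol/100` washout.
#'
#' `E_peak` here is the *initial* peak — the enhancement at the end of the
#' first-pass upstroke — not the global maximum, which for a persistently
#' enhancing curve is simply its last sample and would erase the very
#' signal being typed. Both the initial peak and the late endpoint are read
#' off a continuous two-segment piecewise-linear fit of the enhancement
#' series (knee chosen by grid search), which also averages measurement
#' noise over all samples.
#'
#' @param curve A `time_signal_curve`.
#' @param tol Plateau tolerance band as a percentage of the peak
#'   enhancement (default 10).
#' @return One of `"persistent"`, `"plateau"`, `"washout"`; `NA` if the
#'   peak enhancement is not positive.
#' @export
classify_curve <- function(curve, tol = 10) {
  e <- percent_enhancement(curve)
  if (max(e) <= 0) return(NA_character_)
  kn <- fit_knee(curve$times, e)
  e_peak <- kn$e_knee; e_last <- kn$e_last
  if (e_peak <= 0) {  # degenerate fit; fall back to sample-based reading
    e_peak <- max(e); e_last <- e[length(e)]
  }
  r <- (e_last - e_peak) / e_peak
  if (r > tol / 100) "persistent"
  else if (r >= -tol / 100) "plateau"
  else "washout"
}

#' Full DCE curve quantification
#'
#' @param curve A `time_signal_curve`.
#' @param tol Plateau tolerance, % of peak.
#' @return A list with `ss` (%/s), `wr` (%), `curve_type`, `peak_time` (s)
#'   and `peak_enhancement` (%).
#' @export
dce_params <- function(curve, tol = 10) {
  e <- percent_enhancement(curve)
  k <- which.max(e)
  list(ss = steepest_slope(curve),
       wr = washout_ratio(curve),
       curve_type = classify_curve(curve, tol),
       peak_time = curve$times[k],
       peak_enhancement = e[k])
}

#' Apparent diffusion coefficient from a multi-b-value series
#'
#' Ordinary least-squares fit of the log-linearized mono-exponential model
#' `ln S(b) = ln S0 - b * ADC` over all b values; with exactly two b values
#' this reduces to the closed form `ADC = ln(S1/S2) / (b2 - b1)`.
#'
#' @param series A `dwi_series` (fields `b_values`, `signals`), or a list
#'   with those names.
#' @return A list with `adc` (mm^2/s), `s0_fit` (a.u.) and `r_squared`
#'   (1 by construction for two points).
#' @export
compute_adc <- function(series) {
  b <- series$b_values; s <- series$signals
  if (length(b) < 2) stop_invalid("b_values", "need at least 2 b values")
  if (any(diff(b) <= 0)) stop_invalid("b_values", "must be strictly increasing")
  if (any(!is.finite(s)) || any(s <= 0))
    stop_invalid("signals", "all signals must be positive and finite")
  fit <- stats::lm(log(s) ~ b)
  r2 <- if (length(b) == 2) 1 else
    suppressWarnings(summary(fit)$r.squared)  # silences the perfect-fit note
  list(adc = -unname(stats::coef(fit)[2]),
       s0_fit = exp(unname(stats::coef(fit)[1])),
       r_squared = r2)
}
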