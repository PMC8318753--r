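#' Specification of a synthetic lung-slice phantom
#'
#' Describes a 2D grayscale phantom containing two bright elliptical "lung
#' fields" on a darker background, with optional in-lung texture, Gaussian
#' noise and a nodule disc. The phantom stands in for clinical slices in
#' tests and benchmarks; by convention the lung fields are rendered
#' *brighter* than the background (real MR lung parenchyma is dark — swap
#' the two intensities to emulate that polarity).
#'
#' @param height,width Image size in pixels (each at least 32).
#' @param lung_intensity,background_intensity Mean gray values of the two
#'   classes on an arbitrary 0-255 scale.
#' @param noise_sigma Standard deviation of the additive Gaussian noise, in
#'   gray-value units. Also scales the in-lung texture (amplitude
#'   `noise_sigma/2`).
#' @param texture_scale Correlation length, in pixels, of the smoothed
#'   in-lung texture field.
#' @param nodule_radius Radius in pixels of a nodule disc placed in the
#'   right lung field; 0 disables the nodule. Must be below
#'   `min(height, width)/4`.
#' @param seed Integer seed; identical spec + seed gives bit-identical output.
#'
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(height = 128L, width = 128L,
                         lung_intensity = 200, background_intensity = 50,
                         noise_sigma = 10, texture_scale = 5L,
                         nodule_radius = 0L, seed = 1L) {
  check_scalar_number(height, "height"); check_scalar_number(width, "width")
  if (height < 32 || width < 32)
    stop_invalid("height/width", "phantom must be at least 32x32")
  check_scalar_number(lung_intensity, "lung_intensity")
  check_scalar_number(background_intensity, "background_intensity")
  check_scalar_number(noise_sigma, "noise_sigma")
  if (noise_sigma < 0) stop_invalid("noise_sigma", "must be non-negative")
  check_scalar_number(texture_scale, "texture_scale")
  if (texture_scale < 1) stop_invalid("texture_scale", "must be at least 1 pixel")
  check_scalar_number(nodule_radius, "nodule_radius")
  if (nodule_radius < 0 || nodule_radius >= min(height, width) / 4)
    stop_invalid("nodule_radius", "must be in [0, min(height,width)/4)")
  check_scalar_number(seed, "seed")
  structure(list(height = as.integer(height), width = as.integer(width),
                 lung_intensity = lung_intensity,
                 background_intensity = background_intensity,
                 noise_sigma = noise_sigma,
                 texture_scale = as.integer(texture_scale),
                 nodule_radius = nodule_radius,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Geometry of the two lung ellipses and the nodule, shared with tests.
# Centers sit left/right of the vertical midline; semi-axes width/5 x height/3.
phantom_geometry <- function(spec) {
  list(a = spec$width / 5, b = spec$height / 3,
       cx = c(0.27, 0.73) * spec$width,
       cy = rep(spec$height / 2, 2L),
       nodule_cx = 0.73 * spec$width, nodule_cy = 0.40 * spec$height)
}

#' Generate a synthetic lung-slice image with its ground-truth mask
#'
#' The lung mask is the union of two ellipses (semi-axes `width/5` by
#' `height/3`, centered left and right of the midline) plus an optional
#' nodule disc. Lung pixels are drawn from
#' `N(lung_intensity, noise_sigma)` plus a smoothed texture field of
#' amplitude `noise_sigma/2` (white noise passed through a uniform filter of
#' width `texture_scale`); background pixels from
#' `N(background_intensity, noise_sigma)`. The nodule, when present, is
#' rendered 15% of the class contrast brighter than lung.
#'
#' @param spec A [phantom_spec()].
#' @return A list with components `image` (numeric matrix, class
#'   intensities in arbitrary units) and `mask` (0/1 matrix, 1 = lung).
#' @examples
#' ph <- generate_lung_phantom(phantom_spec(seed = 7))
#' mean(ph$mask)
#' @export
generate_lung_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  g <- phantom_geometry(spec)
  x <- matrix(seq_len(spec$width), spec$height, spec$width, byrow = TRUE)
  y <- matrix(seq_len(spec$height), spec$height, spec$width)
  inside <- ((x - g$cx[1]) / g$a)^2 + ((y - g$cy[1]) / g$b)^2 <= 1 |
    ((x - g$cx[2]) / g$a)^2 + ((y - g$cy[2]) / g$b)^2 <= 1
  nodule <- matrix(FALSE, spec$height, spec$width)
  if (spec$nodule_radius > 0) {
    nodule <- (x - g$nodule_cx)^2 + (y - g$nodule_cy)^2 <= spec$nodule_radius^2
  }
  mask <- (inside | nodule) * 1
  contrast <- spec$lung_intensity - spec$background_intensity
  img <- with_seed(spec$seed, {
    base <- matrix(spec$background_intensity, spec$height, spec$width)
    base[mask == 1] <- spec$lung_intensity
    base[nodule] <- spec$lung_intensity + 0.15 * contrast
    if (spec$noise_sigma > 0) {
      k <- max(1L, (spec$texture_scale - 1L) %/% 2L)
      tex <- box_mean(matrix(stats::rnorm(spec$height * spec$width),
                             spec$height, spec$width), k)
      tex <- tex / stats::sd(tex) * (spec$noise_sigma / 2)
      base[mask == 1] <- base[mask == 1] + tex[mask == 1]
      base <- base + matrix(stats::rnorm(spec$height * spec$width,
                                         sd = spec$noise_sigma),
                            spec$height, spec$width)
    }
    base
  })
  list(image = img, mask = mask)
}

#' Specification of a synthetic enhancement (time-signal) curve
#'
#' A piecewise-linear dynamic contrast-enhancement curve: the signal rises
#' from `baseline_signal` to `baseline_signal * (1 + peak_enhancement)` at
#' `time_to_peak`, then changes linearly by
#' `late_slope_fraction * peak enhancement` over the remaining acquisition.
#' Positive late slopes give persistent curves, near-zero plateaus, negative
#' washout.
#'
#' @param curve_type One of `"persistent"`, `"plateau"`, `"washout"`. Sets
#'   the default `late_slope_fraction` (+0.3, 0, -0.4).
#' @param baseline_signal Pre-contrast signal, arbitrary units (> 0).
#' @param peak_enhancement Peak enhancement as a fraction of baseline.
#' @param time_to_peak Seconds to peak; in (0, `duration`).
#' @param late_slope_fraction Signed fraction of the peak enhancement gained
#'   or lost between the peak and the end of acquisition; `NULL` uses the
#'   `curve_type` default.
#' @param duration Total acquisition time, seconds.
#' @param sampling_interval Sampling interval, seconds.
#' @param noise_sigma Additive Gaussian noise SD, arbitrary units.
#' @param seed Integer seed.
#' @return An object of class `curve_spec`.
#' @export
curve_spec <- function(curve_type = c("persistent", "plateau", "washout"),
                       baseline_signal = 100, peak_enhancement = 0.8,
                       time_to_peak = 60, late_slope_fraction = NULL,
                       duration = 180, sampling_interval = 6,
                       noise_sigma = 0, seed = 1L) {
  curve_type <- match.arg(curve_type)
  if (is.null(late_slope_fraction))
    late_slope_fraction <- switch(curve_type, persistent = 0.3, plateau = 0,
                                  washout = -0.4)
  check_scalar_number(baseline_signal, "baseline_signal")
  if (baseline_signal <= 0) stop_invalid("baseline_signal", "must be positive")
  check_scalar_number(peak_enhancement, "peak_enhancement")
  if (peak_enhancement < 0) stop_invalid("peak_enhancement", "must be non-negative")
  check_scalar_number(time_to_peak, "time_to_peak")
  check_scalar_number(duration, "duration")
  if (time_to_peak <= 0 || time_to_peak >= duration)
    stop_invalid("time_to_peak", "must lie strictly between 0 and duration")
  check_scalar_number(sampling_interval, "sampling_interval")
  if (sampling_interval <= 0) stop_invalid("sampling_interval", "must be positive")
  check_scalar_number(noise_sigma, "noise_sigma")
  if (noise_sigma < 0) stop_invalid("noise_sigma", "must be non-negative")
  structure(list(curve_type = curve_type, baseline_signal = baseline_signal,
                 peak_enhancement = peak_enhancement,
                 time_to_peak = time_to_peak,
                 late_slope_fraction = late_slope_fraction,
                 duration = duration, sampling_interval = sampling_interval,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "curve_spec")
}

#' Generate a synthetic time-signal enhancement curve
#'
#' @param spec A [curve_spec()].
#' @return A `time_signal_curve`: list with `times` (s), `signal` (a.u.) and
#'   `baseline_index_count` (number of pre-contrast samples, here 1).
#' @export
generate_tic <- function(spec) {
  if (!inherits(spec, "curve_spec")) spec <- do.call(curve_spec, spec)
  times <- seq(0, spec$duration, by = spec$sampling_interval)
  s0 <- spec$baseline_signal
  peak <- s0 * spec$peak_enhancement
  late_total <- spec$late_slope_fraction * peak
  up <- times <= spec$time_to_peak
  signal <- numeric(length(times))
  signal[up] <- s0 + peak * times[up] / spec$time_to_peak
  rem <- spec$duration - spec$time_to_peak
  signal[!up] <- s0 + peak + late_total * (times[!up] - spec$time_to_peak) / rem
  if (spec$noise_sigma > 0) {
    signal <- with_seed(spec$seed,
                        signal + stats::rnorm(length(signal),
                                              sd = spec$noise_sigma))
  }
  time_signal_curve(times, signal, baseline_index_count = 1L)
}

#' Construct a time-signal curve object
#'
#' @param times Sample times in seconds, strictly increasing, at least 4.
#' @param signal Signal intensities, arbitrary units.
#' @param baseline_index_count Number of leading pre-contrast samples.
#' @return An object of class `time_signal_curve`.
#' @export
time_signal_curve <- function(times, signal, baseline_index_count = 1L) {
  if (length(times) < 4) stop_invalid("times", "need at least 4 samples")
  if (length(times) != length(signal))
    stop_invalid("signal", "length must match times")
  if (any(diff(times) <= 0)) stop_invalid("times", "must be strictly increasing")
  if (!all(is.finite(times)) || !all(is.finite(signal)))
    stop_invalid("signal", "times and signal must be finite")
  if (baseline_index_count < 1 || baseline_index_count >= length(times))
    stop_invalid("baseline_index_count", "must be in [1, n_samples)")
  structure(list(times = as.numeric(times), signal = as.numeric(signal),
                 baseline_index_count = as.integer(baseline_index_count)),
            class = "time_signal_curve")
}

#' Specification of a synthetic DWI decay
#'
#' Mono-exponential diffusion decay `S(b) = s0 * exp(-b * adc_true)` with
#' additive Gaussian noise.
#'
#' @param s0 Signal at b = 0, arbitrary units (> 0).
#' @param adc_true True apparent diffusion coefficient, mm^2/s (> 0).
#' @param b_values Diffusion weightings, s/mm^2; non-negative, strictly
#'   increasing, at least 2.
#' @param noise_sigma Additive Gaussian noise SD, arbitrary units.
#' @param seed Integer seed.
#' @return An object of class `dwi_spec`.
#' @export
dwi_spec <- function(s0 = 1000, adc_true = 1.0e-3,
                     b_values = c(0, 500, 1000), noise_sigma = 0, seed = 1L) {
  check_scalar_number(s0, "s0")
  if (s0 <= 0) stop_invalid("s0", "must be positive")
  check_scalar_number(adc_true, "adc_true")
  if (adc_true <= 0) stop_invalid("adc_true", "must be positive")
  if (length(b_values) < 2) stop_invalid("b_values", "need at least 2 b values")
  if (any(b_values < 0)) stop_invalid("b_values", "must be non-negative")
  if (any(diff(b_values) <= 0)) stop_invalid("b_values", "must be strictly increasing")
  check_scalar_number(noise_sigma, "noise_sigma")
  if (noise_sigma < 0) stop_invalid("noise_sigma", "must be non-negative")
  structure(list(s0 = s0, adc_true = adc_true, b_values = as.numeric(b_values),
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "dwi_spec")
}

#' Generate a synthetic multi-b-value DWI series
#'
#' @param spec A [dwi_spec()].
#' @return A `dwi_series`: list with `b_values` (s/mm^2) and `signals` (a.u.).
#' @export
generate_dwi <- function(spec) {
  if (!inherits(spec, "dwi_spec")) spec <- do.call(dwi_spec, spec)
  s <- spec$s0 * exp(-spec$b_values * spec$adc_true)
  if (spec$noise_sigma > 0) {
    s <- with_seed(spec$seed, s + stats::rnorm(length(s), sd = spec$noise_sigma))
  }
  structure(list(b_values = spec$b_values, signals = s), class = "dwi_series")
}
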