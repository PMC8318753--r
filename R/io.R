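img_format <- function(path) {
  lower <- tolower(path)
  if (grepl("\\.png$", lower)) "png"
  else if (grepl("\\.nii(\\.gz)?$", lower)) "nifti"
  else stop(sprintf("unsupported image format: '%s' (use .png, .nii or .nii.gz)",
                    path), call. = FALSE)
}

#' Read a 2D grayscale image
#'
#' PNG (8- or 16-bit, rescaled to the 0-255 gray scale; 16-bit depth is
#' preserved in the fractional part) or single-slice NIfTI.
#'
#' @param path Path ending in `.png`, `.nii` or `.nii.gz`.
#' @return Numeric intensity matrix.
#' @export
read_gray_image <- function(path) {
  fmt <- img_format(path)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (fmt == "png") {
    p <- png::readPNG(path)
    if (length(dim(p)) == 3) p <- p[, , 1]  # collapse gray-stored-as-RGB
    p * 255
  } else {
    v <- RNifti::readNifti(path)
    d <- dim(v)
    if (length(d) > 2 && any(d[-(1:2)] > 1))
      stop(sprintf("expected a single-slice NIfTI, got volume of shape %s",
                   paste(d, collapse = "x")), call. = FALSE)
    m <- array(as.numeric(v), dim = d[1:2])
    m
  }
}

#' Write a 2D grayscale image
#'
#' PNG output is 8-bit with intensities clipped to \[0, 255\]; NIfTI keeps
#' the raw values.
#'
#' @param image Numeric intensity matrix.
#' @param path Output path ending in `.png`, `.nii` or `.nii.gz`.
#' @return The path, invisibly.
#' @export
write_gray_image <- function(image, path) {
  check_gray_image(image)
  fmt <- img_format(path)
  if (fmt == "png") {
    png::writePNG(pmin(pmax(image / 255, 0), 1), path)
  } else {
    RNifti::writeNifti(RNifti::asNifti(image), path, datatype = "double")
  }
  invisible(path)
}

#' Write a binary mask
#'
#' Masks are stored as \{0, 255\} 8-bit PNG or \{0, 1\} NIfTI; the
#' roundtrip through [read_mask()] is exact.
#'
#' @param mask Binary 0/1 mask.
#' @param path Output path ending in `.png`, `.nii` or `.nii.gz`.
#' @return The path, invisibly.
#' @export
write_mask <- function(mask, path) {
  check_binary_mask(mask)
  fmt <- img_format(path)
  if (fmt == "png") png::writePNG(mask, path)
  else RNifti::writeNifti(RNifti::asNifti(mask), path, datatype = "uint8")
  invisible(path)
}

#' Read a binary mask
#'
#' @param path Path to a \{0, 255\} PNG or \{0, 1\} NIfTI mask.
#' @return Binary 0/1 matrix. Files containing other values are rejected.
#' @export
read_mask <- function(path) {
  m <- read_gray_image(path)
  vals <- sort(unique(as.vector(m)))
  ok <- if (img_format(path) == "png") c(0, 255) else c(0, 1)
  bad <- setdiff(vals, ok)
  if (length(bad))
    stop(sprintf("mask is not binary: found value(s) %s",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  (m == max(ok)) * 1
}

#' Write / read a time-signal curve as CSV
#'
#' Two-column CSV with header `time_s,signal`.
#'
#' @param curve A `time_signal_curve`.
#' @param path CSV path.
#' @return The path (write) or a `time_signal_curve` (read).
#' @export
write_tic_csv <- function(curve, path) {
  stopifnot(inherits(curve, "time_signal_curve"))
  utils::write.csv(data.frame(time_s = curve$times, signal = curve$signal),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tic_csv
#' @param baseline_index_count Number of leading pre-contrast samples.
#' @export
read_tic_csv <- function(path, baseline_index_count = 1L) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "signal") %in% names(d)))
    stop("curve CSV must have columns time_s,signal", call. = FALSE)
  time_signal_curve(d$time_s, d$signal, baseline_index_count)
}

#' Write / read a DWI series as CSV
#'
#' Two-column CSV with header `b_value,signal`.
#'
#' @param series A `dwi_series`.
#' @param path CSV path.
#' @return The path (write) or a `dwi_series` (read).
#' @export
write_dwi_csv <- function(series, path) {
  utils::write.csv(data.frame(b_value = series$b_values,
                              signal = series$signals),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dwi_csv
#' @export
read_dwi_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("b_value", "signal") %in% names(d)))
    stop("DWI CSV must have columns b_value,signal", call. = FALSE)
  structure(list(b_values = d$b_value, signals = d$signal),
            class = "dwi_series")
}

#' Save / load a trained SVM model as JSON
#'
#' The `.svml` bundle is a single JSON file holding the kernel and
#' regularization parameters, standardization statistics, support vectors,
#' multipliers, labels and bias.
#'
#' @param model A trained `svml_model`.
#' @param path Output path (conventionally `.svml` or `.json`).
#' @return The path (write) or a `svml_model` (read).
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "svml_model"))
  payload <- list(format = "svml-model", version = 1L,
                  gamma = model$gamma, C = model$C, bias = model$bias,
                  center = model$center, scale = model$scale,
                  n_train = model$n_train, Ns = model$Ns,
                  sv = model$sv, beta = model$beta, sv_y = model$sv_y)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "svml-model"))
    stop("not a svml model bundle", call. = FALSE)
  sv <- p$sv
  if (is.null(dim(sv))) sv <- matrix(sv, nrow = p$Ns)
  structure(list(sv = sv, beta = p$beta, sv_y = p$sv_y, bias = p$bias,
                 gamma = p$gamma, C = p$C, center = p$center,
                 scale = p$scale, n_train = p$n_train, Ns = p$Ns,
                 standardized_sv = TRUE),
            class = "svml_model")
}
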