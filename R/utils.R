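#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stop_invalid <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_scalar_number <- function(x, field, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || (finite && !is.finite(x)))
    stop_invalid(field, "must be a single finite number")
  invisible(x)
}

check_gray_image <- function(image, min_dim = 2L, field = "image") {
  if (!is.matrix(image) || !is.numeric(image))
    stop_invalid(field, "must be a numeric matrix")
  if (nrow(image) < min_dim || ncol(image) < min_dim)
    stop_invalid(field, sprintf("must be at least %dx%d", min_dim, min_dim))
  if (!all(is.finite(image)))
    stop_invalid(field, "all intensities must be finite")
  invisible(image)
}

check_binary_mask <- function(mask, field = "mask") {
  if (!is.matrix(mask) || !is.numeric(mask))
    stop_invalid(field, "must be a numeric matrix")
  if (!all(mask %in% c(0, 1)))
    stop_invalid(field, "values must be 0 or 1")
  invisible(mask)
}

check_same_shape <- function(a, b, fields = c("a", "b")) {
  if (!identical(dim(a), dim(b)))
    stop_invalid(fields[2], sprintf("shape %s does not match %s shape %s",
                                    paste(dim(b), collapse = "x"),
                                    fields[1],
                                    paste(dim(a), collapse = "x")))
  invisible(TRUE)
}

# Symmetric (edge-duplicating) padding by `k` pixels on each side.
pad_symmetric <- function(m, k) {
  nr <- nrow(m); nc <- ncol(m)
  if (k >= nr || k >= nc) stop_invalid("image", "too small for requested padding")
  ri <- c(rev(seq_len(k)), seq_len(nr), nr + 1L - seq_len(k))
  ci <- c(rev(seq_len(k)), seq_len(nc), nc + 1L - seq_len(k))
  m[ri, ci, drop = FALSE]
}

# Mean of each sliding (2k+1)x(2k+1) window over a symmetric-padded matrix,
# returned at the original size. Uses 2D cumulative sums: O(N) in pixels.
box_mean <- function(m, k) {
  p <- pad_symmetric(m, k)
  cp <- apply(apply(p, 2L, cumsum), 1L, cumsum)  # transposed cumulative sum
  cp <- t(cp)
  cp <- rbind(0, cbind(0, cp))
  w <- 2L * k + 1L
  nr <- nrow(m); nc <- ncol(m)
  i1 <- seq_len(nr); i2 <- i1 + w
  j1 <- seq_len(nc); j2 <- j1 + w
  (cp[i2, j2, drop = FALSE] - cp[i1, j2, drop = FALSE] -
     cp[i2, j1, drop = FALSE] + cp[i1, j1, drop = FALSE]) / (w * w)
}
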