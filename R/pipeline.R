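# EBImage returns Image objects; strip back to plain numeric matrices.
as_mat <- function(x) {
  if (inherits(x, "Image")) x <- EBImage::imageData(x)
  if (length(dim(x)) > 2) dim(x) <- dim(x)[1:2]
  storage.mode(x) <- "double"
  x
}

#' Pipeline configuration
#'
#' Parameters of the end-to-end segmentation flow: parenchyma
#' pre-extraction, texture features, pixel SVM, 2D morphological
#' post-processing.
#'
#' @param Lg,Lv Gray / gradient quantization levels.
#' @param C,gamma Inner SVM hyperparameters.
#' @param self_paced Train under the self-paced curriculum (`TRUE`) or as a
#'   plain SVM baseline (`FALSE`).
#' @param sp A [self_paced_config()] (its `C`/`gamma` are overridden by the
#'   values above).
#' @param min_component_px Post-processing: components smaller than this
#'   are removed.
#' @param closing_radius Post-processing disc radius for morphological
#'   closing, pixels.
#' @param roi_dilate Dilation radius, in pixels, applied to the extracted
#'   parenchyma mask to form the working region of interest. The dilated
#'   ring supplies background training pixels and gives the classifier the
#'   boundary band where the actual decisions happen.
#' @param train_fraction Fraction of labeled ROI pixels sampled per class
#'   for training (stratified, seeded).
#' @param max_per_class Cap on sampled training pixels per class per image.
#' @param seed Integer seed for the pixel sampling.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(Lg = 16L, Lv = 16L, C = 10, gamma = 0.5,
                            self_paced = TRUE, sp = self_paced_config(),
                            min_component_px = 50L, closing_radius = 1L,
                            roi_dilate = 4L, train_fraction = 0.1,
                            max_per_class = 500L, seed = 1L) {
  if (min_component_px < 0) stop_invalid("min_component_px", "must be non-negative")
  if (closing_radius < 0) stop_invalid("closing_radius", "must be non-negative")
  if (train_fraction <= 0 || train_fraction > 1)
    stop_invalid("train_fraction", "must lie in (0, 1]")
  sp$C <- C; sp$gamma <- gamma
  structure(list(Lg = as.integer(Lg), Lv = as.integer(Lv), C = C,
                 gamma = gamma, self_paced = isTRUE(self_paced), sp = sp,
                 min_component_px = as.integer(min_component_px),
                 closing_radius = as.integer(closing_radius),
                 roi_dilate = as.integer(roi_dilate),
                 train_fraction = train_fraction,
                 max_per_class = as.integer(max_per_class),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

#' Extract the lung parenchyma region of interest
#'
#' Otsu threshold on intensity (lung assumed the bright class, the phantom
#' convention), keep the two largest connected components that do not touch
#' the image border, and fill interior holes. The result restricts every
#' later pipeline stage.
#'
#' @param image Numeric intensity matrix, at least 32x32.
#' @return Binary 0/1 mask. An image with no candidate component yields an
#'   empty mask with a warning.
#' @export
extract_parenchyma <- function(image) {
  check_gray_image(image, min_dim = 32L)
  lo <- min(image); hi <- max(image)
  if (hi == lo) {
    warning("constant image: no parenchyma candidate found")
    return(matrix(0, nrow(image), ncol(image)))
  }
  img01 <- (image - lo) / (hi - lo)
  th <- EBImage::otsu(EBImage::Image(img01), range = c(0, 1))
  bw <- (img01 > th) * 1
  lab <- as_mat(EBImage::bwlabel(bw))
  nlab <- max(lab)
  if (nlab < 1) {
    warning("no parenchyma candidate found")
    return(matrix(0, nrow(image), ncol(image)))
  }
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  sizes <- tabulate(lab[lab > 0], nbins = nlab)
  sizes[intersect(border, seq_len(nlab))] <- 0L
  keep <- order(sizes, decreasing = TRUE)[1:2]
  keep <- keep[sizes[keep] > 0]
  if (length(keep) == 0) {
    warning("no parenchyma candidate found")
    return(matrix(0, nrow(image), ncol(image)))
  }
  roi <- matrix(as.numeric(lab %in% keep), nrow(lab), ncol(lab))
  as_mat(EBImage::fillHull(roi))
}

dilate_mask <- function(mask, radius) {
  if (radius <= 0) return(mask)
  as_mat(EBImage::dilate(mask, EBImage::makeBrush(2L * radius + 1L, "disc")))
}

#' Fit the segmentation pipeline on labeled image/mask pairs
#'
#' For each training pair: extract the parenchyma ROI, dilate it by
#' `roi_dilate` pixels, compute the 4-component GLGCM feature stack, and
#' sample `train_fraction` of the ROI pixels per class (+1 lung, -1 other;
#' stratified, seeded, capped at `max_per_class`). The pooled pixels train
#' either a self-paced SVM or a plain weighted SVM with `v = 1`.
#'
#' @param images List of intensity matrices (a single matrix is accepted).
#' @param masks List of matching 0/1 ground-truth masks.
#' @param config A [pipeline_config()].
#' @return A trained `svml_model`, with the self-paced state (if any) in
#'   attribute `"self_paced_state"` and the training report in
#'   attribute `"report"`.
#' @export
fit_pipeline <- function(images, masks, config = pipeline_config()) {
  if (is.matrix(images)) images <- list(images)
  if (is.matrix(masks)) masks <- list(masks)
  if (length(images) < 1 || length(images) != length(masks))
    stop_invalid("images", "need matching non-empty image and mask lists")
  xs <- list(); ys <- list()
  for (k in seq_along(images)) {
    img <- images[[k]]; msk <- masks[[k]]
    check_binary_mask(msk); check_same_shape(img, msk, c("image", "mask"))
    roi <- with_stage("extract_parenchyma", extract_parenchyma(img))
    roi_d <- dilate_mask(roi, config$roi_dilate)
    fs <- with_stage("feature_stack", feature_stack(img, config$Lg, config$Lv))
    fm <- feature_matrix(fs)
    idx <- which(roi_d == 1)
    lab <- ifelse(msk[idx] == 1, 1, -1)
    sel <- with_seed(config$seed + k, {
      unlist(lapply(c(-1, 1), function(cls) {
        pool <- idx[lab == cls]
        if (length(pool) == 0) return(integer(0))
        n_take <- min(max(1L, ceiling(config$train_fraction * length(pool))),
                      config$max_per_class, length(pool))
        sample(pool, n_take)
      }))
    })
    if (length(sel) == 0) next
    xs[[k]] <- fm[sel, , drop = FALSE]
    ys[[k]] <- ifelse(msk[sel] == 1, 1, -1)
  }
  x <- do.call(rbind, xs); y <- unlist(ys)
  if (is.null(x) || length(unique(y)) < 2)
    stop("[fit] sampled training pixels contain fewer than two classes",
         call. = FALSE)
  if (config$self_paced) {
    res <- with_stage("self_paced_train", self_paced_train(x, y, config$sp))
    model <- res$model
    attr(model, "self_paced_state") <- res$state
  } else {
    res <- with_stage("train_weighted_svm",
                      train_weighted_svm(x, y, C = config$C,
                                         gamma = config$gamma))
    model <- res$model
  }
  attr(model, "report") <- res$report
  model
}

#' Segment one image with a trained pixel classifier
#'
#' Per-pixel prediction of the SVM inside the dilated parenchyma ROI;
#' pixels outside the ROI are background. Deterministic.
#'
#' @param image Intensity matrix.
#' @param model A trained `svml_model`.
#' @param config A [pipeline_config()].
#' @return Binary 0/1 mask, same shape as `image`.
#' @export
segment_image <- function(image, model, config = pipeline_config()) {
  stopifnot(inherits(model, "svml_model"))
  roi <- with_stage("extract_parenchyma",
                    suppressWarnings(extract_parenchyma(image)))
  out <- matrix(0, nrow(image), ncol(image))
  roi_d <- dilate_mask(roi, config$roi_dilate)
  idx <- which(roi_d == 1)
  if (length(idx) == 0) return(out)
  fs <- with_stage("feature_stack", feature_stack(image, config$Lg, config$Lv))
  fm <- feature_matrix(fs)
  pred <- with_stage("segment", predict_label(model, fm[idx, , drop = FALSE]))
  out[idx] <- as.numeric(pred == 1)
  out
}

#' Morphological post-processing of a predicted mask
#'
#' Closing with a disc of `closing_radius` pixels, interior hole filling,
#' then removal of connected components below `min_component_px`. Never
#' increases the number of connected components.
#'
#' @param mask Binary 0/1 mask.
#' @param config A [pipeline_config()].
#' @return Cleaned binary mask.
#' @export
postprocess_mask <- function(mask, config = pipeline_config()) {
  check_binary_mask(mask)
  if (sum(mask) == 0) return(mask)
  m <- mask
  if (config$closing_radius > 0) {
    kern <- EBImage::makeBrush(2L * config$closing_radius + 1L, "disc")
    m <- as_mat(EBImage::closing(m, kern))
  }
  m <- as_mat(EBImage::fillHull(m))
  if (config$min_component_px > 0) {
    lab <- as_mat(EBImage::bwlabel(m))
    nlab <- max(lab)
    if (nlab > 0) {
      sizes <- tabulate(lab[lab > 0], nbins = nlab)
      drop_ids <- which(sizes < config$min_component_px)
      if (length(drop_ids)) m[lab %in% drop_ids] <- 0
    }
  }
  m
}

#' Run the full segmentation flow on one image
#'
#' Parenchyma extraction, feature stack, SVM pixel classification and 2D
#' morphological post-processing; segmentation metrics are computed when a
#' reference mask is supplied.
#'
#' @param image Intensity matrix.
#' @param model A trained `svml_model`.
#' @param config A [pipeline_config()].
#' @param ref Optional reference 0/1 mask.
#' @return A list with `mask` (post-processed binary mask) and `metrics`
#'   (a `svml_metrics` report, or `NULL` when no reference is given).
#' @export
run_pipeline <- function(image, model, config = pipeline_config(),
                         ref = NULL) {
  raw <- segment_image(image, model, config)
  mask <- with_stage("postprocess", postprocess_mask(raw, config))
  metrics <- if (!is.null(ref)) with_stage("evaluate", evaluate_masks(mask, ref))
  list(mask = mask, metrics = metrics)
}
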