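# Grad-CAM heatmaps and the two region-emphasis statistics:
# size-normalized region activation weight and masking-induced emphasis
# shift (redirection).

#' Grad-CAM heatmap for one image and target class
#'
#' Channel weights are the spatial average of the target-class score
#' gradient with respect to the last convolutional layer's activations;
#' the map is the rectified channel-weighted sum of those activations,
#' bilinearly upsampled to the input grid and min-max scaled to 0-255.
#' A constant pre-scaling map cannot be normalized and is returned as an
#' all-zero, `degenerate`-flagged heatmap.
#'
#' @param model A `face_cnn`.
#' @param image H x W matrix or H x W x C array on the model's input grid.
#' @param target_class 0-based class index (typically the image's true
#'   identity; predicted-class maps are obtained by passing the prediction).
#' @return A `gradcam_heatmap`: `grid` (H x W, 0-255), `target_class`,
#'   `degenerate`; attributes `raw_small` (pre-upsampling, pre-scaling
#'   rectified map), `raw` (upsampled, pre-scaling) and `scores` (class
#'   scores of the forward pass).
#' @export
gradcam <- function(model, image, target_class) {
  stopifnot(inherits(model, "face_cnn"))
  if (!is_count(target_class, 0L) || target_class >= model$config$n_classes)
    stopf("target_class must be a 0-based index below %d",
          model$config$n_classes)
  fwd <- model_forward(model, prepare_batch(list(image), model$config),
                       keep = TRUE)
  hw <- fwd$last_hw
  side <- as.integer(sqrt(hw))
  A <- matrix(fwd$acts[[length(fwd$acts)]][, 1L], nrow = hw)   # hw x cout
  # d score / d A is spatially constant for GAP + fc, so its spatial
  # average (the Grad-CAM channel weight) is fc W row / hw
  alpha <- model$fc$W[target_class + 1L, ] / hw
  raw_small <- matrix(pmax(A %*% alpha, 0), side, side)
  S <- model$config$input_size
  raw <- bilinear_upsample(raw_small, S, S)
  rng <- range(raw)
  degenerate <- (rng[2] - rng[1]) < 1e-12
  grid <- if (degenerate) matrix(0, S, S)
          else (raw - rng[1]) / (rng[2] - rng[1]) * 255
  structure(list(grid = grid, target_class = as.integer(target_class),
                 degenerate = degenerate),
            class = "gradcam_heatmap",
            raw_small = raw_small, raw = raw,
            scores = as.numeric(fwd$scores[, 1L]))
}

#' @export
print.gradcam_heatmap <- function(x, ...) {
  cat(sprintf("gradcam_heatmap: %d x %d, class %d, range [%.1f, %.1f]%s\n",
              nrow(x$grid), ncol(x$grid), x$target_class,
              min(x$grid), max(x$grid),
              if (x$degenerate) " [degenerate: constant map]" else ""))
  invisible(x)
}

#' Size-normalized region emphasis of a heatmap
#'
#' Mean heatmap value over the region's intersection with the grid. Using
#' the mean (not the sum) implements the size normalization: 800- and
#' 400-pixel regions are directly comparable on the 0-255 scale.
#'
#' @param heatmap A [gradcam()] heatmap.
#' @param region A `feature_region`.
#' @return Scalar weight in `[0, 255]`.
#' @export
region_emphasis <- function(heatmap, region) {
  stopifnot(inherits(heatmap, "gradcam_heatmap"),
            inherits(region, "feature_region"))
  ri <- region_index(region, nrow(heatmap$grid), ncol(heatmap$grid))
  if (is.null(ri)) stopf("region does not intersect the heatmap")
  mean(heatmap$grid[ri$rows, ri$cols])
}

#' Masking-induced emphasis shift around a feature
#'
#' `delta` = (region emphasis of the Grad-CAM map of the lesioned image)
#' minus (region emphasis of the intact image's map), both measured over
#' the intact image's feature region. The correctness stratum records
#' whether the lesioned image was still classified correctly.
#'
#' @param model A trained `face_cnn`.
#' @param sample A `face_sample`.
#' @param feature The masked feature whose region is measured (must be in
#'   `lesion$features`).
#' @param lesion A [lesion_spec()] masking `feature`.
#' @param target_class 0-based class for the maps (default: the sample's
#'   identity).
#' @param area_config Target mask areas per feature.
#' @return A `redirection_record`: `feature`, `delta`, `stratum`
#'   (`"true"`/`"false"`), and the two emphasis weights.
#' @export
emphasis_shift <- function(model, sample, feature, lesion,
                           target_class = NULL,
                           area_config = default_areas()) {
  stopifnot(inherits(lesion, "lesion_spec"))
  if (!feature %in% lesion$features)
    stopf("feature '%s' is not lesioned by spec '%s'", feature, lesion$label)
  if (is.null(target_class)) target_class <- sample$identity_id
  region <- sample_regions(sample, feature, area_config)[[1L]]
  h_int <- gradcam(model, sample$image, target_class)
  lesioned <- apply_lesion(sample, lesion, area_config)
  h_les <- gradcam(model, lesioned, target_class)
  w_int <- region_emphasis(h_int, region)
  w_les <- region_emphasis(h_les, region)
  pred <- which.max(attr(h_les, "scores")) - 1L
  structure(list(feature = feature, delta = w_les - w_int,
                 stratum = if (pred == sample$identity_id) "true" else "false",
                 weight_intact = w_int, weight_lesioned = w_les,
                 predicted = pred),
            class = "redirection_record")
}
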