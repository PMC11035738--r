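# Lesion construction and application: exact-area keypoint-anchored
# rectangles, zero-masking, randomized-placement control masks, and
# region-restricted Gaussian blur.
#
# Rectangles are 0-based and half-open: [x0, x0 + width) x [y0, y0 + height).

#' Describe one perturbation condition
#'
#' @param kind One of `"mask"`, `"blur"`, `"random_mask"`, `"none"`.
#' @param features Subset of `c("eyebrows","eyes","nose","mouth")` (ignored
#'   for `"none"`).
#' @param sigma Gaussian kernel SD for `"blur"` (any positive value; the
#'   graded severity levels 1-4 of [blur_sigma_levels()] are 2, 8, 10, 20).
#' @param seed Integer seed for `"random_mask"` placement.
#' @param label Optional condition label (defaults to a canonical one).
#' @return A `lesion_spec`.
#' @export
lesion_spec <- function(kind = c("mask", "blur", "random_mask", "none"),
                        features = character(), sigma = NULL, seed = NULL,
                        label = NULL) {
  kind <- match.arg(kind)
  features <- as.character(features)
  if (kind != "none") {
    if (length(features) == 0L) stopf("%s lesion needs at least one feature", kind)
    bad <- setdiff(features, FEATURES)
    if (length(bad)) stopf("unknown feature name: %s", paste(bad, collapse = ", "))
    features <- FEATURES[FEATURES %in% features]   # canonical order
  }
  if (kind == "blur") {
    if (is.null(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
      stopf("blur lesion needs a single sigma > 0")
  } else sigma <- NULL
  if (kind == "random_mask") {
    if (is.null(seed)) seed <- 0L
    seed <- as.integer(seed)
  } else seed <- NULL
  if (is.null(label)) {
    label <- switch(kind,
      none = "none",
      random_mask = "random",
      mask = paste0("mask_", paste(features, collapse = ".")),
      blur = sprintf("blur_%s_sigma%g", paste(features, collapse = "."), sigma))
  }
  structure(list(kind = kind, features = features, sigma = sigma,
                 seed = seed, label = label),
            class = "lesion_spec")
}

#' @export
print.lesion_spec <- function(x, ...) {
  cat(sprintf("lesion_spec '%s': %s%s%s\n", x$label, x$kind,
              if (length(x$features))
                paste0(" [", paste(x$features, collapse = ", "), "]") else "",
              if (!is.null(x$sigma)) sprintf(", sigma = %g", x$sigma) else ""))
  invisible(x)
}

#' Exact-area rectangular region from feature keypoints
#'
#' Starting from the minimal axis-aligned bounding rectangle of the
#' keypoints, the rectangle is inflated about its center to integer
#' dimensions covering the keypoints with `width * height` equal to
#' `target_area` exactly whenever some covering factorization exists
#' (otherwise the smallest covering area above the target, preferring the
#' aspect ratio closest to the keypoint box). Clipping to the image bounds
#' happens last and is recorded in `actual_area`.
#'
#' @param points Matrix-like set of >= 2 distinct `(x, y)` keypoints,
#'   0-based pixel coordinates.
#' @param target_area Target pixel count (800 default; 400 for eyebrows).
#' @param image_shape `c(H, W)` in pixels.
#' @param feature Optional feature name carried on the region.
#' @return A `feature_region`: `feature`, `x0`, `y0`, `width`, `height`,
#'   `target_area`, `actual_area`, and flags `area_unachievable` (target
#'   smaller than the keypoint box) and `area_inexact`.
#' @export
region_from_keypoints <- function(points, target_area, image_shape,
                                  feature = NA_character_) {
  pts <- as.matrix(points)
  if (ncol(pts) != 2L || nrow(pts) < 2L)
    stopf("points must be an n x 2 matrix with n >= 2")
  if (nrow(unique(pts)) < 2L)
    stopf("degenerate keypoints: all points identical")
  H <- image_shape[1]; W <- image_shape[2]
  if (any(pts[, 1] < 0 | pts[, 1] >= W | pts[, 2] < 0 | pts[, 2] >= H))
    stopf("keypoints outside the %d x %d image", H, W)
  x0b <- floor(min(pts[, 1])); x1b <- ceiling(max(pts[, 1]))
  y0b <- floor(min(pts[, 2])); y1b <- ceiling(max(pts[, 2]))
  wb <- x1b - x0b + 1L; hb <- y1b - y0b + 1L
  target_area <- as.integer(round(target_area))

  flag_unach <- FALSE
  if (target_area < wb * hb) {
    w <- wb; h <- hb
    flag_unach <- TRUE
  } else {
    # candidate heights: minimal covering width for each, keep the smallest
    # area >= target; among exact hits prefer aspect closest to the
    # keypoint box (matching the inflate-then-trim intent)
    hs <- hb:max(hb, min(H, target_area))
    ws <- pmax(wb, ceiling(target_area / hs))
    keep <- ws <= max(W, wb)        # never propose rects wider than the image
    hs <- hs[keep]; ws <- ws[keep]
    areas <- ws * hs
    best <- which(areas == min(areas))
    if (length(best) > 1L) {
      aspect <- wb / hb
      best <- best[which.min(abs(log(ws[best] / hs[best]) - log(aspect)))]
    }
    w <- ws[best]; h <- hs[best]
  }
  # center on the keypoint box; coverage is guaranteed since w >= wb, h >= hb
  cx <- (x0b + x1b) / 2; cy <- (y0b + y1b) / 2
  x0 <- round(cx - (w - 1) / 2); y0 <- round(cy - (h - 1) / 2)
  x0 <- min(max(x0, x1b - w + 1L), x0b)
  y0 <- min(max(y0, y1b - h + 1L), y0b)
  # clip to image bounds last
  cx0 <- max(x0, 0L); cy0 <- max(y0, 0L)
  cx1 <- min(x0 + w, W); cy1 <- min(y0 + h, H)
  actual <- max(0L, cx1 - cx0) * max(0L, cy1 - cy0)
  structure(list(feature = feature,
                 x0 = as.integer(x0), y0 = as.integer(y0),
                 width = as.integer(w), height = as.integer(h),
                 target_area = target_area, actual_area = as.integer(actual),
                 area_unachievable = flag_unach,
                 area_inexact = (w * h != target_area)),
            class = "feature_region")
}

#' @export
print.feature_region <- function(x, ...) {
  cat(sprintf(
    "feature_region '%s': [%d, %d) x [%d, %d) (%d x %d), target %d, actual %d%s\n",
    x$feature, x$x0, x$x0 + x$width, x$y0, x$y0 + x$height,
    x$width, x$height, x$target_area, x$actual_area,
    if (x$area_unachievable) " [target below keypoint box]" else ""))
  invisible(x)
}

# 1-based R index ranges of rect-image intersection, or NULL if empty.
region_index <- function(region, H, W) {
  rows <- max(region$y0, 0L):min(region$y0 + region$height - 1L, H - 1L)
  cols <- max(region$x0, 0L):min(region$x0 + region$width - 1L, W - 1L)
  if (region$y0 + region$height <= 0L || region$y0 >= H ||
      region$x0 + region$width <= 0L || region$x0 >= W) return(NULL)
  list(rows = rows + 1L, cols = cols + 1L)
}

#' Zero-mask a region of an image
#'
#' Sets every pixel (all channels) inside the rectangle's intersection with
#' the image to zero; all other pixels are untouched. Idempotent.
#'
#' @param image H x W matrix or H x W x C array.
#' @param region A [region_from_keypoints()] rectangle.
#' @return The masked image, same form as the input.
#' @export
apply_mask <- function(image, region) {
  stopifnot(inherits(region, "feature_region"))
  arr <- as_image_array(image)
  ri <- region_index(region, nrow(arr), ncol(arr))
  if (is.null(ri)) stopf("region does not overlap the image")
  arr[ri$rows, ri$cols, ] <- 0
  restore_image_form(arr, image)
}

#' Randomized-placement control masks
#'
#' For each template region, draws a rectangle of identical width and
#' height at a position uniform over all placements fully inside the image
#' (the edge threshold: no clipping), sequentially rejecting placements
#' that overlap an already-placed rectangle (staged randomization).
#' Deterministic given `seed`.
#'
#' @param templates List of `feature_region` templates.
#' @param image_shape `c(H, W)`.
#' @param seed Integer seed.
#' @param max_tries Rejection budget per template.
#' @return List of `feature_region`s (feature = `"random"`).
#' @export
sample_random_regions <- function(templates, image_shape, seed,
                                  max_tries = 1000L) {
  H <- image_shape[1]; W <- image_shape[2]
  for (tp in templates)
    if (tp$width > W || tp$height > H)
      stopf("template %d x %d does not fit in a %d x %d image",
            tp$width, tp$height, H, W)
  overlaps <- function(a, b) {
    a$x0 < b$x0 + b$width && b$x0 < a$x0 + a$width &&
      a$y0 < b$y0 + b$height && b$y0 < a$y0 + a$height
  }
  with_seed(seed, {
    placed <- list()
    for (tp in templates) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        cand <- tp
        cand$feature <- "random"
        cand$x0 <- as.integer(sample.int(W - tp$width + 1L, 1L) - 1L)
        cand$y0 <- as.integer(sample.int(H - tp$height + 1L, 1L) - 1L)
        cand$actual_area <- cand$width * cand$height
        if (!any(vapply(placed, overlaps, logical(1), b = cand))) {
          placed <- c(placed, list(cand)); ok <- TRUE; break
        }
      }
      if (!ok) stopf("could not place a %d x %d random mask in %d tries",
                     tp$width, tp$height, max_tries)
    }
    placed
  })
}

#' Normalized Gaussian convolution kernel
#'
#' Kernel size is `k = 2 * ceiling(3 * sigma) + 1` (3-sigma support);
#' weights follow the isotropic Gaussian density
#' `G(i, j) = exp(-(i^2 + j^2) / (2 sigma^2)) / (2 pi sigma^2)` and are then
#' renormalized to sum to one.
#'
#' @param sigma Kernel standard deviation (> 0).
#' @return A `gaussian_kernel`: `sigma`, `size`, `weights` (k x k), and the
#'   1-D factor `g1d` used by the separable implementation.
#' @export
gaussian_kernel <- function(sigma) {
  if (length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stopf("sigma must be a single positive number")
  k <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  r <- (k - 1L) / 2
  d <- seq(-r, r)
  raw1 <- exp(-d^2 / (2 * sigma^2))
  w <- outer(raw1, raw1) / (2 * pi * sigma^2)
  structure(list(sigma = sigma, size = k, weights = w / sum(w),
                 g1d = raw1 / sum(raw1)),
            class = "gaussian_kernel")
}

#' Region-restricted Gaussian blur
#'
#' Blurs the whole image by convolution with the normalized Gaussian kernel
#' (half-sample symmetric reflective borders), then replaces only the
#' pixels inside the region with their blurred values; everything outside
#' the region is bit-identical to the input.
#'
#' @inheritParams apply_mask
#' @param sigma Kernel standard deviation (> 0).
#' @return The blurred image, same form as the input.
#' @export
blur_region <- function(image, region, sigma) {
  stopifnot(inherits(region, "feature_region"))
  kern <- gaussian_kernel(sigma)
  arr <- as_image_array(image)
  ri <- region_index(region, nrow(arr), ncol(arr))
  if (is.null(ri)) stopf("region does not overlap the image")
  for (ch in seq_len(dim(arr)[3])) {
    blurred <- .sep_conv_reflect(arr[, , ch], kern$g1d)
    arr[ri$rows, ri$cols, ch] <- blurred[ri$rows, ri$cols]
  }
  restore_image_form(arr, image)
}

# Feature regions of a sample for the given features.
sample_regions <- function(sample, features, area_config = default_areas()) {
  missing <- setdiff(features, names(sample$keypoints))
  if (length(missing))
    stopf("sample lacks keypoints for: %s", paste(missing, collapse = ", "))
  shape <- dim(as_image_array(sample$image))[1:2]
  lapply(features, function(f)
    region_from_keypoints(sample$keypoints[[f]], area_config[[f]], shape,
                          feature = f))
}

#' Apply a lesion condition to a face sample
#'
#' Dispatches on the spec kind: keypoint-anchored exact-area zero masks,
#' region-restricted Gaussian blur, randomized-placement control masks
#' (templates matching the sample's own feature regions), or the identity
#' for `kind = "none"`. Multi-feature specs are applied independently per
#' feature.
#'
#' @param sample A `face_sample` (needs keypoints for the spec's features).
#' @param spec A [lesion_spec()].
#' @param area_config Named target areas per feature, see [default_areas()].
#' @return The lesioned image (same form as `sample$image`).
#' @export
apply_lesion <- function(sample, spec, area_config = default_areas()) {
  stopifnot(inherits(spec, "lesion_spec"))
  img <- sample$image
  if (spec$kind == "none") return(img)
  regions <- sample_regions(sample, spec$features, area_config)
  shape <- dim(as_image_array(img))[1:2]
  if (spec$kind == "random_mask")
    regions <- sample_random_regions(regions, shape, spec$seed)
  for (rg in regions) {
    img <- switch(spec$kind,
      mask = , random_mask = apply_mask(img, rg),
      blur = blur_region(img, rg, spec$sigma))
  }
  img
}
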