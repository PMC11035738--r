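# Synthetic face generator: parametric, identity-labelled face-like images
# with ground-truth landmarks for eyebrows, eyes, nose and mouth.
#
# Each identity is a point in a geometric parameter space (brow angle and
# thickness, eye spacing and radius, nose width and length, mouth width and
# curvature, outline axes). Between-identity spread of a feature's
# parameters scales with that feature's `informativeness`, so the amount of
# identity signal carried by each feature is controlled explicitly.
# Within-identity variation comes from geometric jitter and additive pixel
# noise. All coordinates in the public interface are 0-based pixels,
# x = column, origin at the top-left corner.

# Geometry table, units = pixels (angle in radians, curvature in pixels of
# sag) on the reference 112 px canvas. `sd` is the between-identity SD at
# informativeness 1; `jsd` is the within-identity jitter SD at
# within_jitter 1, in the same (absolute) parameter units. Hard bounds
# lo/hi = mean +/- 4.4 sd (the envelope at informativeness 2 with the
# +/-2.2 truncation below) keep every combination renderable with
# disjoint features.
face_param_table <- function() {
  tab <- read.csv(text = "
param,feature,mean,sd,jsd
ax,outline,40,0.8,0.8
ay,outline,50,0.8,0.8
brow_dx,eyebrows,17,0.8,0.6
brow_y,eyebrows,29,0.7,0.6
brow_len,eyebrows,13,1.0,0.8
brow_th,eyebrows,3.2,0.5,0.4
brow_angle,eyebrows,0,0.08,0.06
eye_dx,eyes,17,0.35,0.5
eye_y,eyes,47,0.25,0.4
eye_r,eyes,4.2,0.2,0.3
nose_w,nose,11,1.5,0.8
nose_len,nose,13,0.8,0.7
nose_top,nose,59,0.6,0.5
mouth_w,mouth,24,1.2,1.0
mouth_y,mouth,84,0.7,0.6
mouth_curv,mouth,2,0.5,0.5
mouth_th,mouth,3,0.4,0.4
", stringsAsFactors = FALSE)
  tab$lo <- tab$mean - 4.4 * tab$sd
  tab$hi <- tab$mean + 4.4 * tab$sd
  tab$lo[tab$param == "mouth_curv"] <- 0   # upward-curled mouths collide with the nose
  tab
}

FACE_CX <- 56
FACE_CY <- 58
INK_BG <- 0.30
INK_HAIR <- 0.05
INK_FACE <- 0.75
INK_DARK <- 0.15
INK_NOSE <- 0.30

#' Configuration of the synthetic face generator
#'
#' @param n_identities Number of identities (>= 2).
#' @param images_per_identity Images rendered per identity (>= 2).
#' @param image_size Side of the square canvas in pixels.
#' @param informativeness Named nonnegative vector over
#'   `c("eyebrows","eyes","nose","mouth")`: between-identity SD scale of each
#'   feature's geometry parameters, i.e. how much identity information the
#'   feature carries. Must not be all zero.
#' @param within_jitter Within-identity geometric jitter, as a multiple of
#'   each parameter's unit between-identity SD.
#' @param noise_sd SD of additive pixel noise (intensity units; images are
#'   clipped to `[0, 1]`).
#' @param redundancy In `[0, 1]`: loading of a common per-identity factor
#'   shared by all feature parameters, planting non-independence between
#'   features.
#' @param split_ratio Positive pair, train:validation (default 7:3).
#' @param seed Integer seed; the full dataset is a deterministic function of
#'   the configuration.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_identities = 32L, images_per_identity = 50L,
                             image_size = 112L,
                             informativeness = c(eyebrows = 2, eyes = 1,
                                                 mouth = 0.5, nose = 0.25),
                             within_jitter = 0.5, noise_sd = 0.05,
                             redundancy = 0, split_ratio = c(7, 3),
                             seed = 1L) {
  if (!is_count(n_identities, 2L)) stopf("n_identities must be an integer >= 2")
  if (!is_count(images_per_identity, 2L))
    stopf("images_per_identity must be an integer >= 2")
  if (!is_count(image_size, 32L)) stopf("image_size must be an integer >= 32")
  if (is.null(names(informativeness)) ||
      !setequal(names(informativeness), FEATURES))
    stopf("informativeness must be named with exactly: %s",
          paste(FEATURES, collapse = ", "))
  informativeness <- informativeness[FEATURES]
  if (any(!is.finite(informativeness)) || any(informativeness < 0))
    stopf("informativeness values must be nonnegative")
  if (all(informativeness == 0))
    stopf("informativeness is zero for every feature: no identity signal")
  if (length(within_jitter) != 1L || within_jitter < 0)
    stopf("within_jitter must be a nonnegative scalar")
  if (length(noise_sd) != 1L || noise_sd < 0)
    stopf("noise_sd must be a nonnegative scalar")
  if (length(redundancy) != 1L || redundancy < 0 || redundancy > 1)
    stopf("redundancy must lie in [0, 1]")
  if (length(split_ratio) != 2L || any(split_ratio <= 0))
    stopf("split_ratio must be two positive numbers")
  split_frac <- split_ratio / sum(split_ratio)
  if (!is_count(seed, -2147483646)) stopf("seed must be an integer")
  structure(list(n_identities = as.integer(n_identities),
                 images_per_identity = as.integer(images_per_identity),
                 image_size = as.integer(image_size),
                 informativeness = informativeness,
                 within_jitter = within_jitter, noise_sd = noise_sd,
                 redundancy = redundancy, split_frac = split_frac,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# Truncated standard normal draws (+/- trunc), via the inverse CDF so the
# number of RNG draws is deterministic.
rtruncnorm <- function(n, trunc = 2.2) {
  lo <- stats::pnorm(-trunc)
  stats::qnorm(runif(n, lo, 1 - lo))
}

#' Draw identity-specific geometry parameters
#'
#' Each identity's parameter vector is `mean + informativeness[feature] *
#' sd * z`, with `z` truncated standard normal. With `redundancy` r, the
#' `z` of every feature parameter shares a common per-identity factor with
#' loading r, planting correlated (non-independent) feature information.
#'
#' @param config A [generator_config()].
#' @return List of `identity_params` objects (fields `identity_id`, 0-based,
#'   and the named parameter vector `params`), with the parameter table as
#'   attribute `param_table`.
#' @export
sample_identities <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  tab <- face_param_table()
  npar <- nrow(tab)
  n <- config$n_identities
  r <- config$redundancy
  scale <- ifelse(tab$feature == "outline", 1,
                  config$informativeness[tab$feature])
  ids <- with_seed(derive_seed(config$seed, 101L), {
    u <- rtruncnorm(n)                       # common identity factor
    eps <- matrix(rtruncnorm(n * npar), n, npar)
    z <- r * u + sqrt(1 - r^2) * eps         # recycled u down columns
    lapply(seq_len(n), function(i) {
      p <- tab$mean + scale * tab$sd * z[i, ]
      p <- pmin(pmax(p, tab$lo), tab$hi)
      names(p) <- tab$param
      structure(list(identity_id = i - 1L, params = p),
                class = "identity_params")
    })
  })
  attr(ids, "param_table") <- tab
  ids
}

# -- rendering ---------------------------------------------------------------

# Per-feature ink masks for a parameter vector on an S x S canvas.
# X and Y are 0-based column/row coordinate matrices.
feature_masks <- function(p, S) {
  sc <- S / 112
  X <- matrix(seq_len(S) - 1, S, S, byrow = TRUE)
  Y <- matrix(seq_len(S) - 1, S, S)
  cx <- FACE_CX * sc; cy <- FACE_CY * sc
  q <- as.list(p * sc)
  q$brow_angle <- p[["brow_angle"]]       # angle and curvature don't scale
  q$mouth_curv <- p[["mouth_curv"]] * sc

  outline <- ((X - cx) / q$ax)^2 + ((Y - cy) / q$ay)^2 <= 1
  # dark hair surround (top and sides), so the rendered intensity
  # distribution contains near-black regions as aligned face photos do
  hair <- !outline & Y < cy + 0.25 * q$ay &
    ((X - cx) / (q$ax * 1.22 + 3 * sc))^2 +
      ((Y - cy) / (q$ay * 1.12 + 3 * sc))^2 <= 1

  brow_one <- function(bx, ang) {
    u <- (X - bx) * cos(ang) + (Y - q$brow_y) * sin(ang)
    v <- -(X - bx) * sin(ang) + (Y - q$brow_y) * cos(ang)
    abs(u) <= q$brow_len / 2 & abs(v) <= q$brow_th / 2
  }
  eyebrows <- brow_one(cx - q$brow_dx, q$brow_angle) |
    brow_one(cx + q$brow_dx, -q$brow_angle)

  eye_one <- function(ex) (X - ex)^2 + (Y - q$eye_y)^2 <= q$eye_r^2
  eyes <- eye_one(cx - q$eye_dx) | eye_one(cx + q$eye_dx)

  ny <- Y - q$nose_top
  nose <- ny >= 0 & ny <= q$nose_len &
    abs(X - cx) <= (q$nose_w / 2) * ny / pmax(q$nose_len, 1e-9)
  nostril_one <- function(nx)
    (X - nx)^2 + (Y - (q$nose_top + 0.82 * q$nose_len))^2 <= (1.3 * sc)^2
  nostrils <- nostril_one(cx - q$nose_w / 4) | nostril_one(cx + q$nose_w / 4)
  nose <- nose | nostrils

  t_ <- (X - cx) / (q$mouth_w / 2)
  mouth <- abs(t_) <= 1 &
    abs(Y - (q$mouth_y + q$mouth_curv * t_^2)) <= q$mouth_th / 2

  list(outline = outline, hair = hair, eyebrows = eyebrows, eyes = eyes,
       nose = nose, nostrils = nostrils, mouth = mouth)
}

# Vertical-ordering / containment predicate used to accept a jittered
# parameter vector before rendering (margins in reference pixels).
geometry_valid <- function(p) {
  brow_bottom <- p[["brow_y"]] + p[["brow_th"]] / 2 +
    (p[["brow_len"]] / 2) * abs(sin(p[["brow_angle"]]))
  eye_top <- p[["eye_y"]] - p[["eye_r"]]
  eye_bottom <- p[["eye_y"]] + p[["eye_r"]]
  nose_bottom <- p[["nose_top"]] + p[["nose_len"]]
  mouth_top <- p[["mouth_y"]] + min(p[["mouth_curv"]], 0) - p[["mouth_th"]] / 2
  mouth_bottom <- p[["mouth_y"]] + max(p[["mouth_curv"]], 0) + p[["mouth_th"]] / 2
  inside <- function(x, y, margin = 2) {
    ((x - FACE_CX) / (p[["ax"]] - margin))^2 +
      ((y - FACE_CY) / (p[["ay"]] - margin))^2 <= 1
  }
  # horizontal containment is not enforced for brows/eyes: at extreme
  # geometries a brow tip may graze the hairline, which is harmless (ink
  # masks and keypoints are computed from the drawn geometry either way)
  brow_bottom < eye_top - 0.5 &&
    eye_bottom < p[["nose_top"]] - 0.5 &&
    nose_bottom < mouth_top - 0.5 &&
    inside(FACE_CX + p[["mouth_w"]] / 2, mouth_bottom) &&
    inside(FACE_CX, mouth_bottom)
}

# 5 landmarks from an ink mask: leftmost, rightmost, topmost, bottommost
# (tie-broken by the mean position along the other axis) plus the centroid.
# 0-based (x, y) rows.
keypoints_from_mask <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  ys <- idx[, 1] - 1; xs <- idx[, 2] - 1
  at <- function(x, y) c(x, y)
  xmin <- min(xs); xmax <- max(xs); ymin <- min(ys); ymax <- max(ys)
  kp <- rbind(
    at(xmin, round(mean(ys[xs == xmin]))),
    at(xmax, round(mean(ys[xs == xmax]))),
    at(round(mean(xs[ys == ymin])), ymin),
    at(round(mean(xs[ys == ymax])), ymax),
    at(round(mean(xs)), round(mean(ys))))
  dimnames(kp) <- list(c("left", "right", "top", "bottom", "centroid"),
                       c("x", "y"))
  kp
}

#' Render one face image for an identity
#'
#' Deterministic given `(config$seed, identity_id, draw_index)`. The
#' identity's geometry is perturbed by within-identity jitter (resampled up
#' to 20 times if it breaks the face layout), rendered as flat-shaded
#' geometry on the canvas, and degraded with additive Gaussian pixel noise
#' clipped to `[0, 1]`. Landmarks describe the jittered (actually rendered)
#' geometry.
#'
#' @param identity An `identity_params` from [sample_identities()].
#' @param config The same [generator_config()].
#' @param draw_index Integer >= 1 distinguishing repeated draws.
#' @return A `face_sample`: list with `image` (H x W matrix in `[0, 1]`),
#'   `identity_id`, `keypoints` (named list of 5 x 2 matrices of 0-based
#'   (x, y) pixel coordinates) and `split_tag`.
#' @export
render_face <- function(identity, config, draw_index = 1L) {
  stopifnot(inherits(identity, "identity_params"),
            inherits(config, "generator_config"))
  tab <- face_param_table()
  S <- config$image_size
  with_seed(derive_seed(config$seed, 1000L + identity$identity_id, draw_index), {
    p <- NULL
    for (try in seq_len(20L)) {
      cand <- identity$params +
        config$within_jitter * tab$jsd * rtruncnorm(nrow(tab), trunc = 3)
      if (geometry_valid(cand)) { p <- cand; break }
    }
    # fall back to the identity's unjittered geometry, which the parameter
    # bounds keep renderable except at astronomically unlikely joint extremes
    if (is.null(p) && geometry_valid(identity$params)) p <- identity$params
    if (is.null(p))
      stopf("identity %d, draw %d: jitter kept breaking the face layout",
            identity$identity_id, draw_index)
    masks <- feature_masks(p, S)
    img <- matrix(INK_BG, S, S)
    img[masks$hair] <- INK_HAIR
    img[masks$outline] <- INK_FACE
    img[masks$nose] <- INK_NOSE
    img[masks$nostrils] <- INK_HAIR
    img[masks$eyebrows] <- INK_DARK
    img[masks$eyes] <- INK_DARK
    img[masks$mouth] <- INK_DARK
    if (config$noise_sd > 0)
      img <- img + matrix(rnorm(S * S, 0, config$noise_sd), S, S)
    img <- pmin(pmax(img, 0), 1)
    kp <- lapply(masks[FEATURES], keypoints_from_mask)
    if (any(vapply(kp, is.null, logical(1))))
      stopf("identity %d, draw %d: a feature rendered no ink",
            identity$identity_id, draw_index)
    bboxes <- lapply(masks[FEATURES], function(m) {
      idx <- which(m, arr.ind = TRUE)
      c(xmin = min(idx[, 2]) - 1, xmax = max(idx[, 2]) - 1,
        ymin = min(idx[, 1]) - 1, ymax = max(idx[, 1]) - 1)
    })
    structure(list(image = img, identity_id = identity$identity_id,
                   keypoints = kp, split_tag = NA_character_,
                   draw_index = as.integer(draw_index)),
              class = "face_sample", ink_bboxes = bboxes)
  })
}

# -- dataset assembly --------------------------------------------------------

#' Train/validation counts for a split ratio
#'
#' Deterministic rounding: `train = floor(frac_train * n + 0.5)`.
#'
#' @param n Number of items.
#' @param split_ratio Positive pair, e.g. `c(7, 3)`.
#' @return Named integer vector `c(train =, val =)`.
#' @export
split_counts <- function(n, split_ratio = c(7, 3)) {
  stopifnot(is_count(n), length(split_ratio) == 2L, all(split_ratio > 0))
  fr <- split_ratio[1] / sum(split_ratio)
  tr <- as.integer(floor(fr * n + 0.5))
  c(train = tr, val = as.integer(n) - tr)
}

#' Split indices into train and validation sets
#'
#' @inheritParams split_counts
#' @param seed Integer seed for the shuffle (`NULL` = no shuffle).
#' @return List with integer vectors `train` and `val`.
#' @export
split_indices <- function(n, split_ratio = c(7, 3), seed = NULL) {
  cnt <- split_counts(n, split_ratio)
  perm <- if (is.null(seed)) seq_len(n) else with_seed(seed, sample.int(n))
  list(train = sort(perm[seq_len(cnt["train"])]),
       val = sort(perm[seq_len(cnt["val"]) + cnt["train"]]))
}

#' Generate a complete split dataset of synthetic faces
#'
#' Renders `n_identities * images_per_identity` images and splits each
#' identity's images at `split_ratio` (per-identity stratification, so every
#' identity appears in both splits), with a seeded shuffle within identity.
#'
#' @param config A [generator_config()].
#' @return A `split_dataset`: list with `samples` (list of `face_sample`),
#'   `n_identities`, and the `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  m <- config$images_per_identity
  cnt <- split_counts(m, config$split_frac)
  if (cnt["train"] < 1L || cnt["val"] < 1L)
    stopf("images_per_identity = %d gives an empty split at ratio %.2f:%.2f",
          m, config$split_frac[1], config$split_frac[2])
  ids <- sample_identities(config)
  samples <- vector("list", config$n_identities * m)
  k <- 0L
  for (id in ids) {
    sp <- split_indices(m, config$split_frac,
                        seed = derive_seed(config$seed, 2000L + id$identity_id))
    tags <- character(m)
    tags[sp$train] <- "train"; tags[sp$val] <- "val"
    for (j in seq_len(m)) {
      s <- render_face(id, config, j)
      s$split_tag <- tags[j]
      k <- k + 1L
      samples[[k]] <- s
    }
  }
  structure(list(samples = samples, n_identities = config$n_identities,
                 config = config),
            class = "split_dataset")
}

#' @export
print.split_dataset <- function(x, ...) {
  tags <- vapply(x$samples, `[[`, character(1), "split_tag")
  cat(sprintf("split_dataset: %d samples, %d identities (%d train / %d val)\n",
              length(x$samples), x$n_identities,
              sum(tags == "train"), sum(tags == "val")))
  invisible(x)
}

subset_split <- function(dataset, tag) {
  stopifnot(inherits(dataset, "split_dataset"))
  keep <- vapply(dataset$samples, `[[`, character(1), "split_tag") == tag
  dataset$samples[keep]
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf(paste0("generator_config: %d identities x %d images, %d px, ",
                     "jitter %.2f, noise %.3f, redundancy %.2f, seed %d\n"),
              x$n_identities, x$images_per_identity, x$image_size,
              x$within_jitter, x$noise_sd, x$redundancy, x$seed))
  cat("informativeness:",
      paste(sprintf("%s=%.3g", names(x$informativeness), x$informativeness),
            collapse = ", "), "\n")
  invisible(x)
}

# -- on-disk format ----------------------------------------------------------

#' Write a dataset to disk (PNG + keypoint sidecars + manifest)
#'
#' Images are written as grayscale PNG; keypoints as one JSON sidecar per
#' image mapping feature name to a list of `[x, y]` 0-based pixel
#' coordinates; `manifest.csv` lists `path, keypoint_path, identity, split`.
#'
#' @param dataset A `split_dataset`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest data frame.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "split_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "images"), showWarnings = FALSE)
  rows <- lapply(seq_along(dataset$samples), function(i) {
    s <- dataset$samples[[i]]
    stem <- sprintf("id%04d_%04d", s$identity_id, s$draw_index)
    img_rel <- file.path("images", paste0(stem, ".png"))
    kp_rel <- file.path("images", paste0(stem, ".json"))
    png::writePNG(s$image, file.path(dir, img_rel))
    kp <- lapply(s$keypoints, function(m) unname(as.matrix(m)))
    jsonlite::write_json(kp, file.path(dir, kp_rel), matrix = "rowmajor")
    data.frame(path = img_rel, keypoint_path = kp_rel,
               identity = s$identity_id, split = s$split_tag,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a dataset written by [write_dataset()] (or externally supplied in
#' the same format)
#'
#' @param dir Directory containing `manifest.csv`.
#' @return A `split_dataset` (with `config = NULL` for external data).
#' @export
read_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) stopf("no manifest.csv under %s", dir)
  manifest <- read.csv(mf, stringsAsFactors = FALSE)
  needed <- c("path", "keypoint_path", "identity", "split")
  if (!all(needed %in% names(manifest)))
    stopf("manifest must have columns: %s", paste(needed, collapse = ", "))
  samples <- lapply(seq_len(nrow(manifest)), function(i) {
    f <- file.path(dir, manifest$path[i])
    if (!file.exists(f)) stopf("missing image file: %s", f)
    img <- png::readPNG(f)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    kp_raw <- jsonlite::read_json(file.path(dir, manifest$keypoint_path[i]),
                                  simplifyVector = TRUE)
    kp <- lapply(kp_raw, function(m) {
      m <- matrix(as.numeric(m), ncol = 2)
      colnames(m) <- c("x", "y")
      m
    })
    structure(list(image = img, identity_id = as.integer(manifest$identity[i]),
                   keypoints = kp, split_tag = manifest$split[i],
                   draw_index = i),
              class = "face_sample")
  })
  ids <- sort(unique(vapply(samples, `[[`, integer(1), "identity_id")))
  structure(list(samples = samples, n_identities = length(ids), config = NULL),
            class = "split_dataset")
}
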