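# Experiment orchestration and statistics: the condition grid, paired
# bootstrap accuracy tests, importance ranking, super-additivity,
# error-set overlap, and the emphasis tables.

pair_label <- function(pair) {
  pair <- FEATURES[FEATURES %in% pair]
  paste0("mask_", paste(pair, collapse = "."))
}

#' The full lesion condition grid
#'
#' Enumerates: intact (`none`); the randomized-mask control; each single
#' feature masked; each single feature blurred at every sigma level; all
#' feature pairs masked; and all four features masked. With the defaults
#' this is 1 + 1 + 4 + 16 + 6 + 1 = 29 uniquely labelled conditions.
#'
#' @param features Feature set (default all four).
#' @param sigmas Blur levels (default [blur_sigma_levels()]).
#' @param random_seed Seed of the randomized-mask placements.
#' @param include_random,include_blur,include_pairs,include_all Toggle the
#'   corresponding condition families.
#' @return Named list of [lesion_spec()]s (class `experiment_grid`).
#' @export
experiment_grid <- function(features = FEATURES, sigmas = blur_sigma_levels(),
                            random_seed = 1L, include_random = TRUE,
                            include_blur = TRUE, include_pairs = TRUE,
                            include_all = TRUE) {
  specs <- list(lesion_spec("none"))
  if (include_random)
    specs <- c(specs, list(lesion_spec("random_mask", features,
                                       seed = random_seed)))
  for (f in features) specs <- c(specs, list(lesion_spec("mask", f)))
  if (include_blur)
    for (f in features) for (s in sigmas)
      specs <- c(specs, list(lesion_spec("blur", f, sigma = s)))
  if (include_pairs && length(features) >= 2L) {
    cmb <- utils::combn(features, 2L, simplify = FALSE)
    for (p in cmb) specs <- c(specs, list(lesion_spec("mask", p)))
  }
  if (include_all && length(features) > 1L)
    specs <- c(specs, list(lesion_spec("mask", features, label = "mask_all")))
  labels <- vapply(specs, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stopf("grid labels are not unique")
  names(specs) <- labels
  structure(specs, class = c("experiment_grid", "list"))
}

#' Evaluate a model under every condition of a grid
#'
#' Every condition is scored on the identical validation image set, and
#' the per-image correctness vectors are retained for all downstream
#' statistics.
#'
#' @param model A trained `face_cnn`.
#' @param dataset A `split_dataset` (the `split` tag selects the images).
#' @param grid An [experiment_grid()].
#' @param area_config Target mask areas per feature.
#' @param split Which split to evaluate (default `"val"`).
#' @return Named list of [condition_result()]s, one per condition.
#' @export
run_grid <- function(model, dataset, grid = experiment_grid(),
                     area_config = default_areas(), split = "val") {
  stopifnot(inherits(model, "face_cnn"), inherits(dataset, "split_dataset"))
  samples <- subset_split(dataset, split)
  if (!length(samples)) stopf("dataset has no '%s' split", split)
  res <- lapply(grid, function(spec)
    evaluate_model(model, samples, spec, area_config))
  names(res) <- names(grid)
  attr(res, "n") <- length(samples)
  res
}

#' Paired bootstrap test of an accuracy difference
#'
#' Resamples image indices with replacement `n_iter` times; each
#' replicate's statistic is `accuracy_A - accuracy_B` over the resampled
#' indices (paired: both conditions are evaluated on the same resample).
#' The two-sided p-value is the fraction of replicates on the far side of
#' zero from the observed statistic, with a `+1/(n_iter + 1)` continuity
#' correction; `ci95` is the 2.5/97.5 percentile interval.
#'
#' @param resA,resB [condition_result()]s over the same image set, paired
#'   by index.
#' @param n_iter Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @return A `bootstrap_result`: `statistic`, `n_iter`, `p_value`, `ci95`,
#'   `seed`, and the replicate vector.
#' @export
bootstrap_accuracy_diff <- function(resA, resB, n_iter = 1000L, seed = 1L) {
  stopifnot(inherits(resA, "condition_result"),
            inherits(resB, "condition_result"))
  a <- resA$correct; b <- resB$correct
  if (length(a) != length(b))
    stopf("conditions cover %d vs %d images; they must be paired",
          length(a), length(b))
  n <- length(a)
  reps <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_iter, replace = TRUE), n, n_iter)
    colSums(matrix(a[idx], n)) / n - colSums(matrix(b[idx], n)) / n
  })
  obs <- mean(a) - mean(b)
  extreme <- if (obs >= 0) sum(reps <= 0) else sum(reps >= 0)
  p <- min(1, 2 * (extreme + 1) / (n_iter + 1))
  structure(list(statistic = obs, n_iter = as.integer(n_iter), p_value = p,
                 ci95 = unname(quantile(reps, c(0.025, 0.975))),
                 seed = as.integer(seed), replicates = reps,
                 conditions = c(resA$condition, resB$condition)),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(
    "bootstrap (%d iter): '%s' - '%s' = %+.4f, 95%% CI [%+.4f, %+.4f], p = %.4g\n",
    x$n_iter, x$conditions[1], x$conditions[2], x$statistic,
    x$ci95[1], x$ci95[2], x$p_value))
  invisible(x)
}

#' Rank features by lesion-induced accuracy drop
#'
#' Features are ordered by ascending masked accuracy (a larger drop means
#' a more important feature). Each feature is also tested against the
#' intact condition, and adjacent features in the importance order are
#' tested against each other, by paired bootstrap.
#'
#' @param results A [run_grid()] result list containing `none` and each
#'   `mask_<feature>` condition.
#' @param features Features to rank.
#' @param n_iter,seed Bootstrap settings.
#' @return An `importance_ranking`: `ranking` data frame (importance
#'   order), `order` (feature names, most important first), `vs_none` and
#'   `adjacent` lists of [bootstrap_accuracy_diff()] results.
#' @export
rank_importance <- function(results, features = FEATURES, n_iter = 1000L,
                            seed = 1L) {
  need <- c("none", paste0("mask_", features))
  missing <- setdiff(need, names(results))
  if (length(missing))
    stopf("results lack conditions: %s", paste(missing, collapse = ", "))
  acc <- vapply(features, function(f)
    results[[paste0("mask_", f)]]$accuracy, numeric(1))
  none <- results[["none"]]
  ord <- order(acc)                               # stable for ties
  vs_none <- lapply(features, function(f)
    bootstrap_accuracy_diff(none, results[[paste0("mask_", f)]],
                            n_iter, derive_seed(seed, match(f, features))))
  names(vs_none) <- features
  ranked <- features[ord]
  adjacent <- list()
  if (length(ranked) > 1L)
    adjacent <- lapply(seq_len(length(ranked) - 1L), function(i)
      bootstrap_accuracy_diff(results[[paste0("mask_", ranked[i + 1L])]],
                              results[[paste0("mask_", ranked[i])]],
                              n_iter, derive_seed(seed, 100L + i)))
  ranking <- data.frame(feature = ranked, accuracy = acc[ord],
                        drop = (none$accuracy - acc[ord]) * 100,
                        p_vs_none = vapply(vs_none[ord], `[[`, numeric(1),
                                           "p_value"),
                        row.names = NULL)
  structure(list(ranking = ranking, order = ranked, vs_none = vs_none,
                 adjacent = adjacent, none_accuracy = none$accuracy),
            class = "importance_ranking")
}

#' @export
print.importance_ranking <- function(x, ...) {
  cat("feature importance (largest masking drop first):",
      paste(x$order, collapse = " > "), "\n")
  cat(sprintf("intact accuracy: %.3f\n", x$none_accuracy))
  print(x$ranking, digits = 4)
  invisible(x)
}

#' Super-additivity of a pair of feature lesions
#'
#' Accuracy drops are in percentage points relative to the intact
#' condition. `excess = drop_AB - (drop_A + drop_B)`; a positive excess
#' means the joint lesion removes more than its parts — evidence of
#' non-independent (holistic) feature processing.
#'
#' @param results A [run_grid()] result list with `none`, both single
#'   masks, and the pair mask (`mask_<a>.<b>`).
#' @param pair Character vector of the two features.
#' @return A `superadditivity_report`.
#' @export
superadditivity <- function(results, pair) {
  if (length(pair) != 2L || anyDuplicated(pair))
    stopf("pair must name two distinct features")
  pair <- FEATURES[FEATURES %in% pair]
  need <- c("none", paste0("mask_", pair), pair_label(pair))
  missing <- setdiff(need, names(results))
  if (length(missing))
    stopf("results lack conditions: %s", paste(missing, collapse = ", "))
  none <- results[["none"]]$accuracy * 100
  drop_a <- none - results[[paste0("mask_", pair[1])]]$accuracy * 100
  drop_b <- none - results[[paste0("mask_", pair[2])]]$accuracy * 100
  drop_ab <- none - results[[pair_label(pair)]]$accuracy * 100
  structure(list(pair = pair, drop_A = drop_a, drop_B = drop_b,
                 drop_AB = drop_ab, sum_drops = drop_a + drop_b,
                 excess = drop_ab - (drop_a + drop_b)),
            class = "superadditivity_report")
}

#' @export
print.superadditivity_report <- function(x, ...) {
  cat(sprintf(
    "super-additivity %s + %s: drops %.1f + %.1f = %.1f pp, joint %.1f pp, excess %+.1f pp\n",
    x$pair[1], x$pair[2], x$drop_A, x$drop_B, x$sum_drops, x$drop_AB,
    x$excess))
  invisible(x)
}

#' Overlap of the error sets of two conditions
#'
#' Error sets are the image indices misclassified under each condition;
#' the fractions are `|A intersect B| / |A|` and `|A intersect B| / |B|`.
#' Both are reported as 0 (flagged) when either error set is empty.
#'
#' @param resA,resB [condition_result()]s over the same image set.
#' @return An `overlap_report`.
#' @export
error_overlap <- function(resA, resB) {
  stopifnot(inherits(resA, "condition_result"),
            inherits(resB, "condition_result"))
  if (length(resA$correct) != length(resB$correct))
    stopf("conditions cover different image sets")
  ea <- which(!resA$correct); eb <- which(!resB$correct)
  common <- length(intersect(ea, eb))
  empty <- length(ea) == 0L || length(eb) == 0L
  structure(list(pair = c(resA$condition, resB$condition),
                 fraction_of_A = if (empty) 0 else common / length(ea),
                 fraction_of_B = if (empty) 0 else common / length(eb),
                 n_common = common, n_A = length(ea), n_B = length(eb),
                 empty_error_set = empty),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf(
    "error overlap '%s' vs '%s': %d shared errors = %.1f%% of A (%d), %.1f%% of B (%d)%s\n",
    x$pair[1], x$pair[2], x$n_common, 100 * x$fraction_of_A, x$n_A,
    100 * x$fraction_of_B, x$n_B,
    if (x$empty_error_set) " [an error set is empty]" else ""))
  invisible(x)
}

#' Region emphasis and emphasis-redirection tables
#'
#' For every sample, computes the Grad-CAM map of the intact image and,
#' per feature, the map with that feature masked. Reports (a) the mean
#' size-normalized region weight per feature on intact images and (b) the
#' mean emphasis shift per feature, stratified by whether the masked image
#' was still recognized (`true` / `false` / `all`).
#'
#' @param model A trained `face_cnn`.
#' @param samples List of `face_sample`s (typically the validation split).
#' @param features Features to tabulate.
#' @param area_config Target mask areas per feature.
#' @return List with data frames `weights` (feature, weight, n) and
#'   `redirection` (feature, stratum, mean_delta, n).
#' @export
emphasis_tables <- function(model, samples, features = FEATURES,
                            area_config = default_areas()) {
  stopifnot(inherits(model, "face_cnn"))
  if (!length(samples)) stopf("no samples")
  w_int <- matrix(NA_real_, length(samples), length(features),
                  dimnames = list(NULL, features))
  deltas <- matrix(NA_real_, length(samples), length(features),
                   dimnames = list(NULL, features))
  strata <- matrix(NA_character_, length(samples), length(features),
                   dimnames = list(NULL, features))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    regions <- sample_regions(s, features, area_config)
    h_int <- gradcam(model, s$image, s$identity_id)
    for (j in seq_along(features)) {
      w_int[i, j] <- region_emphasis(h_int, regions[[j]])
      spec <- lesion_spec("mask", features[j])
      h_les <- gradcam(model, apply_lesion(s, spec, area_config),
                       s$identity_id)
      deltas[i, j] <- region_emphasis(h_les, regions[[j]]) - w_int[i, j]
      pred <- which.max(attr(h_les, "scores")) - 1L
      strata[i, j] <- if (pred == s$identity_id) "true" else "false"
    }
  }
  weights <- data.frame(feature = features, weight = colMeans(w_int),
                        n = nrow(w_int), row.names = NULL)
  red <- do.call(rbind, lapply(seq_along(features), function(j) {
    do.call(rbind, lapply(c("true", "false", "all"), function(st) {
      keep <- if (st == "all") rep(TRUE, nrow(deltas)) else strata[, j] == st
      data.frame(feature = features[j], stratum = st,
                 mean_delta = if (any(keep)) mean(deltas[keep, j]) else NA_real_,
                 n = sum(keep))
    }))
  }))
  list(weights = weights, redirection = red,
       per_image = list(weights = w_int, deltas = deltas, strata = strata))
}
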