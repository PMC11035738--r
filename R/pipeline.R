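# Run configuration and the three pipeline stages (generate, train,
# analyze) binding the modules into reproducible file-based runs. One
# global seed deterministically derives every stage seed.

#' Read and validate a run configuration
#'
#' The configuration is YAML with sections `generator`, `classifier`,
#' `areas`, `grid` and `bootstrap`, plus a global `seed`. Any omitted
#' entry falls back to the package default; the global seed derives the
#' stage seeds.
#'
#' @param path Path to a YAML file, or a list with the same structure.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (is.character(path)) {
    if (!file.exists(path)) stopf("config file not found: %s", path)
    yaml::read_yaml(path)
  } else if (is.list(path)) path else stopf("config must be a path or list")
  seed <- as.integer(raw$seed %||% 1L)

  g <- raw$generator %||% list()
  if (!is.null(g$informativeness)) {
    g$informativeness <- unlist(g$informativeness)
    missing <- setdiff(FEATURES, names(g$informativeness))
    if (length(missing))
      stopf("generator.informativeness is missing: %s",
            paste(missing, collapse = ", "))
  }
  gen_args <- g[intersect(names(g),
                          names(formals(generator_config)))]
  gen_args$seed <- as.integer(g$seed %||% derive_seed(seed, 1L))
  generator <- do.call(generator_config, gen_args)

  cl <- raw$classifier %||% list()
  cl_args <- cl[intersect(names(cl), names(formals(classifier_config)))]
  cl_args$n_classes <- as.integer(cl$n_classes %||% generator$n_identities)
  cl_args$input_size <- as.integer(cl$input_size %||% generator$image_size)
  cl_args$seed <- as.integer(cl$seed %||% derive_seed(seed, 2L))
  classifier <- do.call(classifier_config, cl_args)

  areas <- default_areas()
  if (!is.null(raw$areas)) {
    ar <- unlist(raw$areas)
    bad <- setdiff(names(ar), FEATURES)
    if (length(bad)) stopf("unknown area key: %s", paste(bad, collapse = ", "))
    areas[names(ar)] <- as.integer(ar)
  }

  gr <- raw$grid %||% list()
  grid_args <- list(
    sigmas = as.numeric(unlist(gr$sigmas %||% blur_sigma_levels())),
    include_random = isTRUE(gr$random %||% TRUE),
    include_blur = isTRUE(gr$blur %||% TRUE),
    include_pairs = isTRUE(gr$pairs %||% TRUE),
    include_all = isTRUE(gr$all %||% TRUE),
    random_seed = derive_seed(seed, 3L))

  bs <- raw$bootstrap %||% list()
  structure(list(seed = seed, generator = generator, classifier = classifier,
                 areas = areas, grid_args = grid_args,
                 bootstrap = list(n_iter = as.integer(bs$n_iter %||% 1000L),
                                  seed = as.integer(bs$seed %||%
                                                      derive_seed(seed, 4L)))),
            class = "run_config")
}

#' Generate a dataset on disk
#'
#' Renders the configured synthetic dataset and writes PNG images,
#' keypoint sidecars and `manifest.csv` under `out_dir`.
#'
#' @param config Path to a YAML run configuration, or a `run_config`.
#' @param out_dir Output directory.
#' @return Invisibly, the manifest data frame.
#' @export
pipeline_generate <- function(config, out_dir) {
  rc <- if (inherits(config, "run_config")) config else read_run_config(config)
  dataset <- generate_dataset(rc$generator)
  manifest <- write_dataset(dataset, out_dir)
  message(sprintf("wrote %d images (%d identities) to %s",
                  nrow(manifest), dataset$n_identities, out_dir))
  invisible(manifest)
}

#' Train a classifier on a dataset directory
#'
#' Reads the dataset manifest, trains the configured classifier on the
#' intact training split, and writes `checkpoint.rds` (plus a plain-text
#' config echo) and `history.csv` (epoch, loss, val_accuracy).
#'
#' @inheritParams pipeline_generate
#' @param dataset_dir Directory written by [pipeline_generate()].
#' @return Invisibly, the trained model.
#' @export
pipeline_train <- function(config, dataset_dir, out_dir = dataset_dir) {
  rc <- if (inherits(config, "run_config")) config else read_run_config(config)
  dataset <- read_dataset(dataset_dir)
  if (dataset$n_identities != rc$classifier$n_classes)
    stopf("manifest has %d identities but the classifier expects %d classes",
          dataset$n_identities, rc$classifier$n_classes)
  model <- train_classifier(build_model(rc$classifier), dataset)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  save_model(model, file.path(out_dir, "checkpoint.rds"))
  write.csv(model$history, file.path(out_dir, "history.csv"),
            row.names = FALSE)
  message(sprintf("trained %d epochs; final val accuracy %.3f",
                  nrow(model$history), model$val_accuracy))
  invisible(model)
}

#' Run the full analysis grid and write the result tables
#'
#' Evaluates every grid condition on the validation split and writes:
#' `accuracy.csv` (per-condition accuracy, drop and bootstrap p against
#' the intact condition), `importance.csv`, `blur_curves.csv`,
#' `superadditivity.csv`, `overlap.csv`, `emphasis_weights.csv`,
#' `redirection.csv`, and `run_manifest.csv` (seeds and settings). Every
#' row carries its condition label and the run seed.
#'
#' @inheritParams pipeline_train
#' @param checkpoint Path to a `checkpoint.rds` from [pipeline_train()].
#' @param n_emphasis Cap on the number of validation images used for the
#'   Grad-CAM emphasis tables (they need five maps per image).
#' @return Invisibly, a list with every table.
#' @export
pipeline_analyze <- function(config, dataset_dir, checkpoint,
                             out_dir = dataset_dir, n_emphasis = 200L) {
  rc <- if (inherits(config, "run_config")) config else read_run_config(config)
  if (!file.exists(checkpoint))
    stopf("missing checkpoint: %s (run pipeline_train first)", checkpoint)
  model <- load_model(checkpoint)
  dataset <- read_dataset(dataset_dir)
  grid <- do.call(experiment_grid, rc$grid_args)
  results <- run_grid(model, dataset, grid, rc$areas)
  none <- results[["none"]]
  nb <- rc$bootstrap

  acc_tab <- do.call(rbind, lapply(names(results), function(lab) {
    r <- results[[lab]]
    p <- if (lab == "none") NA_real_ else
      bootstrap_accuracy_diff(none, r, nb$n_iter,
                              derive_seed(nb$seed, match(lab, names(results))))$p_value
    data.frame(condition = lab, n = length(r$correct), accuracy = r$accuracy,
               drop_pp = (none$accuracy - r$accuracy) * 100,
               p_vs_none = p, seed = rc$seed)
  }))

  imp <- rank_importance(results, n_iter = nb$n_iter, seed = nb$seed)
  imp_tab <- cbind(imp$ranking, seed = rc$seed)

  blur_tab <- NULL
  if (rc$grid_args$include_blur) {
    blur_tab <- do.call(rbind, lapply(FEATURES, function(f) {
      labs <- c("none", sprintf("blur_%s_sigma%g", f, rc$grid_args$sigmas),
                paste0("mask_", f))
      data.frame(feature = f, condition = labs,
                 sigma = c(0, rc$grid_args$sigmas, Inf),
                 accuracy = vapply(labs, function(l) results[[l]]$accuracy,
                                   numeric(1)),
                 seed = rc$seed, row.names = NULL)
    }))
  }

  sup_tab <- over_tab <- NULL
  if (rc$grid_args$include_pairs) {
    pairs <- utils::combn(FEATURES, 2L, simplify = FALSE)
    sup_tab <- do.call(rbind, lapply(pairs, function(p) {
      s <- superadditivity(results, p)
      data.frame(featA = p[1], featB = p[2], drop_A = s$drop_A,
                 drop_B = s$drop_B, drop_AB = s$drop_AB,
                 sum_drops = s$sum_drops, excess = s$excess, seed = rc$seed)
    }))
    over_tab <- do.call(rbind, lapply(pairs, function(p) {
      o <- error_overlap(results[[paste0("mask_", p[1])]],
                         results[[paste0("mask_", p[2])]])
      data.frame(condA = o$pair[1], condB = o$pair[2],
                 fraction_of_A = o$fraction_of_A,
                 fraction_of_B = o$fraction_of_B,
                 n_common = o$n_common, seed = rc$seed)
    }))
  }

  val <- subset_split(dataset, "val")
  emp_idx <- seq_len(min(length(val), n_emphasis))
  emp <- emphasis_tables(model, val[emp_idx], area_config = rc$areas)
  emp_w <- cbind(emp$weights, seed = rc$seed)
  emp_r <- cbind(emp$redirection, seed = rc$seed)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- list(accuracy = acc_tab, importance = imp_tab,
               blur_curves = blur_tab, superadditivity = sup_tab,
               overlap = over_tab, emphasis_weights = emp_w,
               redirection = emp_r)
  for (nm in names(tabs))
    if (!is.null(tabs[[nm]]))
      write.csv(tabs[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                row.names = FALSE)
  manifest <- data.frame(
    key = c("seed", "bootstrap_n_iter", "bootstrap_seed", "n_val",
            "n_conditions", "checkpoint", "bootstrap_scheme"),
    value = c(rc$seed, nb$n_iter, nb$seed, length(val), length(results),
              checkpoint,
              "paired percentile bootstrap, two-sided continuity-corrected"))
  write.csv(manifest, file.path(out_dir, "run_manifest.csv"),
            row.names = FALSE)
  message(sprintf("analyzed %d conditions on %d validation images",
                  length(results), length(val)))
  invisible(c(tabs, list(results = results, importance = imp)))
}
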