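# Small configurable convolutional identity classifier: plain conv+ReLU
# blocks ending in global average pooling and one fully connected layer,
# trained with softmax cross-entropy by momentum SGD. Forward and backward
# passes run through the compiled im2col/GEMM kernels in src/.

#' Default desk-scale backbone
#'
#' Three conv+ReLU blocks. On 112 px inputs the spatial grid shrinks
#' 112 -> 28 -> 14 -> 7; the 7 x 7 x 64 output feeds global average pooling
#' and the class layer.
#'
#' @return List of block descriptors (`channels`, `kernel`, `stride`).
#' @export
default_backbone <- function() {
  list(list(channels = 16L, kernel = 5L, stride = 4L),
       list(channels = 32L, kernel = 3L, stride = 2L),
       list(channels = 64L, kernel = 3L, stride = 2L))
}

#' Configuration of the convolutional identity classifier
#'
#' @param n_classes Number of identities C (>= 2); the final fully
#'   connected layer has C units.
#' @param input_size Input side in pixels (default 112).
#' @param channel_means,channel_sds Per-channel normalization constants
#'   (defaults: the ImageNet constants `[0.485, 0.456, 0.406]` and
#'   `[0.229, 0.224, 0.225]`).
#' @param backbone Ordered list of conv-block descriptors (`channels`,
#'   `kernel`, `stride`), ending implicitly in global average pooling plus
#'   one C-unit fully connected layer. Kernels must be odd; padding is
#'   `(kernel - 1) / 2`.
#' @param epochs,learning_rate,momentum,batch_size Training defaults
#'   (artifact defaults, not empirical claims: momentum SGD, lr 0.1,
#'   batch 64; training is capped at `epochs`).
#' @param spatial_dropout Training-time dropout probability on the last
#'   conv layer's spatial cells (shared across channels). Regularizes the
#'   pooled readout to tolerate locally missing evidence; images
#'   themselves are never perturbed during training.
#' @param seed Integer seed controlling initialization and shuffling.
#' @return A `classifier_config`.
#' @export
classifier_config <- function(n_classes, input_size = 112L,
                              channel_means = c(0.485, 0.456, 0.406),
                              channel_sds = c(0.229, 0.224, 0.225),
                              backbone = default_backbone(),
                              epochs = 30L, learning_rate = 0.1,
                              momentum = 0.9, batch_size = 64L,
                              spatial_dropout = 0.25, seed = 1L) {
  if (!is_count(n_classes, 2L)) stopf("n_classes must be an integer >= 2")
  if (!is_count(input_size, 6L)) stopf("input_size must be an integer >= 6")
  if (length(channel_means) != 3L || length(channel_sds) != 3L ||
      any(channel_sds <= 0))
    stopf("normalization constants must be 3 per-channel values, sds > 0")
  if (!length(backbone)) stopf("backbone needs at least one conv block")
  if (!is_count(epochs, 0L)) stopf("epochs must be a nonnegative integer")
  if (learning_rate <= 0) stopf("learning_rate must be positive")
  if (momentum < 0 || momentum >= 1) stopf("momentum must lie in [0, 1)")
  if (!is_count(batch_size, 1L)) stopf("batch_size must be a positive integer")
  if (spatial_dropout < 0 || spatial_dropout >= 1)
    stopf("spatial_dropout must lie in [0, 1)")
  cfg <- structure(list(n_classes = as.integer(n_classes),
                        input_size = as.integer(input_size),
                        channel_means = channel_means,
                        channel_sds = channel_sds, backbone = backbone,
                        epochs = as.integer(epochs),
                        learning_rate = learning_rate, momentum = momentum,
                        batch_size = as.integer(batch_size),
                        spatial_dropout = spatial_dropout,
                        seed = as.integer(seed)),
                   class = "classifier_config")
  backbone_dims(cfg)   # errors early when strides are incompatible
  cfg
}

# Resolve per-layer spatial sizes; errors when a layer collapses below 1 px
# or a kernel is even.
backbone_dims <- function(config) {
  H <- config$input_size
  cin <- 3L
  lapply(config$backbone, function(blk) {
    k <- as.integer(blk$kernel %||% 3L)
    s <- as.integer(blk$stride %||% 1L)
    cout <- as.integer(blk$channels)
    if (k %% 2L == 0L) stopf("conv kernels must be odd (got %d)", k)
    pad <- (k - 1L) %/% 2L
    Hout <- (H + 2L * pad - k) %/% s + 1L
    if (Hout < 1L)
      stopf("input_size %d incompatible with backbone strides (layer -> %d px)",
            config$input_size, Hout)
    d <- list(Hin = H, Hout = Hout, cin = cin, cout = cout,
              kernel = k, stride = s, pad = pad)
    H <<- Hout; cin <<- cout
    d
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Softmax cross-entropy loss
#'
#' `-(1/N) sum_i sum_j y_ij log softmax(z_i)_j`, computed with
#' log-sum-exp stabilization (the literal form overflows for |z| above
#' ~700). Always nonnegative.
#'
#' @param scores N x C matrix of unnormalized class scores.
#' @param labels Either an N x C one-hot matrix or a length-N vector of
#'   0-based class indices.
#' @return The scalar loss.
#' @export
cross_entropy <- function(scores, labels) {
  z <- as.matrix(scores)
  if (nrow(z) < 1L || any(!is.finite(z))) stopf("scores must be finite, N >= 1")
  C <- ncol(z)
  if (is.matrix(labels)) {
    y <- labels
    if (!all(dim(y) == dim(z))) stopf("labels must match the score matrix")
    if (any(y != 0 & y != 1) || any(abs(rowSums(y) - 1) > 1e-12))
      stopf("each label row must be one-hot")
    idx <- max.col(y, ties.method = "first")
  } else {
    idx <- as.integer(labels) + 1L
    if (length(idx) != nrow(z) || any(idx < 1L | idx > C))
      stopf("labels must be 0-based class indices below ncol(scores)")
  }
  m <- apply(z, 1, max)
  lse <- m + log(rowSums(exp(z - m)))
  mean(lse - z[cbind(seq_len(nrow(z)), idx)])
}

#' Build an untrained classifier
#'
#' Deterministic He-style initialization given `config$seed`. The model
#' exposes forward scores, parameter gradients, and the last convolutional
#' layer's activations (as used by Grad-CAM).
#'
#' @param config A [classifier_config()].
#' @return An untrained `face_cnn` object.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "classifier_config"))
  dims <- backbone_dims(config)
  with_seed(derive_seed(config$seed, 11L), {
    blocks <- lapply(dims, function(d) {
      fan_in <- d$cin * d$kernel^2
      list(W = matrix(rnorm(d$cout * fan_in, sd = sqrt(2 / fan_in)),
                      d$cout, fan_in),
           b = numeric(d$cout), dims = d)
    })
    last <- dims[[length(dims)]]
    fc <- list(W = matrix(rnorm(config$n_classes * last$cout,
                                sd = sqrt(1 / last$cout)),
                          config$n_classes, last$cout),
               b = numeric(config$n_classes))
    structure(list(config = config, blocks = blocks, fc = fc,
                   trained = FALSE, history = NULL),
              class = "face_cnn")
  })
}

# Replicate grayscale to 3 channels and z-normalize; one column per image.
prepare_batch <- function(images, config) {
  S <- config$input_size
  cm <- config$channel_means; cs <- config$channel_sds
  cols <- vapply(images, function(img) {
    a <- as_image_array(img)
    if (nrow(a) != S || ncol(a) != S)
      stopf("image is %d x %d but the model expects %d x %d",
            nrow(a), ncol(a), S, S)
    if (dim(a)[3] == 1L) a <- array(a, c(S, S, 3L))
    for (ch in 1:3) a[, , ch] <- (a[, , ch] - cm[ch]) / cs[ch]
    as.vector(a)
  }, numeric(S * S * 3L))
  matrix(cols, ncol = length(images))
}

# Forward pass over a prepared batch; returns scores plus (optionally) all
# intermediate activations. acts[[i]] is the input of block i.
model_forward <- function(model, xmat, keep = FALSE, drop = NULL) {
  acts <- vector("list", length(model$blocks) + 1L)
  acts[[1L]] <- xmat
  for (i in seq_along(model$blocks)) {
    blk <- model$blocks[[i]]; d <- blk$dims
    acts[[i + 1L]] <- .conv_forward(acts[[i]], d$Hin, d$Hin, d$cin, blk$W,
                                    blk$b, d$kernel, d$stride, d$pad, TRUE)
  }
  last <- model$blocks[[length(model$blocks)]]$dims
  hw <- last$Hout^2
  A <- acts[[length(acts)]]
  # training-time spatial dropout: `drop` is an hw x N inverted-scale
  # Bernoulli mask applied to every channel of the last conv layer
  dropx <- NULL
  if (!is.null(drop)) {
    dropx <- drop[rep(seq_len(hw), last$cout), , drop = FALSE]
    A <- A * dropx
  }
  g <- matrix(colMeans(matrix(A, nrow = hw)), nrow = last$cout)  # cout x N
  z <- model$fc$W %*% g + model$fc$b                             # C x N
  out <- list(scores = z, pooled = g, last_hw = hw, last_cout = last$cout,
              dropx = dropx)
  if (keep) out$acts <- acts
  out
}

# Full backward pass from the softmax gradient; returns per-parameter
# gradients in the block structure.
model_backward <- function(model, fwd, dz) {
  g <- fwd$pooled
  grads <- list(fc = list(W = dz %*% t(g), b = rowSums(dz)))
  dg <- t(model$fc$W) %*% dz                     # cout x N
  hw <- fwd$last_hw
  dA <- matrix(rep(dg / hw, each = hw), ncol = ncol(dg))
  if (!is.null(fwd$dropx)) dA <- dA * fwd$dropx
  acts <- fwd$acts
  gb <- vector("list", length(model$blocks))
  for (i in rev(seq_along(model$blocks))) {
    blk <- model$blocks[[i]]; d <- blk$dims
    bk <- .conv_backward(acts[[i]], acts[[i + 1L]], dA, d$Hin, d$Hin, d$cin,
                         blk$W, d$kernel, d$stride, d$pad, TRUE)
    gb[[i]] <- list(W = bk$dw, b = as.numeric(bk$db))
    dA <- bk$dx
  }
  grads$blocks <- gb
  grads
}

#' Train the classifier on the intact training split
#'
#' Momentum SGD on softmax cross-entropy, intact (unlesioned) images only.
#' Deterministic given the seed (fixed initialization and shuffling).
#' History records per-epoch mean training loss and validation accuracy.
#'
#' @param model An untrained (or partially trained) `face_cnn`.
#' @param dataset A `split_dataset` whose identities match
#'   `config$n_classes`.
#' @param epochs,learning_rate,momentum,batch_size Override the config.
#' @param seed Shuffling seed (defaults to the config seed).
#' @return The trained model with a `history` data frame.
#' @export
train_classifier <- function(model, dataset,
                             epochs = NULL, learning_rate = NULL,
                             momentum = NULL, batch_size = NULL, seed = NULL) {
  stopifnot(inherits(model, "face_cnn"), inherits(dataset, "split_dataset"))
  cfg <- model$config
  epochs <- as.integer(epochs %||% cfg$epochs)
  lr <- learning_rate %||% cfg$learning_rate
  mom <- momentum %||% cfg$momentum
  bs <- as.integer(batch_size %||% cfg$batch_size)
  seed <- as.integer(seed %||% cfg$seed)
  if (dataset$n_identities != cfg$n_classes)
    stopf("dataset has %d identities but the model expects %d classes",
          dataset$n_identities, cfg$n_classes)

  train <- subset_split(dataset, "train")
  val <- subset_split(dataset, "val")
  if (!length(train)) stopf("dataset has no training split")
  ytr <- vapply(train, `[[`, integer(1), "identity_id")
  if (!all(sort(unique(ytr)) == seq_len(cfg$n_classes) - 1L))
    stopf("training labels are not the contiguous range 0..%d",
          cfg$n_classes - 1L)
  xtr <- prepare_batch(lapply(train, `[[`, "image"), cfg)

  vel <- list(blocks = lapply(model$blocks,
                              function(b) list(W = 0 * b$W, b = 0 * b$b)),
              fc = list(W = 0 * model$fc$W, b = 0 * model$fc$b))
  hist <- data.frame(epoch = integer(), loss = numeric(),
                     val_accuracy = numeric())
  n <- length(train)
  for (ep in seq_len(epochs)) {
    perm <- with_seed(derive_seed(seed, 3000L + ep), sample.int(n))
    starts <- seq(1L, n, by = bs)
    losses <- numeric(length(starts))
    for (si in seq_along(starts)) {
      take <- perm[starts[si]:min(starts[si] + bs - 1L, n)]
      xb <- xtr[, take, drop = FALSE]
      yb <- ytr[take]
      dmask <- NULL
      if (cfg$spatial_dropout > 0) {
        hw <- model$blocks[[length(model$blocks)]]$dims$Hout^2
        keepp <- 1 - cfg$spatial_dropout
        dmask <- with_seed(derive_seed(seed, 4000L + ep, si), matrix(
          (runif(hw * length(take)) < keepp) / keepp, hw, length(take)))
      }
      fwd <- model_forward(model, xb, keep = TRUE, drop = dmask)
      z <- fwd$scores
      m <- apply(z, 2, max)
      p <- exp(sweep(z, 2, m))
      p <- sweep(p, 2, colSums(p), "/")
      nb <- length(take)
      losses[si] <- -mean(log(pmax(p[cbind(yb + 1L, seq_len(nb))], 1e-300)))
      if (!is.finite(losses[si]))
        stopf("training diverged (non-finite loss) at epoch %d", ep)
      dz <- p
      dz[cbind(yb + 1L, seq_len(nb))] <- dz[cbind(yb + 1L, seq_len(nb))] - 1
      dz <- dz / nb
      gr <- model_backward(model, fwd, dz)
      for (i in seq_along(model$blocks)) {
        vel$blocks[[i]]$W <- mom * vel$blocks[[i]]$W - lr * gr$blocks[[i]]$W
        vel$blocks[[i]]$b <- mom * vel$blocks[[i]]$b - lr * gr$blocks[[i]]$b
        model$blocks[[i]]$W <- model$blocks[[i]]$W + vel$blocks[[i]]$W
        model$blocks[[i]]$b <- model$blocks[[i]]$b + vel$blocks[[i]]$b
      }
      vel$fc$W <- mom * vel$fc$W - lr * gr$fc$W
      vel$fc$b <- mom * vel$fc$b - lr * gr$fc$b
      model$fc$W <- model$fc$W + vel$fc$W
      model$fc$b <- model$fc$b + vel$fc$b
    }
    va <- if (length(val))
      evaluate_model(model, val, lesion_spec("none"))$accuracy else NA_real_
    hist <- rbind(hist, data.frame(epoch = ep, loss = mean(losses),
                                   val_accuracy = va))
  }
  model$trained <- epochs > 0L || isTRUE(model$trained)
  model$history <- if (is.null(model$history)) hist else rbind(model$history, hist)
  model$val_accuracy <- if (nrow(hist)) hist$val_accuracy[nrow(hist)] else NA_real_
  model
}

#' Fit a convolutional identity classifier to a synthetic face dataset
#'
#' Convenience fitting front end: builds an untrained model for the
#' dataset's identity count and trains it on the intact training split.
#'
#' @param dataset A `split_dataset` from [generate_dataset()] or
#'   [read_dataset()].
#' @param config Optional [classifier_config()]; defaults to the desk-scale
#'   backbone sized to the dataset.
#' @param ... Passed to [classifier_config()] when `config` is NULL
#'   (e.g. `epochs`, `seed`).
#' @return A trained `face_cnn`.
#' @export
face_cnn <- function(dataset, config = NULL, ...) {
  stopifnot(inherits(dataset, "split_dataset"))
  if (is.null(config))
    config <- classifier_config(n_classes = dataset$n_identities, ...)
  train_classifier(build_model(config), dataset)
}

#' Evaluate the classifier under a lesion condition
#'
#' Applies the lesion to every sample, normalizes, scores, and predicts by
#' argmax (lowest class index on ties).
#'
#' @param model A `face_cnn`.
#' @param samples List of `face_sample`s (each needs keypoints for the
#'   spec's features).
#' @param lesion A [lesion_spec()] (default: intact images).
#' @param area_config Target mask areas per feature.
#' @return A [condition_result()]: per-image correctness, predictions and
#'   aggregate accuracy.
#' @export
evaluate_model <- function(model, samples, lesion = lesion_spec("none"),
                           area_config = default_areas()) {
  stopifnot(inherits(model, "face_cnn"), inherits(lesion, "lesion_spec"))
  if (!length(samples)) stopf("no samples to evaluate")
  labels <- vapply(samples, `[[`, integer(1), "identity_id")
  predicted <- integer(length(samples))
  for (start in seq(1L, length(samples), by = 64L)) {
    take <- start:min(start + 63L, length(samples))
    imgs <- lapply(take, function(i) {
      sp <- lesion
      if (sp$kind == "random_mask") sp$seed <- derive_seed(lesion$seed, i)
      apply_lesion(samples[[i]], sp, area_config)
    })
    z <- model_forward(model, prepare_batch(imgs, model$config))$scores
    predicted[take] <- max.col(t(z), ties.method = "first") - 1L
  }
  condition_result(correct = predicted == labels, condition = lesion$label,
                   predicted = predicted)
}

#' Per-image correctness under one condition
#'
#' The unit every downstream statistic (bootstrap, overlap,
#' super-additivity) operates on: accuracy is always the mean of the
#' retained per-image correctness vector.
#'
#' @param correct Logical vector, one entry per evaluated image.
#' @param condition Condition label.
#' @param predicted Optional per-image predicted class indices.
#' @return A `condition_result`.
#' @export
condition_result <- function(correct, condition = "condition",
                             predicted = NULL) {
  correct <- as.logical(correct)
  if (!length(correct) || anyNA(correct))
    stopf("correct must be a nonempty logical vector without NAs")
  structure(list(condition = condition, correct = correct,
                 predicted = predicted, accuracy = mean(correct)),
            class = "condition_result")
}

#' @export
print.condition_result <- function(x, ...) {
  cat(sprintf("condition '%s': accuracy %.3f (%d/%d correct)\n",
              x$condition, x$accuracy, sum(x$correct), length(x$correct)))
  invisible(x)
}

# -- face_cnn methods --------------------------------------------------------

#' @export
print.face_cnn <- function(x, ...) {
  d <- backbone_dims(x$config)
  arch <- paste(vapply(d, function(b)
    sprintf("conv%dx%d/%d->%dch@%dpx", b$kernel, b$kernel, b$stride,
            b$cout, b$Hout), character(1)), collapse = " | ")
  cat(sprintf("face_cnn (%s): %s | GAP | fc -> %d classes\n",
              if (isTRUE(x$trained)) "trained" else "untrained",
              arch, x$config$n_classes))
  if (!is.null(x$history) && nrow(x$history))
    cat(sprintf("final epoch %d: loss %.4f, val accuracy %.3f\n",
                max(x$history$epoch), x$history$loss[nrow(x$history)],
                x$history$val_accuracy[nrow(x$history)]))
  invisible(x)
}

#' @export
summary.face_cnn <- function(object, ...) {
  print(object)
  npar <- sum(vapply(object$blocks,
                     function(b) length(b$W) + length(b$b), numeric(1))) +
    length(object$fc$W) + length(object$fc$b)
  cat(sprintf("parameters: %d; input %d px, normalization means [%s]\n",
              npar, object$config$input_size,
              paste(object$config$channel_means, collapse = ", ")))
  invisible(object)
}

#' Predict identities (or scores) for face samples or images
#'
#' @param object A `face_cnn`.
#' @param newdata List of `face_sample`s or of images, or a single image.
#' @param type `"class"` (0-based identity indices) or `"scores"` (N x C).
#' @param lesion Optional [lesion_spec()] applied before scoring (samples
#'   with keypoints only).
#' @param ... Unused.
#' @export
predict.face_cnn <- function(object, newdata, type = c("class", "scores"),
                             lesion = NULL, ...) {
  type <- match.arg(type)
  if (inherits(newdata, "face_sample") || is.matrix(newdata) ||
      (is.array(newdata) && length(dim(newdata)) == 3L))
    newdata <- list(newdata)
  imgs <- lapply(seq_along(newdata), function(i) {
    nd <- newdata[[i]]
    if (inherits(nd, "face_sample")) {
      if (is.null(lesion)) nd$image else {
        sp <- lesion
        if (sp$kind == "random_mask") sp$seed <- derive_seed(lesion$seed, i)
        apply_lesion(nd, sp)
      }
    } else nd
  })
  out <- matrix(0, length(imgs), object$config$n_classes)
  for (start in seq(1L, length(imgs), by = 64L)) {
    take <- start:min(start + 63L, length(imgs))
    z <- model_forward(object,
                       prepare_batch(imgs[take], object$config))$scores
    out[take, ] <- t(z)
  }
  if (type == "scores") out else max.col(out, ties.method = "first") - 1L
}

#' @export
coef.face_cnn <- function(object, ...) {
  c(lapply(object$blocks, function(b) list(W = b$W, b = b$b)),
    list(fc = object$fc))
}

#' Plot the training history of a fitted classifier
#'
#' @param x A trained `face_cnn`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.face_cnn <- function(x, ...) {
  h <- x$history
  if (is.null(h) || !nrow(h)) stopf("model has no training history")
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$loss, type = "b", xlab = "epoch",
                 ylab = "training loss", main = "loss", ...)
  graphics::plot(h$epoch, h$val_accuracy, type = "b", xlab = "epoch",
                 ylab = "validation accuracy", main = "accuracy",
                 ylim = c(0, 1), ...)
  graphics::abline(h = 1 / x$config$n_classes, lty = 3)
  invisible(x)
}

#' Save / load a fitted classifier
#'
#' Checkpoints use R's native serialization, with a plain-text echo of the
#' configuration next to the binary file.
#'
#' @param model A `face_cnn`.
#' @param path Checkpoint path (`.rds`).
#' @return `save_model`: the path, invisibly. `load_model`: the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "face_cnn"))
  saveRDS(model, path)
  cfg <- model$config
  echo <- c(sprintf("n_classes: %d", cfg$n_classes),
            sprintf("input_size: %d", cfg$input_size),
            sprintf("epochs: %d", cfg$epochs),
            sprintf("learning_rate: %g", cfg$learning_rate),
            sprintf("momentum: %g", cfg$momentum),
            sprintf("batch_size: %d", cfg$batch_size),
            sprintf("seed: %d", cfg$seed),
            sprintf("backbone: %s", paste(vapply(cfg$backbone, function(b)
              sprintf("%dch k%d s%d", b$channels, b$kernel, b$stride),
              character(1)), collapse = " | ")))
  writeLines(echo, paste0(path, ".config.txt"))
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "face_cnn")) stopf("%s is not a face_cnn checkpoint", path)
  model
}
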