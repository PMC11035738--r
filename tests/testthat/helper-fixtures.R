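# Shared fixtures. Heavy objects (trained models, grid evaluations) are
# built lazily and cached for the whole test run.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# Desk-scale study conditions: 32 identities x 50 images, planted
# informativeness 2:1:0.5:0.25, 15 training epochs.
desk_dataset <- function(seed) {
  cached(sprintf("desk_ds_%d", seed),
         generate_dataset(generator_config(seed = seed)))
}

desk_model <- function(seed) {
  cached(sprintf("desk_model_%d", seed),
         face_cnn(desk_dataset(seed), epochs = 15, seed = seed))
}

desk_val <- function(seed) {
  ds <- desk_dataset(seed)
  Filter(function(s) s$split_tag == "val", ds$samples)
}

# Lazily evaluated lesion conditions for a desk model, keyed by label.
desk_condition <- function(seed, spec) {
  cached(sprintf("desk_cond_%d_%s", seed, spec$label),
         evaluate_model(desk_model(seed), desk_val(seed), spec))
}

# A small fast dataset + model for structural tests (64 px canvas).
tiny_area_config <- function(size = 64) {
  round(default_areas() * (size / 112)^2)
}

tiny_dataset <- function(seed = 7) {
  cached(sprintf("tiny_ds_%d", seed),
         generate_dataset(generator_config(
           n_identities = 8, images_per_identity = 10, image_size = 64,
           seed = seed)))
}

tiny_model <- function(seed = 7) {
  cached(sprintf("tiny_model_%d", seed), {
    cfg <- classifier_config(n_classes = 8, input_size = 64, epochs = 12,
                             batch_size = 32, seed = seed)
    train_classifier(build_model(cfg), tiny_dataset(seed))
  })
}

# A single rendered face sample at full resolution, noise-free (so masked
# zeros are countable exactly).
clean_sample <- function(seed = 3) {
  cached(sprintf("clean_sample_%d", seed), {
    cfg <- generator_config(n_identities = 2, images_per_identity = 2,
                            noise_sd = 0, seed = seed)
    render_face(sample_identities(cfg)[[1]], cfg, 1)
  })
}

# Hand-specified single-conv model on a 6 px input, used for the Grad-CAM
# closed-form oracle. Returns the model plus its exact weights.
handmade_model <- function() {
  cached("handmade_model", {
    cfg <- classifier_config(
      n_classes = 3, input_size = 6,
      channel_means = c(0, 0, 0), channel_sds = c(1, 1, 1),
      backbone = list(list(channels = 2L, kernel = 3L, stride = 1L)),
      seed = 1)
    m <- build_model(cfg)
    set.seed(41)
    m$blocks[[1]]$W <- matrix(round(rnorm(2 * 27), 2), 2, 27)
    m$blocks[[1]]$b <- c(0.1, -0.2)
    m$fc$W <- matrix(round(rnorm(3 * 2), 2), 3, 2)
    m$fc$b <- c(0, 0.5, -0.5)
    m
  })
}

# Reference 2-D convolution with zero padding for the oracle (image given
# as H x W x C array, weights as cout x (cin*k*k) in im2col row order).
oracle_conv <- function(x, W, b, k, stride, pad, relu = TRUE) {
  H <- dim(x)[1]; Wd <- dim(x)[2]; cin <- dim(x)[3]
  Ho <- (H + 2 * pad - k) %/% stride + 1
  Wo <- (Wd + 2 * pad - k) %/% stride + 1
  cout <- nrow(W)
  out <- array(0, c(Ho, Wo, cout))
  for (co in seq_len(cout)) for (ho in seq_len(Ho)) for (wo in seq_len(Wo)) {
    acc <- b[co]
    for (ci in seq_len(cin)) for (dj in 0:(k - 1)) for (di in 0:(k - 1)) {
      hi <- (ho - 1) * stride - pad + di + 1
      wi <- (wo - 1) * stride - pad + dj + 1
      v <- if (hi >= 1 && hi <= H && wi >= 1 && wi <= Wd) x[hi, wi, ci] else 0
      wrow <- (ci - 1) * k * k + dj * k + di + 1
      acc <- acc + W[co, wrow] * v
    }
    out[ho, wo, co] <- if (relu) max(acc, 0) else acc
  }
  out
}

# Condition-result fixture with an exact accuracy (first `round(acc*n)`
# entries correct).
fixture_result <- function(acc, n = 1000, label = "fix") {
  k <- round(acc * n)
  condition_result(c(rep(TRUE, k), rep(FALSE, n - k)), label)
}
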