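# The synthetic face generator: determinism, planted identity signal,
# landmark contracts, and split arithmetic.

test_that("configuration invariants are enforced", {
  expect_error(generator_config(n_identities = 1), "n_identities")
  expect_error(generator_config(informativeness = c(eyebrows = 1)),
               "informativeness")
  expect_error(generator_config(
    informativeness = c(eyebrows = 0, eyes = 0, mouth = 0, nose = 0)),
    "zero")
  expect_error(generator_config(split_ratio = c(1, 0)), "split_ratio")
  expect_error(generator_config(redundancy = 1.2), "redundancy")
  cfg <- generator_config(images_per_identity = 2, split_ratio = c(9, 1))
  expect_error(generate_dataset(cfg), "empty split")
})

test_that("identity sampling is deterministic and informativeness scales spread", {
  cfg <- generator_config(seed = 7)
  expect_identical(sample_identities(cfg), sample_identities(cfg))

  only_brows <- generator_config(
    n_identities = 16,
    informativeness = c(eyebrows = 1, eyes = 0, mouth = 0, nose = 0),
    seed = 2)
  ids <- sample_identities(only_brows)
  tab <- attr(ids, "param_table")
  P <- t(vapply(ids, function(i) i$params, numeric(nrow(tab))))
  sds <- apply(P, 2, sd)
  expect_true(all(sds[tab$feature %in% c("eyes", "mouth", "nose")] == 0))
  expect_true(all(sds[tab$feature == "eyebrows"] > 0))
})

test_that("between-identity spread is proportional to informativeness", {
  # planted 2:1 for eyebrows:eyes must be recovered from the sampled
  # parameter sets (z-scaled per parameter) within 20%
  cfg <- generator_config(n_identities = 64, seed = 5)
  ids <- sample_identities(cfg)
  tab <- attr(ids, "param_table")
  P <- t(vapply(ids, function(i) i$params, numeric(nrow(tab))))
  zsd <- apply(P, 2, sd) / tab$sd
  by_feat <- tapply(zsd, tab$feature, mean)
  ratio <- by_feat[["eyebrows"]] / by_feat[["eyes"]]
  expect_gt(ratio, 2 * 0.8)
  expect_lt(ratio, 2 * 1.2)
})

test_that("rendering is deterministic and keypoints describe the drawn ink", {
  cfg <- generator_config(seed = 9)
  ids <- sample_identities(cfg)
  s1 <- render_face(ids[[1]], cfg, 3)
  s2 <- render_face(ids[[1]], cfg, 3)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$keypoints, s2$keypoints)

  S <- cfg$image_size
  for (f in names(s1$keypoints)) {
    kp <- s1$keypoints[[f]]
    expect_gte(nrow(kp), 4)
    expect_true(all(kp[, "x"] >= 0 & kp[, "x"] < S))
    expect_true(all(kp[, "y"] >= 0 & kp[, "y"] < S))
    bb <- attr(s1, "ink_bboxes")[[f]]
    expect_true(all(kp[, "x"] >= bb["xmin"] - 2 & kp[, "x"] <= bb["xmax"] + 2))
    expect_true(all(kp[, "y"] >= bb["ymin"] - 2 & kp[, "y"] <= bb["ymax"] + 2))
  }
})

test_that("feature keypoint boxes are pairwise disjoint across a render sweep", {
  cfg <- generator_config(n_identities = 25, images_per_identity = 2, seed = 13)
  ids <- sample_identities(cfg)
  boxes_disjoint <- function(a, b) {
    a["xmax"] < b["xmin"] || b["xmax"] < a["xmin"] ||
      a["ymax"] < b["ymin"] || b["ymax"] < a["ymin"]
  }
  for (id in ids) for (d in 1:2) {
    s <- render_face(id, cfg, d)
    bbs <- lapply(s$keypoints, function(kp)
      c(xmin = min(kp[, "x"]), xmax = max(kp[, "x"]),
        ymin = min(kp[, "y"]), ymax = max(kp[, "y"])))
    pairs <- utils::combn(names(bbs), 2, simplify = FALSE)
    for (p in pairs)
      expect_true(boxes_disjoint(bbs[[p[1]]], bbs[[p[2]]]),
                  label = sprintf("%s vs %s disjoint (id %d draw %d)",
                                  p[1], p[2], id$identity_id, d))
  }
})

test_that("no variation sources means pixel-identical repeated draws", {
  cfg <- generator_config(n_identities = 2, images_per_identity = 2,
                          within_jitter = 0, noise_sd = 0, seed = 21)
  id <- sample_identities(cfg)[[1]]
  expect_identical(render_face(id, cfg, 1)$image, render_face(id, cfg, 2)$image)
})

test_that("pixel noise matches the folded-normal difference law", {
  # two draws of one identity with jitter 0 differ per pixel by
  # N(0, sd) - N(0, sd); E|d| = 2 sd / sqrt(pi) away from the clip bounds
  sd <- 0.05
  base <- list(n_identities = 2, images_per_identity = 2,
               within_jitter = 0, seed = 4)
  cfg0 <- do.call(generator_config, c(base, list(noise_sd = 0)))
  cfgN <- do.call(generator_config, c(base, list(noise_sd = sd)))
  tmpl <- render_face(sample_identities(cfg0)[[1]], cfg0, 1)$image
  a <- render_face(sample_identities(cfgN)[[1]], cfgN, 1)$image
  b <- render_face(sample_identities(cfgN)[[1]], cfgN, 2)$image
  sel <- tmpl >= 0.2 & tmpl <= 0.8       # no clipping within 3 sd
  expect_gt(sum(sel), 5000)
  expected <- 2 * sd / sqrt(pi)
  expect_lt(abs(mean(abs(a - b)[sel]) - expected), 0.05 * expected)
})

test_that("split arithmetic follows floor(frac * n + 0.5)", {
  expect_identical(split_counts(52000, c(7, 3)),
                   c(train = 36400L, val = 15600L))
  expect_identical(split_counts(10, c(7, 3)), c(train = 7L, val = 3L))
  sp <- split_indices(52000, c(7, 3), seed = 1)
  expect_length(sp$train, 36400)
  expect_length(sp$val, 15600)
  expect_identical(sort(c(sp$train, sp$val)), seq_len(52000))
})

test_that("generated datasets are balanced, stratified and deterministic", {
  cfg <- generator_config(n_identities = 10, images_per_identity = 10,
                          image_size = 64, seed = 31)
  ds <- generate_dataset(cfg)
  labs <- vapply(ds$samples, `[[`, integer(1), "identity_id")
  tags <- vapply(ds$samples, `[[`, character(1), "split_tag")
  expect_identical(sort(unique(labs)), 0:9)          # contiguous labels
  expect_true(all(table(labs) == 10))                # class balance
  per_id <- table(labs, tags)
  expect_true(all(per_id[, "train"] == 7))           # exact 7:3 per identity
  expect_true(all(per_id[, "val"] == 3))
  ds2 <- generate_dataset(cfg)
  expect_identical(vapply(ds2$samples, `[[`, character(1), "split_tag"), tags)
  expect_identical(ds$samples[[17]]$image, ds2$samples[[17]]$image)
})

test_that("datasets round-trip through the on-disk format", {
  dir <- withr::local_tempdir()
  cfg <- generator_config(n_identities = 3, images_per_identity = 4,
                          image_size = 64, seed = 17)
  ds <- generate_dataset(cfg)
  mf <- write_dataset(ds, dir)
  expect_equal(nrow(mf), 12)
  back <- read_dataset(dir)
  expect_equal(length(back$samples), 12)
  expect_equal(back$n_identities, 3)
  # PNG is 8-bit: images agree to quantization error
  expect_lt(max(abs(back$samples[[5]]$image - ds$samples[[5]]$image)), 1 / 255)
  expect_equal(unname(back$samples[[5]]$keypoints$mouth),
               unname(ds$samples[[5]]$keypoints$mouth))
  expect_identical(back$samples[[5]]$split_tag, ds$samples[[5]]$split_tag)
  # manifests are byte-identical across reruns
  dir2 <- withr::local_tempdir()
  write_dataset(generate_dataset(cfg), dir2)
  expect_identical(readLines(file.path(dir, "manifest.csv")),
                   readLines(file.path(dir2, "manifest.csv")))
})
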