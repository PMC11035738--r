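# Exact-area regions, masking, randomized control masks, and the
# region-restricted Gaussian blur against a brute-force oracle.

test_that("feature regions hit the exact target area when interior", {
  s <- clean_sample()
  shape <- dim(s$image)
  for (f in names(default_areas())) {
    rg <- region_from_keypoints(s$keypoints[[f]], default_areas()[[f]],
                                shape, feature = f)
    expect_identical(rg$actual_area, rg$target_area)
    expect_false(rg$area_unachievable)
    expect_identical(rg$width * rg$height, rg$target_area)
    # all keypoints covered
    kp <- s$keypoints[[f]]
    expect_true(all(kp[, "x"] >= rg$x0 & kp[, "x"] < rg$x0 + rg$width))
    expect_true(all(kp[, "y"] >= rg$y0 & kp[, "y"] < rg$y0 + rg$height))
  }
})

test_that("region construction rejects degenerate input and flags tight targets", {
  expect_error(region_from_keypoints(rbind(c(10, 10), c(10, 10)), 800,
                                     c(112, 112)), "degenerate")
  # target below the keypoint bounding box: bounding box returned, flagged
  pts <- rbind(c(10, 10), c(40, 30))
  rg <- region_from_keypoints(pts, 100, c(112, 112))
  expect_true(rg$area_unachievable)
  expect_identical(rg$width, 31L)
  expect_identical(rg$height, 21L)
})

test_that("masking zeroes exactly the region and is idempotent", {
  img <- matrix(1, 112, 112)
  pts <- rbind(c(40, 50), c(70, 60))
  rg <- region_from_keypoints(pts, 800, c(112, 112))
  masked <- apply_mask(img, rg)
  expect_identical(sum(masked == 0), 800L)
  expect_identical(apply_mask(masked, rg), masked)
  # untouched pixels bit-identical
  expect_identical(masked[masked != 0], img[masked != 0])

  # region straddling the border zeroes only the clipped intersection
  rg2 <- rg
  rg2$x0 <- -10L
  rg2$y0 <- 100L
  clipped <- apply_mask(img, rg2)
  inter <- max(0, min(rg2$x0 + rg2$width, 112) - max(rg2$x0, 0)) *
    max(0, min(rg2$y0 + rg2$height, 112) - max(rg2$y0, 0))
  expect_identical(sum(clipped == 0), as.integer(inter))
  expect_lt(inter, rg2$target_area)
})

test_that("random control masks are deterministic, interior and non-overlapping", {
  s <- clean_sample()
  shape <- dim(s$image)
  templates <- lapply(names(default_areas()), function(f)
    region_from_keypoints(s$keypoints[[f]], default_areas()[[f]], shape, f))
  r1 <- sample_random_regions(templates, shape, seed = 11)
  r2 <- sample_random_regions(templates, shape, seed = 11)
  expect_identical(r1, r2)
  for (rg in r1) {
    expect_gte(rg$x0, 0)
    expect_gte(rg$y0, 0)
    expect_lte(rg$x0 + rg$width, shape[2])
    expect_lte(rg$y0 + rg$height, shape[1])
  }
  overlap <- function(a, b) {
    a$x0 < b$x0 + b$width && b$x0 < a$x0 + a$width &&
      a$y0 < b$y0 + b$height && b$y0 < a$y0 + a$height
  }
  pairs <- utils::combn(seq_along(r1), 2, simplify = FALSE)
  for (p in pairs) expect_false(overlap(r1[[p[1]]], r1[[p[2]]]))
})

test_that("random placements are uniform over the anchor grid", {
  # one 20 x 40 template in a 112 x 112 image; 10,000 seeded draws binned
  # on an 8 x 8 anchor grid must pass a chi-square test at alpha = 0.01
  tp <- region_from_keypoints(rbind(c(10, 10), c(49, 29)), 800, c(112, 112))
  expect_identical(c(tp$width, tp$height), c(40L, 20L))
  nx <- 112 - tp$width + 1
  ny <- 112 - tp$height + 1
  xs <- ys <- integer(10000)
  for (i in seq_len(10000)) {
    rg <- sample_random_regions(list(tp), c(112, 112), seed = i)[[1]]
    xs[i] <- rg$x0
    ys[i] <- rg$y0
  }
  bx <- pmin(floor(xs / nx * 8), 7)
  by <- pmin(floor(ys / ny * 8), 7)
  counts <- table(factor(bx + 8 * by, levels = 0:63))
  p <- stats::chisq.test(as.vector(counts))$p.value
  expect_gt(p, 0.01)
})

test_that("gaussian kernels are normalized, symmetric and correctly sized", {
  for (s in blur_sigma_levels()) {
    k <- gaussian_kernel(s)
    expect_lt(abs(sum(k$weights) - 1), 1e-9)
    expect_identical(k$size, 2L * as.integer(ceiling(3 * s)) + 1L)
    expect_equal(k$weights, k$weights[k$size:1, ], tolerance = 1e-12)
    expect_equal(k$weights, t(k$weights), tolerance = 1e-12)
    expect_identical(which.max(k$weights),
                     as.integer((k$size^2 + 1) / 2))   # center maximal
  }
  expect_identical(gaussian_kernel(2)$size, 13L)
  # weights follow the Gaussian density formula, then renormalization;
  # pre-normalization center value is 1/(2 pi sigma^2)
  d <- seq(-3, 3)
  raw <- outer(d, d, function(i, j) exp(-(i^2 + j^2) / 2)) / (2 * pi)
  expect_lt(abs(raw[4, 4] - 1 / (2 * pi)), 1e-12)
  expect_equal(gaussian_kernel(1)$weights, raw / sum(raw), tolerance = 1e-12)
  expect_error(gaussian_kernel(0), "sigma")
  expect_error(gaussian_kernel(-2), "sigma")
})

test_that("region blur is local, inert on constants and variance-reducing", {
  set.seed(8)
  img <- matrix(runif(112 * 112), 112, 112)
  rg <- region_from_keypoints(rbind(c(30, 40), c(69, 59)), 800, c(112, 112))
  out2 <- blur_region(img, rg, 2)
  out20 <- blur_region(img, rg, 20)
  inside <- matrix(FALSE, 112, 112)
  inside[rg$y0:(rg$y0 + rg$height - 1) + 1, rg$x0:(rg$x0 + rg$width - 1) + 1] <- TRUE
  expect_identical(out2[!inside], img[!inside])       # locality, bit-exact
  expect_identical(out20[!inside], img[!inside])
  expect_lt(var(out20[inside]), var(out2[inside]))    # stronger smoothing
  expect_lt(var(out2[inside]), var(img[inside]))

  const <- matrix(0.37, 50, 50)
  rgc <- region_from_keypoints(rbind(c(5, 5), c(30, 30)), 700, c(50, 50))
  expect_equal(blur_region(const, rgc, 8), const, tolerance = 1e-12)
})

test_that("blur matches a brute-force double-sum with reflective borders", {
  set.seed(5)
  img <- matrix(runif(81), 9, 9)
  sigma <- 1.3
  k <- gaussian_kernel(sigma)
  r <- (k$size - 1) / 2
  reflect <- function(i, n) {
    while (i < 0 || i >= n) {
      if (i < 0) i <- -i - 1
      if (i >= n) i <- 2 * n - i - 1
    }
    i
  }
  oracle <- matrix(0, 9, 9)
  for (x in 0:8) for (y in 0:8) {
    acc <- 0
    for (i in -r:r) for (j in -r:r)
      acc <- acc + k$weights[i + r + 1, j + r + 1] *
        img[reflect(x + i, 9) + 1, reflect(y + j, 9) + 1]
    oracle[x + 1, y + 1] <- acc
  }
  rg <- region_from_keypoints(rbind(c(0, 0), c(8, 8)), 81, c(9, 9))
  expect_lt(max(abs(blur_region(img, rg, sigma) - oracle)), 1e-6)
})

test_that("lesion dispatch honors kind, locality and area accounting", {
  s <- clean_sample()
  expect_identical(apply_lesion(s, lesion_spec("none")), s$image)

  # all four features masked: zeroed pixels are exactly the union of the
  # four regions by direct pixel scan (regions of neighboring features
  # may overlap, so the union — not the area sum — is the contract)
  spec_all <- lesion_spec("mask", names(default_areas()))
  masked <- apply_lesion(s, spec_all)
  union <- matrix(FALSE, nrow(s$image), ncol(s$image))
  for (f in names(default_areas())) {
    rg <- region_from_keypoints(s$keypoints[[f]], default_areas()[[f]],
                                dim(s$image))
    union[rg$y0:(rg$y0 + rg$height - 1) + 1,
          rg$x0:(rg$x0 + rg$width - 1) + 1] <- TRUE
  }
  expect_identical(sum(masked == 0), sum(union))
  expect_true(all(masked[union] == 0))
  expect_identical(masked[!union], s$image[!union])

  # blur sigma levels differ only inside the lesioned region
  b2 <- apply_lesion(s, lesion_spec("blur", "eyes", sigma = 2))
  b20 <- apply_lesion(s, lesion_spec("blur", "eyes", sigma = 20))
  rg <- region_from_keypoints(s$keypoints$eyes, 800, dim(s$image))
  diff <- b2 != b20
  inside <- matrix(FALSE, nrow(diff), ncol(diff))
  inside[rg$y0:(rg$y0 + rg$height - 1) + 1,
         rg$x0:(rg$x0 + rg$width - 1) + 1] <- TRUE
  expect_true(all(!diff[!inside]))

  expect_error(lesion_spec("mask", "chin"), "unknown feature")
  expect_error(lesion_spec("blur", "eyes"), "sigma")
  # random masks reuse the features' template sizes, deterministically
  ra <- apply_lesion(s, lesion_spec("random_mask", "eyes", seed = 3))
  rb <- apply_lesion(s, lesion_spec("random_mask", "eyes", seed = 3))
  expect_identical(ra, rb)
  expect_identical(sum(ra == 0), 800L)
})
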