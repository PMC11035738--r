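# The condition grid, paired bootstrap, importance ranking,
# super-additivity arithmetic, error overlap, and emphasis tables.

test_that("the full grid enumerates 29 uniquely labelled conditions", {
  grid <- experiment_grid()
  expect_length(grid, 29)                     # 1 + 1 + 4 + 16 + 6 + 1
  expect_false(anyDuplicated(names(grid)) > 0)
  expect_setequal(
    names(grid)[startsWith(names(grid), "blur_")],
    as.vector(outer(c("eyebrows", "eyes", "nose", "mouth"),
                    c(2, 8, 10, 20),
                    function(f, s) sprintf("blur_%s_sigma%g", f, s))))
  expect_true(all(c("none", "random", "mask_all") %in% names(grid)))
})

test_that("run_grid on the none-only grid reduces to a single evaluation", {
  m <- tiny_model()
  ds <- tiny_dataset()
  grid <- experiment_grid(include_random = FALSE, include_blur = FALSE,
                          include_pairs = FALSE, include_all = FALSE)[1]
  res <- run_grid(m, ds, grid, tiny_area_config())
  expect_length(res, 1)
  val <- Filter(function(s) s$split_tag == "val", ds$samples)
  expect_identical(res$none$correct, evaluate_model(m, val)$correct)
})

test_that("paired bootstrap behaves at the identity, under separation and under the null", {
  a <- condition_result(rep(c(TRUE, FALSE), c(400, 100)), "a")
  same <- bootstrap_accuracy_diff(a, a, n_iter = 500, seed = 1)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # strong separation: 0.9 vs 0.5 at n = 500 (three seeds)
  for (s in 1:3) {
    hi <- condition_result(runif(500) < 0.9, "hi")
    lo <- condition_result(runif(500) < 0.5, "lo")
    bt <- bootstrap_accuracy_diff(hi, lo, n_iter = 5000, seed = s)
    expect_lt(bt$p_value, 0.001)
    expect_gt(bt$ci95[1], 0)
  }

  # determinism and A/B relabelling symmetry
  set.seed(9)
  b <- condition_result(runif(500) < 0.7, "b")
  c_ <- condition_result(runif(500) < 0.68, "c")
  t1 <- bootstrap_accuracy_diff(b, c_, n_iter = 1000, seed = 4)
  t2 <- bootstrap_accuracy_diff(b, c_, n_iter = 1000, seed = 4)
  expect_identical(t1$replicates, t2$replicates)
  flip <- bootstrap_accuracy_diff(c_, b, n_iter = 1000, seed = 4)
  expect_equal(flip$statistic, -t1$statistic)
  expect_equal(flip$p_value, t1$p_value)

  expect_error(bootstrap_accuracy_diff(a, condition_result(TRUE)), "paired")
})

test_that("bootstrap test is calibrated under the null", {
  # two independent 0.7-accuracy vectors: rejection rate at alpha = 0.05
  # over 300 repetitions should be near nominal
  set.seed(123)
  rej <- 0
  for (i in 1:300) {
    x <- condition_result(runif(500) < 0.7, "x")
    y <- condition_result(runif(500) < 0.7, "y")
    if (bootstrap_accuracy_diff(x, y, n_iter = 500, seed = i)$p_value < 0.05)
      rej <- rej + 1
  }
  expect_gt(rej / 300, 0.02)
  expect_lt(rej / 300, 0.09)
})

test_that("importance ranking orders features by masked accuracy", {
  # reference-style accuracy DROPS of 43.0 / 30.1 / 20.3 / 14.5 points
  # from an 86.5% baseline: eyebrows leave the lowest masked accuracy and
  # rank most important, giving eyebrows > eyes > mouth > nose
  res <- list(none = fixture_result(0.865, label = "none"),
              mask_eyebrows = fixture_result(0.865 - 0.430,
                                             label = "mask_eyebrows"),
              mask_eyes = fixture_result(0.865 - 0.301, label = "mask_eyes"),
              mask_mouth = fixture_result(0.865 - 0.203, label = "mask_mouth"),
              mask_nose = fixture_result(0.865 - 0.145, label = "mask_nose"))
  imp <- rank_importance(res, seed = 2)
  expect_identical(imp$order, c("eyebrows", "eyes", "mouth", "nose"))
  expect_equal(imp$ranking$drop, c(43.0, 30.1, 20.3, 14.5), tolerance = 1e-9)
  expect_true(all(imp$ranking$p_vs_none < 0.05))

  # all-equal accuracies: stable input order, nothing significant
  eq <- fixture_result(0.5)
  res_eq <- list(none = eq, mask_eyebrows = eq, mask_eyes = eq,
                 mask_nose = eq, mask_mouth = eq)
  imp_eq <- rank_importance(res_eq, seed = 3)
  expect_identical(imp_eq$order, c("eyebrows", "eyes", "nose", "mouth"))
  expect_true(all(imp_eq$ranking$p_vs_none > 0.5))
  expect_error(rank_importance(res[-1]), "lack conditions")
})

test_that("super-additivity reproduces the reference arithmetic exactly", {
  res <- list(none = fixture_result(0.862, label = "none"),
              mask_eyes = fixture_result(0.862 - 0.331, label = "mask_eyes"),
              mask_mouth = fixture_result(0.862 - 0.214, label = "mask_mouth"),
              mask_eyes.mouth = fixture_result(0.862 - 0.682,
                                               label = "mask_eyes.mouth"))
  rep_ <- superadditivity(res, c("eyes", "mouth"))
  expect_equal(rep_$drop_A, 33.1)
  expect_equal(rep_$drop_B, 21.4)
  expect_equal(rep_$drop_AB, 68.2)
  expect_equal(rep_$sum_drops, 54.5)
  expect_equal(rep_$excess, 13.7)
  # independent of pair ordering
  rev_ <- superadditivity(res, c("mouth", "eyes"))
  expect_equal(rev_$excess, rep_$excess)
  expect_identical(rev_$pair, rep_$pair)

  # exact additivity: zero excess
  res2 <- list(none = fixture_result(0.9, label = "none"),
               mask_eyes = fixture_result(0.8, label = "mask_eyes"),
               mask_mouth = fixture_result(0.7, label = "mask_mouth"),
               mask_eyes.mouth = fixture_result(0.6,
                                                label = "mask_eyes.mouth"))
  expect_equal(superadditivity(res2, c("eyes", "mouth"))$excess, 0)
  expect_error(superadditivity(res2, c("eyes", "nose")), "lack conditions")
})

test_that("error-set overlap follows direct set arithmetic", {
  mk <- function(err, n = 10) {
    correct <- rep(TRUE, n)
    correct[err] <- FALSE
    condition_result(correct)
  }
  same <- error_overlap(mk(2:4), mk(2:4))
  expect_equal(same$fraction_of_A, 1)
  expect_equal(same$fraction_of_B, 1)

  dis <- error_overlap(mk(1:3), mk(7:9))
  expect_equal(dis$fraction_of_A, 0)
  expect_equal(dis$fraction_of_B, 0)

  ov <- error_overlap(mk(1:5), mk(4:7))
  expect_equal(ov$fraction_of_A, 2 / 5)
  expect_equal(ov$fraction_of_B, 2 / 4)

  none_err <- error_overlap(mk(integer(0)), mk(1:3))
  expect_true(none_err$empty_error_set)
  expect_equal(none_err$fraction_of_A, 0)
})

test_that("emphasis tables stay on the 0-255 scale and mix strata exactly", {
  m <- tiny_model()
  val <- Filter(function(s) s$split_tag == "val", tiny_dataset()$samples)
  emp <- emphasis_tables(m, val[1:10], area_config = tiny_area_config())
  expect_true(all(emp$weights$weight >= 0 & emp$weights$weight <= 255))
  expect_true(all(abs(emp$redirection$mean_delta) <= 255, na.rm = TRUE))
  # the All stratum is the count-weighted mean of true/false
  for (f in unique(emp$redirection$feature)) {
    sub <- emp$redirection[emp$redirection$feature == f, ]
    tr <- sub[sub$stratum == "true", ]
    fa <- sub[sub$stratum == "false", ]
    al <- sub[sub$stratum == "all", ]
    parts <- c(tr$mean_delta * tr$n, fa$mean_delta * fa$n)
    expect_equal(sum(parts, na.rm = TRUE) / al$n, al$mean_delta,
                 tolerance = 1e-9)
  }
})
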