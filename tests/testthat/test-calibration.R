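test_that("zscore_interval matches the hand-computed normal-quantile interval", {
  # constant values: zero-width interval
  ci0 <- zscore_interval(rep(0.9, 4))
  expect_equal(ci0$lower, 0.9)
  expect_equal(ci0$upper, 0.9)

  # values (0.8, 1.0): sd = sqrt(0.02), limits 0.9 -/+ 1.96... * sqrt(0.02)
  ci <- zscore_interval(c(0.8, 1.0))
  z <- qnorm(0.975)
  expect_equal(ci$lower, 0.9 - z * sqrt(0.02))
  expect_equal(ci$upper, 0.9 + z * sqrt(0.02))

  expect_error(zscore_interval(0.5), "at least 2")
})

test_that("roc_auc equals the brute-force pairwise oracle on random inputs", {
  withr::with_seed(42, {
    for (i in 1:100) {
      n_p <- sample(2:12, 1)
      n_b <- sample(2:12, 1)
      # occasional ties via rounding
      p <- round(runif(n_p), sample(c(1, 3), 1))
      b <- round(runif(n_b), sample(c(1, 3), 1))
      expect_equal(roc_auc(p, b), brute_force_auc(p, b))
    }
  })
})

test_that("roc_auc is 1 for separated groups, 0.5 for identical, complementary on swap", {
  expect_identical(roc_auc(c(0.84, 0.9, 1.03), c(0.14, 0.26, 0.48)), 1)
  expect_equal(roc_auc(c(1, 2, 3), c(1, 2, 3)), 0.5)
  expect_equal(roc_auc(c(0.9, 0.2), c(0.1, 0.8)),
               brute_force_auc(c(0.9, 0.2), c(0.1, 0.8)))
  withr::with_seed(7, {
    a <- runif(9)
    b <- runif(7)
    expect_equal(roc_auc(a, b) + roc_auc(b, a), 1)
  })
})

test_that("intermediate cutoff is the benchmark midpoint when AUC is 1", {
  expect_equal(intermediate_cutoff(c(0.84, 0.9), c(0.2, 0.48), auc = 1), 0.66)
  expect_equal(intermediate_cutoff(c(1, 1.2), c(0, 0), auc = 1), 0.5)
})

test_that("intermediate cutoff maximizes Youden's J when groups overlap", {
  p <- c(0.9, 0.6)
  b <- c(0.7, 0.2)
  expect_lt(roc_auc(p, b), 1)
  expect_equal(intermediate_cutoff(p, b), brute_force_youden(p, b))
  expect_equal(intermediate_cutoff(p, b), 0.4) # frozen from the oracle; tie -> smallest

  withr::with_seed(11, {
    for (i in 1:25) {
      pp <- runif(sample(3:9, 1))
      bb <- runif(sample(3:9, 1))
      if (abs(roc_auc(pp, bb) - 1) <= 1e-12) next
      expect_equal(intermediate_cutoff(pp, bb), brute_force_youden(pp, bb))
    }
  })
})

test_that("per-group calibration uses each group's Z-score limit", {
  bench <- tibble::tibble(
    mean_value = c(0.85, 0.9, 0.95, 0.2, 0.25, 0.3),
    benchmark_label = rep(c("pathogenic", "benign"), each = 3)
  )
  ts <- calibrate_thresholds(bench)
  z <- qnorm(0.975)
  expect_equal(ts$t_deleterious, 0.9 - z * sd(c(0.85, 0.9, 0.95)))
  expect_equal(ts$t_neutral, 0.25 + z * sd(c(0.2, 0.25, 0.3)))
  expect_identical(ts$auc, 1)
  expect_equal(ts$t_mid, (0.85 + 0.3) / 2)
})

test_that("zero-variance benchmarks give the group means as thresholds", {
  bench <- tibble::tibble(
    mean_value = c(1, 1, 0, 0),
    benchmark_label = rep(c("pathogenic", "benign"), each = 2)
  )
  ts <- calibrate_thresholds(bench)
  expect_equal(ts$t_deleterious, 1)
  expect_equal(ts$t_neutral, 0)
})

test_that("overlapping benchmark intervals are a calibration error", {
  bench <- tibble::tibble(
    mean_value = c(0.5, 0.6, 0.4, 0.55),
    benchmark_label = rep(c("pathogenic", "benign"), each = 2)
  )
  # hand check: pathogenic lower 0.55 - 1.96*sd < benign upper
  expect_error(calibrate_thresholds(bench), "overlap")
  expect_error(calibrate_thresholds(bench[c(1, 3), ]), ">= 2")
})

test_that("thresholds are translation-equivariant", {
  withr::with_seed(3, {
    p <- rnorm(9, 0.9, 0.05)
    b <- rnorm(7, 0.26, 0.1)
    bench <- tibble::tibble(
      mean_value = c(p, b),
      benchmark_label = rep(c("pathogenic", "benign"), c(9, 7))
    )
    delta <- 0.37
    shifted <- bench |> dplyr::mutate(mean_value = mean_value + delta)
    t0 <- calibrate_thresholds(bench)
    t1 <- calibrate_thresholds(shifted)
    expect_equal(t1$t_deleterious, t0$t_deleterious + delta)
    expect_equal(t1$t_neutral, t0$t_neutral + delta)
    expect_equal(t1$t_mid, t0$t_mid + delta)
  })
})

test_that("synthetic benchmarks at the study conditions recover the structure", {
  hits <- 0
  for (seed in 1:20) {
    withr::with_seed(seed, {
      p <- rnorm(9, 0.90, 0.05)
      b <- rnorm(7, 0.26, 0.10)
    })
    bench <- tibble::tibble(
      mean_value = c(p, b),
      benchmark_label = rep(c("pathogenic", "benign"), c(9, 7))
    )
    ts <- try(calibrate_thresholds(bench), silent = TRUE)
    if (!inherits(ts, "try-error") &&
        abs(ts$auc - 1) <= 1e-12 &&
        ts$t_deleterious < 0.90 && ts$t_neutral > 0.26) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 19)
})

test_that("explicit thresholds validate ordering and tidy/glance round out the fit", {
  expect_error(threshold_set(0.44, 0.81, 0.66), "t_neutral < t_mid")
  ts <- threshold_set(0.81, 0.44, 0.66)
  td <- tidy(ts)
  expect_equal(td$value, c(0.81, 0.66, 0.44))
  expect_equal(td$threshold, c("deleterious", "midpoint", "neutral"))
  bench <- tibble::tibble(
    mean_value = c(0.85, 0.9, 0.95, 0.2, 0.25, 0.3),
    benchmark_label = rep(c("pathogenic", "benign"), each = 3)
  )
  g <- glance(calibrate_thresholds(bench))
  expect_equal(g$pathogenic_mean, 0.9)
  expect_equal(g$benign_mean, 0.25)
  expect_equal(g$n_pathogenic, 3L)
})

test_that("pooled interval mode uses one interval over the union", {
  bench <- tibble::tibble(
    mean_value = c(0.85, 0.9, 0.95, 0.2, 0.25, 0.3),
    benchmark_label = rep(c("pathogenic", "benign"), each = 3)
  )
  ts <- calibrate_thresholds(bench, interval_mode = "pooled")
  ci <- zscore_interval(bench$mean_value)
  expect_equal(ts$t_deleterious, ci$upper)
  expect_equal(ts$t_neutral, ci$lower)
})

test_that("roc_auc matches an established ROC implementation", {
  withr::with_seed(555, {
    p <- rnorm(9, 0.9, 0.1)
    b <- rnorm(7, 0.3, 0.15)
  })
  ref <- as.numeric(pROC::auc(
    response = rep(c(1, 0), c(length(p), length(b))),
    predictor = c(p, b), direction = "<", quiet = TRUE))
  expect_equal(roc_auc(p, b), ref)
})
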