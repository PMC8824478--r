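test_that("cell-cycle tables are validated for range and row sums", {
  ok <- tibble::tibble(variant = "v", pct_g1 = 47, pct_s = 10.5, pct_g2m = 42.5)
  expect_silent(validate_cell_cycle(ok))
  expect_error(validate_cell_cycle(ok |> dplyr::mutate(pct_g1 = 105)), "0, 100")
  expect_error(validate_cell_cycle(ok |> dplyr::mutate(pct_s = 30)), "sum")
  expect_error(validate_cell_cycle(ok |> dplyr::select(-pct_s)), "pct_s")
})

test_that("group summaries give mean and range per functional group", {
  profiles <- tibble::tibble(
    variant = c("a", "b", "c", "d"),
    pct_g1 = c(43.0, 50.9, 47.7, 60),
    pct_s = c(10, 10, 10, 10),
    pct_g2m = c(47.0, 39.1, 42.3, 30)
  )
  calls <- tibble::tibble(
    variant = c("a", "b", "c", "d"),
    benchmark_label = c("pathogenic", "pathogenic", "pathogenic", "benign"),
    category = NA_character_
  )
  s <- suppressWarnings(cell_cycle_group_summary(profiles, calls))
  path_g1 <- s |> dplyr::filter(functional_group == "benchmark_pathogenic",
                                phase == "G1")
  expect_equal(path_g1$mean, mean(c(43, 50.9, 47.7)))
  expect_equal(path_g1$min, 43)
  expect_equal(path_g1$max, 50.9)
  single <- s |> dplyr::filter(functional_group == "benchmark_benign",
                               phase == "G1")
  expect_equal(c(single$mean, single$min, single$max), c(60, 60, 60))
  # VUS groups are empty here and flagged
  expect_warning(cell_cycle_group_summary(profiles, calls), "empty")
})

test_that("students_t_test reproduces the hand-evaluated pooled formula", {
  tt <- students_t_test(c(1, 2, 3), c(4, 5, 6))
  oracle <- students_t_oracle(c(1, 2, 3), c(4, 5, 6))
  expect_equal(tt$df, 4)
  expect_equal(tt$t_statistic, oracle$t)
  expect_equal(tt$p_value, oracle$p, tolerance = 1e-10)

  expect_error(students_t_test(1, c(1, 2, 3)), "at least 2")
})

test_that("t test is symmetric and handles degenerate zero-variance input", {
  a <- c(47, 48, 49)
  b <- c(50, 52, 55)
  ab <- students_t_test(a, b)
  ba <- students_t_test(b, a)
  expect_equal(ab$t_statistic, -ba$t_statistic)
  expect_equal(ab$p_value, ba$p_value)

  same <- students_t_test(c(47, 48, 49), c(47, 48, 49))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)

  flat_same <- students_t_test(c(5, 5), c(5, 5))
  expect_equal(flat_same$p_value, 1)
  expect_true(flat_same$degenerate)
  flat_diff <- students_t_test(c(5, 5), c(6, 6))
  expect_equal(flat_diff$p_value, 0)
  expect_true(flat_diff$degenerate)
})

test_that("p values agree with the numerically integrated t-density oracle", {
  withr::with_seed(2024, {
    for (i in 1:20) {
      a <- rnorm(sample(3:8, 1), 50, 4)
      b <- rnorm(sample(3:8, 1), 55, 4)
      tt <- students_t_test(a, b)
      oracle <- students_t_oracle(a, b)
      expect_equal(tt$p_value, oracle$p, tolerance = 1e-8)
    }
  })
})

test_that("the four reported comparisons run and detect the simulated separation", {
  # G1 means 47 vs 63, sd 3, n = 9 and 7: power check across seeds
  significant <- 0
  n_seeds <- 40
  for (seed in seq_len(n_seeds)) {
    withr::with_seed(seed, {
      a <- rnorm(9, 47, 3)
      b <- rnorm(7, 63, 3)
    })
    if (students_t_test(a, b)$p_value < 0.01) significant <- significant + 1
  }
  expect_gte(significant / n_seeds, 0.95)
})

test_that("compare_functional_groups flags an inverted G1 direction", {
  profiles <- tibble::tibble(
    variant = sprintf("v%02d", 1:8),
    pct_g1 = c(65, 66, 64, 63, 47, 46, 48, 45), # deleterious-side HIGH: inverted
    pct_s = 10,
    pct_g2m = 100 - c(65, 66, 64, 63, 47, 46, 48, 45) - 10
  )
  calls <- tibble::tibble(
    variant = profiles$variant,
    benchmark_label = rep(c("pathogenic", "benign"), each = 4),
    category = NA_character_
  )
  cmp <- suppressWarnings(compare_functional_groups(profiles, calls))
  g1 <- cmp |> dplyr::filter(phase == "G1", group_a == "benchmark_pathogenic")
  expect_true(g1$direction_inverted)
  # the same construction inverts G2/M as well (lower on the deleterious side)
  g2m <- cmp |> dplyr::filter(phase == "G2M", group_a == "benchmark_pathogenic")
  expect_true(g2m$direction_inverted)
})

test_that("fixture group means land inside the published ranges", {
  fx <- published_fixture()
  calls <- fx$replicates |>
    normalize_proliferation() |>
    dplyr::filter(variant != EMPTY_VECTOR, cell_line == "PANC-1") |>
    summarize_proliferation() |>
    classify_variants(threshold_set(0.81, 0.44, 0.66)) |>
    dplyr::left_join(fx$variants, by = "variant")
  s <- cell_cycle_group_summary(fx$cell_cycle, calls)
  g1 <- function(grp) s |> dplyr::filter(functional_group == grp, phase == "G1")
  expect_true(g1("benchmark_pathogenic")$mean >= 43 &&
                g1("benchmark_pathogenic")$mean <= 50.9)
  expect_true(g1("benchmark_benign")$mean >= 58.4 &&
                g1("benchmark_benign")$mean <= 67.1)
  expect_true(g1("vus_deleterious")$mean >= 42.2 &&
                g1("vus_deleterious")$mean <= 52.3)
  expect_true(g1("vus_neutral")$mean >= 57.6 &&
                g1("vus_neutral")$mean <= 68.8)
})
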