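published_ts <- threshold_set(0.81, 0.44, 0.66)

test_that("values map to the published four tiers, boundaries included", {
  got <- classify_value(c(0.84, 0.70, 0.50, 0.26, 0.81, 0.66, 0.44), published_ts)
  expect_equal(as.character(got), c(
    "functionally_deleterious",
    "potentially_functionally_deleterious",
    "potentially_functionally_neutral",
    "functionally_neutral",
    "potentially_functionally_deleterious", # 0.81 exactly: <= t_deleterious
    "potentially_functionally_neutral",     # 0.66 exactly: <= t_mid
    "potentially_functionally_neutral"      # 0.44 exactly: >= t_neutral
  ))
  expect_error(classify_value(-0.1, published_ts), "nonnegative")
})

test_that("the legend boundary convention flips only the exact-midpoint case", {
  expect_equal(
    as.character(classify_value(0.66, published_ts, boundary = "mid_inclusive")),
    "potentially_functionally_deleterious")
  same <- c(0.659, 0.661, 0.2, 0.9)
  expect_equal(classify_value(same, published_ts),
               classify_value(same, published_ts, boundary = "mid_inclusive"))
})

test_that("the four categories partition nonnegative values for random thresholds", {
  withr::with_seed(99, {
    for (i in 1:1000) {
      cuts <- sort(runif(3, 0, 1.5))
      ts <- threshold_set(cuts[3], cuts[1], cuts[2])
      x <- runif(1, 0, 2)
      cat <- classify_value(x, ts)
      expect_false(is.na(cat))
      expect_length(cat, 1)
    }
  })
})

test_that("increasing the mean never moves the call toward the neutral side", {
  withr::with_seed(123, {
    for (i in 1:50) {
      cuts <- sort(runif(3, 0, 1.5))
      ts <- threshold_set(cuts[3], cuts[1], cuts[2])
      x <- sort(runif(40, 0, 2))
      codes <- as.integer(classify_value(x, ts)) # level 1 = deleterious
      expect_true(all(diff(codes) <= 0))
    }
  })
})

test_that("consensus calls classify pooled means against pooled-benchmark thresholds", {
  fx <- published_fixture()
  summaries <- fx$replicates |>
    normalize_proliferation() |>
    dplyr::filter(variant != EMPTY_VECTOR) |>
    summarize_proliferation()
  cons <- consensus_calls(summaries, fx$variants, thresholds = published_ts)
  expect_true(all(cons$cell_line == "pooled"))
  vus <- cons |> dplyr::filter(benchmark_label == "vus")
  tab <- tabulate_categories(vus)
  expect_equal(tab$n, c(11L, 1L, 2L, 15L))
  expect_equal(
    sort(vus$variant[vus$category == "potentially_functionally_neutral"]),
    c("p.Asp74His", "p.Gly122Val"))
  expect_equal(
    vus$variant[vus$category == "potentially_functionally_deleterious"],
    "p.Ala20Gly")

  # recalibrated pooled thresholds derive from the pooled benchmark means
  cons2 <- consensus_calls(summaries, fx$variants)
  expect_s3_class(cons2, "tbl_df")
  expect_equal(nrow(cons2), 45)
})

test_that("agreement fails only across deleterious/neutral sides", {
  calls <- tibble::tibble(
    variant = c("a", "a", "a", "b", "b", "c", "c", "d"),
    cell_line = c("L1", "L2", "L3", "L1", "L2", "L1", "L2", "L1"),
    category = c("functionally_deleterious",
                 "potentially_functionally_deleterious",
                 "functionally_deleterious",
                 "functionally_deleterious", "functionally_neutral",
                 "potentially_functionally_neutral", "functionally_neutral",
                 "functionally_deleterious")
  )
  rep <- check_agreement(calls) |> dplyr::arrange(variant)
  expect_true(rep$agrees[rep$variant == "a"])
  expect_false(rep$agrees[rep$variant == "b"])
  expect_match(rep$conflict_detail[rep$variant == "b"], "L1.*L2")
  expect_true(rep$agrees[rep$variant == "c"])
  expect_false(rep$evaluable[rep$variant == "d"])
  expect_true(is.na(rep$agrees[rep$variant == "d"]))
})

test_that("ACMG reclassification upgrades only deleterious-side VUSs, idempotently", {
  calls <- tibble::tibble(
    prior_class = c("vus", "vus", "vus", "vus", "pathogenic", "likely_benign"),
    category = c("functionally_deleterious",
                 "potentially_functionally_deleterious",
                 "potentially_functionally_neutral", "functionally_neutral",
                 "functionally_deleterious", "functionally_neutral")
  )
  out <- reclassify_acmg(calls)
  expect_equal(out$new_class,
               c("likely_pathogenic", "likely_pathogenic", "remains_vus",
                 "remains_vus", "pathogenic", "likely_benign"))
  expect_equal(out$evidence_code,
               c("PS3", "PS3", NA, NA, NA, NA))
  # idempotence: reclassifying the already-reclassified output changes nothing
  again <- reclassify_acmg(out |> dplyr::mutate(prior_class = new_class) |>
                             dplyr::select(prior_class, category))
  expect_equal(again$new_class, out$new_class)
})

test_that("category tables count every tier and report one-decimal percentages", {
  calls <- tibble::tibble(category = factor(
    rep(functional_categories(), c(11, 1, 3, 14)),
    levels = functional_categories()))
  tab <- tabulate_categories(calls)
  expect_equal(sum(tab$n), 29L)
  expect_equal(tab$pct, c(37.9, 3.4, 10.3, 48.3))

  empty <- tabulate_categories(calls[0, , drop = FALSE])
  expect_equal(sum(empty$n), 0L)
  expect_true(all(is.na(empty$pct)))

  all_del <- tabulate_categories(
    tibble::tibble(category = rep("functionally_deleterious", 4)))
  expect_equal(all_del$pct, c(100, 0, 0, 0))
})
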