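# Constraint-satisfying synthetic fixture reproducing the published summary
# statistics (group means, range extrema, category lists, cohort counts).
# Per-variant values inside the printed ranges are otherwise arbitrary: the
# real per-variant measurements are not public in per-variant form and are
# not bundled.

fixture_variant_values <- function() {
  # PANC-1 means: pathogenic benchmarks average exactly 0.90 with range
  # [0.84, 1.03]; benign benchmarks average exactly 0.26 with range
  # [0.14, 0.48]. VUS means place each variant in its published category.
  tibble::tribble(
    ~variant,           ~prior_class,        ~panc1, ~miapaca2, ~aspc1,
    "p.Leu16Arg",       "pathogenic",         0.85,  0.85,  0.85,
    "p.Arg24Pro",       "pathogenic",         0.87,  0.87,  0.87,
    "p.Met53Ile",       "pathogenic",         0.89,  0.89,  0.89,
    "p.Gly101Trp",      "pathogenic",         0.94,  0.94,  0.94,
    "p.Val126Asp",      "pathogenic",         1.03,  1.03,  1.03,
    "p.Ile49Thr",       "likely_pathogenic",  0.86,  0.86,  0.86,
    "p.Leu78Hisfs*41",  "likely_pathogenic",  0.84,  0.84,  0.84,
    "p.His83Tyr",       "likely_pathogenic",  0.90,  0.90,  0.90,
    "p.Asp84Asn",       "likely_pathogenic",  0.92,  0.92,  0.92,
    "WT",               "wild_type",          0.14,  0.14,  0.14,
    "p.Ala57Val",       "likely_benign",      0.16,  0.16,  0.16,
    "p.Ala100Ser",      "likely_benign",      0.20,  0.20,  0.20,
    "p.His123Gln",      "likely_benign",      0.24,  0.24,  0.24,
    "p.Ala127Ser",      "likely_benign",      0.28,  0.28,  0.28,
    "p.Arg144Cys",      "likely_benign",      0.32,  0.32,  0.32,
    "p.Ala148Thr",      "benign",             0.48,  0.48,  0.48,
    "p.Thr18Pro",       "vus",                0.95,  0.93,  0.91,
    "p.Ala20Gly",       "vus",                0.82,  0.77,  0.75,
    "p.Gln50Arg",       "vus",                0.99,  0.80,  0.80,
    "p.Leu65Pro",       "vus",                0.72,  0.95,  0.90,
    "p.His66Pro",       "vus",                0.96,  0.92,  0.90,
    "p.Ala68Val",       "vus",                1.00,  0.79,  0.78,
    "p.Asp74Ala",       "vus",                0.94,  0.92,  0.96,
    "p.Asp84Ala",       "vus",                0.98,  0.94,  0.92,
    "p.Gly89Asp",       "vus",                1.02,  0.80,  0.79,
    "p.Ala109Pro",      "vus",                0.93,  0.89,  0.80,
    "p.Ala127Pro",      "vus",                1.01,  0.78,  0.77,
    "p.Arg128Pro",      "vus",                0.92,  0.90,  0.88,
    "p.Asp74His",       "vus",                0.60,  0.55,  0.50,
    "p.Gly111Ser",      "vus",                0.50,  0.30,  0.40,
    "p.Gly122Val",      "vus",                0.55,  0.60,  0.52,
    "p.Met9Thr",        "vus",                0.20,  0.46,  0.45,
    "p.Pro11Leu",       "vus",                0.18,  0.30,  0.46,
    "p.Arg24Gln",       "vus",                0.22,  0.28,  0.47,
    "p.Pro41Gln",       "vus",                0.25,  0.32,  0.48,
    "p.His66Arg",       "vus",                0.30,  0.34,  0.49,
    "p.Gly67Arg",       "vus",                0.15,  0.18,  0.20,
    "p.Glu69Gly",       "vus",                0.17,  0.20,  0.22,
    "p.Arg99Gly",       "vus",                0.35,  0.36,  0.50,
    "p.Gly101Arg",      "vus",                0.19,  0.22,  0.24,
    "p.Arg124Cys",      "vus",                0.28,  0.30,  0.32,
    "p.Asp125His",      "vus",                0.33,  0.35,  0.36,
    "p.Ala134Thr",      "vus",                0.24,  0.26,  0.28,
    "p.Gly139Arg",      "vus",                0.21,  0.23,  0.25,
    "p.Ala143Thr",      "vus",                0.26,  0.28,  0.30
  )
}

# Published per-category VUS lists for PANC-1 calls.
fixture_published_lists <- function() {
  list(
    deleterious = c("p.Thr18Pro", "p.Ala20Gly", "p.Gln50Arg", "p.His66Pro",
                    "p.Ala68Val", "p.Asp74Ala", "p.Asp84Ala", "p.Gly89Asp",
                    "p.Ala109Pro", "p.Ala127Pro", "p.Arg128Pro"),
    potentially_deleterious = "p.Leu65Pro",
    potentially_neutral = c("p.Asp74His", "p.Gly111Ser", "p.Gly122Val"),
    neutral = c("p.Met9Thr", "p.Pro11Leu", "p.Arg24Gln", "p.Pro41Gln",
                "p.His66Arg", "p.Gly67Arg", "p.Glu69Gly", "p.Arg99Gly",
                "p.Gly101Arg", "p.Arg124Cys", "p.Asp125His", "p.Ala134Thr",
                "p.Gly139Arg", "p.Ala143Thr")
  )
}

# Cell-cycle values: offsets from the published group mean, chosen to sum
# to zero (exact group mean) while touching the published range endpoints.
fixture_cell_cycle_values <- function() {
  mk <- function(mean, offsets) mean + offsets
  g1 <- list(
    benchmark_pathogenic = mk(47.2, c(-4.2, 3.7, -2, 2, -1, 1, -0.5, 0.5, 0.5)),
    benchmark_benign = mk(63.1, c(-4.7, 4.0, -2, 2, -1, 1, 0.7)),
    vus_deleterious = mk(48.5, c(-6.3, 3.8, 2.5, -2, 2, -1, 1, -0.5, 0.5, 0, 0, 0)),
    vus_neutral = mk(62.8, c(-5.2, 6.0, -0.8, -2, 2, -1, 1, -1.5, 1.5, -0.5,
                             0.5, -1, 1, -2, 2, 0, 0))
  )
  g2m <- list(
    benchmark_pathogenic = mk(42.4, c(-4.7, 6.8, -2, 2, -1, 1, -0.7, -0.7, -0.7)),
    benchmark_benign = mk(25.7, c(-6.4, 9.4, -2, 2, -1, 1, -3)),
    vus_deleterious = mk(40.4, c(-3.1, 5.1, -2, 2, -1, 1, -0.5, 0.5, -1, -1, 0, 0)),
    vus_neutral = mk(26.6, c(-7.7, 10.0, -2.3, -2, 2, -1, 1, -1.5, 1.5, -0.5,
                             0.5, -1, 1, -2, 2, 0, 0))
  )
  list(g1 = g1, g2m = g2m)
}

fixture_cell_cycle <- function(variants_by_group) {
  vals <- fixture_cell_cycle_values()
  purrr::map_dfr(names(variants_by_group), function(grp) {
    members <- variants_by_group[[grp]]
    # Pair low G1 with high G2/M so every row's S fraction stays positive.
    g1 <- sort(vals$g1[[grp]])
    g2m <- sort(vals$g2m[[grp]], decreasing = TRUE)
    stopifnot(length(members) == length(g1))
    tibble(
      variant = members,
      functional_group = grp,
      pct_g1 = g1,
      pct_s = 100 - g1 - g2m,
      pct_g2m = g2m
    )
  })
}

#' Synthetic fixture reproducing the published summary constraints
#'
#' Builds the full 45-variant synthetic dataset (9 benchmark pathogenic, 7
#' benchmark benign including the wild-type control, 29 VUSs) across the
#' three CDKN2A-null PDAC cell lines, with per-variant PANC-1 means chosen
#' to satisfy every published summary simultaneously: benchmark group means
#' of exactly 0.90 and 0.26 with range extrema 0.84/1.03 and 0.14/0.48, and
#' the published four-tier category membership of each VUS under thresholds
#' (0.81, 0.44, 0.66). Replicates are back-computed to give each mean
#' exactly with a replicate s.d. of 0.02. Cell-cycle G1 and G2/M values hit
#' the published group means exactly and stay within the published ranges.
#' All values are synthetic constraint solutions, not measurements.
#'
#' The fixture's internal consistency is verified at generation time; an
#' assembly that violated any constraint would raise an error.
#'
#' @return A list of tibbles: `variants` (annotations and prior ACMG class),
#'   `replicates` (raw synthetic cell counts including empty-vector
#'   controls), `panc1_means` (the designed per-variant PANC-1 means),
#'   `cell_cycle` (per-variant phase percentages), and `cohorts`
#'   (the published cohort count table, as [pdac_cohorts()]).
#' @examples
#' fx <- published_fixture()
#' dplyr::count(fx$variants, benchmark_label)
#' @export
published_fixture <- function() {
  vals <- fixture_variant_values()
  variants <- vals |>
    mutate(
      benchmark_label = dplyr::case_when(
        .data$prior_class %in% c("pathogenic", "likely_pathogenic") ~ "pathogenic",
        .data$prior_class %in% c("benign", "likely_benign", "wild_type") ~ "benign",
        TRUE ~ "vus"
      )
    ) |>
    select("variant", "prior_class", "benchmark_label")

  lines <- c("PANC-1" = "panc1", "MIA PaCa-2" = "miapaca2", "AsPC-1" = "aspc1")
  controls <- c("PANC-1" = 1e6, "MIA PaCa-2" = 8e5, "AsPC-1" = 1.2e6)
  days <- c("PANC-1" = 14L, "MIA PaCa-2" = 7L, "AsPC-1" = 14L)
  rep_half_spread <- 0.02 # replicate values mean +/- 0.02 -> s.d. exactly 0.02

  replicates <- purrr::map_dfr(names(lines), function(cl) {
    means <- vals[[lines[[cl]]]]
    var_rows <- tidyr::expand_grid(
      tibble(variant = vals$variant, mean_value = means),
      replicate = 1:3
    ) |>
      mutate(
        value = .data$mean_value + rep_half_spread * (.data$replicate - 2L),
        cell_line = cl,
        endpoint_day = days[[cl]],
        cell_count = .data$value * controls[[cl]]
      ) |>
      select("variant", "cell_line", "replicate", "endpoint_day", "cell_count")
    ctrl_rows <- tibble(
      variant = EMPTY_VECTOR, cell_line = cl, replicate = 1:3,
      endpoint_day = days[[cl]], cell_count = controls[[cl]]
    )
    bind_rows(var_rows, ctrl_rows)
  })

  published <- fixture_published_lists()
  groups <- list(
    benchmark_pathogenic = variants$variant[variants$benchmark_label == "pathogenic"],
    benchmark_benign = variants$variant[variants$benchmark_label == "benign"],
    vus_deleterious = c(published$deleterious, published$potentially_deleterious),
    vus_neutral = c(published$potentially_neutral, published$neutral)
  )
  cell_cycle <- fixture_cell_cycle(groups) |>
    select("variant", "pct_g1", "pct_s", "pct_g2m")

  fx <- list(
    variants = variants,
    replicates = replicates,
    panc1_means = vals |> select("variant", mean_value = "panc1"),
    cell_cycle = cell_cycle,
    cohorts = pdac_cohorts()
  )
  verify_published_fixture(fx)
  fx
}

# Internal consistency check run every time the fixture is built.
verify_published_fixture <- function(fx) {
  ok <- function(cond, what) if (!isTRUE(cond)) {
    stop("fixture constraint violated: ", what, call. = FALSE)
  }
  v <- fx$variants
  ok(nrow(v) == 45, "45 variants")
  ok(sum(v$benchmark_label == "pathogenic") == 9, "9 pathogenic benchmarks")
  ok(sum(v$benchmark_label == "benign") == 7, "7 benign benchmarks")
  ok(sum(v$benchmark_label == "vus") == 29, "29 VUSs")

  summaries <- fx$replicates |>
    normalize_proliferation() |>
    filter(.data$variant != EMPTY_VECTOR) |>
    summarize_proliferation()
  panc1 <- summaries |>
    filter(.data$cell_line == "PANC-1") |>
    left_join(v, by = "variant")
  path <- panc1$mean_value[panc1$benchmark_label == "pathogenic"]
  ben <- panc1$mean_value[panc1$benchmark_label == "benign"]
  tol <- 1e-9
  ok(abs(mean(path) - 0.90) < tol, "pathogenic mean 0.90")
  ok(abs(min(path) - 0.84) < tol && abs(max(path) - 1.03) < tol,
     "pathogenic range 0.84-1.03")
  ok(abs(mean(ben) - 0.26) < tol, "benign mean 0.26")
  ok(abs(min(ben) - 0.14) < tol && abs(max(ben) - 0.48) < tol,
     "benign range 0.14-0.48")
  ok(abs(roc_auc(path, ben) - 1) <= 1e-12, "benchmark AUC 1")
  ok(abs(intermediate_cutoff(path, ben) - 0.66) < tol, "midpoint cutoff 0.66")
  ok(all(abs(panc1$sd_value - 0.02) < tol), "replicate s.d. 0.02")

  published <- fixture_published_lists()
  calls <- panc1 |>
    filter(.data$benchmark_label == "vus") |>
    classify_variants(threshold_set(0.81, 0.44, 0.66))
  got <- split(calls$variant, calls$category)
  ok(setequal(got$functionally_deleterious, published$deleterious),
     "published deleterious list")
  ok(setequal(got$potentially_functionally_deleterious,
              published$potentially_deleterious),
     "published potentially deleterious list")
  ok(setequal(got$potentially_functionally_neutral,
              published$potentially_neutral),
     "published potentially neutral list")
  ok(setequal(got$functionally_neutral, published$neutral),
     "published neutral list")

  all_calls <- summaries |>
    left_join(v, by = "variant") |>
    filter(.data$benchmark_label == "vus") |>
    classify_variants(threshold_set(0.81, 0.44, 0.66))
  agreement <- check_agreement(all_calls)
  ok(all(agreement$agrees), "cross-cell-line agreement")

  cc <- fx$cell_cycle
  validate_cell_cycle(cc)
  ranges <- list(
    benchmark_pathogenic = list(g1 = c(43, 50.9, 47.2), g2m = c(37.7, 49.2, 42.4)),
    benchmark_benign = list(g1 = c(58.4, 67.1, 63.1), g2m = c(19.3, 35.1, 25.7)),
    vus_deleterious = list(g1 = c(42.2, 52.3, 48.5), g2m = c(37.3, 45.5, 40.4)),
    vus_neutral = list(g1 = c(57.6, 68.8, 62.8), g2m = c(18.9, 36.6, 26.6))
  )
  cc_groups <- assign_functional_group(
    all_calls |> select("variant", "category") |>
      dplyr::right_join(v, by = "variant")
  )
  cc_joined <- cc |> left_join(cc_groups |> select("variant", "functional_group"),
                               by = "variant")
  for (grp in names(ranges)) {
    g1 <- cc_joined$pct_g1[cc_joined$functional_group == grp]
    g2m <- cc_joined$pct_g2m[cc_joined$functional_group == grp]
    r <- ranges[[grp]]
    ok(all(g1 >= r$g1[1] - tol & g1 <= r$g1[2] + tol) &&
         abs(mean(g1) - r$g1[3]) < tol, paste(grp, "G1 constraints"))
    ok(all(g2m >= r$g2m[1] - tol & g2m <= r$g2m[2] + tol) &&
         abs(mean(g2m) - r$g2m[3]) < tol, paste(grp, "G2/M constraints"))
  }

  co <- fx$cohorts
  ok(all(co$n_deleterious_vus_carriers <= co$n_vus_carriers) &&
       all(co$n_vus_carriers <= co$n_patients), "cohort count ordering")
  invisible(TRUE)
}
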