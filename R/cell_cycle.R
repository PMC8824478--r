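#' Validate a cell-cycle phase-percentage table
#'
#' Each profile gives per-variant percentages of cells in G1, S, and G2/M.
#' Percentages must lie in \[0, 100\] and sum to 100 within a rounding
#' tolerance of +/- 1.
#'
#' @param profiles Tibble with columns `variant`, `pct_g1`, `pct_s`,
#'   `pct_g2m`.
#' @return `profiles`, invisibly.
#' @export
validate_cell_cycle <- function(profiles) {
  required <- c("variant", "pct_g1", "pct_s", "pct_g2m")
  missing_cols <- setdiff(required, names(profiles))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  pcts <- as.matrix(profiles[, c("pct_g1", "pct_s", "pct_g2m")])
  if (any(pcts < 0 | pcts > 100)) {
    stop("phase percentages must lie in [0, 100]", call. = FALSE)
  }
  sums <- rowSums(pcts)
  bad <- which(sums < 99 | sums > 101)
  if (length(bad) > 0) {
    stop("phase percentages do not sum to 100 (+/- 1) for variant(s): ",
         paste(utils::head(profiles$variant[bad], 5), collapse = ", "),
         call. = FALSE)
  }
  invisible(as_tibble(profiles))
}

#' Assign variants to the four cell-cycle comparison groups
#'
#' Benchmark variants group by their prior label; VUSs group by the side of
#' their functional call: `benchmark_pathogenic`, `benchmark_benign`,
#' `vus_deleterious` (functionally or potentially functionally deleterious),
#' `vus_neutral` (functionally or potentially functionally neutral).
#'
#' @param calls Tibble with columns `variant`, `benchmark_label`, `category`.
#' @return `calls` with an added `functional_group` column.
#' @export
assign_functional_group <- function(calls) {
  stopifnot(all(c("benchmark_label", "category") %in% names(calls)))
  calls |>
    mutate(functional_group = dplyr::case_when(
      .data$benchmark_label == "pathogenic" ~ "benchmark_pathogenic",
      .data$benchmark_label == "benign" ~ "benchmark_benign",
      deleterious_side(.data$category) ~ "vus_deleterious",
      neutral_side(.data$category) ~ "vus_neutral",
      TRUE ~ NA_character_
    ))
}

#' Summarize cell-cycle phase percentages by functional group
#'
#' @param profiles Validated cell-cycle table (see [validate_cell_cycle()]).
#' @param calls Tibble with `variant`, `benchmark_label`, `category` used to
#'   assign groups via [assign_functional_group()].
#' @return Tibble with one row per (functional_group, phase): `n`, `mean`,
#'   `min`, `max`. Empty groups are absent (a warning names them).
#' @export
cell_cycle_group_summary <- function(profiles, calls) {
  validate_cell_cycle(profiles)
  grouped <- profiles |>
    left_join(assign_functional_group(calls) |>
                select("variant", "functional_group"), by = "variant")
  unmatched <- grouped |> filter(is.na(.data$functional_group))
  if (nrow(unmatched) > 0) {
    warning("profiles without a functional group excluded: ",
            paste(utils::head(unmatched$variant, 5), collapse = ", "),
            call. = FALSE)
    grouped <- grouped |> filter(!is.na(.data$functional_group))
  }
  all_groups <- c("benchmark_pathogenic", "benchmark_benign",
                  "vus_deleterious", "vus_neutral")
  empty <- setdiff(all_groups, unique(grouped$functional_group))
  if (length(empty) > 0) {
    warning("empty functional group(s) excluded from summaries: ",
            paste(empty, collapse = ", "), call. = FALSE)
  }
  grouped |>
    tidyr::pivot_longer(c("pct_g1", "pct_s", "pct_g2m"),
                        names_to = "phase", values_to = "pct") |>
    mutate(phase = dplyr::recode(.data$phase, pct_g1 = "G1", pct_s = "S",
                                 pct_g2m = "G2M")) |>
    group_by(.data$functional_group, .data$phase) |>
    summarise(
      n = dplyr::n(),
      mean = mean(.data$pct),
      min = min(.data$pct),
      max = max(.data$pct),
      .groups = "drop"
    )
}

#' Two-sample t test on per-variant percentages
#'
#' Classical pooled-variance (Student) two-sample t test by default, as used
#' for the group comparisons; Welch's unequal-variance form is available via
#' `var_equal = FALSE`. Two-sided. With zero pooled variance the test is
#' degenerate: equal means give `t = 0, p = 1`; unequal means give an
#' infinite statistic and `p = 0`, flagged in the `degenerate` column.
#'
#' @param values_a,values_b Numeric vectors, each with at least 2 values.
#' @param var_equal Use the pooled-variance form (default `TRUE`).
#' @return One-row tibble: `t_statistic`, `df`, `p_value`, `mean_a`,
#'   `mean_b`, `n_a`, `n_b`, `degenerate`.
#' @export
students_t_test <- function(values_a, values_b, var_equal = TRUE) {
  if (length(values_a) < 2 || length(values_b) < 2) {
    stop("each group needs at least 2 values (got ", length(values_a), " and ",
         length(values_b), ")", call. = FALSE)
  }
  n_a <- length(values_a)
  n_b <- length(values_b)
  m_a <- mean(values_a)
  m_b <- mean(values_b)
  pooled_var <- ((n_a - 1) * stats::var(values_a) +
                   (n_b - 1) * stats::var(values_b)) / (n_a + n_b - 2)
  if (var_equal && pooled_var == 0) {
    if (m_a == m_b) {
      return(tibble(t_statistic = 0, df = n_a + n_b - 2, p_value = 1,
                    mean_a = m_a, mean_b = m_b, n_a = n_a, n_b = n_b,
                    degenerate = TRUE))
    }
    return(tibble(t_statistic = sign(m_a - m_b) * Inf, df = n_a + n_b - 2,
                  p_value = 0, mean_a = m_a, mean_b = m_b, n_a = n_a,
                  n_b = n_b, degenerate = TRUE))
  }
  fit <- stats::t.test(values_a, values_b, var.equal = var_equal)
  tibble(
    t_statistic = unname(fit$statistic),
    df = unname(fit$parameter),
    p_value = fit$p.value,
    mean_a = m_a,
    mean_b = m_b,
    n_a = n_a,
    n_b = n_b,
    degenerate = FALSE
  )
}

#' Compare cell-cycle phase fractions between functional groups
#'
#' Runs the four reported comparisons -- benchmark pathogenic vs benchmark
#' benign and deleterious-side VUS vs neutral-side VUS, for the G1 and G2/M
#' phases -- with the pooled-variance Student's t test. p16^INK4A^-functional
#' variants arrest cells in G1, so the deleterious-side groups are expected
#' to show a *lower* G1 fraction; `direction_inverted` flags comparisons
#' where the deleterious-side group's G1 mean is not lower (or the G2/M mean
#' not higher).
#'
#' @inheritParams cell_cycle_group_summary
#' @param phases Phases to compare (default G1 and G2/M).
#' @param alpha Significance threshold annotated in the output (default 0.01,
#'   the level quoted for these comparisons).
#' @param var_equal Passed to [students_t_test()].
#' @return Tibble with one row per comparison and phase: group labels, group
#'   means, `t_statistic`, `df`, `p_value`, `significant`,
#'   `direction_inverted`.
#' @export
compare_functional_groups <- function(profiles, calls,
                                      phases = c("G1", "G2M"), alpha = 0.01,
                                      var_equal = TRUE) {
  validate_cell_cycle(profiles)
  grouped <- profiles |>
    left_join(assign_functional_group(calls) |>
                select("variant", "functional_group"), by = "variant") |>
    filter(!is.na(.data$functional_group))
  phase_col <- c(G1 = "pct_g1", S = "pct_s", G2M = "pct_g2m")
  pairs <- list(
    c("benchmark_pathogenic", "benchmark_benign"),
    c("vus_deleterious", "vus_neutral")
  )
  purrr::map_dfr(phases, function(ph) {
    purrr::map_dfr(pairs, function(pr) {
      a <- grouped[[phase_col[[ph]]]][grouped$functional_group == pr[1]]
      b <- grouped[[phase_col[[ph]]]][grouped$functional_group == pr[2]]
      if (length(a) < 2 || length(b) < 2) {
        warning("comparison skipped (group with < 2 members): ",
                pr[1], " vs ", pr[2], " [", ph, "]", call. = FALSE)
        return(tibble())
      }
      tt <- students_t_test(a, b, var_equal = var_equal)
      # G1 should be lower on the deleterious side, G2M higher.
      inverted <- if (ph == "G1") tt$mean_a >= tt$mean_b else tt$mean_a <= tt$mean_b
      tibble(
        phase = ph, group_a = pr[1], group_b = pr[2],
        n_a = tt$n_a, n_b = tt$n_b, mean_a = tt$mean_a, mean_b = tt$mean_b,
        t_statistic = tt$t_statistic, df = tt$df, p_value = tt$p_value,
        significant = tt$p_value < alpha,
        direction_inverted = inverted
      )
    })
  })
}
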