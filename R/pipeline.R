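#' Per-cohort and combined prevalence report
#'
#' Recomputes, for every cohort and for each family-history stratum with
#' more than one cohort (counts summed with [combine_cohorts()]): the
#' fraction of reported VUSs found functionally deleterious, the prevalence
#' of deleterious-VUS carriers with its modified Wald CI, and -- where a
#' known-pathogenic carrier count is available -- the cumulative prevalence
#' of pathogenic plus reclassified likely pathogenic carriers.
#'
#' @param cohorts Cohort count tibble (see [pdac_cohorts()]).
#' @inheritParams modified_wald_ci
#' @return Tibble with one row per cohort or combined stratum; proportions
#'   at full precision plus `pct_*` convenience columns rounded to one
#'   decimal.
#' @export
prevalence_report <- function(cohorts, ci_level = 0.95) {
  strata <- unique(cohorts$family_history_stratum)
  combined <- purrr::map_dfr(strata, function(s) {
    sub <- cohorts |> filter(.data$family_history_stratum == s)
    if (nrow(sub) < 2) return(tibble())
    combine_cohorts(sub, label = paste0(s, "_combined"))
  })
  all_rows <- bind_rows(cohorts, combined)
  purrr::map_dfr(seq_len(nrow(all_rows)), function(i) {
    row <- all_rows[i, ]
    est <- modified_wald_ci(row$n_deleterious_vus_carriers, row$n_patients,
                            ci_level)
    frac <- if (row$n_vus_carriers >= 1) {
      100 * row$n_deleterious_vus_carriers / row$n_vus_carriers
    } else {
      NA_real_
    }
    cum <- if (!is.na(row$n_known_pathogenic_carriers)) {
      cumulative_prevalence(row, ci_level = ci_level)
    } else {
      NULL
    }
    tibble(
      study_label = row$study_label,
      family_history_stratum = row$family_history_stratum,
      n_patients = row$n_patients,
      n_vus_carriers = row$n_vus_carriers,
      n_deleterious_vus_carriers = row$n_deleterious_vus_carriers,
      pct_deleterious_of_vus = round(frac, 1),
      prevalence = est$point,
      prevalence_ci_low = est$ci_low,
      prevalence_ci_high = est$ci_high,
      pct_prevalence = round(100 * est$point, 1),
      pct_prevalence_ci_low = round(100 * est$ci_low, 1),
      pct_prevalence_ci_high = round(100 * est$ci_high, 1),
      n_known_pathogenic_carriers = row$n_known_pathogenic_carriers,
      cumulative_prevalence = if (!is.null(cum)) cum$point else NA_real_,
      cumulative_ci_low = if (!is.null(cum)) cum$ci_low else NA_real_,
      cumulative_ci_high = if (!is.null(cum)) cum$ci_high else NA_real_
    )
  })
}

#' Run the full classification pipeline
#'
#' Composes the stages in order: normalize replicate counts, summarize per
#' variant and cell line, calibrate thresholds (or accept explicit ones),
#' classify per cell line, form cross-cell-line consensus calls, apply ACMG
#' reclassification, check agreement, compare cell-cycle groups, and
#' recompute cohort prevalence. Stages whose inputs are absent (`cell_cycle`,
#' `cohorts`) are skipped with a warning. The result is deterministic for a
#' given input.
#'
#' @param replicates Replicate count table (see [read_replicates()]).
#' @param variants Variant annotations with `variant`, `prior_class`,
#'   `benchmark_label`.
#' @param cell_cycle Optional per-variant phase-percentage table.
#' @param cohorts Optional cohort count table.
#' @param thresholds Optional explicit [threshold_set()]; when `NULL`,
#'   thresholds are calibrated from the benchmark variants of
#'   `primary_cell_line` and the consensus stage recalibrates from pooled
#'   benchmark means.
#' @param primary_cell_line Cell line used for calibration (default the
#'   first in the data).
#' @param ci_level,interval_mode Passed to [calibrate_thresholds()].
#' @param boundary Passed to [classify_value()].
#' @return A `vus_report` list: `thresholds`, `summaries`, `calls`,
#'   `consensus`, `agreement`, `category_tables`, `cell_cycle_summary`,
#'   `cell_cycle_tests`, `prevalence`, `provenance`.
#' @export
run_pipeline <- function(replicates, variants, cell_cycle = NULL,
                         cohorts = NULL, thresholds = NULL,
                         primary_cell_line = NULL, ci_level = 0.95,
                         interval_mode = "per_group",
                         boundary = "mid_exclusive") {
  stopifnot(all(c("variant", "prior_class", "benchmark_label") %in%
                  names(variants)))
  summaries <- replicates |>
    normalize_proliferation() |>
    filter(.data$variant != EMPTY_VECTOR) |>
    summarize_proliferation() |>
    left_join(variants, by = "variant")
  unknown <- unique(summaries$variant[is.na(summaries$benchmark_label)])
  if (length(unknown) > 0) {
    stop("measurements for unannotated variant(s): ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }

  primary_cell_line <- primary_cell_line %||% summaries$cell_line[1]
  explicit <- !is.null(thresholds)
  if (!explicit) {
    bench <- summaries |>
      filter(.data$cell_line == primary_cell_line,
             .data$benchmark_label %in% c("pathogenic", "benign"))
    thresholds <- calibrate_thresholds(bench, ci_level = ci_level,
                                       interval_mode = interval_mode)
  }

  calls <- summaries |>
    classify_variants(thresholds, boundary) |>
    reclassify_acmg()

  consensus <- consensus_calls(
    summaries, variants,
    thresholds = if (explicit) thresholds else NULL,
    boundary = boundary, ci_level = ci_level, interval_mode = interval_mode
  ) |>
    left_join(variants |> select("variant", "prior_class"), by = "variant") |>
    reclassify_acmg()

  n_lines <- dplyr::n_distinct(summaries$cell_line)
  agreement <- if (n_lines >= 2) check_agreement(calls) else NULL

  vus_calls <- calls |> filter(.data$benchmark_label == "vus")
  category_tables <- vus_calls |>
    group_by(.data$cell_line) |>
    dplyr::group_modify(~ tabulate_categories(.x)) |>
    ungroup() |>
    bind_rows(
      tabulate_categories(consensus |>
                            filter(.data$benchmark_label == "vus")) |>
        mutate(cell_line = "pooled")
    )

  primary_calls <- calls |> filter(.data$cell_line == primary_cell_line)
  cc_summary <- NULL
  cc_tests <- NULL
  if (!is.null(cell_cycle)) {
    cc_summary <- cell_cycle_group_summary(cell_cycle, primary_calls)
    cc_tests <- compare_functional_groups(cell_cycle, primary_calls)
  } else {
    warning("no cell-cycle table supplied; cell-cycle stage skipped",
            call. = FALSE)
  }

  prev <- NULL
  if (!is.null(cohorts)) {
    prev <- prevalence_report(cohorts, ci_level = ci_level)
  } else {
    warning("no cohort table supplied; prevalence stage skipped",
            call. = FALSE)
  }

  structure(
    list(
      thresholds = thresholds,
      summaries = summaries,
      calls = calls,
      consensus = consensus,
      agreement = agreement,
      category_tables = category_tables,
      cell_cycle_summary = cc_summary,
      cell_cycle_tests = cc_tests,
      prevalence = prev,
      provenance = list(
        package_version = as.character(utils::packageVersion("vusclassifyr")),
        primary_cell_line = primary_cell_line,
        explicit_thresholds = explicit,
        ci_level = ci_level,
        interval_mode = if (explicit) NA_character_ else interval_mode,
        boundary = boundary
      )
    ),
    class = "vus_report"
  )
}

#' @export
print.vus_report <- function(x, ...) {
  cat("<vus_report>\n")
  print(x$thresholds)
  vus <- x$calls |> filter(.data$benchmark_label == "vus")
  cat(sprintf("  %d variants x %d cell line(s); %d VUS calls, %d reclassified likely pathogenic\n",
              dplyr::n_distinct(x$calls$variant),
              dplyr::n_distinct(x$calls$cell_line),
              dplyr::n_distinct(vus$variant),
              dplyr::n_distinct(vus$variant[vus$reclassified])))
  invisible(x)
}

#' Render a pipeline report to TSV tables and a JSON summary
#'
#' Writes every table of a `vus_report` as a tab-delimited UTF-8 file plus
#' one machine-readable `summary.json` holding the thresholds, category
#' tallies, reclassified-variant list, cell-cycle tests, prevalence
#' estimates (all at full precision), and the provenance block.
#'
#' @param report A `vus_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths of the files written.
#' @export
render_report <- function(report, dir) {
  stopifnot(inherits(report, "vus_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  wr <- function(tbl, name) {
    if (is.null(tbl)) return(invisible(NULL))
    p <- file.path(dir, paste0(name, ".tsv"))
    readr::write_tsv(tbl, p)
    paths <<- c(paths, p)
  }
  wr(report$calls, "calls")
  wr(report$consensus, "consensus")
  wr(report$agreement, "agreement")
  wr(report$category_tables, "category_tables")
  wr(report$cell_cycle_summary, "cell_cycle_summary")
  wr(report$cell_cycle_tests, "cell_cycle_tests")
  wr(report$prevalence, "prevalence")

  vus <- report$calls |> filter(.data$benchmark_label == "vus")
  reclassified <- sort(unique(vus$variant[vus$reclassified]))
  summary <- list(
    thresholds = as.list(glance(report$thresholds)),
    category_tables = report$category_tables,
    reclassified_likely_pathogenic = reclassified,
    n_vus = dplyr::n_distinct(vus$variant),
    n_reclassified = length(reclassified),
    pct_reclassified = round(
      100 * length(reclassified) / max(1, dplyr::n_distinct(vus$variant)), 1),
    cell_cycle_tests = report$cell_cycle_tests,
    prevalence = report$prevalence,
    provenance = report$provenance
  )
  json_path <- file.path(dir, "summary.json")
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  paths <- c(paths, json_path)
  invisible(paths)
}
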