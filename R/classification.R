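#' Four-tier functional category labels
#'
#' Ordered from the deleterious side to the neutral side.
#' @return Character vector of the four category labels.
#' @export
functional_categories <- function() {
  c("functionally_deleterious", "potentially_functionally_deleterious",
    "potentially_functionally_neutral", "functionally_neutral")
}

deleterious_side <- function(category) {
  category %in% functional_categories()[1:2]
}

neutral_side <- function(category) {
  category %in% functional_categories()[3:4]
}

#' Classify proliferation values into four functional tiers
#'
#' Deterministic mapping of a mean proliferation value against a
#' [threshold_set()]:
#' \itemize{
#'   \item `> t_deleterious` -- functionally deleterious;
#'   \item `(t_mid, t_deleterious]` -- potentially functionally deleterious;
#'   \item `[t_neutral, t_mid]` -- potentially functionally neutral;
#'   \item `< t_neutral` -- functionally neutral.
#' }
#' A value exactly at `t_mid` is potentially functionally neutral under the
#' default `boundary = "mid_exclusive"` convention; `"mid_inclusive"` assigns
#' it to the deleterious side instead.
#'
#' @param values Numeric vector of nonnegative mean proliferation values.
#' @param thresholds A `threshold_set`.
#' @param boundary Convention for a value exactly equal to `t_mid`.
#' @return Factor with the four levels of [functional_categories()].
#' @examples
#' classify_value(c(0.84, 0.70, 0.50, 0.26), threshold_set(0.81, 0.44, 0.66))
#' @export
classify_value <- function(values, thresholds,
                           boundary = c("mid_exclusive", "mid_inclusive")) {
  boundary <- match.arg(boundary)
  stopifnot(inherits(thresholds, "threshold_set"))
  if (any(values < 0, na.rm = TRUE)) {
    stop("proliferation values must be nonnegative", call. = FALSE)
  }
  lv <- functional_categories()
  above_mid <- if (boundary == "mid_exclusive") {
    values > thresholds$t_mid
  } else {
    values >= thresholds$t_mid
  }
  out <- ifelse(values > thresholds$t_deleterious, lv[1],
         ifelse(above_mid, lv[2],
         ifelse(values >= thresholds$t_neutral, lv[3], lv[4])))
  factor(out, levels = lv)
}

#' Assign functional calls to summarized variants
#'
#' Data-frame front end to [classify_value()]: appends a `category` column to
#' a per-variant summary table (per cell line or pooled).
#'
#' @param summaries Tibble with a `mean_value` column (e.g. from
#'   [summarize_proliferation()] or [pool_cell_lines()]).
#' @inheritParams classify_value
#' @return `summaries` with an added `category` factor column.
#' @export
classify_variants <- function(summaries, thresholds,
                              boundary = c("mid_exclusive", "mid_inclusive")) {
  boundary <- match.arg(boundary)
  stopifnot("mean_value" %in% names(summaries))
  summaries |>
    mutate(category = classify_value(.data$mean_value, thresholds, boundary))
}

#' Cross-cell-line consensus functional calls
#'
#' Pools per-cell-line means per variant (unweighted mean of cell-line
#' means), recalibrates thresholds from the pooled benchmark means, and
#' classifies the pooled values. Benchmark labels are taken from `variants`
#' (`benchmark_label` of `"pathogenic"` / `"benign"` / `"vus"`).
#'
#' @param summaries Per-variant, per-cell-line tibble from
#'   [summarize_proliferation()].
#' @param variants Variant annotation tibble with columns `variant` and
#'   `benchmark_label`.
#' @param thresholds Optional explicit `threshold_set`; when `NULL`
#'   (default), thresholds are derived from the pooled benchmark means with
#'   [calibrate_thresholds()].
#' @param ... Passed on to [calibrate_thresholds()].
#' @inheritParams classify_value
#' @return Tibble with `variant`, `cell_line = "pooled"`, `n_cell_lines`,
#'   `mean_value`, `category`.
#' @export
consensus_calls <- function(summaries, variants, thresholds = NULL,
                            boundary = c("mid_exclusive", "mid_inclusive"),
                            ...) {
  boundary <- match.arg(boundary)
  stopifnot(all(c("variant", "benchmark_label") %in% names(variants)))
  pooled <- pool_cell_lines(summaries) |>
    left_join(variants |> select("variant", "benchmark_label"), by = "variant")
  if (is.null(thresholds)) {
    bench <- pooled |>
      filter(.data$benchmark_label %in% c("pathogenic", "benign")) |>
      rename(.keep_mean = "mean_value")
    thresholds <- calibrate_thresholds(
      tibble(mean_value = bench$.keep_mean,
             benchmark_label = bench$benchmark_label), ...)
  }
  pooled |>
    mutate(cell_line = "pooled",
           category = classify_value(.data$mean_value, thresholds, boundary)) |>
    select("variant", "cell_line", "n_cell_lines", "mean_value",
           "benchmark_label", "category")
}

#' Check agreement of functional calls across cell lines
#'
#' A variant's calls disagree only when one cell line places it on the
#' deleterious side (functionally or potentially functionally deleterious)
#' and another on the neutral side. Differences within a side (e.g.
#' deleterious vs potentially deleterious) count as agreement.
#'
#' @param calls Tibble with columns `variant`, `cell_line`, `category`
#'   (per-cell-line calls from [classify_variants()]).
#' @return Tibble with one row per variant: `n_cell_lines`, `evaluable`
#'   (`FALSE` when fewer than two cell lines were assayed), `agrees`, and
#'   `conflict_detail` naming the conflicting cell lines (or `NA`).
#' @export
check_agreement <- function(calls) {
  stopifnot(all(c("variant", "cell_line", "category") %in% names(calls)))
  calls |>
    group_by(.data$variant) |>
    summarise(
      n_cell_lines = dplyr::n_distinct(.data$cell_line),
      evaluable = .data$n_cell_lines >= 2,
      agrees = !(any(deleterious_side(.data$category)) &&
                   any(neutral_side(.data$category))),
      conflict_detail = if (.data$evaluable[1] && !.data$agrees[1]) {
        paste0(
          "deleterious-side in ",
          paste(.data$cell_line[deleterious_side(.data$category)], collapse = "/"),
          " vs neutral-side in ",
          paste(.data$cell_line[neutral_side(.data$category)], collapse = "/")
        )
      } else {
        NA_character_
      },
      .groups = "drop"
    ) |>
    mutate(agrees = ifelse(.data$evaluable, .data$agrees, NA))
}

#' Apply the ACMG PS3-based reclassification rule
#'
#' A variant of uncertain significance whose assay call is on the deleterious
#' side (functionally or potentially functionally deleterious) is reclassified
#' as likely pathogenic, citing the PS3 evidence code (well-established
#' functional studies supporting a damaging effect). Neutral-side results
#' leave the VUS unchanged (no benign evidence is generated), and benchmark
#' variants pass through with their prior classification.
#'
#' @param calls Tibble with columns `category` and `prior_class` (ACMG prior:
#'   `"vus"`, `"pathogenic"`, `"likely_pathogenic"`, `"benign"`,
#'   `"likely_benign"`); typically a call table joined to the variant
#'   annotations.
#' @return `calls` with added columns `new_class` (`"likely_pathogenic"` /
#'   `"remains_vus"` for VUS rows, the unchanged prior otherwise),
#'   `evidence_code` (`"PS3"` where applied), and `reclassified` (logical).
#' @export
reclassify_acmg <- function(calls) {
  stopifnot(all(c("category", "prior_class") %in% names(calls)))
  calls |>
    mutate(
      reclassified = .data$prior_class == "vus" &
        deleterious_side(.data$category),
      new_class = dplyr::case_when(
        .data$reclassified ~ "likely_pathogenic",
        .data$prior_class == "vus" ~ "remains_vus",
        TRUE ~ .data$prior_class
      ),
      evidence_code = ifelse(.data$reclassified, "PS3", NA_character_)
    )
}

#' Tabulate functional categories
#'
#' Counts calls per category (all four categories always present, zero
#' counts included) with percentages reported to one decimal.
#'
#' @param calls Tibble with a `category` column.
#' @return Tibble `category`, `n`, `prop` (full precision), `pct`
#'   (percentage rounded to one decimal).
#' @export
tabulate_categories <- function(calls) {
  stopifnot("category" %in% names(calls))
  lv <- functional_categories()
  cat_f <- factor(as.character(calls$category), levels = lv)
  tab <- table(cat_f)
  total <- sum(tab)
  tibble(
    category = factor(lv, levels = lv),
    n = as.integer(tab),
    prop = if (total > 0) as.numeric(tab) / total else rep(NA_real_, 4),
    pct = if (total > 0) round(100 * as.numeric(tab) / total, 1) else rep(NA_real_, 4)
  )
}
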