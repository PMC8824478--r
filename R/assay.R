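#' Reserved label for empty-vector control rows
#'
#' Replicate tables mark the matched empty-vector control measurement of each
#' `(cell_line, replicate)` group with this value in the `variant` column.
#' @export
EMPTY_VECTOR <- "empty_vector"

#' Read replicate proliferation measurements from a delimited file
#'
#' Reads a long-format (one row per measurement) TSV or CSV of raw cell
#' counts and validates it: required columns present, counts nonnegative,
#' every replicate group that contains a variant measurement also contains
#' exactly one positive empty-vector control, and (if supplied) the assay
#' endpoint day is constant within a cell line.
#'
#' @param path Path to a UTF-8 delimited file with a header row. `.csv` is
#'   read comma-delimited, anything else tab-delimited.
#' @param col_map Optional named character vector mapping required names to
#'   the file's column names, e.g.
#'   `c(variant = "hgvs", cell_line = "line", replicate = "rep", cell_count = "count")`.
#'   Unmapped required names are looked up directly.
#' @return A validated tibble with columns `variant`, `cell_line`,
#'   `replicate` (integer), `cell_count` (double) and, when present in the
#'   file, `endpoint_day`.
#' @seealso [normalize_proliferation()], [validate_replicates()]
#' @export
read_replicates <- function(path, col_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  required <- c("variant", "cell_line", "replicate", "cell_count")
  if (!is.null(col_map)) {
    missing_src <- setdiff(unname(col_map), names(raw))
    if (length(missing_src) > 0) {
      stop("column map refers to absent columns: ",
           paste(missing_src, collapse = ", "), call. = FALSE)
    }
    for (nm in names(col_map)) names(raw)[names(raw) == col_map[[nm]]] <- nm
  }
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- raw |>
    mutate(
      variant = as.character(.data$variant),
      cell_line = as.character(.data$cell_line),
      replicate = as.integer(.data$replicate),
      cell_count = as.double(.data$cell_count)
    )
  validate_replicates(out)
}

#' Validate a replicate measurement table
#'
#' Checks the structural invariants a replicate table must satisfy before
#' normalization. Returns the table invisibly unchanged so it can be used in
#' a pipe.
#'
#' @param replicates Tibble with columns `variant`, `cell_line`, `replicate`,
#'   `cell_count` (and optionally `endpoint_day`).
#' @return `replicates`, invisibly validated.
#' @export
validate_replicates <- function(replicates) {
  required <- c("variant", "cell_line", "replicate", "cell_count")
  missing_cols <- setdiff(required, names(replicates))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad_count <- which(is.na(replicates$cell_count) | replicates$cell_count < 0)
  if (length(bad_count) > 0) {
    stop("negative or missing cell_count at row(s): ",
         paste(utils::head(bad_count, 5), collapse = ", "), call. = FALSE)
  }
  bad_rep <- which(is.na(replicates$replicate) | replicates$replicate < 1)
  if (length(bad_rep) > 0) {
    stop("replicate index must be a positive integer; offending row(s): ",
         paste(utils::head(bad_rep, 5), collapse = ", "), call. = FALSE)
  }

  grp <- replicates |>
    group_by(.data$cell_line, .data$replicate) |>
    summarise(
      n_variant = sum(.data$variant != EMPTY_VECTOR),
      n_control = sum(.data$variant == EMPTY_VECTOR),
      control_positive = any(.data$variant == EMPTY_VECTOR & .data$cell_count > 0),
      .groups = "drop"
    )
  bad <- grp |> filter(.data$n_variant > 0 &
                         (.data$n_control != 1L | !.data$control_positive))
  if (nrow(bad) > 0) {
    stop("replicate group(s) without exactly one positive empty-vector control: ",
         paste(sprintf("(%s, replicate %d)", bad$cell_line, bad$replicate),
               collapse = "; "),
         call. = FALSE)
  }

  if ("endpoint_day" %in% names(replicates)) {
    days <- replicates |>
      distinct(.data$cell_line, .data$endpoint_day) |>
      count(.data$cell_line) |>
      filter(.data$n > 1)
    if (nrow(days) > 0) {
      stop("endpoint_day varies within cell line(s): ",
           paste(days$cell_line, collapse = ", "), call. = FALSE)
    }
  }
  invisible(as_tibble(replicates))
}

#' Normalize replicate cell counts to the empty-vector control
#'
#' Converts raw cell counts to relative proliferation values by dividing each
#' variant measurement by its matched empty-vector control count. A value
#' near 1 means growth indistinguishable from the control (no p16^INK4A^
#' suppression, deleterious-like); low values mean strong growth inhibition
#' (functional, benign-like). Control rows normalize to exactly 1.
#'
#' @param replicates Validated replicate table (see [read_replicates()]).
#' @param per_replicate If `TRUE` (default) each variant count is divided by
#'   the control count of the same `(cell_line, replicate)`; if `FALSE` all
#'   counts in a cell line are divided by that line's mean control count.
#' @return Tibble `variant`, `cell_line`, `replicate`, `value` (dimensionless).
#' @export
normalize_proliferation <- function(replicates, per_replicate = TRUE) {
  validate_replicates(replicates)
  controls <- replicates |>
    filter(.data$variant == EMPTY_VECTOR) |>
    select("cell_line", "replicate", control_count = "cell_count")
  zero <- controls |> filter(.data$control_count == 0)
  if (nrow(zero) > 0) {
    stop("empty-vector control count is zero in: ",
         paste(sprintf("(%s, replicate %d)", zero$cell_line, zero$replicate),
               collapse = "; "),
         call. = FALSE)
  }
  if (!per_replicate) {
    controls <- controls |>
      group_by(.data$cell_line) |>
      summarise(control_count = mean(.data$control_count), .groups = "drop")
  }
  by_cols <- if (per_replicate) c("cell_line", "replicate") else "cell_line"
  replicates |>
    left_join(controls, by = by_cols) |>
    mutate(value = .data$cell_count / .data$control_count) |>
    select("variant", "cell_line", "replicate", "value")
}

#' Summarize normalized proliferation values per variant and cell line
#'
#' @param normalized Tibble from [normalize_proliferation()] with columns
#'   `variant`, `cell_line`, `value`.
#' @return Tibble `variant`, `cell_line`, `n_replicates`, `mean_value`,
#'   `sd_value` (sample s.d., `n - 1` denominator; `NA` when a single
#'   replicate is available).
#' @export
summarize_proliferation <- function(normalized) {
  stopifnot(all(c("variant", "cell_line", "value") %in% names(normalized)))
  normalized |>
    group_by(.data$variant, .data$cell_line) |>
    summarise(
      n_replicates = dplyr::n(),
      mean_value = mean(.data$value),
      sd_value = stats::sd(.data$value),
      .groups = "drop"
    )
}

#' Pool per-cell-line proliferation means across cell lines
#'
#' Cross-cell-line pooling is the unweighted mean of the per-cell-line means
#' (not of all replicates): cell lines are assayed at different endpoint days
#' and contribute one summary each.
#'
#' @param summaries Tibble from [summarize_proliferation()].
#' @return Tibble `variant`, `n_cell_lines`, `mean_value` with one row per
#'   variant.
#' @export
pool_cell_lines <- function(summaries) {
  stopifnot(all(c("variant", "cell_line", "mean_value") %in% names(summaries)))
  summaries |>
    group_by(.data$variant) |>
    summarise(
      n_cell_lines = dplyr::n_distinct(.data$cell_line),
      mean_value = mean(.data$mean_value),
      .groups = "drop"
    )
}
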