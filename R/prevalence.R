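#' Modified Wald (adjusted) binomial confidence interval
#'
#' The adjusted "add 2 successes and 2 failures" interval: at the 95% level
#' the adjusted proportion is `(x + 2) / (n + 4)` and the interval is
#' `p~ +/- z * sqrt(p~ (1 - p~) / (n + 4))`, truncated to \[0, 1\]
#' (the "modified Wald method" convention of common biostatistics software;
#' Agresti-Coull in the statistics literature). At other confidence levels
#' the general form `(x + z^2/2) / (n + z^2)` is used.
#'
#' @param x Number of carriers (successes), `0 <= x <= n`.
#' @param n Cohort size, `>= 1`.
#' @param ci_level Confidence level, default 0.95.
#' @return One-row tibble: `numerator`, `denominator`, `point` (the raw
#'   proportion `x/n`), `adjusted` (the shifted proportion the interval is
#'   centred on), `ci_low`, `ci_high`, `ci_level`, `method`.
#' @examples
#' modified_wald_ci(10, 638)
#' @export
modified_wald_ci <- function(x, n, ci_level = 0.95) {
  stopifnot(length(x) == 1, length(n) == 1)
  if (is.na(x) || is.na(n) || n < 1 || x < 0 || x > n) {
    stop("need 0 <= x <= n with n >= 1; got x = ", x, ", n = ", n,
         call. = FALSE)
  }
  stopifnot(ci_level > 0, ci_level < 1)
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  if (identical(ci_level, 0.95)) {
    add_x <- 2
    add_n <- 4
  } else {
    add_x <- z^2 / 2
    add_n <- z^2
  }
  p_adj <- (x + add_x) / (n + add_n)
  half <- z * sqrt(p_adj * (1 - p_adj) / (n + add_n))
  tibble(
    numerator = as.integer(x),
    denominator = as.integer(n),
    point = x / n,
    adjusted = p_adj,
    ci_low = max(0, p_adj - half),
    ci_high = min(1, p_adj + half),
    ci_level = ci_level,
    method = "modified Wald"
  )
}

#' Combine disjoint cohorts by summing their counts
#'
#' @param cohorts Tibble of cohort count rows with `study_label`,
#'   `n_patients`, `n_vus_carriers`, `n_deleterious_vus_carriers` and
#'   optionally `n_known_pathogenic_carriers`; assumed disjoint studies.
#'   Duplicate study labels trigger a warning.
#' @param label Label for the combined row.
#' @return One-row tibble with summed counts (a pathogenic-carrier sum is
#'   `NA` if any input is `NA`).
#' @export
combine_cohorts <- function(cohorts, label = "combined") {
  stopifnot(all(c("study_label", "n_patients", "n_vus_carriers",
                  "n_deleterious_vus_carriers") %in% names(cohorts)))
  dup <- cohorts$study_label[duplicated(cohorts$study_label)]
  if (length(dup) > 0) {
    warning("duplicate study label(s): ", paste(unique(dup), collapse = ", "),
            call. = FALSE)
  }
  tibble(
    study_label = label,
    family_history_stratum = if ("family_history_stratum" %in% names(cohorts) &&
                                   dplyr::n_distinct(cohorts$family_history_stratum) == 1) {
      cohorts$family_history_stratum[1]
    } else {
      NA_character_
    },
    n_patients = sum(cohorts$n_patients),
    n_vus_carriers = sum(cohorts$n_vus_carriers),
    n_deleterious_vus_carriers = sum(cohorts$n_deleterious_vus_carriers),
    n_known_pathogenic_carriers = if ("n_known_pathogenic_carriers" %in% names(cohorts)) {
      sum(cohorts$n_known_pathogenic_carriers)
    } else {
      NA_integer_
    }
  )
}

#' Fraction of a cohort's VUSs found functionally deleterious
#'
#' @param cohort One-row cohort tibble (see [pdac_cohorts()]).
#' @return Percentage (0-100) at full precision; `NA` with a warning when
#'   the cohort reported no VUS carriers.
#' @export
fraction_deleterious_vus <- function(cohort) {
  stopifnot(nrow(cohort) == 1)
  if (cohort$n_vus_carriers < 1) {
    warning("no VUS carriers in cohort ", cohort$study_label,
            "; fraction undefined", call. = FALSE)
    return(NA_real_)
  }
  100 * cohort$n_deleterious_vus_carriers / cohort$n_vus_carriers
}

#' Cumulative prevalence of pathogenic plus reclassified variants
#'
#' Prevalence of pathogenic and likely pathogenic carriers once functionally
#' deleterious VUSs are reclassified:
#' `modified_wald_ci(known pathogenic + reclassified, n_patients)`.
#'
#' @param cohort One-row cohort tibble with a non-missing
#'   `n_known_pathogenic_carriers`.
#' @param reclassified Count of VUS carriers reclassified as likely
#'   pathogenic; defaults to the cohort's `n_deleterious_vus_carriers`.
#' @inheritParams modified_wald_ci
#' @return One-row tibble as from [modified_wald_ci()].
#' @export
cumulative_prevalence <- function(cohort, reclassified = NULL,
                                  ci_level = 0.95) {
  stopifnot(nrow(cohort) == 1)
  if (!"n_known_pathogenic_carriers" %in% names(cohort) ||
      is.na(cohort$n_known_pathogenic_carriers)) {
    stop("cohort ", cohort$study_label,
         " has no known-pathogenic carrier count", call. = FALSE)
  }
  reclassified <- reclassified %||% cohort$n_deleterious_vus_carriers
  modified_wald_ci(cohort$n_known_pathogenic_carriers + reclassified,
                   cohort$n_patients, ci_level)
}

#' Reconstruct an integer count from a printed percentage
#'
#' Finds the integer `k` with `100 k / n` closest to a percentage printed to
#' one decimal. Errors when two integers are equidistant or when no integer
#' actually rounds to the printed value.
#'
#' @param percent Printed percentage (one decimal).
#' @param n Denominator.
#' @return Integer count.
#' @examples
#' infer_count_from_percent(2.5, 638) # 16
#' @export
infer_count_from_percent <- function(percent, n) {
  stopifnot(n >= 1, percent >= 0, percent <= 100)
  k <- 0:n
  dist <- abs(100 * k / n - percent)
  best <- which(dist == min(dist))
  if (length(best) > 1) {
    stop("ambiguous count: ", paste(k[best], collapse = " and "),
         " are equidistant from ", percent, "% of ", n, call. = FALSE)
  }
  k_best <- k[best]
  if (round(100 * k_best / n, 1) != round(percent, 1)) {
    stop("no integer count over ", n, " rounds to ", percent, "%",
         call. = FALSE)
  }
  as.integer(k_best)
}

#' Published PDAC cohort count table
#'
#' The five literature cohorts whose CDKN2A VUSs were assayed: patients
#' screened, VUS carriers found, VUS carriers whose variant proved
#' functionally deleterious in the assay, and (where reconstructable from
#' the printed prevalence) known pathogenic-variant carriers. The
#' known-pathogenic count for the familial pancreatic cancer cohort (16) is
#' reconstructed from its printed 2.5% prevalence; per-study counts for the
#' other strata are not recoverable from the printed combined figures and
#' are `NA`.
#'
#' @return Tibble with columns `study_label`, `family_history_stratum`,
#'   `n_patients`, `n_vus_carriers`, `n_deleterious_vus_carriers`,
#'   `n_known_pathogenic_carriers`.
#' @export
pdac_cohorts <- function() {
  tibble(
    study_label = c("fpc_638", "fh_727", "fh_302", "unselected_350",
                    "unselected_854"),
    family_history_stratum = c("familial_pancreatic_cancer",
                               "family_history_positive",
                               "family_history_positive",
                               "unselected", "unselected"),
    n_patients = c(638L, 727L, 302L, 350L, 854L),
    n_vus_carriers = c(17L, 13L, 9L, 8L, 1L),
    n_deleterious_vus_carriers = c(10L, 6L, 4L, 3L, 0L),
    n_known_pathogenic_carriers = c(16L, NA_integer_, NA_integer_,
                                    NA_integer_, NA_integer_)
  )
}
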