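#' Z-score confidence interval of a set of group means
#'
#' The interval `mean +/- z * sd`, where `sd` is the sample standard
#' deviation of the supplied per-variant means and
#' `z = qnorm(1 - (1 - ci_level) / 2)` (1.96 at the default 0.95). This is a
#' descriptive spread interval over benchmark variants, not a standard error
#' of the mean.
#'
#' @param values Numeric vector of per-variant mean proliferation values
#'   (at least 2).
#' @param ci_level Confidence level in (0, 1); default 0.95.
#' @return Tibble with columns `lower`, `upper`, `mean`, `sd`, `z`, `n`.
#' @export
zscore_interval <- function(values, ci_level = 0.95) {
  values <- values[!is.na(values)]
  if (length(values) < 2) {
    stop("zscore_interval needs at least 2 values, got ", length(values),
         call. = FALSE)
  }
  stopifnot(ci_level > 0, ci_level < 1)
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  m <- mean(values)
  s <- stats::sd(values)
  tibble(lower = m - z * s, upper = m + z * s, mean = m, sd = s, z = z,
         n = length(values))
}

#' ROC area under the curve as the Mann-Whitney probability
#'
#' AUC for discriminating pathogenic (positive class, higher proliferation)
#' from benign benchmark variants: the fraction of (pathogenic, benign) pairs
#' in which the pathogenic mean exceeds the benign mean, ties counted 1/2.
#' Equals the area under the empirical ROC curve.
#'
#' @param pathogenic,benign Numeric vectors of per-variant mean proliferation
#'   values; both non-empty.
#' @return A single number in \[0, 1\].
#' @export
roc_auc <- function(pathogenic, benign) {
  stopifnot(length(pathogenic) > 0, length(benign) > 0,
            !anyNA(pathogenic), !anyNA(benign))
  # Rank formulation of the Mann-Whitney U statistic.
  r <- rank(c(pathogenic, benign))
  n_p <- length(pathogenic)
  n_b <- length(benign)
  u <- sum(r[seq_len(n_p)]) - n_p * (n_p + 1) / 2
  u / (n_p * n_b)
}

#' Intermediate cutoff between the deleterious and neutral thresholds
#'
#' When the benchmark groups are perfectly separated (AUC exactly 1, within
#' `tol`), the cutoff is the midpoint between the lowest pathogenic mean and
#' the highest benign mean. Otherwise it is the cutoff maximizing Youden's
#' J = sensitivity + specificity - 1 over candidate cutoffs (midpoints of
#' adjacent distinct values in the sorted union of all benchmark means), with
#' ties broken toward the smallest cutoff.
#'
#' @inheritParams roc_auc
#' @param auc ROC AUC of the benchmark groups; computed with [roc_auc()] if
#'   not supplied.
#' @param tol Tolerance for treating the AUC as exactly 1.
#' @return A single cutoff value.
#' @export
intermediate_cutoff <- function(pathogenic, benign, auc = NULL, tol = 1e-12) {
  if (is.null(auc)) auc <- roc_auc(pathogenic, benign)
  if (abs(auc - 1) <= tol) {
    return((min(pathogenic) + max(benign)) / 2)
  }
  pool <- sort(unique(c(pathogenic, benign)))
  if (length(pool) < 2) return(pool[1])
  candidates <- (pool[-length(pool)] + pool[-1]) / 2
  j <- vapply(candidates, function(cutoff) {
    sens <- mean(pathogenic > cutoff)
    spec <- mean(benign <= cutoff)
    sens + spec - 1
  }, numeric(1))
  candidates[which.max(j)] # which.max takes the first, i.e. smallest cutoff
}

new_threshold_set <- function(t_deleterious, t_neutral, t_mid, auc = NA_real_,
                              ci_level = 0.95, z_value = NA_real_,
                              interval_mode = NA_character_,
                              group_stats = NULL, method_notes = character()) {
  structure(
    list(
      t_deleterious = t_deleterious,
      t_neutral = t_neutral,
      t_mid = t_mid,
      auc = auc,
      ci_level = ci_level,
      z_value = z_value,
      interval_mode = interval_mode,
      group_stats = group_stats,
      method_notes = method_notes
    ),
    class = "threshold_set"
  )
}

#' Construct a threshold set from explicit cutoffs
#'
#' Builds a valid `threshold_set` directly from user-supplied cutoffs, e.g.
#' the published (0.81, 0.44, 0.66) triple, bypassing calibration.
#'
#' @param t_deleterious Cutoff above which a variant is functionally
#'   deleterious.
#' @param t_neutral Cutoff below which a variant is functionally neutral.
#' @param t_mid Intermediate cutoff splitting the zone between the two.
#' @param auc Optional benchmark AUC to record alongside the cutoffs.
#' @return A `threshold_set` object.
#' @examples
#' threshold_set(0.81, 0.44, 0.66)
#' @export
threshold_set <- function(t_deleterious, t_neutral, t_mid,
                          auc = NA_real_) {
  stopifnot(is.numeric(t_deleterious), is.numeric(t_neutral), is.numeric(t_mid))
  if (!(t_neutral < t_mid && t_mid < t_deleterious)) {
    stop("thresholds must satisfy t_neutral < t_mid < t_deleterious; got (",
         t_deleterious, ", ", t_neutral, ", ", t_mid, ")", call. = FALSE)
  }
  new_threshold_set(t_deleterious, t_neutral, t_mid, auc = auc,
                    method_notes = "explicit thresholds supplied by user")
}

#' Calibrate classification thresholds from benchmark variants
#'
#' Derives the three cutoffs of the four-tier functional classification from
#' per-variant mean proliferation values of benchmark pathogenic and benign
#' variants:
#' \itemize{
#'   \item `t_deleterious` -- in the default `"per_group"` mode, the lower
#'     limit of the pathogenic group's Z-score CI (values above it behave
#'     like known pathogenic variants);
#'   \item `t_neutral` -- the upper limit of the benign group's Z-score CI;
#'   \item `t_mid` -- the midpoint between the lowest pathogenic and highest
#'     benign mean when the groups are perfectly separated (AUC = 1),
#'     otherwise the Youden-optimal cutoff (see [intermediate_cutoff()]).
#' }
#' In `"pooled"` mode (for sensitivity analysis) a single Z-score CI over
#' the union of both groups supplies both limits.
#'
#' @param benchmarks Data frame with one row per benchmark variant and
#'   columns `mean_value` and `benchmark_label`
#'   (`"pathogenic"` / `"benign"`; other labels are ignored).
#' @param ci_level Confidence level for the Z-score intervals.
#' @param interval_mode `"per_group"` (default) or `"pooled"`.
#' @return A `threshold_set` object; see [threshold_set()], [tidy.threshold_set()].
#' @examples
#' bench <- tibble::tibble(
#'   mean_value = c(0.85, 0.9, 0.95, 0.2, 0.25, 0.3),
#'   benchmark_label = rep(c("pathogenic", "benign"), each = 3)
#' )
#' calibrate_thresholds(bench)
#' @export
calibrate_thresholds <- function(benchmarks, ci_level = 0.95,
                                 interval_mode = c("per_group", "pooled")) {
  interval_mode <- match.arg(interval_mode)
  stopifnot(all(c("mean_value", "benchmark_label") %in% names(benchmarks)))
  path <- benchmarks$mean_value[benchmarks$benchmark_label == "pathogenic"]
  ben <- benchmarks$mean_value[benchmarks$benchmark_label == "benign"]
  if (length(path) < 2 || length(ben) < 2) {
    stop("calibration needs >= 2 pathogenic and >= 2 benign benchmark means (got ",
         length(path), " and ", length(ben), ")", call. = FALSE)
  }
  if (any(c(path, ben) < 0)) {
    stop("benchmark proliferation means must be nonnegative", call. = FALSE)
  }

  ci_p <- zscore_interval(path, ci_level)
  ci_b <- zscore_interval(ben, ci_level)
  if (interval_mode == "per_group") {
    t_del <- ci_p$lower
    t_neu <- ci_b$upper
  } else {
    ci_all <- zscore_interval(c(path, ben), ci_level)
    t_del <- ci_all$upper
    t_neu <- ci_all$lower
  }
  if (t_del <= t_neu) {
    stop("benchmark groups overlap: deleterious cutoff (", signif(t_del, 4),
         ") <= neutral cutoff (", signif(t_neu, 4),
         "); supply explicit thresholds via threshold_set()", call. = FALSE)
  }
  auc <- roc_auc(path, ben)
  t_mid <- intermediate_cutoff(path, ben, auc)
  if (!(t_neu < t_mid && t_mid < t_del)) {
    stop("calibrated midpoint (", signif(t_mid, 4),
         ") falls outside (t_neutral, t_deleterious); supply explicit ",
         "thresholds via threshold_set()", call. = FALSE)
  }

  group_stats <- tibble(
    group = c("pathogenic", "benign"),
    n = c(ci_p$n, ci_b$n),
    mean = c(ci_p$mean, ci_b$mean),
    sd = c(ci_p$sd, ci_b$sd),
    ci_lower = c(ci_p$lower, ci_b$lower),
    ci_upper = c(ci_p$upper, ci_b$upper)
  )
  notes <- c(
    t_deleterious = sprintf(
      "%s Z-score %g%% CI limit", interval_mode, 100 * ci_level),
    t_neutral = sprintf(
      "%s Z-score %g%% CI limit", interval_mode, 100 * ci_level),
    t_mid = if (abs(auc - 1) <= 1e-12) {
      "midpoint of min(pathogenic) and max(benign) (AUC = 1)"
    } else {
      "Youden-index optimal cutoff (AUC < 1)"
    }
  )
  new_threshold_set(t_del, t_neu, t_mid, auc = auc, ci_level = ci_level,
                    z_value = ci_p$z, interval_mode = interval_mode,
                    group_stats = group_stats, method_notes = notes)
}

#' @export
print.threshold_set <- function(x, ...) {
  cat("<threshold_set>\n")
  cat(sprintf("  deleterious : > %.4g\n", x$t_deleterious))
  cat(sprintf("  midpoint    :   %.4g\n", x$t_mid))
  cat(sprintf("  neutral     : < %.4g\n", x$t_neutral))
  if (!is.na(x$auc)) cat(sprintf("  benchmark AUC: %.4g\n", x$auc))
  if (!is.na(x$interval_mode)) {
    cat(sprintf("  mode: %s, ci_level: %g\n", x$interval_mode, x$ci_level))
  }
  invisible(x)
}

#' Tidy a threshold set into one row per cutoff
#'
#' @param x A `threshold_set`.
#' @param ... Unused.
#' @return Tibble with columns `threshold`, `value`, `method`.
#' @method tidy threshold_set
#' @export
tidy.threshold_set <- function(x, ...) {
  notes <- x$method_notes
  method <- function(key) {
    if (!is.null(names(notes)) && key %in% names(notes)) notes[[key]]
    else if (length(notes) > 0) notes[[1]] else NA_character_
  }
  tibble(
    threshold = c("deleterious", "midpoint", "neutral"),
    value = c(x$t_deleterious, x$t_mid, x$t_neutral),
    method = c(method("t_deleterious"), method("t_mid"), method("t_neutral"))
  )
}

#' One-row summary of a threshold calibration
#'
#' @param x A `threshold_set`.
#' @param ... Unused.
#' @return One-row tibble with the cutoffs, AUC, mode, and benchmark group
#'   means when available.
#' @method glance threshold_set
#' @export
glance.threshold_set <- function(x, ...) {
  gs <- x$group_stats
  tibble(
    t_deleterious = x$t_deleterious,
    t_neutral = x$t_neutral,
    t_mid = x$t_mid,
    auc = x$auc,
    ci_level = x$ci_level,
    interval_mode = x$interval_mode,
    pathogenic_mean = if (!is.null(gs)) gs$mean[gs$group == "pathogenic"] else NA_real_,
    benign_mean = if (!is.null(gs)) gs$mean[gs$group == "benign"] else NA_real_,
    n_pathogenic = if (!is.null(gs)) gs$n[gs$group == "pathogenic"] else NA_integer_,
    n_benign = if (!is.null(gs)) gs$n[gs$group == "benign"] else NA_integer_
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
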