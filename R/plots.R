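#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_errorbar geom_hline
#'   geom_rect labs theme_minimal scale_colour_manual annotate geom_boxplot
#'   geom_jitter facet_wrap
NULL

category_palette <- function() {
  stats::setNames(
    c("#b2182b", "#ef8a62", "#67a9cf", "#2166ac"),
    functional_categories()
  )
}

#' Plot per-variant proliferation means against the thresholds
#'
#' Mean +/- s.d. per variant, coloured by functional category, with the
#' intermediate zone shaded and the three cutoffs drawn -- the standard
#' presentation of a benchmark-anchored proliferation assay.
#'
#' @param calls Tibble with `variant`, `mean_value`, `category`, and
#'   optionally `sd_value`; e.g. from [classify_variants()].
#' @param thresholds The `threshold_set` used for the calls.
#' @return A ggplot object.
#' @export
plot_proliferation <- function(calls, thresholds) {
  stopifnot(inherits(thresholds, "threshold_set"))
  calls <- calls |> arrange(dplyr::desc(.data$mean_value)) |>
    mutate(variant = factor(.data$variant, levels = unique(.data$variant)))
  p <- ggplot(calls, aes(x = .data$variant, y = .data$mean_value,
                         colour = .data$category)) +
    annotate("rect", xmin = -Inf, xmax = Inf,
             ymin = thresholds$t_neutral, ymax = thresholds$t_deleterious,
             alpha = 0.12, fill = "grey40") +
    geom_hline(yintercept = thresholds$t_mid, linetype = "dashed") +
    geom_point(size = 2)
  if ("sd_value" %in% names(calls)) {
    p <- p + geom_errorbar(
      aes(ymin = .data$mean_value - .data$sd_value,
          ymax = .data$mean_value + .data$sd_value), width = 0.3)
  }
  p +
    scale_colour_manual(values = category_palette(), drop = FALSE) +
    labs(x = NULL, y = "normalized cell proliferation", colour = NULL) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' Plot cell-cycle phase fractions by functional group
#'
#' @param profiles Per-variant phase percentages (see
#'   [validate_cell_cycle()]).
#' @param calls Tibble with `variant`, `benchmark_label`, `category` for
#'   group assignment.
#' @param phases Phases to show.
#' @return A ggplot object.
#' @export
plot_cell_cycle <- function(profiles, calls, phases = c("G1", "G2M")) {
  validate_cell_cycle(profiles)
  long <- profiles |>
    left_join(assign_functional_group(calls) |>
                select("variant", "functional_group"), by = "variant") |>
    filter(!is.na(.data$functional_group)) |>
    tidyr::pivot_longer(c("pct_g1", "pct_s", "pct_g2m"),
                        names_to = "phase", values_to = "pct") |>
    mutate(phase = dplyr::recode(.data$phase, pct_g1 = "G1", pct_s = "S",
                                 pct_g2m = "G2M")) |>
    filter(.data$phase %in% phases)
  ggplot(long, aes(x = .data$functional_group, y = .data$pct,
                   colour = .data$functional_group)) +
    geom_boxplot(outlier.shape = NA) +
    geom_jitter(width = 0.15, alpha = 0.7) +
    facet_wrap(~ .data$phase, scales = "free_y") +
    labs(x = NULL, y = "% of cells", colour = NULL) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1),
                   legend.position = "none")
}

#' @rdname plot_proliferation
#' @param object A `threshold_set`.
#' @param ... Unused.
#' @method autoplot threshold_set
#' @export
autoplot.threshold_set <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = 1, y = .data$value)) +
    annotate("rect", xmin = -Inf, xmax = Inf,
             ymin = object$t_neutral, ymax = object$t_deleterious,
             alpha = 0.12, fill = "grey40") +
    geom_hline(aes(yintercept = .data$value, linetype = .data$threshold)) +
    labs(y = "normalized cell proliferation", x = NULL, linetype = "cutoff") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' @export
ggplot2::autoplot
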