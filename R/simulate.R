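#' Simulation configuration for synthetic proliferation assays
#'
#' Defaults encode the study conditions the analysis assumes: benchmark
#' pathogenic variants centred at a normalized proliferation of 0.90 and
#' benign variants at 0.26, three replicates per variant per cell line,
#' multiplicative replicate noise, a small per-cell-line shift, and G1
#' fractions of 48.5% (deleterious-side) vs 62.8% (neutral-side).
#'
#' @param seed Integer seed; every generator is a pure function of
#'   (config, seed).
#' @param n_replicates Replicates per variant per cell line (default 3).
#' @param cell_lines Character vector of cell-line labels.
#' @param n_pathogenic,n_benign Numbers of benchmark variants (defaults 9, 7).
#' @param pathogenic_mean,pathogenic_sd Benchmark pathogenic group
#'   distribution (defaults 0.90, 0.05).
#' @param benign_mean,benign_sd Benchmark benign group distribution
#'   (defaults 0.26, 0.10).
#' @param replicate_cv Coefficient of variation of multiplicative replicate
#'   noise (default 0.05).
#' @param vus_effects Numeric vector of true VUS mean proliferation values,
#'   spanning both regimes by default.
#' @param cell_line_shift_sd S.d. of the additive per-cell-line shift
#'   (default 0.02).
#' @param g1_deleterious_mean,g1_neutral_mean,g1_sd Cell-cycle G1 percentage
#'   distributions by functional side (defaults 48.5, 62.8, 3).
#' @param s_fraction Fixed S-phase percentage (default 10; the remainder
#'   goes to G2/M).
#' @param control_count Empty-vector control cell count all replicate counts
#'   are scaled by.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_replicates = 3L,
                              cell_lines = "PANC-1",
                              n_pathogenic = 9L,
                              n_benign = 7L,
                              pathogenic_mean = 0.90, pathogenic_sd = 0.05,
                              benign_mean = 0.26, benign_sd = 0.10,
                              replicate_cv = 0.05,
                              vus_effects = seq(0.10, 1.00, by = 0.10),
                              cell_line_shift_sd = 0.02,
                              g1_deleterious_mean = 48.5,
                              g1_neutral_mean = 62.8,
                              g1_sd = 3,
                              s_fraction = 10,
                              control_count = 1e6) {
  stopifnot(
    n_replicates >= 1, n_pathogenic >= 2, n_benign >= 2,
    pathogenic_sd >= 0, benign_sd >= 0, replicate_cv >= 0,
    cell_line_shift_sd >= 0, g1_sd >= 0,
    pathogenic_mean >= 0, pathogenic_mean <= 2,
    benign_mean >= 0, benign_mean <= 2,
    g1_deleterious_mean >= 0, g1_deleterious_mean <= 100,
    g1_neutral_mean >= 0, g1_neutral_mean <= 100,
    s_fraction >= 0, s_fraction <= 100,
    control_count > 0
  )
  structure(as.list(environment()), class = "simulation_config")
}

#' Simulate a replicate proliferation assay
#'
#' Draws a true mean proliferation value per variant (benchmark groups from
#' their normal distributions, VUSs from the configured explicit effects),
#' adds an independent per-cell-line shift, and generates replicate cell
#' counts with multiplicative Gaussian noise against a fixed empty-vector
#' control count. Deterministic given the config's seed.
#'
#' @param config A [simulation_config()].
#' @return A list with `replicates` (tibble `variant`, `cell_line`,
#'   `replicate`, `cell_count`, including the `empty_vector` control rows)
#'   and `variants` (tibble `variant`, `benchmark_label`, `true_mean`).
#' @export
simulate_assay <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, {
    n_vus <- length(config$vus_effects)
    variants <- tibble(
      variant = c(sprintf("path_%02d", seq_len(config$n_pathogenic)),
                  sprintf("benign_%02d", seq_len(config$n_benign)),
                  if (n_vus > 0) sprintf("vus_%02d", seq_len(n_vus))),
      benchmark_label = c(rep("pathogenic", config$n_pathogenic),
                          rep("benign", config$n_benign),
                          rep("vus", n_vus)),
      true_mean = pmax(0, c(
        stats::rnorm(config$n_pathogenic, config$pathogenic_mean,
                     config$pathogenic_sd),
        stats::rnorm(config$n_benign, config$benign_mean, config$benign_sd),
        config$vus_effects
      ))
    )
    grid <- tidyr::expand_grid(
      variants,
      cell_line = config$cell_lines
    ) |>
      mutate(shift = rep(
        stats::rnorm(length(config$cell_lines), 0, config$cell_line_shift_sd),
        times = nrow(variants)
      ))
    reps <- tidyr::expand_grid(grid, replicate = seq_len(config$n_replicates)) |>
      mutate(
        value = pmax(0, (.data$true_mean + .data$shift) *
                       (1 + stats::rnorm(dplyr::n(), 0, config$replicate_cv))),
        cell_count = .data$value * config$control_count
      ) |>
      select("variant", "cell_line", "replicate", "cell_count")
    controls <- tidyr::expand_grid(
      variant = EMPTY_VECTOR,
      cell_line = config$cell_lines,
      replicate = seq_len(config$n_replicates)
    ) |>
      mutate(cell_count = config$control_count)
    list(
      replicates = bind_rows(reps, controls) |>
        arrange(.data$cell_line, .data$replicate, .data$variant),
      variants = variants
    )
  })
}

#' Simulate per-variant cell-cycle profiles
#'
#' Draws a G1 percentage per variant from its functional side's normal
#' distribution, keeps the S fraction fixed, and assigns the remainder to
#' G2/M; values are clipped to \[0, 100\]. Deterministic given the seed.
#'
#' @param calls Tibble with `variant` plus either a `functional_group`
#'   column or the `benchmark_label` and `category` columns needed by
#'   [assign_functional_group()].
#' @param config A [simulation_config()] (uses the `g1_*`, `s_fraction`,
#'   and `seed` entries).
#' @return Tibble `variant`, `pct_g1`, `pct_s`, `pct_g2m` with rows summing
#'   to 100.
#' @export
simulate_cell_cycle <- function(calls, config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  if (!"functional_group" %in% names(calls)) {
    calls <- assign_functional_group(calls)
  }
  withr::with_seed(config$seed, {
    del <- calls$functional_group %in% c("benchmark_pathogenic",
                                         "vus_deleterious")
    g1_mean <- ifelse(del, config$g1_deleterious_mean, config$g1_neutral_mean)
    g1 <- stats::rnorm(nrow(calls), g1_mean, config$g1_sd)
    g1 <- pmin(pmax(g1, 0), 100 - config$s_fraction)
    tibble(
      variant = calls$variant,
      pct_g1 = g1,
      pct_s = config$s_fraction,
      pct_g2m = 100 - g1 - config$s_fraction
    )
  })
}

#' Simulate a cohort carrier count
#'
#' Binomial draw of carrier counts for confidence-interval coverage studies.
#'
#' @param true_prevalence Carrier probability in \[0, 1\].
#' @param n_patients Cohort size.
#' @param seed Integer seed.
#' @return One-row tibble `study_label`, `n_patients`, `n_carriers`,
#'   `true_prevalence`.
#' @export
simulate_cohorts <- function(true_prevalence, n_patients, seed = 1L) {
  stopifnot(true_prevalence >= 0, true_prevalence <= 1, n_patients >= 1)
  withr::with_seed(seed, {
    tibble(
      study_label = "simulated",
      n_patients = as.integer(n_patients),
      n_carriers = stats::rbinom(1, n_patients, true_prevalence),
      true_prevalence = true_prevalence
    )
  })
}
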