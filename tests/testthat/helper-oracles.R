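# Independent oracles used across test files. These deliberately avoid the
# package's own code paths.

# AUC by explicit double loop over all (pathogenic, benign) pairs.
brute_force_auc <- function(pathogenic, benign) {
  total <- 0
  for (p in pathogenic) {
    for (b in benign) {
      total <- total + if (p > b) 1 else if (p == b) 0.5 else 0
    }
  }
  total / (length(pathogenic) * length(benign))
}

# Adjusted ("add 2 / add 4") Wald interval, transliterated independently.
adjusted_wald_oracle <- function(x, n) {
  p_tilde <- (x + 2) / (n + 4)
  half <- 1.959963984540054 * sqrt(p_tilde * (1 - p_tilde) / (n + 4))
  c(low = max(0, p_tilde - half), high = min(1, p_tilde + half))
}

# Pooled-variance two-sample t test from the textbook formula, with the
# p value obtained by numerical integration of the t density rather than pt().
students_t_oracle <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t_stat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  dens <- function(u) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + u^2 / df)^(-(df + 1) / 2)
  }
  tail <- stats::integrate(dens, abs(t_stat), Inf, rel.tol = 1e-12)$value
  list(t = t_stat, df = df, p = 2 * tail)
}

# Youden-optimal cutoff by brute force over candidate midpoints.
brute_force_youden <- function(pathogenic, benign) {
  pool <- sort(unique(c(pathogenic, benign)))
  cands <- (pool[-length(pool)] + pool[-1]) / 2
  j <- sapply(cands, function(cut) {
    mean(pathogenic > cut) + mean(benign <= cut) - 1
  })
  cands[which(j == max(j))][1]
}

# Small well-formed replicate table: 2 variants + control, 3 replicates.
tiny_replicates <- function() {
  tidyr::expand_grid(
    variant = c("p.Gly101Trp", "p.Ala148Thr", EMPTY_VECTOR),
    cell_line = "PANC-1",
    replicate = 1:3
  ) |>
    dplyr::mutate(cell_count = dplyr::case_when(
      variant == EMPTY_VECTOR ~ 1e6,
      variant == "p.Gly101Trp" ~ 9e5,
      TRUE ~ 2.5e5
    ))
}
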