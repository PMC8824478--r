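---
title: "Benchmark-anchored functional classification of CDKN2A variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmark-anchored functional classification of CDKN2A variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vusclassifyr)
library(dplyr)
```

## The assay and its statistical model

*CDKN2A* encodes p16^INK4A^, a CDK4/6 inhibitor whose loss removes a brake
on the G1-to-S transition. In a *CDKN2A*-null pancreatic cancer cell line,
re-expressing a functional allele suppresses proliferation; a deleterious
allele does not. The assay's unit of measurement is therefore the
*normalized proliferation value*: the cell count of a variant-expressing
culture divided by the count of the matched empty-vector control culture
(same cell line, same replicate). Values near 1 mean the variant protein has
lost its growth-suppressing function; low values mean the brake still works.

The analysis never models growth kinetics. It treats per-variant mean
proliferation values as exchangeable draws within known groups and asks a
classification question: anchored by variants of *known* classification
(benchmark pathogenic and benign variants assayed alongside), where should
the decision cutoffs sit, and on which side does each variant of uncertain
significance (VUS) fall?

## Calibration

Three cutoffs are derived from the benchmark per-variant means:

* `t_deleterious` — the lower limit of the pathogenic group's Z-score 95%
  interval, mean − 1.96·sd, where sd is the *sample standard deviation
  across per-variant means* (not a standard error). Values above it are
  indistinguishable from known pathogenic behaviour.
* `t_neutral` — symmetrically, the benign group's upper limit.
* `t_mid` — splits the intermediate zone. When the two benchmark groups are
  perfectly separated (ROC AUC exactly 1, tolerance 1e−12 — AUC from ranks
  of finite data is rational, so exact equality is meaningful), the midpoint
  between the lowest pathogenic mean and the highest benign mean is used.
  When the groups overlap, the Youden-optimal cutoff (maximizing
  sensitivity + specificity − 1 over midpoints of adjacent sorted benchmark
  means, ties resolved toward the smaller cutoff) replaces it.

The AUC itself is computed as the Mann–Whitney probability — the fraction of
(pathogenic, benign) pairs ranked correctly, ties counted ½ — with
pathogenic as the positive class and higher proliferation as more positive.

Two genuinely open design points deserve a note. First, "Z-score 95% CI
limit calculated from benchmark pathogenic variants and benign variants" can
be read per-group or pooled; we default to the per-group reading
(`interval_mode = "per_group"`) because it is the only reading under which
plausible group spreads reproduce the conventional cutoffs (0.90 − 1.96σ ≈
0.81 requires σ ≈ 0.046; 0.26 + 1.96σ ≈ 0.44 requires σ ≈ 0.092), and we
ship the pooled variant for sensitivity analysis. Second, the normal
quantile (1.96) is used rather than Student's t, matching the "Z-score"
naming; `ci_level` is configurable. Users who want the published cutoffs
exactly can bypass calibration entirely with
`threshold_set(0.81, 0.44, 0.66)` — the route the worked examples take,
since the real per-variant benchmark data are not bundled.

If the benchmark intervals overlap (`t_deleterious ≤ t_neutral`), the
calibration aborts with instructions to supply explicit thresholds rather
than silently producing an unusable ordering.

## Classification, consensus, and reclassification

The four-tier rule is a deterministic partition of the nonnegative reals:
deleterious above `t_deleterious`, potentially deleterious down to (and
including) values just above `t_mid`, potentially neutral from `t_neutral`
to `t_mid` inclusive, neutral below `t_neutral`. A value exactly at `t_mid`
is *potentially neutral* by default; the alternative convention (assigning
it to the deleterious side, as one published figure legend has it) is
available via `boundary = "mid_inclusive"`. The choice affects only
measure-zero inputs but is kept explicit because classification tables are
the package's main deliverable.

Cross-cell-line consensus pools per-cell-line means with an *unweighted*
mean (cell lines are assayed at different endpoint days — day 7 for
MIA PaCa-2, day 14 for PANC-1 and AsPC-1 — so replicate-level pooling would
mix timescales), then re-derives thresholds from the pooled benchmark means
unless explicit thresholds are in force. Agreement checking deliberately
distinguishes *sides* rather than exact tiers: a variant called deleterious
in one line and potentially deleterious in another agrees; only a
deleterious-side vs neutral-side split is a conflict.

Reclassification applies the ACMG PS3 rule: a VUS with a deleterious-side
call becomes likely pathogenic; a neutral-side call leaves it a VUS. No
benign evidence (BS3) is generated — the assay validation here supports
upgrading damaging variants, and the symmetric claim was never made.
Benchmark variants pass through unchanged, which also makes the operation
idempotent.

## Cell-cycle comparison

Phase fractions (G1, S, G2/M percentages summing to 100 ± 1 for rounding)
are compared between four groups: benchmark pathogenic, benchmark benign,
deleterious-side VUS, neutral-side VUS. The test is the classical
pooled-variance Student's t test (two-sided, df = n₁ + n₂ − 2), matching
the named method; Welch's form is available via `var_equal = FALSE`. The
unit of analysis is the per-variant percentage — one value per variant —
because the reported group ranges are ranges *across variants*. Degenerate
zero-variance inputs are handled explicitly (equal means: t = 0, p = 1;
unequal: p = 0, flagged) rather than erroring mid-pipeline. Because
functional p16 arrests cells in G1, the deleterious-side groups should show
*lower* G1 and *higher* G2/M; each comparison carries a
`direction_inverted` flag so a fixture with the opposite ordering is
caught.

## Prevalence

Carrier proportions use the modified Wald (Agresti–Coull) interval in its
add-2/add-4 form at the 95% level — p̃ = (x+2)/(n+4),
p̃ ± 1.96·√(p̃(1−p̃)/(n+4)), truncated to [0, 1] — the convention of the
commercial statistics packages that popularized the name; other confidence
levels use the general (x + z²/2)/(n + z²) form. Percentages are rounded
half-up to one decimal *for display only*; JSON output keeps full precision.

Converting reported variant counts to carrier counts assumes one carrier
per reported variant, and combining cohorts assumes disjoint studies; both
assumptions are surfaced in the documentation because the source studies
overlap to an unknown degree. Known-pathogenic carrier counts are not
always published directly; `infer_count_from_percent()` reconstructs the
integer numerator closest to a printed one-decimal percentage and errors on
ties. One reconstruction is genuinely ambiguous: for the combined
family-history stratum (n = 1029), both 17 and 18 carriers print as 1.7%,
and the nearest integer (17) differs from the count the downstream
cumulative figure implies (18). The function follows its stated
nearest-integer contract; the bundled cohort table stores only counts that
are unambiguous and leaves the rest `NA`.

## The synthetic-data generator

`simulate_assay()` emulates the assay's stated structure: per-variant true
means drawn from the benchmark group distributions — pathogenic
N(0.90, 0.05²), benign N(0.26, 0.10²), nine and seven variants — VUS means
given explicitly (default a grid spanning 0.1–1.0 so every tier is
populated), an additive per-cell-line shift N(0, 0.02²), and three
replicates per variant with multiplicative Gaussian noise (cv 0.05) scaled
to counts against a fixed control count. The replicate noise model is a
package choice: no replicate-level error model is published, and a
cv-parameterized multiplicative form keeps noise proportional to signal,
which is how cell-count error behaves. Cell-cycle simulation draws G1 from
N(48.5, 3²) or N(62.8, 3²) by functional side with a fixed 10% S fraction
and the remainder to G2/M, consistent with published G1 + G2/M group means
summing near 90. All generators are pure functions of (config, seed).

`published_fixture()` is different in kind: not a random draw but a
*constraint solution*. Per-variant PANC-1 means are chosen so that every
published summary holds simultaneously — benchmark means exactly 0.90 and
0.26, range extrema exactly 0.84/1.03 and 0.14/0.48, each of the 29 VUSs in
its published category under thresholds (0.81, 0.44, 0.66), replicate s.d.
exactly 0.02 by back-computation (v − 0.02, v, v + 0.02), cell-cycle group
means exactly at the published values inside the published ranges, and the
published cohort table. Within those constraints the individual values are
arbitrary and synthetic, and the fixture re-verifies all of them every time
it is built. Two bookkeeping choices: the 45th variant of the published
figure counts is the wild-type control, carried as `"WT"` in the benign
benchmark group (the published variant table lists 44 HGVS strings); and
the additional cell lines' values reproduce the published per-cell-line
category counts (7/5/3/14 and 6/6/8/9) and cross-line agreement, though
only the PANC-1 constraints are hard-verified.

What passing tests on this fixture shows: the *arithmetic* of every stage
reproduces the published numbers when fed data satisfying the published
summaries. What it cannot show: robustness to real replicate noise
structure, plate effects, or the actual per-variant values, which are not
public in per-variant form and are not bundled. The generator-based property tests
(category recovery ≥ 95% for variants ≥ 2 replicate-sd from every cutoff,
CI coverage ≈ 95%) cover the stochastic side at the stated study sizes.

## Numerical choices and degenerate inputs

* AUC uses the rank formulation of the Mann–Whitney U; tests verify
  equality with a brute-force double loop, and `auc(A,B) + auc(B,A) = 1`
  for tie-free inputs.
* Thresholds are translation-equivariant; the test suite checks this
  directly.
* `zscore_interval()` refuses fewer than two values; a single replicate
  yields `sd = NA` rather than a silent zero.
* Youden ties break toward the smallest cutoff (first maximum in the sorted
  candidate sequence), making the cutoff deterministic.
* Exact-boundary proliferation values (0.44, 0.66, 0.81) are classified by
  the documented inclusive/exclusive conventions, tested explicitly.
* The fixture's internal verifier uses 1e−9 tolerances for constraint
  equality (values are built from short decimals) and the exact-1 AUC rule
  at 1e−12.

## Problem sizes

The test suite and acceptance script run entirely from generated data: the
45-variant fixture across three cell lines (3 replicates each), ten
simulated assays of 26 variants for recovery checks, 10,000 binomial draws
at n = 638 for CI coverage, and oracle comparisons over 100–1000 random
cases per property. A full run takes well under a minute on one core.

## Limitations

* The package applies a single PS3-based upgrade rule; it is not an ACMG
  multi-criteria engine and ignores population frequency, computational
  predictors, and segregation evidence.
* Only p16^INK4A^ consequences are modelled; p14^ARF^ reading-frame effects
  and DNA-level (c.) notation are out of scope.
* Prevalence arithmetic inherits the source studies' one-carrier-per-variant
  reporting and possible cohort overlap; no meta-analytic weighting is
  attempted.
* The published 0.81/0.44 cutoffs cannot be re-derived exactly without the
  real per-variant values; calibration on the fixture yields (≈0.78, ≈0.49)
  with the same midpoint 0.66, and the explicit-threshold path exists
  precisely for this case.
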