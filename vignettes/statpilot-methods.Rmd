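---
title: "How statpilot decides: assumptions, transformations, and valid test selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How statpilot decides: assumptions, transformations, and valid test selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(statpilot)
```

## The problem

Grouped laboratory measurements — viability assays, qPCR, densitometry,
behavioral scores — are routinely analyzed with a t-test or ANOVA chosen by
habit rather than by the data's properties. Parametric tests assume
(approximately) normal errors and equal group variances; when those fail,
their p-values can manufacture significance or hide it. `statpilot` is a
headless workflow engine that makes the branch decision itself: it checks
the assumptions, guides a variance-stabilizing transformation when they
fail, runs the only statistically valid test for the design, and records
every decision in a replayable trace exported alongside the results.

The user intervenes at exactly two points: choosing the transformation when
the raw checks fail, and choosing the post-hoc procedure after a
significant omnibus test. Everything else is forced by the data.

## The decision procedure

For a one-factor design the engine executes, in order:

1. **Planning.** The design (independent vs dependent, from subject
   labels), the number of groups `k`, and the number of factors determine
   the candidate test family:

   | design | parametric | non-parametric |
   |---|---|---|
   | 2 groups, independent | t-test / Welch's t | Mann–Whitney U |
   | 2 groups, dependent | paired t | Wilcoxon signed-rank |
   | >2 groups, independent | one-way ANOVA / Welch | Kruskal–Wallis |
   | >2 groups, dependent | repeated-measures ANOVA | — (refusal) |

2. **Optional outlier screen** (Grubbs or modified Z-score, per group).
   Flagged points are highlighted, never removed; `drop_outliers = TRUE` is
   an explicit opt-in recorded in the trace.

3. **Raw assumption checks.** Shapiro–Wilk per group (a transformation is
   warranted only when some group itself deviates from normality) and the
   Brown–Forsythe test across groups. Both use a global `alpha`
   (default 0.05).

4. **Branch selection.**
   - both pass → parametric;
   - normality passes, homoscedasticity fails → the Welch variant
     (heteroscedasticity-robust but still normal-theory);
   - normality fails → a transformation is requested (log10, Box–Cox with
     pooled maximum-likelihood exponent, or arcsine square root).

5. **Post-transform checks.** After transforming, normality is assessed on
   the *model residuals* (observations minus their group means): the
   residuals pool all groups after removing the group effect, which is the
   quantity the ANOVA error assumption actually concerns. Homoscedasticity
   is re-tested on the transformed groups. Pass → parametric on the
   transformed values; normal residuals with unequal variances → Welch;
   still non-normal → the non-parametric test, computed on the *original*
   values (rank tests are invariant under the strictly monotone
   transforms offered, so this choice is presentational, not inferential).

6. **Omnibus and post-hoc.** The post-hoc menu is gated by the branch:
   parametric → Tukey HSD, Dunnett, or Šídák-adjusted selected pairs;
   non-parametric → Dunn's test or Šídák-adjusted pairwise Mann–Whitney.
   Post-hoc runs only after a significant omnibus (`force_posthoc`
   overrides with a trace warning). Cohen's d accompanies every parametric
   comparison: pooled-sd for independent groups, sd-of-differences for
   paired designs.

Designs with no valid fallback — dependent designs with more than two
groups, two-way, and mixed (split-plot) designs whose assumptions survive
neither the raw check nor one transformation attempt — end in a *refusal*:
a hard stop with an explicit reason, still exported as a full audit
workbook, rather than a silently wrong test. Friedman-type alternatives
were deliberately not offered; their type-I behavior is unreliable outside
narrow conditions, so refusing is the safer default.

### Decisions that were genuinely open

- **Welch routing.** The trigger for the Welch variants ("normal but
  heteroscedastic") is the standard statistical rationale for their
  existence; the trace marks the rule as inferred when it fires.
- **Homoscedasticity test.** Always the median-centered (Brown–Forsythe)
  form of Levene's test: the median makes the deviation scores robust to
  the very outliers and skew that motivate the check. A `center = "mean"`
  option exposes the classical mean-centered variant.
- **Paired designs and Welch.** A paired t-test has no Welch analogue;
  when a dependent 2-group design shows heteroscedasticity with normal
  data, the paired t runs with an explanatory trace note (the paired test
  conditions on within-pair differences, where group-variance inequality
  is not the operative assumption).
- **One transformation attempt per run** (mirroring the idea that each
  transformation defines a distinct analysis); `retry_transform = TRUE`
  permits a second, fully traced attempt.
- **Inapplicable transforms.** If the chosen transform cannot be applied
  at all (e.g. Box–Cox on data with non-positive values), the direct
  transform functions raise a hard error, but inside the workflow the
  failed attempt is recorded and the engine continues to the
  non-parametric branch — the same terminal it would reach if the
  transform had been applied and failed to rescue normality.
- **Pooled Box–Cox exponent.** The exponent is estimated once on the
  pooled values of all selected groups and applied identically everywhere;
  per-group exponents would place group means on incommensurable scales.
- **Outlier tests per group.** Whether to screen per group or pooled was
  open; per group matches the per-group normality philosophy and is
  recorded in the trace.
- **Sphericity.** The repeated-measures ANOVA applies no sphericity
  correction; every result carries a permanent "sphericity not assessed"
  note so the omission is visible rather than silent.
- **Unbalanced two-way designs** use Type-II sums of squares (no
  interaction-priority ambiguity, no contrast-coding dependence); balanced
  designs use the classical decomposition, and the two agree exactly on
  balanced data (tested).

## Numerical and procedural choices

- **Shapiro–Wilk** is Royston's AS R94 algorithm (3 ≤ n ≤ 5000). Zero
  variance and n < 3 make a group "not testable", which conservatively
  counts as a normality failure (pushing toward the rank tests) with an
  explanatory note.
- **Box–Cox exponent**: profile log-likelihood
  `LL(λ) = −(n/2)·log σ̂²(λ) + (λ−1)·Σ log xᵢ` maximized over
  `λ ∈ [−5, 5]` by bracketed scalar optimization, tolerance 1e-5; the
  transform switches to `log x` for `|λ| < 1e-10`, where the two branches
  agree to floating point.
- **Exact vs approximate rank tests**: Mann–Whitney p-values are exact by
  enumeration for `n₁+n₂ ≤ 12` without ties; Wilcoxon signed-rank exact
  for `n ≤ 15` without ties (zero differences dropped and counted);
  otherwise normal approximations with tie-corrected variance and
  continuity correction. The policy is recorded in each result's note.
- **Dunnett's adjustment** integrates the equicorrelated multivariate t
  distribution by Genz–Bretz quasi–Monte-Carlo with a fixed private seed,
  ≥ 10⁴ nodes and absolute tolerance 5e-4, so repeated runs and exports
  are identical.
- **Compact letter display**: insert-and-absorb over the non-significance
  graph, followed (for up to eight groups) by an exact minimization over
  maximal cliques, because the plain heuristic occasionally spends one
  letter more than necessary (10 of the 1024 five-group significance
  graphs). The letter assignment always satisfies: two groups share a
  letter iff their comparison is not significant.
- **Grubbs' test** is the two-sided single-outlier form, applied once —
  no iterative re-testing; the modified Z-score uses the 3.5 cutoff and,
  when the MAD collapses to zero, the mean absolute deviation about the
  median scaled by 1.253314.
- **p-value display**: values below `p_display_floor` (default 0.001)
  print as "p < 0.001"; stored numbers are never rounded.
- **Workbook reproducibility**: in-memory log entries carry monotone
  wall-clock timestamps, but the exported Analysis Log sheet prints the
  monotone sequence number and message, and the writer pins zip member
  timestamps — identical seeded runs therefore produce byte-identical
  workbooks, which makes exports diffable and auditable.

## What the synthetic generators emulate — and what they do not

`generate_fixture()` provides the package's study conditions:

- **`three_group_clean`**: three genotype-like groups (WT/KO/KI), n = 8
  each, unit variance, means 10/15/20 — separations of ≥ 5σ, so the
  omnibus F is large and every pairwise contrast is detected. Because the
  data are *genuinely* normal and homoscedastic, the probability that all
  three per-group Shapiro tests and the Brown–Forsythe test jointly pass
  at α = 0.05 is about 0.95⁴ ≈ 0.81 — an upper bound no generator tuning
  can move, since each test holds its nominal size under its own null.
  The calibration test asserts the parametric path on ≥ 75 % of seeds
  (a binomial-error band around that ceiling).
- **`viability_dirty`**: five viability-assay arms (ctrl/A/B/C/D, n drawn
  from 8–12) built to defeat parametric rescue: a tight control near
  100 %, right- and left-skewed arms with ceiling effects (values pressed
  against an upper plateau), and two bimodal responder/non-responder
  arms. Opposite skews plus bimodality cannot be normalized by any single
  monotone transform, so per-group normality fails (measured: 100 % of
  200 seeds), Brown–Forsythe fails (90 %), and residual normality still
  fails after log10 (100 %) or pooled-exponent Box–Cox (99.5 %). The
  high-variance arms are deliberately light-tailed: heavy-tailed noise
  would inflate the within-group variance of the deviation scores and
  paradoxically *hide* the heteroscedasticity from the Brown–Forsythe
  test.
- **`null_k_groups`**: i.i.d. N(0, 1), for operating-characteristic
  studies. With fixed choices (boxcox, tukey) the full pipeline's
  family-wise false-positive rate over 2000 seeded replicates sits near
  0.04–0.05, inside the [0.03, 0.08] band the acceptance suite asserts,
  and each omnibus test rejects at 0.05 within Monte-Carlo error.

What passing these tests does *not* show: real assays have correlated
technical replicates, batch effects, detection limits and censoring — none
of which the generators emulate. The generators validate the *decision
logic*, not the universe of laboratory data.

## Problem sizes used by the test and acceptance runs

The exhaustive compact-letter sweep covers all 1098 significance graphs
with k ≤ 5; the oracle-equivalence suite uses 500 random datasets; the
operating-characteristic run uses 2000 replicates of the full pipeline at
k = 3, n = 10 (the acceptance script reports a 1000-replicate version);
Box–Cox recovery uses n = 200 with 50 seeds per exponent in
{−1, −0.5, 0, 0.5, 1, 2}, with generating distributions chosen to keep
`1 + λz` positive and the profile likelihood well curved, and stated
tolerances (median |error| ≤ 0.3, maximum ≤ 1.2) of roughly three standard
errors of the estimator under those conditions.

## Known limitations

- No sphericity corrections (Greenhouse–Geisser/Huynh–Feldt) for
  repeated-measures designs.
- No non-parametric factorial alternatives (deliberate refusal instead).
- Effect sizes are limited to Cohen's d; η², rank-biserial and others are
  out of scope.
- The Welch two-way/mixed case has no established analogue here; the
  engine proceeds classically with a trace note when only
  homoscedasticity fails in a factorial design.
- The XLSX writer emits minimal SpreadsheetML (inline strings, no styling)
  — sufficient for any spreadsheet application or `readxl`, but it is not
  a general-purpose formatting library.

## A worked example

```{r example, eval = FALSE}
ds <- generate_fixture("viability_dirty", seed = 1)
result <- run_workflow(ds, workflow_config(),
                       choices = list(transform = "log10", posthoc = "dunn"))
writeLines(render_decision_tree(result, "text"))
export_workbook(result, "viability_analysis.xlsx")
```

The rendered tree shows every template node with the executed path marked
`[x]`, e.g. failed raw checks, the log10 attempt, failed residual
normality, and the Kruskal–Wallis terminal with Dunn's pairwise
comparisons — the same information that lands in the workbook's Decision
Tree sheet.
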