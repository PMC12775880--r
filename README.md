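# statpilot

A headless statistical copilot for grouped laboratory data. Given a
long-format table of experimental measurements (a group column, a value
column, optionally subject IDs for dependent designs and a second factor
for factorial designs), `statpilot` screens outliers, checks the
parametric assumptions, guides a variance-stabilizing transformation when
they fail, routes the data to the only statistically valid test, runs
branch-appropriate post-hoc comparisons with effect sizes, and exports a
fully traceable eight-sheet results workbook including a rendered decision
tree. It is aimed at bench scientists who want the branch decision —
parametric or not — taken by a procedure instead of by habit, and at
analysts who need every automated decision to be auditable.

## The method in brief

For `k` groups with values `x_ij`:

- **Normality.** Shapiro–Wilk `W` per group on the raw data; after a
  transformation, on the model residuals `x_ij − x̄_j` (the residuals pool
  all groups after removing the group effect — the quantity the ANOVA
  error assumption is about).
- **Homoscedasticity.** Brown–Forsythe: a one-way ANOVA on the
  median-centered absolute deviations `z_ij = |x_ij − median_j|`,
  `F = MS_between(z)/MS_within(z)` with df `(k−1, N−k)`.
- **Branch rule.** Both pass → parametric (t-test / one-way ANOVA);
  normal but heteroscedastic → Welch variant; non-normal → one guided
  transformation (log10; Box–Cox `(x^λ−1)/λ` with λ maximizing the profile
  likelihood `−(n/2)·log σ̂²(λ) + (λ−1)Σlog x_i` over `λ ∈ [−5,5]`;
  arcsine square root), then the residual check decides; still non-normal
  → Mann–Whitney U / Kruskal–Wallis (with tie correction). Dependent
  designs with > 2 groups and factorial designs have no valid
  non-parametric fallback: the run is *refused* with an explicit reason
  rather than analyzed wrongly.
- **Post-hoc** (branch-gated, after a significant omnibus): Tukey HSD
  (studentized range, Tukey–Kramer for unequal n), Dunnett (equicorrelated
  multivariate t, deterministic Genz–Bretz integration), Šídák-adjusted
  selected pairs (`p_adj = 1 − (1 − p)^m`), or Dunn's rank test.
  Cohen's d (pooled sd, or sd of differences for paired designs)
  accompanies every parametric comparison, and a compact letter display
  (groups share a letter iff not significantly different, minimal letter
  count) summarizes the pairwise pattern.

## Worked example

A five-arm viability assay that violates every parametric assumption:

```r
library(statpilot)

ds <- generate_fixture("viability_dirty", seed = 1)
result <- run_workflow(ds, workflow_config(),
                       choices = list(transform = "log10", posthoc = "dunn"))
print(result)
#> <sp_analysis_result> status: completed
#>   design: independent, 5 groups, 1 factor(s)
#>   Kruskal-Wallis: H = 27.4454, p < 0.001
#>   pairwise: 10 comparison(s), 4 significant

writeLines(render_decision_tree(result, "text"))
#> decision tree (executed path marked [x])
#> [x] design check (groups / factors / dependence) -> candidates: One-Way ANOVA / Welch's ANOVA / Kruskal-Wallis | k = 5, independent, 1 factor(s)
#> [ ] outlier screen
#> [x] normality check (raw, per group) -> fail | min per-group Shapiro-Wilk p = 0.0004365
#> [x] homoscedasticity check (raw, Brown-Forsythe) -> fail | p = 0.009753
#> [x] transformation -> log10 on strictly positive values
#> [x] normality check (post-transform, model residuals) -> fail | residual Shapiro-Wilk p = 8.673e-05
#> [x] homoscedasticity check (post-transform, Brown-Forsythe) -> fail | p = 0.004134
#> [x] branch decision (parametric / Welch / non-parametric) -> nonparametric | post-transform report
#> [x] omnibus test -> significant | H = 27.4454, p < 0.001
#> [x] post-hoc comparisons -> 4 significant at alpha = 0.05 | 10 comparison(s)
#> [ ] terminal: refusal
```

Reading the trace: at least one group fails Shapiro–Wilk (smallest
p = 0.00044) and the variances are unequal (Brown–Forsythe p = 0.0098), so
a parametric ANOVA is off the table; after the chosen log10 transform the
pooled residuals are still non-normal (p = 8.7e-05), so the engine runs
Kruskal–Wallis (H = 27.4, p < 0.001) and Šídák-adjusted Dunn comparisons,
four of which are significant (e.g. ctrl vs D, adjusted p = 3.7e-05).

```r
export_workbook(result, "viability_analysis.xlsx")
```

writes the eight-sheet workbook (Summary, Assumptions, Statistical
Results, Descriptive Statistics, Decision Tree, Raw Data, Pairwise
Comparisons, Analysis Log); identical seeded runs produce byte-identical
files. `make_plot()` renders bar/box/violin figures with significance
letters or brackets as SVG/PNG.

## Command line

```sh
Rscript inst/exec/statpilot analyze --in data.csv --group-col Group --value-col Values \
    --choices transform=log10,posthoc=dunn --out results.xlsx
Rscript inst/exec/statpilot fixtures --kind viability_dirty --seed 1 --out demo.csv
Rscript inst/exec/statpilot template --out template.xlsx
```

Exit codes: 0 = completed; 2 = valid refusal (unsupported design or an
assumption-blocked run — the audit workbook is still written); 1 =
input/configuration error.

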