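# Omnibus and two-group tests of the selection matrix, plus Welch variants.
#
#                       parametric              non-parametric
#   2 groups (indep.)   t-test / Welch t        Mann-Whitney U
#   2 groups (dep.)     paired t                Wilcoxon signed-rank
#   >2 groups (indep.)  one-way ANOVA / Welch   Kruskal-Wallis
#   >2 groups (dep.)    repeated-measures ANOVA (no non-parametric analogue)
#
# All p-values are two-sided. Cohen's d uses the pooled sd for independent
# groups (for Welch too, with a note) and the sd of differences for paired
# designs. The standard fits are delegated to stats; this module enforces
# the exact-vs-approximate policies and the effect-size conventions.

#' Two-sample t-test with Cohen's d
#'
#' @param x,y Numeric vectors, each n >= 2.
#' @param variant `"student"` (pooled variance, df = n1+n2-2) or `"welch"`
#'   (Welch-Satterthwaite df).
#' @param alpha Significance threshold recorded on the result.
#' @return An `sp_omnibus` (design "independent", k = 2, branch
#'   "parametric") whose `effect` is pooled-sd Cohen's d for both variants.
#' @export
t_test_2g <- function(x, y, variant = c("student", "welch"), alpha = 0.05) {
  variant <- match.arg(variant)
  assert_numeric_vec(x); assert_numeric_vec(y)
  if (length(x) < 2 || length(y) < 2) stop_statpilot("t-test needs n >= 2 per group")
  if (sd(x) == 0 && sd(y) == 0)
    stop_statpilot("t-test undefined: zero variance in both groups")
  tt <- t.test(x, y, var.equal = variant == "student")
  tr <- test_result(if (variant == "student") "t-test" else "Welch's t-test",
                    "t", unname(tt$statistic), df = unname(tt$parameter),
                    p = tt$p.value, n_used = length(x) + length(y),
                    note = if (variant == "welch")
                      "d uses pooled sd despite Welch denominator" else "")
  omnibus_result(tr, "independent", 2, "parametric", alpha,
                 effect = cohens_d_pooled(x, y))
}

#' Paired t-test with Cohen's d on differences
#'
#' @param x,y Paired numeric vectors of equal length (n >= 2 pairs).
#' @param alpha Significance threshold recorded on the result.
#' @return An `sp_omnibus` (design "dependent", k = 2); `effect` is
#'   `mean(x - y) / sd(x - y)`.
#' @export
paired_t_test <- function(x, y, alpha = 0.05) {
  assert_numeric_vec(x); assert_numeric_vec(y)
  if (length(x) != length(y)) stop_statpilot("paired t-test needs equal-length vectors")
  if (length(x) < 2) stop_statpilot("paired t-test needs n >= 2 pairs")
  d <- x - y
  if (sd(d) == 0) stop_statpilot("degenerate paired design: zero-variance differences")
  tt <- t.test(d)
  tr <- test_result("paired t-test", "t", unname(tt$statistic),
                    df = unname(tt$parameter), p = tt$p.value,
                    n_used = length(x))
  omnibus_result(tr, "dependent", 2, "parametric", alpha,
                 effect = cohens_d_paired(d))
}

#' One-way ANOVA (classic or Welch)
#'
#' @param groups List of numeric vectors, k >= 2, each n >= 2.
#' @param variant `"classic"` (F = MSB/MSW, df = (k-1, N-k)) or `"welch"`
#'   (heteroscedastic ANOVA with Satterthwaite-type denominator df).
#' @param alpha Significance threshold recorded on the result.
#' @return An `sp_omnibus` on the parametric branch.
#' @export
one_way_anova <- function(groups, variant = c("classic", "welch"), alpha = 0.05) {
  variant <- match.arg(variant)
  stopifnot(is.list(groups), length(groups) >= 2)
  lapply(groups, assert_numeric_vec)
  if (any(lengths(groups) < 2)) stop_statpilot("one-way ANOVA needs n >= 2 per group")
  allv <- unlist(groups, use.names = FALSE)
  if (sd(allv) == 0) stop_statpilot("ANOVA undefined: all values identical")
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ow <- oneway.test(allv ~ g, var.equal = variant == "classic")
  tr <- test_result(if (variant == "classic") "One-Way ANOVA" else "Welch's ANOVA",
                    "F", unname(ow$statistic), df = unname(ow$parameter),
                    p = ow$p.value, n_used = length(allv))
  omnibus_result(tr, "independent", length(groups), "parametric", alpha)
}

#' Kruskal-Wallis rank-sum test
#'
#' Mid-ranks for ties with the usual tie-correction factor
#' `1 - sum(t^3 - t) / (N^3 - N)`; p from chi-square with k - 1 df.
#'
#' @param groups List of numeric vectors, k >= 2, each n >= 1, N >= 3.
#' @param alpha Significance threshold recorded on the result.
#' @return An `sp_omnibus` on the non-parametric branch. With every value
#'   tied the statistic is reported as H = 0, p = 1 with a note.
#' @export
kruskal_wallis <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2)
  lapply(groups, assert_numeric_vec)
  if (any(lengths(groups) < 1)) stop_statpilot("Kruskal-Wallis needs n >= 1 per group")
  allv <- unlist(groups, use.names = FALSE)
  if (length(allv) < 3) stop_statpilot("Kruskal-Wallis needs N >= 3")
  k <- length(groups)
  if (length(unique(allv)) == 1) {
    tr <- test_result("Kruskal-Wallis", "H", 0, df = k - 1, p = 1,
                      n_used = length(allv), note = "all values tied")
    return(omnibus_result(tr, "independent", k, "nonparametric", alpha))
  }
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kw <- kruskal.test(allv, g)
  tr <- test_result("Kruskal-Wallis", "H", unname(kw$statistic),
                    df = unname(kw$parameter), p = kw$p.value,
                    n_used = length(allv))
  omnibus_result(tr, "independent", k, "nonparametric", alpha)
}

#' Mann-Whitney U test
#'
#' U is computed from mid-rank sums. The p-value is exact (by enumeration of
#' arrangements) when `n1 + n2 <= 12` and there are no ties, otherwise the
#' normal approximation with tie-corrected variance and continuity
#' correction is used; two-sided throughout.
#'
#' @param x,y Numeric vectors, each n >= 1.
#' @param alpha Significance threshold recorded on the result.
#' @return An `sp_omnibus` on the non-parametric branch; the statistic is U
#'   for the first sample.
#' @export
mann_whitney_u <- function(x, y, alpha = 0.05) {
  assert_numeric_vec(x); assert_numeric_vec(y)
  ties <- any(duplicated(c(x, y)))
  exact <- (length(x) + length(y) <= 12) && !ties
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  tr <- test_result("Mann-Whitney U", "U", unname(wt$statistic),
                    p = wt$p.value, n_used = length(x) + length(y),
                    note = if (exact) "exact enumeration (N <= 12, no ties)"
                           else "normal approximation, tie-corrected, continuity-corrected")
  omnibus_result(tr, "independent", 2, "nonparametric", alpha)
}

#' Wilcoxon signed-rank test
#'
#' Zero differences are dropped (their count is noted); V is the sum of
#' positive-difference ranks of `|diff|`. Exact p for n <= 15 without ties
#' in `|diff|`, else normal approximation with continuity correction.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @param alpha Significance threshold recorded on the result.
#' @return An `sp_omnibus` (design "dependent") on the non-parametric branch.
#' @export
wilcoxon_signed_rank <- function(x, y, alpha = 0.05) {
  assert_numeric_vec(x); assert_numeric_vec(y)
  if (length(x) != length(y)) stop_statpilot("signed-rank test needs equal-length vectors")
  d <- x - y
  nzero <- sum(d == 0)
  d <- d[d != 0]
  if (length(d) == 0) stop_statpilot("signed-rank test undefined: all differences zero")
  ties <- any(duplicated(abs(d)))
  exact <- length(d) <= 15 && !ties
  wt <- suppressWarnings(wilcox.test(d, exact = exact, correct = TRUE))
  note <- paste0(if (exact) "exact enumeration (n <= 15, no ties)"
                 else "normal approximation, continuity-corrected",
                 if (nzero > 0) sprintf("; %d zero difference(s) dropped", nzero) else "")
  tr <- test_result("Wilcoxon signed-rank", "V", unname(wt$statistic),
                    p = wt$p.value, n_used = length(d), note = note)
  omnibus_result(tr, "dependent", 2, "nonparametric", alpha)
}

# Long data with subject labels -> complete k x s cell matrix, or an error
# listing the missing (subject, group) cells.
rm_cell_matrix <- function(ds) {
  df <- ds$data
  subj <- sort(unique(df$subject))
  missing <- character()
  m <- matrix(NA_real_, nrow = length(subj), ncol = length(ds$group_order),
              dimnames = list(subj, ds$group_order))
  for (i in seq_len(nrow(df)))
    m[df$subject[i], df$group[i]] <- df$value[i]
  for (s in subj) for (g in ds$group_order)
    if (is.na(m[s, g])) missing <- c(missing, sprintf("(%s, %s)", s, g))
  if (length(missing))
    stop_statpilot(sprintf("incomplete repeated-measures design; missing cells: %s",
                           paste(missing, collapse = ", ")))
  m
}

#' Repeated-measures ANOVA (one within factor)
#'
#' Univariate decomposition of the complete balanced subject x condition
#' table: `F = MS_treatment / MS_(treatment x subject)` with df
#' `(k-1, (k-1)(s-1))`. No sphericity correction is applied; every result
#' carries a "sphericity not assessed" note.
#'
#' @param ds An `sp_dataset` with subject labels, every subject observed
#'   exactly once in every group.
#' @param alpha Significance threshold recorded on the result.
#' @return An `sp_omnibus` (design "dependent", parametric branch).
#' @export
rm_anova <- function(ds, alpha = 0.05) {
  stopifnot(inherits(ds, "sp_dataset"))
  if (!has_subjects(ds)) stop_statpilot("repeated-measures ANOVA needs subject labels")
  m <- rm_cell_matrix(ds)
  s <- nrow(m); k <- ncol(m)
  if (s < 2 || k < 2) stop_statpilot("repeated-measures ANOVA needs >= 2 subjects and >= 2 conditions")
  grand <- mean(m)
  ss_treat <- s * sum((colMeans(m) - grand)^2)
  ss_subj <- k * sum((rowMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_treat - ss_subj
  df1 <- k - 1; df2 <- (k - 1) * (s - 1)
  ms_err <- ss_err / df2
  if (ms_err <= 0) {
    f <- if (ss_treat == 0) 0 else Inf
    p <- if (ss_treat == 0) 1 else 0
  } else {
    f <- (ss_treat / df1) / ms_err
    p <- pf(f, df1, df2, lower.tail = FALSE)
  }
  tr <- test_result("Repeated-Measures ANOVA", "F", f, df = c(df1, df2),
                    p = p, n_used = s * k, note = "sphericity not assessed")
  omnibus_result(tr, "dependent", k, "parametric", alpha)
}

#' Two-way fixed-effects ANOVA
#'
#' Balanced designs use the classical decomposition; unbalanced designs use
#' Type-II sums of squares (via `car::Anova`) with a note. The interaction
#' is testable only if some cell has n >= 2; with all cells at n = 1 an
#' additive model is fitted.
#'
#' @param ds An `sp_dataset` whose observations carry a second factor.
#' @param alpha Significance threshold recorded on the results.
#' @return List of three `sp_omnibus` results: main effect of the group
#'   factor, main effect of the second factor, and their interaction
#'   (`NULL` statistic with a note when not testable).
#' @export
two_way_anova <- function(ds, alpha = 0.05) {
  stopifnot(inherits(ds, "sp_dataset"))
  if (!has_factor2(ds)) stop_statpilot("two-way ANOVA needs a second factor column")
  df <- ds$data
  A <- factor(df$group, levels = ds$group_order)
  B <- factor(df$factor2)
  cells <- table(A, B)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)
    stop_statpilot(sprintf("empty cell(s) in two-way design: %s",
      paste(sprintf("(%s, %s)", rownames(cells)[empty[, 1]],
                    colnames(cells)[empty[, 2]]), collapse = ", ")))
  }
  with_interaction <- any(cells >= 2)
  balanced <- length(unique(as.vector(cells))) == 1
  fml <- if (with_interaction) df$value ~ A * B else df$value ~ A + B
  fit <- lm(fml)
  tab <- if (balanced) anova(fit) else car::Anova(fit, type = 2)
  note <- if (balanced) "balanced design: classical decomposition"
          else "unbalanced design: Type-II sums of squares"
  df_res <- tab["Residuals", "Df"]
  mk <- function(term, label) {
    if (!term %in% rownames(tab)) return(NULL)
    f <- tab[term, "F value"]
    tr <- test_result(label, "F", f, df = c(tab[term, "Df"], df_res),
                      p = tab[term, "Pr(>F)"],
                      n_used = nrow(df), note = note)
    omnibus_result(tr, "independent", nlevels(A), "parametric", alpha)
  }
  out <- list(factor_a = mk("A", "Two-Way ANOVA: main effect A (group)"),
              factor_b = mk("B", "Two-Way ANOVA: main effect B"),
              interaction = if (with_interaction)
                mk("A:B", "Two-Way ANOVA: interaction A x B") else NULL)
  if (!with_interaction)
    out$interaction_note <- "interaction not testable: every cell has n = 1"
  out
}

#' Mixed (split-plot) ANOVA
#'
#' One between-subjects factor and one within-subjects factor; the factor
#' that is constant within each subject is taken as the between factor.
#' Classical decomposition: the between effect is tested against subjects
#' within groups; the within effect and the interaction are tested against
#' the subject x within-factor interaction.
#'
#' @param ds An `sp_dataset` with subject labels and a second factor,
#'   complete within-subject data, balanced cell sizes.
#' @param alpha Significance threshold recorded on the results.
#' @return List of three `sp_omnibus` results: `between`, `within`,
#'   `interaction`.
#' @export
mixed_anova <- function(ds, alpha = 0.05) {
  stopifnot(inherits(ds, "sp_dataset"))
  if (!has_subjects(ds) || !has_factor2(ds))
    stop_statpilot("mixed ANOVA needs subject labels and a second factor")
  df <- ds$data
  # identify the between factor: constant within each subject
  const_within <- function(col) all(tapply(df[[col]], df$subject,
                                           function(v) length(unique(v)) == 1))
  if (const_within("group")) {
    between <- factor(df$group, levels = ds$group_order); bname <- "group"
    within <- factor(df$factor2); wname <- "factor2"
  } else if (const_within("factor2")) {
    between <- factor(df$factor2); bname <- "factor2"
    within <- factor(df$group, levels = ds$group_order); wname <- "group"
  } else {
    stop_statpilot("mixed ANOVA: neither factor is constant within subjects")
  }
  subj <- factor(df$subject)
  # completeness: every subject seen once at every within level
  tab <- table(subj, within)
  if (any(tab != 1))
    stop_statpilot("incomplete within-subject data: every subject needs exactly one observation per within-factor level")
  a <- nlevels(between); b <- nlevels(within)
  s_per <- table(tapply(as.character(between), subj, `[`, 1))
  if (length(unique(as.vector(s_per))) != 1)
    stop_statpilot("mixed ANOVA requires equal numbers of subjects per between-factor group")
  s <- unname(s_per[1])
  y <- df$value
  grand <- mean(y)
  mean_ab <- tapply(y, list(between, within), mean)
  mean_a <- rowMeans(mean_ab); mean_b <- colMeans(mean_ab)
  mean_subj <- tapply(y, subj, mean)
  subj_grp <- tapply(as.character(between), subj, `[`, 1)

  ss_between <- b * s * sum((mean_a - grand)^2)
  ss_subj_within <- b * sum((mean_subj - mean_a[subj_grp])^2)
  ss_within <- a * s * sum((mean_b - grand)^2)
  ss_inter <- s * sum((mean_ab - outer(mean_a, rep(1, b)) -
                       outer(rep(1, a), mean_b) + grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_err_within <- ss_tot - ss_between - ss_subj_within - ss_within - ss_inter

  df_b <- a - 1; df_sw <- a * (s - 1)
  df_w <- b - 1; df_i <- (a - 1) * (b - 1); df_e <- a * (s - 1) * (b - 1)
  safe_f <- function(ssn, dfn, sse, dfe) {
    msn <- ssn / dfn; mse <- sse / dfe
    if (mse <= 0) list(f = if (msn == 0) 0 else Inf, p = if (msn == 0) 1 else 0)
    else list(f = msn / mse, p = pf(msn / mse, dfn, dfe, lower.tail = FALSE))
  }
  fb <- safe_f(ss_between, df_b, ss_subj_within, df_sw)
  fw <- safe_f(ss_within, df_w, ss_err_within, df_e)
  fi <- safe_f(ss_inter, df_i, ss_err_within, df_e)
  note <- sprintf("split-plot decomposition; between = %s, within = %s", bname, wname)
  mk <- function(res, dfs, label, design, k)
    omnibus_result(test_result(label, "F", res$f, df = dfs, p = res$p,
                               n_used = length(y), note = note),
                   design, k, "parametric", alpha)
  list(between = mk(fb, c(df_b, df_sw), "Mixed ANOVA: between-subjects effect", "independent", a),
       within = mk(fw, c(df_w, df_e), "Mixed ANOVA: within-subjects effect", "dependent", b),
       interaction = mk(fi, c(df_i, df_e), "Mixed ANOVA: interaction", "dependent", a * b))
}
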