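#' Construct a test result record
#'
#' The common currency of the package: every statistical check (normality,
#' homoscedasticity, omnibus, two-group) returns one of these.
#'
#' @param test Human-readable test name, e.g. `"Shapiro-Wilk"`.
#' @param statistic_name One of `"W"`, `"F"`, `"t"`, `"H"`, `"U"`, `"V"`,
#'   `"q"`, `"z"`, `"d-adjusted"`.
#' @param statistic Numeric test statistic (may be `NA` when not testable).
#' @param df `NULL` or a numeric vector of length 1 or 2 (df1, df2).
#' @param p Two-sided p-value in `[0, 1]` (or `NA` when not testable).
#' @param n_used Number of observations entering the test.
#' @param note Free-text annotation ("not testable", exactness policy, ...).
#' @return An object of class `sp_test_result`.
#' @export
test_result <- function(test, statistic_name, statistic, df = NULL, p,
                        n_used = NA_integer_, note = "") {
  if (!is.na(p) && (p < 0 || p > 1)) stop_statpilot("p outside [0, 1]")
  if (!is.null(df) && any(df <= 0)) stop_statpilot("df must be positive")
  structure(list(test = test, statistic_name = statistic_name,
                 statistic = statistic, df = df, p = p,
                 n_used = as.integer(n_used), note = note),
            class = "sp_test_result")
}

#' @export
print.sp_test_result <- function(x, ...) {
  dfs <- if (is.null(x$df)) "" else sprintf(" df = (%s)", paste(signif(x$df, 6), collapse = ", "))
  cat(sprintf("%s: %s = %s,%s %s%s\n", x$test, x$statistic_name,
              format(signif(x$statistic, 6)), dfs, format_p(x$p),
              if (nzchar(x$note)) paste0(" [", x$note, "]") else ""))
  invisible(x)
}

# Internal: an omnibus result is a test result plus routing metadata.
omnibus_result <- function(tr, design, k_groups, branch, alpha = 0.05,
                           effect = NULL) {
  stopifnot(inherits(tr, "sp_test_result"))
  tr$design <- design
  tr$k_groups <- as.integer(k_groups)
  tr$branch <- branch
  tr$alpha <- alpha
  tr$significant <- !is.na(tr$p) && tr$p < alpha
  tr$effect <- effect
  class(tr) <- c("sp_omnibus", class(tr))
  tr
}

#' @export
print.sp_omnibus <- function(x, ...) {
  NextMethod()
  cat(sprintf("  design = %s, k = %d, branch = %s, significant at alpha = %g: %s\n",
              x$design, x$k_groups, x$branch, x$alpha, x$significant))
  invisible(x)
}

# Cohen's d with pooled-sd denominator (independent groups).
cohens_d_pooled <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  if (sp2 <= 0) stop_statpilot("Cohen's d undefined: zero pooled variance")
  list(name = "cohens_d_pooled", value = (mean(x) - mean(y)) / sqrt(sp2),
       numerator = mean(x) - mean(y), denominator = sqrt(sp2))
}

# Cohen's d for paired designs: mean difference over sd of differences.
cohens_d_paired <- function(d) {
  s <- sd(d)
  if (s <= 0) stop_statpilot("Cohen's d undefined: zero-variance differences")
  list(name = "cohens_d_paired", value = mean(d) / s,
       numerator = mean(d), denominator = s)
}
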