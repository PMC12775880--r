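# Normality and homoscedasticity checks that drive the decision engine.
#
# Normality is Shapiro-Wilk (Royston's AS R94, via stats::shapiro.test):
# per group on raw data, on the model residuals after a transformation --
# residuals pool all groups after subtracting the group effect, which is
# what the ANOVA error assumption is actually about. Homoscedasticity is
# the Brown-Forsythe (median-centered Levene) test throughout: robust to
# outliers because the group median is insensitive to extreme values.

#' Shapiro-Wilk normality test
#'
#' @param values Numeric vector, 3 <= n <= 5000.
#' @return An `sp_test_result` with the W statistic and p-value. Zero
#'   variance yields a "not testable" result (`p = NA`), which the decision
#'   engine treats as a normality failure.
#' @export
shapiro_wilk <- function(values) {
  assert_numeric_vec(values)
  n <- length(values)
  if (n < 3 || n > 5000)
    stop_statpilot(sprintf("Shapiro-Wilk requires 3 <= n <= 5000 (got %d)", n))
  if (sd(values) == 0)
    return(test_result("Shapiro-Wilk", "W", NA_real_, p = NA_real_,
                       n_used = n, note = "not testable: zero variance"))
  sw <- shapiro.test(values)
  test_result("Shapiro-Wilk", "W", unname(sw$statistic), p = sw$p.value,
              n_used = n)
}

#' Brown-Forsythe test of homoscedasticity
#'
#' Levene-type test on absolute deviations from the group center:
#' `z_ij = |x_ij - center_j|` with the median as center (Brown-Forsythe)
#' or the mean (classical Levene), followed by a one-way fixed-effects
#' ANOVA on the `z_ij`.
#'
#' @param groups List of numeric vectors (>= 2 groups, each n >= 2).
#' @param center `"median"` (default, Brown-Forsythe) or `"mean"` (Levene).
#' @return An `sp_test_result` with F, df = (k-1, N-k) and p. If every
#'   deviation is identically zero the result is `p = 1` with a
#'   "no dispersion" note.
#' @export
brown_forsythe <- function(groups, center = c("median", "mean")) {
  center <- match.arg(center)
  stopifnot(is.list(groups))
  if (length(groups) < 2) stop_statpilot("Brown-Forsythe needs >= 2 groups")
  lapply(groups, assert_numeric_vec)
  if (any(lengths(groups) < 2))
    stop_statpilot("Brown-Forsythe needs n >= 2 in every group")
  cfun <- if (center == "median") median else mean
  z <- lapply(groups, function(x) abs(x - cfun(x)))
  k <- length(z)
  n <- lengths(z)
  N <- sum(n)
  allz <- unlist(z, use.names = FALSE)
  if (all(allz == 0))
    return(test_result("Brown-Forsythe", "F", 0, df = c(k - 1, N - k), p = 1,
                       n_used = N, note = "no dispersion"))
  grand <- mean(allz)
  ssb <- sum(n * (vapply(z, mean, 0) - grand)^2)
  ssw <- sum(vapply(z, function(x) sum((x - mean(x))^2), 0))
  if (ssw == 0)
    return(test_result("Brown-Forsythe", "F", Inf, df = c(k - 1, N - k),
                       p = 0, n_used = N,
                       note = "zero within-group dispersion variance"))
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  test_result(if (center == "median") "Brown-Forsythe" else "Levene (mean-centered)",
              "F", f, df = c(k - 1, N - k),
              p = pf(f, k - 1, N - k, lower.tail = FALSE), n_used = N)
}

#' Model residuals of the one-way group layout
#'
#' @param groups List of numeric vectors (each n >= 1).
#' @return Concatenated `x_ij - mean_j`, the residuals of the cell-means
#'   model; they sum to zero within each group.
#' @export
model_residuals <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 1)
  lapply(groups, assert_numeric_vec)
  unlist(lapply(groups, function(x) x - mean(x)), use.names = FALSE)
}

#' Assumption assessment at one workflow stage
#'
#' Raw stage: Shapiro-Wilk per group (a transformation is warranted only if
#' some group already deviates from normality) plus Brown-Forsythe across
#' groups. Post-transform stage: Shapiro-Wilk on the model residuals of the
#' transformed data plus Brown-Forsythe on the transformed groups.
#'
#' @param ds An `sp_dataset` (transformed values for the post stage).
#' @param stage `"raw"` or `"post_transform"`.
#' @param alpha Decision threshold for both pass flags, default 0.05.
#' @param center Centering for the homoscedasticity test, default `"median"`.
#' @return An `sp_assumption_report` with the component results and the two
#'   pass flags. A "not testable" normality result (zero variance, n < 3)
#'   forces `normality_pass = FALSE` with an explanatory note.
#' @export
assess_assumptions <- function(ds, stage = c("raw", "post_transform"),
                               alpha = 0.05, center = "median") {
  stopifnot(inherits(ds, "sp_dataset"))
  stage <- match.arg(stage)
  gv <- group_values(ds)
  notes <- character()

  per_group <- NULL
  residual <- NULL
  if (stage == "raw") {
    per_group <- lapply(gv, function(v) {
      if (length(v) < 3)
        test_result("Shapiro-Wilk", "W", NA_real_, p = NA_real_,
                    n_used = length(v), note = "not testable: n < 3")
      else shapiro_wilk(v)
    })
    ps <- vapply(per_group, function(tr) tr$p, 0)
    if (anyNA(ps)) {
      normality_pass <- FALSE
      notes <- c(notes, "per-group normality not testable in >= 1 group; treated as failure")
    } else {
      normality_pass <- min(ps) >= alpha
    }
  } else {
    res <- model_residuals(gv)
    residual <- if (length(res) >= 3 && sd(res) > 0) shapiro_wilk(res)
      else test_result("Shapiro-Wilk", "W", NA_real_, p = NA_real_,
                       n_used = length(res), note = "not testable")
    if (is.na(residual$p)) {
      normality_pass <- FALSE
      notes <- c(notes, "residual normality not testable; treated as failure")
    } else {
      normality_pass <- residual$p >= alpha
    }
  }

  homo <- brown_forsythe(gv, center = center)
  structure(list(stage = stage, alpha = alpha,
                 per_group_normality = per_group,
                 residual_normality = residual,
                 homoscedasticity = homo,
                 normality_pass = normality_pass,
                 homoscedasticity_pass = !is.na(homo$p) && homo$p >= alpha,
                 notes = notes),
            class = "sp_assumption_report")
}

#' @export
print.sp_assumption_report <- function(x, ...) {
  cat(sprintf("<assumption report: %s stage, alpha = %g>\n", x$stage, x$alpha))
  if (!is.null(x$per_group_normality))
    for (g in names(x$per_group_normality)) {
      cat(sprintf("  normality %-12s ", g))
      print(x$per_group_normality[[g]])
    }
  if (!is.null(x$residual_normality)) {
    cat("  residual normality   ")
    print(x$residual_normality)
  }
  cat("  homoscedasticity     ")
  print(x$homoscedasticity)
  cat(sprintf("  normality_pass = %s, homoscedasticity_pass = %s\n",
              x$normality_pass, x$homoscedasticity_pass))
  invisible(x)
}
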