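# Per-group descriptive statistics and outlier flagging.
#
# Outliers are flagged, never removed here; removal is a deliberate opt-in
# handled by the workflow engine (`drop_outliers`), and both tests are
# applied once per group, not iteratively.

#' Descriptive summary of one group
#'
#' @param values Numeric vector (n >= 1).
#' @param conf_level Confidence level for the t-interval on the mean.
#' @return One-row tibble: n, mean, median, sd (n-1 denominator), sem,
#'   ci_low/ci_high (t-interval), min, max. With n = 1 the dispersion and
#'   interval fields are `NA` (undefined).
#' @export
summarize_group <- function(values, conf_level = 0.95) {
  assert_numeric_vec(values)
  n <- length(values)
  if (n == 1)
    return(tibble::tibble(n = 1L, mean = values, median = values,
                          sd = NA_real_, sem = NA_real_,
                          ci_low = NA_real_, ci_high = NA_real_,
                          min = values, max = values))
  s <- sd(values)
  sem <- s / sqrt(n)
  tcrit <- qt(1 - (1 - conf_level) / 2, df = n - 1)
  tibble::tibble(n = n, mean = mean(values), median = median(values),
                 sd = s, sem = sem,
                 ci_low = mean(values) - tcrit * sem,
                 ci_high = mean(values) + tcrit * sem,
                 min = min(values), max = max(values))
}

#' Descriptive statistics for every group of a dataset
#'
#' @param ds An `sp_dataset`.
#' @param conf_level Confidence level for the t-interval, default 0.95.
#' @return Tibble with one row per group in `group_order`.
#' @export
describe_groups <- function(ds, conf_level = 0.95) {
  stopifnot(inherits(ds, "sp_dataset"))
  gv <- group_values(ds)
  out <- do.call(rbind, lapply(gv, summarize_group, conf_level = conf_level))
  tibble::as_tibble(cbind(tibble::tibble(group = names(gv)), out))
}

outlier_report <- function(method, threshold, index, score, flagged,
                           testable = TRUE, note = "") {
  structure(list(method = method, alpha_or_threshold = threshold,
                 per_point = tibble::tibble(index = index, score = score,
                                            flagged = flagged),
                 n_flagged = sum(flagged), testable = testable, note = note),
            class = "sp_outlier_report")
}

#' @export
print.sp_outlier_report <- function(x, ...) {
  cat(sprintf("<outlier screen: %s> %d/%d flagged%s\n", x$method,
              x$n_flagged, nrow(x$per_point),
              if (nzchar(x$note)) paste0(" [", x$note, "]") else ""))
  invisible(x)
}

#' Grubbs' test for a single outlier
#'
#' Two-sided, single application: the statistic is
#' `G = max |x_i - mean| / sd`, compared with the critical value
#' `G_crit = ((N-1)/sqrt(N)) * sqrt(t^2 / (N - 2 + t^2))` where `t` is the
#' upper `alpha/(2N)` quantile of Student's t with `N - 2` df. At most the
#' single most extreme point is flagged; flagging means "highlight", never
#' automatic removal, and the test is not re-applied after exclusion.
#'
#' @param values Numeric vector, n >= 3.
#' @param alpha Significance level, default 0.05.
#' @return An outlier report; for zero-variance input, a "not testable"
#'   report with zero flags.
#' @export
grubbs_test <- function(values, alpha = 0.05) {
  assert_numeric_vec(values)
  n <- length(values)
  if (n < 3) stop_statpilot("Grubbs' test needs n >= 3")
  s <- sd(values)
  if (s == 0)
    return(outlier_report("grubbs", alpha, seq_len(n), rep(NA_real_, n),
                          rep(FALSE, n), testable = FALSE,
                          note = "not testable: zero variance"))
  dev <- abs(values - mean(values)) / s
  tq <- qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)
  gcrit <- ((n - 1) / sqrt(n)) * sqrt(tq^2 / (n - 2 + tq^2))
  flagged <- rep(FALSE, n)
  imax <- which.max(dev)
  if (dev[imax] > gcrit) flagged[imax] <- TRUE
  rep_out <- outlier_report("grubbs", alpha, seq_len(n), dev, flagged)
  rep_out$G <- dev[imax]
  rep_out$G_crit <- gcrit
  rep_out
}

#' Modified Z-score outlier screen
#'
#' `M_i = 0.6745 (x_i - median) / MAD` with `MAD = median |x_i - median|`;
#' points with `|M_i|` above the cutoff (default 3.5, the Iglewicz-Hoaglin
#' convention) are flagged. When the MAD is zero the scale falls back to the
#' mean absolute deviation about the median times 1.253314; if that is also
#' zero the sample is not testable.
#'
#' @param values Numeric vector, n >= 3.
#' @param threshold Cutoff on `|M_i|`, default 3.5.
#' @return An outlier report.
#' @export
modified_zscore <- function(values, threshold = 3.5) {
  assert_numeric_vec(values)
  n <- length(values)
  if (n < 3) stop_statpilot("modified Z-score needs n >= 3")
  med <- median(values)
  mad0 <- median(abs(values - med))
  note <- ""
  if (mad0 > 0) {
    m <- 0.6745 * (values - med) / mad0
  } else {
    meanad <- mean(abs(values - med)) * 1.253314
    if (meanad == 0)
      return(outlier_report("modified_z", threshold, seq_len(n),
                            rep(NA_real_, n), rep(FALSE, n), testable = FALSE,
                            note = "not testable: zero dispersion"))
    m <- 0.6745 * (values - med) / meanad
    note <- "MAD = 0; mean-absolute-deviation fallback scale"
  }
  outlier_report("modified_z", threshold, seq_len(n), m,
                 abs(m) > threshold, note = note)
}

#' Screen every group of a dataset for outliers
#'
#' Applies the chosen test independently within each group (matching the
#' per-group philosophy of the normality checks).
#'
#' @param ds An `sp_dataset`.
#' @param method `"grubbs"` or `"modified_z"`.
#' @param alpha Grubbs significance level.
#' @param threshold Modified Z-score cutoff.
#' @return Named list of outlier reports, one per group. Groups with n < 3
#'   receive a "not testable" report rather than an error.
#' @export
screen_outliers <- function(ds, method = c("grubbs", "modified_z"),
                            alpha = 0.05, threshold = 3.5) {
  stopifnot(inherits(ds, "sp_dataset"))
  method <- match.arg(method)
  lapply(group_values(ds), function(v) {
    if (length(v) < 3)
      return(outlier_report(method, if (method == "grubbs") alpha else threshold,
                            seq_along(v), rep(NA_real_, length(v)),
                            rep(FALSE, length(v)), testable = FALSE,
                            note = "not testable: n < 3"))
    if (method == "grubbs") grubbs_test(v, alpha) else modified_zscore(v, threshold)
  })
}
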