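# Workbook export: the complete analysis -- including refused runs -- as a
# fixed eight-sheet XLSX audit artifact plus an optional plain-text log.

workbook_sheet_names <- c("Summary", "Assumptions", "Statistical Results",
                          "Descriptive Statistics", "Decision Tree",
                          "Raw Data", "Pairwise Comparisons", "Analysis Log")

empty_sheet <- function(reason) {
  data.frame(Note = reason, stringsAsFactors = FALSE)
}

fmt_num <- function(x) if (is.null(x) || length(x) == 0) NA_real_ else as.numeric(x)

omnibus_rows <- function(o, floor) {
  if (is.null(o)) return(NULL)
  if (inherits(o, "sp_omnibus")) o <- list(o)
  o <- Filter(function(x) inherits(x, "sp_omnibus"), o)
  do.call(rbind, lapply(o, function(x) data.frame(
    Test = x$test, Statistic = x$statistic_name,
    Value = fmt_num(x$statistic),
    df1 = if (length(x$df) >= 1) x$df[1] else NA_real_,
    df2 = if (length(x$df) >= 2) x$df[2] else NA_real_,
    p = fmt_num(x$p), `p (display)` = format_p(x$p, floor),
    Branch = x$branch, Significant = as.character(x$significant),
    `Effect size` = if (!is.null(x$effect)) x$effect$name else NA_character_,
    `Effect value` = if (!is.null(x$effect)) x$effect$value else NA_real_,
    Note = x$note, stringsAsFactors = FALSE, check.names = FALSE)))
}

assumption_rows <- function(rep_, stage, floor) {
  if (is.null(rep_)) return(NULL)
  rows <- list()
  if (!is.null(rep_$per_group_normality))
    for (g in names(rep_$per_group_normality)) {
      x <- rep_$per_group_normality[[g]]
      rows[[length(rows) + 1]] <- data.frame(
        Stage = stage, Check = "normality", Scope = g, Test = x$test,
        Statistic = fmt_num(x$statistic), p = fmt_num(x$p),
        `p (display)` = format_p(x$p, floor), Note = x$note,
        stringsAsFactors = FALSE, check.names = FALSE)
    }
  if (!is.null(rep_$residual_normality)) {
    x <- rep_$residual_normality
    rows[[length(rows) + 1]] <- data.frame(
      Stage = stage, Check = "normality", Scope = "model residuals",
      Test = x$test, Statistic = fmt_num(x$statistic), p = fmt_num(x$p),
      `p (display)` = format_p(x$p, floor), Note = x$note,
      stringsAsFactors = FALSE, check.names = FALSE)
  }
  x <- rep_$homoscedasticity
  rows[[length(rows) + 1]] <- data.frame(
    Stage = stage, Check = "homoscedasticity", Scope = "all groups",
    Test = x$test, Statistic = fmt_num(x$statistic), p = fmt_num(x$p),
    `p (display)` = format_p(x$p, floor), Note = x$note,
    stringsAsFactors = FALSE, check.names = FALSE)
  verdict <- data.frame(
    Stage = stage, Check = "verdict", Scope = "-",
    Test = sprintf("normality_pass = %s; homoscedasticity_pass = %s",
                   rep_$normality_pass, rep_$homoscedasticity_pass),
    Statistic = NA_real_, p = NA_real_, `p (display)` = "",
    Note = paste(rep_$notes, collapse = "; "),
    stringsAsFactors = FALSE, check.names = FALSE)
  do.call(rbind, c(rows, list(verdict)))
}

#' Export an analysis result as a multi-sheet workbook
#'
#' Every run -- completed, non-significant, or refused -- produces a
#' workbook with exactly eight sheets: Summary, Assumptions, Statistical
#' Results, Descriptive Statistics, Decision Tree, Raw Data, Pairwise
#' Comparisons, Analysis Log. Sheets with nothing to report carry one
#' explanatory row. Numeric cells keep full precision; display strings use
#' the configured p-value floor. Identical results give byte-identical
#' files.
#'
#' @param result An `sp_analysis_result` from [run_workflow()].
#' @param path Output `.xlsx` path.
#' @return `path`, invisibly.
#' @export
export_workbook <- function(result, path) {
  stopifnot(inherits(result, "sp_analysis_result"))
  floor <- result$config$p_display_floor
  ds <- result$dataset

  omni <- result$omnibus
  first_omni <- if (inherits(omni, "sp_omnibus")) omni
                else if (is.list(omni)) Filter(function(x) inherits(x, "sp_omnibus"), omni)[[1]]
                else NULL
  summary_rows <- rbind(
    data.frame(Field = "Status", Value = result$status, stringsAsFactors = FALSE),
    if (!is.null(result$refusal_reason))
      data.frame(Field = "Refusal reason", Value = result$refusal_reason),
    data.frame(Field = "Design",
               Value = if (!is.null(result$plan)) result$plan$design else "unknown"),
    data.frame(Field = "Groups",
               Value = paste(ds$group_order, collapse = ", ")),
    data.frame(Field = "Observations", Value = as.character(nrow(ds$data))),
    data.frame(Field = "Transformation",
               Value = sprintf("%s (%s)", result$transform$name,
                               result$transform$input_domain_note)),
    if (!is.null(first_omni))
      data.frame(Field = "Omnibus",
                 Value = sprintf("%s: %s = %s, %s", first_omni$test,
                                 first_omni$statistic_name,
                                 format(signif(first_omni$statistic, 6)),
                                 format_p(first_omni$p, floor))),
    data.frame(Field = "alpha", Value = format(result$config$alpha)),
    data.frame(Field = "Seed", Value = format(result$config$seed)))

  assum <- rbind(assumption_rows(result$assumptions$raw, "raw", floor),
                 assumption_rows(result$assumptions$post, "post_transform", floor))
  stat <- omnibus_rows(result$omnibus, floor)

  desc <- if (!is.null(result$descriptives)) as.data.frame(result$descriptives)
          else NULL

  tree_lines <- tryCatch(render_decision_tree(result, "text"),
                         error = function(e) "trace empty")
  tree <- data.frame(`Decision Tree` = tree_lines,
                     stringsAsFactors = FALSE, check.names = FALSE)

  raw <- data.frame(Group = ds$data$group, Values = ds$data$value,
                    stringsAsFactors = FALSE, check.names = FALSE)
  if (has_subjects(ds)) raw$Subject <- ds$data$subject
  if (has_factor2(ds)) raw$Factor2 <- ds$data$factor2

  pw <- if (!is.null(result$pairwise)) {
    p <- as.data.frame(result$pairwise)
    p$`p (display)` <- vapply(p$p_adj, format_p, "", floor = floor)
    p$significant <- as.character(p$significant)
    if (!is.null(result$letters)) {
      lmap <- setNames(result$letters$letters, result$letters$group)
      p$letters_a <- unname(lmap[p$group_a])
      p$letters_b <- unname(lmap[p$group_b])
    }
    p
  } else NULL

  log_df <- if (length(result$trace$log)) {
    do.call(rbind, lapply(result$trace$log, function(e) data.frame(
      Seq = e$seq, Level = e$level, Message = e$message,
      stringsAsFactors = FALSE)))
  } else NULL

  sheets <- list(
    Summary = summary_rows,
    Assumptions = assum %||% empty_sheet("no assumption checks were run"),
    `Statistical Results` = stat %||% empty_sheet("no statistical test was run"),
    `Descriptive Statistics` = desc %||% empty_sheet("no descriptives computed"),
    `Decision Tree` = tree,
    `Raw Data` = raw,
    `Pairwise Comparisons` = pw %||% empty_sheet("no pairwise comparisons (omnibus not significant, two-group design, or run refused)"),
    `Analysis Log` = log_df %||% empty_sheet("log empty"))
  stopifnot(identical(names(sheets), workbook_sheet_names))
  write_xlsx_sheets(sheets, path)
}

#' Write the plain-text analysis log
#'
#' Mirror of the workbook's Analysis Log sheet.
#'
#' @param result An `sp_analysis_result`.
#' @param path Output text file.
#' @return `path`, invisibly.
#' @export
write_log_file <- function(result, path) {
  stopifnot(inherits(result, "sp_analysis_result"))
  lines <- vapply(result$trace$log, function(e)
    sprintf("[%03d] %-8s %s", e$seq, e$level, e$message), "")
  writeLines(lines, path)
  invisible(path)
}
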