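# Long-format dataset container and ingestion.
#
# A dataset holds observations (group, value, optional subject, optional
# second factor), an explicit group order, and the provenance of the data
# (file, sheet, column mapping) plus the validation report from ingestion.

new_dataset <- function(df, group_order = NULL, source = list(),
                        validation = NULL) {
  df <- tibble::as_tibble(df)
  stopifnot(all(c("group", "value") %in% names(df)))
  if (!"subject" %in% names(df)) df$subject <- NA_character_
  if (!"factor2" %in% names(df)) df$factor2 <- NA_character_
  df$group <- trimws(as.character(df$group))
  df$subject <- trimws(as.character(df$subject))
  df$factor2 <- trimws(as.character(df$factor2))
  assert_numeric_vec(df$value, "value column")

  groups <- unique(df$group)
  if (length(groups) < 2)
    stop_statpilot("a dataset needs at least 2 distinct groups")
  group_order <- group_order %||% groups
  if (!setequal(group_order, groups) || anyDuplicated(group_order))
    stop_statpilot("group_order must be a permutation of the distinct group labels")

  has_subj <- !is.na(df$subject) & nzchar(df$subject)
  if (any(has_subj) && !all(has_subj))
    stop_statpilot("mixed subject annotation: either every observation has a subject label or none does")
  if (all(has_subj) && all(is.na(df$factor2) | !nzchar(df$factor2))) {
    dup <- duplicated(df[, c("subject", "group")])
    if (any(dup))
      stop_statpilot(sprintf(
        "duplicate (subject, group) rows in a dependent design: %s",
        paste(unique(sprintf("(%s, %s)", df$subject[dup], df$group[dup])), collapse = ", ")))
  }
  structure(list(data = df[, c("group", "value", "subject", "factor2")],
                 group_order = group_order, source = source,
                 validation = validation),
            class = "sp_dataset")
}

#' @export
print.sp_dataset <- function(x, ...) {
  n <- table(factor(x$data$group, levels = x$group_order))
  cat(sprintf("<sp_dataset> %d observations, %d groups (%s)\n",
              nrow(x$data), length(x$group_order),
              paste(sprintf("%s: n=%d", names(n), as.integer(n)), collapse = ", ")))
  if (has_subjects(x)) cat("  dependent design (subject labels present)\n")
  if (has_factor2(x)) cat("  second factor present\n")
  invisible(x)
}

has_subjects <- function(ds) {
  s <- ds$data$subject
  any(!is.na(s) & nzchar(s))
}

has_factor2 <- function(ds) {
  f <- ds$data$factor2
  any(!is.na(f) & nzchar(f))
}

# Values split by group, in group_order.
group_values <- function(ds) {
  lapply(setNames(ds$group_order, ds$group_order),
         function(g) ds$data$value[ds$data$group == g])
}

#' Read a long-format dataset from CSV or XLSX
#'
#' Rows whose value cell is missing, blank, or non-numeric are dropped and
#' itemized in the validation report; they are never imputed. Group labels
#' are whitespace-trimmed and compared case-sensitively.
#'
#' @param path Input file; format inferred from the extension (`.csv`, `.xlsx`).
#' @param group_col,value_col Names of the group and value columns.
#' @param subject_col Optional subject-identifier column for dependent designs.
#' @param factor_col Optional second-factor column for two-way/mixed designs.
#' @param sheet Optional sheet name (XLSX only; default first sheet).
#' @param decimal Decimal mark in CSV value cells: `"."` (default) or `","`.
#'   Never auto-detected.
#' @return An `sp_dataset`; its `validation` field is the [tibble::tibble()]
#'   based report (rows read/dropped, per-row drop reasons, groups found).
#' @export
read_dataset <- function(path, group_col = "Group", value_col = "Values",
                         subject_col = NULL, factor_col = NULL,
                         sheet = NULL, decimal = ".") {
  if (!file.exists(path)) stop_statpilot(sprintf("file not found: %s", path))
  if (!decimal %in% c(".", ",")) stop_statpilot('decimal must be "." or ","')
  if (identical(group_col, value_col))
    stop_statpilot("group column and value column must differ")
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                           fileEncoding = "UTF-8", na.strings = NULL)
  } else if (ext %in% c("xlsx", "xls")) {
    if (!is.null(sheet) && !sheet %in% readxl::excel_sheets(path))
      stop_statpilot(sprintf("sheet not found: %s", sheet))
    suppressMessages(
      raw <- readxl::read_excel(path, sheet = sheet, col_types = "text"))
    raw <- as.data.frame(raw, check.names = FALSE)
  } else {
    stop_statpilot(sprintf("unsupported file extension: .%s", ext))
  }
  for (col in c(group_col, value_col, subject_col, factor_col))
    if (!col %in% names(raw))
      stop_statpilot(sprintf("mapped column not found in %s: %s", basename(path), col))

  n_read <- nrow(raw)
  gl <- trimws(raw[[group_col]])
  vtxt <- trimws(raw[[value_col]])
  if (decimal == ",") vtxt <- gsub(",", ".", vtxt, fixed = TRUE)
  val <- suppressWarnings(as.numeric(vtxt))

  reason <- rep(NA_character_, n_read)
  bad_group <- is.na(gl) | !nzchar(gl)
  bad_value <- !bad_group & (is.na(vtxt) | !nzchar(vtxt))
  nonnum <- !bad_group & !bad_value & is.na(val)
  nonfin <- !bad_group & !bad_value & !nonnum & !is.finite(val)
  reason[bad_group] <- "missing group label"
  reason[bad_value] <- "missing value"
  reason[nonnum] <- "non-numeric value"
  reason[nonfin] <- "non-finite value"
  keep <- is.na(reason)
  if (!any(keep)) stop_statpilot("zero valid rows after validation")

  df <- tibble::tibble(
    group = gl[keep], value = val[keep],
    subject = if (is.null(subject_col)) NA_character_ else trimws(raw[[subject_col]][keep]),
    factor2 = if (is.null(factor_col)) NA_character_ else trimws(raw[[factor_col]][keep]))

  groups_found <- table(df$group)
  report <- list(
    n_rows_read = n_read,
    n_rows_dropped = sum(!keep),
    drop_reasons = tibble::tibble(row = which(!keep), reason = reason[!keep]),
    groups_found = tibble::tibble(group = names(groups_found),
                                  n = as.integer(groups_found)),
    warnings = character())
  new_dataset(df, group_order = unique(df$group),
              source = list(path = path, sheet = sheet,
                            mapping = list(group = group_col, value = value_col,
                                           subject = subject_col, factor2 = factor_col)),
              validation = report)
}

#' Restrict a dataset to selected groups, in a given order
#'
#' @param ds An `sp_dataset`.
#' @param groups Ordered character vector of group labels to keep (>= 2).
#' @return A new `sp_dataset` containing only those groups, with
#'   `group_order` equal to `groups`.
#' @export
select_groups <- function(ds, groups) {
  stopifnot(inherits(ds, "sp_dataset"))
  groups <- trimws(as.character(groups))
  unknown <- setdiff(groups, unique(ds$data$group))
  if (length(unknown))
    stop_statpilot(sprintf("unknown group label(s): %s", paste(unknown, collapse = ", ")))
  if (length(groups) < 2) stop_statpilot("select at least 2 groups")
  if (anyDuplicated(groups)) stop_statpilot("duplicate group labels in selection")
  df <- ds$data[ds$data$group %in% groups, ]
  new_dataset(df, group_order = groups, source = ds$source,
              validation = ds$validation)
}

#' Write the XLSX input template
#'
#' Emits a workbook whose first sheet has the documented header row
#' `Group | Values | Subject | Factor2` and a small worked example block
#' (three groups, three values each).
#'
#' @param path Output `.xlsx` path; an existing file is overwritten with a
#'   warning.
#' @return `path`, invisibly.
#' @export
write_template <- function(path) {
  if (file.exists(path)) warning(sprintf("overwriting existing file: %s", path))
  example <- template_example()
  write_xlsx_sheets(list(Data = example), path)
}

# The worked example embedded in the template (and used by round-trip tests).
template_example <- function() {
  data.frame(
    Group = rep(c("control", "treatment_A", "treatment_B"), each = 3),
    Values = c(1.2, 1.4, 1.1, 2.6, 2.9, 2.4, 4.1, 3.8, 4.4),
    Subject = NA_character_, Factor2 = NA_character_,
    stringsAsFactors = FALSE, check.names = FALSE)
}
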