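# Minimal SpreadsheetML (.xlsx) writer.
#
# Sheets are written with inline strings and full-precision numeric cells.
# Zip member timestamps are pinned to a constant so that identical inputs
# produce byte-identical workbooks (needed for reproducible exports).

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

col_letter <- function(j) {
  s <- ""
  while (j > 0) {
    r <- (j - 1) %% 26
    s <- paste0(LETTERS[r + 1], s)
    j <- (j - 1) %/% 26
  }
  s
}

sheet_xml <- function(df) {
  cell <- function(v, ref) {
    if (is.na(v)) return("")
    if (is.numeric(v))
      sprintf('<c r="%s"><v>%s</v></c>', ref,
              format(v, digits = 17, scientific = FALSE, trim = TRUE))
    else
      sprintf('<c r="%s" t="inlineStr"><is><t xml:space="preserve">%s</t></is></c>',
              ref, xml_escape(as.character(v)))
  }
  rows <- character(nrow(df) + 1)
  hdr <- vapply(seq_along(df), function(j) cell(names(df)[j], paste0(col_letter(j), 1)), "")
  rows[1] <- sprintf('<row r="1">%s</row>', paste(hdr, collapse = ""))
  for (i in seq_len(nrow(df))) {
    cs <- vapply(seq_along(df), function(j) cell(df[[j]][i], paste0(col_letter(j), i + 1)), "")
    rows[i + 1] <- sprintf('<row r="%d">%s</row>', i + 1, paste(cs, collapse = ""))
  }
  paste0('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
         '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main"><sheetData>',
         paste(rows, collapse = ""), "</sheetData></worksheet>")
}

#' Write data frames to a minimal XLSX workbook
#'
#' @param sheets Named list of data frames; names become sheet names, in order.
#' @param path Output path ending in `.xlsx`.
#' @return `path`, invisibly.
#' @details Cells are either numeric (full precision) or inline strings; no
#'   formatting is applied. Identical `sheets` yield byte-identical files.
#' @export
write_xlsx_sheets <- function(sheets, path) {
  stopifnot(is.list(sheets), length(sheets) >= 1, !is.null(names(sheets)))
  n <- length(sheets)
  tmp <- tempfile("xlsx")
  dir.create(file.path(tmp, "xl", "worksheets"), recursive = TRUE)
  dir.create(file.path(tmp, "_rels"), recursive = TRUE)
  dir.create(file.path(tmp, "xl", "_rels"), recursive = TRUE)

  ct <- paste0('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    paste(sprintf('<Override PartName="/xl/worksheets/sheet%d.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>', seq_len(n)), collapse = ""),
    '<Override PartName="/xl/styles.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.styles+xml"/>',
    "</Types>")
  rels <- paste0('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/></Relationships>')
  wb <- paste0('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships"><sheets>',
    paste(sprintf('<sheet name="%s" sheetId="%d" r:id="rId%d"/>',
                  xml_escape(names(sheets)), seq_len(n), seq_len(n)), collapse = ""),
    "</sheets></workbook>")
  wbrels <- paste0('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    paste(sprintf('<Relationship Id="rId%d" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" Target="worksheets/sheet%d.xml"/>', seq_len(n), seq_len(n)), collapse = ""),
    sprintf('<Relationship Id="rId%d" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/styles" Target="styles.xml"/>', n + 1),
    "</Relationships>")
  styles <- paste0('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<styleSheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
    '<fonts count="1"><font><sz val="11"/><name val="Calibri"/></font></fonts>',
    '<fills count="1"><fill><patternFill patternType="none"/></fill></fills>',
    '<borders count="1"><border/></borders>',
    '<cellStyleXfs count="1"><xf/></cellStyleXfs><cellXfs count="1"><xf/></cellXfs></styleSheet>')

  writeLines(ct, file.path(tmp, "[Content_Types].xml"))
  writeLines(rels, file.path(tmp, "_rels", ".rels"))
  writeLines(wb, file.path(tmp, "xl", "workbook.xml"))
  writeLines(wbrels, file.path(tmp, "xl", "_rels", "workbook.xml.rels"))
  writeLines(styles, file.path(tmp, "xl", "styles.xml"))
  for (i in seq_len(n))
    writeLines(sheet_xml(as.data.frame(sheets[[i]])),
               file.path(tmp, "xl", "worksheets", sprintf("sheet%d.xml", i)))

  files <- list.files(tmp, recursive = TRUE, all.files = TRUE, full.names = TRUE)
  Sys.setFileTime(files, as.POSIXct("2000-01-01 00:00:00", tz = "UTC"))
  path <- normalizePath(path, mustWork = FALSE)
  old <- setwd(tmp)
  on.exit({ setwd(old); unlink(tmp, recursive = TRUE) })
  zip::zip(path, files = list.files(".", recursive = TRUE, all.files = TRUE),
           recurse = FALSE, include_directories = FALSE)
  invisible(path)
}
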