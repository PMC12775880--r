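# Render the decision trace as a template decision tree with the executed
# path highlighted. The text form is stable: identical traces give
# byte-identical renders.

tree_template <- function() {
  list(
    c("design",            "design check (groups / factors / dependence)"),
    c("outlier_screen",    "outlier screen"),
    c("normality_raw",     "normality check (raw, per group)"),
    c("variance_raw",      "homoscedasticity check (raw, Brown-Forsythe)"),
    c("transform",         "transformation"),
    c("normality_post_transform", "normality check (post-transform, model residuals)"),
    c("variance_post_transform",  "homoscedasticity check (post-transform, Brown-Forsythe)"),
    c("branch",            "branch decision (parametric / Welch / non-parametric)"),
    c("omnibus",           "omnibus test"),
    c("posthoc",           "post-hoc comparisons"),
    c("refusal",           "terminal: refusal"))
}

#' Render the decision tree of a completed (or refused) run
#'
#' The full template tree is always shown; nodes executed by this run are
#' marked `[x]` and annotated with their outcome, unvisited nodes are
#' marked `[ ]`. The text render is byte-identical for identical traces.
#'
#' @param result An `sp_analysis_result` (or a frozen trace list).
#' @param format `"text"` (default) or `"svg"`.
#' @return Character vector of lines (`"text"`) or a single SVG string.
#' @export
render_decision_tree <- function(result, format = c("text", "svg")) {
  format <- match.arg(format)
  trace <- if (inherits(result, "sp_analysis_result")) result$trace else result
  nodes <- trace$nodes
  if (length(nodes) == 0) stop_statpilot("empty trace: nothing to render")
  by_id <- list()
  for (nd in nodes) {
    key <- nd$id
    # multi-instance ids (two-way omnibus, repeated transforms): join outcomes
    if (startsWith(key, "omnibus")) key <- "omnibus"
    by_id[[key]] <- c(by_id[[key]], sprintf("%s%s", nd$outcome,
      if (nzchar(nd$evidence)) paste0(" | ", nd$evidence) else ""))
  }
  rows <- lapply(tree_template(), function(tpl) {
    hit <- tpl[1] %in% names(by_id)
    ann <- if (hit) paste(by_id[[tpl[1]]], collapse = " ;; ") else ""
    list(id = tpl[1], label = tpl[2], hit = hit, ann = ann)
  })
  if (format == "text") {
    lines <- vapply(rows, function(r)
      sprintf("%s %s%s", if (r$hit) "[x]" else "[ ]", r$label,
              if (nzchar(r$ann)) paste0(" -> ", r$ann) else ""), "")
    c("decision tree (executed path marked [x])", lines)
  } else {
    h <- 28
    boxes <- vapply(seq_along(rows), function(i) {
      r <- rows[[i]]
      y <- 10 + (i - 1) * (h + 10)
      fill <- if (r$hit) "#cfe8cf" else "#f0f0f0"
      txt <- xml_escape(paste0(r$label, if (nzchar(r$ann)) paste0(": ", r$ann) else ""))
      paste0(
        sprintf('<rect x="10" y="%d" width="740" height="%d" fill="%s" stroke="#555"/>', y, h, fill),
        sprintf('<text x="18" y="%d" font-size="12" font-family="monospace">%s</text>', y + 18, txt),
        if (i < length(rows))
          sprintf('<line x1="380" y1="%d" x2="380" y2="%d" stroke="#555"/>', y + h, y + h + 10)
        else "")
    }, "")
    total_h <- 10 + length(rows) * (h + 10)
    paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
           sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="760" height="%d">', total_h),
           paste(boxes, collapse = ""), "</svg>")
  }
}
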