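# Publication plots: bar / box / violin with error bars and significance
# annotations (compact letters above groups, or brackets for significant
# pairs), written as SVG or PNG.

#' Plot a grouped dataset with optional significance annotations
#'
#' @param ds An `sp_dataset`.
#' @param result Optional `sp_analysis_result` supplying letters/pairwise
#'   results for annotations.
#' @param kind `"bar"` (mean + error bar), `"box"`, or `"violin"`.
#' @param error Error bar for bar charts: `"sd"` (default), `"sem"`, `"ci"`.
#' @param annotate `"none"`, `"letters"` (requires a letter assignment), or
#'   `"bars"` (brackets over significant pairs; requires pairwise results).
#' @param path Output file; format from the extension (`.svg` or `.png`).
#' @param width,height Device size in inches.
#' @return `path`, invisibly.
#' @export
make_plot <- function(ds, result = NULL, kind = c("bar", "box", "violin"),
                      error = c("sd", "sem", "ci"),
                      annotate = c("none", "letters", "bars"),
                      path, width = 7, height = 5) {
  stopifnot(inherits(ds, "sp_dataset"))
  kind <- match.arg(kind)
  error <- match.arg(error)
  annotate <- match.arg(annotate)
  if (annotate == "letters" && (is.null(result) || is.null(result$letters)))
    stop_statpilot("annotation 'letters' requires an analysis result with a letter assignment")
  if (annotate == "bars" && (is.null(result) || is.null(result$pairwise)))
    stop_statpilot("annotation 'bars' requires an analysis result with pairwise comparisons")
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("svg", "png")) stop_statpilot("plot format must be .svg or .png")

  df <- ds$data
  df$group <- factor(df$group, levels = ds$group_order)
  desc <- describe_groups(ds)
  desc$group <- factor(desc$group, levels = ds$group_order)
  desc$err <- switch(error, sd = desc$sd, sem = desc$sem,
                     ci = desc$ci_high - desc$mean)
  desc$err[is.na(desc$err)] <- 0

  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$value,
                                        fill = .data$group))
  p <- switch(kind,
    bar = ggplot2::ggplot(desc, ggplot2::aes(x = .data$group, y = .data$mean,
                                             fill = .data$group)) +
      ggplot2::geom_col(color = "black", width = 0.7) +
      ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$err,
                                          ymax = .data$mean + .data$err),
                             width = 0.2),
    box = p + ggplot2::geom_boxplot(),
    violin = p + ggplot2::geom_violin(scale = "width"))
  p <- p + ggplot2::theme_classic() +
    ggplot2::theme(legend.position = "none") +
    ggplot2::labs(x = NULL, y = "value")

  top <- max(df$value, desc$mean + desc$err, na.rm = TRUE)
  span <- max(top - min(df$value, 0, na.rm = TRUE), 1e-9)

  if (annotate == "letters") {
    lmap <- setNames(result$letters$letters, result$letters$group)
    ann <- data.frame(group = factor(ds$group_order, levels = ds$group_order),
                      y = top + 0.06 * span,
                      lab = unname(lmap[ds$group_order]))
    p <- p + ggplot2::geom_text(data = ann, inherit.aes = FALSE,
                                ggplot2::aes(x = .data$group, y = .data$y,
                                             label = .data$lab))
  } else if (annotate == "bars") {
    pw <- result$pairwise[result$pairwise$significant, , drop = FALSE]
    if (nrow(pw) > 0) {
      xs <- stats::setNames(seq_along(ds$group_order), ds$group_order)
      segs <- do.call(rbind, lapply(seq_len(nrow(pw)), function(i) {
        y <- top + (0.08 + 0.08 * (i - 1)) * span
        data.frame(x = xs[[pw$group_a[i]]], xend = xs[[pw$group_b[i]]],
                   y = y, lab = format_p(pw$p_adj[i], result$config$p_display_floor))
      }))
      p <- p + ggplot2::geom_segment(data = segs, inherit.aes = FALSE,
             ggplot2::aes(x = .data$x, xend = .data$xend,
                          y = .data$y, yend = .data$y)) +
        ggplot2::geom_text(data = segs, inherit.aes = FALSE, size = 3,
             ggplot2::aes(x = (.data$x + .data$xend) / 2,
                          y = .data$y + 0.02 * span, label = .data$lab))
    }
  }

  if (ext == "svg") grDevices::svg(path, width = width, height = height)
  else grDevices::png(path, width = width, height = height, units = "in",
                      res = 150)
  print(p)
  grDevices::dev.off()
  invisible(path)
}
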