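# Bar and lollipop enrichment plots with the significance-star convention:
# *, **, *** for adjusted p below 0.05, 0.01, 0.001. Plots are plain ggplot2
# objects, so callers can restyle them with the usual grammar.

#' Describe how an enrichment plot should look
#'
#' @param style `"bar"` or `"lollipop"`.
#' @param value_axis Quantity on the value axis: `"ratio"` (enrichment
#'   ratio, default) or `"neg_log10_padj"`.
#' @param alpha_stars Strictly decreasing significance thresholds for one,
#'   two, and three stars (default `c(0.05, 0.01, 0.001)`), applied to
#'   adjusted p-values.
#' @param top_n Optional cap on the number of categories shown (the
#'   `top_n` strongest on the value axis).
#' @param fill Mark colour.
#' @param title Optional plot title.
#' @return An object of class `plot_spec`.
#' @export
plot_spec <- function(style = c("bar", "lollipop"),
                      value_axis = c("ratio", "neg_log10_padj"),
                      alpha_stars = c(0.05, 0.01, 0.001),
                      top_n = NULL,
                      fill = "#2e8b57",
                      title = NULL) {
  style <- match.arg(style)
  value_axis <- match.arg(value_axis)
  if (length(alpha_stars) != 3L || any(diff(alpha_stars) >= 0)) {
    stop("alpha_stars must be three strictly decreasing thresholds",
      call. = FALSE
    )
  }
  if (!is.null(top_n) && (length(top_n) != 1L || top_n < 1)) {
    stop("top_n must be a single value >= 1", call. = FALSE)
  }
  structure(
    list(
      style = style, value_axis = value_axis, alpha_stars = alpha_stars,
      top_n = top_n, fill = fill, title = title
    ),
    class = "plot_spec"
  )
}

#' Significance stars for adjusted p-values
#'
#' `***`, `**`, `*`, or `""` for p below the third, second, and first
#' threshold of `alpha_stars`, in that order.
#'
#' @param p Numeric vector of (adjusted) p-values.
#' @param alpha_stars Strictly decreasing thresholds (see [plot_spec()]).
#' @return Character vector of star strings.
#' @export
significance_stars <- function(p, alpha_stars = c(0.05, 0.01, 0.001)) {
  ifelse(p < alpha_stars[[3L]], "***",
    ifelse(p < alpha_stars[[2L]], "**",
      ifelse(p < alpha_stars[[1L]], "*", "")
    )
  )
}

#' Build an enrichment plot as a ggplot object
#'
#' One mark per category, ordered by the value axis, with significance
#' stars appended to category labels. KOG letter reports (which carry a
#' class in `group`) are split into class panels. Returned unrendered so it
#' can be customized with ggplot2 grammar; [render_enrichment_plot()]
#' writes it to a file.
#'
#' @param report An `enrichment_report`.
#' @param spec A [plot_spec()].
#' @return A ggplot object.
#' @export
enrichment_plot <- function(report, spec = plot_spec()) {
  stopifnot(inherits(report, "enrichment_report"), inherits(spec, "plot_spec"))
  df <- report$results
  if (nrow(df) == 0L) {
    stop(
      "enrichment report is empty; check that the query ids match the ",
      "model's protein identifiers",
      call. = FALSE
    )
  }
  df$value <- switch(spec$value_axis,
    ratio = df$ratio,
    neg_log10_padj = -log10(pmax(df$p_adjusted, .Machine$double.xmin))
  )
  df <- df[order(-df$value, df$category_id, method = "radix"), , drop = FALSE]
  if (!is.null(spec$top_n) && nrow(df) > spec$top_n) {
    df <- df[seq_len(spec$top_n), , drop = FALSE]
  }
  stars <- significance_stars(df$p_adjusted, spec$alpha_stars)
  df$display <- trimws2(paste(df$label, stars))
  df$display <- factor(df$display, levels = rev(df$display))
  axis_title <- switch(spec$value_axis,
    ratio = "Enrichment ratio",
    neg_log10_padj = expression(-log[10] ~ "adjusted p-value")
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$value, y = .data$display))
  p <- switch(spec$style,
    bar = p + ggplot2::geom_col(fill = spec$fill),
    lollipop = p +
      ggplot2::geom_segment(
        ggplot2::aes(x = 0, xend = .data$value, yend = .data$display),
        colour = spec$fill
      ) +
      ggplot2::geom_point(colour = spec$fill, size = 3)
  )
  grouped <- identical(report$model_kind, "kog_letter") &&
    all(!is.na(df$group)) && all(nzchar(df$group))
  if (grouped) {
    p <- p + ggplot2::facet_grid(
      rows = ggplot2::vars(.data$group),
      scales = "free_y", space = "free_y",
      labeller = ggplot2::label_wrap_gen(18)
    )
  }
  p +
    ggplot2::labs(x = axis_title, y = NULL, title = spec$title) +
    ggplot2::theme_bw() +
    ggplot2::theme(
      strip.text.y = ggplot2::element_text(angle = 0),
      plot.title.position = "plot"
    )
}

#' Render an enrichment plot to an image file
#'
#' Writes [enrichment_plot()] output to SVG or PNG, inferred from the
#' filename suffix. SVG output (cairo device) is byte-deterministic for a
#' given report and spec.
#'
#' @param report An `enrichment_report`.
#' @param spec A [plot_spec()].
#' @param out Output path ending in `.svg` or `.png`.
#' @param width,height Device size in inches.
#' @return The ggplot object, invisibly.
#' @export
render_enrichment_plot <- function(report, spec = plot_spec(), out,
                                   width = 7, height = 5) {
  p <- enrichment_plot(report, spec)
  ext <- tolower(tools::file_ext(out))
  switch(ext,
    svg = grDevices::svg(out, width = width, height = height),
    png = grDevices::png(out,
      width = width, height = height, units = "in", res = 150
    ),
    stop("unsupported image format '.", ext, "'; use .svg or .png",
      call. = FALSE
    )
  )
  on.exit(grDevices::dev.off())
  print(p)
  invisible(p)
}
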