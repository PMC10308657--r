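# Rendering: a plot_spec in, a ggplot (or patchwork of panels) out.
# All layout decisions were made when the spec was computed; this file
# only translates spec tables into geoms.

#' Render a plot specification with ggplot2
#'
#' @param spec A `plot_spec` from one of the `*_spec()` functions.
#' @return A ggplot object (single-panel kinds) or a patchwork stack
#'   (regional kinds).
#' @export
render_plot_spec <- function(spec) {
  stopifnot(inherits(spec, "plot_spec"))
  switch(spec$kind,
         manhattan = render_manhattan(spec),
         region = render_region(spec),
         locuszoom = render_locuszoom(spec),
         effect = render_effect(spec),
         stop("unknown plot kind: ", spec$kind, call. = FALSE))
}

gwasviz_theme <- function() {
  ggplot2::theme_classic(base_size = 11) +
    ggplot2::theme(strip.background = ggplot2::element_blank())
}

series_scales <- function(spec) {
  s <- spec$series
  list(
    ggplot2::scale_colour_manual(values = setNames(s$color, s$dataset),
                                 breaks = s$dataset, name = NULL),
    ggplot2::scale_shape_manual(values = setNames(s$shape, s$dataset),
                                breaks = s$dataset, name = NULL)
  )
}

add_points <- function(p, spec) {
  pts <- merge(spec$points, spec$series, by = "dataset", sort = FALSE)
  # keep dataset draw order: first dataset drawn first (underneath)
  pts$dataset <- factor(pts$dataset, levels = spec$series$dataset)
  pts <- pts[order(pts$dataset, pts$x), , drop = FALSE]
  p + ggplot2::geom_point(
    data = pts,
    ggplot2::aes(x = .data$x, y = .data$y, colour = .data$dataset,
                 shape = .data$dataset),
    size = pts$size, alpha = pts$alpha
  )
}

add_hlines <- function(p, spec, mirrored = FALSE) {
  h <- spec$hlines
  if (is.null(h) || nrow(h) == 0L) return(p)
  y <- h$y
  if (mirrored) y <- c(y, -y)
  p + ggplot2::geom_hline(yintercept = y, linetype = "dashed",
                          colour = "grey40", linewidth = 0.3)
}

add_vlines <- function(p, spec) {
  v <- spec$vlines
  if (is.null(v) || nrow(v) == 0L) return(p)
  p + ggplot2::geom_vline(xintercept = v$x, linetype = "dashed",
                          colour = "grey55", linewidth = 0.3)
}

add_labels <- function(p, spec) {
  l <- spec$labels
  if (is.null(l) || nrow(l) == 0L) return(p)
  p + ggplot2::geom_text(
    data = l,
    ggplot2::aes(x = .data$x, y = .data$y, label = .data$text),
    colour = l$color, fontface = l$fontface, angle = l$angle,
    size = 2.8, vjust = -0.4, inherit.aes = FALSE
  )
}

render_manhattan <- function(spec) {
  mirrored <- isTRUE(spec$axes$mirrored)
  p <- ggplot2::ggplot()
  sh <- spec$shades[spec$shades$shaded, , drop = FALSE]
  if (nrow(sh) > 0) {
    p <- p + ggplot2::geom_rect(
      data = sh,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax),
      ymin = -Inf, ymax = Inf, fill = sh$fill, alpha = sh$alpha
    )
  }
  p <- add_points(p, spec)
  p <- add_hlines(p, spec, mirrored)
  p <- add_vlines(p, spec)
  if (mirrored) {
    p <- p + ggplot2::geom_hline(yintercept = 0, colour = "grey30",
                                 linewidth = 0.3)
  }
  hl <- spec$highlight
  if (!is.null(hl) && nrow(hl) > 0) {
    p <- p + ggplot2::annotate("segment", x = hl$xmin, xend = hl$xmax,
                               y = 0, yend = 0, colour = "darkgreen",
                               linewidth = 2) +
      ggplot2::annotate("text", x = hl$xmid, y = 0, label = hl$gene_name,
                        vjust = 1.6, size = 2.8, colour = "darkgreen")
  }
  p <- add_labels(p, spec)
  p <- p +
    ggplot2::scale_x_continuous(breaks = spec$axes$xticks,
                                labels = spec$axes$xlabels,
                                expand = ggplot2::expansion(mult = 0.01)) +
    ggplot2::scale_y_continuous(labels = function(b) abs(b)) +
    ggplot2::labs(x = spec$axes$xlab, y = spec$axes$ylab) +
    series_scales(spec) +
    gwasviz_theme()
  if (!spec$legend$show) {
    p <- p + ggplot2::theme(legend.position = "none")
  } else {
    p <- p + ggplot2::theme(legend.position = spec$legend$position)
  }
  p
}

render_overview_panel <- function(spec) {
  ov <- spec$overview
  rect <- data.frame(xmin = ov$rect[1], xmax = ov$rect[2])
  ggplot2::ggplot() +
    ggplot2::geom_point(data = ov$points,
                        ggplot2::aes(x = .data$x, y = .data$y),
                        colour = "grey60", size = 0.3) +
    ggplot2::geom_rect(data = rect,
                       ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax),
                       ymin = -Inf, ymax = Inf, colour = "red",
                       fill = "red", alpha = 0.15, linewidth = 0.4) +
    ggplot2::labs(x = NULL, y = NULL, title = spec$region$label) +
    gwasviz_theme() +
    ggplot2::theme(axis.text = ggplot2::element_text(size = 6),
                   plot.title = ggplot2::element_text(size = 9))
}

render_main_panel <- function(spec) {
  mirrored <- isTRUE(spec$axes$mirrored)
  p <- ggplot2::ggplot()
  p <- add_points(p, spec)
  p <- add_hlines(p, spec, mirrored)
  p <- add_vlines(p, spec)
  p <- add_labels(p, spec)
  p <- p +
    ggplot2::coord_cartesian(xlim = spec$axes$xlim) +
    ggplot2::scale_y_continuous(labels = function(b) abs(b)) +
    ggplot2::labs(x = spec$axes$xlab, y = spec$axes$ylab) +
    series_scales(spec) +
    gwasviz_theme()
  p + ggplot2::theme(legend.position =
                       if (spec$legend$show) spec$legend$position else "none")
}

render_gene_panel <- function(spec) {
  gl <- spec$genes
  p <- ggplot2::ggplot()
  if (!is.null(gl) && nrow(gl$genes) > 0) {
    g <- gl$genes
    p <- p +
      ggplot2::geom_segment(data = g,
                            ggplot2::aes(x = .data$gene_start,
                                         xend = .data$gene_end,
                                         y = -.data$row, yend = -.data$row),
                            linewidth = if (gl$show_exons) 0.4 else 2,
                            colour = "navy") +
      ggplot2::geom_text(data = g,
                         ggplot2::aes(x = (.data$gene_start + .data$gene_end) / 2,
                                      y = -.data$row, label = .data$gene_name),
                         vjust = -0.9, size = 2.6, fontface = "italic")
    if (gl$show_exons && nrow(gl$exons) > 0) {
      p <- p + ggplot2::geom_rect(data = gl$exons,
                                  ggplot2::aes(xmin = .data$start,
                                               xmax = .data$end,
                                               ymin = -.data$row - 0.25,
                                               ymax = -.data$row + 0.25),
                                  fill = "navy")
    }
  }
  nr <- max(1, if (is.null(gl)) 1 else gl$n_rows)
  p +
    ggplot2::coord_cartesian(xlim = spec$axes$xlim,
                             ylim = c(-nr - 0.7, 0)) +
    ggplot2::labs(x = spec$axes$xlab, y = NULL) +
    gwasviz_theme() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.ticks.y = ggplot2::element_blank(),
                   axis.line.y = ggplot2::element_blank())
}

render_region <- function(spec) {
  panels <- list(render_overview_panel(spec), render_main_panel(spec))
  heights <- c(1, 4)
  if ("genes" %in% spec$panels) {
    panels <- c(panels, list(render_gene_panel(spec)))
    heights <- c(heights, 1)
  }
  patchwork::wrap_plots(panels, ncol = 1, heights = heights)
}

render_locuszoom_main <- function(spec) {
  pts <- spec$points
  pts$bin <- factor(pts$bin, levels = spec$r2$labels)
  main <- pts[!pts$index, , drop = FALSE]
  idx <- pts[pts$index, , drop = FALSE]
  p <- ggplot2::ggplot() +
    ggplot2::geom_point(data = main,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     fill = .data$bin),
                        shape = 21, size = 1.6, colour = "grey30",
                        stroke = 0.2) +
    ggplot2::scale_fill_manual(values = unlist(spec$r2$colors),
                               limits = spec$r2$labels, name = expression(r^2),
                               drop = FALSE, na.value = "grey80")
  if (nrow(idx) > 0) {
    p <- p + ggplot2::geom_point(data = idx,
                                 ggplot2::aes(x = .data$x, y = .data$y),
                                 shape = 23, size = 2.6, fill = "purple",
                                 colour = "black")
  }
  p <- add_hlines(p, spec)
  p <- add_labels(p, spec)
  p +
    ggplot2::coord_cartesian(xlim = spec$axes$xlim) +
    ggplot2::labs(x = spec$axes$xlab, y = spec$axes$ylab,
                  title = spec$region$label) +
    gwasviz_theme() +
    ggplot2::theme(plot.title = ggplot2::element_text(size = 9))
}

render_locuszoom <- function(spec) {
  if (!"genes" %in% spec$panels) return(render_locuszoom_main(spec))
  patchwork::wrap_plots(list(render_locuszoom_main(spec),
                             render_gene_panel(spec)),
                        ncol = 1, heights = c(4, 1))
}

render_effect <- function(spec) {
  pts <- spec$points
  p <- ggplot2::ggplot()
  if (isTRUE(spec$zero_axes)) {
    p <- p + ggplot2::geom_hline(yintercept = 0, colour = "grey70",
                                 linewidth = 0.3) +
      ggplot2::geom_vline(xintercept = 0, colour = "grey70", linewidth = 0.3)
  }
  if (isTRUE(spec$identity_line)) {
    p <- p + ggplot2::geom_abline(slope = 1, intercept = 0,
                                  linetype = "dashed", colour = "grey50")
  }
  if (nrow(pts) > 0) {
    p <- p + ggplot2::geom_point(
      data = pts,
      ggplot2::aes(x = .data$x, y = .data$y),
      shape = ifelse(pts$filled, 19, 1), size = 2, colour = "#0072B2"
    )
  }
  p <- add_labels(p, spec)
  p + ggplot2::labs(x = spec$axes$xlab, y = spec$axes$ylab) +
    gwasviz_theme()
}
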