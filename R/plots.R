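# Spec constructors and user-facing plot functions.

#' Compute a Manhattan plot specification
#'
#' Lays out one or more datasets in cumulative genome coordinates
#' (variant position on the x-axis, `-log10(P)` on the y-axis) with
#' alternating semi-transparent chromosome shades, a genome-wide
#' significance line at `5e-8` by default (alterable, removable, or
#' multiple), optional lead-variant labels, vertical position lines,
#' rsid labels and highlighted genes on a bottom strip. With several
#' datasets, `ntop` controls how many are drawn on the top axis and how
#' many on the mirrored bottom axis.
#'
#' @param data A summary-statistics data frame or a (optionally named)
#'   list of them; list order fixes the palette, legend and `ntop` split.
#' @param ntop Number of datasets on the top axis; default all.
#' @param annotate P-value threshold(s) for labelling lead variants with
#'   their nearest gene (or their gene column, when present); length 1 or
#'   one per dataset; `NULL` (default) labels nothing.
#' @param annotate_with_vline Like `annotate`, additionally drawing a
#'   vertical line at each labelled variant.
#' @param region_size Labelling-density window, see [get_lead_snps()].
#' @param sign_thresh Significance threshold(s) drawn as horizontal
#'   line(s); `NULL`/`NA` removes them. Default `5e-8`.
#' @param track Optional [genetrack()] for nearest-gene labels and
#'   `highlight_genes`.
#' @param annotate_with Label text source, `"gene"` (default on Manhattan
#'   plots) or `"id"`.
#' @param protein_coding_only Passed to nearest-gene annotation.
#' @param highlight_genes Gene symbols to mark on a strip at the bottom.
#' @param vline Vertical line position(s): `"chrom:pos"` strings, a data
#'   frame with chromosome/position columns, or bare numbers for
#'   single-chromosome data.
#' @param rsids,rsids_with_vline Variant identifiers to label (the latter
#'   also draws vertical lines through them).
#' @param color,shape,size,alpha Point aesthetics; length 1 or one per
#'   dataset.
#' @param shade_fill,shade_alpha Chromosome shade colour and transparency.
#' @param legend_position Legend position (`"none"` hides it); the legend
#'   is shown only when more than one dataset is plotted.
#' @param nudge_x,nudge_y,angle,fontface Label aesthetics; length 1 or
#'   one per dataset.
#' @param gap_frac Inter-chromosome gap fraction, see [genome_layout()].
#' @return A `plot_spec` (render with [render_plot_spec()] or use
#'   [manhattan()] directly).
#' @export
manhattan_spec <- function(data, ntop = NULL, annotate = NULL,
                           annotate_with_vline = NULL, region_size = 1e6,
                           sign_thresh = 5e-8, track = NULL,
                           annotate_with = "gene", protein_coding_only = TRUE,
                           highlight_genes = NULL, vline = NULL, rsids = NULL,
                           rsids_with_vline = NULL, color = NULL, shape = NULL,
                           size = NULL, alpha = NULL, shade_fill = "white",
                           shade_alpha = 0.5, legend_position = "right",
                           nudge_x = NULL, nudge_y = NULL, angle = NULL,
                           fontface = NULL, gap_frac = 0.003) {
  datasets <- as_dataset_list(data)
  n <- length(datasets)
  orientation <- split_ntop(n, ntop)
  series <- build_series(names(datasets), orientation, color, shape, size, alpha)
  layout <- genome_layout(datasets, gap_frac)
  xfun <- function(ch, pos) layout_x(layout, ch, pos)

  pts <- do.call(rbind, lapply(seq_len(n), function(i) {
    d <- datasets[[i]]
    sgn <- if (orientation[i] == "bottom") -1 else 1
    data.frame(dataset = names(datasets)[i],
               x = xfun(d$CHROM, d$POS), y = sgn * -log10(d$P),
               stringsAsFactors = FALSE)
  }))
  hlines <- build_hlines(sign_thresh)
  ymax <- max(abs(pts$y), hlines$y, 1)
  lb <- build_labels(datasets, series, annotate, annotate_with_vline,
                     rsids, rsids_with_vline, region_size, annotate_with,
                     track, protein_coding_only, xfun,
                     nudge_x, nudge_y, angle, fontface,
                     char_w = layout$total * 0.008, line_h = 0.05 * ymax)
  vl <- rbind(parse_positions(vline, layout$chroms), lb$vline_pos)
  vlines <- data.frame(CHROM = vl$CHROM, POS = vl$POS,
                       x = if (nrow(vl)) xfun(vl$CHROM, vl$POS) else numeric(0),
                       stringsAsFactors = FALSE)

  highlight <- data.frame(gene_name = character(0), xmin = numeric(0),
                          xmax = numeric(0), xmid = numeric(0),
                          stringsAsFactors = FALSE)
  if (!is.null(highlight_genes)) {
    if (is.null(track)) stop("highlight_genes needs a gene track", call. = FALSE)
    hl <- lapply(highlight_genes, function(gn) {
      g <- get_gene_coords(gn, track)
      data.frame(gene_name = gn, xmin = xfun(g$chrom, g$start),
                 xmax = xfun(g$chrom, g$end),
                 xmid = xfun(g$chrom, (g$start + g$end) / 2),
                 stringsAsFactors = FALSE)
    })
    highlight <- do.call(rbind, hl)
  }

  shades <- layout$shades
  shades$fill <- shade_fill
  shades$alpha <- shade_alpha

  new_plot_spec(
    "manhattan", panels = "main", series = series, points = pts,
    shades = shades, hlines = hlines, vlines = vlines, labels = lb$labels,
    highlight = highlight,
    axes = list(xticks = unname(layout$ticks), xlabels = layout$chroms,
                xlab = "Chromosome", ylab = "-log10(P)",
                mirrored = any(orientation == "bottom")),
    legend = list(show = n > 1 && !identical(legend_position, "none"),
                  position = legend_position),
    layout = list(chroms = layout$chroms, spans = unname(layout$spans),
                  offsets = unname(layout$offsets), gap = layout$gap,
                  total = layout$total)
  )
}

#' Compute a regional association plot specification
#'
#' Three stacked panels: an overview of the whole chromosome with a red
#' rectangle marking the displayed region (drawn no narrower than
#' `min_rect_frac` of the chromosome span so tiny regions remain
#' visible as a line), the main regional association panel, and a gene
#' panel. The region is given by gene name (padded by `gene_padding` on
#' each side), variant identifier (padded by `variant_flank`), or
#' explicit coordinates. The gene panel shows exon structure for regions
#' narrower than 1 Mb and whole-gene structure otherwise; `show_genes =
#' TRUE` forces gene-level display. The resolved region coordinates are
#' embedded in the spec (and printed on the rendered plot) so they can be
#' passed straight to [get_snps_within_region()].
#'
#' @inheritParams manhattan_spec
#' @inheritParams resolve_region
#' @param show_genes Force gene-level (`TRUE`) or exon-level (`FALSE`)
#'   structure in the gene panel; `NULL` (default) applies the 1 Mb rule.
#' @param min_rect_frac Minimum drawn width of the overview rectangle as
#'   a fraction of the chromosome span.
#' @return A `plot_spec` with `overview`, `main` and (given a track)
#'   `genes` panels.
#' @export
regionplot_spec <- function(data, track = NULL, gene = NULL, variant = NULL,
                            region = NULL, chrom = NULL, start = NULL,
                            end = NULL, gene_padding = 1e5,
                            variant_flank = 1e5, ntop = NULL, annotate = NULL,
                            annotate_with_vline = NULL, region_size = 1e6,
                            sign_thresh = 5e-8, annotate_with = "id",
                            protein_coding_only = TRUE, show_genes = NULL,
                            vline = NULL, rsids = NULL,
                            rsids_with_vline = NULL, color = NULL,
                            shape = NULL, size = NULL, alpha = NULL,
                            legend_position = "right", nudge_x = NULL,
                            nudge_y = NULL, angle = NULL, fontface = NULL,
                            min_rect_frac = 0.005) {
  datasets <- as_dataset_list(data)
  n <- length(datasets)
  reg <- resolve_region(data = datasets[[1]], track = track, gene = gene,
                        variant = variant, region = region, chrom = chrom,
                        start = start, end = end, gene_padding = gene_padding,
                        variant_flank = variant_flank)
  orientation <- split_ntop(n, ntop)
  series <- build_series(names(datasets), orientation, color, shape, size, alpha)

  regional <- lapply(datasets, get_snps_within_region, region = reg)
  pts <- do.call(rbind, lapply(seq_len(n), function(i) {
    d <- regional[[i]]
    sgn <- if (orientation[i] == "bottom") -1 else 1
    data.frame(dataset = names(datasets)[i], x = d$POS,
               y = sgn * -log10(d$P), stringsAsFactors = FALSE)
  }))

  # overview: the whole chromosome, always drawn upward
  chrom_rows <- lapply(datasets, function(d) d$POS[d$CHROM == reg$chrom])
  chrom_p <- lapply(datasets, function(d) d$P[d$CHROM == reg$chrom])
  ov_pts <- data.frame(x = unlist(chrom_rows),
                       y = -log10(unlist(chrom_p)))
  chrom_span <- max(unlist(chrom_rows), reg$end)
  rect <- c(reg$start, reg$end)
  min_w <- min_rect_frac * chrom_span
  if (diff(rect) < min_w) {
    mid <- mean(rect)
    rect <- c(mid - min_w / 2, mid + min_w / 2)
  }

  hlines <- build_hlines(sign_thresh)
  ymax <- max(abs(pts$y), hlines$y, 1, na.rm = TRUE)
  width <- reg$end - reg$start
  lb <- build_labels(regional, series, annotate, annotate_with_vline,
                     rsids, rsids_with_vline, region_size, annotate_with,
                     track, protein_coding_only,
                     xfun = function(ch, pos) pos,
                     nudge_x, nudge_y, angle, fontface,
                     char_w = width * 0.01, line_h = 0.05 * ymax)
  vl <- rbind(parse_positions(vline, reg$chrom), lb$vline_pos)
  vlines <- data.frame(CHROM = vl$CHROM, POS = vl$POS,
                       x = if (nrow(vl)) vl$POS else numeric(0),
                       stringsAsFactors = FALSE)

  panels <- c("overview", "main")
  genes <- NULL
  show_exons <- if (is.null(show_genes)) width < 1e6 else !isTRUE(show_genes)
  if (!is.null(track)) {
    genes <- gene_row_layout(track, reg, show_exons = show_exons,
                             protein_coding_only = FALSE)
    panels <- c(panels, "genes")
  }

  new_plot_spec(
    "region", panels = panels, series = series, points = pts,
    hlines = hlines, vlines = vlines, labels = lb$labels,
    region = list(chrom = reg$chrom, start = reg$start, end = reg$end,
                  label = format(reg), provenance = reg$provenance),
    overview = list(points = ov_pts, rect = rect, chrom_span = chrom_span),
    genes = genes, show_exons = show_exons,
    axes = list(xlab = sprintf("Position on chromosome %s", reg$chrom),
                ylab = "-log10(P)", xlim = c(reg$start, reg$end),
                mirrored = any(orientation == "bottom")),
    legend = list(show = n > 1 && !identical(legend_position, "none"),
                  position = legend_position)
  )
}

#' Compute a locuszoom-style plot specification
#'
#' A regional association plot whose points are coloured by the
#' pre-calculated variant correlation `r2` against an index variant
#' (binned into the conventional quintiles `[0,0.2)` ... `[0.8,1]`; a
#' variant with `r2 = 1`, when present, is drawn as the distinct index
#' marker), above the gene panel of [regionplot_spec()]. `r2` must be
#' supplied in the data — it is consumed, never computed, here.
#'
#' @inheritParams regionplot_spec
#' @param data A single dataset carrying an `R2` column. When no region
#'   is specified the span of the data (which must then sit on one
#'   chromosome) is used.
#' @return A `plot_spec` with `main` and (given a track) `genes` panels.
#' @export
locuszoom_spec <- function(data, track = NULL, gene = NULL, variant = NULL,
                           region = NULL, chrom = NULL, start = NULL,
                           end = NULL, gene_padding = 1e5,
                           variant_flank = 1e5, annotate = NULL,
                           region_size = 1e6, sign_thresh = 5e-8,
                           annotate_with = "id", protein_coding_only = TRUE,
                           show_genes = NULL, size = NULL, alpha = NULL,
                           nudge_x = NULL, nudge_y = NULL, angle = NULL,
                           fontface = NULL) {
  datasets <- as_dataset_list(data)
  if (length(datasets) > 1L) {
    stop("locuszoom displays a single dataset", call. = FALSE)
  }
  d <- datasets[[1]]
  if (is.null(d$R2)) {
    stop(paste("locuszoom needs a pre-calculated variant correlation (R2)",
               "column: compute r2 of one index variant against the rest",
               "and include it in the input"), call. = FALSE)
  }
  no_region <- is.null(gene) && is.null(variant) && is.null(region) &&
    is.null(chrom) && is.null(start) && is.null(end)
  reg <- if (no_region) {
    if (length(unique(d$CHROM)) != 1L) {
      stop("no region given and the data span several chromosomes", call. = FALSE)
    }
    region(d$CHROM[1], min(d$POS), max(d$POS), provenance = "literal")
  } else {
    resolve_region(data = d, track = track, gene = gene, variant = variant,
                   region = region, chrom = chrom, start = start, end = end,
                   gene_padding = gene_padding, variant_flank = variant_flank)
  }
  sub <- get_snps_within_region(d, reg)
  bin <- cut(sub$R2, breaks = R2_BREAKS, labels = R2_LABELS,
             right = FALSE, include.lowest = TRUE)
  pts <- data.frame(dataset = attr(d, "label"), x = sub$POS,
                    y = -log10(sub$P), r2 = sub$R2,
                    bin = as.character(bin),
                    index = !is.na(sub$R2) & sub$R2 == 1,
                    stringsAsFactors = FALSE)
  series <- build_series(attr(d, "label"), "top", NULL, NULL, size, alpha)
  hlines <- build_hlines(sign_thresh)
  ymax <- max(abs(pts$y), hlines$y, 1, na.rm = TRUE)
  width <- reg$end - reg$start
  lb <- build_labels(list(sub), series, annotate, NULL, NULL, NULL,
                     region_size, annotate_with, track, protein_coding_only,
                     xfun = function(ch, pos) pos,
                     nudge_x, nudge_y, angle, fontface,
                     char_w = width * 0.01, line_h = 0.05 * ymax)

  panels <- "main"
  genes <- NULL
  show_exons <- if (is.null(show_genes)) width < 1e6 else !isTRUE(show_genes)
  if (!is.null(track)) {
    genes <- gene_row_layout(track, reg, show_exons = show_exons,
                             protein_coding_only = FALSE)
    panels <- c(panels, "genes")
  }

  new_plot_spec(
    "locuszoom", panels = panels, series = series, points = pts,
    hlines = hlines,
    vlines = data.frame(CHROM = character(0), POS = numeric(0), x = numeric(0)),
    labels = lb$labels,
    region = list(chrom = reg$chrom, start = reg$start, end = reg$end,
                  label = format(reg), provenance = reg$provenance),
    genes = genes, show_exons = show_exons,
    r2 = list(breaks = R2_BREAKS, labels = R2_LABELS,
              colors = as.list(R2_COLORS)),
    axes = list(xlab = sprintf("Position on chromosome %s", reg$chrom),
                ylab = "-log10(P)", xlim = c(reg$start, reg$end),
                mirrored = FALSE),
    legend = list(show = TRUE, position = "right")
  )
}

#' Compute an effect-size comparison plot specification
#'
#' Scatter of harmonised effect sizes: dataset-1 lead-variant effects on
#' the x-axis against the matching dataset-2 effects on the y-axis, one
#' point per snpset row ([get_snpset()] is applied first when two
#' datasets are given). Points whose dataset-2 p-value is genome-wide
#' significant (`P2 < sign_thresh2`) are filled and labelled in black;
#' the rest are open circles with grey labels. An identity line and zero
#' axes are drawn.
#'
#' @inheritParams effect_table
#' @return A `plot_spec` of kind `"effect"`.
#' @export
effectplot_spec <- function(d1, d2 = NULL, track = NULL, thresh = 5e-8,
                            region_size = 1e6, sign_thresh2 = 5e-8) {
  lab1 <- if (is.null(d2)) "D1" else attr(ensure_gwas(d1, "D1"), "label") %||% "D1"
  lab2 <- if (is.null(d2)) "D2" else attr(ensure_gwas(d2, "D2"), "label") %||% "D2"
  tbl <- effect_table(d1, d2, track = track, thresh = thresh,
                      region_size = region_size, sign_thresh2 = sign_thresh2)
  pts <- data.frame(CHROM = tbl$CHROM, POS = tbl$POS,
                    x = tbl$E1, y = tbl$E2, filled = tbl$significant2,
                    stringsAsFactors = FALSE)
  labels <- data.frame(dataset = rep("snpset", nrow(tbl)),
                       CHROM = tbl$CHROM, POS = tbl$POS,
                       x = tbl$E1, y = tbl$E2,
                       text = ifelse(is.na(tbl$gene_label), "", tbl$gene_label),
                       fontface = rep("plain", nrow(tbl)),
                       angle = rep(0, nrow(tbl)),
                       color = ifelse(tbl$significant2, "black", "grey50"),
                       stringsAsFactors = FALSE)
  labels <- labels[nzchar(labels$text), , drop = FALSE]
  if (nrow(pts) > 0) {
    rng <- max(abs(c(pts$x, pts$y)), 0.1, na.rm = TRUE)
    if (nrow(labels) > 1) {
      labels <- repel_labels(labels, char_w = rng * 0.02, line_h = rng * 0.06)
    }
  }
  new_plot_spec(
    "effect", panels = "main", points = pts, labels = labels,
    identity_line = TRUE, zero_axes = TRUE,
    sign_thresh2 = sign_thresh2,
    axes = list(xlab = sprintf("Effect (%s)", lab1),
                ylab = sprintf("Effect (%s)", lab2), mirrored = FALSE),
    legend = list(show = FALSE, position = "none")
  )
}

#' Manhattan plot of one or more GWAS datasets
#'
#' Computes a [manhattan_spec()] and renders it with ggplot2. The spec is
#' attached to the result as the `"spec"` attribute.
#'
#' @inheritParams manhattan_spec
#' @return A ggplot object.
#' @export
manhattan <- function(data, ...) {
  spec <- manhattan_spec(data, ...)
  p <- render_plot_spec(spec)
  attr(p, "spec") <- spec
  p
}

#' Regional association plot (overview, association and gene panels)
#'
#' Computes a [regionplot_spec()] and renders the three stacked panels.
#'
#' @inheritParams regionplot_spec
#' @return A patchwork/ggplot object with the spec attached as the
#'   `"spec"` attribute.
#' @export
regionplot <- function(data, ...) {
  spec <- regionplot_spec(data, ...)
  p <- render_plot_spec(spec)
  attr(p, "spec") <- spec
  p
}

#' Locuszoom-style regional plot coloured by r2
#'
#' @inheritParams locuszoom_spec
#' @return A patchwork/ggplot object with the spec attached as the
#'   `"spec"` attribute.
#' @export
locuszoom <- function(data, ...) {
  spec <- locuszoom_spec(data, ...)
  p <- render_plot_spec(spec)
  attr(p, "spec") <- spec
  p
}

#' Effect-size comparison plot of two GWAS datasets
#'
#' @inheritParams effectplot_spec
#' @return A ggplot object with the spec attached as the `"spec"`
#'   attribute.
#' @export
effectplot <- function(d1, d2 = NULL, ...) {
  spec <- effectplot_spec(d1, d2, ...)
  p <- render_plot_spec(spec)
  attr(p, "spec") <- spec
  p
}

#' Retrieve the plot specification attached to a rendered plot
#'
#' @param p A plot returned by [manhattan()], [regionplot()],
#'   [locuszoom()] or [effectplot()].
#' @return The `plot_spec` object.
#' @export
get_plot_spec <- function(p) {
  spec <- attr(p, "spec")
  if (is.null(spec)) stop("no plot_spec attached to this object", call. = FALSE)
  spec
}

#' Save a plot to PNG, SVG or PDF
#'
#' The format is taken from the file extension.
#'
#' @param p A ggplot/patchwork object (or a `plot_spec`, rendered first).
#' @param path Output path ending in `.png`, `.svg` or `.pdf`.
#' @param width,height Figure size in inches.
#' @param dpi Resolution for raster output.
#' @return `path`, invisibly.
#' @export
save_plot <- function(p, path, width = 10, height = 5, dpi = 150) {
  if (inherits(p, "plot_spec")) p <- render_plot_spec(p)
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("png", "svg", "pdf")) {
    stop("unsupported figure format: .", ext, call. = FALSE)
  }
  ggplot2::ggsave(path, plot = p, width = width, height = height, dpi = dpi)
  invisible(path)
}
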