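# Declarative plot specifications.
#
# Every plot function first computes a renderer-independent description
# of the figure — point coordinates, chromosome shades, threshold lines,
# labels, axes, legend — as a `plot_spec` object. Rendering consumes only
# the spec, so layout logic is testable (and serialisable to JSON for
# golden-file comparison) without image diffing.

# fixed qualitative palette indexed by dataset order
GWASVIZ_PALETTE <- c("#E69F00", "#56B4E9", "#009E73", "#0072B2",
                     "#D55E00", "#CC79A7", "#F0E442", "#999999")

# locuszoom r2 bins: conventional quintiles, index variant drawn apart
R2_BREAKS <- c(0, 0.2, 0.4, 0.6, 0.8, 1)
R2_LABELS <- c("[0,0.2)", "[0.2,0.4)", "[0.4,0.6)", "[0.6,0.8)", "[0.8,1]")
R2_COLORS <- setNames(c("#2166AC", "#92C5DE", "#4DAF4A", "#FF7F00", "#E41A1C"),
                      R2_LABELS)

new_plot_spec <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "plot_spec")
}

#' @export
print.plot_spec <- function(x, ...) {
  cat(sprintf("<plot_spec> %s: %d panel(s), %d point(s), %d label(s)\n",
              x$kind, length(x$panels),
              if (is.null(x$points)) 0L else nrow(x$points),
              if (is.null(x$labels)) 0L else nrow(x$labels)))
  invisible(x)
}

#' Serialise a plot specification to JSON
#'
#' @param spec A `plot_spec`.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
spec_to_json <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "plot_spec"))
  x <- rapply(unclass(spec), unclass, how = "replace")
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, na = "null",
                           null = "null", dataframe = "columns")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

# per-dataset style table (one row per dataset; vectors recycled 1 -> n)
build_series <- function(labels, orientation, color, shape, size, alpha) {
  n <- length(labels)
  data.frame(
    dataset = labels,
    orientation = orientation,
    color = recycle_opt(color, n, "color") %||% GWASVIZ_PALETTE[(seq_len(n) - 1) %% length(GWASVIZ_PALETTE) + 1],
    shape = recycle_opt(shape, n, "shape") %||% rep(19, n),
    size = recycle_opt(size, n, "size") %||% rep(0.6, n),
    alpha = recycle_opt(alpha, n, "alpha") %||% rep(0.8, n),
    stringsAsFactors = FALSE
  )
}

# significance thresholds -> hline table; NULL/NA removes the line(s)
build_hlines <- function(sign_thresh) {
  st <- sign_thresh[!is.na(sign_thresh)]
  if (length(st) == 0L) {
    return(data.frame(p = numeric(0), y = numeric(0)))
  }
  if (any(st <= 0 | st > 1)) stop("sign_thresh must be p-values in (0, 1]", call. = FALSE)
  data.frame(p = st, y = -log10(st))
}

# Parse vertical-line positions: "chrom:pos" strings, a data frame with
# chromosome/position columns, or bare numbers (single-chromosome data).
parse_positions <- function(v, chroms) {
  if (is.null(v)) return(data.frame(CHROM = character(0), POS = numeric(0)))
  if (is.data.frame(v)) {
    lower <- tolower(names(v))
    ci <- which(lower %in% COLUMN_ALIASES$chrom)
    pi <- which(lower %in% COLUMN_ALIASES$pos)
    if (length(ci) != 1L || length(pi) != 1L) {
      stop("position table needs one chromosome and one position column",
           call. = FALSE)
    }
    return(data.frame(CHROM = canonicalise_chrom(v[[ci]]),
                      POS = as.numeric(v[[pi]]), stringsAsFactors = FALSE))
  }
  if (is.character(v)) {
    parts <- lapply(v, function(s) {
      clean <- gsub(",", "", trimws(s), fixed = TRUE)
      m <- regmatches(clean, regexec("^(chr)?([0-9XYMTxymt]+):([0-9]+)$", clean,
                                     ignore.case = TRUE))[[1]]
      if (length(m) == 0L) stop("malformed position '", s,
                                "' (expected \"chrom:pos\")", call. = FALSE)
      data.frame(CHROM = canonicalise_chrom(m[3]), POS = as.numeric(m[4]),
                 stringsAsFactors = FALSE)
    })
    return(do.call(rbind, parts))
  }
  if (is.numeric(v)) {
    if (length(chroms) != 1L) {
      stop("bare numeric positions are only unambiguous for single-chromosome data",
           call. = FALSE)
    }
    return(data.frame(CHROM = chroms, POS = as.numeric(v),
                      stringsAsFactors = FALSE))
  }
  stop("cannot interpret vline/position input", call. = FALSE)
}

# Assemble the label table for one plot: annotate(+vline) thresholds and
# rsids(+vline) requests, with per-dataset aesthetics and greedy repel.
build_labels <- function(datasets, series, annotate, annotate_with_vline,
                         rsids, rsids_with_vline, region_size, annotate_with,
                         track, protein_coding_only, xfun,
                         nudge_x, nudge_y, angle, fontface,
                         char_w, line_h) {
  n <- length(datasets)
  nudge_x <- recycle_opt(nudge_x, n, "nudge_x") %||% rep(0, n)
  nudge_y <- recycle_opt(nudge_y, n, "nudge_y") %||% rep(0, n)
  angle <- recycle_opt(angle, n, "angle") %||% rep(0, n)
  fontface <- recycle_opt(fontface, n, "fontface") %||% rep("plain", n)

  out <- list()
  vline_pos <- data.frame(CHROM = character(0), POS = numeric(0))
  add_rows <- function(rows, i, with_vline) {
    if (nrow(rows) == 0L) return()
    sgn <- if (series$orientation[i] == "bottom") -1 else 1
    out[[length(out) + 1]] <<- data.frame(
      dataset = series$dataset[i],
      CHROM = rows$CHROM, POS = rows$POS,
      x = xfun(rows$CHROM, rows$POS) + nudge_x[i],
      y = sgn * -log10(rows$P) + nudge_y[i] * sgn,
      text = rows$text, fontface = fontface[i], angle = angle[i],
      color = "black", stringsAsFactors = FALSE
    )
    if (with_vline) {
      vline_pos <<- rbind(vline_pos, rows[, c("CHROM", "POS")])
    }
  }
  for (pass in c("plain", "vline")) {
    ann <- if (pass == "plain") annotate else annotate_with_vline
    if (is.null(ann)) next
    labs <- select_labels(datasets, annotate = ann, region_size = region_size,
                          annotate_with = annotate_with, track = track,
                          protein_coding_only = protein_coding_only)
    for (i in seq_len(n)) add_rows(labs[[i]], i, pass == "vline")
  }
  for (pass in c("plain", "vline")) {
    ids <- if (pass == "plain") rsids else rsids_with_vline
    if (is.null(ids)) next
    for (i in seq_len(n)) {
      d <- datasets[[i]]
      if (is.null(d$ID)) next
      hit <- d[d$ID %in% ids, , drop = FALSE]
      if (nrow(hit) == 0L) next
      rows <- data.frame(CHROM = hit$CHROM, POS = hit$POS, P = hit$P,
                         text = hit$ID, stringsAsFactors = FALSE)
      add_rows(rows, i, pass == "vline")
    }
  }
  labels <- if (length(out)) do.call(rbind, out) else
    data.frame(dataset = character(0), CHROM = character(0), POS = numeric(0),
               x = numeric(0), y = numeric(0), text = character(0),
               fontface = character(0), angle = numeric(0),
               color = character(0), stringsAsFactors = FALSE)
  if (nrow(labels) > 1L) labels <- repel_labels(labels, char_w, line_h)
  rownames(labels) <- NULL
  list(labels = labels, vline_pos = unique(vline_pos))
}
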