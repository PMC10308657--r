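# Coordinate layout: cumulative genome x-axis, top/bottom orientation of
# multiple datasets, label selection, and gene-row packing for gene panels.

#' Cumulative genome coordinates for Manhattan plots
#'
#' Concatenates the chromosomes present in the data along a single x-axis.
#' Each chromosome's span is the largest observed position; its offset is
#' the sum of all preceding spans plus a fixed inter-chromosome gap
#' (`gap_frac` of the total genome span, 0.3% by default). A variant at
#' (CHROM, POS) is drawn at `offset(CHROM) + POS`, so identical
#' coordinates land on identical x in every dataset. Background shades
#' alternate per chromosome and one axis tick sits at each chromosome
#' midpoint.
#'
#' @param datasets A `gwas` dataset or list of them.
#' @param gap_frac Inter-chromosome gap as a fraction of total genome span.
#' @return A `genome_layout`: list with `chroms`, `spans`, `offsets`,
#'   `gap`, `ticks` (all named by chromosome), `total`, and a `shades`
#'   data frame (`chrom`, `xmin`, `xmax`, `shaded` alternation flag).
#' @export
genome_layout <- function(datasets, gap_frac = 0.003) {
  datasets <- as_dataset_list(datasets)
  all_chrom <- unlist(lapply(datasets, function(d) d$CHROM))
  if (length(all_chrom) == 0L) stop("no variants to lay out", call. = FALSE)
  chroms <- CHROM_LEVELS[CHROM_LEVELS %in% unique(all_chrom)]
  spans <- vapply(chroms, function(ch) {
    max(unlist(lapply(datasets, function(d) d$POS[d$CHROM == ch])), 0)
  }, numeric(1))
  gap <- gap_frac * sum(spans)
  offsets <- setNames(cumsum(c(0, head(spans, -1) + gap)), chroms)
  shades <- data.frame(chrom = chroms, xmin = offsets,
                       xmax = offsets + spans,
                       shaded = seq_along(chroms) %% 2 == 1,
                       stringsAsFactors = FALSE, row.names = NULL)
  structure(list(chroms = chroms, spans = spans, offsets = offsets,
                 gap = gap, ticks = offsets + spans / 2,
                 total = sum(spans) + gap * (length(chroms) - 1),
                 shades = shades),
            class = "genome_layout")
}

# x-coordinate of (chrom, pos) under a genome layout
layout_x <- function(layout, chrom, pos) {
  unname(layout$offsets[as.character(chrom)]) + pos
}

# Normalise plot input to a named list of gwas datasets; list names (or
# label attributes, or D1..Dn) become the dataset labels that drive
# legend entries, palette indexing and the ntop split.
as_dataset_list <- function(datasets) {
  if (is.data.frame(datasets)) datasets <- list(datasets)
  stopifnot(is.list(datasets), length(datasets) >= 1L)
  nm <- names(datasets) %||% rep("", length(datasets))
  out <- vector("list", length(datasets))
  for (i in seq_along(datasets)) {
    lbl <- if (nzchar(nm[i])) nm[i] else attr(datasets[[i]], "label") %||% paste0("D", i)
    out[[i]] <- ensure_gwas(datasets[[i]], label = lbl)
    attr(out[[i]], "label") <- lbl
  }
  labels <- vapply(out, function(d) attr(d, "label"), "")
  if (anyDuplicated(labels)) {
    stop("dataset labels must be unique: ", paste(labels, collapse = ", "),
         call. = FALSE)
  }
  names(out) <- labels
  out
}

#' Assign datasets to the top or mirrored bottom axis
#'
#' With several datasets on one plot the y-axis can be duplicated: the
#' first `ntop` datasets are drawn upwards on `-log10(P)` and the rest
#' downwards on a reversed axis. `ntop` equal to the number of datasets
#' (the default) gives the conventional single-axis overlapping display.
#'
#' @param n_datasets Number of datasets, or a list of datasets.
#' @param ntop How many datasets go on the top axis, `0 <= ntop <= n`.
#' @return Character vector of `"top"`/`"bottom"` per dataset.
#' @export
split_ntop <- function(n_datasets, ntop = NULL) {
  n <- if (is.list(n_datasets)) length(as_dataset_list(n_datasets)) else n_datasets
  stopifnot(is_scalar_number(n), n >= 1)
  ntop <- ntop %||% n
  if (!is_scalar_number(ntop) || ntop < 0 || ntop > n || ntop != round(ntop)) {
    stop(sprintf("ntop must be an integer in [0, %d]", n), call. = FALSE)
  }
  rep(c("top", "bottom"), c(ntop, n - ntop))
}

#' Select and name the variants to label on a plot
#'
#' Per dataset, the labelled variants are its lead variants at that
#' dataset's annotation threshold (`annotate` may be a single p-value or
#' one per dataset; unset means no labels). Label text comes from the
#' dataset's own gene column when present, otherwise the nearest gene
#' from `track` (`annotate_with = "gene"`, the Manhattan default) or the
#' variant identifier (`annotate_with = "id"`, the regional default),
#' falling back to `"chrom:pos"`.
#'
#' @param datasets A `gwas` dataset or list of them.
#' @param annotate P-value threshold(s) for labelling; length 1 or one
#'   per dataset; `NULL` disables labelling.
#' @param region_size Labelling-density window passed to
#'   [get_lead_snps()].
#' @param annotate_with `"gene"` or `"id"`.
#' @param track Optional [genetrack()] for nearest-gene label text.
#' @param protein_coding_only Passed to [nearest_gene()].
#' @return A list (one element per dataset) of data frames with columns
#'   `CHROM`, `POS`, `P`, `text`.
#' @export
select_labels <- function(datasets, annotate = NULL, region_size = 1e6,
                          annotate_with = c("gene", "id"), track = NULL,
                          protein_coding_only = TRUE) {
  datasets <- as_dataset_list(datasets)
  annotate_with <- match.arg(annotate_with)
  n <- length(datasets)
  empty <- data.frame(CHROM = character(0), POS = numeric(0), P = numeric(0),
                      text = character(0), stringsAsFactors = FALSE)
  if (is.null(annotate)) return(rep(list(empty), n))
  annotate <- recycle_opt(annotate, n, "annotate")
  out <- vector("list", n)
  for (i in seq_len(n)) {
    d <- datasets[[i]]
    if (is.na(annotate[i])) { out[[i]] <- empty; next }
    leads <- get_lead_snps(d, thresh = annotate[i], region_size = region_size)
    text <- rep(NA_character_, nrow(leads))
    if (!is.null(leads$GENE)) text <- leads$GENE
    fill <- is.na(text)
    if (any(fill)) {
      text[fill] <- label_text(leads[fill, , drop = FALSE], annotate_with,
                               track, protein_coding_only)
    }
    out[[i]] <- data.frame(CHROM = leads$CHROM, POS = leads$POS, P = leads$P,
                           text = text, stringsAsFactors = FALSE)
  }
  names(out) <- names(datasets)
  out
}

label_text <- function(rows, annotate_with, track, protein_coding_only) {
  fallback <- sprintf("%s:%.0f", rows$CHROM, rows$POS)
  if (annotate_with == "gene" && !is.null(track)) {
    txt <- annotate_with_nearest_gene(rows[, c("CHROM", "POS")], track,
                                      protein_coding_only)$Gene_Symbol
  } else if (!is.null(rows$ID)) {
    txt <- rows$ID
  } else {
    txt <- rep(NA_character_, nrow(rows))
  }
  ifelse(is.na(txt), fallback, txt)
}

#' Pack genes of a region into non-overlapping display rows
#'
#' Greedy interval packing: genes are sorted by their label-extended left
#' edge and each is placed on the first row where it does not overlap
#' (label extent included) anything already placed. Used for the gene
#' panel of regional plots.
#'
#' @param track A [genetrack()] object.
#' @param region A [region()] object.
#' @param show_exons Include per-gene exon boxes in the output.
#' @param protein_coding_only Restrict to protein-coding genes.
#' @param char_frac Approximate width of one label character as a
#'   fraction of the region width (label-collision estimate).
#' @return A `gene_row_layout` list: `genes` data frame (`gene_name`,
#'   `gene_start`, `gene_end`, `x_ext_start`, `x_ext_end`, `row`),
#'   `exons` data frame (`gene_name`, `row`, `start`, `end`), `n_rows`,
#'   and `show_exons`.
#' @export
gene_row_layout <- function(track, region, show_exons = TRUE,
                            protein_coding_only = FALSE, char_frac = 0.012) {
  stopifnot(inherits(track, "genetrack"), inherits(region, "region"))
  g <- candidate_genes(track, region$chrom, protein_coding_only)
  g <- g[g$gene_end >= region$start & g$gene_start <= region$end, , drop = FALSE]
  width <- region$end - region$start + 1
  empty <- list(genes = data.frame(gene_name = character(0),
                                   gene_start = numeric(0), gene_end = numeric(0),
                                   x_ext_start = numeric(0), x_ext_end = numeric(0),
                                   row = integer(0), stringsAsFactors = FALSE),
                exons = data.frame(gene_name = character(0), row = integer(0),
                                   start = numeric(0), end = numeric(0),
                                   stringsAsFactors = FALSE),
                n_rows = 0L, show_exons = show_exons)
  if (nrow(g) == 0L) return(structure(empty, class = "gene_row_layout"))
  mid <- (g$gene_start + g$gene_end) / 2
  half_label <- nchar(g$gene_name) * char_frac * width / 2
  ext_start <- pmin(g$gene_start, mid - half_label)
  ext_end <- pmax(g$gene_end, mid + half_label)
  o <- order(ext_start, ext_end, g$gene_name)
  g <- g[o, , drop = FALSE]
  ext_start <- ext_start[o]; ext_end <- ext_end[o]
  pad <- width / 200
  row_end <- numeric(0)      # rightmost occupied x per row
  row_idx <- integer(nrow(g))
  for (i in seq_len(nrow(g))) {
    fits <- which(row_end + pad < ext_start[i])
    r <- if (length(fits)) fits[1] else length(row_end) + 1L
    row_end[r] <- ext_end[i]
    row_idx[i] <- r
  }
  genes <- data.frame(gene_name = g$gene_name, gene_start = g$gene_start,
                      gene_end = g$gene_end, x_ext_start = ext_start,
                      x_ext_end = ext_end, row = row_idx,
                      stringsAsFactors = FALSE)
  exons <- empty$exons
  if (show_exons) {
    ex <- lapply(seq_len(nrow(g)), function(i) {
      if (length(g$exon_starts[[i]]) == 0L) return(NULL)
      data.frame(gene_name = g$gene_name[i], row = row_idx[i],
                 start = g$exon_starts[[i]], end = g$exon_ends[[i]],
                 stringsAsFactors = FALSE)
    })
    ex <- do.call(rbind, ex)
    if (!is.null(ex)) exons <- ex
  }
  structure(list(genes = genes, exons = exons, n_rows = max(row_idx),
                 show_exons = show_exons), class = "gene_row_layout")
}

# Greedy label repel in spec coordinates: labels are processed in x
# order; any label whose text box overlaps an already-placed box is
# pushed outward (up on the top axis, down on the mirrored axis) until
# free. User nudges are applied before collision resolution and are
# never undone.
repel_labels <- function(labels, char_w, line_h) {
  if (nrow(labels) <= 1L) return(labels)
  labels <- labels[order(labels$x), , drop = FALSE]
  half_w <- ifelse(labels$angle %% 180 == 90, char_w,
                   nchar(labels$text) * char_w / 2)
  placed <- matrix(numeric(0), ncol = 4)  # xmin, xmax, ymin, ymax
  for (i in seq_len(nrow(labels))) {
    dir <- if (labels$y[i] < 0) -1 else 1
    repeat {
      box <- c(labels$x[i] - half_w[i], labels$x[i] + half_w[i],
               labels$y[i] - line_h / 2, labels$y[i] + line_h / 2)
      clash <- nrow(placed) > 0 &&
        any(placed[, 1] < box[2] & placed[, 2] > box[1] &
              placed[, 3] < box[4] & placed[, 4] > box[3])
      if (!clash) break
      labels$y[i] <- labels$y[i] + dir * line_h
    }
    placed <- rbind(placed, c(labels$x[i] - half_w[i], labels$x[i] + half_w[i],
                              labels$y[i] - line_h / 2, labels$y[i] + line_h / 2))
  }
  labels
}
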