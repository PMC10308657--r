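# Gene/exon models and interval queries: overlap, nearest gene, coordinates.

#' Construct a gene track
#'
#' A gene track holds one gene model per row: symbol, chromosome, 1-based
#' inclusive span, biotype, and the gene's exon intervals. It backs
#' nearest-gene annotation, gene-based region resolution and the gene
#' panel of regional plots.
#'
#' @param genes Data frame with columns `chrom`, `gene_start`, `gene_end`,
#'   `gene_name`, `biotype`, and list columns `exon_starts`, `exon_ends`
#'   (integer vectors; may be empty). Exons must lie within the gene span;
#'   overlapping exons are merged.
#' @param build Genome build label (e.g. `"GRCh38"`, `"GRCh37"`, or a
#'   synthetic-track tag).
#' @return An object of class `genetrack`.
#' @export
genetrack <- function(genes, build = "GRCh38") {
  stopifnot(is.data.frame(genes))
  needed <- c("chrom", "gene_start", "gene_end", "gene_name", "biotype")
  miss <- setdiff(needed, names(genes))
  if (length(miss)) {
    stop("gene table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  genes$chrom <- canonicalise_chrom(genes$chrom)
  genes$gene_start <- as.numeric(genes$gene_start)
  genes$gene_end <- as.numeric(genes$gene_end)
  if (any(genes$gene_start > genes$gene_end)) {
    stop("gene_start > gene_end for some gene(s)", call. = FALSE)
  }
  if (is.null(genes$exon_starts)) genes$exon_starts <- replicate(nrow(genes), numeric(0), simplify = FALSE)
  if (is.null(genes$exon_ends)) genes$exon_ends <- replicate(nrow(genes), numeric(0), simplify = FALSE)
  for (i in seq_len(nrow(genes))) {
    es <- as.numeric(genes$exon_starts[[i]])
    ee <- as.numeric(genes$exon_ends[[i]])
    if (length(es) != length(ee)) {
      stop("exon start/end length mismatch for gene ", genes$gene_name[i],
           call. = FALSE)
    }
    if (length(es)) {
      if (any(es > ee) || min(es) < genes$gene_start[i] || max(ee) > genes$gene_end[i]) {
        stop("exons outside gene span for gene ", genes$gene_name[i],
             call. = FALSE)
      }
      m <- merge_intervals(es, ee)
      genes$exon_starts[[i]] <- m$start
      genes$exon_ends[[i]] <- m$end
    }
  }
  key <- paste(genes$chrom, genes$gene_start, genes$gene_name)
  if (anyDuplicated(key)) {
    stop("duplicate gene entries at identical (chrom, start)", call. = FALSE)
  }
  genes <- genes[order(chrom_rank(genes$chrom), genes$gene_start), , drop = FALSE]
  rownames(genes) <- NULL
  structure(list(build = build, genes = genes), class = "genetrack")
}

# Merge possibly-overlapping intervals into a disjoint sorted set.
merge_intervals <- function(start, end) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me + 1) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  list(start = c(out_s, ms), end = c(out_e, me))
}

#' @export
print.genetrack <- function(x, ...) {
  cat(sprintf("<genetrack> build %s: %d genes on %d chromosome(s)\n",
              x$build, nrow(x$genes), length(unique(x$genes$chrom))))
  invisible(x)
}

#' Read a gene track
#'
#' Two on-disk dialects are accepted. The native dialect is tab-delimited
#' with columns `build`, `chrom`, `gene_start`, `gene_end`, `gene_name`,
#' `biotype`, `exon_starts`, `exon_ends`, the last two comma-joined
#' coordinate lists (empty string for no exons). Files ending in `.gtf`
#' or `.gff` are imported via \pkg{rtracklayer} restricted to gene and
#' exon features, with `gene_name` (falling back to `gene_id`) as the
#' symbol.
#'
#' @param path Path to a gene-track file.
#' @return A [genetrack()] object.
#' @export
read_genetrack <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.(gtf|gff[23]?)$", path, ignore.case = TRUE)) {
    return(read_genetrack_gtf(path))
  }
  x <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                  check.names = FALSE, quote = "", comment.char = "",
                  colClasses = "character")
  split_coords <- function(s) {
    lapply(s, function(v) {
      if (is.na(v) || !nzchar(v)) numeric(0) else as.numeric(strsplit(v, ",", fixed = TRUE)[[1]])
    })
  }
  genes <- data.frame(chrom = x$chrom, gene_start = as.numeric(x$gene_start),
                      gene_end = as.numeric(x$gene_end), gene_name = x$gene_name,
                      biotype = x$biotype, stringsAsFactors = FALSE)
  genes$exon_starts <- split_coords(x$exon_starts)
  genes$exon_ends <- split_coords(x$exon_ends)
  genetrack(genes, build = unique(x$build)[1])
}

read_genetrack_gtf <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("reading GTF gene tracks requires the rtracklayer package",
         call. = FALSE)
  }
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  sym <- df$gene_name %||% df$gene_id
  if (is.null(sym)) stop("GTF lacks gene_name/gene_id attributes", call. = FALSE)
  sym[is.na(sym)] <- (df$gene_id %||% sym)[is.na(sym)]
  df$symbol <- sym
  g <- df[df$type == "gene", , drop = FALSE]
  e <- df[df$type == "exon", , drop = FALSE]
  genes <- data.frame(chrom = as.character(g$seqnames), gene_start = g$start,
                      gene_end = g$end, gene_name = g$symbol,
                      biotype = g$gene_biotype %||% rep("protein_coding", nrow(g)),
                      stringsAsFactors = FALSE)
  genes$exon_starts <- lapply(g$symbol, function(s) e$start[e$symbol == s])
  genes$exon_ends <- lapply(g$symbol, function(s) e$end[e$symbol == s])
  genetrack(genes, build = "GTF")
}

#' Write a gene track in the native tab-delimited dialect
#'
#' @param track A [genetrack()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genetrack <- function(track, path) {
  stopifnot(inherits(track, "genetrack"))
  g <- track$genes
  out <- data.frame(build = track$build, chrom = g$chrom,
                    gene_start = sprintf("%.0f", g$gene_start),
                    gene_end = sprintf("%.0f", g$gene_end),
                    gene_name = g$gene_name, biotype = g$biotype,
                    exon_starts = vapply(g$exon_starts, function(v) paste(sprintf("%.0f", v), collapse = ","), ""),
                    exon_ends = vapply(g$exon_ends, function(v) paste(sprintf("%.0f", v), collapse = ","), ""),
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Candidate genes on one chromosome, optionally restricted to
# protein_coding (the default: annotation should label peaks with
# familiar coding symbols, not every non-coding entry in the track).
candidate_genes <- function(track, chrom, protein_coding_only = TRUE) {
  g <- track$genes
  g <- g[g$chrom == canonicalise_chrom(chrom), , drop = FALSE]
  if (protein_coding_only) g <- g[g$biotype == "protein_coding", , drop = FALSE]
  g
}

#' Find the overlapping or nearest gene for a genomic position
#'
#' If `pos` falls within a gene span the distance is 0; when it falls in
#' several overlapping genes the one with the smallest span wins (most
#' specific), ties broken alphabetically. Otherwise the gene minimising
#' the distance to its nearer boundary is returned, equidistant ties
#' broken alphabetically. Distance is unstranded base pairs to the nearer
#' gene boundary, signed positive when the position lies right of the
#' gene and negative when left of it.
#'
#' @param chrom Chromosome label.
#' @param pos 1-based base-pair position.
#' @param track A [genetrack()] object.
#' @param protein_coding_only Restrict candidates to protein-coding genes
#'   (default `TRUE`); set `FALSE` to consider every biotype in the track.
#' @return A list with `gene_name` and `distance`; both `NA` when the
#'   chromosome carries no candidate gene.
#' @export
nearest_gene <- function(chrom, pos, track, protein_coding_only = TRUE) {
  stopifnot(inherits(track, "genetrack"), is_scalar_number(pos))
  g <- candidate_genes(track, chrom, protein_coding_only)
  if (nrow(g) == 0L) return(list(gene_name = NA_character_, distance = NA_real_))
  inside <- g$gene_start <= pos & pos <= g$gene_end
  if (any(inside)) {
    gi <- g[inside, , drop = FALSE]
    span <- gi$gene_end - gi$gene_start
    gi <- gi[order(span, gi$gene_name), , drop = FALSE]
    return(list(gene_name = gi$gene_name[1], distance = 0))
  }
  d <- pmin(abs(pos - g$gene_start), abs(pos - g$gene_end))
  g <- g[order(d, g$gene_name), , drop = FALSE]
  dmin <- sort(d)[1]
  signed <- if (pos > g$gene_end[1]) dmin else -dmin
  list(gene_name = g$gene_name[1], distance = signed)
}

#' Annotate a table of genomic positions with the nearest gene
#'
#' Takes any data frame carrying recognisable chromosome and position
#' columns and appends a `Gene_Symbol` column holding the overlapping or
#' nearest gene per row ([nearest_gene()] semantics). Row count and order
#' are preserved; rows on chromosomes absent from the track get `NA`.
#'
#' @param variants Data frame with chromosome and position columns (any
#'   recognised alias, case-insensitive).
#' @param track A [genetrack()] object.
#' @param protein_coding_only Passed to [nearest_gene()].
#' @return `variants` with a `Gene_Symbol` column appended.
#' @export
annotate_with_nearest_gene <- function(variants, track, protein_coding_only = TRUE) {
  stopifnot(is.data.frame(variants), inherits(track, "genetrack"))
  lower <- tolower(names(variants))
  ci <- which(lower %in% COLUMN_ALIASES$chrom)
  pi <- which(lower %in% COLUMN_ALIASES$pos)
  if (length(ci) != 1L || length(pi) != 1L) {
    stop("input must have exactly one chromosome and one position column",
         call. = FALSE)
  }
  n <- nrow(variants)
  sym <- character(n)
  if (n > 0) {
    chrom <- canonicalise_chrom(variants[[ci]])
    pos <- as.numeric(variants[[pi]])
    for (i in seq_len(n)) {
      sym[i] <- nearest_gene(chrom[i], pos[i], track, protein_coding_only)$gene_name
    }
  }
  variants$Gene_Symbol <- if (n > 0) sym else character(0)
  variants
}

#' Look up the genomic coordinates of a gene
#'
#' Symbol matching is case-insensitive. Unknown symbols raise an error
#' that lists close matches from the track, when any exist.
#'
#' @param gene_name Gene symbol.
#' @param track A [genetrack()] object.
#' @return A [region()] covering the gene span, with provenance `"gene"`.
#' @export
get_gene_coords <- function(gene_name, track) {
  stopifnot(inherits(track, "genetrack"), is.character(gene_name),
            length(gene_name) == 1L)
  g <- track$genes
  hit <- which(toupper(g$gene_name) == toupper(gene_name))
  if (length(hit) == 0L) {
    near <- unique(agrep(gene_name, g$gene_name, ignore.case = TRUE,
                         max.distance = 0.25, value = TRUE))
    hint <- if (length(near)) paste0("; did you mean ",
                                     paste(sQuote(head(near, 5)), collapse = ", "), "?") else ""
    stop(sprintf("gene '%s' not found in %s track%s", gene_name, track$build, hint),
         call. = FALSE)
  }
  if (length(hit) > 1L) {
    warning(sprintf("gene '%s' has %d entries; using the first by position",
                    gene_name, length(hit)), call. = FALSE)
    hit <- hit[1]
  }
  region(g$chrom[hit], g$gene_start[hit], g$gene_end[hit], provenance = "gene")
}
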