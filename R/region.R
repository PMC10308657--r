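# Genomic regions, lead-variant selection and regional extraction.

#' Construct a genomic region
#'
#' @param chrom Chromosome label (canonicalised).
#' @param start,end 1-based inclusive bounds, `start <= end`, `start >= 1`.
#' @param provenance How the region was obtained: `"gene"`, `"variant"` or
#'   `"literal"`.
#' @return An object of class `region`.
#' @export
region <- function(chrom, start, end, provenance = "literal") {
  chrom <- canonicalise_chrom(chrom)
  start <- as.numeric(start); end <- as.numeric(end)
  if (!chrom %in% CHROM_LEVELS) stop("unrecognised chromosome: ", chrom, call. = FALSE)
  if (!is_scalar_number(start) || !is_scalar_number(end)) {
    stop("region bounds must be finite numbers", call. = FALSE)
  }
  if (start < 1) stop("region start must be >= 1", call. = FALSE)
  if (start > end) stop("region start exceeds end", call. = FALSE)
  provenance <- match.arg(provenance, c("gene", "variant", "literal"))
  structure(list(chrom = chrom, start = start, end = end,
                 provenance = provenance), class = "region")
}

#' @export
format.region <- function(x, ...) {
  sprintf("%s:%.0f-%.0f", x$chrom, x$start, x$end)
}

#' @export
print.region <- function(x, ...) {
  cat(sprintf("<region> %s (%.0f bp, from %s)\n", format(x),
              x$end - x$start + 1, x$provenance))
  invisible(x)
}

# Parse "chrom:start-end"; tolerates a "chr" prefix and thousands
# separators ("chr1:1,000-2,000").
parse_region_string <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  clean <- gsub(",", "", trimws(s), fixed = TRUE)
  m <- regmatches(clean, regexec("^(chr)?([0-9XYMTxymt]+):([0-9]+)-([0-9]+)$",
                                 clean, ignore.case = TRUE))[[1]]
  if (length(m) == 0L) {
    stop(sprintf("malformed region string '%s' (expected \"chrom:start-end\")", s),
         call. = FALSE)
  }
  region(m[3], as.numeric(m[4]), as.numeric(m[5]), provenance = "literal")
}

#' Resolve a display region from a gene, variant or coordinates
#'
#' Exactly one of `gene`, `variant`, `region`, or the `chrom`/`start`/`end`
#' triple must be supplied. A gene region spans the gene plus
#' `gene_padding` base pairs on each side (default 100 kb), clipped at
#' position 1. A variant region spans the variant's position plus
#' `variant_flank` on each side. Literal forms are parsed verbatim; the
#' string dialect is `"chrom:start-end"` with optional `chr` prefix and
#' thousands separators.
#'
#' @param data A `gwas` dataset; required for the variant form.
#' @param track A [genetrack()]; required for the gene form.
#' @param gene Gene symbol.
#' @param variant Variant identifier present in `data$ID`.
#' @param region Region string or a ready-made [region()] object.
#' @param chrom,start,end Literal coordinate triple.
#' @param gene_padding Flank added to each side of a gene span, in bp.
#' @param variant_flank Flank added to each side of a variant position.
#' @return A [region()] with provenance recording the spec form used.
#' @export
resolve_region <- function(data = NULL, track = NULL, gene = NULL,
                           variant = NULL, region = NULL,
                           chrom = NULL, start = NULL, end = NULL,
                           gene_padding = 1e5, variant_flank = 1e5) {
  forms <- c(gene = !is.null(gene), variant = !is.null(variant),
             region = !is.null(region),
             coords = !is.null(chrom) || !is.null(start) || !is.null(end))
  if (sum(forms) != 1L) {
    stop("supply exactly one of gene, variant, region, or chrom/start/end",
         call. = FALSE)
  }
  if (forms[["gene"]]) {
    if (is.null(track)) stop("gene-based regions need a gene track", call. = FALSE)
    g <- get_gene_coords(gene, track)
    return(structure(list(chrom = g$chrom,
                          start = max(1, g$start - gene_padding),
                          end = g$end + gene_padding,
                          provenance = "gene"), class = "region"))
  }
  if (forms[["variant"]]) {
    if (is.null(data)) stop("variant-based regions need a dataset", call. = FALSE)
    data <- ensure_gwas(data)
    if (is.null(data$ID)) stop("dataset has no variant ID column", call. = FALSE)
    hit <- which(data$ID == variant)
    if (length(hit) == 0L) {
      stop(sprintf("variant '%s' not found in dataset '%s'", variant,
                   attr(data, "label")), call. = FALSE)
    }
    pos <- data$POS[hit[1]]
    return(structure(list(chrom = data$CHROM[hit[1]],
                          start = max(1, pos - variant_flank),
                          end = pos + variant_flank,
                          provenance = "variant"), class = "region"))
  }
  if (forms[["region"]]) {
    if (inherits(region, "region")) return(region)
    return(parse_region_string(region))
  }
  if (is.null(chrom) || is.null(start) || is.null(end)) {
    stop("coordinate regions need all of chrom, start and end", call. = FALSE)
  }
  region(chrom, start, end, provenance = "literal")
}

#' Extract lead (index) variants per genomic window
#'
#' Greedy windowed selection of association peaks: on each chromosome the
#' unexcluded variant with the smallest p-value below `thresh` is taken as
#' a lead, then every variant closer than `region_size / 2` bp on either
#' side is excluded (a window of total width `region_size` centred on the
#' lead), and the step repeats until no candidate remains. This yields one
#' lead per peak rather than one per fixed genome bin, so peaks straddling
#' bin edges are never split or double-labelled.
#'
#' Ties in p-value are broken towards the smaller position; the exclusion
#' boundary is strict, so a variant at exactly `region_size / 2` bp from a
#' lead remains eligible.
#'
#' @param data A `gwas` dataset (or anything [as_gwas()] accepts).
#' @param thresh Genome-wide significance threshold on the p-value scale;
#'   only variants with `P < thresh` are eligible. Default `5e-8`.
#' @param region_size Total width of the exclusion window in bp, default
#'   1 Mb.
#' @return The selected rows, sorted by (chromosome rank, position), with
#'   a `window_rank` column giving the selection order (1 = most
#'   significant) within each chromosome.
#' @export
get_lead_snps <- function(data, thresh = 5e-8, region_size = 1e6) {
  data <- ensure_gwas(data)
  if (!is_scalar_number(thresh) || thresh <= 0 || thresh > 1) {
    stop("thresh must be a p-value in (0, 1]", call. = FALSE)
  }
  if (!is_scalar_number(region_size) || region_size <= 0) {
    stop("region_size must be a positive number of base pairs", call. = FALSE)
  }
  half <- region_size / 2
  picked <- integer(0)
  ranks <- integer(0)
  for (chr in unique(data$CHROM)) {
    idx <- which(data$CHROM == chr & data$P < thresh)
    if (length(idx) == 0L) next
    ord <- idx[order(data$P[idx], data$POS[idx])]
    r <- 0L
    while (length(ord) > 0L) {
      lead <- ord[1]
      r <- r + 1L
      picked <- c(picked, lead)
      ranks <- c(ranks, r)
      ord <- ord[abs(data$POS[ord] - data$POS[lead]) >= half]
    }
  }
  out <- as.data.frame(data)[picked, , drop = FALSE]
  out$window_rank <- ranks
  out <- out[order(chrom_rank(out$CHROM), out$POS), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "label") <- attr(data, "label")
  out
}

#' Extract the variants inside a region
#'
#' Returns exactly the rows with `CHROM` equal to the region's chromosome
#' and `start <= POS <= end`, preserving input row order — convenient for
#' pulling out the variants displayed on a regional plot, whose
#' coordinates are printed on the plot itself.
#'
#' @param data A `gwas` dataset.
#' @param region A [region()] or a `"chrom:start-end"` string.
#' @return The matching subset of `data`.
#' @export
get_snps_within_region <- function(data, region) {
  data <- ensure_gwas(data)
  if (is.character(region)) region <- parse_region_string(region)
  stopifnot(inherits(region, "region"))
  keep <- data$CHROM == region$chrom &
    data$POS >= region$start & data$POS <= region$end
  out <- as.data.frame(data)[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "label") <- attr(data, "label")
  out
}
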