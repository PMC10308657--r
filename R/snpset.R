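# Cross-dataset variant matching, allele harmonisation and effect flipping.
#
# A snpset compares the lead variants of a first dataset (D1) with the
# corresponding variants of a second (D2) in four steps:
#   1. extract the lead variants of D1 (get_lead_snps);
#   2. pair them with D2 rows sharing (CHROM, POS) (match_by_pos);
#   3. reconcile REF/ALT alleles, flipping D2's effect when the allele
#      designation is swapped between the datasets (match_by_alleles);
#   4. orient every row so D1's effect is non-negative
#      (flip_to_positive_allele_for_dat1).
# Odds ratios are converted to log-scale betas before any comparison.

#' Convert odds ratios to beta estimates
#'
#' The natural logarithm of the odds ratio, the effect size on the scale
#' used for cross-dataset comparison. NA values pass through.
#'
#' @param or_value Numeric vector of odds ratios, all `> 0`.
#' @return `log(or_value)`.
#' @export
or_to_beta <- function(or_value) {
  if (!is.numeric(or_value)) stop("odds ratios must be numeric", call. = FALSE)
  if (any(!is.na(or_value) & or_value <= 0)) {
    stop("odds ratios must be positive", call. = FALSE)
  }
  log(or_value)
}

# Effect sizes on the beta scale for a canonical dataset; BETA wins over
# OR (OR has already been dropped at validation when both were supplied).
effect_beta <- function(data, who = "dataset") {
  if (!is.null(data$BETA)) return(data$BETA)
  if (!is.null(data$OR)) return(or_to_beta(data$OR))
  stop(sprintf("%s carries neither a BETA nor an OR column", who), call. = FALSE)
}

check_snpset_columns <- function(data, who) {
  miss <- setdiff(c("REF", "ALT"), names(data))
  if (length(miss)) {
    stop(sprintf("%s lacks allele column(s): %s", who,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (is.null(data$BETA) && is.null(data$OR)) {
    stop(sprintf("%s lacks an effect column (BETA or OR)", who), call. = FALSE)
  }
  invisible(TRUE)
}

#' Pair dataset-1 lead variants with dataset-2 rows by position
#'
#' Every D1 lead is joined with all D2 rows sharing (CHROM, POS); leads
#' with no positional partner go to `not_found` with their original
#' columns untouched. The two outputs partition the input leads exactly.
#'
#' @param d1_leads Lead variants of the first dataset (rows of a `gwas`
#'   table, e.g. from [get_lead_snps()]), carrying REF/ALT and BETA or OR.
#' @param d2 The second dataset.
#' @return A list with `matched` (paired rows: D1 columns CHROM, POS, ID,
#'   GENE, REF1, ALT1, P1, E1 and D2 columns REF2, ALT2, P2, E2) and
#'   `not_found` (unpaired D1 rows).
#' @export
match_by_pos <- function(d1_leads, d2) {
  d2 <- ensure_gwas(d2, label = "D2")
  stopifnot(is.data.frame(d1_leads))
  check_snpset_columns(d1_leads, "dataset 1")
  check_snpset_columns(d2, "dataset 2")
  e1 <- effect_beta(d1_leads, "dataset 1")
  e2 <- effect_beta(d2, "dataset 2")
  key1 <- paste(d1_leads$CHROM, d1_leads$POS)
  key2 <- paste(d2$CHROM, d2$POS)

  rows <- vector("list", nrow(d1_leads))
  found <- logical(nrow(d1_leads))
  for (i in seq_len(nrow(d1_leads))) {
    js <- which(key2 == key1[i])
    if (length(js) == 0L) next
    found[i] <- TRUE
    rows[[i]] <- data.frame(
      .d1row = i,
      CHROM = d1_leads$CHROM[i], POS = d1_leads$POS[i],
      ID = if (is.null(d1_leads$ID)) NA_character_ else d1_leads$ID[i],
      GENE = if (is.null(d1_leads$GENE)) NA_character_ else d1_leads$GENE[i],
      REF1 = d1_leads$REF[i], ALT1 = d1_leads$ALT[i],
      P1 = d1_leads$P[i], E1 = e1[i],
      REF2 = d2$REF[js], ALT2 = d2$ALT[js],
      P2 = d2$P[js], E2 = e2[js],
      stringsAsFactors = FALSE
    )
  }
  matched <- do.call(rbind, rows[found])
  if (is.null(matched)) matched <- empty_pair_frame()
  not_found <- as.data.frame(d1_leads)[!found, , drop = FALSE]
  rownames(not_found) <- NULL
  list(matched = matched, not_found = not_found)
}

empty_pair_frame <- function() {
  data.frame(.d1row = integer(0), CHROM = character(0), POS = numeric(0),
             ID = character(0), GENE = character(0),
             REF1 = character(0), ALT1 = character(0),
             P1 = numeric(0), E1 = numeric(0),
             REF2 = character(0), ALT2 = character(0),
             P2 = numeric(0), E2 = numeric(0), stringsAsFactors = FALSE)
}

#' Reconcile alleles between positionally matched variant pairs
#'
#' A pair is kept when the allele designations agree exactly
#' (`REF1 == REF2` and `ALT1 == ALT2`), or when they are swapped
#' (`REF1 == ALT2` and `ALT1 == REF2`), in which case the D2 effect sign
#' is flipped and its alleles swapped so both datasets report the same
#' effect allele. Any other combination cannot be reconciled and is
#' routed to `no_allele_match`. Matching is by literal allele identity
#' only — no reverse-complement rescue is attempted, since silent strand
#' flips of ambiguous A/T and C/G pairs are a classic source of
#' undetected sign errors.
#'
#' When several D2 rows at one position harmonise with the same D1 lead
#' (duplicate rows), the first in position-sorted order is kept with a
#' warning.
#'
#' @param pairs Positionally matched pairs from [match_by_pos()].
#' @return A list with `matched` (harmonised pairs) and `no_allele_match`
#'   (one row per irreconcilable D1 lead).
#' @export
match_by_alleles <- function(pairs) {
  stopifnot(is.data.frame(pairs))
  need <- c("REF1", "ALT1", "REF2", "ALT2", "E2")
  miss <- setdiff(need, names(pairs))
  if (length(miss)) {
    stop("pairs lack allele/effect column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(pairs$REF1) | is.na(pairs$ALT1) | is.na(pairs$REF2) | is.na(pairs$ALT2))) {
    stop("missing allele values in matched pairs", call. = FALSE)
  }
  grp <- if (".d1row" %in% names(pairs)) pairs$.d1row else seq_len(nrow(pairs))

  exact <- pairs$REF1 == pairs$REF2 & pairs$ALT1 == pairs$ALT2
  swapped <- !exact & pairs$REF1 == pairs$ALT2 & pairs$ALT1 == pairs$REF2
  ok <- exact | swapped

  harm <- pairs[ok, , drop = FALSE]
  sw <- swapped[ok]
  if (any(sw)) {
    harm$E2[sw] <- -harm$E2[sw]
    tmp <- harm$REF2[sw]
    harm$REF2[sw] <- harm$ALT2[sw]
    harm$ALT2[sw] <- tmp
  }
  # one harmonised partner per D1 lead: first in position-sorted order
  hg <- grp[ok]
  if (anyDuplicated(hg)) {
    warning("multiple harmonisable rows at one position; keeping the first",
            call. = FALSE)
    keep <- !duplicated(hg)
    harm <- harm[keep, , drop = FALSE]
    hg <- hg[keep]
  }
  bad_grp <- setdiff(unique(grp), hg)
  nam <- pairs[!ok & grp %in% bad_grp, , drop = FALSE]
  nam <- nam[!duplicated(grp[!ok & grp %in% bad_grp]), , drop = FALSE]
  rownames(harm) <- rownames(nam) <- NULL
  list(matched = harm, no_allele_match = nam)
}

#' Orient harmonised pairs to the positive dataset-1 allele
#'
#' Rows with a negative D1 effect have both effects negated and the
#' REF/ALT designation swapped in both datasets, keeping the pair
#' harmonised while reporting every effect for the allele that increases
#' the trait in dataset 1. Non-negative rows (including exact zero) are
#' untouched. Applying the transform twice is the identity.
#'
#' @param rows Harmonised pairs from [match_by_alleles()].
#' @return `rows` with `E1 >= 0` everywhere.
#' @export
flip_to_positive_allele_for_dat1 <- function(rows) {
  stopifnot(is.data.frame(rows))
  if (nrow(rows) == 0L) return(rows)
  neg <- !is.na(rows$E1) & rows$E1 < 0
  if (any(neg)) {
    rows$E1[neg] <- -rows$E1[neg]
    rows$E2[neg] <- -rows$E2[neg]
    tmp <- rows$REF1[neg]; rows$REF1[neg] <- rows$ALT1[neg]; rows$ALT1[neg] <- tmp
    tmp <- rows$REF2[neg]; rows$REF2[neg] <- rows$ALT2[neg]; rows$ALT2[neg] <- tmp
  }
  rows
}

#' Build a snpset: matched, harmonised, positively oriented variant pairs
#'
#' Composes the four-step pipeline (lead extraction on D1, positional
#' matching against D2, allele harmonisation with effect flipping,
#' orientation to D1's positive allele). Odds ratios are converted to
#' betas beforehand. The three partitions — matched pairs, D1 leads with
#' no positional partner, and positionally matched but allele-
#' irreconcilable leads — always account for every D1 lead exactly once.
#'
#' @param d1,d2 Datasets carrying REF, ALT and BETA or OR columns.
#' @param thresh,region_size Lead-selection parameters for D1, see
#'   [get_lead_snps()].
#' @param verbose If `TRUE`, return all three partitions as a
#'   `snpset_report`; otherwise return the snpset table alone.
#' @return A data frame with columns CHROM, POS, ID, GENE, P1, E1, ALT1,
#'   REF1, P2, E2, ALT2, REF2 (the snpset), or a `snpset_report` list
#'   with elements `snpset`, `not_found` and `no_allele_match`.
#' @export
get_snpset <- function(d1, d2, thresh = 5e-8, region_size = 1e6,
                       verbose = FALSE) {
  d1 <- ensure_gwas(d1, label = "D1")
  d2 <- ensure_gwas(d2, label = "D2")
  check_snpset_columns(d1, "dataset 1")
  check_snpset_columns(d2, "dataset 2")
  leads <- get_lead_snps(d1, thresh = thresh, region_size = region_size)
  mp <- match_by_pos(leads, d2)
  ma <- match_by_alleles(mp$matched)
  snpset <- flip_to_positive_allele_for_dat1(ma$matched)
  snpset <- snpset[order(chrom_rank(snpset$CHROM), snpset$POS), , drop = FALSE]
  snpset$.d1row <- NULL
  cols <- c("CHROM", "POS", "ID", "GENE",
            "P1", "E1", "ALT1", "REF1", "P2", "E2", "ALT2", "REF2")
  snpset <- snpset[, cols, drop = FALSE]
  rownames(snpset) <- NULL
  nam <- ma$no_allele_match
  nam$.d1row <- NULL
  if (!verbose) return(snpset)
  structure(list(snpset = snpset, not_found = mp$not_found,
                 no_allele_match = nam, n_leads = nrow(leads)),
            class = "snpset_report")
}

#' @export
print.snpset_report <- function(x, ...) {
  cat(sprintf(paste0("<snpset_report> %d lead variant(s): %d matched, ",
                     "%d not found by position, %d with irreconcilable alleles\n"),
              x$n_leads, nrow(x$snpset), nrow(x$not_found),
              nrow(x$no_allele_match)))
  invisible(x)
}

#' Effect-comparison table for two datasets or a ready-made snpset
#'
#' The table consumed by [effectplot()]: one row per snpset entry with a
#' gene label (the dataset's own gene column when present, otherwise the
#' nearest gene from `track`, otherwise `NA`) and a logical
#' `significant2` flag marking rows whose dataset-2 p-value is below
#' `sign_thresh2` (genome-wide significance, `5e-8`, by default).
#'
#' @param d1 First dataset, or an existing snpset table (then `d2` is
#'   omitted).
#' @param d2 Second dataset.
#' @param track Optional [genetrack()] used to fill missing gene labels.
#' @param thresh,region_size Passed to [get_snpset()] when two datasets
#'   are given.
#' @param sign_thresh2 Significance threshold applied to `P2`.
#' @return The snpset with `gene_label` and `significant2` columns.
#' @export
effect_table <- function(d1, d2 = NULL, track = NULL, thresh = 5e-8,
                         region_size = 1e6, sign_thresh2 = 5e-8) {
  snpset <- if (is.null(d2)) {
    need <- c("CHROM", "POS", "P1", "E1", "ALT1", "REF1", "P2", "E2", "ALT2", "REF2")
    miss <- setdiff(need, names(d1))
    if (length(miss)) {
      stop("snpset input lacks column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    as.data.frame(d1)
  } else {
    get_snpset(d1, d2, thresh = thresh, region_size = region_size)
  }
  gene <- if (!is.null(snpset$GENE)) snpset$GENE else rep(NA_character_, nrow(snpset))
  if (!is.null(track) && nrow(snpset) > 0) {
    fill <- is.na(gene)
    if (any(fill)) {
      ann <- annotate_with_nearest_gene(snpset[fill, c("CHROM", "POS")], track)
      gene[fill] <- ann$Gene_Symbol
    }
  }
  snpset$gene_label <- gene
  snpset$significant2 <- !is.na(snpset$P2) & snpset$P2 < sign_thresh2
  snpset
}

#' Write a snpset table as TSV
#'
#' @param snpset A snpset table from [get_snpset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_snpset <- function(snpset, path) {
  write.table(as.data.frame(snpset), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
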