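# Reading, validating and canonicalising GWAS summary-statistics tables.
#
# Canonical column roles after validation:
#   CHROM  chromosome label, no "chr" prefix, one of 1-22, X, Y, MT
#   POS    1-based base-pair position
#   P      association p-value in (0, 1]
#   ID     optional variant identifier (rsid)
#   REF    optional reference allele
#   ALT    optional alternative allele
#   BETA   optional effect size on the log scale
#   OR     optional odds ratio (dropped with a warning when BETA is present)
#   R2     optional variant correlation in [0, 1]
#   GENE   optional gene symbol used verbatim for labelling

# role -> accepted (case-insensitive) column-name aliases
COLUMN_ALIASES <- list(
  chrom = c("chr", "chrom", "chromosome"),
  pos   = c("pos", "bp", "base_pair_location", "position"),
  p     = c("p", "pval", "p_value", "pvalue"),
  id    = c("id", "rsid", "snp", "variant_id"),
  ref   = c("ref", "reference"),
  alt   = c("alt", "alternative"),
  beta  = c("beta"),
  or    = c("or", "odds_ratio"),
  r2    = c("r2", "rsq"),
  gene  = c("gene", "gene_symbol", "gene_name")
)

#' Resolve summary-statistics column roles from a header
#'
#' Maps flexibly named columns onto canonical roles, case-insensitively.
#' The chromosome column may be called `chr`, `chrom` or `chromosome` (any
#' case), position `pos`/`bp`/`base_pair_location`/`position`, p-value
#' `p`/`pval`/`p_value`/`pvalue`, and so on for the optional roles (variant
#' ID, REF/ALT alleles, BETA or OR effect, r-squared, gene symbol).
#'
#' @param header Character vector of column names.
#' @return An object of class `column_map`: a named list with one source
#'   column name (or `NA`) per role, plus an `effect` element naming which
#'   effect role (`"beta"` or `"or"`) applies.
#' @details At least the chromosome, position and p-value roles must
#'   resolve; a missing mandatory role is an error naming the role(s).
#'   Two columns resolving to the same role is an ambiguity error. When
#'   both a BETA and an OR column are present, BETA takes precedence and
#'   the OR column is ignored with a warning, so effects are never
#'   converted twice.
#' @examples
#' infer_columns(c("CHROM", "POS", "P"))
#' infer_columns(c("chr", "pos", "pval", "rsid"))
#' @export
infer_columns <- function(header) {
  if (length(header) == 0L) stop("header is empty", call. = FALSE)
  lower <- tolower(trimws(header))
  map <- list()
  for (role in names(COLUMN_ALIASES)) {
    hits <- which(lower %in% COLUMN_ALIASES[[role]])
    if (length(hits) > 1L) {
      stop(sprintf("ambiguous header: columns %s all resolve to the '%s' role",
                   paste(sQuote(header[hits]), collapse = ", "), role),
           call. = FALSE)
    }
    map[[role]] <- if (length(hits) == 1L) header[hits] else NA_character_
  }
  missing <- c("chromosome" = is.na(map$chrom),
               "position"   = is.na(map$pos),
               "p-value"    = is.na(map$p))
  if (any(missing)) {
    stop(sprintf("missing mandatory column(s): %s",
                 paste(names(missing)[missing], collapse = ", ")),
         call. = FALSE)
  }
  if (!is.na(map$beta) && !is.na(map$or)) {
    warning("both BETA and OR columns present; using BETA and ignoring OR",
            call. = FALSE)
    map$or <- NA_character_
  }
  map$effect <- if (!is.na(map$beta)) "beta" else if (!is.na(map$or)) "or" else NA_character_
  structure(map, class = "column_map")
}

#' @export
print.column_map <- function(x, ...) {
  cat("<column_map>\n")
  for (role in setdiff(names(x), "effect")) {
    if (!is.na(x[[role]])) cat(sprintf("  %-5s <- %s\n", role, x[[role]]))
  }
  if (!is.na(x$effect)) cat("  effect source:", x$effect, "\n")
  invisible(x)
}

#' Validate and canonicalise a summary-statistics data frame
#'
#' Accepts any data frame with recognisable chromosome, position and
#' p-value columns (see [infer_columns()]), renames them to the canonical
#' roles, normalises chromosome labels (strips `chr` prefixes, uppercases,
#' maps `M` to `MT`), coerces numeric columns, drops invalid rows with a
#' per-reason summary message, and sorts by (chromosome rank, position).
#'
#' P-values of exactly zero are clamped to the smallest representable
#' positive double (and counted in the `n_clamped` attribute) so that the
#' -log10 transform used throughout plotting stays finite. Rows with
#' chromosome labels outside 1-22, X, Y, MT are rejected with a warning:
#' the Manhattan layout requires the fixed canonical ordering.
#'
#' @param x A data frame of per-variant summary statistics.
#' @param label Dataset label (non-empty string); defaults to the name of
#'   the object passed in.
#' @return A data frame of class `gwas` with canonical columns, carrying
#'   `label`, `n_dropped` and `n_clamped` attributes.
#' @export
as_gwas <- function(x, label = NULL) {
  if (inherits(x, "gwas")) {
    if (!is.null(label)) attr(x, "label") <- label
    return(x)
  }
  if (is.null(label)) label <- deparse(substitute(x))[1]
  stopifnot(is.data.frame(x))
  if (!nzchar(label)) stop("dataset label must be non-empty", call. = FALSE)
  map <- infer_columns(names(x))

  n0 <- nrow(x)
  out <- data.frame(
    CHROM = canonicalise_chrom(x[[map$chrom]]),
    POS = suppressWarnings(as.numeric(x[[map$pos]])),
    P = suppressWarnings(as.numeric(x[[map$p]])),
    stringsAsFactors = FALSE
  )
  take_chr <- function(role) {
    if (is.na(map[[role]])) NULL else as.character(x[[map[[role]]]])
  }
  take_num <- function(role) {
    if (is.na(map[[role]])) NULL else suppressWarnings(as.numeric(x[[map[[role]]]]))
  }
  out$ID <- take_chr("id")
  ref <- take_chr("ref"); if (!is.null(ref)) out$REF <- toupper(ref)
  alt <- take_chr("alt"); if (!is.null(alt)) out$ALT <- toupper(alt)
  out$BETA <- take_num("beta")
  if (is.na(map$beta)) {
    or <- take_num("or")
    if (!is.null(or)) {
      bad_or <- !is.na(or) & or <= 0
      if (any(bad_or)) {
        warning(sprintf("%d non-positive odds ratio(s) set to NA", sum(bad_or)),
                call. = FALSE)
        or[bad_or] <- NA_real_
      }
      out$OR <- or
    }
  }
  r2 <- take_num("r2")
  if (!is.null(r2)) {
    bad_r2 <- !is.na(r2) & (r2 < 0 | r2 > 1)
    if (any(bad_r2)) {
      warning(sprintf("%d r2 value(s) outside [0, 1] set to NA", sum(bad_r2)),
              call. = FALSE)
      r2[bad_r2] <- NA_real_
    }
    out$R2 <- r2
  }
  out$GENE <- take_chr("gene")

  # row-level validation with reason bookkeeping
  reasons <- character(0)
  keep <- rep(TRUE, n0)
  flag <- function(bad, why) {
    bad <- bad & keep
    if (any(bad)) reasons <<- c(reasons, sprintf("%d row(s): %s", sum(bad), why))
    keep <<- keep & !bad
  }
  flag(is.na(out$POS) | out$POS < 1, "missing or non-positive position")
  flag(is.na(out$P), "unparseable p-value")
  flag(!is.na(out$P) & (out$P < 0 | out$P > 1), "p-value outside [0, 1]")
  unknown <- !(out$CHROM %in% CHROM_LEVELS)
  if (any(unknown & keep)) {
    warning(sprintf("rejecting %d row(s) on unrecognised contig(s): %s",
                    sum(unknown & keep),
                    paste(unique(out$CHROM[unknown & keep]), collapse = ", ")),
            call. = FALSE)
  }
  flag(unknown, "unrecognised chromosome")

  out <- out[keep, , drop = FALSE]
  n_clamped <- sum(out$P == 0)
  if (n_clamped > 0) out$P[out$P == 0] <- .Machine$double.xmin

  out <- out[order(chrom_rank(out$CHROM), out$POS), , drop = FALSE]
  rownames(out) <- NULL
  n_dropped <- n0 - nrow(out)
  if (n_dropped > 0) {
    message(sprintf("dropped %d of %d row(s) [%s]", n_dropped, n0,
                    paste(reasons, collapse = "; ")))
  }
  structure(out, class = c("gwas", "data.frame"),
            label = label, n_dropped = n_dropped, n_clamped = n_clamped)
}

# Pass-through for already-canonical data, validation otherwise.
ensure_gwas <- function(x, label = "dataset") {
  if (inherits(x, "gwas")) x else as_gwas(x, label = label)
}

#' @export
print.gwas <- function(x, n = 6L, ...) {
  cat(sprintf("<gwas> %s: %d variants, %d chromosome(s)\n",
              attr(x, "label") %||% "unlabelled", nrow(x),
              length(unique(x$CHROM))))
  print(head(as.data.frame(x), n))
  if (nrow(x) > n) cat(sprintf("... and %d more rows\n", nrow(x) - n))
  invisible(x)
}

#' Read a summary-statistics file
#'
#' Reads a delimited text table (tab, comma or whitespace; auto-detected
#' from the header line unless `delim` is given), then validates and
#' canonicalises it with [as_gwas()]. Rows failing validation are dropped
#' and summarised in a message.
#'
#' @param path Path to a delimited text file with a header line.
#' @param delim Field delimiter; `NULL` (default) auto-detects among tab,
#'   comma and whitespace.
#' @param label Dataset label; defaults to the file name without extension.
#' @return A `gwas` data frame (see [as_gwas()]).
#' @export
read_sumstats <- function(path, delim = NULL, label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L || !nzchar(trimws(first))) {
    stop("empty file: ", path, call. = FALSE)
  }
  if (is.null(delim)) {
    delim <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  }
  x <- read.table(path, header = TRUE, sep = delim, stringsAsFactors = FALSE,
                  check.names = FALSE, comment.char = "", quote = "\"")
  if (nrow(x) == 0L) stop("no data rows in ", path, call. = FALSE)
  as_gwas(x, label = label %||% tools::file_path_sans_ext(basename(path)))
}

#' Write a canonical summary-statistics table as TSV
#'
#' Numeric fields are written with full double precision (`%.17g`) so a
#' write/read round trip reproduces the table exactly.
#'
#' @param x A `gwas` data frame (or anything [as_gwas()] accepts).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  x <- ensure_gwas(x)
  out <- as.data.frame(x)
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      v <- out[[col]]
      out[[col]] <- ifelse(is.na(v),
                           "NA",
                           ifelse(v == round(v) & abs(v) < 2^53,
                                  sprintf("%.0f", v), sprintf("%.17g", v)))
    }
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
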