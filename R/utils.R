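# Shared internals: chromosome ordering, seeded RNG scoping, small helpers.

# Canonical chromosome labels in display order. Manhattan layout and sorting
# rely on this fixed ordering; contigs outside the set are rejected upstream.
CHROM_LEVELS <- c(as.character(1:22), "X", "Y", "MT")

chrom_rank <- function(chrom) match(as.character(chrom), CHROM_LEVELS)

canonicalise_chrom <- function(chrom) {
  x <- toupper(trimws(as.character(chrom)))
  x <- sub("^CHR", "", x)
  x[x == "M"] <- "MT"
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream (the global .Random.seed is restored on exit).
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Recycle a per-dataset option vector: length 1 or n, anything else errors.
recycle_opt <- function(x, n, what) {
  if (is.null(x)) return(NULL)
  if (length(x) == 1L) return(rep(x, n))
  if (length(x) != n) {
    stop(sprintf("`%s` must have length 1 or %d (one per dataset), got %d",
                 what, n, length(x)), call. = FALSE)
  }
  x
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
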