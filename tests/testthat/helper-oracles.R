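# Independent brute-force oracles and random-input generators for
# property tests. These deliberately re-derive results with the
# simplest possible code, sharing nothing with the implementation.

# Greedy windowed lead selection, re-implemented naively: scan a working
# copy, always deleting the global per-chromosome minimum and everything
# strictly closer than half a window.
oracle_lead_snps <- function(df, thresh = 5e-8, region_size = 1e6) {
  out <- NULL
  for (chr in unique(df$CHROM)) {
    work <- df[df$CHROM == chr & df$P < thresh, , drop = FALSE]
    while (nrow(work) > 0) {
      best <- which(work$P == min(work$P))
      if (length(best) > 1) best <- best[which.min(work$POS[best])]
      out <- rbind(out, work[best, , drop = FALSE])
      work <- work[abs(work$POS - work$POS[best]) >= region_size / 2, ,
                   drop = FALSE]
    }
  }
  if (is.null(out)) return(df[0, , drop = FALSE])
  out[order(match(out$CHROM, c(as.character(1:22), "X", "Y", "MT")), out$POS), ,
      drop = FALSE]
}

# Exhaustive nearest-gene scan over every gene on the chromosome,
# applying the documented tie rules by explicit sorting.
oracle_nearest_gene <- function(chrom, pos, track, protein_coding_only = TRUE) {
  g <- track$genes
  g <- g[g$chrom == chrom, , drop = FALSE]
  if (protein_coding_only) g <- g[g$biotype == "protein_coding", , drop = FALSE]
  if (nrow(g) == 0) return(NA_character_)
  d <- numeric(nrow(g))
  span <- numeric(nrow(g))
  for (i in seq_len(nrow(g))) {
    d[i] <- if (g$gene_start[i] <= pos && pos <= g$gene_end[i]) 0 else
      min(abs(pos - g$gene_start[i]), abs(pos - g$gene_end[i]))
    span[i] <- g$gene_end[i] - g$gene_start[i]
  }
  if (any(d == 0)) {
    cand <- g[d == 0, , drop = FALSE]
    cand <- cand[order(span[d == 0], cand$gene_name), , drop = FALSE]
  } else {
    cand <- g[d == min(d), , drop = FALSE]
    cand <- cand[order(cand$gene_name), , drop = FALSE]
  }
  cand$gene_name[1]
}

# Random canonical summary-statistics table (already-valid columns).
random_gwas_table <- function(n = 200, chroms = c("1", "2", "3"),
                              maxpos = 5e6, sig_frac = 0.1) {
  p <- runif(n)
  sig <- sample(n, round(sig_frac * n))
  p[sig] <- 10^runif(length(sig), -14, -7.5)
  pairs <- matrix(c("A", "C", "A", "G", "T", "C", "T", "G"), ncol = 2,
                  byrow = TRUE)
  k <- sample(4, n, replace = TRUE)
  df <- data.frame(CHROM = sample(chroms, n, replace = TRUE),
                   POS = sample(maxpos, n, replace = TRUE),
                   P = p, REF = pairs[k, 1], ALT = pairs[k, 2],
                   BETA = rnorm(n, 0, 0.2),
                   ID = sprintf("rs%06d", sample(1e6, n)),
                   stringsAsFactors = FALSE)
  as_gwas(df, label = "rand")
}

# Random gene track with possibly overlapping genes and mixed biotypes.
random_track <- function(n_genes = 15, chroms = c("1", "2"), maxpos = 5e6) {
  start <- sample(maxpos, n_genes, replace = TRUE)
  span <- sample(5e3:2e5, n_genes, replace = TRUE)
  genetrack(data.frame(
    chrom = sample(chroms, n_genes, replace = TRUE),
    gene_start = start, gene_end = start + span,
    gene_name = paste0("G", sample(1e5, n_genes)),
    biotype = sample(c("protein_coding", "lincRNA"), n_genes,
                     replace = TRUE, prob = c(0.8, 0.2)),
    stringsAsFactors = FALSE
  ), build = "synthetic")
}

# A small track with hand-picked coordinates used across files.
fixed_track <- function() {
  genetrack(data.frame(
    chrom = c("1", "1", "1", "2"),
    gene_start = c(5e5, 8e5, 8.5e5, 1e6),
    gene_end = c(6e5, 9e5, 8.8e5, 1.2e6),
    gene_name = c("GENE7", "GENEA", "GENEB", "GENEC"),
    biotype = "protein_coding",
    stringsAsFactors = FALSE
  ), build = "synthetic")
}

# Planted-peak study shared by plot and acceptance tests.
planted_study <- function(k = 3, seed = 11, min_p = 1e-12) {
  lens <- c("1" = 10e6, "2" = 8e6, "3" = 6e6, "X" = 5e6)
  apex <- list(c("1", 2e6), c("2", 3e6), c("3", 1.5e6), c("X", 2.5e6),
               c("1", 7e6))
  peaks <- lapply(apex[seq_len(k)], function(a) {
    peak_spec(a[1], as.numeric(a[2]), min_p = min_p, effect = 0.25)
  })
  list(data = simulate_sumstats(3000, chrom_lengths = lens, peaks = peaks,
                                seed = seed, label = "study"),
       apex = apex[seq_len(k)])
}
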