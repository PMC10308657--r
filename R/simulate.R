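# Deterministic simulators: GWAS summary statistics with planted
# association peaks, a consistent synthetic gene track, and derived
# second cohorts for cross-dataset matching.
#
# The peak shape is a deterministic linear decay of -log10(P) from the
# apex over the flank width — the generators exercise selection, layout
# and matching logic, and make no attempt at LD-realistic simulation.

# Default fixture genome: three autosomes plus X, small enough that
# whole-genome operations run in milliseconds.
default_chrom_lengths <- function() {
  c("1" = 10e6, "2" = 8e6, "3" = 6e6, "X" = 5e6)
}

# unambiguous allele pairs (no A/T or C/G, whose strand flips are
# undetectable from summary statistics)
UNAMBIGUOUS_PAIRS <- matrix(c("A", "C", "A", "G", "C", "A", "C", "T",
                              "G", "A", "G", "T", "T", "C", "T", "G"),
                            ncol = 2, byrow = TRUE)

#' Describe a planted association peak
#'
#' @param chrom Chromosome label.
#' @param center_pos Apex position in bp.
#' @param min_p Apex p-value (the smallest in the peak), in (0, 1).
#' @param width Bp over which `-log10(P)` decays linearly to the
#'   background on each side of the apex.
#' @param n_variants Number of variants in the peak (>= 1; one sits
#'   exactly at the apex).
#' @param effect Effect size (beta) at the apex; its sign is shared by
#'   the whole peak.
#' @param alleles Length-2 character vector `(REF, ALT)` used for every
#'   peak variant.
#' @return An object of class `peak_spec`.
#' @export
peak_spec <- function(chrom, center_pos, min_p = 1e-10, width = 250e3,
                      n_variants = 25, effect = 0.2,
                      alleles = c("A", "G")) {
  stopifnot(is_scalar_number(center_pos), center_pos >= 1,
            is_scalar_number(min_p), min_p > 0, min_p < 1,
            is_scalar_number(width), width > 0,
            is_scalar_number(n_variants), n_variants >= 1,
            is.character(alleles), length(alleles) == 2)
  structure(list(chrom = canonicalise_chrom(chrom), center_pos = center_pos,
                 min_p = min_p, width = width,
                 n_variants = as.integer(n_variants), effect = effect,
                 alleles = toupper(alleles)), class = "peak_spec")
}

#' Simulate GWAS summary statistics with planted peaks
#'
#' Background variants are placed uniformly along each chromosome
#' (allocated proportionally to chromosome length) with `P ~
#' Uniform(0, 1)` and small random effects — the global null. Each
#' [peak_spec()] plants `n_variants` variants around its apex whose
#' `-log10(P)` decays linearly from `-log10(min_p)` to 0 over `width` bp,
#' the apex variant sitting exactly at `center_pos` with exactly `min_p`;
#' peak effects share the apex sign and shrink with the same profile.
#' All variants get unambiguous REF/ALT pairs (unless
#' `allow_ambiguous`) and unique `rs`-style identifiers. Output is fully
#' deterministic for a fixed seed.
#'
#' @param n_background Number of null background variants.
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @param peaks List of [peak_spec()] objects. Peaks whose flanks overlap
#'   on one chromosome trigger a warning, not an error.
#' @param seed Integer seed; the caller's RNG state is left untouched.
#' @param label Dataset label.
#' @param background_effect_sd Standard deviation of null effects.
#' @param allow_ambiguous Permit strand-ambiguous (A/T, C/G) background
#'   allele pairs.
#' @return A `gwas` dataset.
#' @export
simulate_sumstats <- function(n_background = 5000,
                              chrom_lengths = default_chrom_lengths(),
                              peaks = list(), seed = 42, label = "sim",
                              background_effect_sd = 0.05,
                              allow_ambiguous = FALSE) {
  stopifnot(is.numeric(chrom_lengths), length(chrom_lengths) >= 1,
            all(chrom_lengths > 0), !is.null(names(chrom_lengths)))
  if (inherits(peaks, "peak_spec")) peaks <- list(peaks)
  stopifnot(all(vapply(peaks, inherits, TRUE, "peak_spec")))
  warn_overlapping_peaks(peaks)
  chroms <- canonicalise_chrom(names(chrom_lengths))

  with_seed(seed, {
    # background: multinomial allocation over chromosomes, uniform POS
    n_per <- if (n_background > 0) {
      as.vector(stats::rmultinom(1, n_background,
                                 chrom_lengths / sum(chrom_lengths)))
    } else {
      rep(0L, length(chroms))
    }
    bg <- data.frame(
      CHROM = rep(chroms, n_per),
      POS = unlist(lapply(seq_along(chroms), function(i) {
        ceiling(runif(n_per[i], 0, chrom_lengths[i]))
      })),
      P = runif(n_background),
      stringsAsFactors = FALSE
    )
    pair <- UNAMBIGUOUS_PAIRS
    if (allow_ambiguous) {
      pair <- rbind(pair, matrix(c("A", "T", "T", "A", "C", "G", "G", "C"),
                                 ncol = 2, byrow = TRUE))
    }
    pk <- sample(nrow(pair), n_background, replace = TRUE)
    bg$REF <- pair[pk, 1]
    bg$ALT <- pair[pk, 2]
    bg$BETA <- rnorm(n_background, 0, background_effect_sd)

    peak_rows <- lapply(peaks, function(p) {
      mlogp_apex <- -log10(p$min_p)
      off <- if (p$n_variants == 1) 0 else {
        unique(round(seq(-p$width, p$width, length.out = p$n_variants)))
      }
      if (!0 %in% off) off <- sort(c(off, 0))
      mlogp <- mlogp_apex * (1 - abs(off) / p$width)
      # tiny downward jitter keeps the apex the strict minimum p
      jit <- runif(length(off), 0, 0.05)
      mlogp <- pmax(mlogp - jit * (off != 0), 0)
      eff <- p$effect * pmax(1 - abs(off) / p$width, 0.1) +
        rnorm(length(off), 0, abs(p$effect) * 0.05)
      eff <- sign(p$effect) * abs(eff)
      data.frame(CHROM = p$chrom, POS = p$center_pos + off,
                 P = 10^(-mlogp), REF = p$alleles[1], ALT = p$alleles[2],
                 BETA = eff, stringsAsFactors = FALSE)
    })
    out <- rbind(bg, do.call(rbind, c(peak_rows, list(NULL))))
    out <- out[out$POS >= 1, , drop = FALSE]
    out <- out[order(chrom_rank(out$CHROM), out$POS), , drop = FALSE]
    out$ID <- sprintf("rs%07d", seq_len(nrow(out)))
    as_gwas(out, label = label)
  })
}

warn_overlapping_peaks <- function(peaks) {
  if (length(peaks) < 2) return(invisible())
  for (i in seq_along(peaks)[-1]) {
    for (j in seq_len(i - 1)) {
      a <- peaks[[i]]; b <- peaks[[j]]
      if (a$chrom == b$chrom &&
          abs(a$center_pos - b$center_pos) <= a$width + b$width) {
        warning(sprintf("peaks at %s:%d and %s:%d have overlapping flanks",
                        a$chrom, as.integer(a$center_pos),
                        b$chrom, as.integer(b$center_pos)), call. = FALSE)
      }
    }
  }
  invisible()
}

#' Simulate a synthetic gene track
#'
#' Random but non-pathological gene models: spans of 5-200 kb placed
#' uniformly (allocated proportionally to chromosome length), 2-10
#' disjoint exons inside each span, mostly protein-coding biotypes, and
#' unique symbols `GENE1` ... `GENEn`. Deterministic per seed.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @param n_genes Number of genes.
#' @param seed Integer seed.
#' @param prop_coding Fraction of protein-coding genes (the rest are
#'   lincRNA).
#' @return A [genetrack()] with build label `"synthetic"`.
#' @export
simulate_gene_track <- function(chrom_lengths = default_chrom_lengths(),
                                n_genes = 30, seed = 42,
                                prop_coding = 0.85) {
  stopifnot(is.numeric(chrom_lengths), all(chrom_lengths > 0),
            !is.null(names(chrom_lengths)), n_genes >= 1)
  chroms <- canonicalise_chrom(names(chrom_lengths))
  with_seed(seed, {
    chr_i <- sample(seq_along(chroms), n_genes, replace = TRUE,
                    prob = chrom_lengths / sum(chrom_lengths))
    span <- round(runif(n_genes, 5e3, 2e5))
    start <- vapply(seq_len(n_genes), function(i) {
      ceiling(runif(1, 1, max(2, chrom_lengths[chr_i[i]] - span[i])))
    }, numeric(1))
    biotype <- ifelse(runif(n_genes) < prop_coding, "protein_coding", "lincRNA")
    genes <- data.frame(chrom = chroms[chr_i], gene_start = start,
                        gene_end = start + span,
                        gene_name = paste0("GENE", seq_len(n_genes)),
                        biotype = biotype, stringsAsFactors = FALSE)
    exs <- vector("list", n_genes); exe <- vector("list", n_genes)
    for (i in seq_len(n_genes)) {
      k <- sample(2:10, 1)
      cuts <- sort(sample(seq(genes$gene_start[i], genes$gene_end[i]), 2 * k))
      exs[[i]] <- cuts[seq(1, 2 * k, by = 2)]
      exe[[i]] <- cuts[seq(2, 2 * k, by = 2)]
    }
    genes$exon_starts <- exs
    genes$exon_ends <- exe
    genetrack(genes, build = "synthetic")
  })
}

#' Derive a second cohort from a base dataset with known perturbations
#'
#' Builds a comparison dataset by (i) dropping a fraction of positions
#' (which become positional non-matches), (ii) corrupting the ALT allele
#' on a fraction of the remainder to an allele outside the original pair
#' (irreconcilable by construction), (iii) swapping REF/ALT with a
#' negated effect on a further fraction (exercising the harmonisation
#' flip), and (iv) adding Gaussian noise to the effects. The three
#' manipulations are applied to disjoint row sets. Ground-truth labels
#' per base row are returned alongside, so the expected snpset partition
#' is known exactly.
#'
#' @param base A `gwas` dataset with REF/ALT and BETA.
#' @param drop_frac,allele_corrupt_frac,flip_frac Fractions in `[0, 1]`
#'   of base rows to drop, allele-corrupt, and flip.
#' @param effect_noise_sd Standard deviation of effect noise.
#' @param seed Integer seed.
#' @param label Label for the derived dataset.
#' @return A list with `data` (the derived `gwas`) and `truth` (data
#'   frame `CHROM`, `POS`, `action` in
#'   dropped/corrupted/flipped/kept, aligned with the rows of `base`).
#' @export
paired_cohorts <- function(base, drop_frac = 0, allele_corrupt_frac = 0,
                           effect_noise_sd = 0, flip_frac = 0, seed = 42,
                           label = "derived") {
  base <- ensure_gwas(base)
  check_snpset_columns(base, "base dataset")
  fr <- c(drop_frac, allele_corrupt_frac, flip_frac)
  if (any(!is.finite(fr) | fr < 0 | fr > 1)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  if (sum(fr) > 1) {
    stop("drop, corrupt and flip fractions must sum to at most 1", call. = FALSE)
  }
  n <- nrow(base)
  with_seed(seed, {
    action <- rep("kept", n)
    pool <- seq_len(n)
    take <- function(k) {
      idx <- if (k >= length(pool)) pool else
        sort(pool[sample.int(length(pool), k)])
      pool <<- setdiff(pool, idx)
      idx
    }
    idx_drop <- take(round(drop_frac * n))
    idx_corrupt <- take(round(allele_corrupt_frac * n))
    idx_flip <- take(round(flip_frac * n))
    action[idx_drop] <- "dropped"
    action[idx_corrupt] <- "corrupted"
    action[idx_flip] <- "flipped"

    d2 <- as.data.frame(base)
    d2$BETA <- effect_beta(base) + rnorm(n, 0, effect_noise_sd)
    d2$OR <- NULL
    for (i in idx_corrupt) {
      d2$ALT[i] <- sample(setdiff(c("A", "C", "G", "T"),
                                  c(d2$REF[i], d2$ALT[i])), 1)
    }
    if (length(idx_flip)) {
      tmp <- d2$REF[idx_flip]
      d2$REF[idx_flip] <- d2$ALT[idx_flip]
      d2$ALT[idx_flip] <- tmp
      d2$BETA[idx_flip] <- -d2$BETA[idx_flip]
    }
    if (length(idx_drop)) d2 <- d2[-idx_drop, , drop = FALSE]
    truth <- data.frame(CHROM = base$CHROM, POS = base$POS, action = action,
                        stringsAsFactors = FALSE)
    list(data = as_gwas(d2, label = label), truth = truth)
  })
}
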