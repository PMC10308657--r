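# Cross-dataset matching, allele harmonisation, effect orientation.

make_cohort <- function(pos = c(1e6, 3e6, 5e6), chrom = "1",
                        p = 1e-10, ref = "A", alt = "G", beta = 0.3,
                        label = "c") {
  n <- length(pos)
  as_gwas(data.frame(CHROM = chrom, POS = pos, P = rep_len(p, n),
                     REF = rep_len(ref, n), ALT = rep_len(alt, n),
                     BETA = rep_len(beta, n),
                     ID = sprintf("rs%d", seq_len(n))), label = label)
}

test_that("or_to_beta is the natural log with a positivity domain", {
  expect_equal(or_to_beta(1), 0)
  expect_equal(or_to_beta(exp(1)), 1)
  expect_equal(or_to_beta(0.5), -log(2))
  expect_equal(or_to_beta(c(2, NA)), c(log(2), NA))
  expect_error(or_to_beta(0), "positive")
  expect_error(or_to_beta(-1), "positive")
  # inverse property
  b <- c(-1.3, 0, 0.7)
  expect_equal(or_to_beta(exp(b)), b)
})

test_that("match_by_pos partitions leads into matched and not_found", {
  d1 <- make_cohort()
  # empty partner set
  d2 <- make_cohort(pos = c(2e6, 4e6))
  r <- match_by_pos(d1, d2)
  expect_equal(nrow(r$matched), 0)
  expect_equal(nrow(r$not_found), 3)
  expect_equal(r$not_found$POS, d1$POS)
  # full overlap
  r2 <- match_by_pos(d1, make_cohort())
  expect_equal(nrow(r2$matched), 3)
  expect_equal(nrow(r2$not_found), 0)
  # nested-loop join oracle on random tables
  set.seed(406)
  for (trial in 1:15) {
    a <- random_gwas_table(50)
    b <- random_gwas_table(50)
    r <- match_by_pos(a, b)
    n_pairs <- 0
    n_found <- 0
    for (i in seq_len(nrow(a))) {
      hits <- sum(b$CHROM == a$CHROM[i] & b$POS == a$POS[i])
      n_pairs <- n_pairs + hits
      n_found <- n_found + (hits > 0)
    }
    expect_equal(nrow(r$matched), n_pairs)
    expect_equal(nrow(r$not_found), nrow(a) - n_found)
  }
})

test_that("match_by_alleles keeps exact, flips swapped, rejects the rest", {
  pairs <- data.frame(
    .d1row = 1:3, CHROM = "1", POS = c(1, 2, 3) * 1e6,
    ID = NA_character_, GENE = NA_character_,
    REF1 = "A", ALT1 = "G", P1 = 1e-10, E1 = 0.3,
    REF2 = c("A", "G", "A"), ALT2 = c("G", "A", "C"),
    P2 = 1e-5, E2 = c(0.3, 0.5, 0.2), stringsAsFactors = FALSE
  )
  r <- match_by_alleles(pairs)
  expect_equal(nrow(r$matched), 2)
  expect_equal(nrow(r$no_allele_match), 1)
  # exact match untouched
  expect_equal(r$matched$E2[1], 0.3)
  # swapped match: effect negated, alleles swapped into D1's frame
  expect_equal(r$matched$E2[2], -0.5)
  expect_equal(r$matched$REF2[2], "A")
  expect_equal(r$matched$ALT2[2], "G")
  # irreconcilable pair keeps its original row
  expect_equal(r$no_allele_match$ALT2, "C")
  expect_error(match_by_alleles(pairs[, -7]), "lack")
  pairs$REF2[1] <- NA
  expect_error(match_by_alleles(pairs), "missing allele")
})

test_that("swapped-allele flipping is an involution", {
  row <- data.frame(.d1row = 1L, CHROM = "1", POS = 1e6, ID = NA, GENE = NA,
                    REF1 = "A", ALT1 = "G", P1 = 1e-9, E1 = 0.4,
                    REF2 = "G", ALT2 = "A", P2 = 1e-4, E2 = 0.5,
                    stringsAsFactors = FALSE)
  once <- match_by_alleles(row)$matched
  # re-swap the harmonised row and run again: back to harmonised original
  again <- once
  tmp <- again$REF2; again$REF2 <- again$ALT2; again$ALT2 <- tmp
  again$E2 <- -again$E2
  twice <- match_by_alleles(again)$matched
  expect_equal(twice$E2, once$E2)
  expect_equal(twice$REF2, once$REF2)
})

test_that("multi-allelic duplicates resolve to one partner with a warning", {
  d1 <- make_cohort(pos = 1e6)
  d2 <- as_gwas(data.frame(CHROM = "1", POS = c(1e6, 1e6), P = c(1e-4, 1e-3),
                           REF = c("A", "A"), ALT = c("G", "G"),
                           BETA = c(0.1, 0.9)), label = "dup")
  mp <- match_by_pos(d1, d2)
  expect_warning(r <- match_by_alleles(mp$matched), "multiple")
  expect_equal(nrow(r$matched), 1)
  expect_equal(r$matched$E2, 0.1)  # first in position-sorted order
})

test_that("flip_to_positive_allele_for_dat1 orients and is idempotent", {
  rows <- data.frame(
    CHROM = "1", POS = c(1, 2, 3) * 1e6,
    REF1 = "A", ALT1 = "G", P1 = 1e-9, E1 = c(0.4, -0.4, 0),
    REF2 = "A", ALT2 = "G", P2 = 1e-4, E2 = c(0.2, 0.2, 0.1),
    stringsAsFactors = FALSE
  )
  out <- flip_to_positive_allele_for_dat1(rows)
  expect_equal(out$E1, c(0.4, 0.4, 0))
  expect_equal(out$E2, c(0.2, -0.2, 0.1))
  expect_equal(out$REF1, c("A", "G", "A"))
  expect_equal(out$ALT1, c("G", "A", "G"))
  expect_equal(out$REF2, out$REF1)  # harmonisation preserved
  # fixed point: applying again changes nothing
  expect_identical(flip_to_positive_allele_for_dat1(out), out)
})

test_that("get_snpset self-comparison yields E1 = E2 with empty remainders", {
  d <- make_cohort(beta = c(0.3, 0.2, 0.5))
  r <- get_snpset(d, d, verbose = TRUE)
  expect_equal(nrow(r$snpset), 3)
  expect_equal(nrow(r$not_found), 0)
  expect_equal(nrow(r$no_allele_match), 0)
  expect_equal(r$snpset$E1, r$snpset$E2)
  # with negative effects the identity still holds after orientation
  dn <- make_cohort(beta = c(-0.3, 0.2, -0.5))
  rn <- get_snpset(dn, dn)
  expect_equal(rn$E1, rn$E2)
  expect_true(all(rn$E1 >= 0))
})

test_that("an allele-swapped, effect-negated copy reproduces the snpset", {
  d1 <- make_cohort(beta = c(0.3, -0.2, 0.5))
  d2 <- as.data.frame(d1)
  tmp <- d2$REF; d2$REF <- d2$ALT; d2$ALT <- tmp
  d2$BETA <- -d2$BETA
  ss_self <- get_snpset(d1, d1)
  ss_flip <- get_snpset(d1, as_gwas(d2, label = "flipped"))
  expect_equal(ss_flip$E1, ss_self$E1)
  expect_equal(ss_flip$E2, ss_self$E2)
  expect_equal(ss_flip$REF2, ss_flip$REF1)
  expect_equal(ss_flip$ALT2, ss_flip$ALT1)
})

test_that("snpset carries the eight effect-comparison columns", {
  d <- make_cohort()
  ss <- get_snpset(d, d)
  expect_true(all(c("P1", "E1", "ALT1", "REF1", "P2", "E2", "ALT2", "REF2")
                  %in% names(ss)))
  expect_true(all(c("CHROM", "POS") %in% names(ss)))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_snpset(ss, f)
  back <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(nrow(back), nrow(ss))
})

test_that("get_snpset names the missing columns it needs", {
  bad <- as_gwas(data.frame(CHROM = "1", POS = 1e6, P = 1e-10), label = "b")
  good <- make_cohort()
  expect_error(get_snpset(bad, good), "allele")
  noeff <- as_gwas(data.frame(CHROM = "1", POS = 1e6, P = 1e-10,
                              REF = "A", ALT = "G"), label = "n")
  expect_error(get_snpset(noeff, good), "BETA or OR")
})

test_that("odds ratios are converted to betas before comparison", {
  d1 <- make_cohort(beta = 0.3)
  d2 <- data.frame(CHROM = "1", POS = c(1e6, 3e6, 5e6), P = 1e-6,
                   REF = "A", ALT = "G", OR = exp(c(0.25, 0.35, 0.45)))
  ss <- get_snpset(d1, as_gwas(d2, label = "orset"))
  expect_equal(ss$E2, c(0.25, 0.35, 0.45))
})

test_that("partition conservation holds over randomised paired cohorts", {
  set.seed(407)
  for (trial in 1:25) {
    base <- random_gwas_table(n = 200, sig_frac = 0.2)
    pc <- paired_cohorts(base, drop_frac = runif(1, 0, 0.3),
                         allele_corrupt_frac = runif(1, 0, 0.2),
                         flip_frac = runif(1, 0, 0.3),
                         effect_noise_sd = 0.05, seed = trial)
    r <- get_snpset(base, pc$data, verbose = TRUE)
    expect_equal(r$n_leads,
                 nrow(r$snpset) + nrow(r$not_found) + nrow(r$no_allele_match))
    expect_true(all(r$snpset$E1 >= 0))
    expect_equal(r$snpset$REF1, r$snpset$REF2)
    expect_equal(r$snpset$ALT1, r$snpset$ALT2)
  }
})

test_that("effect_table flags dataset-2 significance and labels genes", {
  d <- make_cohort(p = c(1e-10, 1e-10, 1e-10))
  d2 <- as.data.frame(d)
  d2$P <- c(1e-10, 0.01, 1e-9)
  tbl <- effect_table(d, as_gwas(d2, label = "d2"))
  expect_equal(tbl$significant2, c(TRUE, FALSE, TRUE))
  # snpset input route
  ss <- get_snpset(d, as_gwas(d2, label = "d2"))
  tbl2 <- effect_table(ss)
  expect_equal(tbl2$significant2, tbl$significant2)
  # empty snpset stays empty but typed
  tbl3 <- effect_table(ss[0, , drop = FALSE])
  expect_equal(nrow(tbl3), 0)
  expect_true(all(c("gene_label", "significant2") %in% names(tbl3)))
  # nearest-gene fill from a track
  tr <- genetrack(data.frame(chrom = "1", gene_start = c(0.9e6, 2.9e6, 4.9e6),
                             gene_end = c(1.1e6, 3.1e6, 5.1e6),
                             gene_name = c("GA", "GB", "GC"),
                             biotype = "protein_coding"))
  tbl4 <- effect_table(d, as_gwas(d2, label = "d2"), track = tr)
  expect_equal(tbl4$gene_label, c("GA", "GB", "GC"))
})
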