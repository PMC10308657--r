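# Lead-variant selection, region resolution, regional extraction.

gwas_rows <- function(chrom, pos, p) {
  as_gwas(data.frame(CHROM = chrom, POS = pos, P = p), label = "toy")
}

test_that("get_lead_snps implements greedy centred-window exclusion", {
  # nothing significant
  expect_equal(nrow(get_lead_snps(gwas_rows("1", c(1e6, 2e6), c(0.5, 1e-7)))), 0)
  # two significant variants 2 Mb apart: both kept under the default window
  g <- gwas_rows("1", c(1e6, 3e6), c(1e-9, 1e-10))
  expect_equal(get_lead_snps(g)$POS, c(1e6, 3e6))
  # hand-simulated greedy exclusion: 1.3 Mb lead shadowed by the 1.0 Mb one
  g3 <- gwas_rows("1", c(1.0e6, 1.3e6, 2.2e6), c(1e-12, 1e-9, 1e-10))
  leads <- get_lead_snps(g3)
  expect_equal(leads$POS, c(1.0e6, 2.2e6))
  expect_equal(oracle_lead_snps(as.data.frame(g3))$POS, c(1.0e6, 2.2e6))
  # strict boundary: a variant at exactly region_size/2 away survives
  gb <- gwas_rows("1", c(1e6, 1.5e6, 1.5e6 - 1), c(1e-12, 1e-9, 1e-10))
  expect_equal(get_lead_snps(gb)$POS, c(1e6, 1.5e6))
  # p-value tie broken towards the smaller position
  gt <- gwas_rows("1", c(2e6, 1e6), c(1e-9, 1e-9))
  expect_equal(get_lead_snps(gt, region_size = 4e6)$POS, 1e6)
})

test_that("get_lead_snps validates its parameters", {
  g <- gwas_rows("1", 1e6, 1e-9)
  expect_error(get_lead_snps(g, thresh = 0), "thresh")
  expect_error(get_lead_snps(g, thresh = 2), "thresh")
  expect_error(get_lead_snps(g, region_size = -1), "region_size")
})

test_that("get_lead_snps equals the brute-force oracle on random tables", {
  set.seed(403)
  for (trial in 1:50) {
    g <- random_gwas_table(n = sample(50:400, 1), sig_frac = 0.2)
    rs <- sample(c(2e5, 5e5, 1e6, 3e6), 1)
    th <- sample(c(5e-8, 1e-9), 1)
    got <- get_lead_snps(g, thresh = th, region_size = rs)
    want <- oracle_lead_snps(as.data.frame(g), thresh = th, region_size = rs)
    expect_equal(got$POS, want$POS)
    expect_equal(got$P, want$P)
    # pairwise same-chromosome lead separation >= half-window
    for (chr in unique(got$CHROM)) {
      pos <- got$POS[got$CHROM == chr]
      if (length(pos) > 1) expect_true(all(diff(sort(pos)) >= rs / 2))
    }
  }
})

test_that("lead selection is monotone in thresh and region_size", {
  set.seed(404)
  for (trial in 1:10) {
    g <- random_gwas_table(n = 300, sig_frac = 0.25)
    strict <- get_lead_snps(g, thresh = 1e-9)
    loose <- get_lead_snps(g, thresh = 5e-8)
    # every locus found under the strict threshold persists when relaxed:
    # each strict lead is within half a window of some loose lead
    for (i in seq_len(nrow(strict))) {
      same <- loose[loose$CHROM == strict$CHROM[i], , drop = FALSE]
      expect_true(any(abs(same$POS - strict$POS[i]) < 5e5))
    }
    wide <- nrow(get_lead_snps(g, region_size = 2e6))
    narrow <- nrow(get_lead_snps(g, region_size = 5e5))
    expect_gte(narrow, wide)
  }
})

test_that("resolve_region pads genes by 100 kb each side and clips at 1", {
  tr <- fixed_track()
  r <- resolve_region(track = tr, gene = "GENE7")
  expect_equal(c(r$start, r$end), c(4e5, 7e5))
  expect_equal(r$provenance, "gene")
  # width = gene length + 2 * padding when unclipped
  expect_equal(r$end - r$start, (6e5 - 5e5) + 2 * 1e5)
  r2 <- resolve_region(track = tr, gene = "GENE7", gene_padding = 2.5e5)
  expect_equal(c(r2$start, r2$end), c(2.5e5, 8.5e5))
  # clipping at chromosome start
  tr_low <- genetrack(data.frame(chrom = "1", gene_start = 5e4, gene_end = 6e4,
                                 gene_name = "LOW", biotype = "protein_coding"))
  r3 <- resolve_region(track = tr_low, gene = "LOW")
  expect_equal(c(r3$start, r3$end), c(1, 1.6e5))
})

test_that("resolve_region handles literal, variant, and error forms", {
  expect_equal(format(resolve_region(region = "2:1000-2000")), "2:1000-2000")
  r <- resolve_region(region = "chr1:1,000-2,000")
  expect_equal(c(r$start, r$end), c(1000, 2000))
  r <- resolve_region(chrom = "3", start = 5, end = 10)
  expect_equal(r$chrom, "3")
  d <- as_gwas(data.frame(CHROM = "2", POS = 5e6, P = 0.1, ID = "rs42"),
               label = "d")
  rv <- resolve_region(data = d, variant = "rs42")
  expect_equal(c(rv$chrom, rv$start, rv$end), c("2", 4.9e6, 5.1e6))
  expect_equal(rv$provenance, "variant")
  expect_error(resolve_region(data = d, variant = "rs999"), "not found")
  expect_error(resolve_region(region = "banana"), "malformed")
  expect_error(resolve_region(track = fixed_track(), gene = "NOPE"), "not found")
  expect_error(resolve_region(), "exactly one")
  expect_error(resolve_region(region = "1:5-4", track = fixed_track()),
               "start exceeds end")
})

test_that("get_snps_within_region returns exactly the covered rows", {
  g <- gwas_rows("1", c(10, 100, 1000), c(0.1, 0.2, 0.3))
  expect_equal(nrow(get_snps_within_region(g, region("1", 1, 1e6))), 3)
  expect_equal(nrow(get_snps_within_region(g, region("1", 11, 99))), 0)
  expect_equal(get_snps_within_region(g, "1:50-500")$POS, 100)
  set.seed(405)
  for (trial in 1:20) {
    g <- random_gwas_table(100)
    a <- sort(sample(5e6, 2))
    chrom <- sample(c("1", "2"), 1)
    got <- get_snps_within_region(g, region(chrom, a[1], a[2]))
    want <- as.data.frame(g)[g$CHROM == chrom & g$POS >= a[1] & g$POS <= a[2], ]
    expect_equal(got$POS, want$POS)
    expect_equal(got$P, want$P)
  }
})
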