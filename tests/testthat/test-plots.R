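# Plot specifications and rendering.

study <- planted_study(k = 3, seed = 31)

test_that("default Manhattan spec: one 5e-8 line, no labels, no legend", {
  spec <- manhattan_spec(study$data)
  expect_equal(nrow(spec$hlines), 1)
  expect_equal(spec$hlines$p, 5e-8)
  expect_equal(spec$hlines$y, -log10(5e-8))
  expect_equal(nrow(spec$labels), 0)
  expect_false(spec$legend$show)
  expect_equal(length(unique(spec$points$dataset)), 1)
  # the line is removable and replaceable by multiple thresholds
  expect_equal(nrow(manhattan_spec(study$data, sign_thresh = NULL)$hlines), 0)
  expect_equal(nrow(manhattan_spec(study$data, sign_thresh = NA)$hlines), 0)
  multi <- manhattan_spec(study$data, sign_thresh = c(5e-8, 1e-6, 1e-9))
  expect_equal(sort(multi$hlines$p), sort(c(5e-8, 1e-6, 1e-9)))
})

test_that("three datasets with ntop = 3 overlap on one axis with a legend", {
  ds <- list(A = study$data,
             B = simulate_sumstats(1000, seed = 32, label = "B"),
             C = simulate_sumstats(1000, seed = 33, label = "C"))
  spec <- manhattan_spec(ds, ntop = 3, annotate = c(1e-11, 1e-8, 1e-8))
  expect_equal(spec$series$orientation, rep("top", 3))
  expect_false(spec$axes$mirrored)
  expect_true(spec$legend$show)
  expect_equal(spec$series$dataset, c("A", "B", "C"))
  expect_true(all(spec$points$y >= 0))
})

test_that("mirrored datasets sit below zero; top ones above", {
  ds <- list(A = study$data, B = simulate_sumstats(1000, seed = 34, label = "B"))
  spec <- manhattan_spec(ds, ntop = 1)
  expect_true(all(spec$points$y[spec$points$dataset == "A"] >= 0))
  expect_true(all(spec$points$y[spec$points$dataset == "B"] <= 0))
  expect_true(spec$axes$mirrored)
  # ntop = 0 mirrors everything
  spec0 <- manhattan_spec(ds, ntop = 0)
  expect_true(all(spec0$points$y <= 0))
})

test_that("per-dataset style vectors must match the dataset count", {
  ds <- list(A = study$data, B = simulate_sumstats(500, seed = 35, label = "B"))
  spec <- manhattan_spec(ds, color = c("red", "blue"), alpha = 0.5)
  expect_equal(spec$series$color, c("red", "blue"))
  expect_equal(spec$series$alpha, c(0.5, 0.5))
  expect_error(manhattan_spec(ds, color = c("a", "b", "c")), "length")
  expect_error(manhattan_spec(ds, annotate = c(1e-8, 1e-8, 1e-8)), "length")
})

test_that("highlighted genes land at their cumulative midpoints", {
  tr <- simulate_gene_track(n_genes = 20, seed = 36)
  spec <- manhattan_spec(study$data, track = tr,
                         highlight_genes = c("GENE3", "GENE5"))
  expect_equal(nrow(spec$highlight), 2)
  lay <- genome_layout(study$data)
  for (i in 1:2) {
    g <- get_gene_coords(spec$highlight$gene_name[i], tr)
    expect_equal(spec$highlight$xmid[i],
                 unname(lay$offsets[g$chrom]) + (g$start + g$end) / 2)
  }
  expect_error(manhattan_spec(study$data, highlight_genes = "GENE3"),
               "track")
})

test_that("annotate_with_vline and rsids draw matching vertical lines", {
  spec <- manhattan_spec(study$data, annotate_with_vline = 1e-11)
  leads <- get_lead_snps(study$data, thresh = 1e-11)
  expect_equal(nrow(spec$labels), nrow(leads))
  expect_equal(sort(spec$vlines$POS), sort(leads$POS))
  id <- study$data$ID[which.min(study$data$P)]
  spec2 <- manhattan_spec(study$data, rsids_with_vline = id)
  expect_equal(spec2$labels$text, id)
  expect_equal(nrow(spec2$vlines), 1)
})

test_that("spec computation is deterministic and serialises to JSON", {
  s1 <- manhattan_spec(study$data, annotate = 1e-11)
  s2 <- manhattan_spec(study$data, annotate = 1e-11)
  expect_identical(spec_to_json(s1), spec_to_json(s2))
  parsed <- jsonlite::fromJSON(spec_to_json(s1))
  expect_equal(parsed$kind, "manhattan")
  expect_equal(parsed$hlines$p, 5e-8)
})

test_that("regionplot switches exon/gene structure exactly at 1 Mb", {
  tr <- simulate_gene_track(n_genes = 30, seed = 37)
  base <- list(chrom = "1", mid = 3e6)
  mk <- function(width, ...) {
    regionplot_spec(study$data, track = tr,
                    chrom = "1", start = 3e6 - width / 2,
                    end = 3e6 + width / 2, ...)
  }
  expect_true(mk(0.9e6)$show_exons)
  expect_false(mk(1.1e6)$show_exons)
  # show_genes overrides the rule in both directions
  expect_false(mk(0.9e6, show_genes = TRUE)$show_exons)
  expect_true(mk(1.1e6, show_genes = FALSE)$show_exons)
})

test_that("regionplot embeds the resolved region and pads genes", {
  tr <- genetrack(data.frame(chrom = "1", gene_start = 5e5, gene_end = 6e5,
                             gene_name = "GENE7", biotype = "protein_coding"))
  spec <- regionplot_spec(study$data, track = tr, gene = "GENE7")
  expect_equal(spec$region$start, 4e5)
  expect_equal(spec$region$end, 7e5)
  expect_equal(spec$region$label, "1:400000-700000")
  expect_equal(spec$axes$xlim, c(4e5, 7e5))
  # overview rectangle spans the same interval
  expect_equal(spec$overview$rect, c(4e5, 7e5))
  # all main-panel points lie inside the region
  expect_true(all(spec$points$x >= 4e5 & spec$points$x <= 7e5))
  expect_equal(spec$panels, c("overview", "main", "genes"))
})

test_that("tiny regions widen the overview rectangle to stay visible", {
  spec <- regionplot_spec(study$data, chrom = "1", start = 2e6, end = 2e6 + 10)
  span <- spec$overview$chrom_span
  expect_gte(diff(spec$overview$rect), 0.005 * span * 0.999)
})

test_that("locuszoom bins r2 into quintiles and singles out the index", {
  d <- get_snps_within_region(study$data, "1:1500000-2500000")
  d$R2 <- 0
  d$R2[seq_len(3)] <- c(0.1, 0.3, 0.9)
  d$R2[which.min(abs(d$POS - 2e6))] <- 1
  spec <- locuszoom_spec(as_gwas(d, label = "lz"))
  expect_equal(sum(spec$points$index), 1)
  bins <- spec$points$bin[seq_len(3)]
  expect_equal(bins, c("[0,0.2)", "[0.2,0.4)", "[0.8,1]"))
  # all-zero r2 collapses to the lowest bin
  d0 <- d; d0$R2 <- 0
  s0 <- locuszoom_spec(as_gwas(d0, label = "lz0"))
  expect_equal(unique(s0$points$bin), "[0,0.2)")
  # missing R2 errors with advice
  d$R2 <- NULL
  expect_error(locuszoom_spec(as_gwas(d, label = "nor2")), "pre-calculated")
})

test_that("effectplot marks dataset-2 significance and the identity case", {
  d <- as_gwas(data.frame(CHROM = "1", POS = c(1e6, 3e6), P = 1e-10,
                          REF = "A", ALT = "G", BETA = c(0.4, 0.2)),
               label = "d")
  spec <- effectplot_spec(d, d)
  expect_equal(spec$points$x, spec$points$y)  # identity line
  d2 <- as.data.frame(d); d2$P <- c(1e-10, 0.01)
  spec2 <- effectplot_spec(d, as_gwas(d2, label = "d2"))
  expect_equal(spec2$points$filled, c(TRUE, FALSE))
  # empty snpset renders axes only
  ss <- get_snpset(d, d)[0, , drop = FALSE]
  spec3 <- effectplot_spec(ss)
  expect_equal(nrow(spec3$points), 0)
  expect_s3_class(render_plot_spec(spec3), "ggplot")
})

test_that("all four kinds render and save to file", {
  tr <- simulate_gene_track(n_genes = 20, seed = 38)
  d2 <- paired_cohorts(study$data, flip_frac = 0.3, seed = 39)$data
  p1 <- manhattan(list(A = study$data, B = d2), ntop = 1, annotate = 1e-11,
                  track = tr)
  p2 <- regionplot(study$data, track = tr, region = "1:1500000-2500000",
                   annotate = 1e-9)
  dl <- get_snps_within_region(study$data, "1:1500000-2500000")
  dl$R2 <- pmin(1, pmax(0, 1 - abs(dl$POS - 2e6) / 1e6))
  p3 <- locuszoom(as_gwas(dl, label = "lz"), track = tr)
  p4 <- effectplot(study$data, d2, track = tr)
  expect_s3_class(p1, "ggplot")
  expect_s3_class(get_plot_spec(p1), "plot_spec")
  for (p in list(p1, p4)) {
    f <- withr::local_tempfile(fileext = ".png")
    save_plot(p, f, width = 6, height = 4)
    expect_gt(file.size(f), 1000)
  }
  fpdf <- withr::local_tempfile(fileext = ".pdf")
  save_plot(p2, fpdf, width = 6, height = 6)
  expect_gt(file.size(fpdf), 1000)
  f3 <- withr::local_tempfile(fileext = ".png")
  save_plot(p3, f3, width = 6, height = 5)
  expect_gt(file.size(f3), 1000)
  expect_error(save_plot(p1, withr::local_tempfile(fileext = ".bmp")),
               "format")
})
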