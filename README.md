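# gwasviz

Visualisation, annotation and comparison of GWAS summary statistics in R.

A genome-wide association study (GWAS) reports, for millions of variants, a
chromosome, a base-pair position, a p-value and usually alleles and an
effect size. Interpreting such results starts visually: a Manhattan plot of
`-log10(p)` across the genome to spot association peaks, a regional plot
with gene models to see which genes a peak covers, a locuszoom-style view of
the local linkage-disequilibrium (LD) structure, and — when a second cohort
exists for the same trait — a comparison of matched effect sizes. gwasviz
provides these displays for one or many datasets at once, together with the
table-level helpers behind them: lead-variant extraction, nearest-gene
annotation, region resolution, and cross-dataset variant matching with
allele harmonisation.

The package is aimed at analysts working with summary statistics (no
individual-level genotypes required): inputs are plain delimited tables with
at least `CHROM`, `POS` and `P` columns under flexible, case-insensitive
names (`chr`/`chrom`, `pos`/`bp`, `p`/`pval`, ...).

## What the core functions compute

**Lead (index) variants** — `get_lead_snps(data, thresh = 5e-8,
region_size = 1e6)` selects one variant per association peak: on each
chromosome the smallest p-value below `thresh` becomes a lead, every variant
strictly closer than `region_size / 2` bp is excluded, and the step repeats.
This greedy centred-window rule labels each peak exactly once, regardless of
where fixed genome bins would fall.

**Nearest gene** — `annotate_with_nearest_gene(variants, track)` returns the
overlapping gene (distance 0; the smallest-span gene if several overlap) or
the gene minimising the distance to its nearer boundary, with deterministic
alphabetical tie-breaking.

**Snpset** — `get_snpset(d1, d2)` compares two cohorts in four steps:
(1) extract the lead variants of `d1`; (2) pair them with `d2` rows at the
same `(CHROM, POS)`; (3) reconcile alleles — pairs matching exactly
(`REF1 = REF2`, `ALT1 = ALT2`) are kept, swapped designations
(`REF1 = ALT2`, `ALT1 = REF2`) flip the sign of `E2` and are kept,
anything else is set aside; (4) orient each pair so `E1 >= 0`. Odds ratios
are converted to betas (`beta = ln OR`) first. With `verbose = TRUE` the
three partitions — matched, not found by position, no allele match — are all
returned, and they always account for every lead exactly once.

**Plots** — `manhattan()`, `regionplot()`, `locuszoom()` and `effectplot()`
each first build a declarative, renderer-independent `plot_spec` (points,
shades, threshold lines, labels, axes — inspect it with `manhattan_spec()`
etc. or serialise it with `spec_to_json()`) and then render it with ggplot2.
Multiple datasets can be overlaid on one axis or split top/bottom with
`ntop`; per-dataset vectors control colours, annotation thresholds and label
aesthetics.

## Worked example

The package ships deterministic simulators, so a full analysis runs without
any download. Plant three association peaks, derive a second cohort with
known perturbations, and run the pipeline:

```r
library(gwasviz)

cd_a <- simulate_sumstats(
  n_background = 3000,
  peaks = list(peak_spec("1", 2e6,   min_p = 1e-12, effect =  0.30),
               peak_spec("2", 3e6,   min_p = 1e-11, effect = -0.25),
               peak_spec("3", 1.5e6, min_p = 1e-10, effect =  0.20)),
  seed = 7, label = "cohortA")
cd_b  <- paired_cohorts(cd_a, drop_frac = 0.10, flip_frac = 0.20,
                        effect_noise_sd = 0.02, seed = 8)$data
genes <- simulate_gene_track(n_genes = 40, seed = 7)

leads <- get_lead_snps(cd_a, thresh = 5e-8, region_size = 1e6)
annotate_with_nearest_gene(leads, genes)[, c("CHROM","POS","P","BETA","Gene_Symbol")]
#>   CHROM     POS     P       BETA Gene_Symbol
#> 1     1 2000000 1e-12  0.3316480      GENE14
#> 2     2 3000000 1e-11 -0.2518379      GENE10
#> 3     3 1500000 1e-10  0.2125563      GENE21
```

All three planted apexes come back as leads at exactly their planted
positions and p-values, each annotated with the gene the simulator placed
over it. Matching them against the derived cohort:

```r
get_snpset(cd_a, cd_b, verbose = TRUE)
#> <snpset_report> 3 lead variant(s): 3 matched, 0 not found by position,
#>                 0 with irreconcilable alleles

get_snpset(cd_a, cd_b)[, c("CHROM","POS","P1","E1","ALT1","REF1","P2","E2","ALT2","REF2")]
#>   CHROM     POS    P1        E1 ALT1 REF1    P2        E2 ALT2 REF2
#> 1     1 2000000 1e-12 0.3316480    G    A 1e-12 0.3265172    G    A
#> 2     2 3000000 1e-11 0.2518379    A    G 1e-11 0.2159508    A    G
#> 3     3 1500000 1e-10 0.2125563    G    A 1e-10 0.2662736    G    A
```

The chromosome-2 peak was planted with a negative effect: step 4 has
re-oriented it (`E1 = 0.252 >= 0`, alleles reported as `A`/`G` instead of
`G`/`A`), and the derived cohort's flipped rows have been harmonised back,
so `E2` differs from `E1` only by the injected noise. Regions resolve from
gene names with the default 100 kb flank on each side:

```r
resolve_region(track = genes, gene = "GENE14")
#> <region> 1:1698840-2026253 (327414 bp, from gene)
```

Figures follow the same pattern:

```r
manhattan(list(A = cd_a, B = cd_b), ntop = 1, annotate = 1e-9, track = genes)
regionplot(cd_a, track = genes, gene = "GENE14", annotate = 1e-9)
effectplot(cd_a, cd_b, track = genes)
```

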