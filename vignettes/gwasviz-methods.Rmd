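---
title: "Methods and design of gwasviz"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of gwasviz}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwasviz)
```

gwasviz turns GWAS summary statistics — per-variant tables of chromosome,
position, p-value, and usually alleles and effect sizes — into annotated
genome-wide and regional displays, and matches variants across cohorts for
effect-size comparison. This vignette records the package's model of the
data, the algorithms behind each operation, the parameter defaults and why
they were chosen, and the places where a design decision was genuinely open.

## The data model

A validated dataset (`as_gwas()`, `read_sumstats()`) has canonical columns
`CHROM`, `POS`, `P` plus optional `ID`, `REF`, `ALT`, `BETA`, `OR`, `R2`
and `GENE`. Column-name aliases are resolved case-insensitively, so files
from different pipelines (`chr`/`chrom`/`chromosome`, `pos`/`bp`/
`base_pair_location`, `p`/`pval`/`p_value`, ...) load without renaming.
Conventions applied at validation:

* **Coordinates are 1-based inclusive** throughout, matching the Ensembl
  convention gene tracks are distributed in.
* **Chromosomes** are normalised to `1`–`22`, `X`, `Y`, `MT` (any `chr`
  prefix stripped, `M` mapped to `MT`). The Manhattan layout needs a fixed
  ordering, so rows on other contigs are rejected with a warning rather
  than placed arbitrarily.
* **`P = 0` is clamped** to the smallest representable positive double and
  counted in the `n_clamped` attribute. Every display works on
  `-log10(P)`, which must stay finite; dropping such rows would silently
  remove the strongest signals.
* **`BETA` beats `OR`** when a file carries both; the odds-ratio column is
  ignored with a warning so an effect is never log-transformed twice.
* Rows failing validation (unparseable positions or p-values, `P` outside
  `[0, 1]`) are dropped per-row with a summarised reason, never silently.
* Output of `write_sumstats()` prints doubles at full precision (`%.17g`),
  so a write/read round trip reproduces the table exactly.

Duplicate `(CHROM, POS, ALT)` rows are retained at read time; how they are
resolved is an operation-level question (see the snpset section).

## Lead-variant selection

`get_lead_snps(data, thresh = 5e-8, region_size = 1e6)` implements "the top
variant per window" as a greedy exclusion process, not fixed genome
binning: per chromosome, take the unexcluded variant with the smallest
`P < thresh`, exclude everything strictly closer than `region_size / 2` bp,
repeat. Fixed bins split peaks that straddle a bin edge into two labels;
the greedy centred window yields one lead per peak, which is what a peak
label means. Two conventions make the procedure fully deterministic and
testable:

* p-value ties break towards the smaller position;
* the exclusion boundary is strict — a variant at exactly
  `region_size / 2` bp from a lead remains eligible, so same-chromosome
  leads are separated by at least (not more than) half a window.

The defaults (`5e-8`, the conventional genome-wide significance level, and
a 1 Mb window) govern both helper output and plot labelling density; both
are per-call and, on multi-dataset plots, per-dataset parameters.

## Nearest-gene annotation

`nearest_gene()` returns the overlapping gene with distance 0, else the
gene minimising the distance to its nearer boundary. Open choices, decided
and documented rather than left implicit:

* **Distance is unstranded bp to the nearer gene boundary**, not to the
  transcription start site. "Nearest gene" in GWAS figure captions
  conventionally means the nearest gene body; TSS distance is a
  fine-mapping notion, out of scope here.
* **Ties**: at exact equidistance the alphabetically first symbol wins;
  for a position inside several overlapping genes the smallest span wins
  (the most specific annotation), then alphabetical. Both rules exist so
  that annotation is reproducible across runs and platforms.
* **Biotype filter**: candidates default to `protein_coding`
  (`protein_coding_only = TRUE`), because peak labels are most useful as
  familiar coding symbols and Ensembl-style tracks are dominated by
  non-coding entries; the flag exposes the full track since which biotypes
  belong in a track is a property of the track, not of the algorithm.
* A chromosome with no candidate gene yields an `NA` sentinel, not an
  error: annotation of a table must not abort on one odd row.

Gene tracks load from a tab-delimited dialect (one row per gene,
comma-joined exon coordinate lists) or from GTF restricted to gene/exon
features via rtracklayer. Exons are validated against the gene span and
merged when overlapping.

## Regions

`resolve_region()` accepts a gene symbol, a variant identifier, a
`"chrom:start-end"` string (tolerating `chr` prefixes and thousands
separators) or an explicit triple. Gene regions take the gene span plus
`gene_padding = 100` kb on each side — wide enough to show the local LD
neighbourhood around a typical gene — clipped at position 1.
Variant-centred regions use `variant_flank = 100` kb per side, mirroring
the gene padding, since a comparable amount of context is wanted around a
point as around a span.

## The snpset pipeline

Cross-cohort comparison runs in four composable steps (`match_by_pos()`,
`match_by_alleles()`, `flip_to_positive_allele_for_dat1()`, composed by
`get_snpset()`), with `or_to_beta()` (`ln OR`) applied first where needed:

1. lead variants of dataset 1 at (`thresh`, `region_size`);
2. positional join against dataset 2 on `(CHROM, POS)`; leads with no
   partner are reported as *not found*;
3. allele reconciliation: identical `REF`/`ALT` kept as-is; swapped
   designations kept with `E2` negated and the alleles swapped into
   dataset 1's frame; anything else reported as *no allele match*;
4. orientation so every `E1 >= 0` (negating both effects and swapping both
   allele pairs where needed) — effects are then read "per dataset-1 risk
   allele".

Invariants maintained (and property-tested): the three partitions are an
exact partition of the leads; after the pipeline `REF1 = REF2`,
`ALT1 = ALT2` and `E1 >= 0` on every row; the swap transform is an
involution and orientation is idempotent.

Two deliberate restrictions:

* **No reverse-complement rescue.** Only literal identity and literal swap
  are accepted. Complement matching would silently "fix" strand-ambiguous
  A/T and C/G pairs, which is a classic source of undetected sign errors;
  irreconcilable rows are surfaced in the `no_allele_match` partition
  where they can be inspected instead. (The simulators avoid generating
  ambiguous pairs by default for the same reason.)
* **Multi-allelic positions** resolve in the allele step: at most one
  dataset-2 row can harmonise with a given lead's allele pair; if
  duplicates harmonise, the first in position-sorted order is kept with a
  warning.

The diagnostic partitions keep the original dataset-1 columns untouched so
a failed match can be traced to its source row.

## Plot architecture

Every figure is computed in two stages: a declarative `plot_spec` — point
coordinates, chromosome shades, threshold lines, labels with their final
positions, axes, legend — and a renderer that consumes only the spec.
Layout logic is therefore testable by direct inspection (and serialisable
with `spec_to_json()` for golden-file comparison) without pixel diffing,
and the renderer stays free of decisions. Numerical layout choices, none
of which had a single "correct" value:

* **Genome coordinates**: chromosome offsets are cumulative observed spans
  plus a fixed inter-chromosome gap of 0.3% of the genome span — visible
  as a separation but negligible as distortion. Ticks sit at chromosome
  midpoints; shades alternate.
* **Mirrored display**: `ntop` sends the first datasets up and the rest
  down as negated `-log10(P)`; the axis labels show magnitudes. The
  default is all-up overlap, the conventional display.
* **Significance lines**: one dashed line at `5e-8` by default; a vector
  draws several, `NULL`/`NA` removes them.
* **Labels**: collision handling is a greedy repel in spec coordinates —
  labels are processed in x order and pushed outward (away from the axis)
  until their text boxes are free. Deterministic, and user
  `nudge_x`/`nudge_y`/`angle` overrides are applied first and never
  undone.
* **Region plots**: overview:main:genes panel heights are 1:4:1; the red
  overview rectangle is drawn no narrower than 0.5% of the chromosome
  span, so a tiny region still appears as a visible line. Gene panels show
  exon boxes for regions narrower than 1 Mb and whole-gene glyphs
  otherwise (`show_genes` overrides); at 1 Mb and beyond, exon boxes would
  be sub-pixel. The resolved region string is embedded in the spec and
  printed on the plot so it can be pasted into
  `get_snps_within_region()`.
* **Locuszoom**: `r2` is consumed pre-computed and binned into the
  conventional quintiles `[0,0.2), ..., [0.8,1]`; a variant with `r2 = 1`
  is drawn as the distinct index marker. Computing LD requires genotypes
  and is explicitly out of scope.
* **Colours**: a fixed qualitative palette indexed by dataset order, so
  the same list order always gives the same colours; every aesthetic is
  per-dataset overridable.
* **Gene rows**: genes are packed greedily into rows by their
  label-extended intervals (label width estimated at 1.2% of region width
  per character), guaranteeing no within-row overlap.

## The synthetic-data generators

`simulate_sumstats()` emulates the structure the package operates on: a
uniform null background (`P ~ U(0,1)`, small Gaussian effects, unambiguous
allele pairs, `rs`-style IDs) plus planted peaks whose `-log10(P)` decays
linearly from the apex over a flank width, with the apex variant placed
exactly at the peak centre with exactly the apex p-value, and peak effects
sharing the apex sign. `simulate_gene_track()` produces non-pathological
gene models (5–200 kb spans, 2–10 disjoint exons, mostly protein-coding).
`paired_cohorts()` derives a comparison cohort with known row-level
manipulations (dropped positions, corrupted alleles, swapped-and-negated
allele designations, effect noise) and returns the ground-truth labels, so
the expected snpset partition is known exactly.

Defaults were chosen once as a realistic small study and not revisited: a
four-chromosome fixture genome (10/8/6/5 Mb — large enough for several
1 Mb windows per chromosome, small enough for millisecond tests), 25
variants per peak over a 250 kb flank (inside half the default selection
window, so one peak yields one lead), apex p-values around `1e-10`–`1e-12`
(comfortably genome-wide significant), apex effects of 0.2–0.3 on the beta
scale (typical for replicable complex-trait loci), and background effects
with SD 0.05.

What the generators deliberately do **not** emulate: linkage
disequilibrium (the decay profile is deterministic, not a function of
correlation), allele-frequency structure, genomic inflation, and
population stratification. Passing tests therefore demonstrate that
selection, annotation, matching and layout logic are correct on data of
the right shape — not that the package's statistical displays are robust
to every artefact of real cohorts. All generators are pure functions of
their parameters and a seed, and restore the caller's RNG state.

## Validation strategy and problem sizes

The test suite checks each algorithm against an independent brute-force
oracle written in the plainest possible style: greedy lead selection
against a delete-the-minimum scan (200 randomised tables of up to ~250
rows at several window sizes), nearest-gene against an exhaustive
per-gene distance loop (200 randomised tracks), positional matching
against a nested-loop join, and the snpset partition against the
ground-truth labels of randomised derived cohorts (100 trials). Planted
peaks separated by more than the selection window are recovered exactly —
count, positions and p-values — for one to five peaks. These sizes keep
the full suite under a minute while giving the oracles enough randomised
coverage to hit boundary cases (ties, equidistance, window edges), which
are additionally pinned by hand-constructed examples.

## Known limitations

* No liftover between genome builds; a dataset and its track must share
  coordinates. Tracks carry a build label, but it is informational.
* VCF/tabix ingestion is out of scope — inputs are delimited text.
* Allele matching does not use allele frequencies, so a genuinely
  strand-flipped ambiguous pair is indistinguishable from a swapped one
  and is conservatively excluded.
* The label-width estimate in gene packing and label repel is a
  character-count heuristic in data coordinates; extreme font or device
  choices can make rendered labels wider than their reserved extent.
* Meta-analysis across cohorts is not provided; the package compares and
  displays, it does not combine.
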