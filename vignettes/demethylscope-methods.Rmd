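---
title: "DemethylScope: models, conventions and design choices"
author: "DemethylScope authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DemethylScope: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific setting

DemethylScope implements the integrative analysis used to ask what global
loss of DNA methylation does to the regulatory landscape of a cancer
genome. The reference design contrasts a parental colorectal cancer line
(HCT116-like) with a derivative carrying knockouts of the maintenance and
de novo DNA methyltransferases (DKO1-like), in which CpG methylation is
almost entirely erased. The inputs are per-CpG methylation calls from
whole-genome bisulfite sequencing for both conditions, replicated ChIP-seq
peak sets for H3K4me3, H3K27ac, H3K4me1 and RNAPII, gene models with a
single transcript per gene, and normalized RNA-seq expression with
replicates.

The package's own contributions are the region-level methylation
summarization rules, the promoter/enhancer state classifications, the
two-condition enhancer comparison and its distance/intragenic analyses,
and a calibrated synthetic epigenome generator that provides ground truth
for every downstream operation. Standard machinery is delegated:
`GenomicRanges`/`IRanges` hold intervals and answer overlap and nearest
queries, `rtracklayer` reads and writes GTF/BED, `Biostrings` handles
sequences and degenerate-motif matching, and `stats::t.test` supplies the
built-in location test.

# Coordinate and distance conventions

All containers are `GRanges`, i.e. 1-based, closed intervals — the
Bioconductor convention. BED input/output (0-based, half-open) is converted
at the boundary by `rtracklayer`. Choosing the container library's native
convention, rather than converting internally to 0-based half-open, means
no interval arithmetic in the package ever re-derives an off-by-one.

Three conventions recur and are fixed once:

* **Overlap** means at least one shared base on the same chromosome;
  abutting intervals do not overlap, and no fractional-overlap threshold is
  applied anywhere.
* **Distance** from an anchor position to an interval is 0 if the anchor
  lies inside it and otherwise the coordinate gap to the nearest edge (an
  anchor one base outside an interval is at distance 1). Distances across
  chromosomes are undefined and reported as `NA`; medians are taken over
  reachable anchors only. Ties are broken by smaller target start, then
  end, then input order.
* **Promoter windows** are strand-oriented: the default -100/+700 window
  contains `upstream + downstream + 1` bases because it includes the TSS
  base itself. The proximity rule for peaks uses +/-2 kb around the TSS
  with both boundary bases included. Both windows are clipped at chromosome
  ends.

# Methylation summarization

A region's methylation is the unweighted mean of the methylated fraction
over the CpGs inside it that have at least `minCoverage` (default 3) reads
— a mean of per-CpG ratios, matching the ratio-style summarization used
with tag-density tooling in this field. A coverage-weighted variant is
available behind a flag. Regions with no qualifying CpG are `NA` and are
excluded from medians rather than imputed. Promoters are called highly
methylated when their mean strictly exceeds 0.5.

The binned profile (`methylationProfile()`) averages all (anchor, CpG)
pairs by strand-oriented offset in `[-flank, flank)` with 100-bp bins
(defaults 2,500/100); "2,500 bp surrounding" is read as +/-2,500 bp, i.e.
50 bins.

Random background regions are fixed-length (default 10 kb) intervals drawn
uniformly, chromosome-weighted by length, from a seeded RNG; the source
study does not state its procedure, so this simple design is the package's
own and is exposed as `sampleRandomRegions()`.

# Peaks, enhancers, and the two-condition comparison

Replicate consensus keeps the replicate-1 peaks that overlap at least one
replicate-2 peak, preserving peak identity (an intersection-coordinates
variant exists behind a flag). Enhancers are promoter-distal H3K27ac
consensus peaks: everything not overlapping a +/-2 kb TSS window.
Comparing two enhancer sets partitions each side into common versus
condition-unique by single-base overlap; common enhancers are reported in
condition A's coordinates, and because overlaps can be many-to-one the
B-side common count is reported alongside rather than forced to match.

Genomic compartments (exonic / intronic / intergenic) are assigned by the
peak midpoint with exon > intron precedence; using a single point gives
every peak exactly one label and makes pie-chart style summaries
conservation-safe. The same midpoint rule assigns intragenic enhancers to
genes, so `intronic + exonic = intragenic` holds per gene by construction.
The poised fraction is the share of condition-B-unique enhancers
overlapping at least one parental H3K4me1 peak.

# Expression classes

Gene classing uses mean `log2(x + 1)` of the normalized linear values per
condition; the source analysis does not state its pseudocount, so 1 is the
default and it is configurable. The rules, in order of precedence:

1. `not_expressed`: zero mean in both conditions ("expressed" means a
   positive mean in at least one).
2. `de_repressed`: log2 mean strictly below 1.5 in the parental condition
   and strictly above 2.5 in the demethylated one.
3. `up` / `down`: raw p below 0.05 and linear fold change strictly above
   1.2 in the corresponding direction; fold change is the ratio of
   per-condition means of linear values, and a gene with both means zero is
   `unchanged`.

De-repression takes precedence over ordinary up-regulation because the two
phenomena are reported separately (silent promoters that fire up versus
active genes that increase). The built-in test is a two-sided Welch t-test
on `log2(x + 1)` replicate values — a deliberate, documented stand-in for
the proprietary model-based test used upstream of the published thresholds;
externally computed p-values can be supplied and take precedence.

# Promoter characterization

A gene is a CGI promoter when its TSS base lies inside a supplied CpG
island interval. The TATA scan matches the degenerate `TATAWAW` motif
(W = A/T) with at most one mismatch, sense strand only, with the motif
start constrained to offsets -40..-20 relative to the TSS (the sequence's
last base). `N` never matches. The scan is sense-strand only because
strandedness is not discussed in the reference analysis; scanning the
reverse complement is a caller-side one-liner on the sequence set.

# The synthetic epigenome generator

`simulateEpigenome()` produces the package's study conditions. Defaults:
2 chromosomes of 10 Mb, 2,000 genes on fixed 10-kb slots, uniform CpG
density 0.01/bp (~2x10^5 CpGs), Poisson(10) coverage per CpG and condition
(so the 3x filter actually removes a ~1% tail), and planted classes of 120
de-repressed, 80 up, 160 down and 100 silent genes — the published
genome-scale class proportions, scaled to desk size so every class stays
well populated.

**Promoter methylation** is bimodal: a two-beta mixture with mode means
0.03 and 0.90 (concentrations 4 and 1.2) whose high-mode weight is
calibrated analytically (`calibrateMixture()`) so the mixture median equals
the 30% target. Per-promoter levels are drawn as stratified per-mode
quantiles (random assignment to genes), not i.i.d. draws: with only 2,000
promoters and a between-modes median, an i.i.d. sample median has a
standard deviation of several percentage points, while stratified
quantiles pin the population median at desk scale without touching the
distribution's shape. De-repressed genes receive high-mode promoters
(levels >= 0.7); up/down genes receive low-mode promoters, matching the
biology that their parental promoters were not methylation-silenced.

**Gene bodies and background** target a median of 84%. Body levels are
solved per gene so that the whole-span mean (including the promoter and
enhancer CpGs that fall inside the span) hits a stratified beta target;
intergenic levels are stratified beta quantiles with a single additive
shift calibrated by bisection so that the median over internal random
10-kb regions hits 84%. Each CpG then gets additive N(0, 0.04) noise,
clipped to [0, 1].

**The demethylated condition** is the parental value scaled per
compartment, with the promoter/body/background factors calibrated by
bisection against the residual targets (medians 0.5%, 13%, 9%), multiplied
by lognormal noise (sd 0.1 on the log scale) and capped at the parental
value — so the per-site inequality `derived <= parental` is a hard
guarantee, not a statistical tendency.

**Peaks.** Parental H3K4me3/RNAPII/H3K27ac sit at unmethylated promoters.
Common and parental-unique distal H3K27ac enhancers are placed in
intergenic, intronic and exonic positions (0.50/0.45/0.05) at least 2.3 kb
from every TSS and carry low parental methylation; new (B-unique)
enhancers inherit the methylated background, so they are parental-
methylated by construction. 40% of up genes host 1-5 new intragenic
enhancers (59% of hosts get more than one, emulating enhancer spreading;
8% of intragenic midpoints are exonic via small planted exons), and 47% of
all new enhancers receive a parental H3K4me1 peak. 40% of de-repressed
genes gain a B-unique promoter H3K4me3 peak and 13% of the remainder carry
a common one. Replicate 1 of every peak set carries the planted
coordinates and replicate 2 is jittered by up to 25 bp per edge; since
consensus keeps replicate-1 coordinates, planted intervals are recovered
exactly, which is what makes exact ground-truth round-trip tests possible.

**Expression** uses 2 replicates per condition (the study's design) with
lognormal replicate noise of sd 0.1 on the log2 scale. Planted log2
effects for up/down genes are drawn from U(1.0, 2.5): at this noise the
2-vs-2 Welch test has ~0.8-0.98 power, so whole-table class recovery sits
near 98% — above the 95% contract but deliberately below 100%, keeping
misclassification accounting honest. De-repressed genes draw parental
levels in U(0, 1.4) and demethylated levels in U(2.6, 6), leaving a small
boundary-crossing tail for the same reason.

**What the generator does not emulate:** real CpG spatial clustering
(islands are planted as annotation intervals, not as dense CpG runs),
sequence-driven nucleosome or motif structure, copy-number variation,
multi-transcript genes, overlapping genes, and read-level artifacts.
Passing tests therefore certify the analysis logic and its calibration
contracts, not performance on the idiosyncrasies of real bisulfite or
ChIP-seq data.

# Numerical choices and degenerate inputs

* All generator calibrations (mixture weight, background shift,
  per-compartment residual factors) are monotone 1-D problems solved by
  bisection (45 iterations) against step functions of medians; boundary
  values are returned when a target is unattainable.
* `builtinDeTest()` returns 1 for identical constant groups, the smallest
  representable positive double for different constant groups, and
  otherwise the Welch p-value; with fewer than 2 replicates per side it
  errors.
* Fold change with a zero baseline mean is `Inf` (classified by the p/fc
  rule as usual); with both means zero the gene is `unchanged`.
* Empty peak sets, empty CGI tracks and empty TSG lists are legal inputs
  and produce empty/NA results rather than errors; an empty target set for
  a nearest query and an empty set of new enhancers for the poised
  fraction are errors, since their results would be meaningless.
* Medians over regions exclude `NA` (uncovered) regions; a compartment
  with no covered region at all is an error.

# Problem sizes

The default generator (2,000 genes, 2x10^5 CpGs x 2 conditions) runs in a
few seconds; the full analysis adds a few seconds more. The test suite's
property checks run 100 random instances per interval operation with
n, m up to ~1,000 for the nearest-distance check and smaller sizes for the
quadratic oracles; these sizes were chosen to exercise the algorithms well
past their edge cases while keeping the whole suite at around three
minutes on one CPU.

# Known limitations

* One transcript model per gene; alternative TSSs are approximated only
  through the distance-based alternative-promoter scan.
* The built-in expression test is not the proprietary model-based test the
  published thresholds were derived with; supply external p-values to
  reproduce such analyses faithfully.
* Enhancer-gene linkage is proximity-based (nearest TSS, 20-kb windows,
  intragenic midpoints); no chromatin-contact information is used.
* The Venn-style comparison counts each side against the other by overlap,
  so with many-to-one overlaps the two common counts differ; both are
  reported, neither is "the" number.
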