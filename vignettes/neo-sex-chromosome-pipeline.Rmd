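---
title: "Detecting and characterizing neo-sex chromosomes with neoXY"
author: "neoXY package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and characterizing neo-sex chromosomes with neoXY}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages({
    library(neoXY)
    library(GenomicRanges)
    library(SummarizedExperiment)
})
```

## The biological problem

Neo-sex chromosomes arise when an ancestral X fuses with an autosome.  The
fused autosomal arm (the neo-XR) gains a male-limited homolog (the neo-Y)
that progressively stops recombining, accumulates fixed differences,
repeats and loss-of-function mutations, and eventually degenerates.  Two
genomic signatures make the process detectable in ordinary male/female
population resequencing data:

* **Hemizygosity** (the ancestral X arm, here called XL): males carry one
  copy, so male:female coverage is near 0.5 and male heterozygosity is
  near zero.
* **A non-recombining stratum** (the neo-XR/neo-Y region): both sexes are
  diploid (coverage ratio near 1), but every fixed X-Y difference appears
  as a heterozygous call in every male, so male heterozygosity is elevated
  by roughly the X-Y divergence, while females show only background
  polymorphism.

`neoXY` implements the full downstream analysis as composable R functions:
a windowed coverage/heterozygosity scan with confidence-band outlier
flagging and region calling; a hard-filter cascade for genotype calls;
clustering of phased haplotypes to separate the X- and Y-linked
(gametologous) haplotypes, with haploid regenotyping and consensus
coding-sequence extraction; codon-aware alignment and Nei--Gojobori (1986)
dN/dS; ORF-disruption (pseudogene) scoring; whole-genome alignment-block
filtering and rearrangement classification; and sex-differential repeat
statistics.  A ground-truthed simulator (`simulateNeoXY()`) generates the
synthetic populations every stage is validated on.

## The synthetic data generator

`simConfig()` fixes the study conditions.  The defaults describe a 10 Mb
neo-X carrying a 3 Mb hemizygous XL arm and a 2 Mb non-recombining stratum
with 1% fixed X-Y divergence (`xySnpDivergence = 0.01`), 0.05% X-Y indels,
0.1% background polymorphism, four males and four females at 20x expected
depth, plus a 5 Mb autosome — divergence an order of magnitude above
polymorphism and a comfortably detectable hemizygous arm, the regime the
method is designed for.  Genes (default 30 in the stratum, 20 elsewhere;
300--900 bp CDSs ending in a stop) are written into the reference; each
stratum gene's Y copy accrues the stratum's fixed differences and, with
probability `pseudogenizationRate` (default 0.4), one unambiguous
disruption: a premature stop introduced by a single substitution or a
1--2 bp frameshift, with equal probability.  Male genotypes in the stratum
are emitted phased with the X and Y haplotypes in randomized order per
male, and the generator records which haplotype is the Y, the Y allele at
every stratum site, per-gene truth coding sequences and labels, repeat
hits per sex, and a rearranged alignment-block set with known labels.

Three modelling choices deserve mention.

* **Coverage is drawn as Poisson depth totals per fixed tile** (1 kb by
  default): the sum of per-base Poisson counts is itself Poisson, so every
  windowed statistic the scan consumes has exactly the distribution it
  would have under a per-base simulation, at a fraction of the cost.  Read
  placement, mapping bias and GC effects are deliberately not modelled.
* **The neo-Y is clonal**: all males share one Y haplotype.  Y
  polymorphism is far below X-Y divergence in a non-recombining region and
  would only perturb the clustering distances slightly.
* **Structural events are placed so they remain identifiable.**  A
  translocated or duplicated segment re-inserted where the query order
  remains collinear is in principle indistinguishable from the syntenic
  backbone by any order-based classifier, so the generator re-seats such
  segments at order-breaking junctions.  Event sizes (10--40 kb) are at
  least twice the 2 kb alignment-length filter.

Consequently, passing tests demonstrate correctness of the *inference
machinery* under an idealized error-free genotype model — they do not
establish robustness to mapping artifacts, reference bias, or
misassembly, which real data add on top.

## The scan: windowed contrasts, confidence band, region calling

`windowStats()` tiles the genome (100 kb windows by default in the
examples; the real analyses that motivated the design used 100 kb--1 Mb)
and computes per-sample normalized coverage and heterozygosity.  Coverage
is normalized by each sample's genome-wide *median* window depth, so the
autosomal expectation is 1.0 regardless of sequencing effort; this
achieves the comparability that read subsampling to a common depth would,
without touching reads.  Heterozygosity is heterozygous calls over
callable sites, callable being bases with nonzero depth; windows with
fewer than `minCallable` callable sites get `NA`.

`sexDiffTable()` reduces this to per-window male/female means, the F-M
coverage difference, M/F coverage ratio, and M-F heterozygosity
difference.  `flagOutlierWindows()` draws a genome-wide 95% band for each
contrast and flags windows outside it.  The band is
`median +/- z * MAD` (z the two-sided normal quantile) rather than raw
percentiles of the window distribution: a sex-linked region can easily
occupy 10--20% of a small genome, in which case the empirical 2.5%/97.5%
percentiles sit *inside* the signal windows and most of the region escapes
flagging, whereas median and MAD are unaffected by a minority of signal
windows.  On homogeneous noise the two constructions agree (about 5% of
windows flagged at `ciLevel = 0.95`); the robust band is also exactly
antisymmetric under swapping the sex labels.  When the MAD degenerates to
zero the standard deviation is used; if that is also zero nothing is
flagged and a warning is raised.

`callRegions()` joins runs of at least `minRun = 3` flagged windows
(bridging up to `maxGap = 1` unflagged windows per gap) and classifies each
candidate from its pooled evidence:

* **homogametic** (male-hemizygous): mean M/F coverage ratio at most 0.75
  and male heterozygosity below female;
* **heterogametic** (diverged X/Y): coverage ratio within [0.85, 1.15] and
  male heterozygosity at least 1.5 times female;
* anything else is dropped with a warning, and conflicting evidence
  (hemizygous coverage *with* male heterozygosity excess) is called
  homogametic with a warning.

The thresholds are not taken from any publication — the theoretical
signals (ratio 0.5 for hemizygosity; heterozygosity equal to divergence
plus polymorphism against polymorphism alone) sit far inside the accept
windows — and all are exposed as arguments.  The classification step doubles
as the false-positive control: under a null simulation spurious flag runs
occasionally occur, but they essentially never satisfy a class rule, so no
region is called.

```{r scan-example}
cfg <- simConfig(seed = 1)
bundle <- simulateNeoXY(cfg, components = character())
ws <- windowStats(bundle@coverage, bundle@sex,
                  variants = bundle@variants, windowSize = 1e5)
regions <- callRegions(flagOutlierWindows(sexDiffTable(ws)))
regions
regionLengthMb(regions)
```

## The hard-filter cascade

`filterVariants()` applies the usual heuristics for short-read genotype
calls, in order: (1) site QUAL < 30 or mean genotype depth < 3; (2) any
heterozygous genotype with depth < 4; (3) site QUAL < 50 with a homozygous
genotype of depth < 4; then, with the dataset mean depth computed over all
genotypes at sites surviving rules 1--3: (4) heterozygous sites with
QUAL below twice the mean depth; (5) sites whose maximum genotype depth
exceeds `mean + 3 * sqrt(mean)` (likely collapsed repeats or copy-number
variants); (6) sites inside a repeat mask.  Each removed site carries the
first rule it violated, and the result is independent of input order.
Where the underlying heuristics are quoted per-"variant" the rule is
applied at site level (rule 1 uses the mean genotype depth at the site);
where they are quoted per-genotype (rules 2, 3, 5) any offending genotype
condemns the site.  The mean depth in rules 4--5 is the dataset-wide mean
over rule-1..3 survivors, the convention of the depth-based artifact
filters this cascade follows.

## Phasing-based gametolog separation

Within a candidate heterogametic region, every male's phased genotypes are
split into two haplotype rows (`haplotypeMatrix()`; unphased male
heterozygotes are refused, since the X/Y split would be meaningless).
Pairwise distances are mismatch fractions over co-called sites (at least
`minSites = 20` shared sites per pair), clustered by average-linkage
hierarchical clustering and cut into two groups.  The Y cluster must
contain exactly one haplotype from every male and no female haplotype —
the defining property of a male-limited chromosome — and the separation
score (mean between-cluster over mean within-cluster distance) must reach
`minSeparation = 3`; otherwise the region is reported `ambiguous`
(criterion violated) or `rejected` (no usable divergence).  With fixed X-Y
differences an order of magnitude above polymorphism the separation is
typically 10-fold or more.

`regenotypeHaploid()` then maps each male's genotype onto haploid X and Y
panels (females contribute both haplotypes to the X panel), and
`extractGametologPairs()` builds per-gene consensus X and Y coding
sequences by substituting majority haploid alleles — substitutions and
indels — into the reference CDS, reverse-complementing minus-strand genes.
Consensus ties break toward the smaller allele index (the reference).
Genes are assigned `sex-linked` only when their full CDS span lies inside
a heterogametic region; genes straddling a boundary are conservatively
assigned to the pseudo-autosomal region with a warning.

## Divergence: codon alignment, NG86, saturation filters

`alignCodons()` is a global Needleman--Wunsch over codon units (+2 for
amino-acid identity, -1 otherwise, -4 per codon gap, ties broken
diagonal-then-up), which keeps gaps in frame by construction.  `ng86()`
implements Nei--Gojobori (1986) counting: fractional synonymous sites from
single-nucleotide neighbourhoods averaged between the two codons;
difference counts averaged over all orderings of the minimal mutation
paths, excluding paths through stop codons (a column whose every path hits
a stop is skipped and flagged); Jukes--Cantor correction
`d = -3/4 log(1 - 4p/3)`, undefined at `p >= 3/4`.  A counting estimator
was chosen over a maximum-likelihood codon model deliberately: the
downstream use is descriptive (medians, saturation filters, a two-region
test), for which NG86 is standard, transparent, and testable against
exhaustive enumeration.

`filterPairs()` retains pairs with `dS < 2` and `omega < 10` — beyond
that, substitution saturation makes the estimates unreliable — keeping
`dS = 0` pairs for dS summaries while excluding them from omega summaries.
`summarizeRegions()` reports per-region medians and Welch's
unequal-variance t test (Welch--Satterthwaite degrees of freedom,
two-sided) on dS and on omega; the unequal-variance form is used because
region pair counts and variances differ.  Frameshifted Y copies (length
not a multiple of 3) are excluded from dN/dS with a `frameshifted` flag:
their garbled reading frame has no meaningful synonymous/nonsynonymous
decomposition.

## Pseudogene (ORF-disruption) scoring

`detectDisruptions()` aligns a candidate Y copy to its parent CDS — at
codon granularity when lengths match, else by nucleotide-level global
alignment — and records (i) a *frameshift* at every gap run after which
the cumulative gap length stops being a multiple of 3 (a later
compensating gap does not cancel the event: the intervening peptide is
already garbled), and (ii) every *premature stop* in the candidate's
reading frame strictly before the terminal codon, positions reported in
the parent frame.  The parent's terminal stop is not a disruption.
`classifyPseudogenes()` calls a copy nonfunctional iff any disruption is
found, and `degenerationProportion()` summarizes the nonfunctional
fraction with an exact binomial interval.  Because parentage is known in
this pipeline's data model, candidates are compared directly to their
annotated parent CDS; no homology search is performed.  A known blind
spot: two compensating indels that leave the total length unchanged can be
absorbed by the aligner as mismatches and escape detection — no
alignment-based detector can resolve that case reliably.

## Rearrangement classification

`filterBlocks()` keeps alignment blocks with at least 95% identity and
2 kb of reference span.  `classifyBlocks()` then applies, per block:
*inversion* for minus-strand blocks on the corresponding chromosome
(correspondence by majority of aligned bases); *syntenic* for members of
the longest collinear chain (longest increasing subsequence on query
starts within each reference chromosome); *duplication* for off-chain
blocks whose query interval reciprocally overlaps (>= 50%) another kept
block's; *translocation* otherwise.  Deciding chain membership before the
duplication/copy split matters: of two copies of one source segment, the
one sitting in the backbone keeps its syntenic role regardless of which
has the smaller coordinate, so a copy inserted upstream of its source is
still the one labelled duplication.  This is deliberately a simplified
order/orientation/copy scheme, validated against the package's own
simulator — not a re-implementation of a full structural-variant model
(no nested events, no inverted duplications).  `countBlockVariants()`
counts SNPs as mismatched non-gap columns and indels as maximal gap runs
(one event per run, the natural unit when quoting events per Mb), with
per-Mb medians over 1 Mb reference bins.

## Repeats

`repeatDensityWindows()` reports the percent of repeat-derived bases per
window after merging overlapping hits (a base counts once).
`compareRegionDensity()` contrasts inside- versus outside-region window
densities with a two-sided Mann--Whitney U test with continuity
correction, switching to the exact test when both sides have at most 8
windows.  `sexEnrichment()` computes both directional male/female
abundance ratios and calls a family enriched at the conventional 1.1-fold
threshold, inclusive (a ratio of exactly 1.1 is a call); abundances must
be percent of assayed bases in both sexes or percent of reads in both —
never mixed.  `divergenceLandscape()` bins repeat base pairs by percent
divergence to consensus in 1% bins, as percent of assayed genome bases, so
bin masses sum to the total repeat fraction.

## Numerical and degenerate-input conventions

* Coordinates are GRanges-style 1-based closed everywhere inside the
  package; conversion to and from 0-based half-open (BED, PAF) and 1-based
  (VCF, RepeatMasker, show-coords) happens only in the readers and
  writers, which are round-trip identities on the fields the pipeline
  consumes.
* All simulator randomness flows from the single `simConfig()` seed, with
  per-component derived seeds so that regenerating a subset of components
  is reproducible; the same seed yields byte-identical output files.
* Degenerate inputs have defined behaviour rather than surprises: an
  all-constant contrast flags nothing (warning); all-identical haplotypes
  are `rejected`; a Welch test on two zero-variance groups returns t = 0,
  p = 1 when the means agree; all-tied density comparisons return p = 1;
  a repeat family absent in both sexes is skipped with a warning; zero
  female abundance with male presence yields an infinite ratio and a call.
* Tests and examples run at deliberately desk-sized problem sizes — a
  10 Mb neo-X with a 2 Mb stratum, 4+4 samples at 20x, tens to hundreds of
  genes, 3 Mb block sets — chosen so the binomial/Poisson expectations the
  checks rely on are tight while a full test run stays fast.

## Known limitations

Genotype calling, read mapping, phasing, genome assembly, gene prediction
and de novo repeat discovery are out of scope: the pipeline consumes their
outputs (VCF with phased GT, coverage tracks, GFF3, RepeatMasker tables,
PAF/show-coords blocks).  The simulator's idealizations (no genotyping
error beyond the depth model, clonal Y, uniform placement of differences,
identifiable rearrangements) mean measured accuracies are upper bounds for
real data.  The dN/dS estimator assumes equal mutability across sites and
no transition/transversion bias; the Jukes--Cantor correction saturates
near p = 3/4, which the saturation filters are there to catch.
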