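---
title: "Comparative methylome analysis with methCompare: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative methylome analysis with methCompare: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

methCompare implements a comparative analysis of whole-genome bisulfite
sequencing (BS-seq) methylomes across cell lines: per-cytosine methylation
calling with sequence-context classification, cross-line conservation and
strand-symmetry statistics, window-based differential methylation with a
permutation FDR, bisulfite-aware heterozygous SNP calling, allele-specific
expression (ASE) and allele-specific methylation (ASM) testing with
read-backed phasing, and a methylation-sensitivity screen for
transcription-factor binding sites (TFBS). This vignette documents the
statistical models, the defaults and why they were chosen, the synthetic
data the package tests itself against, and the limits of what those tests
demonstrate.

## Methylation calling and context classification

Bisulfite treatment converts unmethylated cytosine to uracil (read as T);
methylated cytosine stays C. A Watson-derived fragment therefore reports on
plus-strand cytosines (read C = methylated, T = unmethylated); a
Crick-derived fragment, stored in plus-strand orientation, reports on
minus-strand cytosines via plus-strand G positions (G = methylated,
A = unmethylated). `callMethylation()` counts, for every genomic cytosine
on each strand, informative reads of the matching bisulfite strand; the
methylation level of a site is meth/(meth + unmeth). Bases other than the
C/T (or G/A) pair — sequencing errors or allele mismatches — are ignored.

Context is classified from the two bases downstream of the cytosine on its
own strand: CG if the next base is G; CHG if the base after next is G; CHH
otherwise (H = A, C, T). Two finer labels are carried per site: the
dinucleotide (CG/CA/CC/CT) and whether the strand-local 5-mer at offsets
-2..+2 reads TACAG, the non-CG motif whose methylation is elevated and
conserved across lines. Cytosines too close to the chromosome edge to be
classified are excluded.

A read showing three or more consecutive methylated non-CG calls (counted
along the read's own non-CG cytosine positions, regardless of genomic
gaps) is treated as having escaped conversion and is discarded before
piling. The read-order definition matches the failure mode it targets:
a fully unconverted molecule shows a run of retained Cs no matter how far
apart the cytosines sit on the genome.

`globalLevels()` reports, for each context label, the unweighted mean of
per-site levels over sites covered by at least `minCoverage` reads
(default 4). We read the per-cytosine phrasing of the summary statistic as
a mean of per-site ratios; a read-pooled alternative
(`pooled = TRUE`, summed meth over summed totals) is provided because the
two differ when coverage correlates with methylation.

## Conservation, motifs, splice sites and symmetry

For two lines, jointly covered sites are binned — CG sites into
low [0, 33], medium [34, 66] and high [67, 100] percent (the percent is
rounded first so the integer bin edges partition exactly); non-CG sites
into none (no methylated read), low (0, 30] and high (30, 100] — and the
observed 3x3 table is compared with the independence expectation
(row total x column total / grand total). Fold = observed/expected; a site
is conserved when it falls in the same bin in both lines. For motif
analysis, non-CG sites are split into conserved-high (high in both),
unconserved-methylated (high in exactly one line and none in the other —
the strict reading of "methylated in one, unmethylated in the other") and
unmethylated classes; `buildFlankPfm()` accumulates strand-oriented base
counts at offsets -k..+k and `tacagFraction()` reports the fraction of
sites inside a TACAG 5-mer.

`spliceSiteProfile()` measures coding-strand CHG density and high-level
(> 30%) fractions at offsets around exon junctions; at 3' splice sites
offset -1 is the last intronic base (the acceptor G) and the exon starts
at offset 0, so the acceptor's C sits at offset -3 and is CHG by
construction of the canonical CAG acceptor.

Strand symmetry uses 2x2 tables over dyads: for CG, the plus-strand C at i
and the minus-strand C at i+1; for CHG, the plus-strand CHG at i paired
with the minus-strand CHG whose C pairs with the G at i+2 — which requires
the central base to be A or T, so asymmetric CCG/CGG trios are excluded on
both sides. The default methylation "status" is level > 0 at coverage >= 4
(the statement of status is unqualified, so the weakest binarization is
the default); the low/high strata reuse the printed 30% boundary. The
symmetric fraction is the concordant (diagonal) fraction of the table.

## Differentially methylated regions

Chromosomes are tiled with 1-kb windows; a window's level per line is the
unweighted mean of its qualifying CG sites (>= 5 sites covered >= 4x;
windows with fewer sites are treated as missing, since a ratio of means
over a handful of sites is dominated by binomial noise). For a pair of
lines, r = (higher mean + 0.01)/(lower mean + 0.01) — the pseudocount
guards against division by zero — and r is standardized over all jointly
non-missing windows; windows with Z > 2 are differentially methylated.
Z is computed on raw ratios as stated ("Z score of this ratio"); a
log-ratio option is available behind a flag. Conserved DMRs are windows
flagged in all three pairwise comparisons.

The FDR of the conserved fraction is estimated by permutation: each of
300 rounds independently shuffles each line's vector of window means over
its non-missing windows (a genome-wide shuffle; the multiset of means is
asserted unchanged every round), re-runs the three pairwise calls and the
overlap, and the FDR is the mean null conserved fraction over the observed
one. Feature enrichment of a region set is base-pair fold enrichment
against promoter/exon/intron/CpG-island tracks, with shores derived as
2-kb island flanks minus islands, and promoters defined as TSS +/- 1 kb
(a promoter definition is otherwise unstated).

## Bisulfite-aware SNP calling

At a heterozygous site the two alleles must be distinguished in reads that
have themselves been rewritten by bisulfite chemistry. Observations that
are conversion-ambiguous carry no allele information and are excluded: at
a genomic C, a Watson read's C or T (the pair a converted/unconverted C
produces); at a genomic G — a minus-strand C — a Crick read's G or A.
Per-allele counts are the average of the Watson and Crick tallies; the
reported `count1`/`count2` are on that strand-averaged scale, while the
filters are applied to the raw summed evidence. A position is called
heterozygous when raw coverage >= 8, the two main alleles carry more than
75% of the coverage, and their counts differ by at most 20% of their sum
(a major-allele ratio of at most 0.6).

Two structural consequences follow. First, a C/T SNP at a genomic C (or
G/A at a G) loses one whole strand of evidence to the ambiguity rule, so
the two main alleles can no longer reach 75% of coverage: this class is
structurally uncallable, and the synthetic truth marks it so recovery is
measured on the callable remainder. Second, the 20%-balance rule is a
binomial constraint on the allele split of the covering reads: with n
reads and a fair 50/50 allele draw, the pass probability is
P(|2X - n| <= 0.2 n) with X ~ Bin(n, 1/2), which is ~0.80 at n = 30 and
reaches 0.95 only around n = 100. At 30x coverage the caller's recall is
therefore capped near 80% by the filter itself, independent of
implementation — the package reports this honestly rather than relaxing
the filter.

## Allele-specific expression

Heterozygous SNPs inside exon blocks with at least 4 RNA reads across the
two alleles are exonic SNPs; the allele with more RNA reads is the major
allele. Per gene, major and minor counts are summed over its exonic SNPs
(major defined per SNP; a haplotype-consistent mode would require phasing
RNA alleles, which the procedure does not describe, so per-SNP orientation
is the default) and tested against Binomial(n, 1/2) with the exact
two-sided minimum-likelihood convention: the P-value is the total
probability of outcomes no more probable than the observed one (with the
customary 1 + 1e-7 tie tolerance). Significance is Benjamini-Hochberg
control at 1% FDR; `calibrateThreshold()` reports the largest significant
P — the computable analog of a fixed printed cutoff such as 0.0027.
Enrichment of a positive-control list (e.g. imprinted genes) among the
significant genes is an upper-tail hypergeometric test.

## Allele-specific methylation and phasing

Reads covering a heterozygous SNP are segregated by the allele they show;
observations that are conversion-ambiguous at the SNP (a C allele seen as
C/T by a Watson read, a G allele seen as G/A by a Crick read) are left
unassigned. CG cytosines covered by both allele groups are candidates.
The test estimates p from one group (unsmoothed, as stated; degenerate
p in {0, 1} is handled exactly through the point-mass distribution), tests
the other group's methylated count against Binomial(n, p) two-sided, swaps
the groups, and records the larger P-value — a symmetric statistic by
construction. BH control at 5% flags differentially methylated cytosines;
the flagged fraction of candidates is reported. Because alleles are not
phased across SNPs, each candidate is tested per anchor SNP and a cytosine
linked to several SNPs keeps the best-covered anchor. The plug-in estimate
ignores the uncertainty of p-hat, which makes the test mildly
anti-conservative at low per-allele depth; calibration holds on pure-null
batches and in the read-based default simulation, and the sensitivity
condition is stated at per-allele depth >= 10.

Gene-level enrichment (genes with >= 3 tested cytosines, upper-tail
binomial of the significant count at the genome-wide significant rate,
BH 5%) is an invented statistic: the source procedure reports enriched
genes without a formula, and this is the simplest calibrated choice given
per-gene site counts. `phaseMethylation()` reports, per allele, the
methylated fraction at every CG site that shares a read with the SNP —
the read-backed reconstruction of the two parental methylation patterns.

## TFBS methylation-sensitivity screen

For a pair of lines, each binding site's methylation is the unweighted
mean of covered CG cytosines inside the interval; its neighbor methylation
is the same over +/-500 bp excluding the site. Sites kept are those with
expression data for the assigned gene and |delta methylation| >= 0.1 (the
default operationalization of "where differential methylation was
observed"; configurable down to > 0). Per motif, Pearson r and P are
computed for delta methylation versus delta log2(expression + 1) — the
log2(x+1) scale is a choice, with a raw-scale flag — and the same against
neighbor deltas. A motif passes filters with >= 10 kept sites and site
P < 0.05, and is called methylation-sensitive when additionally
|r_site| > |r_neighbor|. Motifs sharing a TF are kept separate.

## The synthetic-data generator

Every analysis is tested against `simulateStudy()`, which plants known
truth:

* **Genome and annotation.** Random sequence at 41% GC; 20 multi-exon
  genes per 100 kb (3-6 exons of 80-200 bp, introns 200-600 bp) whose
  introns end in canonical AG acceptors — 70% carry the full TACAG
  acceptor, so the acceptor-relative -3 position is a CHG cytosine with
  elevated methylation; CpG-island rewrites strictly upstream of 60% of
  promoters; one 8-mer binding site (two CpGs) upstream of each selected
  gene.
* **Diploid.** Heterozygous SNPs at 1e-3 per bp; 15% are C>T at C (G>A at
  G) — the structurally uncallable class that exercises the ambiguity
  rule — and the rest are A<->T substitutions, which bisulfite chemistry
  leaves fully observable on both strands. Transitions such as A>G are
  deliberately not planted: the G allele genuinely reads as A on
  unmethylated Crick fragments, so their recovery would measure chemistry,
  not the caller.
* **Methylation.** CG dyads draw from the bimodal mixture
  0.25 Beta(1, 9) + 0.75 Beta(9, 1); 77% of dyads share one probability
  across strands (per-line jitter is drawn once per shared dyad so the
  sharing stays exact); non-CG sites draw from Beta(0.5, 15) except TACAG
  sites, Beta(2.2, 7.8) (mean 0.22). Per-line jitter is Gaussian
  (sd 0.03, clipped to [0, 1]). Planted on top: pairwise DMR windows (one
  line's CG probabilities shifted down 0.4), conserved DMR windows (lines
  set to 0.80/0.45/0.22, a spacing chosen so each pairwise ratio is an
  outlier without dominating the genome-wide ratio sd that the Z-score
  standardizes against), ASM genes (allele 1 at probability 1, allele 2
  at 0 over gene-body CG sites — the fully methylated versus fully
  unmethylated chromosome picture), optional conserved-high non-CG TACAG
  sites, line-specific non-CG sites, and per-line binding-site methylation
  levels on a 0.01 grid.
* **Reads.** Post-alignment, fixed-length, ungapped, plus-orientation;
  allele and bisulfite strand uniform per read; per-cytosine conversion
  Bernoulli; a per-read non-conversion rate (0.5% of reads fully
  unconverted, giving the filter true positives); uniform substitution
  errors (0.2%). Expression is built as
  log2(e + 1) = base + effect x site methylation + noise, so a planted
  effect with zero noise yields exactly |r| = 1 on the analysis scale, and
  RNA allele counts are Binomial(depth, bias) with bias 0.9 for planted
  ASE genes.

Identical configurations produce byte-identical outputs; every stage
draws from a seed offset of the single configured seed.

**What the simulation does not emulate** — and hence what green tests do
not show about real data: alignment and mapping bias (reads are emitted
pre-aligned), indels and structural variation, PCR duplicates and quality
scores, M-bias along reads, CNVs, context-dependent error profiles,
correlated methylation beyond the planted block structure, and real
inter-individual SNP spectra (transitions dominate real data but are
excluded by design, above). Recovery rates measured here are upper bounds
on real-data behavior.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run: the default 100-kb /
30x study for calling, SNP and symmetry checks; a 500-kb, ~500-window
three-line study with 10 + 5 planted DMRs and 300 permutations for the DMR
suite; a 30-kb dense-SNP (8e-3), 60x study for ASM and phasing; a 300-kb,
120-gene, one-site-per-gene study for the TFBS screen; calibration nulls
at 500-1000 units. These sizes were chosen so each statistic has enough
events for its tolerance (e.g. >= 1000 TACAG sites for the 0.22 +/- 0.02
mean check) while a full run stays in minutes on one core.

Numerical conventions: exact tests use the minimum-likelihood two-sided
convention with a 1 + 1e-7 tie tolerance; the hypergeometric tail is
P(X >= k); BH is `p.adjust(.., "BH")` with significance at adjusted
p <= q; CG bins round the percent before comparison; the DMR ratio uses
pseudocount 0.01; empty classes and labels are reported as missing
(`NA`), never zero; sites covered in one line but not the other are
excluded from two-line tables.

## Known limitations

* SNP recall at 30x is bounded near 80% by the 20%-balance filter (the
  binomial argument above); the package keeps the published filter.
* The ASM plug-in test is anti-conservative at per-allele depth below ~10;
  interpret site calls jointly with depth, as the enrichment and phasing
  stages do.
* The per-SNP anchor in `asmScan()` can test a cytosine against different
  anchor SNPs in different runs only if coverage ties change; ties are
  broken by combined depth.
* `featureEnrichment()` measures base-pair overlap, not site-weighted
  overlap; CpG-dense features are therefore conservative.
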