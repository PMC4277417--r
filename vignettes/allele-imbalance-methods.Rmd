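---
title: "Methods: binomial allele imbalance in F1 hybrids"
author: "asekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: binomial allele imbalance in F1 hybrids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asekit)
```

## The design and its assumptions

`asekit` targets one specific, statistically clean design: an F1 hybrid of
two *inbred* parents, one of which is the reference strain. Under that
design every variant distinguishing the parents is heterozygous in the
hybrid, the alternative allele always belongs to the alternative parent,
and no phasing is ever required. All downstream machinery leans on this
assumption — it is why parental transcript pairs can be built by simply
substituting all variants at once (`apply_variants()`), and why a single
genotype filter (`1/1` on alternative-parent reads, `0/1` on hybrid reads)
suffices when merging per-sample variant calls.

The package deliberately does not perform alignment, read trimming or
variant calling; it consumes their standard outputs (FASTA, GTF, VCF,
mpileup base columns, transcript count tables) and owns everything after:
masking, parental sequences, effects, the imbalance statistics, and the
query layer.

## The imbalance test

For heterozygous counts $(r, a)$ the test is exact binomial against a
symmetric null:

$$p = \min\!\left(1,\; 2\,P\!\big(X \ge \max(r,a)\big)\right),
\qquad X \sim \mathrm{Bin}(r+a, 1/2).$$

Because $p_0 = 1/2$, the doubled symmetric tail is identical to the
standard two-sided exact test; the test suite asserts agreement with R's
`binom.test` to $10^{-9}$ over the full grid $0 \le r,a \le 200$. The test
is conservative by discreteness: at coverage 100 the realized size at
$\alpha = 0.05$ is about 0.035, which the calibration tests bound inside
$[0.03, 0.055]$.

**Undefined p-values.** Counts below `min_het = 20` yield `NA` rather than
a weak p-value — 20 reads is the customary floor for adequate power in
this literature. The rule is applied per library, three times over:

* a SNP needs a library sum of heterozygous reads $\ge 20$;
* a transcript/gene (SNP-coverage measure) needs *at least one member SNP*
  with $\ge 20$ in that library;
* a transcript/gene (read-count measure) needs a rounded parental read
  count sum $\ge 20$.

`NA` never satisfies any p-value filter in the query layer.

**Directions and flags.** A direction is `ref>alt`, `alt>ref`, or `tie`;
ties carry no direction and can never trigger a flag. Two flags mark
internally inconsistent entities:

* *replicate discordance* — a replicate pointing opposite to its library
  sum is tested against the *rest* of the sum (not the total, which would
  double-count the replicate) with a 2x2 chi-square without continuity
  correction; $p < 0.05$ flags the entity. Zero marginals short-circuit to
  "no flag", and a single replicate is vacuously concordant.
* *opposite SNPs* — a transcript is flagged when one library holds at
  least two significant SNPs ($p < 0.05$) in opposite directions. Such
  transcripts often reflect isoform-specific regulation and deserve
  inspection rather than a pooled p-value.

## SNP clustering and the window parameter

Summed SNP coverage over-counts reads that span several SNPs. `asekit`
clusters SNPs greedily left-to-right in *spliced-transcript* coordinates:
a SNP joins the current cluster when its spliced distance to the cluster's
previous member is at most `window`; each cluster contributes only its
representative (highest total heterozygous coverage across libraries,
ties to the 5'-most member) to transcript and gene sums.

The window default is 100 bases — the read length of the sequencing
designs this models — and it is measured along the spliced transcript
because that is the space reads traverse; two SNPs in adjacent exons can
be covered by one read even when they are kilobases apart genomically.
`window = 0` recovers naive (un-deduplicated) summation exactly, which the
tests use as a limit check. Genomic-versus-spliced clustering and the
window size are exposed as configuration because reasonable pipelines
differ here.

At the gene level, the spec-level notion of "spliced coordinates" has no
unique meaning, so the union of exonic SNPs across the gene's transcripts
is clustered on the gene's *merged exon union* treated as a
pseudo-transcript. Gene read counts are the sums of its transcripts'
parental counts; the gene span runs from the leftmost transcript start to
the rightmost end, and all variants in that span are listed for the gene
while only exonic SNPs enter coverage sums (the counts are RNA-derived).

## Parental sequences and effects

Reference spliced sequences come straight from the genome and annotation;
the alternative-parent sequence substitutes each variant's reference span
with its alternative allele, applied in descending spliced coordinate so
upstream positions are unaffected by indel length changes, with
minus-strand alleles reverse-complemented. Variants spanning an
exon–intron boundary are excluded with a warning: partial application is
not well defined and silent truncation would corrupt the sequence.

Proteins are translated with the standard genetic code from the annotated
CDS start; on the alternative haplotype the CDS start is shifted by the
net length change of variants wholly 5' of it, and translation runs to the
*first* stop codon wherever it falls. A lost stop therefore lengthens the
alternative protein into the 3' UTR and an indel-shifted frame shortens
it — the annotated CDS end is intentionally not trusted on the edited
sequence.

Internal effect classification covers the basic vocabulary
(5'/3' UTR, missense, synonymous, stop gained/lost, intron, non-coding),
decided by codon comparison at the variant position. CDS-overlapping
indels are labelled `coding_sequence_variant` and left to external
annotators (VEP, snpEff), whose files can be imported; SIFT "deleterious"
and snpEff impact `HIGH` mark variants damaging, and imported annotations
replace internal ones for the same variant–transcript pair. The test
suite validates the internal classifier against a brute-force oracle that
edits the genome, rebuilds both haplotype proteins and diffs them, across
both strands and every anatomy class.

## GO-set trimming

Enrichment scores are redundant across GO levels (a child is part of its
parent). The trim keeps, among terms enriched below the threshold
(default 0.001, the conventional enrichment cutoff), exactly those terms
$n$ such that

1. no enriched proper descendant has a strictly smaller p-value (the
   effect would live below $n$), and
2. no enriched proper ancestor has a p-value $\le p(n)$ (the enrichment
   would be inherited).

Ancestry is the transitive closure of `is_a` and `part_of`. The asymmetry
between the strict and non-strict comparison is deliberate: an exact tie
along a chain resolves to the more general (ancestral) term, so the rule
is well defined for ties, and kept terms can never stand in an
ancestor–descendant relation — which makes the trim idempotent by
construction. Diamond-shaped ancestries with interleaved scores are not
fully determined by the two informal rules; the closure-based conditions
above are one consistent completion, verified against a brute-force
reachability oracle on random DAGs.

## The synthetic-study generator

`sim_config()` defaults encode the study conditions the package models:
4 libraries (tissues) x 4 replicates, ~2 SNPs/kb within genes, 10% indels,
mean per-replicate SNP coverage 60, a 100-base read scale, and a residual
reference-bias offset `delta = 0.014` — the small bias that survives
masking (a 51.4/48.6 split at balanced theta). Imbalanced genes (30% by
default) are planted at `theta = 0.8` and `0.2` in alternation, so the
expected genome-wide bias is set by `delta` alone.

Genes are built from a transcript-oriented template: 5' UTR, an initial
ATG, codon-aligned stop-free CDS chunks separated by introns, a terminal
stop, 3' UTR. Isoforms share the first and last exon and differ by
skipping internal CDS exons; because chunk boundaries sit on codon
boundaries and chunks are stop-free, every isoform's CDS stays in frame
and translates cleanly. Minus-strand genes are the template
reverse-complemented into the genome, which exercises all coordinate
arithmetic. Indels are restricted to UTRs and introns, clear of
boundaries. Ground-truth labels (region, effect per isoform, theta,
expression weight) are first-class outputs computed from the template
geometry — an independent path from the package's own classifier, so
truth is never re-derived through the code under test.

Counts are sampled per SNP, replicate and library as
$\text{total} \sim \mathrm{Pois}(\text{coverage})$,
$\text{ref} \sim \mathrm{Bin}(\text{total}, \theta + \delta)$; parental
transcript counts follow the same scheme with expression weights halving
by isoform index (planting the ranks), plus a $\pm 0.3$ fractional jitter
on estimated counts that exercises half-up rounding without moving the
rounded integer.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: read-level alignment artifacts (mapping
errors concentrate at specific loci, not uniformly), overdispersion
across replicates beyond Poisson, position-correlated counts for SNPs
sharing reads (counts are drawn independently; clustering behaviour is
exercised by construction instead), allele-specific splicing, and
false-positive or missed variant calls. Conclusions about calibration on
real libraries still require the usual diagnostics.

## Numerical and degenerate-input choices

* Estimated counts are rounded half-up (`floor(x + 0.5)`) before testing:
  the binomial needs integers and half-up is reproducible across
  platforms.
* Isoform ranks order by descending total reads (reference + alternative
  + non-variant mass when a totals table is supplied, otherwise summed
  parental counts) with ties broken by transcript id, so rank 1 is always
  unique.
* `ref + alt = 0` is an error for the bare test, an `NA` result in
  table-building (below threshold); `compute_bias` on zero reads errors.
* Consensus merging deduplicates each sample on (chrom, pos, ref, alt)
  before counting, making the result invariant under sample order; the
  genotype filter requires the expected call in at least `min_samples`
  occurrences (the spec-level alternative — all occurrences — is stricter
  than the sources justify).
* Multi-allelic VCF records split into one variant per alternative
  allele; the inbred design implies one alternative per site, but
  splitting preserves generality.
* Internal coordinates are 1-based inclusive throughout (GTF/VCF native);
  BED's 0-based half-open convention appears only at the file boundary.

## Problem sizes in the test suite

The suite runs entirely on generated fixtures: exhaustive oracle grids up
to counts of 200, per-base classifier sweeps over two hand-built genes on
both strands plus ~1,300 randomized SNPs over 30 simulated genes, 100
random DAGs for the GO oracle, and an end-to-end study of 50 genes with
4 libraries x 3 replicates whose planted imbalance and bias are recovered
against analytic binomial expectations. These sizes were chosen so each
property is measured with comfortable statistical margin while the whole
suite stays fast enough to run on every change.

## Known limitations

* Effects are basic; splice-site and regulatory consequences only arrive
  via external annotators.
* Frameshift consequences are not predicted beyond stop scanning on the
  shifted alternative CDS.
* No multiple-testing adjustment is applied: raw p-value thresholds
  mirror the reporting conventions of the studies this models, and the
  query layer exposes the thresholds rather than hiding a correction.
* The binomial model treats replicate sums as homogeneous; biological
  overdispersion will make real type-I error exceed the nominal level,
  which is one reason the replicate-discordance flag exists.
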