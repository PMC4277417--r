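# asekit

Allele-specific expression (ASE) analysis for F1 hybrids of inbred parents.

## The problem

When an F1 hybrid is formed from two inbred strains and one of them is the
reference strain, every variant site that distinguishes the parents is
heterozygous in the hybrid and the parental origin of each allele is known:
reference allele = reference parent, alternative allele = alternative
parent. RNA-seq reads covering those sites therefore measure the expression
of each parental allele directly, and a site, transcript or gene whose
allele counts deviate from 1:1 shows *allele imbalance* (AI) — the raw
material for studies of cis-regulation, imprinting and heterosis.

Two practical obstacles stand between raw counts and trustworthy AI calls:

* **Reference bias** — reads carrying alternative alleles map less well to
  a single reference genome, inflating reference counts. The standard
  mitigation is to mask every known SNP position with `N` before aligning.
* **Non-independent SNPs** — a read spanning several nearby SNPs is counted
  once per SNP; summing per-SNP counts over a transcript then overweights
  it. `asekit` clusters SNPs that lie within a read length of each other
  *along the spliced transcript* and counts one representative per cluster.

## The statistic

For heterozygous counts `(ref, alt)` the test is the exact two-sided
binomial test of `ref` successes in `n = ref + alt` trials against
`p0 = 1/2`. Because the null is symmetric this equals the doubled tail

```
p = min(1, 2 * P(X >= max(ref, alt))),   X ~ Binomial(n, 1/2).
```

Counts below 20 give an *undefined* p-value (exact tests have too little
power there; 20 reads is the field's customary floor), applied per library
to SNP coverage sums and to parental-transcript read counts alike. Entities
are additionally flagged when a replicate points significantly the other
way from its library sum (2x2 chi-square, replicate vs rest) and when one
library holds significant SNPs in both directions.

Around the test sit the supporting computations: consensus merging of
per-sample variant calls, `N`-masked genome construction, parental
transcript/protein sequence building (substituting SNPs and indels into
the reference isoforms), basic variant-effect classification (UTR /
missense / synonymous / stop / intron), import of VEP or snpEff
annotations with SIFT-deleterious / HIGH-impact marked as damaging,
isoform ranking, a filterable query layer with table set-algebra, and a
trimming algorithm that reduces a redundant set of enriched GO terms to
the terms primarily responsible for the enrichment in their sub-tree.

## Worked example

Everything is testable without downloads: the package ships a
deterministic generator that emulates a hybrid study (multi-exon,
multi-isoform genes on both strands; homozygous-alternative-parent
variants; binomial allele counts with configurable allelic ratio, coverage
and residual reference bias).

```r
library(asekit)
dir <- tempfile()
simulate_ase_study(sim_config(seed = 42, n_genes = 12,
                              n_libraries = 2, n_replicates = 3), dir)
db <- load_ase_study(dir)
summary(db)
```

```
Allele-specific expression overview
  genes: 12 (12 with >=1 SNP, 0 with >=1 indel)
  transcripts: 21 (16 with >=1 SNP)
  SNPs: 20; covered (>=1 library): 20; AI (p<0.05): 10
  substitution classes (%): CG=35.0 CA=20.0 AG=15.0 CT=15.0 AT=10.0 AC=5.0
  variant effects (Count / Covered / AI):
    3_prime_UTR_variant           3        6      4 (67%)
    intron_variant               10       20     11 (55%)
    missense_variant              5       10      4 (40%)
    synonymous_variant            2        4      0 (0%)
  replicate-discordant: 1 SNPs, 0 transcripts
  opposite-direction-SNP transcripts: 0
  reference bias: 49.0%/51.0%
```

Reading the overview: 10 of the 20 simulated SNPs are allele-imbalanced at
p < 0.05 in at least one library (this fixture plants imbalance at
theta = 0.8/0.2 in ~30% of genes); "Covered" in the effect table is
library-weighted (a SNP covered in both libraries contributes 2, so the
maximum is 2 x Count here), and the AI percentage is relative to Covered.
The bias line is the pooled reference-allele fraction.

Querying works on plain tables — for example, the most likely isoform of
each gene with read-count imbalance in library 1:

```r
hits <- filter_table(entity_table(db, "transcript"),
                     rank = 1, p = list("read_count:lib1" = 0.01))
hits[, c("transcript_id", "rank", "p_read_lib1", "dir_read_lib1")]
```

```
   transcript_id rank  p_read_lib1 dir_read_lib1
1        g001.t1    1 1.892580e-17       ref>alt
5        g003.t1    1 1.776109e-13       ref>alt
20       g011.t1    1 1.015744e-16       alt>ref
21       g012.t1    1 1.570654e-17       alt>ref
```

Undefined p-values print as `NA` and never satisfy a p-value filter.
`export_selection()` writes any table as TSV, or the paired `_R`/`_A`
parental transcript and protein FASTA records for protein-folding
comparison of the two alleles.

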