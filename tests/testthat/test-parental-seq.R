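vrow <- function(chrom, pos, ref, alt) {
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             vtype = ifelse(nchar(ref) == 1 & nchar(alt) == 1, "snp",
                            "indel"), stringsAsFactors = FALSE)
}

test_that("splicing concatenates exons and reverse-complements minus", {
  genome <- c(c1 = "ATGCCCGGG")
  tp <- transcript_model("t1", "c1", "+",
                         exons = rbind(c(1L, 3L), c(7L, 9L)))
  expect_identical(splice_transcript(genome, tp), "ATGGGG")
  tm <- transcript_model("t1", "c1", "-",
                         exons = rbind(c(1L, 3L), c(7L, 9L)))
  expect_identical(splice_transcript(genome, tm), "CCCCAT")
  tb <- transcript_model("t1", "c1", "+", exons = cbind(8L, 12L))
  expect_error(splice_transcript(genome, tb), "beyond")
})

test_that("toy transcripts splice and translate consistently", {
  tp <- toy_plus()
  sp <- splice_transcript(tp$genome, tp$t)
  expect_identical(sp, "GGGATGGCATTAGACGAAGGCTAACCCCCCCCCCCC")
  cr <- cds_spliced_range(tp$t)
  expect_equal(cr, c(4L, 24L))
  expect_identical(translate_cds(sp, cr[1L]), "MALDEG")
  tm <- toy_minus()
  expect_identical(splice_transcript(tm$genome, tm$t), sp)
  expect_identical(translate_cds(splice_transcript(tm$genome, tm$t),
                                 cds_spliced_range(tm$t)[1L]), "MALDEG")
})

test_that("variant substitution handles SNPs, deletions and identity", {
  t <- transcript_model("t1", "c1", "+", exons = cbind(1L, 6L))
  pr <- apply_variants(t, "ATGCCC", vrow("c1", 4, "C", "T"))
  expect_identical(pr$alt_seq, "ATGTCC")
  pr2 <- apply_variants(t, "ATGCCC", vrow("c1", 3, "GCC", "G"))
  expect_identical(pr2$alt_seq, "ATGC")
  pr3 <- apply_variants(t, "ATGCCC", vrow("c1", 1, "A", "T")[0L, ])
  expect_identical(pr3$alt_seq, pr3$ref_seq)
})

test_that("minus-strand variants are applied as reverse complements", {
  tm <- toy_minus()
  ref_seq <- splice_transcript(tm$genome, tm$t)
  # genome-forward SNP at the base mapping to spliced position 5 (the T
  # of ATG GCA...); find its genomic position via the package mapping,
  # then check content directly
  gpos <- spliced_to_genomic(tm$t, 5L)
  gbase <- substr(tm$genome[["c1"]], gpos, gpos)
  pr <- apply_variants(tm$t, ref_seq, vrow("c1", gpos, gbase, "A"))
  expect_identical(substr(pr$alt_seq, 5L, 5L), "T")  # revcomp of A
  expect_identical(substr(pr$ref_seq, 5L, 5L), substr(ref_seq, 5L, 5L))
})

test_that("substitution rejects mismatches, overlaps, boundary spans", {
  t <- transcript_model("t1", "c1", "+", exons = cbind(1L, 6L))
  expect_error(apply_variants(t, "ATGCCC", vrow("c1", 4, "G", "T")),
               "mismatch")
  expect_error(apply_variants(t, "ATGCCC",
                              rbind(vrow("c1", 3, "GCC", "G"),
                                    vrow("c1", 4, "C", "T"))),
               "overlapping")
  t2 <- transcript_model("t2", "c1", "+",
                         exons = rbind(c(1L, 4L), c(8L, 10L)))
  expect_warning(
    pr <- apply_variants(t2, "ATGCCCC", vrow("c1", 4, "CAT", "C")),
    "splice boundary")
  expect_identical(pr$alt_seq, pr$ref_seq)
  expect_equal(pr$skipped, "c1:4:CAT>C")
})

test_that("substitution agrees with the sequential one-at-a-time oracle", {
  set.seed(23)
  for (fixture in list(toy_plus(), toy_minus())) {
    t <- fixture$t
    genome <- fixture$genome
    ref_seq <- splice_transcript(genome, t)
    for (rep in 1:20) {
      # pick 1-3 exonic SNPs plus possibly a small exonic deletion
      sp_pos <- sample(seq_len(spliced_length(t) - 3L), sample(1:3, 1))
      sp_pos <- sp_pos[!duplicated(sp_pos)]
      sp_pos <- sp_pos[order(sp_pos)]
      if (length(sp_pos) > 1L && any(diff(sp_pos) < 4L)) {
        sp_pos <- sp_pos[c(TRUE, diff(sp_pos) >= 4L)]
      }
      vars <- do.call(rbind, lapply(sp_pos, function(sp) {
        gpos <- spliced_to_genomic(t, sp)
        ref <- substr(genome[[t$chrom]], gpos, gpos)
        vrow("c1", gpos, ref, sample(setdiff(c("A", "C", "G", "T"), ref),
                                     1L))
      }))
      pr <- apply_variants(t, ref_seq, vars)
      expect_identical(pr$alt_seq, h_apply(t, ref_seq, vars))
      # length bookkeeping
      expect_equal(nchar(pr$alt_seq),
                   nchar(ref_seq) + sum(pr$applied$alt_len -
                                          pr$applied$ref_len))
    }
  }
})

test_that("translation walks the standard code and stops at stops", {
  expect_identical(translate_cds("ATGGCATAA", 1L), "MA")
  expect_identical(translate_cds("ATGTAACCC", 1L), "M")
  expect_identical(translate_cds("ATGGC", 1L), "M")  # partial codon
  expect_error(translate_cds("AT", 1L), "codon")
  expect_error(translate_cds("ATG", 7L), "beyond")
})

test_that("effect classification covers the transcript anatomy", {
  tp <- toy_plus()
  ref_seq <- splice_transcript(tp$genome, tp$t)
  cls <- function(pos, ref, alt) {
    classify_effect(vrow("c1", pos, ref, alt), tp$t, ref_seq)$term
  }
  expect_equal(cls(2, "G", "C"), "5_prime_UTR_variant")
  expect_equal(cls(45, "C", "G"), "3_prime_UTR_variant")
  expect_equal(cls(15, "T", "G"), "intron_variant")
  # codon GCA (spliced 7-9, genomic 7-9): GCA->GAA is A->E missense
  expect_equal(cls(8, "C", "A"), "missense_variant")
  # GCA->GCG stays Ala
  expect_equal(cls(9, "A", "G"), "synonymous_variant")
  # TTA (Leu) -> TAA stop at genomic 11
  expect_equal(cls(11, "T", "A"), "stop_gained")
  # the stop codon TAA (genomic 38-40) -> CAA Gln
  expect_equal(cls(38, "T", "C"), "stop_lost")
  expect_error(cls(200, "A", "C"), "outside")
})

test_that("non-coding transcripts and CDS indels classify correctly", {
  genome <- c(c1 = "ATGCCCGGGTTT")
  tnc <- transcript_model("nc1", "c1", "+", exons = cbind(1L, 9L))
  expect_equal(classify_effect(vrow("c1", 3, "G", "A"), tnc,
                               "ATGCCCGGG")$term, "non_coding_variant")
  tp <- toy_plus()
  ref_seq <- splice_transcript(tp$genome, tp$t)
  eff <- classify_effect(vrow("c1", 22, "AC", "A"), tp$t, ref_seq)
  expect_equal(eff$term, "coding_sequence_variant")
})

test_that("classification agrees with translate-and-diff on both strands", {
  set.seed(41)
  for (fixture in list(toy_plus(), toy_minus())) {
    t <- fixture$t
    genome <- fixture$genome
    ref_seq <- splice_transcript(genome, t)
    span <- transcript_span(t)
    for (pos in span[1L]:span[2L]) {
      ref <- substr(genome[[t$chrom]], pos, pos)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
      v <- vrow(t$chrom, pos, ref, alt)
      expect_equal(classify_effect(v, t, ref_seq)$term,
                   h_classify(genome, t, v),
                   info = sprintf("%s pos %d %s>%s", t$strand, pos, ref,
                                  alt))
    }
  }
})

test_that("external VEP and snpEff effects map damaging flags", {
  vep <- write_tmp(c(
    "## ENSEMBL VARIANT EFFECT PREDICTOR",
    paste("#Uploaded_variation", "Location", "Allele", "Gene", "Feature",
          "Feature_type", "Consequence", "Extra", sep = "\t"),
    paste("rs1", "c1:10", "T", "g1", "t1", "Transcript",
          "missense_variant", "SIFT=deleterious(0.01)", sep = "\t"),
    paste("rs2", "c1:20", "G", "g1", "t1", "Transcript",
          "missense_variant", "SIFT=tolerated(0.4)", sep = "\t"),
    paste("rs3", "c1:30", "A", "g1", "t2", "Transcript",
          "weird_new_term", "-", sep = "\t")), ".txt")
  eff <- import_external_effects(vep, "vep")
  expect_equal(eff$damaging, c(TRUE, FALSE, FALSE))
  expect_equal(eff$term[3L], "weird_new_term")   # passed through verbatim
  expect_equal(eff$source, rep("vep", 3L))
  expect_equal(eff$pos, c(10L, 20L, 30L))

  snpeff <- write_tmp(c(
    paste("chrom", "pos", "ref", "alt", "transcript_id", "effect",
          "impact", sep = "\t"),
    paste("c1", "10", "C", "T", "t1", "NON_SYNONYMOUS_CODING", "HIGH",
          sep = "\t"),
    paste("c1", "20", "A", "G", "t1", "SYNONYMOUS_CODING", "LOW",
          sep = "\t")), ".tsv")
  eff2 <- import_external_effects(snpeff, "snpeff")
  expect_equal(eff2$damaging, c(TRUE, FALSE))
  expect_equal(eff2$term, c("missense_variant", "synonymous_variant"))
  bad <- write_tmp("not\ta\tvep\tfile", ".txt")
  expect_error(import_external_effects(bad, "vep"), "unrecognized")
})

test_that("parental pairs translate identically without CDS variants", {
  tp <- toy_plus()
  # only UTR/intron variants
  v <- rbind(vrow("c1", 2, "G", "C"), vrow("c1", 15, "T", "G"),
             vrow("c1", 45, "C", "G"))
  pairs <- build_parental_pairs(tp$genome, list(gp1 = tp$gene), v)
  p <- pairs$tp1
  expect_identical(p$ref_protein, "MALDEG")
  expect_identical(p$alt_protein, "MALDEG")
  expect_false(identical(p$ref_seq, p$alt_seq))
  # a missense SNP implies different proteins
  v2 <- vrow("c1", 8, "C", "A")
  p2 <- build_parental_pairs(tp$genome, list(gp1 = tp$gene), v2)$tp1
  expect_false(identical(p2$ref_protein, p2$alt_protein))
  # a UTR5 deletion shifts the CDS start but not the protein
  v3 <- vrow("c1", 1, "GG", "G")
  p3 <- build_parental_pairs(tp$genome, list(gp1 = tp$gene), v3)$tp1
  expect_identical(p3$alt_protein, "MALDEG")
})

test_that("parental FASTA export writes suffixed records", {
  tp <- toy_plus()
  pairs <- build_parental_pairs(tp$genome, list(gp1 = tp$gene),
                                vrow("c1", 8, "C", "A"))
  d <- tempfile()
  paths <- write_parental_fasta(pairs, d)
  expect_length(paths, 4L)
  nt_ref <- read_fasta(file.path(d, "transcripts_ref.fa"))
  nt_alt <- read_fasta(file.path(d, "transcripts_alt.fa"))
  expect_named(nt_ref, "tp1_R")
  expect_named(nt_alt, "tp1_A")
  aa <- read_fasta(file.path(d, "proteins_alt.fa"))
  expect_identical(unname(aa[["tp1_A"]]), pairs$tp1$alt_protein)
})
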