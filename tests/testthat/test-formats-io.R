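test_that("FASTA reading joins lines, upper-cases and preserves order", {
  f <- write_tmp(c(">c1 first contig", "ac", "gt", ">c2", "NN"), ".fa")
  seqs <- read_fasta(f)
  expect_identical(names(seqs), c("c1", "c2"))
  expect_identical(unname(seqs[["c1"]]), "ACGT")
  expect_identical(unname(seqs[["c2"]]), "NN")
  expect_identical(unname(attr(seqs, "descriptions")[["c1"]]),
                   "first contig")
})

test_that("FASTA reader rejects empty files and duplicate ids", {
  f <- tempfile(fileext = ".fa")
  file.create(f)
  expect_error(read_fasta(f), "empty")
  f2 <- write_tmp(c(">c1", "A", ">c1", "C"), ".fa")
  expect_error(read_fasta(f2), "c1")
})

test_that("FASTA write/read round-trips canonical records", {
  seqs <- c(alpha = "ACGTACGTACGTACGTACGTACGTACGT", beta = "NNNNAC")
  f <- tempfile(fileext = ".fa")
  write_fasta(seqs, f, width = 10L)
  back <- read_fasta(f)
  expect_identical(unname(back[names(seqs)]), unname(seqs))
})

test_that("GTF exons and CDS are grouped into transcripts and genes", {
  f <- write_tmp(c(
    "# comment",
    paste("c1\tsrc\texon\t100\t150\t.\t+\t.",
          'gene_id "g1"; transcript_id "t1";', sep = "\t"),
    paste("c1\tsrc\texon\t200\t250\t.\t+\t.",
          'gene_id "g1"; transcript_id "t1";', sep = "\t"),
    paste("c1\tsrc\tCDS\t120\t150\t.\t+\t0",
          'gene_id "g1"; transcript_id "t1";', sep = "\t")), ".gtf")
  genes <- read_gtf(f)
  expect_named(genes, "g1")
  t1 <- genes$g1$transcripts$t1
  expect_equal(unname(t1$exons), rbind(c(100L, 150L), c(200L, 250L)),
               ignore_attr = TRUE)
  expect_equal(unname(t1$cds), rbind(c(120L, 150L)), ignore_attr = TRUE)
})

test_that("GTF errors carry the offending line and strand violations", {
  f <- write_tmp(paste("c1\tsrc\texon\t1\t10\t.\t+\t.",
                       'gene_id "g1";', sep = "\t"), ".gtf")
  expect_error(read_gtf(f), "line 1.*transcript_id")
  f2 <- write_tmp(c(
    paste("c1\tsrc\texon\t1\t10\t.\t+\t.",
          'gene_id "g1"; transcript_id "t1";', sep = "\t"),
    paste("c1\tsrc\texon\t20\t30\t.\t-\t.",
          'gene_id "g1"; transcript_id "t1";', sep = "\t")), ".gtf")
  expect_error(read_gtf(f2), "both strands")
})

test_that("GTF round-trips through the writer", {
  tp <- toy_plus()
  f <- tempfile(fileext = ".gtf")
  write_gtf(list(gp1 = tp$gene), f)
  back <- read_gtf(f)
  expect_equal(back$gp1$transcripts$tp1$exons, tp$t$exons)
  expect_equal(back$gp1$transcripts$tp1$cds, tp$t$cds)
})

test_that("VCF parsing types SNPs vs indels and splits multi-allelics", {
  f <- write_tmp(toy_vcf_lines(list(c("c1", "10", "C", "T"),
                                    c("c1", "20", "GCC", "G"),
                                    c("c1", "30", "C", "T,G"))), ".vcf")
  v <- read_vcf(f)
  expect_equal(nrow(v), 4L)
  expect_equal(v$vtype, c("snp", "indel", "snp", "snp"))
  expect_equal(v$pos[3:4], c(30L, 30L))
  expect_setequal(v$alt[v$pos == 30], c("T", "G"))
})

test_that("VCF genotypes come from the first sample and POS is validated", {
  f <- write_tmp(toy_vcf_lines(list(c("c1", "10", "C", "T")),
                               gt = "1|1"), ".vcf")
  v <- read_vcf(f)
  expect_identical(v$genotype, "1/1")
  f2 <- write_tmp(toy_vcf_lines(list(c("c1", "x10", "C", "T"))), ".vcf")
  expect_error(read_vcf(f2), "line .*POS")
})

test_that("VCF write/read round-trips variant rows", {
  v <- data.frame(chrom = "c2", pos = c(5L, 9L), id = ".",
                  ref = c("A", "AT"), alt = c("G", "A"),
                  vtype = c("snp", "indel"), genotype = c("1/1", "1/1"),
                  stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".vcf")
  write_vcf(v, f)
  back <- read_vcf(f)
  expect_equal(back[, c("chrom", "pos", "ref", "alt", "vtype",
                        "genotype")],
               v[, c("chrom", "pos", "ref", "alt", "vtype", "genotype")])
})

test_that("pileup dialect walk counts ref and alt symbols correctly", {
  expect_equal(unname(parse_pileup_column(".,.,AA^].", "C", "A")),
               c(5L, 2L))
  expect_equal(unname(parse_pileup_column(",,,,", "C", "A")), c(4L, 0L))
  expect_equal(unname(parse_pileup_column(".+2AT.", "C", "A")),
               c(2L, 0L))
  # read-end, deletion placeholder, other letters, case-insensitivity
  expect_equal(unname(parse_pileup_column(".$*Tga..,", "C", "G")),
               c(4L, 1L))
  expect_equal(unname(parse_pileup_column("-3ACG..", "C", "A")),
               c(2L, 0L))
})

test_that("pileup parser rejects malformed markers", {
  expect_error(parse_pileup_column("..^", "C", "A"), "dangling")
  expect_error(parse_pileup_column(".+AT", "C", "A"), "malformed indel")
  expect_error(parse_pileup_column(".+9A", "C", "A"), "malformed indel")
})

test_that("pileup counts never exceed the symbol count", {
  set.seed(11)
  syms <- c(".", ",", "A", "C", "G", "T", "a", "t", "*", "$")
  for (i in 1:50) {
    s <- paste(sample(syms, sample(1:30, 1), replace = TRUE),
               collapse = "")
    n <- parse_pileup_column(s, "C", "A")
    expect_lte(sum(n), nchar(s))
  }
})

test_that("xprs tables parse counts and strip parental suffixes", {
  f <- write_tmp(c("target_id\test_counts", "t1_R\t30.4", "t1_A\t0",
                   "odd\t2"), ".xprs")
  x <- read_xprs(f)
  expect_equal(x$est_counts, c(30.4, 0, 2))
  expect_equal(x$transcript_id, c("t1", "t1", "odd"))
  expect_equal(x$allele, c("ref", "alt", NA))
  f2 <- write_tmp(c("target_id\tcounts", "t1_R\t30.4"), ".xprs")
  expect_error(read_xprs(f2), "est_counts")
})

test_that("SNP coverage BED uses 0-based half-open and sorts rows", {
  rec <- data.frame(chrom = c("c1", "c1", "c1"), pos = c(10L, 10L, 5L),
                    replicate = c("r2", "r1", "r1"),
                    ref_count = c(3L, 4L, 5L), alt_count = c(1L, 2L, 0L),
                    library = "lib1", stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".bed")
  write_snp_coverage(rec, f)
  lines <- readLines(f)
  expect_equal(length(lines), 3L)
  first <- strsplit(lines[1L], "\t")[[1L]]
  expect_equal(as.integer(first[2:3]), c(4L, 5L))   # start = pos - 1
  # replicate-sorted within a position
  expect_match(lines[2L], "\tr1\t")
  expect_match(lines[3L], "\tr2\t")
  back <- read_snp_coverage(f)
  expect_equal(back$pos, c(5L, 10L, 10L))
  expect_equal(back$ref_count, c(5L, 4L, 3L))
  # BED invariant: end - start = 1 for every SNP
  starts <- as.integer(vapply(strsplit(lines, "\t"), `[[`, "", 2L))
  ends <- as.integer(vapply(strsplit(lines, "\t"), `[[`, "", 3L))
  expect_true(all(ends - starts == 1L))
})

test_that("empty SNP coverage yields an empty, header-free file", {
  f <- tempfile(fileext = ".bed")
  write_snp_coverage(data.frame(), f)
  expect_equal(file.size(f), 0)
  expect_equal(nrow(read_snp_coverage(f)), 0L)
})
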