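# Small hand-built fixtures shared across tests.

# one plus-strand coding transcript with a 3-exon structure:
#   chrom "c1": exon1 1-12 (UTR5 1-3, CDS 4-12), intron 13-20,
#   exon2 21-29 (CDS), intron 30-37, exon3 38-52 (CDS 38-40, UTR3 41-52)
# spliced CDS: ATGGCATTAGACGAAGGCTAA -> protein "MALDEG"
toy_plus <- function() {
  genome <- c(c1 = paste0("GGG", "ATGGCATTA", # exon1
                          "TTTTTTTT",         # intron
                          "GACGAAGGC",        # exon2
                          "AAAAAAAA",         # intron
                          "TAACCC", "CCCCCCCCC"))
  t <- transcript_model("tp1", "c1", "+",
                        exons = rbind(c(1L, 12L), c(21L, 29L),
                                      c(38L, 52L)),
                        cds = rbind(c(4L, 12L), c(21L, 29L),
                                    c(38L, 40L)))
  list(genome = genome, t = t,
       gene = gene_model("gp1", list(t)))
}

# the same gene content on the minus strand of its chromosome
toy_minus <- function() {
  tp <- toy_plus()
  fw <- tp$genome[["c1"]]
  genome <- c(c1 = h_revcomp(fw))
  L <- nchar(fw)
  flip <- function(iv) cbind(L - iv[, 2L] + 1L, L - iv[, 1L] + 1L)
  t <- transcript_model("tm1", "c1", "-",
                        exons = flip(tp$t$exons), cds = flip(tp$t$cds))
  list(genome = genome, t = t, gene = gene_model("gm1", list(t)))
}

# minimal VCF writer input
toy_vcf_lines <- function(rows, gt = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           if (!is.null(gt))
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
                  if (!is.null(gt)) "\tFORMAT\ts1"))
  body <- vapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    line <- sprintf("%s\t%s\t.\t%s\t%s\t.\t.\t.", r[1L], r[2L], r[3L],
                    r[4L])
    if (!is.null(gt)) line <- paste0(line, "\tGT\t", gt[[i]])
    line
  }, "")
  c(hdr, body)
}

write_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# a small transcript-level entity table for query tests: 10 transcripts,
# 4 with rank 1, 2 of those with >=1 missense, mixed p-values
toy_tx_table <- function() {
  t <- data.frame(
    transcript_id = sprintf("t%02d", 1:10),
    gene_id = sprintf("g%02d", c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5)),
    rank = c(1L, 2L, 1L, 2L, 1L, 2L, 1L, 2L, 2L, 3L),
    n_missense = c(1L, 0L, 2L, 1L, 0L, 0L, 0L, 3L, 1L, 0L),
    n_damaging = c(0L, 0L, 1L, 0L, 0L, 0L, 0L, 1L, 0L, 0L),
    n_snps_covered = c(3L, 1L, 4L, 2L, 0L, 1L, 2L, 5L, 1L, 0L),
    flag_opposite_snps = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE,
                           FALSE, TRUE, FALSE, FALSE),
    p_snp_lib1 = c(0.001, 0.2, 0.005, NA, 0.04, NA, 0.5, 0.009, 0.3,
                   NA),
    dir_snp_lib1 = c("ref>alt", "ref>alt", "alt>ref", "tie", "ref>alt",
                     "tie", "alt>ref", "ref>alt", "alt>ref", "tie"),
    p_read_lib1 = c(0.002, 0.3, 0.5, 0.001, NA, 0.04, 0.2, 0.008, NA,
                    0.9),
    dir_read_lib1 = c("ref>alt", "alt>ref", "ref>alt", "alt>ref",
                      "tie", "ref>alt", "ref>alt", "ref>alt", "tie",
                      "alt>ref"),
    stringsAsFactors = FALSE)
  attr(t, "level") <- "transcript"
  attr(t, "key") <- "transcript_id"
  t
}
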