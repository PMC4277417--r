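# Consensus merging of per-sample variant sets, variant-masked genome
# construction, and representative-SNP selection in clusters of closely
# spaced SNPs.

#' Merge per-sample variant sets into a consensus set
#'
#' A variant is retained iff the same (chrom, pos, ref, alt) is called in at
#' least `min_samples` sample sets and, when `expected_genotype` is given, its
#' genotype matches in at least `min_samples` of those occurrences. Each
#' sample set is deduplicated on the variant key before counting, so the
#' result is invariant under permutation of the sample list.
#'
#' @param per_sample List of variant `data.frame`s ([read_vcf()] layout).
#' @param min_samples Minimum number of samples calling the variant
#'   (default 5).
#' @param expected_genotype Optional diploid call filter, e.g. `"1/1"` when
#'   calling on inbred alternative-parent reads or `"0/1"` on hybrid reads.
#' @return Consensus variant `data.frame`, sorted by (chrom, pos).
#' @export
merge_variant_sets <- function(per_sample, min_samples = 5L,
                               expected_genotype = NULL) {
  if (length(per_sample) == 0L) stop("no variant sets to merge")
  stopifnot(min_samples >= 1L)
  norm_gt <- function(g) gsub("|", "/", g, fixed = TRUE)
  if (!is.null(expected_genotype)) {
    expected_genotype <- norm_gt(expected_genotype)
  }
  keyed <- lapply(per_sample, function(df) {
    key <- paste(df$chrom, df$pos, df$ref, df$alt, sep = "\r")
    df <- df[!duplicated(key), , drop = FALSE]
    df$.key <- key[!duplicated(key)]
    df
  })
  all_keys <- unlist(lapply(keyed, `[[`, ".key"))
  counts <- table(all_keys)
  keep <- names(counts)[counts >= min_samples]
  if (!is.null(expected_genotype)) {
    gt_keys <- unlist(lapply(keyed, function(df) {
      df$.key[!is.na(df$genotype) &
                norm_gt(df$genotype) == expected_genotype]
    }))
    gcounts <- table(gt_keys)
    keep <- keep[keep %in% names(gcounts)[gcounts >= min_samples]]
  }
  pool <- do.call(rbind, keyed)
  out <- pool[match(keep, pool$.key), , drop = FALSE]
  out$.key <- NULL
  out <- out[order(out$chrom, out$pos, out$ref, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mask SNP positions in a genome with N
#'
#' Masking the known SNP positions before aligning hybrid reads reduces the
#' mapping bias toward reference alleles. Only SNPs are masked; indels leave
#' the genome unchanged (masking can only partially address them, and the
#' downstream aligner's ambiguous-base penalty mechanism applies to single
#' bases). Reference alleles are validated against the genome.
#'
#' @param genome Named character vector of sequences ([read_fasta()]).
#' @param variants Variant `data.frame`; rows with `vtype != "snp"` are
#'   ignored.
#' @return `list(genome = masked genome, masked = count of distinct masked
#'   positions)`.
#' @export
mask_genome <- function(genome, variants) {
  snps <- variants[variants$vtype == "snp", , drop = FALSE]
  snps <- snps[!duplicated(paste(snps$chrom, snps$pos)), , drop = FALSE]
  unknown <- setdiff(unique(snps$chrom), names(genome))
  if (length(unknown)) {
    stop("SNP on unknown chromosome(s): ", paste(unknown, collapse = ", "))
  }
  mism <- character(0L)
  for (i in seq_len(nrow(snps))) {
    found <- substr(genome[[snps$chrom[i]]], snps$pos[i], snps$pos[i])
    if (found != toupper(snps$ref[i])) {
      mism <- c(mism, sprintf("%s:%d (expected %s, found %s)", snps$chrom[i],
                              snps$pos[i], snps$ref[i], found))
    }
  }
  if (length(mism)) {
    stop("reference-allele mismatch at: ", paste(mism, collapse = "; "))
  }
  masked <- genome
  for (chrom in unique(snps$chrom)) {
    ch <- strsplit(masked[[chrom]], "", fixed = TRUE)[[1L]]
    ch[snps$pos[snps$chrom == chrom]] <- "N"
    masked[[chrom]] <- paste(ch, collapse = "")
  }
  attributes(masked) <- attributes(genome)
  list(genome = masked, masked = nrow(snps))
}

#' Cluster closely spaced SNPs along a spliced transcript
#'
#' A read covering several SNPs should only be counted once, so SNPs within a
#' read length of each other are grouped and only one representative per
#' cluster contributes to transcript-level sums. Clustering is greedy
#' left-to-right in spliced-transcript coordinates: a SNP joins the current
#' cluster iff its spliced distance to the cluster's previous member is at
#' most `window`. The representative is the member with the highest summed
#' heterozygous coverage across libraries (ties break to the 5'-most member).
#' With `window = 0` every SNP is its own cluster.
#'
#' @param t A transcript model.
#' @param snps `data.frame` with columns `pos` (genomic, all exonic in `t`)
#'   and `coverage` (summed heterozygous coverage across libraries and
#'   replicates).
#' @param window Clustering window in spliced bases (default 100, a typical
#'   read length).
#' @return List of clusters, each
#'   `list(members, members_spliced, representative, representative_spliced)`
#'   with `members` in genomic coordinates ordered 5' to 3'.
#' @export
cluster_snps <- function(t, snps, window = 100L) {
  stopifnot(window >= 0L)
  if (nrow(snps) == 0L) return(list())
  sp <- genomic_to_spliced(t, snps$pos)
  if (anyNA(sp)) {
    stop("SNP outside exons of ", t$transcript_id, ": ",
         paste(snps$pos[is.na(sp)], collapse = ", "))
  }
  o <- order(sp)
  pos <- snps$pos[o]
  cov <- snps$coverage[o]
  sp <- sp[o]
  breaks <- c(TRUE, diff(sp) > window)
  cluster_id <- cumsum(breaks)
  lapply(split(seq_along(sp), cluster_id), function(idx) {
    best <- idx[which.max(cov[idx])]   # which.max takes the first = 5'-most
    list(members = pos[idx], members_spliced = sp[idx],
         representative = pos[best], representative_spliced = sp[best])
  })
}
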