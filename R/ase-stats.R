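# Allele-imbalance statistics: exact binomial tests on heterozygous counts
# at SNP, transcript and gene level, ranks, discordance flags and bias
# summaries. Counts below 20 give undefined (NA) p-values: exact tests lack
# power there, and NA never satisfies a p-value filter.

#' Two-sided exact binomial test of allelic balance
#'
#' Tests `ref` successes in `ref + alt` trials against probability 1/2. The
#' null is symmetric, so the two-sided p-value is the doubled symmetric tail,
#' `min(1, 2 * P(X >= max(ref, alt)))`, identical to the exact two-sided
#' test at p0 = 0.5.
#'
#' @param ref,alt Non-negative integer counts (vectorized; `ref + alt > 0`).
#' @return Numeric p-value(s) in `[0, 1]`.
#' @examples
#' binomial_ai(10, 10)   # 1: perfectly balanced
#' binomial_ai(20, 0)    # 2 * 0.5^20
#' @export
binomial_ai <- function(ref, alt) {
  if (any(ref < 0 | alt < 0)) stop("negative counts")
  n <- ref + alt
  if (any(n == 0)) stop("ref + alt must be positive")
  m <- pmax(ref, alt)
  pmin(1, 2 * stats::pbinom(m - 1, n, 0.5, lower.tail = FALSE))
}

ai_direction <- function(ref, alt) {
  ifelse(ref > alt, "ref>alt", ifelse(alt > ref, "alt>ref", "tie"))
}

#' Per-library allele imbalance for one SNP
#'
#' Replicate counts are summed per library; the binomial test is applied to
#' the library sum when it reaches `min_het` heterozygous reads, otherwise
#' the p-value is undefined (`NA`). Indel counts must never reach this
#' function: their heterozygous counts are not computed.
#'
#' @param counts `data.frame` with columns `library, ref, alt` (one row per
#'   replicate).
#' @param min_het Minimum heterozygous count for a defined p-value
#'   (default 20).
#' @return `data.frame` with one row per library: `library, ref, alt, p,
#'   direction`.
#' @export
snp_ai <- function(counts, min_het = 20L) {
  ref <- tapply(counts$ref, counts$library, sum)
  alt <- tapply(counts$alt, counts$library, sum)
  libs <- names(ref)
  tot <- ref + alt
  p <- rep(NA_real_, length(libs))
  ok <- tot >= min_het & tot > 0
  if (any(ok)) p[ok] <- binomial_ai(ref[ok], alt[ok])
  data.frame(library = libs, ref = as.integer(ref), alt = as.integer(alt),
             p = p, direction = ai_direction(ref, alt),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Transcript-level allele imbalance from summed SNP coverage
#'
#' Per library, the (ref, alt) counts of the cluster representatives are
#' summed — one representative per cluster of closely spaced SNPs, so a read
#' covering several SNPs is not counted repeatedly. The p-value is defined
#' only when at least one member SNP reaches `min_het` heterozygous reads in
#' that library.
#'
#' @param clusters Cluster list from [cluster_snps()].
#' @param lib_counts `data.frame` of per-SNP per-library sums: columns
#'   `pos, library, ref, alt`.
#' @param min_het Coverage threshold (default 20).
#' @return `data.frame` per library: `library, ref, alt, p, direction`.
#' @export
transcript_snp_coverage_ai <- function(clusters, lib_counts,
                                       min_het = 20L) {
  libs <- sort(unique(lib_counts$library))
  if (length(clusters) == 0L || length(libs) == 0L) {
    return(data.frame(library = libs,
                      ref = rep(0L, length(libs)),
                      alt = rep(0L, length(libs)),
                      p = rep(NA_real_, length(libs)),
                      direction = rep("tie", length(libs)),
                      stringsAsFactors = FALSE))
  }
  reps <- vapply(clusters, `[[`, numeric(1L), "representative")
  members <- unlist(lapply(clusters, `[[`, "members"))
  out <- lapply(libs, function(lib) {
    lc <- lib_counts[lib_counts$library == lib, , drop = FALSE]
    rc <- lc[lc$pos %in% reps, , drop = FALSE]
    ref <- sum(rc$ref)
    alt <- sum(rc$alt)
    mem <- lc[lc$pos %in% members, , drop = FALSE]
    covered <- any(mem$ref + mem$alt >= min_het)
    p <- if (covered && ref + alt > 0) binomial_ai(ref, alt) else NA_real_
    data.frame(library = lib, ref = ref, alt = alt, p = p,
               direction = ai_direction(ref, alt), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

round_half_up <- function(x) floor(x + 0.5)

#' Transcript-level allele imbalance from parental read counts
#'
#' Estimated counts of the reference (`_R`) and alternative (`_A`) parental
#' transcripts are rounded half-up to integers; when the rounded
#' heterozygous read count reaches `min_het` the binomial test is applied,
#' otherwise the p-value is undefined.
#'
#' @param ref_est,alt_est Non-negative estimated counts (vectorized; one
#'   element per library, replicate-summed).
#' @param min_het Read-count threshold (default 20).
#' @param library Optional library labels for the output.
#' @return `data.frame`: `library, ref, alt, p, direction`.
#' @export
transcript_read_count_ai <- function(ref_est, alt_est, min_het = 20L,
                                     library = NULL) {
  if (any(ref_est < 0 | alt_est < 0)) stop("negative estimated counts")
  ref <- round_half_up(ref_est)
  alt <- round_half_up(alt_est)
  tot <- ref + alt
  p <- rep(NA_real_, length(ref))
  ok <- tot >= min_het & tot > 0
  if (any(ok)) p[ok] <- binomial_ai(ref[ok], alt[ok])
  data.frame(library = library %||% seq_along(ref), ref = as.integer(ref),
             alt = as.integer(alt), p = p,
             direction = ai_direction(ref, alt), stringsAsFactors = FALSE)
}

#' Aggregate transcript results to the gene level
#'
#' A gene spans its leftmost transcript start to its rightmost transcript
#' end. Gene SNP-coverage counts are cluster-deduplicated sums over the
#' union of exonic SNPs across its transcripts (clustered on the merged exon
#' union); gene read counts are the summed parental read counts of its
#' transcripts. The same coverage thresholds as for transcripts apply per
#' measure.
#'
#' @param g A gene model.
#' @param snp_lib_counts Per-SNP per-library sums (`pos, library, ref, alt`)
#'   for SNPs exonic in at least one transcript of `g`.
#' @param snp_coverage Named numeric: summed heterozygous coverage per SNP
#'   position (for representative selection).
#' @param read_counts Optional `data.frame` `library, ref_est, alt_est`
#'   already summed over the gene's transcripts.
#' @param window Clustering window (default 100).
#' @param min_het Threshold (default 20).
#' @return `list(snp_coverage = data.frame, read_count = data.frame or
#'   NULL)`.
#' @export
gene_aggregate <- function(g, snp_lib_counts, snp_coverage,
                           read_counts = NULL, window = 100L,
                           min_het = 20L) {
  pos <- sort(unique(snp_lib_counts$pos))
  snp_cov <- if (length(pos)) {
    pseudo <- structure(list(transcript_id = paste0(g$gene_id, ".span"),
                             chrom = g$chrom, strand = g$strand,
                             exons = exon_union(g), cds = NULL),
                        class = "transcript_model")
    cl <- cluster_snps(pseudo,
                       data.frame(pos = pos,
                                  coverage = unname(
                                    snp_coverage[as.character(pos)])),
                       window = window)
    transcript_snp_coverage_ai(cl, snp_lib_counts, min_het = min_het)
  } else {
    data.frame(library = character(), ref = integer(), alt = integer(),
               p = numeric(), direction = character(),
               stringsAsFactors = FALSE)
  }
  rc <- NULL
  if (!is.null(read_counts) && nrow(read_counts)) {
    rc <- transcript_read_count_ai(read_counts$ref_est,
                                   read_counts$alt_est,
                                   min_het = min_het,
                                   library = read_counts$library)
  }
  list(snp_coverage = snp_cov, read_count = rc)
}

#' Rank a gene's transcripts by total read count
#'
#' Rank 1 marks the most likely transcribed isoform. Totals are the full
#' read counts (reference + alternative + reads covering no variant),
#' summed over all libraries; ties break by transcript id so rank 1 is
#' unique.
#'
#' @param totals Named numeric vector of total reads per transcript.
#' @return Named integer vector of ranks.
#' @export
rank_transcripts <- function(totals) {
  o <- order(-totals, names(totals))
  r <- integer(length(totals))
  r[o] <- seq_along(totals)
  stats::setNames(r, names(totals))
}

#' Flag a library whose replicates disagree in direction
#'
#' A SNP or transcript is flagged when at least one replicate points
#' significantly in the opposite direction from the library's summed value.
#' Each opposite-direction replicate is tested against the rest of the sum
#' (not the total, which would double-count the replicate) with a 2x2
#' chi-square test without continuity correction; zero marginals
#' short-circuit to no flag.
#'
#' @param reps `data.frame` with one row per replicate: columns `ref, alt`.
#' @param alpha Significance level (default 0.05).
#' @return Logical flag. A single replicate can never be discordant.
#' @export
flag_replicate_discordance <- function(reps, alpha = 0.05) {
  if (nrow(reps) < 2L) return(FALSE)
  tot_ref <- sum(reps$ref)
  tot_alt <- sum(reps$alt)
  d <- sign(tot_ref - tot_alt)
  if (d == 0L) return(FALSE)
  for (i in seq_len(nrow(reps))) {
    di <- sign(reps$ref[i] - reps$alt[i])
    if (di == 0L || di == d) next
    m <- matrix(c(reps$ref[i], reps$alt[i],
                  tot_ref - reps$ref[i], tot_alt - reps$alt[i]),
                nrow = 2L, byrow = TRUE)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    p <- suppressWarnings(stats::chisq.test(m, correct = FALSE)$p.value)
    if (!is.na(p) && p < alpha) return(TRUE)
  }
  FALSE
}

#' Flag a transcript with significant SNPs in opposite directions
#'
#' TRUE iff some library has at least one imbalanced SNP (`p < alpha`) with
#' `ref > alt` and at least one with `alt > ref`. Ties have no direction and
#' can never trigger the flag.
#'
#' @param snp_results Per-SNP per-library results: columns `library, p,
#'   direction`.
#' @param alpha Significance level (default 0.05).
#' @return Logical flag.
#' @export
flag_opposite_snps <- function(snp_results, alpha = 0.05) {
  ai <- snp_results[!is.na(snp_results$p) & snp_results$p < alpha, ,
                    drop = FALSE]
  if (nrow(ai) == 0L) return(FALSE)
  any(vapply(split(ai$direction, ai$library), function(d) {
    ("ref>alt" %in% d) && ("alt>ref" %in% d)
  }, logical(1L)))
}

#' Overall reference-allele bias
#'
#' Fraction of reads carrying the reference allele over all SNPs, replicates
#' and libraries, as a percentage. Residual bias after masking reflects
#' uncalled or false-positive SNPs and indels.
#'
#' @param ref,alt Count vectors (any grouping; they are summed).
#' @return Percentage in `[0, 100]`.
#' @export
compute_bias <- function(ref, alt) {
  tot <- sum(ref) + sum(alt)
  if (tot == 0) stop("no counted reads")
  100 * sum(ref) / tot
}

# canonical substitution class: a SNP and its complement share one label,
# e.g. C>T with G>A reported as "CT"
substitution_class <- function(ref, alt) {
  a <- paste0(ref, alt)
  b <- paste0(comp_base(ref), comp_base(alt))
  ifelse(a <= b, a, b)
}
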