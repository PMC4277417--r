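# Deterministic generator of a miniature F1-hybrid ASE study: genome,
# multi-isoform annotation, homozygous-alternative-parent variants, and
# binomially sampled per-replicate allele counts with known ground truth.
# Genes are built from a transcript-oriented template (5'UTR, codon-aligned
# stop-free CDS chunks, 3'UTR, introns) so that skipping internal CDS exons
# preserves frame and never introduces a stop; minus-strand genes are the
# template reverse-complemented into the genome.

#' Configuration for a simulated ASE study
#'
#' Defaults emulate the study design the toolkit targets: an F1 hybrid of
#' two inbred parents (reference strain x alternative strain, so every
#' variant is heterozygous with genotype 1/1 on the alternative parent),
#' four libraries (tissues) with four replicates each, ~100 bp read scale,
#' and a small residual reference bias after masking
#' (`delta = 0.014`, i.e. a 51.4/48.6 split at balanced theta).
#' Allelically imbalanced genes are planted in both directions
#' (`ai_theta` and `1 - ai_theta`) so `delta` alone sets the expected
#' overall bias.
#'
#' @param seed Integer seed fixing all outputs bit-for-bit.
#' @param n_chroms Number of chromosomes.
#' @param n_genes Number of genes.
#' @param isoforms Integer range `c(min, max)` of isoforms per gene.
#' @param snps_per_kb Expected SNP density within gene spans.
#' @param indel_fraction Fraction of variants that are indels.
#' @param n_libraries,n_replicates Library x replicate design.
#' @param theta Baseline reference-allele ratio for balanced genes.
#' @param ai_fraction Fraction of genes planted with allelic imbalance.
#' @param ai_theta Reference-allele ratio of imbalanced genes (alternating
#'   with `1 - ai_theta`).
#' @param mean_coverage Mean per-replicate heterozygous coverage per SNP.
#' @param read_mean Mean per-replicate heterozygous read count of a gene's
#'   top isoform (lower-rank isoforms are scaled down).
#' @param delta Reference-bias offset added to the ref probability.
#' @param chrom_len Optional fixed chromosome length; genes that do not fit
#'   raise an error.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L, n_chroms = 2L, n_genes = 50L,
                       isoforms = c(1L, 3L), snps_per_kb = 2,
                       indel_fraction = 0.1, n_libraries = 4L,
                       n_replicates = 4L, theta = 0.5, ai_fraction = 0.3,
                       ai_theta = 0.8, mean_coverage = 60,
                       read_mean = 60, delta = 0.014, chrom_len = NULL) {
  stopifnot(theta > 0, theta < 1, ai_theta > 0, ai_theta < 1,
            mean_coverage > 0, read_mean > 0, n_genes >= 1L,
            n_libraries >= 1L, n_replicates >= 1L,
            indel_fraction >= 0, indel_fraction <= 1)
  structure(list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
                 n_genes = as.integer(n_genes), isoforms = isoforms,
                 snps_per_kb = snps_per_kb,
                 indel_fraction = indel_fraction,
                 n_libraries = as.integer(n_libraries),
                 n_replicates = as.integer(n_replicates), theta = theta,
                 ai_fraction = ai_fraction, ai_theta = ai_theta,
                 mean_coverage = mean_coverage, read_mean = read_mean,
                 delta = delta, chrom_len = chrom_len),
            class = "sim_config")
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# random stop-free codons
rand_codons <- function(n_codons) {
  codons <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  paste(sample(codons, n_codons, replace = TRUE), collapse = "")
}

#' Generate a random genome and multi-isoform annotation
#'
#' Genes have 3-6 exons on both strands with valid start/stop codons;
#' isoforms share the first and last exon and differ by skipping internal
#' codon-aligned CDS exons, so shared and unique exons coexist and every
#' isoform's CDS translates without internal stops.
#'
#' @param config A [sim_config()].
#' @return `list(genome, genes, layout)`; `layout` carries the internal
#'   template geometry consumed by [generate_variants()].
#' @export
generate_reference <- function(config) {
  set.seed(config$seed)
  chroms <- paste0("chr", seq_len(config$n_chroms))
  cursors <- stats::setNames(rep(0L, config$n_chroms), chroms)
  chrom_parts <- stats::setNames(vector("list", config$n_chroms), chroms)
  genes <- list()
  layout <- list()
  for (gi in seq_len(config$n_genes)) {
    gene_id <- sprintf("g%03d", gi)
    u5 <- sample(30:80, 1L)
    k <- sample(3:6, 1L)
    chunk_cod <- sample(8:30, k, replace = TRUE)
    chunks <- character(k)
    chunks[1L] <- paste0("ATG", rand_codons(chunk_cod[1L] - 1L))
    if (k > 2L) {
      for (j in 2L:(k - 1L)) chunks[j] <- rand_codons(chunk_cod[j])
    }
    chunks[k] <- paste0(rand_codons(chunk_cod[k] - 1L),
                        sample(c("TAA", "TAG", "TGA"), 1L))
    u3 <- sample(40:100, 1L)
    introns <- sample(60:200, k - 1L, replace = TRUE)
    # template assembly with coordinate bookkeeping
    utr5_seq <- rand_dna(u5)
    utr3_seq <- rand_dna(u3)
    exon_seqs <- c(paste0(utr5_seq, chunks[1L]),
                   if (k > 2L) chunks[2L:(k - 1L)],
                   paste0(chunks[k], utr3_seq))
    pieces <- character(0L)
    exons_t <- matrix(0L, nrow = k, ncol = 2L)
    cds_t <- matrix(0L, nrow = k, ncol = 2L)
    regions <- list()
    cursor <- 0L
    for (j in seq_len(k)) {
      s <- cursor + 1L
      e <- cursor + nchar(exon_seqs[j])
      exons_t[j, ] <- c(s, e)
      if (j == 1L) {
        if (u5 > 0L) regions[[length(regions) + 1L]] <-
            list(type = "utr5", start = s, end = s + u5 - 1L)
        cds_t[j, ] <- c(s + u5, e)
      } else if (j == k) {
        cds_t[j, ] <- c(s, e - u3)
        if (u3 > 0L) regions[[length(regions) + 1L]] <-
            list(type = "utr3", start = e - u3 + 1L, end = e)
      } else {
        cds_t[j, ] <- c(s, e)
      }
      pieces <- c(pieces, exon_seqs[j])
      cursor <- e
      if (j < k) {
        regions[[length(regions) + 1L]] <-
          list(type = "intron", start = cursor + 1L,
               end = cursor + introns[j])
        pieces <- c(pieces, rand_dna(introns[j]))
        cursor <- cursor + introns[j]
      }
    }
    template <- paste(pieces, collapse = "")
    L <- nchar(template)
    strand <- sample(c("+", "-"), 1L)
    chrom <- chroms[((gi - 1L) %% config$n_chroms) + 1L]
    gap <- sample(200:500, 1L)
    G <- cursors[[chrom]] + gap + 1L
    if (!is.null(config$chrom_len) &&
        G + L - 1L > config$chrom_len) {
      stop("gene ", gene_id, " does not fit on ", chrom,
           " (length ", config$chrom_len, ")")
    }
    seg <- if (strand == "+") template else revcomp(template)
    chrom_parts[[chrom]] <- c(chrom_parts[[chrom]], rand_dna(gap), seg)
    cursors[[chrom]] <- G + L - 1L
    # isoforms: all exons, then distinct skip-sets of internal exons
    n_iso <- sample(config$isoforms[1L]:config$isoforms[2L], 1L)
    middles <- if (k > 2L) 2L:(k - 1L) else integer(0L)
    skip_sets <- list(integer(0L))
    if (length(middles) && n_iso > 1L) {
      pool <- unlist(lapply(seq_along(middles), function(sz) {
        utils::combn(middles, sz, simplify = FALSE)
      }), recursive = FALSE)
      pool <- pool[sample.int(length(pool))]
      skip_sets <- c(skip_sets, pool[seq_len(min(n_iso - 1L,
                                                 length(pool)))])
    }
    to_genomic <- function(iv) {
      if (strand == "+") {
        cbind(G + iv[, 1L] - 1L, G + iv[, 2L] - 1L)
      } else {
        cbind(G + L - iv[, 2L], G + L - iv[, 1L])
      }
    }
    txs <- list()
    iso_exons <- list()
    for (ii in seq_along(skip_sets)) {
      inc <- setdiff(seq_len(k), skip_sets[[ii]])
      tid <- sprintf("%s.t%d", gene_id, ii)
      txs[[tid]] <- transcript_model(
        tid, chrom = chrom, strand = strand,
        exons = to_genomic(exons_t[inc, , drop = FALSE]),
        cds = to_genomic(cds_t[inc, , drop = FALSE]))
      iso_exons[[tid]] <- inc
    }
    genes[[gene_id]] <- gene_model(gene_id, txs)
    layout[[gene_id]] <- list(
      gene_id = gene_id, chrom = chrom, strand = strand, G = G, L = L,
      template = template, exons_t = exons_t, cds_t = cds_t,
      regions = regions, iso_exons = iso_exons, n_exons = k)
  }
  genome <- vapply(chrom_parts, paste, "", collapse = "")
  # internal consistency: the spliced transcript must reproduce the
  # template-derived sequence on both strands
  for (gid in names(layout)) {
    lay <- layout[[gid]]
    t1 <- genes[[gid]]$transcripts[[1L]]
    expect <- paste(substring(lay$template, lay$exons_t[, 1L],
                              lay$exons_t[, 2L]), collapse = "")
    if (!identical(splice_transcript(genome, t1), expect)) {
      stop("internal error: template/genome mismatch for ", gid)
    }
  }
  list(genome = genome, genes = genes, layout = layout)
}

template_region <- function(lay, x) {
  for (r in lay$regions) if (x >= r$start && x <= r$end) return(r$type)
  "cds"
}

#' Plant variants with known ground-truth effects
#'
#' SNPs land in UTRs, CDS and introns; indels (deletions and insertions,
#' at the configured fraction) are restricted to UTRs and introns, clear of
#' region boundaries, since the basic effect vocabulary defers coding-indel
#' consequences to external annotators. All genotypes are 1/1: the
#' alternative parent is inbred. Ground-truth effect labels per
#' (variant, transcript) are recorded from the template geometry — an
#' independent path from the package's own classifier.
#'
#' @param config A [sim_config()].
#' @param ref Result of [generate_reference()].
#' @return `list(variants, truth_variants, truth_effects)`.
#' @export
generate_variants <- function(config, ref) {
  set.seed(config$seed + 1L)
  rows <- list()
  truth <- list()
  truth_eff <- list()
  for (lay in ref$layout) {
    n_var <- max(1L, stats::rpois(1L, config$snps_per_kb * lay$L / 1000))
    n_indel <- round(config$indel_fraction * n_var)
    n_snp <- n_var - n_indel
    taken <- integer(0L)   # template positions blocked (with margin)
    pick <- function(candidates, margin) {
      candidates <- candidates[!candidates %in% taken]
      if (!length(candidates)) return(NA_integer_)
      x <- sample(candidates, 1L)
      taken <<- c(taken, (x - margin):(x + margin))
      x
    }
    cds_start_t <- lay$cds_t[1L, 1L]
    cds_end_t <- lay$cds_t[lay$n_exons, 2L]
    # avoid start and stop codon positions only when planting plain SNPs in
    # flanks is required; stop-codon SNPs are allowed (stop_lost is a
    # legitimate class) but the ATG is kept intact
    blocked <- cds_start_t:(cds_start_t + 2L)
    all_pos <- setdiff(4:(lay$L - 3L), blocked)
    tries <- 0L
    placed_snp <- 0L
    while (placed_snp < n_snp) {
      x <- pick(all_pos, 3L)
      if (is.na(x)) {
        if (placed_snp == 0L) stop("variant density too high for gene ",
                                   lay$gene_id)
        break
      }
      placed_snp <- placed_snp + 1L
      ref_t <- substr(lay$template, x, x)
      alt_t <- sample(setdiff(c("A", "C", "G", "T"), ref_t), 1L)
      if (lay$strand == "+") {
        pos <- lay$G + x - 1L
        ref_g <- ref_t
        alt_g <- alt_t
      } else {
        pos <- lay$G + lay$L - x
        ref_g <- comp_base(ref_t)
        alt_g <- comp_base(alt_t)
      }
      region <- template_region(lay, x)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = lay$chrom, pos = pos, id = ".", ref = ref_g, alt = alt_g,
        vtype = "snp", genotype = "1/1", stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        chrom = lay$chrom, pos = pos, ref = ref_g, alt = alt_g,
        vtype = "snp", gene_id = lay$gene_id, region = region,
        template_pos = x, stringsAsFactors = FALSE)
      # per-isoform truth effect
      term_cds <- NULL
      if (region == "cds") {
        cds_seq <- paste(substring(lay$template, lay$cds_t[, 1L],
                                   lay$cds_t[, 2L]), collapse = "")
        # spliced CDS position of x
        prev <- 0L
        cpos <- NA_integer_
        for (j in seq_len(lay$n_exons)) {
          if (x >= lay$cds_t[j, 1L] && x <= lay$cds_t[j, 2L]) {
            cpos <- prev + (x - lay$cds_t[j, 1L] + 1L)
            break
          }
          prev <- prev + (lay$cds_t[j, 2L] - lay$cds_t[j, 1L] + 1L)
        }
        ci <- (cpos - 1L) %/% 3L
        codon <- substr(cds_seq, 3L * ci + 1L, 3L * ci + 3L)
        off <- cpos - 3L * ci
        codon_alt <- codon
        substr(codon_alt, off, off) <- alt_t
        aa_ref <- unname(Biostrings::GENETIC_CODE[codon])
        aa_alt <- unname(Biostrings::GENETIC_CODE[codon_alt])
        term_cds <- if (aa_ref == aa_alt) "synonymous_variant"
          else if (aa_alt == "*") "stop_gained"
          else if (aa_ref == "*") "stop_lost"
          else "missense_variant"
      }
      exon_of_x <- which(lay$exons_t[, 1L] <= x & lay$exons_t[, 2L] >= x)
      for (tid in names(lay$iso_exons)) {
        inc <- lay$iso_exons[[tid]]
        term <- if (region == "intron" || (length(exon_of_x) &&
                                           !exon_of_x %in% inc)) {
          "intron_variant"
        } else if (region == "utr5") {
          "5_prime_UTR_variant"
        } else if (region == "utr3") {
          "3_prime_UTR_variant"
        } else {
          term_cds
        }
        truth_eff[[length(truth_eff) + 1L]] <- data.frame(
          chrom = lay$chrom, pos = pos, alt = alt_g,
          transcript_id = tid, term = term, stringsAsFactors = FALSE)
      }
    }
    # indels in UTRs and introns, clear of boundaries
    noncoding <- lay$regions[vapply(lay$regions, function(r)
      r$type %in% c("utr5", "utr3", "intron"), logical(1L))]
    cand <- unlist(lapply(noncoding, function(r) {
      if (r$end - r$start >= 8L) (r$start + 3L):(r$end - 5L) else integer(0L)
    }))
    for (z in seq_len(n_indel)) {
      x <- pick(cand, 6L)
      if (is.na(x)) break
      region <- template_region(lay, x)
      is_del <- stats::runif(1L) < 0.5
      if (is_del) {
        d <- sample(1:2, 1L)
        if (lay$strand == "+") {
          pos <- lay$G + x - 1L
          ref_g <- substr(lay$template, x, x + d)
          alt_g <- substr(lay$template, x, x)
        } else {
          pos <- lay$G + lay$L - (x + d)
          ref_g <- revcomp(substr(lay$template, x, x + d))
          alt_g <- substr(ref_g, 1L, 1L)
        }
      } else {
        ins <- rand_dna(sample(2:3, 1L))
        if (lay$strand == "+") {
          pos <- lay$G + x - 1L
          ref_g <- substr(lay$template, x, x)
        } else {
          pos <- lay$G + lay$L - x
          ref_g <- comp_base(substr(lay$template, x, x))
        }
        alt_g <- paste0(ref_g, ins)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = lay$chrom, pos = pos, id = ".", ref = ref_g, alt = alt_g,
        vtype = "indel", genotype = "1/1", stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        chrom = lay$chrom, pos = pos, ref = ref_g, alt = alt_g,
        vtype = "indel", gene_id = lay$gene_id, region = region,
        template_pos = x, stringsAsFactors = FALSE)
    }
  }
  variants <- do.call(rbind, rows)
  variants <- variants[order(variants$chrom, variants$pos), , drop = FALSE]
  rownames(variants) <- NULL
  list(variants = variants,
       truth_variants = do.call(rbind, truth),
       truth_effects = do.call(rbind, truth_eff))
}

#' Sample per-replicate allele counts and parental transcript counts
#'
#' Each SNP's per-replicate total is Poisson(mean coverage) and its
#' reference count Binomial(total, theta_gene + delta). Parental transcript
#' counts follow the same structure per isoform with expression weights
#' halving by isoform index (so ranks are planted); est_counts carry a
#' +/-0.3 fractional jitter that exercises half-up rounding without moving
#' the rounded value. Full totals add a non-variant read mass.
#'
#' @param config A [sim_config()].
#' @param ref Result of [generate_reference()].
#' @param variants Result of [generate_variants()].
#' @return `list(design, counts, xprs, totals, truth_theta)`; `counts` and
#'   `xprs` are lists of data.frames keyed by file stem.
#' @export
simulate_counts <- function(config, ref, variants) {
  set.seed(config$seed + 2L)
  gene_ids <- names(ref$layout)
  n_ai <- round(config$ai_fraction * length(gene_ids))
  ai_genes <- sample(gene_ids, n_ai)
  theta <- stats::setNames(rep(config$theta, length(gene_ids)), gene_ids)
  if (n_ai > 0L) {
    updown <- rep(c(config$ai_theta, 1 - config$ai_theta),
                  length.out = n_ai)
    theta[ai_genes] <- updown
  }
  if (any(theta + config$delta <= 0 | theta + config$delta >= 1)) {
    stop("theta + delta outside (0, 1)")
  }
  libs <- sprintf("lib%d", seq_len(config$n_libraries))
  reps <- sprintf("r%d", seq_len(config$n_replicates))
  design <- expand.grid(replicate = reps, library = libs,
                        stringsAsFactors = FALSE)[, c(2L, 1L)]
  design$stem <- paste(design$library, design$replicate, sep = "_")
  design <- design[, c("stem", "library", "replicate")]
  snvs <- variants$truth_variants
  snvs <- snvs[snvs$vtype == "snp", , drop = FALSE]
  p_ref <- theta[snvs$gene_id] + config$delta
  counts <- list()
  xprs <- list()
  truth_theta <- list()
  # isoform expression weights
  w <- list()
  for (gid in gene_ids) {
    tids <- names(ref$layout[[gid]]$iso_exons)
    w[[gid]] <- stats::setNames(2^-(seq_along(tids) - 1L), tids)
    for (tid in tids) {
      truth_theta[[length(truth_theta) + 1L]] <- data.frame(
        gene_id = gid, transcript_id = tid, theta = unname(theta[gid]),
        weight = unname(w[[gid]][tid]), stringsAsFactors = FALSE)
    }
  }
  totals_acc <- NULL
  for (i in seq_len(nrow(design))) {
    stem <- design$stem[i]
    tot <- stats::rpois(nrow(snvs), config$mean_coverage)
    rc <- stats::rbinom(nrow(snvs), tot, p_ref)
    counts[[stem]] <- data.frame(chrom = snvs$chrom, pos = snvs$pos,
                                 ref_count = rc, alt_count = tot - rc,
                                 stringsAsFactors = FALSE)
    xr <- list()
    for (gid in gene_ids) {
      for (tid in names(w[[gid]])) {
        het <- stats::rpois(1L, config$read_mean * w[[gid]][tid])
        refh <- stats::rbinom(1L, het, theta[gid] + config$delta)
        jit <- stats::runif(2L, -0.3, 0.3)
        xr[[length(xr) + 1L]] <- data.frame(
          target_id = c(paste0(tid, "_R"), paste0(tid, "_A")),
          est_counts = pmax(0, c(refh + jit[1L], het - refh + jit[2L])),
          stringsAsFactors = FALSE)
        nonvar <- stats::rpois(1L, config$read_mean * w[[gid]][tid] * 0.8)
        tot_row <- data.frame(transcript_id = tid, total = het + nonvar,
                              stringsAsFactors = FALSE)
        totals_acc <- rbind(totals_acc, tot_row)
      }
    }
    xprs[[stem]] <- do.call(rbind, xr)
  }
  totals <- stats::aggregate(total ~ transcript_id, data = totals_acc,
                             FUN = sum)
  list(design = design, counts = counts, xprs = xprs, totals = totals,
       truth_theta = do.call(rbind, truth_theta),
       theta = theta, ai_genes = ai_genes)
}

#' Generate and write a complete simulated study
#'
#' Emits `genome.fa`, `genes.gtf`, `variants.vcf`, `design.tsv`,
#' `counts/<stem>.tsv`, `xprs/<stem>.xprs`, `totals.tsv` and ground-truth
#' tables under `truth/`. Truth files are first-class outputs so downstream
#' checks never re-derive ground truth through a second code path.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created).
#' @return Invisibly, the full in-memory study
#'   (`list(config, ref, variants, counts)`).
#' @export
simulate_ase_study <- function(config = sim_config(), dir) {
  ref <- generate_reference(config)
  vars <- generate_variants(config, ref)
  cnt <- simulate_counts(config, ref, vars)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "counts"), showWarnings = FALSE)
  dir.create(file.path(dir, "xprs"), showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  write_fasta(ref$genome, file.path(dir, "genome.fa"))
  write_gtf(ref$genes, file.path(dir, "genes.gtf"))
  write_vcf(vars$variants, file.path(dir, "variants.vcf"))
  utils::write.table(cnt$design, file.path(dir, "design.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (stem in names(cnt$counts)) {
    utils::write.table(cnt$counts[[stem]],
                       file.path(dir, "counts", paste0(stem, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_xprs(cnt$xprs[[stem]],
               file.path(dir, "xprs", paste0(stem, ".xprs")))
  }
  utils::write.table(cnt$totals, file.path(dir, "totals.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(vars$truth_variants,
                     file.path(dir, "truth", "variants.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(vars$truth_effects,
                     file.path(dir, "truth", "effects.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cnt$truth_theta,
                     file.path(dir, "truth", "theta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(config = config, ref = ref, variants = vars,
                 counts = cnt))
}
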