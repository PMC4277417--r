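# Assembles genome, annotation, variants and counts into a queryable set of
# SNP / transcript / gene tables with allele-imbalance statistics, ranks,
# flags and an overview summary.

#' Build the allele-specific expression database
#'
#' The central driver: joins heterozygous SNP counts and parental transcript
#' read counts onto the gene models, computes per-library binomial
#' allele-imbalance p-values at SNP, transcript and gene level (SNP counts
#' below `min_het` give undefined p-values), clusters closely spaced SNPs so
#' each cluster contributes one representative to transcript sums, ranks
#' isoforms by total reads, flags replicate discordance and
#' opposite-direction SNPs, classifies basic variant effects, and computes
#' the overview summary.
#'
#' @param genome Named character vector of sequences ([read_fasta()]).
#' @param genes Named list of gene models ([read_gtf()]).
#' @param variants Variant `data.frame` ([read_vcf()]); indels are carried
#'   for information but never counted.
#' @param design Design `data.frame` (`stem, library, replicate`).
#' @param snp_counts Long `data.frame` of per-replicate SNP counts: columns
#'   `stem, chrom, pos, ref_count, alt_count`.
#' @param xprs Optional long `data.frame` of parental transcript counts:
#'   columns `stem, transcript_id, allele ("ref"/"alt"), est_counts`.
#' @param totals Optional `data.frame` `transcript_id, total` of full read
#'   counts (including reads covering no variant) used for isoform ranking;
#'   when absent, ranking falls back to summed parental counts.
#' @param external_effects Optional `data.frame` from
#'   [import_external_effects()]; imported annotations replace internal ones
#'   for the same (variant, transcript).
#' @param window SNP clustering window in spliced bases (default 100).
#' @param min_het Coverage/read-count threshold for defined p-values
#'   (default 20).
#' @param alpha Significance level used for flags and overview counts
#'   (default 0.05).
#' @return An object of class `"ase_db"`: a list of tables (`snps`,
#'   `transcripts`, `genes`, `effects`, `design`), the overview list, and
#'   the run parameters.
#' @export
build_ase_db <- function(genome, genes, variants, design, snp_counts,
                         xprs = NULL, totals = NULL,
                         external_effects = NULL, window = 100L,
                         min_het = 20L, alpha = 0.05) {
  stopifnot(nrow(design) >= 1L)
  libs <- unique(design$library)
  if (!all(c("library", "replicate") %in% names(snp_counts))) {
    snp_counts <- merge(snp_counts, design, by = "stem")
  }
  variants <- variants[!duplicated(paste(variants$chrom, variants$pos,
                                         variants$ref, variants$alt)), ,
                       drop = FALSE]
  snvs <- variants[variants$vtype == "snp", , drop = FALSE]
  key <- function(chrom, pos) paste(chrom, pos, sep = ":")
  snvs$key <- key(snvs$chrom, snvs$pos)
  snp_counts$key <- key(snp_counts$chrom, snp_counts$pos)
  snp_counts <- snp_counts[snp_counts$key %in% snvs$key, , drop = FALSE]

  # per-SNP per-library sums and per-replicate detail
  lib_sum <- stats::aggregate(cbind(ref = ref_count, alt = alt_count) ~
                                key + library, data = snp_counts, FUN = sum)
  cov_total <- tapply(snp_counts$ref_count + snp_counts$alt_count,
                      snp_counts$key, sum)

  snp_rows <- lapply(seq_len(nrow(snvs)), function(i) {
    k <- snvs$key[i]
    ls <- lib_sum[lib_sum$key == k, , drop = FALSE]
    row <- data.frame(chrom = snvs$chrom[i], pos = snvs$pos[i],
                      ref = snvs$ref[i], alt = snvs$alt[i],
                      key = k, stringsAsFactors = FALSE)
    covered <- 0L
    n_ai <- 0L
    for (lib in libs) {
      r <- ls[ls$library == lib, , drop = FALSE]
      ref <- if (nrow(r)) r$ref else 0L
      alt <- if (nrow(r)) r$alt else 0L
      tot <- ref + alt
      p <- if (tot >= min_het) binomial_ai(ref, alt) else NA_real_
      covered <- covered + as.integer(tot >= min_het)
      n_ai <- n_ai + as.integer(!is.na(p) && p < alpha)
      row[[paste0("ref_", lib)]] <- ref
      row[[paste0("alt_", lib)]] <- alt
      row[[paste0("p_snp_", lib)]] <- p
      row[[paste0("dir_snp_", lib)]] <- ai_direction(ref, alt)
    }
    row$n_lib_covered <- covered
    row$n_lib_ai <- n_ai
    # replicate discordance per library, any library flags the SNP
    rc <- snp_counts[snp_counts$key == k, , drop = FALSE]
    row$flag_rep_discordant <- any(vapply(libs, function(lib) {
      rl <- rc[rc$library == lib, , drop = FALSE]
      flag_replicate_discordance(data.frame(ref = rl$ref_count,
                                            alt = rl$alt_count),
                                 alpha = alpha)
    }, logical(1L)))
    row
  })
  snp_table <- if (length(snp_rows)) do.call(rbind, snp_rows) else NULL

  # xprs: per-library replicate-summed parental counts per transcript
  xl <- NULL
  if (!is.null(xprs) && nrow(xprs)) {
    if (!"library" %in% names(xprs)) {
      xprs <- merge(xprs, design, by = "stem")
    }
    xprs <- xprs[!is.na(xprs$allele), , drop = FALSE]
    xl <- stats::aggregate(est_counts ~ transcript_id + allele + library,
                           data = xprs, FUN = sum)
  }

  effects <- list()
  tx_rows <- list()
  gene_rows <- list()
  tx_snp_keys <- list()
  for (g in genes) {
    gspan <- gene_span(g)
    in_span <- variants$chrom == g$chrom & variants$pos >= gspan[1L] &
      variants$pos + nchar(variants$ref) - 1L <= gspan[2L]
    vg <- variants[in_span, , drop = FALSE]
    gene_snp_keys <- character(0L)
    gene_read <- NULL
    tx_ids <- names(g$transcripts)
    tx_results <- list()
    for (t in g$transcripts) {
      ref_seq <- splice_transcript(genome, t)
      tspan <- transcript_span(t)
      vt <- vg[vg$pos >= tspan[1L] & vg$pos <= tspan[2L], , drop = FALSE]
      for (j in seq_len(nrow(vt))) {
        effects[[length(effects) + 1L]] <-
          classify_effect(vt[j, ], t, ref_seq)
      }
      # exonic SNPs with counts
      vsnp <- vt[vt$vtype == "snp", , drop = FALSE]
      if (nrow(vsnp)) {
        sp <- genomic_to_spliced(t, vsnp$pos)
        vsnp <- vsnp[!is.na(sp), , drop = FALSE]
      }
      ks <- key(vsnp$chrom, vsnp$pos)
      tx_snp_keys[[t$transcript_id]] <- ks
      gene_snp_keys <- union(gene_snp_keys, ks)
      lc <- lib_sum[lib_sum$key %in% ks, , drop = FALSE]
      lc$pos <- as.integer(sub("^.*:", "", lc$key))
      counted <- vsnp[ks %in% lib_sum$key, , drop = FALSE]
      clusters <- if (nrow(counted)) {
        cluster_snps(t,
                     data.frame(pos = counted$pos,
                                coverage = unname(cov_total[
                                  key(counted$chrom, counted$pos)])),
                     window = window)
      } else list()
      cov_ai <- transcript_snp_coverage_ai(clusters, lc, min_het = min_het)
      # transcript replicate discordance on representative sums
      reps_pos <- vapply(clusters, `[[`, numeric(1L), "representative")
      rc <- snp_counts[snp_counts$key %in% key(t$chrom, reps_pos), ,
                       drop = FALSE]
      flag_rep <- FALSE
      if (nrow(rc)) {
        flag_rep <- any(vapply(libs, function(lib) {
          rl <- rc[rc$library == lib, , drop = FALSE]
          if (!nrow(rl)) return(FALSE)
          agg <- stats::aggregate(cbind(ref = ref_count, alt = alt_count) ~
                                    replicate, data = rl, FUN = sum)
          flag_replicate_discordance(agg, alpha = alpha)
        }, logical(1L)))
      }
      # per-SNP AI results for the opposite-direction flag
      snp_res <- lib_sum[lib_sum$key %in% ks, , drop = FALSE]
      if (nrow(snp_res)) {
        tot <- snp_res$ref + snp_res$alt
        snp_res$p <- NA_real_
        okp <- tot >= min_het & tot > 0
        if (any(okp)) {
          snp_res$p[okp] <- binomial_ai(snp_res$ref[okp], snp_res$alt[okp])
        }
        snp_res$direction <- ai_direction(snp_res$ref, snp_res$alt)
      } else {
        snp_res <- data.frame(library = character(), p = numeric(),
                              direction = character())
      }
      flag_opp <- flag_opposite_snps(snp_res, alpha = alpha)

      read_ai <- NULL
      if (!is.null(xl)) {
        xt <- xl[xl$transcript_id == t$transcript_id, , drop = FALSE]
        if (nrow(xt)) {
          wide <- lapply(libs, function(lib) {
            re <- xt$est_counts[xt$library == lib & xt$allele == "ref"]
            ae <- xt$est_counts[xt$library == lib & xt$allele == "alt"]
            data.frame(library = lib,
                       ref_est = if (length(re)) re else 0,
                       alt_est = if (length(ae)) ae else 0,
                       stringsAsFactors = FALSE)
          })
          wide <- do.call(rbind, wide)
          read_ai <- transcript_read_count_ai(wide$ref_est, wide$alt_est,
                                              min_het = min_het,
                                              library = wide$library)
          gene_read <- if (is.null(gene_read)) wide else {
            merged <- gene_read
            merged$ref_est <- merged$ref_est + wide$ref_est
            merged$alt_est <- merged$alt_est + wide$alt_est
            merged
          }
        }
      }
      tx_results[[t$transcript_id]] <- list(
        cov_ai = cov_ai, read_ai = read_ai, flag_rep = flag_rep,
        flag_opp = flag_opp, n_snps = length(ks), snp_keys = ks)
    }
    # ranks
    tot_reads <- if (!is.null(totals)) {
      stats::setNames(
        vapply(tx_ids, function(id) {
          v <- totals$total[totals$transcript_id == id]
          if (length(v)) sum(v) else 0
        }, numeric(1L)), tx_ids)
    } else if (!is.null(xl)) {
      stats::setNames(vapply(tx_ids, function(id) {
        sum(xl$est_counts[xl$transcript_id == id])
      }, numeric(1L)), tx_ids)
    } else {
      stats::setNames(rep(0, length(tx_ids)), tx_ids)
    }
    ranks <- rank_transcripts(tot_reads)

    for (id in tx_ids) {
      tr <- tx_results[[id]]
      row <- data.frame(transcript_id = id, gene_id = g$gene_id,
                        rank = unname(ranks[id]), n_snps = tr$n_snps,
                        stringsAsFactors = FALSE)
      ks <- tr$snp_keys
      sub <- lib_sum[lib_sum$key %in% ks, , drop = FALSE]
      tot <- sub$ref + sub$alt
      row$n_snps_covered <- length(unique(sub$key[tot >= min_het]))
      psub <- rep(NA_real_, nrow(sub))
      okp <- tot >= min_het & tot > 0
      if (any(okp)) psub[okp] <- binomial_ai(sub$ref[okp], sub$alt[okp])
      row$n_snps_ai <- length(unique(sub$key[!is.na(psub) & psub < alpha]))
      row$flag_rep_discordant <- tr$flag_rep
      row$flag_opposite_snps <- tr$flag_opp
      for (lib in libs) {
        cv <- tr$cov_ai[tr$cov_ai$library == lib, , drop = FALSE]
        row[[paste0("cov_ref_", lib)]] <- if (nrow(cv)) cv$ref else 0L
        row[[paste0("cov_alt_", lib)]] <- if (nrow(cv)) cv$alt else 0L
        row[[paste0("p_snp_", lib)]] <- if (nrow(cv)) cv$p else NA_real_
        row[[paste0("dir_snp_", lib)]] <-
          if (nrow(cv)) cv$direction else "tie"
        rd <- tr$read_ai
        if (!is.null(rd)) {
          rv <- rd[rd$library == lib, , drop = FALSE]
          row[[paste0("read_ref_", lib)]] <- if (nrow(rv)) rv$ref else 0L
          row[[paste0("read_alt_", lib)]] <- if (nrow(rv)) rv$alt else 0L
          row[[paste0("p_read_", lib)]] <- if (nrow(rv)) rv$p else NA_real_
          row[[paste0("dir_read_", lib)]] <-
            if (nrow(rv)) rv$direction else "tie"
        }
      }
      tx_rows[[id]] <- row
    }

    # gene level
    glc <- lib_sum[lib_sum$key %in% gene_snp_keys, , drop = FALSE]
    glc$pos <- as.integer(sub("^.*:", "", glc$key))
    gcov <- cov_total[gene_snp_keys]
    names(gcov) <- sub("^.*:", "", gene_snp_keys)
    gcov <- gcov[!is.na(gcov)]
    gagg <- gene_aggregate(
      g, glc[!is.na(glc$ref), , drop = FALSE], gcov,
      read_counts = gene_read, window = window, min_het = min_het)
    grow <- data.frame(gene_id = g$gene_id, chrom = g$chrom,
                       start = gspan[1L], end = gspan[2L],
                       n_transcripts = length(tx_ids),
                       n_snps = sum(vg$vtype == "snp"),
                       n_indels = sum(vg$vtype == "indel"),
                       stringsAsFactors = FALSE)
    for (lib in libs) {
      cv <- gagg$snp_coverage[gagg$snp_coverage$library == lib, ,
                              drop = FALSE]
      grow[[paste0("cov_ref_", lib)]] <- if (nrow(cv)) cv$ref else 0L
      grow[[paste0("cov_alt_", lib)]] <- if (nrow(cv)) cv$alt else 0L
      grow[[paste0("p_snp_", lib)]] <- if (nrow(cv)) cv$p else NA_real_
      grow[[paste0("dir_snp_", lib)]] <-
        if (nrow(cv)) cv$direction else "tie"
      if (!is.null(gagg$read_count)) {
        rv <- gagg$read_count[gagg$read_count$library == lib, ,
                              drop = FALSE]
        grow[[paste0("read_ref_", lib)]] <- if (nrow(rv)) rv$ref else 0L
        grow[[paste0("read_alt_", lib)]] <- if (nrow(rv)) rv$alt else 0L
        grow[[paste0("p_read_", lib)]] <- if (nrow(rv)) rv$p else NA_real_
        grow[[paste0("dir_read_", lib)]] <-
          if (nrow(rv)) rv$direction else "tie"
      }
    }
    gene_rows[[g$gene_id]] <- grow
  }

  effects <- if (length(effects)) do.call(rbind, effects) else
    empty_effects()
  if (!is.null(external_effects) && nrow(external_effects)) {
    ext_key <- paste(external_effects$chrom, external_effects$pos,
                     external_effects$alt, external_effects$transcript_id)
    int_key <- paste(effects$chrom, effects$pos, effects$alt,
                     effects$transcript_id)
    effects <- rbind(effects[!int_key %in% ext_key, , drop = FALSE],
                     external_effects[, names(effects)])
  }

  tx_table <- fill_rbind(tx_rows)
  gene_table <- fill_rbind(gene_rows)
  # per-transcript missense/damaging counts from the effect table
  if (!is.null(tx_table) && nrow(effects)) {
    emis <- effects[effects$term == "missense_variant", , drop = FALSE]
    edam <- effects[effects$damaging, , drop = FALSE]
    tx_table$n_missense <- vapply(tx_table$transcript_id, function(id) {
      length(unique(paste(emis$chrom, emis$pos)[emis$transcript_id == id]))
    }, integer(1L))
    tx_table$n_damaging <- vapply(tx_table$transcript_id, function(id) {
      length(unique(paste(edam$chrom, edam$pos)[edam$transcript_id == id]))
    }, integer(1L))
  } else if (!is.null(tx_table)) {
    tx_table$n_missense <- 0L
    tx_table$n_damaging <- 0L
  }

  db <- structure(list(
    snps = snp_table, transcripts = tx_table, genes = gene_table,
    effects = effects, design = design, libraries = libs,
    lib_sum = lib_sum, snp_counts = snp_counts,
    tx_snp_keys = tx_snp_keys,
    params = list(window = window, min_het = min_het, alpha = alpha)),
    class = "ase_db")
  db$overview <- overview_summary(db)
  db
}

# rbind data.frames that may miss columns (filled with NA)
fill_rbind <- function(rows) {
  if (!length(rows)) return(NULL)
  cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (c in setdiff(cols, names(r))) r[[c]] <- NA
    r[, cols]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Overview summary of an assembled database
#'
#' Counts of genes/transcripts bearing SNPs and indels, covered and
#' imbalanced SNPs, substitution-type percentages with complementary pairs
#' grouped, the per-effect table (Count / library-weighted Covered / AI with
#' percentages relative to Covered), discordance-flag counts and the overall
#' reference bias.
#'
#' @param db An `"ase_db"` object.
#' @return A list of class `"ase_overview"`.
#' @export
overview_summary <- function(db) {
  alpha <- db$params$alpha
  min_het <- db$params$min_het
  sn <- db$snps
  tx <- db$transcripts
  ge <- db$genes
  out <- list()
  out$n_genes <- if (is.null(ge)) 0L else nrow(ge)
  out$n_transcripts <- if (is.null(tx)) 0L else nrow(tx)
  out$genes_with_snp <- if (is.null(ge)) 0L else sum(ge$n_snps > 0)
  out$genes_with_indel <- if (is.null(ge)) 0L else sum(ge$n_indels > 0)
  out$transcripts_with_snp <- if (is.null(tx)) 0L else sum(tx$n_snps > 0)
  out$n_snps <- if (is.null(sn)) 0L else nrow(sn)
  out$snps_covered <- if (is.null(sn)) 0L else sum(sn$n_lib_covered > 0)
  out$snps_ai <- if (is.null(sn)) 0L else sum(sn$n_lib_ai > 0)
  if (!is.null(sn) && nrow(sn)) {
    cls <- substitution_class(sn$ref, sn$alt)
    tab <- sort(table(cls), decreasing = TRUE)
    out$substitution_pct <- round(100 * tab / sum(tab), 1)
  } else {
    out$substitution_pct <- numeric(0L)
  }
  # effect table: Count = SNPs bearing the effect; Covered / AI are
  # library-weighted (a SNP covered in 3 of 4 libraries contributes 3)
  eff <- db$effects
  if (!is.null(sn) && nrow(eff)) {
    esnp <- eff[paste(eff$chrom, eff$pos) %in%
                  paste(sn$chrom, sn$pos), , drop = FALSE]
    rows <- lapply(split(esnp, esnp$term), function(e) {
      k <- unique(paste(e$chrom, e$pos))
      idx <- match(k, paste(sn$chrom, sn$pos))
      idx <- idx[!is.na(idx)]
      covered <- sum(sn$n_lib_covered[idx])
      ai <- sum(sn$n_lib_ai[idx])
      data.frame(term = e$term[1L], count = length(k), covered = covered,
                 ai = ai,
                 ai_pct = if (covered > 0) round(100 * ai / covered) else
                   NA_real_,
                 stringsAsFactors = FALSE)
    })
    out$effect_table <- do.call(rbind, rows)
    rownames(out$effect_table) <- NULL
  } else {
    out$effect_table <- NULL
  }
  out$snps_rep_discordant <- if (is.null(sn)) 0L else
    sum(sn$flag_rep_discordant)
  out$transcripts_rep_discordant <- if (is.null(tx)) 0L else
    sum(tx$flag_rep_discordant)
  out$transcripts_opposite_snps <- if (is.null(tx)) 0L else
    sum(tx$flag_opposite_snps)
  out$bias_pct <- if (!is.null(db$snp_counts) && nrow(db$snp_counts)) {
    compute_bias(db$snp_counts$ref_count, db$snp_counts$alt_count)
  } else NA_real_
  structure(out, class = "ase_overview")
}

#' @export
print.ase_overview <- function(x, ...) {
  cat("Allele-specific expression overview\n")
  cat(sprintf("  genes: %d (%d with >=1 SNP, %d with >=1 indel)\n",
              x$n_genes, x$genes_with_snp, x$genes_with_indel))
  cat(sprintf("  transcripts: %d (%d with >=1 SNP)\n", x$n_transcripts,
              x$transcripts_with_snp))
  cat(sprintf("  SNPs: %d; covered (>=1 library): %d; AI (p<0.05): %d\n",
              x$n_snps, x$snps_covered, x$snps_ai))
  if (length(x$substitution_pct)) {
    cat("  substitution classes (%):",
        paste(sprintf("%s=%.1f", names(x$substitution_pct),
                      x$substitution_pct), collapse = " "), "\n")
  }
  if (!is.null(x$effect_table)) {
    cat("  variant effects (Count / Covered / AI):\n")
    et <- x$effect_table
    for (i in seq_len(nrow(et))) {
      cat(sprintf("    %-24s %6d %8d %6d (%s%%)\n", et$term[i],
                  et$count[i], et$covered[i], et$ai[i],
                  ifelse(is.na(et$ai_pct[i]), "-", et$ai_pct[i])))
    }
  }
  cat(sprintf("  replicate-discordant: %d SNPs, %d transcripts\n",
              x$snps_rep_discordant, x$transcripts_rep_discordant))
  cat(sprintf("  opposite-direction-SNP transcripts: %d\n",
              x$transcripts_opposite_snps))
  if (!is.na(x$bias_pct)) {
    cat(sprintf("  reference bias: %.1f%%/%.1f%%\n", x$bias_pct,
                100 - x$bias_pct))
  }
  invisible(x)
}

#' @export
print.ase_db <- function(x, ...) {
  cat(sprintf("<ase_db> %d genes, %d transcripts, %d SNPs, %d libraries\n",
              x$overview$n_genes, x$overview$n_transcripts,
              x$overview$n_snps, length(x$libraries)))
  invisible(x)
}

#' @export
summary.ase_db <- function(object, ...) object$overview

#' Load a simulated or exported study directory and build the database
#'
#' Expects the layout written by [simulate_ase_study()]: `genome.fa`,
#' `genes.gtf`, `variants.vcf`, `design.tsv`, `counts/<stem>.tsv`,
#' optionally `xprs/<stem>.xprs` and `totals.tsv`.
#'
#' @param dir Study directory.
#' @param ... Passed to [build_ase_db()].
#' @return An `"ase_db"` object.
#' @export
load_ase_study <- function(dir, ...) {
  genome <- read_fasta(file.path(dir, "genome.fa"))
  genes <- read_gtf(file.path(dir, "genes.gtf"))
  variants <- read_vcf(file.path(dir, "variants.vcf"))
  design <- read_design(file.path(dir, "design.tsv"))
  snp_counts <- do.call(rbind, lapply(seq_len(nrow(design)), function(i) {
    f <- file.path(dir, "counts", paste0(design$stem[i], ".tsv"))
    df <- utils::read.delim(f, stringsAsFactors = FALSE)
    df$stem <- design$stem[i]
    df
  }))
  xprs <- NULL
  if (dir.exists(file.path(dir, "xprs"))) {
    xprs <- do.call(rbind, lapply(seq_len(nrow(design)), function(i) {
      f <- file.path(dir, "xprs", paste0(design$stem[i], ".xprs"))
      df <- read_xprs(f)
      df$stem <- design$stem[i]
      df
    }))
  }
  totals <- NULL
  tot_path <- file.path(dir, "totals.tsv")
  if (file.exists(tot_path)) {
    totals <- utils::read.delim(tot_path, stringsAsFactors = FALSE)
  }
  build_ase_db(genome, genes, variants, design, snp_counts, xprs = xprs,
               totals = totals, ...)
}
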