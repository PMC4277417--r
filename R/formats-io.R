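# Readers and writers for the standard formats the toolkit touches.
# Internal coordinates are 1-based inclusive (GTF/VCF native); BED is emitted
# 0-based half-open only at the file boundary.

#' Read a FASTA file into a named character vector
#'
#' Sequences are upper-cased; record order is preserved. The identifier is the
#' header token up to the first whitespace; the remainder is kept in a
#' `"descriptions"` attribute.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty FASTA file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  if (any(!nzchar(ids))) stop("FASTA record with empty id in ", path)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  attr(seqs, "descriptions") <- stats::setNames(desc, ids)
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  set <- Biostrings::BStringSet(as.character(seqs))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read gene models from a GTF file
#'
#' Exon and CDS features are grouped into transcripts and transcripts into
#' genes. Coordinates stay 1-based inclusive. Features on chromosomes absent
#' from the genome are retained (validated downstream).
#'
#' @param path Path to a GTF file.
#' @return Named list of [gene_model()] objects, keyed by `gene_id`.
#' @export
read_gtf <- function(path) {
  lines <- readLines(path)
  rows <- list()
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(trimws(line)) || startsWith(line, "#")) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 9L) stop("line ", i, ": fewer than 9 GTF fields")
    feature <- f[3L]
    if (!feature %in% c("exon", "CDS")) next
    start <- suppressWarnings(as.integer(f[4L]))
    end <- suppressWarnings(as.integer(f[5L]))
    if (is.na(start) || is.na(end)) {
      stop("line ", i, ": non-numeric coordinates")
    }
    attrs <- f[9L]
    gene_id <- gtf_attr(attrs, "gene_id")
    tx_id <- gtf_attr(attrs, "transcript_id")
    if (is.na(gene_id)) stop("line ", i, ": missing gene_id attribute")
    if (is.na(tx_id)) stop("line ", i, ": missing transcript_id attribute")
    rows[[length(rows) + 1L]] <- list(
      chrom = f[1L], feature = feature, start = start, end = end,
      strand = f[7L], gene_id = gene_id, transcript_id = tx_id, line = i)
  }
  if (length(rows) == 0L) stop("no exon/CDS features in ", path)
  df <- do.call(rbind, lapply(rows, as.data.frame))
  genes <- list()
  for (gid in unique(df$gene_id)) {
    gdf <- df[df$gene_id == gid, , drop = FALSE]
    txs <- list()
    for (tid in unique(gdf$transcript_id)) {
      tdf <- gdf[gdf$transcript_id == tid, , drop = FALSE]
      if (length(unique(tdf$strand)) != 1L) {
        stop("transcript ", tid, ": features on both strands (lines ",
             paste(tdf$line, collapse = ","), ")")
      }
      if (length(unique(tdf$chrom)) != 1L) {
        stop("transcript ", tid, ": features on multiple chromosomes")
      }
      ex <- tdf[tdf$feature == "exon", c("start", "end"), drop = FALSE]
      cds <- tdf[tdf$feature == "CDS", c("start", "end"), drop = FALSE]
      if (nrow(ex) == 0L) stop("transcript ", tid, ": no exon features")
      txs[[tid]] <- transcript_model(
        tid, chrom = tdf$chrom[1L], strand = tdf$strand[1L],
        exons = as.matrix(ex),
        cds = if (nrow(cds)) as.matrix(cds) else NULL)
    }
    genes[[gid]] <- gene_model(gid, txs)
  }
  genes
}

gtf_attr <- function(attrs, key) {
  pat <- paste0(key, "\\s+\"([^\"]*)\"")
  m <- regmatches(attrs, regexec(pat, attrs))[[1L]]
  if (length(m) < 2L || !nzchar(m[2L])) NA_character_ else m[2L]
}

#' Write gene models to GTF
#' @param genes Named list of gene models.
#' @param path Output path.
#' @export
write_gtf <- function(genes, path) {
  out <- character(0L)
  for (g in genes) {
    for (t in g$transcripts) {
      attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                       g$gene_id, t$transcript_id)
      ex <- t$exons
      out <- c(out, sprintf("%s\tasekit\texon\t%d\t%d\t.\t%s\t.\t%s",
                            t$chrom, ex[, 1L], ex[, 2L], t$strand, attrs))
      if (!is.null(t$cds)) {
        cds <- t$cds
        # frame: bases of the previous codon carried into each CDS chunk,
        # walked in transcript (5'->3') order
        ord <- if (t$strand == "+") order(cds[, 1L]) else order(-cds[, 1L])
        lens <- cds[ord, 2L] - cds[ord, 1L] + 1L
        carried <- cumsum(c(0L, lens[-length(lens)])) %% 3L
        frame <- (3L - carried) %% 3L
        out <- c(out, sprintf("%s\tasekit\tCDS\t%d\t%d\t.\t%s\t%d\t%s",
                              t$chrom, cds[ord, 1L], cds[ord, 2L],
                              t$strand, frame, attrs))
      }
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Read variants from a VCF file
#'
#' Multi-allelic records are split into one row per alternative allele.
#' The first sample's GT is captured when genotypes are present.
#'
#' @param path Path to a VCF 4.x file.
#' @return `data.frame` with columns `chrom, pos, id, ref, alt, vtype,
#'   genotype` (one row per record x alt allele).
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  is_header <- startsWith(lines, "#")
  body_lines <- which(!is_header & nzchar(lines))
  for (i in body_lines) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) >= 2L && is.na(suppressWarnings(as.integer(f[2L])))) {
      stop("line ", i, ": malformed POS field '", f[2L], "'")
    }
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  gt <- NULL
  if (!is.null(v@gt) && ncol(v@gt) >= 2L) {
    gt <- suppressWarnings(vcfR::extract.gt(v, element = "GT"))[, 1L]
    gt <- gsub("|", "/", gt, fixed = TRUE)
  }
  out <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1L]]
    ref <- toupper(fix[i, "REF"])
    for (alt in alts) {
      alt <- toupper(alt)
      vtype <- if (nchar(ref) == 1L && nchar(alt) == 1L) "snp" else "indel"
      out[[length(out) + 1L]] <- data.frame(
        chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
        id = fix[i, "ID"], ref = ref, alt = alt, vtype = vtype,
        genotype = if (is.null(gt)) NA_character_ else unname(gt[i]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      id = character(), ref = character(),
                      alt = character(), vtype = character(),
                      genotype = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write variants to a minimal VCF 4.2 file
#' @param variants `data.frame` as returned by [read_vcf()].
#' @param path Output path.
#' @export
write_vcf <- function(variants, path) {
  has_gt <- "genotype" %in% names(variants) && any(!is.na(variants$genotype))
  hdr <- c("##fileformat=VCFv4.2",
           if (has_gt)
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
                  if (has_gt) "\tFORMAT\tsample1"))
  id <- if ("id" %in% names(variants)) variants$id else "."
  id[is.na(id)] <- "."
  rows <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.", variants$chrom,
                  as.integer(variants$pos), id, variants$ref, variants$alt)
  if (has_gt) {
    g <- variants$genotype
    g[is.na(g)] <- "./."
    rows <- paste0(rows, "\tGT\t", g)
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Parse one samtools mpileup base column
#'
#' Counts reference-matching symbols (`.` and `,`) and case-insensitive
#' occurrences of the alternative allele letter. Read-start markers (`^` plus
#' its mapping-quality character), read-end markers (`$`), indel suffixes
#' (`+n...`/`-n...`) and deletion placeholders (`*`) are consumed without
#' being counted; so are other substitution letters. Base and mapping
#' qualities are ignored: all covering reads count.
#'
#' @param bases The pileup base string for one site.
#' @param ref Reference base (unused in counting; kept for the call contract).
#' @param alt Alternative base.
#' @return Integer vector `c(ref_count, alt_count)`.
#' @export
parse_pileup_column <- function(bases, ref, alt) {
  chars <- strsplit(bases, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  alt_u <- toupper(alt)
  ref_count <- 0L
  alt_count <- 0L
  i <- 1L
  while (i <= n) {
    ch <- chars[[i]]
    if (ch == "^") {
      if (i + 1L > n) stop("dangling '^' at end of pileup string")
      i <- i + 2L                       # skip the quality character
    } else if (ch == "$") {
      i <- i + 1L
    } else if (ch == "+" || ch == "-") {
      j <- i + 1L
      while (j <= n && grepl("[0-9]", chars[[j]])) j <- j + 1L
      if (j == i + 1L) stop("malformed indel suffix at position ", i)
      len <- as.integer(paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      if (j + len - 1L > n) stop("malformed indel length at position ", i)
      i <- j + len
    } else {
      if (ch == "." || ch == ",") {
        ref_count <- ref_count + 1L
      } else if (toupper(ch) == alt_u) {
        alt_count <- alt_count + 1L
      }
      i <- i + 1L
    }
  }
  c(ref_count = ref_count, alt_count = alt_count)
}

#' Read a transcript-quantification count table (.xprs dialect)
#'
#' Expects a TSV with header columns `target_id` and `est_counts`. Target ids
#' carrying a parental suffix (`_R` reference / `_A` alternative) are split
#' into the bare transcript id and an `allele` column.
#'
#' @param path Path to the TSV file.
#' @return `data.frame` with columns `target_id, transcript_id, allele,
#'   est_counts` (`allele` is `"ref"`, `"alt"` or `NA`).
#' @export
read_xprs <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  for (col in c("target_id", "est_counts")) {
    if (!col %in% names(df)) {
      stop("missing required column '", col, "' in ", path)
    }
  }
  est <- suppressWarnings(as.numeric(df$est_counts))
  if (anyNA(est)) stop("non-numeric est_counts in ", path)
  if (any(est < 0)) stop("negative est_counts in ", path)
  allele <- rep(NA_character_, nrow(df))
  allele[grepl("_R$", df$target_id)] <- "ref"
  allele[grepl("_A$", df$target_id)] <- "alt"
  tx <- sub("_(R|A)$", "", df$target_id)
  data.frame(target_id = df$target_id, transcript_id = tx, allele = allele,
             est_counts = est, stringsAsFactors = FALSE)
}

#' Write an xprs-style count table
#' @param df `data.frame` with `target_id` and `est_counts` columns.
#' @param path Output path.
#' @export
write_xprs <- function(df, path) {
  utils::write.table(df[, c("target_id", "est_counts")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-SNP per-replicate counts as BED
#'
#' BED convention: 0-based start = pos - 1, half-open end = pos. Columns are
#' `chrom, start, end, replicate, ref_count, alt_count, library`; rows are
#' sorted by (chrom, start, replicate). No header; an empty record set yields
#' an empty file.
#'
#' @param records `data.frame` with columns `chrom, pos, replicate,
#'   ref_count, alt_count` and optionally `library`.
#' @param path Output path.
#' @export
write_snp_coverage <- function(records, path) {
  if (nrow(records) == 0L) {
    writeLines(character(0L), path)
    return(invisible(path))
  }
  need <- c("chrom", "pos", "replicate", "ref_count", "alt_count")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  lib <- if ("library" %in% names(records)) records$library else "."
  bed <- data.frame(chrom = records$chrom,
                    start = as.integer(records$pos) - 1L,
                    end = as.integer(records$pos),
                    replicate = records$replicate,
                    ref_count = records$ref_count,
                    alt_count = records$alt_count,
                    library = lib, stringsAsFactors = FALSE)
  bed <- bed[order(bed$chrom, bed$start, bed$replicate), , drop = FALSE]
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a SNP-coverage BED file written by [write_snp_coverage()]
#' @param path Path to the BED file.
#' @return `data.frame` with 1-based `pos` restored.
#' @export
read_snp_coverage <- function(path) {
  if (file.size(path) == 0) {
    return(data.frame(chrom = character(), pos = integer(),
                      replicate = character(), ref_count = integer(),
                      alt_count = integer(), library = character(),
                      stringsAsFactors = FALSE))
  }
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("chrom", "start", "end", "replicate", "ref_count",
                 "alt_count", "library")[seq_len(ncol(df))]
  data.frame(chrom = df$chrom, pos = df$start + 1L,
             replicate = as.character(df$replicate),
             ref_count = df$ref_count, alt_count = df$alt_count,
             library = if ("library" %in% names(df)) df$library else ".",
             stringsAsFactors = FALSE)
}

#' Read a design table mapping file stems to library conditions
#'
#' The file-naming convention carries each replicate's condition through the
#' pipeline; the design table makes the mapping explicit.
#'
#' @param path TSV with header columns `stem, library, replicate`.
#' @return `data.frame` with those columns.
#' @export
read_design <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("stem", "library", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("design file missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$stem)) stop("duplicate stems in design file")
  if (nrow(df) == 0L) stop("empty design file")
  df[, need]
}
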