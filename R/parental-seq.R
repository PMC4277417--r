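# Reference and alternative parental transcript/protein construction and
# basic variant-effect classification. The F1 design has two inbred parents
# with the reference strain as one of them, so every alternative allele
# belongs to the alternative parent and no phasing is needed.

comp_base <- function(x) chartr("ACGTN", "TGCAN", x)

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Spliced sequence of a transcript
#'
#' Exon sequences concatenated 5' to 3'; minus-strand transcripts are
#' reverse-complemented.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param t A transcript model.
#' @return Character scalar.
#' @export
splice_transcript <- function(genome, t) {
  if (!t$chrom %in% names(genome)) {
    stop("chromosome ", t$chrom, " not in genome")
  }
  chrom_seq <- genome[[t$chrom]]
  if (max(t$exons[, 2L]) > nchar(chrom_seq)) {
    stop("transcript ", t$transcript_id, ": exon beyond end of ", t$chrom)
  }
  parts <- substring(chrom_seq, t$exons[, 1L], t$exons[, 2L])
  s <- paste(parts, collapse = "")
  if (t$strand == "-") revcomp(s) else s
}

#' Substitute variants into a spliced transcript sequence
#'
#' Builds the alternative-parent transcript by replacing each variant's
#' reference span with its alternative allele. Edits are applied in
#' descending spliced coordinate so upstream positions are unaffected by
#' length changes; minus-strand variants are applied as reverse complements
#' of their alleles. Variants spanning an exon-intron boundary (or lying
#' outside the exons) are excluded with a warning — partial application is
#' not well defined.
#'
#' @param t A transcript model.
#' @param ref_seq Spliced reference sequence of `t` ([splice_transcript()]).
#' @param variants Variant `data.frame` (columns `chrom, pos, ref, alt`).
#' @return `list(transcript_id, ref_seq, alt_seq, applied, skipped)` where
#'   `applied` records each edit's spliced position and length change.
#' @export
apply_variants <- function(t, ref_seq, variants) {
  edits <- list()
  skipped <- character(0L)
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    span <- v$pos:(v$pos + nchar(v$ref) - 1L)
    sp <- genomic_to_spliced(t, span)
    key <- sprintf("%s:%d:%s>%s", v$chrom, v$pos, v$ref, v$alt)
    if (anyNA(sp) || (length(sp) > 1L && any(diff(sort(sp)) != 1L))) {
      warning("variant ", key, " spans a splice boundary or lies outside ",
              "the exons of ", t$transcript_id, "; excluded")
      skipped <- c(skipped, key)
      next
    }
    if (t$strand == "-") {
      sp_start <- min(sp)
      ref_t <- revcomp(v$ref)
      alt_t <- revcomp(v$alt)
    } else {
      sp_start <- sp[1L]
      ref_t <- toupper(v$ref)
      alt_t <- toupper(v$alt)
    }
    found <- substr(ref_seq, sp_start, sp_start + nchar(ref_t) - 1L)
    if (found != ref_t) {
      stop("reference mismatch for ", key, " on ", t$transcript_id,
           ": expected ", ref_t, ", found ", found)
    }
    edits[[length(edits) + 1L]] <- data.frame(
      key = key, sp_start = sp_start, ref_len = nchar(ref_t),
      alt_len = nchar(alt_t), alt_t = alt_t, stringsAsFactors = FALSE)
  }
  alt_seq <- ref_seq
  applied <- data.frame(key = character(), sp_start = integer(),
                        ref_len = integer(), alt_len = integer(),
                        alt_t = character(), stringsAsFactors = FALSE)
  if (length(edits)) {
    applied <- do.call(rbind, edits)
    ends <- applied$sp_start + applied$ref_len - 1L
    o <- order(applied$sp_start)
    if (any(applied$sp_start[o][-1L] <= ends[o][-length(o)])) {
      stop("overlapping variants on ", t$transcript_id)
    }
    for (j in order(-applied$sp_start)) {
      s <- applied$sp_start[j]
      e <- s + applied$ref_len[j] - 1L
      alt_seq <- paste0(substr(alt_seq, 1L, s - 1L), applied$alt_t[j],
                        substr(alt_seq, e + 1L, nchar(alt_seq)))
    }
    applied <- applied[o, , drop = FALSE]
    rownames(applied) <- NULL
  }
  list(transcript_id = t$transcript_id, ref_seq = ref_seq,
       alt_seq = alt_seq, applied = applied, skipped = skipped)
}

#' Translate from a CDS start to the first stop codon
#'
#' Standard genetic code; translation runs from `cds_start` to the first stop
#' codon (not emitted) or the end of the sequence, ignoring a trailing
#' partial codon. Running past the annotated CDS end is intentional: on the
#' alternative haplotype an upstream indel or a lost stop can move the actual
#' stop downstream.
#'
#' @param spliced_seq Spliced nucleotide sequence.
#' @param cds_start 1-based spliced position of the first CDS base.
#' @return Amino-acid string.
#' @export
translate_cds <- function(spliced_seq, cds_start) {
  n <- nchar(spliced_seq)
  if (cds_start > n) stop("CDS start beyond sequence end")
  sub <- substr(spliced_seq, cds_start, n)
  if (nchar(sub) < 3L) stop("CDS shorter than one codon")
  n3 <- (nchar(sub) %/% 3L) * 3L
  sub <- substr(sub, 1L, n3)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                           no.init.codon = TRUE,
                                           if.fuzzy.codon = "X"))
  sub("\\*.*$", "", aa)
}

#' Classify the basic effect of a variant on one transcript
#'
#' Maps the variant position onto the transcript anatomy: exonic upstream of
#' the CDS start (in transcript orientation) is a 5' UTR variant, downstream
#' of the CDS end a 3' UTR variant, within the CDS a codon comparison decides
#' synonymous / missense / stop_gained / stop_lost, intronic positions within
#' the (gene) span are intron variants, and exonic positions of a transcript
#' without CDS are non-coding variants. Indels overlapping the CDS are
#' labelled `coding_sequence_variant` (their detailed consequence is left to
#' external annotators). Internally computed effects are never damaging.
#'
#' @param v One-row variant `data.frame` (or list) with `chrom, pos, ref,
#'   alt, vtype`.
#' @param t A transcript model on the same chromosome.
#' @param ref_seq Spliced reference sequence of `t`.
#' @param span Optional genomic span to test the variant against (defaults
#'   to the transcript span; pass the gene span when classifying gene-wise).
#' @return `data.frame` row: `chrom, pos, ref, alt, transcript_id, term,
#'   damaging, source`.
#' @export
classify_effect <- function(v, t, ref_seq, span = NULL) {
  span <- span %||% transcript_span(t)
  if (v$pos < span[1L] || v$pos + nchar(v$ref) - 1L > span[2L]) {
    stop("variant ", v$chrom, ":", v$pos, " outside span ",
         span[1L], "-", span[2L])
  }
  cr <- cds_spliced_range(t)
  term <- if (identical(v$vtype, "snp")) {
    sp <- genomic_to_spliced(t, v$pos)
    if (is.na(sp)) {
      "intron_variant"
    } else if (is.null(cr)) {
      "non_coding_variant"
    } else if (sp < cr[1L]) {
      "5_prime_UTR_variant"
    } else if (sp > cr[2L]) {
      "3_prime_UTR_variant"
    } else {
      alt_t <- if (t$strand == "-") comp_base(toupper(v$alt)) else
        toupper(v$alt)
      ci <- (sp - cr[1L]) %/% 3L
      cstart <- cr[1L] + 3L * ci
      codon_ref <- substr(ref_seq, cstart, cstart + 2L)
      off <- sp - cstart + 1L
      codon_alt <- codon_ref
      substr(codon_alt, off, off) <- alt_t
      aa_ref <- unname(Biostrings::GENETIC_CODE[codon_ref])
      aa_alt <- unname(Biostrings::GENETIC_CODE[codon_alt])
      if (is.na(aa_ref) || is.na(aa_alt)) {
        "non_coding_variant"          # ambiguous bases: cannot translate
      } else if (aa_ref == aa_alt) {
        "synonymous_variant"
      } else if (aa_alt == "*") {
        "stop_gained"
      } else if (aa_ref == "*") {
        "stop_lost"
      } else {
        "missense_variant"
      }
    }
  } else {
    sp <- genomic_to_spliced(t, v$pos:(v$pos + nchar(v$ref) - 1L))
    if (all(is.na(sp))) {
      "intron_variant"
    } else if (is.null(cr)) {
      "non_coding_variant"
    } else if (any(!is.na(sp) & sp >= cr[1L] & sp <= cr[2L])) {
      "coding_sequence_variant"
    } else if (all(sp[!is.na(sp)] < cr[1L])) {
      "5_prime_UTR_variant"
    } else {
      "3_prime_UTR_variant"
    }
  }
  data.frame(chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
             transcript_id = t$transcript_id, term = term, damaging = FALSE,
             source = "internal", stringsAsFactors = FALSE)
}

#' Import variant effects from an external annotator
#'
#' Two dialects are supported. `"vep"` is the Ensembl VEP default
#' tab-separated output (header line starting `#Uploaded_variation`); a SIFT
#' prediction of "deleterious" marks the variant damaging. `"snpeff"` is a
#' snpEff-style effect table (TSV with columns `chrom, pos, ref, alt,
#' transcript_id, effect, impact`); impact HIGH (e.g. frameshifts) marks the
#' variant damaging. Known effect terms are mapped onto the internal
#' vocabulary; unknown terms pass through verbatim.
#'
#' @param path Path to the annotation file.
#' @param dialect `"vep"` or `"snpeff"`.
#' @return `data.frame` with the [classify_effect()] layout (VEP rows carry
#'   `NA` ref alleles: the VEP default output does not report them).
#' @export
import_external_effects <- function(path, dialect = c("vep", "snpeff")) {
  dialect <- match.arg(dialect)
  if (dialect == "vep") {
    lines <- readLines(path)
    hdr_i <- grep("^#Uploaded_variation", lines)
    if (length(hdr_i) != 1L) {
      stop("unrecognized VEP header in ", path,
           " (expected a '#Uploaded_variation' header line)")
    }
    cols <- strsplit(sub("^#", "", lines[hdr_i]), "\t", fixed = TRUE)[[1L]]
    body <- lines[-seq_len(hdr_i)]
    body <- body[nzchar(body) & !startsWith(body, "#")]
    if (!length(body)) return(empty_effects())
    m <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
    colnames(m) <- cols[seq_len(ncol(m))]
    need <- c("Location", "Allele", "Feature", "Consequence")
    if (!all(need %in% colnames(m))) {
      stop("unrecognized VEP header: missing ",
           paste(setdiff(need, colnames(m)), collapse = ", "))
    }
    loc <- strsplit(m[, "Location"], ":", fixed = TRUE)
    chrom <- vapply(loc, `[[`, "", 1L)
    pos <- as.integer(sub("-.*$", "", vapply(loc, `[[`, "", 2L)))
    term <- vapply(strsplit(m[, "Consequence"], ",", fixed = TRUE),
                   function(x) map_effect_term(x[[1L]]), "")
    extra <- if ("Extra" %in% colnames(m)) m[, "Extra"] else ""
    sift_col <- if ("SIFT" %in% colnames(m)) m[, "SIFT"] else ""
    damaging <- grepl("SIFT=deleterious", extra) |
      grepl("^deleterious", sift_col)
    data.frame(chrom = chrom, pos = pos, ref = NA_character_,
               alt = m[, "Allele"], transcript_id = m[, "Feature"],
               term = term, damaging = damaging, source = "vep",
               stringsAsFactors = FALSE)
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("chrom", "pos", "ref", "alt", "transcript_id", "effect",
              "impact")
    if (!all(need %in% names(df))) {
      stop("unrecognized snpEff table header: missing ",
           paste(setdiff(need, names(df)), collapse = ", "))
    }
    data.frame(chrom = df$chrom, pos = as.integer(df$pos), ref = df$ref,
               alt = df$alt, transcript_id = df$transcript_id,
               term = vapply(df$effect, map_effect_term, ""),
               damaging = toupper(df$impact) == "HIGH", source = "snpeff",
               stringsAsFactors = FALSE)
  }
}

empty_effects <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), transcript_id = character(),
             term = character(), damaging = logical(), source = character(),
             stringsAsFactors = FALSE)
}

# legacy annotator vocabularies mapped onto the internal (Sequence
# Ontology style) terms; unknown terms pass through verbatim
map_effect_term <- function(term) {
  map <- c(NON_SYNONYMOUS_CODING = "missense_variant",
           SYNONYMOUS_CODING = "synonymous_variant",
           STOP_GAINED = "stop_gained",
           STOP_LOST = "stop_lost",
           UTR_5_PRIME = "5_prime_UTR_variant",
           UTR_3_PRIME = "3_prime_UTR_variant",
           INTRON = "intron_variant")
  if (term %in% names(map)) unname(map[term]) else term
}

#' Build both parental sequences for every transcript
#'
#' For each transcript the reference spliced sequence is extracted, the
#' exonic variants are substituted to obtain the alternative-parent
#' sequence, and both are translated when the transcript has a CDS. The
#' alternative CDS start is shifted by the net length change of applied
#' variants lying wholly 5' of it, and the alternative protein stops at its
#' first stop codon (which may shorten or lengthen it relative to the
#' reference).
#'
#' @param genome Named character vector of sequences.
#' @param genes Named list of gene models.
#' @param variants Variant `data.frame`.
#' @return Named list (by transcript id) of
#'   `list(transcript_id, gene_id, ref_seq, alt_seq, ref_protein,
#'   alt_protein, applied, skipped)`.
#' @export
build_parental_pairs <- function(genome, genes, variants) {
  pairs <- list()
  for (g in genes) {
    vg <- variants[variants$chrom == g$chrom, , drop = FALSE]
    for (t in g$transcripts) {
      ref_seq <- splice_transcript(genome, t)
      span <- transcript_span(t)
      vt <- vg[vg$pos >= span[1L] & vg$pos <= span[2L], , drop = FALSE]
      if (nrow(vt)) {
        sp1 <- genomic_to_spliced(t, vt$pos)
        vt <- vt[!is.na(sp1), , drop = FALSE]    # exonic anchor only
      }
      pr <- apply_variants(t, ref_seq, vt)
      ref_protein <- alt_protein <- ""
      cr <- cds_spliced_range(t)
      if (!is.null(cr)) {
        ref_protein <- translate_cds(ref_seq, cr[1L])
        shift <- 0L
        if (nrow(pr$applied)) {
          before <- pr$applied$sp_start + pr$applied$ref_len - 1L < cr[1L]
          shift <- sum(pr$applied$alt_len[before] -
                         pr$applied$ref_len[before])
        }
        alt_protein <- translate_cds(pr$alt_seq, cr[1L] + shift)
      }
      pairs[[t$transcript_id]] <- list(
        transcript_id = t$transcript_id, gene_id = g$gene_id,
        ref_seq = ref_seq, alt_seq = pr$alt_seq,
        ref_protein = ref_protein, alt_protein = alt_protein,
        applied = pr$applied, skipped = pr$skipped)
    }
  }
  pairs
}

#' Write parental sequence FASTA files
#'
#' Emits four FASTA files under `outdir`: reference and alternative
#' transcripts (`transcripts_ref.fa`, `transcripts_alt.fa`) and, for coding
#' transcripts, proteins (`proteins_ref.fa`, `proteins_alt.fa`). Record ids
#' carry the reversible parental suffixes `_R` and `_A`.
#'
#' @param pairs Result of [build_parental_pairs()].
#' @param outdir Output directory (created if missing).
#' @return Invisible character vector of the written paths.
#' @export
write_parental_fasta <- function(pairs, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ids <- names(pairs)
  grab <- function(field) vapply(pairs, `[[`, "", field)
  paths <- c(file.path(outdir, "transcripts_ref.fa"),
             file.path(outdir, "transcripts_alt.fa"))
  write_fasta(stats::setNames(grab("ref_seq"), paste0(ids, "_R")), paths[1L])
  write_fasta(stats::setNames(grab("alt_seq"), paste0(ids, "_A")), paths[2L])
  prot <- grab("ref_protein")
  coding <- nzchar(prot)
  if (any(coding)) {
    p3 <- file.path(outdir, "proteins_ref.fa")
    p4 <- file.path(outdir, "proteins_alt.fa")
    write_fasta(stats::setNames(prot[coding],
                                paste0(ids[coding], "_R")), p3)
    write_fasta(stats::setNames(grab("alt_protein")[coding],
                                paste0(ids[coding], "_A")), p4)
    paths <- c(paths, p3, p4)
  }
  invisible(paths)
}
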