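#' Construct a transcript model
#'
#' A transcript model is the minimal description of an isoform needed for
#' spliced-coordinate arithmetic: its exons (1-based inclusive genomic
#' intervals, non-overlapping), optional CDS intervals (each contained in an
#' exon) and strand. Coordinates are genomic throughout; spliced (transcript)
#' coordinates are derived on demand.
#'
#' @param transcript_id Identifier string.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix (start, end), 1-based inclusive.
#' @param cds Optional two-column matrix of coding intervals.
#' @return A list of class `"transcript_model"`.
#' @export
transcript_model <- function(transcript_id, chrom, strand, exons, cds = NULL) {
  stopifnot(is.character(transcript_id), length(transcript_id) == 1L,
            nzchar(transcript_id))
  if (!strand %in% c("+", "-")) {
    stop("strand must be '+' or '-' for transcript ", transcript_id)
  }
  exons <- as_interval_matrix(exons)
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (nrow(exons) == 0L) stop("transcript ", transcript_id, " has no exons")
  if (any(exons[, 2L] < exons[, 1L])) {
    stop("transcript ", transcript_id, ": exon end precedes start")
  }
  if (nrow(exons) > 1L &&
      any(exons[-1L, 1L] <= exons[-nrow(exons), 2L])) {
    stop("transcript ", transcript_id, ": overlapping exons")
  }
  if (!is.null(cds)) {
    cds <- as_interval_matrix(cds)
    cds <- cds[order(cds[, 1L]), , drop = FALSE]
    if (nrow(cds) == 0L) cds <- NULL
  }
  if (!is.null(cds)) {
    contained <- vapply(seq_len(nrow(cds)), function(i) {
      any(cds[i, 1L] >= exons[, 1L] & cds[i, 2L] <= exons[, 2L])
    }, logical(1L))
    if (!all(contained)) {
      stop("transcript ", transcript_id,
           ": CDS interval not contained in an exon")
    }
  }
  structure(list(transcript_id = transcript_id, chrom = chrom,
                 strand = strand, exons = exons, cds = cds),
            class = "transcript_model")
}

#' Construct a gene model
#'
#' @param gene_id Identifier string.
#' @param transcripts List of [transcript_model()] objects sharing one
#'   chromosome and strand.
#' @return A list of class `"gene_model"`. The gene span is the leftmost
#'   transcript start to the rightmost transcript end.
#' @export
gene_model <- function(gene_id, transcripts) {
  stopifnot(length(transcripts) >= 1L)
  chroms <- unique(vapply(transcripts, `[[`, "", "chrom"))
  strands <- unique(vapply(transcripts, `[[`, "", "strand"))
  if (length(chroms) != 1L) {
    stop("gene ", gene_id, ": transcripts on multiple chromosomes")
  }
  if (length(strands) != 1L) {
    stop("gene ", gene_id, ": transcripts on both strands")
  }
  names(transcripts) <- vapply(transcripts, `[[`, "", "transcript_id")
  structure(list(gene_id = gene_id, chrom = chroms, strand = strands,
                 transcripts = transcripts),
            class = "gene_model")
}

as_interval_matrix <- function(x) {
  m <- matrix(as.integer(as.matrix(x)), ncol = 2L,
              dimnames = list(NULL, c("start", "end")))
  m
}

#' @export
print.gene_model <- function(x, ...) {
  sp <- gene_span(x)
  cat(sprintf("<gene_model> %s %s:%d-%d (%s), %d transcript(s)\n",
              x$gene_id, x$chrom, sp[1L], sp[2L], x$strand,
              length(x$transcripts)))
  invisible(x)
}

#' Genomic span of a transcript or gene
#'
#' @param x A transcript or gene model.
#' @return Integer vector `c(start, end)`.
#' @export
transcript_span <- function(x) {
  c(min(x$exons[, 1L]), max(x$exons[, 2L]))
}

#' @rdname transcript_span
#' @export
gene_span <- function(x) {
  spans <- vapply(x$transcripts, transcript_span, integer(2L))
  c(min(spans[1L, ]), max(spans[2L, ]))
}

#' Spliced length of a transcript
#' @param t A transcript model.
#' @return Total exonic length in bases.
#' @export
spliced_length <- function(t) {
  sum(t$exons[, 2L] - t$exons[, 1L] + 1L)
}

#' Map genomic positions to spliced transcript coordinates
#'
#' Position 1 is the transcript's 5' end, so minus-strand transcripts count
#' from their rightmost genomic base. Non-exonic positions map to `NA`.
#'
#' @param t A transcript model.
#' @param pos Integer vector of genomic positions.
#' @return Integer vector of spliced positions (NA where intronic/outside).
#' @export
genomic_to_spliced <- function(t, pos) {
  ex <- t$exons
  w <- ex[, 2L] - ex[, 1L] + 1L
  off <- cumsum(c(0L, w))[seq_len(nrow(ex))]
  idx <- findInterval(pos, ex[, 1L])
  sp <- rep(NA_integer_, length(pos))
  ok <- idx >= 1L & pos <= ex[pmax(idx, 1L), 2L]
  sp[ok] <- off[idx[ok]] + (pos[ok] - ex[idx[ok], 1L] + 1L)
  if (t$strand == "-") {
    L <- sum(w)
    sp <- ifelse(is.na(sp), NA_integer_, L - sp + 1L)
  }
  as.integer(sp)
}

#' Map spliced transcript coordinates back to genomic positions
#' @param t A transcript model.
#' @param sp Integer vector of spliced positions (1..spliced_length).
#' @return Integer vector of genomic positions.
#' @export
spliced_to_genomic <- function(t, sp) {
  ex <- t$exons
  w <- ex[, 2L] - ex[, 1L] + 1L
  L <- sum(w)
  if (any(sp < 1L | sp > L)) stop("spliced position out of range")
  sp_plus <- if (t$strand == "-") L - sp + 1L else sp
  ends <- cumsum(w)
  idx <- vapply(sp_plus, function(p) which(p <= ends)[1L], integer(1L))
  off <- c(0L, ends[-length(ends)])
  as.integer(ex[idx, 1L] + (sp_plus - off[idx]) - 1L)
}

#' Spliced-coordinate range of a transcript's CDS
#'
#' @param t A transcript model with a non-NULL `cds`.
#' @return Integer `c(start, end)` in spliced coordinates, or `NULL` when the
#'   transcript is non-coding.
#' @export
cds_spliced_range <- function(t) {
  if (is.null(t$cds)) return(NULL)
  sp <- genomic_to_spliced(t, as.vector(t$cds))
  if (anyNA(sp)) stop("transcript ", t$transcript_id,
                      ": CDS outside exons")
  c(min(sp), max(sp))
}

# merged exon union across a gene's transcripts, as an interval matrix
exon_union <- function(g) {
  ex <- do.call(rbind, lapply(g$transcripts, `[[`, "exons"))
  ex <- ex[order(ex[, 1L], ex[, 2L]), , drop = FALSE]
  out <- ex[1L, , drop = FALSE]
  if (nrow(ex) > 1L) {
    for (i in 2L:nrow(ex)) {
      j <- nrow(out)
      if (ex[i, 1L] <= out[j, 2L] + 1L) {
        out[j, 2L] <- max(out[j, 2L], ex[i, 2L])
      } else {
        out <- rbind(out, ex[i, , drop = FALSE])
      }
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
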