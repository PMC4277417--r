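# Non-graphical query layer: filter entity tables on ranks, effect counts,
# per-library p-value ceilings and flags; combine tables with set algebra;
# export selections as TSV or parental FASTA.

#' Extract an entity table from a database
#'
#' @param db An `"ase_db"` object.
#' @param level `"gene"`, `"transcript"` or `"snp"`.
#' @return The table with a `"level"` attribute and its key column set.
#' @export
entity_table <- function(db, level = c("transcript", "gene", "snp")) {
  level <- match.arg(level)
  tab <- switch(level, transcript = db$transcripts, gene = db$genes,
                snp = db$snps)
  if (is.null(tab)) stop("no ", level, " table in database")
  attr(tab, "level") <- level
  attr(tab, "key") <- switch(level, transcript = "transcript_id",
                             gene = "gene_id", snp = "key")
  tab
}

table_level <- function(t) {
  lv <- attr(t, "level")
  if (is.null(lv)) stop("not an entity table (missing level attribute)")
  lv
}

table_key <- function(t) {
  k <- attr(t, "key")
  if (is.null(k)) stop("not an entity table (missing key attribute)")
  t[[k]]
}

#' Filter an entity table
#'
#' All supplied criteria combine by conjunction; row order is preserved.
#' Undefined (`NA`) p-values fail every p-value criterion. P-value ceilings
#' are given as a named list `"measure:library" = ceiling` with measure
#' `snp_coverage` or `read_count`, e.g.
#' `p = list("snp_coverage:lib1" = 0.01, "read_count:lib1" = 0.01)`; a row
#' passes a ceiling when that library's p-value for that measure is below
#' it. Disjunctive queries are built with [combine_tables()].
#'
#' @param t An entity table ([entity_table()]).
#' @param rank Optional exact isoform rank (transcript tables).
#' @param min_missense Optional minimum number of missense SNPs.
#' @param min_damaging Optional minimum number of damaging SNPs.
#' @param p Optional named list of p-value ceilings (see above).
#' @param min_snps_covered Optional minimum `n_snps_covered`.
#' @param direction Optional `"ref>alt"` or `"alt>ref"`: at least one
#'   library must show that direction with a defined p-value (for the
#'   measures named in `p`, or SNP coverage by default).
#' @param flags Optional character vector of flag columns that must be TRUE
#'   (e.g. `"flag_opposite_snps"`).
#' @return The filtered table.
#' @export
filter_table <- function(t, rank = NULL, min_missense = NULL,
                         min_damaging = NULL, p = NULL,
                         min_snps_covered = NULL, direction = NULL,
                         flags = NULL) {
  crit <- list(rank, min_missense, min_damaging, p, min_snps_covered,
               direction, flags)
  if (all(vapply(crit, is.null, logical(1L)))) {
    stop("empty filter: set at least one criterion")
  }
  level <- table_level(t)
  keep <- rep(TRUE, nrow(t))
  need_col <- function(col, what) {
    if (!col %in% names(t)) stop("no ", what, " column '", col,
                                 "' in ", level, " table")
    t[[col]]
  }
  if (!is.null(rank)) keep <- keep & need_col("rank", "rank") == rank
  if (!is.null(min_missense)) {
    keep <- keep & need_col("n_missense", "missense") >= min_missense
  }
  if (!is.null(min_damaging)) {
    keep <- keep & need_col("n_damaging", "damaging") >= min_damaging
  }
  if (!is.null(min_snps_covered)) {
    keep <- keep & need_col("n_snps_covered", "coverage") >=
      min_snps_covered
  }
  measures <- c(snp_coverage = "p_snp_", read_count = "p_read_")
  dirs <- c(snp_coverage = "dir_snp_", read_count = "dir_read_")
  p_cols <- character(0L)
  if (!is.null(p)) {
    if (any(unlist(p) <= 0 | unlist(p) > 1)) {
      stop("p-value ceilings must lie in (0, 1]")
    }
    for (spec in names(p)) {
      parts <- strsplit(spec, ":", fixed = TRUE)[[1L]]
      if (length(parts) != 2L || !parts[1L] %in% names(measures)) {
        stop("p ceiling must be named 'measure:library' with measure ",
             "snp_coverage or read_count: ", spec)
      }
      col <- paste0(measures[parts[1L]], parts[2L])
      if (!col %in% names(t)) {
        stop("unknown library '", parts[2L], "' for measure ", parts[1L])
      }
      p_cols <- c(p_cols, col)
      keep <- keep & !is.na(t[[col]]) & t[[col]] < p[[spec]]
    }
  }
  if (!is.null(direction)) {
    if (!direction %in% c("ref>alt", "alt>ref")) {
      stop("direction must be 'ref>alt' or 'alt>ref'")
    }
    dir_cols <- if (length(p_cols)) {
      sub("^p_", "dir_", p_cols)
    } else {
      grep("^dir_snp_", names(t), value = TRUE)
    }
    if (!length(dir_cols)) stop("no direction columns in table")
    hit <- rep(FALSE, nrow(t))
    for (dc in dir_cols) {
      pc <- sub("^dir_", "p_", dc)
      hit <- hit | (t[[dc]] == direction & !is.na(t[[pc]]))
    }
    keep <- keep & hit
  }
  if (!is.null(flags)) {
    for (fl in flags) keep <- keep & need_col(fl, "flag")
  }
  out <- t[keep, , drop = FALSE]
  attr(out, "level") <- level
  attr(out, "key") <- attr(t, "key")
  out
}

#' Combine two entity tables by key-set algebra
#'
#' Tables must be at the same level. Union prefers the first table's row on
#' key collision; difference is `a` minus `b`'s keys. Row order follows `a`
#' (union appends `b`'s novel rows).
#'
#' @param a,b Entity tables of equal level.
#' @param op `"union"`, `"intersection"` or `"difference"`.
#' @return The combined table.
#' @export
combine_tables <- function(a, b, op = c("union", "intersection",
                                        "difference")) {
  op <- match.arg(op)
  if (!identical(table_level(a), table_level(b))) {
    stop("cannot combine tables of different levels (",
         table_level(a), " vs ", table_level(b), ")")
  }
  ka <- table_key(a)
  kb <- table_key(b)
  out <- switch(op,
    union = rbind(a, b[!kb %in% ka, , drop = FALSE]),
    intersection = a[ka %in% kb, , drop = FALSE],
    difference = a[!ka %in% kb, , drop = FALSE])
  attr(out, "level") <- table_level(a)
  attr(out, "key") <- attr(a, "key")
  rownames(out) <- NULL
  out
}

#' Export a selection as TSV or parental FASTA
#'
#' TSV export writes a header plus one row per entity with `NA` for
#' undefined values; re-reading reproduces the table. FASTA export writes
#' the paired reference/alternative parental records (`_R`/`_A` suffixes)
#' for each selected transcript — nucleotide files always, protein files
#' when the transcripts are coding — e.g. for downstream protein-folding
#' comparison of the two parental proteins.
#'
#' @param t An entity table.
#' @param path Output path (TSV) or directory (FASTA).
#' @param what `"tsv"` or `"parental_fasta"`.
#' @param pairs Parental sequence store ([build_parental_pairs()]); required
#'   for FASTA export.
#' @param columns Optional column selection (in order) for TSV export.
#' @return Invisible path(s) written.
#' @export
export_selection <- function(t, path, what = c("tsv", "parental_fasta"),
                             pairs = NULL, columns = NULL) {
  what <- match.arg(what)
  if (what == "tsv") {
    out <- if (is.null(columns)) t else t[, columns, drop = FALSE]
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    return(invisible(path))
  }
  if (is.null(pairs)) stop("parental_fasta export needs a sequence store")
  ids <- t$transcript_id
  if (is.null(ids)) stop("parental_fasta export needs a transcript table")
  missing <- setdiff(ids, names(pairs))
  if (length(missing)) {
    stop("no parental sequences built for: ",
         paste(missing, collapse = ", "))
  }
  invisible(write_parental_fasta(pairs[ids], path))
}

#' Re-read a TSV exported by [export_selection()]
#' @param path TSV path.
#' @param level Entity level to restore.
#' @return An entity table.
#' @export
read_exported_tsv <- function(path, level = "transcript") {
  t <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  attr(t, "level") <- level
  attr(t, "key") <- switch(level, transcript = "transcript_id",
                           gene = "gene_id", snp = "key")
  t
}
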