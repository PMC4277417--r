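# Independent oracles: deliberately separate code paths from the package
# implementation (own coordinate walks, own translation, closure via igraph).

h_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1L]]),
        collapse = "")
}

# own genomic -> spliced mapping by explicit per-base walk
h_g2s <- function(exons, strand, pos) {
  bases <- unlist(lapply(seq_len(nrow(exons)),
                         function(i) exons[i, 1L]:exons[i, 2L]))
  if (strand == "-") bases <- rev(bases)
  match(pos, bases)
}

h_splice <- function(genome, chrom, exons, strand) {
  s <- paste(substring(genome[[chrom]], exons[, 1L], exons[, 2L]),
             collapse = "")
  if (strand == "-") h_revcomp(s) else s
}

# own codon-table translation, stops before the first stop codon
h_translate <- function(seq) {
  gc <- Biostrings::GENETIC_CODE
  n <- (nchar(seq) %/% 3L) * 3L
  aa <- character(0L)
  for (i in seq(1L, n, by = 3L)) {
    a <- unname(gc[substr(seq, i, i + 2L)])
    if (is.na(a) || a == "*") break
    aa <- c(aa, a)
  }
  paste(aa, collapse = "")
}

# brute-force effect classification: substitute the SNP into the genome,
# rebuild and translate both haplotype proteins, and diff them
h_classify <- function(genome, t, v) {
  sp <- h_g2s(t$exons, t$strand, v$pos)
  if (is.na(sp)) return("intron_variant")
  if (is.null(t$cds)) return("non_coding_variant")
  cds_sp <- h_g2s(t$exons, t$strand, as.vector(t$cds))
  lo <- min(cds_sp); hi <- max(cds_sp)
  if (sp < lo) return("5_prime_UTR_variant")
  if (sp > hi) return("3_prime_UTR_variant")
  g2 <- genome
  ch <- g2[[v$chrom]]
  substr(ch, v$pos, v$pos) <- toupper(v$alt)
  g2[[v$chrom]] <- ch
  ref_tail <- substr(h_splice(genome, t$chrom, t$exons, t$strand), lo,
                     spliced_length(t))
  alt_tail <- substr(h_splice(g2, t$chrom, t$exons, t$strand), lo,
                     spliced_length(t))
  rp <- h_translate(ref_tail)
  ap <- h_translate(alt_tail)
  if (rp == ap) return("synonymous_variant")
  if (nchar(ap) < nchar(rp) && ap == substr(rp, 1L, nchar(ap))) {
    return("stop_gained")
  }
  if (nchar(rp) < nchar(ap) && rp == substr(ap, 1L, nchar(rp))) {
    return("stop_lost")
  }
  "missense_variant"
}

# naive sequential-edit oracle: one variant at a time on the spliced
# sequence, ascending spliced order, tracking the cumulative length shift
h_apply <- function(t, ref_seq, variants) {
  if (nrow(variants) == 0L) return(ref_seq)
  ed <- lapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    span <- v$pos:(v$pos + nchar(v$ref) - 1L)
    sp <- h_g2s(t$exons, t$strand, span)
    if (anyNA(sp)) return(NULL)
    if (t$strand == "-") {
      list(sp = min(sp), ref = h_revcomp(v$ref), alt = h_revcomp(v$alt))
    } else {
      list(sp = sp[1L], ref = toupper(v$ref), alt = toupper(v$alt))
    }
  })
  ed <- Filter(Negate(is.null), ed)
  ed <- ed[order(vapply(ed, `[[`, 0, "sp"))]
  out <- ref_seq
  shift <- 0L
  for (e in ed) {
    s <- e$sp + shift
    stopifnot(substr(out, s, s + nchar(e$ref) - 1L) == e$ref)
    out <- paste0(substr(out, 1L, s - 1L), e$alt,
                  substr(out, s + nchar(e$ref), nchar(out)))
    shift <- shift + nchar(e$alt) - nchar(e$ref)
  }
  out
}

# GO trim oracle: transitive closure through igraph reachability
h_go_trim <- function(edges, p, threshold) {
  nodes <- union(names(p), union(edges$child, edges$parent))
  g <- igraph::graph_from_data_frame(edges[, c("child", "parent")],
                                     vertices = nodes)
  reach <- function(n, mode) {
    setdiff(names(igraph::subcomponent(g, n, mode = mode)), n)
  }
  E <- names(p)[p < threshold]
  keep <- vapply(E, function(n) {
    anc <- intersect(reach(n, "out"), E)
    desc <- intersect(reach(n, "in"), E)
    !any(p[desc] < p[n]) && !any(p[anc] <= p[n])
  }, logical(1L))
  sort(E[keep])
}

h_random_dag <- function(n_nodes, n_scored, edge_prob = 0.15) {
  n_scored <- min(n_scored, n_nodes)
  ids <- sprintf("GO:%07d", seq_len(n_nodes))
  edges <- list()
  for (i in 2:n_nodes) {
    parents <- which(stats::runif(i - 1L) < edge_prob)
    for (j in parents) {
      edges[[length(edges) + 1L]] <- data.frame(
        child = ids[i], parent = ids[j],
        relation = sample(c("is_a", "part_of"), 1L),
        stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(child = character(), parent = character(),
               relation = character(), stringsAsFactors = FALSE)
  scored <- sample(ids, n_scored)
  p <- stats::setNames(10^stats::runif(n_scored, -8, 0), scored)
  list(edges = edges, p = p)
}

# analytic power of the two-sided exact test at fixed n
h_binom_power <- function(n, theta, alpha = 0.05) {
  if (n == 0L) return(0)
  x <- 0:n
  p2 <- pmin(1, 2 * stats::pbinom(pmax(x, n - x) - 1L, n, 0.5,
                                  lower.tail = FALSE))
  sum(stats::dbinom(x, n, theta)[p2 < alpha])
}

# power mixed over Poisson coverage with the >=min_het defined-p rule
h_pois_mixed_power <- function(lambda, theta, min_het = 20L,
                               alpha = 0.05) {
  ns <- 0:stats::qpois(1 - 1e-12, lambda)
  sum(stats::dpois(ns, lambda) *
        vapply(ns, function(n) {
          if (n < min_het) 0 else h_binom_power(n, theta, alpha)
        }, numeric(1L)))
}
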