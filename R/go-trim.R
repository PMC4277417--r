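# Project-specific trimming of enriched Gene Ontology terms. Enrichment
# scores are highly redundant across DAG levels (a child is part of its
# parent), so the trim keeps only the terms primarily responsible for the
# enrichment in their sub-tree.

#' Read a child/parent/relation edge table
#' @param path TSV with columns `child, parent, relation`
#'   (relation in is_a/part_of).
#' @return `data.frame` of edges.
#' @export
read_go_edges <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("child", "parent", "relation")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("edge file missing column(s): ",
                         paste(miss, collapse = ", "))
  df[, need]
}

#' Read a term/p-value score table
#' @param path TSV with columns `term, p_value`.
#' @return Named numeric vector of p-values.
#' @export
read_go_scores <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("term", "p_value")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("score file missing column(s): ",
                         paste(miss, collapse = ", "))
  stats::setNames(as.numeric(df$p_value), df$term)
}

#' Parse a minimal OBO ontology file into an edge table
#'
#' Reads `[Term]` stanzas, keeping `id`, `name`, `is_a` and
#' `relationship: part_of` lines. Obsolete terms are skipped.
#'
#' @param path Path to an OBO file.
#' @return `list(edges = data.frame(child, parent, relation),
#'   names = named character)`.
#' @export
read_obo <- function(path) {
  lines <- readLines(path)
  edges <- list()
  names_map <- character(0L)
  id <- NULL
  in_term <- FALSE
  obsolete <- FALSE
  flush <- function() NULL
  for (line in lines) {
    line <- trimws(line)
    if (line == "[Term]") {
      in_term <- TRUE; id <- NULL; obsolete <- FALSE
    } else if (startsWith(line, "[")) {
      in_term <- FALSE
    } else if (in_term && startsWith(line, "id: ")) {
      id <- sub("^id: ", "", line)
    } else if (in_term && startsWith(line, "name: ") && !is.null(id)) {
      names_map[id] <- sub("^name: ", "", line)
    } else if (in_term && startsWith(line, "is_obsolete: true")) {
      obsolete <- TRUE
    } else if (in_term && !obsolete && startsWith(line, "is_a: ")) {
      parent <- sub("\\s*!.*$", "", sub("^is_a: ", "", line))
      edges[[length(edges) + 1L]] <-
        data.frame(child = id, parent = parent, relation = "is_a",
                   stringsAsFactors = FALSE)
    } else if (in_term && !obsolete &&
               grepl("^relationship: part_of ", line)) {
      parent <- sub("\\s*!.*$", "",
                    sub("^relationship: part_of ", "", line))
      edges[[length(edges) + 1L]] <-
        data.frame(child = id, parent = parent, relation = "part_of",
                   stringsAsFactors = FALSE)
    }
  }
  list(edges = if (length(edges)) do.call(rbind, edges) else
    data.frame(child = character(), parent = character(),
               relation = character(), stringsAsFactors = FALSE),
    names = names_map)
}

# ancestors of every node over the transitive closure of is_a + part_of;
# errors on cycles
go_ancestors <- function(edges, nodes) {
  parents <- split(edges$parent, edges$child)
  anc <- new.env(parent = emptyenv())
  visiting <- new.env(parent = emptyenv())
  get_anc <- function(n) {
    if (!is.null(anc[[n]])) return(anc[[n]])
    if (!is.null(visiting[[n]])) stop("cycle detected at term ", n)
    assign(n, TRUE, envir = visiting)
    ps <- parents[[n]]
    res <- character(0L)
    for (p in ps) res <- union(res, c(p, get_anc(p)))
    rm(list = n, envir = visiting)
    assign(n, res, envir = anc)
    res
  }
  stats::setNames(lapply(nodes, get_anc), nodes)
}

#' Trim an enriched GO term set to its primary terms
#'
#' Restricts to terms enriched below `threshold` and keeps a term iff (a) no
#' enriched proper descendant has a strictly better (smaller) p-value — a
#' better child means the effect is happening at or below the child, seen in
#' diluted form on the parent — and (b) no enriched proper ancestor has a
#' p-value at least as good — such a term's enrichment is inherited from the
#' ancestor. Ancestry is the transitive closure of is_a and part_of edges.
#' Ties between an ancestor and a descendant resolve in favour of the more
#' general (ancestral) term. Kept terms never stand in an
#' ancestor/descendant relation, so trimming the kept set again returns it
#' unchanged.
#'
#' @param edges Edge `data.frame` (`child, parent, relation`) or the result
#'   of [read_obo()].
#' @param p Named numeric vector of enrichment p-values per term.
#' @param threshold Enrichment threshold in (0, 1] (default 0.001).
#' @return A list of class `"go_trim"`: `kept` (data.frame `term, p`,
#'   p-ascending), `dropped` (with the displacing term), `threshold`.
#' @export
trim_go_terms <- function(edges, p, threshold = 0.001) {
  if (is.list(edges) && !is.data.frame(edges) && !is.null(edges$edges)) {
    edges <- edges$edges
  }
  if (!(threshold > 0 && threshold <= 1)) {
    stop("threshold must be in (0, 1]")
  }
  if (nrow(edges)) {
    bad <- setdiff(unique(edges$relation), c("is_a", "part_of"))
    if (length(bad)) {
      stop("unsupported relation(s): ", paste(bad, collapse = ", "))
    }
  }
  if (any(is.na(p) | p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  nodes <- union(names(p), union(edges$child, edges$parent))
  anc <- go_ancestors(edges, nodes)
  enriched <- names(p)[p < threshold]
  kept <- character(0L)
  dropped <- data.frame(term = character(), p = numeric(),
                        displaced_by = character(),
                        stringsAsFactors = FALSE)
  desc <- stats::setNames(vector("list", length(nodes)), nodes)
  for (n in nodes) for (a in anc[[n]]) desc[[a]] <- c(desc[[a]], n)
  for (n in enriched) {
    anc_e <- intersect(anc[[n]], enriched)
    desc_e <- intersect(desc[[n]], enriched)
    better_desc <- desc_e[p[desc_e] < p[n]]
    dominating_anc <- anc_e[p[anc_e] <= p[n]]
    if (length(better_desc) == 0L && length(dominating_anc) == 0L) {
      kept <- c(kept, n)
    } else {
      by <- if (length(better_desc)) {
        better_desc[which.min(p[better_desc])]
      } else {
        dominating_anc[which.min(p[dominating_anc])]
      }
      dropped <- rbind(dropped,
                       data.frame(term = n, p = unname(p[n]),
                                  displaced_by = by,
                                  stringsAsFactors = FALSE))
    }
  }
  kept_df <- data.frame(term = kept, p = unname(p[kept]),
                        stringsAsFactors = FALSE)
  kept_df <- kept_df[order(kept_df$p, kept_df$term), , drop = FALSE]
  rownames(kept_df) <- NULL
  structure(list(kept = kept_df, dropped = dropped,
                 threshold = threshold, n_enriched = length(enriched)),
            class = "go_trim")
}

#' @export
print.go_trim <- function(x, ...) {
  cat(sprintf("GO trim: %d enriched term(s) (p < %g) reduced to %d\n",
              x$n_enriched, x$threshold, nrow(x$kept)))
  if (nrow(x$kept)) {
    print(x$kept, row.names = FALSE)
  }
  invisible(x)
}
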