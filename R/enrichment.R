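# Hypergeometric gene-set enrichment and Gene Ontology utilities.

#' Upper-tail hypergeometric probability
#'
#' P\[X >= k\] where X counts the overlap between a query of size `n` drawn
#' without replacement from a universe of `N` genes, `K` of which belong to
#' the gene set.
#'
#' @param k Observed overlap count.
#' @param n Query size.
#' @param K Gene-set size.
#' @param N Universe size.
#' @return The upper-tail probability, in (0, 1\]; exactly 1 when `k = 0`.
#' @export
hypergeom_upper_tail <- function(k, n, K, N) {
  if (any(k < 0 | n < 0 | K < 0 | N < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(n > N | K > N)) stop("`n` and `K` cannot exceed `N`", call. = FALSE)
  if (any(k > n | k > K)) stop("`k` cannot exceed `n` or `K`", call. = FALSE)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Build a gene-set collection
#'
#' Each set is restricted to the universe; empty sets (after restriction) are
#' dropped.
#'
#' @param sets Named list of character vectors (term -> genes).
#' @param universe Character vector of all assayable genes.
#' @param name Label for the collection.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe, name = "collection") {
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  universe <- unique(as.character(universe))
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop("`sets` must have unique names", call. = FALSE)
  }
  sets <- lapply(sets, function(g) sort(intersect(unique(as.character(g)), universe)))
  sets <- sets[vapply(sets, length, integer(1)) > 0]
  structure(
    list(name = name, sets = sets, universe = sort(universe)),
    class = "gene_set_collection"
  )
}

#' Hypergeometric enrichment of a gene list against a collection
#'
#' Query genes outside the universe are dropped (with a message); results are
#' ordered by p-value, ties broken by term label, and filtered to overlaps of
#' at least `min_overlap`. Raw p-values are reported by default, mirroring
#' screen-analysis convention; Benjamini-Hochberg q-values (computed over all
#' terms before the overlap filter) are added when `adjust = TRUE`.
#'
#' @param query Character vector of genes.
#' @param collection A [gene_set_collection()].
#' @param min_overlap Minimum overlap `k` for a term to be reported
#'   (default 1).
#' @param adjust Add BH-adjusted q-values (default `FALSE`).
#' @return Data frame with columns `term`, `k`, `n`, `K`, `N`, `p`, `q`,
#'   `genes` (overlap genes, semicolon-joined).
#' @export
enrich <- function(query, collection, min_overlap = 1L, adjust = FALSE) {
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- unique(as.character(query))
  inside <- intersect(query, collection$universe)
  dropped <- length(query) - length(inside)
  if (dropped > 0) {
    message(dropped, " query gene(s) outside the universe dropped")
  }
  n <- length(inside)
  N <- length(collection$universe)
  terms <- names(collection$sets)
  res <- data.frame(
    term = terms,
    k = vapply(collection$sets, function(s) length(intersect(inside, s)), integer(1)),
    n = n,
    K = vapply(collection$sets, length, integer(1)),
    N = N,
    stringsAsFactors = FALSE, row.names = NULL
  )
  res$p <- hypergeom_upper_tail(res$k, res$n, res$K, res$N)
  res$q <- if (adjust) stats::p.adjust(res$p, method = "BH") else NA_real_
  res$genes <- vapply(collection$sets, function(s) {
    paste(sort(intersect(inside, s)), collapse = ";")
  }, character(1))
  res <- res[res$k >= min_overlap, , drop = FALSE]
  res <- res[order(res$p, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}

term_ancestors <- function(parents) {
  # memoised DFS over the is_a DAG with cycle detection
  anc <- new.env(parent = emptyenv())
  state <- new.env(parent = emptyenv()) # 1 = in progress, 2 = done
  visit <- function(term, path) {
    st <- mget(term, envir = state, ifnotfound = 0L)[[1]]
    if (st == 1L) {
      cyc <- c(path[which(path == term)[1]:length(path)], term)
      stop("cycle in ontology: ", paste(cyc, collapse = " -> "), call. = FALSE)
    }
    if (st == 2L) return(get(term, envir = anc))
    assign(term, 1L, envir = state)
    ps <- parents[[term]]
    res <- character(0)
    for (p in ps) res <- union(res, c(p, visit(p, c(path, term))))
    assign(term, res, envir = anc)
    assign(term, 2L, envir = state)
    res
  }
  all_terms <- union(names(parents), unlist(parents, use.names = FALSE))
  out <- lapply(all_terms, function(t) visit(t, character(0)))
  names(out) <- all_terms
  out
}

#' Propagate annotations up an ontology (true-path rule)
#'
#' Under the true-path rule a gene annotated to a term is implicitly
#' annotated to every ancestor of that term. The closure is computed by
#' memoised traversal of the `is_a` DAG; the operation is idempotent and
#' annotations only grow.
#'
#' @param annotations Named list, gene -> character vector of directly
#'   annotated terms.
#' @param parents Named list, term -> character vector of parent terms
#'   (terms absent from the list are roots). A cycle raises an error naming
#'   the offending terms.
#' @return Named list, gene -> sorted character vector of terms closed under
#'   ancestry.
#' @export
propagate_ontology <- function(annotations, parents) {
  anc <- term_ancestors(parents)
  lapply(annotations, function(terms) {
    terms <- unique(as.character(terms))
    extra <- unlist(anc[intersect(terms, names(anc))], use.names = FALSE)
    sort(union(terms, extra))
  })
}

#' Count query genes per annotation category
#'
#' Frequency of annotation terms among a gene list, filtered to terms
#' covering at least `min_genes` genes (the convention used for reporting
#' the most frequent GO Biological Process categories).
#'
#' @param genes Character vector of genes.
#' @param annotations Named list, gene -> terms (typically after
#'   [propagate_ontology()]).
#' @param min_genes Minimum number of genes for a term to be reported
#'   (default 18).
#' @return Data frame `term`, `count`, sorted by decreasing count then term.
#' @export
category_counts <- function(genes, annotations, min_genes = 18L) {
  genes <- unique(as.character(genes))
  terms <- unlist(annotations[intersect(genes, names(annotations))], use.names = FALSE)
  if (length(terms) == 0) {
    return(data.frame(term = character(0), count = integer(0), stringsAsFactors = FALSE))
  }
  tab <- table(terms)
  out <- data.frame(
    term = names(tab), count = as.integer(tab),
    stringsAsFactors = FALSE
  )
  out <- out[out$count >= min_genes, , drop = FALSE]
  out <- out[order(-out$count, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
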