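#' Propagate gene annotations up an ontology
#'
#' Applies the true-path rule: a gene annotated to a term is implicitly
#' annotated to all of that term's ancestors via the chosen relations
#' (is_a / part_of edges supplied as child -> parent pairs). With no
#' ontology, the direct annotations are used as-is (pre-propagated files are
#' supported this way).
#'
#' @param gene2terms data.frame with columns `gene`, `term` (direct
#'   annotations).
#' @param ontology optional data.frame with columns `child`, `parent`; must
#'   be acyclic.
#' @param universe character vector of genes forming the reference set
#'   (e.g. the ORFs represented in the screen pool). Annotated genes outside
#'   the universe are dropped and counted.
#' @return object of class `annotation_set`: list with `term_genes` (named
#'   list of gene sets after propagation), `universe`, `n_dropped`.
#' @export
propagate_annotations <- function(gene2terms, ontology = NULL, universe) {
  gene2terms <- as.data.frame(gene2terms, stringsAsFactors = FALSE)
  if (!all(c("gene", "term") %in% names(gene2terms)))
    stopf("'gene2terms' needs columns 'gene' and 'term'")
  universe <- unique(as.character(universe))
  if (!length(universe)) stopf("empty universe")

  outside <- !(gene2terms$gene %in% universe)
  n_dropped <- length(unique(gene2terms$gene[outside]))
  gene2terms <- gene2terms[!outside, , drop = FALSE]

  ancestors <- NULL
  if (!is.null(ontology) && nrow(ontology) > 0) {
    ontology <- as.data.frame(ontology, stringsAsFactors = FALSE)
    if (!all(c("child", "parent") %in% names(ontology)))
      stopf("'ontology' needs columns 'child' and 'parent'")
    g <- igraph::graph_from_data_frame(ontology[c("child", "parent")],
                                       directed = TRUE)
    if (!igraph::is_dag(g)) {
      comp <- igraph::components(g, mode = "strong")
      cyc <- names(comp$membership)[comp$membership %in%
                                      which(comp$csize > 1)]
      stopf("ontology contains a cycle involving: %s",
            paste(sort(cyc), collapse = ", "))
    }
    verts <- igraph::V(g)$name
    ancestors <- lapply(seq_along(verts), function(i)
      verts[as.integer(igraph::subcomponent(g, i, mode = "out"))])
    names(ancestors) <- verts
  }

  pairs <- unique(gene2terms[c("gene", "term")])
  if (!is.null(ancestors)) {
    expanded <- lapply(seq_len(nrow(pairs)), function(i) {
      tm <- pairs$term[i]
      all_terms <- unique(c(tm, ancestors[[tm]]))
      data.frame(gene = pairs$gene[i], term = all_terms,
                 stringsAsFactors = FALSE)
    })
    pairs <- unique(do.call(rbind, expanded))
  }
  term_genes <- lapply(split(pairs$gene, pairs$term), function(g)
    sort(unique(g)))
  structure(list(term_genes = term_genes, universe = universe,
                 n_dropped = n_dropped),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation_set: %d terms over a universe of %d genes (%d annotated genes dropped)\n",
              length(x$term_genes), length(x$universe), x$n_dropped))
  invisible(x)
}

#' Hypergeometric overrepresentation analysis
#'
#' For each term with at least one query gene, computes the upper-tail
#' hypergeometric probability of drawing at least `k` term genes in a query
#' of size `n` from a universe of `N` genes of which `K` carry the term,
#' then adjusts across tested terms by Benjamini-Hochberg. The universe is
#' the user-supplied reference set (the screen background), not the whole
#' genome.
#'
#' @param query character vector of hit genes. Genes outside the universe
#'   are dropped with a warning.
#' @param annotations an [propagate_annotations()] result.
#' @param alpha significance level on q-values (default 0.05).
#' @return data.frame of class `enrichment_table`: per tested term `term`,
#'   `k`, `n`, `K`, `N`, `p`, `q`, `significant`, `genes` (comma-joined),
#'   sorted by p. Attribute `"n_untested"` counts terms with no query gene.
#' @export
hypergeometric_enrichment <- function(query, annotations, alpha = 0.05) {
  stopifnot(inherits(annotations, "annotation_set"))
  alpha <- assert_number(alpha, "alpha", min = 0, strict = TRUE)
  query <- unique(as.character(query))
  outside <- setdiff(query, annotations$universe)
  if (length(outside)) {
    warnf("%d query gene(s) outside the universe were dropped", length(outside))
    query <- setdiff(query, outside)
  }
  if (!length(query)) stopf("empty query after universe intersection")

  N <- length(annotations$universe)
  n <- length(query)
  rows <- lapply(names(annotations$term_genes), function(tm) {
    genes <- annotations$term_genes[[tm]]
    K <- length(genes)
    hit <- intersect(query, genes)
    k <- length(hit)
    if (k < 1) return(NULL)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, k = k, n = n, K = K, N = N, p = p,
               genes = paste(sort(hit), collapse = ","),
               stringsAsFactors = FALSE)
  })
  n_untested <- sum(vapply(rows, is.null, logical(1)))
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    out <- data.frame(term = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p = numeric(),
                      q = numeric(), significant = logical(),
                      genes = character(), stringsAsFactors = FALSE)
    return(structure(out, class = c("enrichment_table", "data.frame"),
                     n_untested = n_untested))
  }
  out <- do.call(rbind, rows)
  out$q <- bh_qvalues(out$p)
  out$significant <- out$q < alpha
  out <- out[order(out$p, out$term), c("term", "k", "n", "K", "N", "p", "q",
                                       "significant", "genes")]
  rownames(out) <- NULL
  structure(out, class = c("enrichment_table", "data.frame"),
            n_untested = n_untested)
}
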