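#' Over-representation analysis against gene-set collections
#'
#' One-sided hypergeometric tail test per gene set: with the universe as the
#' population, set members as successes and the query as the draw,
#' `p = P(X >= overlap)`. P-values are Benjamini-Hochberg adjusted within
#' each collection; sets with `FDR <= 0.05` are flagged significant
#' (inclusive boundary).
#'
#' @param query Non-empty character vector of gene ids, a subset of the
#'   universe.
#' @param collections Named list of collections, each a named list of gene
#'   sets (a bare list of gene sets is treated as one collection named
#'   `"sets"`). Sets are intersected with the universe before testing.
#' @param universe Non-empty character vector of background gene ids
#'   (typically the genes on the analyzed expression matrix).
#' @param fdr_threshold Significance boundary (default 0.05, inclusive).
#' @return Data frame of class `enrichment_table`: `collection`, `term`,
#'   `overlap_size`, `set_size`, `query_size`, `universe_size`, `p`, `fdr`,
#'   `significant`, `overlap` (semicolon-joined gene ids).
#' @export
ora <- function(query, collections, universe, fdr_threshold = 0.05) {
  if (!length(query)) stop("empty query")
  if (!length(universe)) stop("empty universe")
  if (!all(query %in% universe)) stop("query must be a subset of the universe")
  query <- unique(query)
  universe <- unique(universe)
  if (!is.list(collections[[1]])) collections <- list(sets = collections)
  res <- lapply(names(collections), function(cn) {
    sets <- lapply(collections[[cn]], intersect, universe)
    rows <- lapply(names(sets), function(tn) {
      s <- sets[[tn]]
      ov <- intersect(query, s)
      p <- stats::phyper(length(ov) - 1, length(s),
                         length(universe) - length(s), length(query),
                         lower.tail = FALSE)
      data.frame(collection = cn, term = tn, overlap_size = length(ov),
                 set_size = length(s), query_size = length(query),
                 universe_size = length(universe), p = p,
                 overlap = paste(sort(ov), collapse = ";"),
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    tab$fdr <- stats::p.adjust(tab$p, method = "BH")
    tab
  })
  out <- do.call(rbind, res)
  out$significant <- out$fdr <= fdr_threshold
  out <- out[order(out$collection, out$p), ]
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", class(out))
  out
}

#' Bipartite term-gene graph of significant enrichment results
#'
#' Builds the node-link structure behind the enrichment plots: one node per
#' significant term and per overlapping gene, an edge wherever the gene
#' belongs to the term's overlap, and an up/down/ns regulation attribute on
#' gene nodes taken from the DEG table.
#'
#' @param enr An `enrichment_table` with at least one significant term.
#' @param degs A `deg_table` (or `NULL`: all genes marked `ns`).
#' @return A list of class `term_gene_graph`: `nodes` (data frame `id`,
#'   `type`, `collection`, `direction`), `edges` (data frame `term`, `gene`).
#' @export
term_gene_graph <- function(enr, degs = NULL) {
  sig <- enr[enr$significant & enr$overlap_size > 0, ]
  if (!nrow(sig)) stop("no significant term with a non-empty overlap")
  edges <- do.call(rbind, lapply(seq_len(nrow(sig)), function(i) {
    data.frame(term = sig$term[i],
               gene = strsplit(sig$overlap[i], ";", fixed = TRUE)[[1]],
               stringsAsFactors = FALSE)
  }))
  genes <- sort(unique(edges$gene))
  dir <- stats::setNames(rep("ns", length(genes)), genes)
  if (!is.null(degs)) {
    hit <- intersect(genes, degs$gene_id)
    dir[hit] <- degs$direction[match(hit, degs$gene_id)]
  }
  nodes <- rbind(
    data.frame(id = sig$term, type = "term", collection = sig$collection,
               direction = NA_character_, stringsAsFactors = FALSE),
    data.frame(id = genes, type = "gene", collection = NA_character_,
               direction = unname(dir), stringsAsFactors = FALSE))
  structure(list(nodes = nodes, edges = edges), class = "term_gene_graph")
}

#' Serialize a term-gene graph
#'
#' @param graph A `term_gene_graph`.
#' @param json_path,dot_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the DOT source as a character scalar.
#' @export
write_term_gene_graph <- function(graph, json_path = NULL, dot_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(list(nodes = graph$nodes, links = graph$edges),
                         json_path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
  }
  colors <- c(up = "red", down = "green", ns = "grey")
  node_lines <- vapply(seq_len(nrow(graph$nodes)), function(i) {
    nd <- graph$nodes[i, ]
    if (nd$type == "term") {
      sprintf('  "%s" [shape=box];', nd$id)
    } else {
      sprintf('  "%s" [shape=ellipse, color=%s];', nd$id,
              colors[[nd$direction]])
    }
  }, character(1))
  edge_lines <- sprintf('  "%s" -- "%s";', graph$edges$term,
                        graph$edges$gene)
  dot <- paste(c("graph term_gene {", node_lines, edge_lines, "}"),
               collapse = "\n")
  if (!is.null(dot_path)) writeLines(dot, dot_path)
  invisible(dot)
}
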