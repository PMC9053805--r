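#' Filter a functional network by edge weight and tissue expression
#'
#' Edges with weight at or below `min_weight` are removed (low functional
#' similarity, the 0-0.1 band by default); nodes absent from the
#' tissue-expressed gene list are then removed together with their incident
#' edges, and any node left isolated is dropped.
#'
#' @param net A `functional_network`.
#' @param min_weight Weight threshold in `[0, 1)`; edges kept iff
#'   `weight > min_weight` (default 0.1).
#' @param tissue_genes Character vector of tissue-expressed gene ids, or
#'   `NULL` to skip the tissue filter.
#' @return A filtered `functional_network`.
#' @export
filter_network <- function(net, min_weight = 0.1, tissue_genes = NULL) {
  stopifnot(min_weight >= 0, min_weight < 1)
  g <- igraph::delete_edges(net,
                            igraph::E(net)[igraph::E(net)$weight <= min_weight])
  if (!is.null(tissue_genes)) {
    drop <- setdiff(igraph::V(g)$name, tissue_genes)
    g <- igraph::delete_vertices(g, drop)
  }
  g <- igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) == 0])
  if (igraph::vcount(g) == 0) stop("network is empty after filtering")
  as_functional_network(g)
}

#' Largest connected component of a network
#'
#' Connected components are computed; the component with the most nodes is
#' returned, ties broken by the smallest lexicographic member node id.
#'
#' @param net A `functional_network` with at least one node.
#' @return A list: `network` (the largest component), `n_components`,
#'   `component_sizes` (decreasing).
#' @export
largest_component <- function(net) {
  stopifnot(igraph::vcount(net) >= 1)
  cmp <- igraph::components(net)
  sizes <- cmp$csize
  first_id <- vapply(seq_along(sizes), function(i) {
    min(igraph::V(net)$name[cmp$membership == i])
  }, character(1))
  best <- order(-sizes, first_id)[1]
  sub <- igraph::induced_subgraph(net,
                                  igraph::V(net)[cmp$membership == best])
  list(network = as_functional_network(sub),
       n_components = cmp$no,
       component_sizes = sort(sizes, decreasing = TRUE))
}

#' Induced submodule network of a gene set
#'
#' Order-0 mapping of module genes onto the functional network: the subgraph
#' induced on `module_genes` intersected with the node set, after which
#' nodes with no remaining neighbor are dropped, so only genes directly
#' connected to each other remain. Setting `order = 1` instead expands to the
#' one-step ego neighborhood before inducing.
#'
#' @param net A `functional_network`.
#' @param module_genes Non-empty character vector of gene ids.
#' @param order 0 (default, direct connections only) or 1 (include
#'   first neighbors).
#' @return An induced `functional_network`.
#' @export
induced_submodule <- function(net, module_genes, order = 0) {
  stopifnot(length(module_genes) >= 1, order %in% c(0, 1))
  present <- intersect(module_genes, igraph::V(net)$name)
  if (!length(present)) stop("no module gene is present in the network")
  if (order == 1) {
    nb <- igraph::ego(net, order = 1, nodes = present)
    present <- unique(unlist(lapply(nb, function(v) v$name)))
  }
  g <- igraph::induced_subgraph(net, present)
  g <- igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) == 0])
  if (igraph::vcount(g) == 0) stop("induced submodule is empty (no two ",
                                   "module genes are directly connected)")
  as_functional_network(g)
}
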