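#' Probe-level expression container
#'
#' A probe x sample matrix of log2 intensities plus the probe-to-gene
#' annotation table (`gene_id` may be `NA` for unannotated probes).
#'
#' @param values Numeric matrix, probes in rows (rownames = probe ids),
#'   samples in columns.
#' @param annotation Data frame with columns `probe_id`, `gene_id`.
#' @return A list of class `probe_matrix`.
#' @export
probe_matrix <- function(values, annotation) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            all(c("probe_id", "gene_id") %in% names(annotation)))
  if (anyDuplicated(rownames(values))) stop("duplicate probe ids")
  if (!setequal(rownames(values), annotation$probe_id)) {
    stop("annotation table must cover exactly the probes in the matrix")
  }
  structure(list(values = values, annotation = annotation),
            class = "probe_matrix")
}

#' Gene-level expression container
#'
#' A gene x sample matrix of log2 values with attached sample metadata
#' (`sample_id`, `phenotype` in `{normal, polyp}`, `batch`). Column order of
#' the matrix always matches the row order of the metadata.
#'
#' @param values Numeric matrix, genes in rows (unique rownames), samples in
#'   columns.
#' @param metadata Data frame with columns `sample_id`, `phenotype`, `batch`.
#' @return A list of class `expression_matrix`.
#' @export
expression_matrix <- function(values, metadata) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            all(c("sample_id", "phenotype", "batch") %in% names(metadata)))
  if (anyDuplicated(rownames(values))) stop("duplicate gene ids")
  if (!identical(colnames(values), metadata$sample_id)) {
    stop("matrix columns must match metadata sample_id order")
  }
  if (any(!is.finite(values))) stop("expression values must be finite")
  if (any(is.na(metadata$phenotype)) || any(is.na(metadata$batch))) {
    stop("phenotype and batch must be non-missing")
  }
  bad <- setdiff(unique(metadata$phenotype), c("normal", "polyp"))
  if (length(bad)) stop("unknown phenotype labels: ",
                        paste(bad, collapse = ", "))
  structure(list(values = values, metadata = metadata),
            class = "expression_matrix")
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Coerce an igraph graph to a validated functional network
#'
#' A functional network is an undirected igraph graph whose edges carry a
#' `weight` attribute in `(0, 1]`, with no self-loops and no parallel edges.
#'
#' @param g An igraph graph with edge weights.
#' @return The graph, validated, with class attribute `functional_network`
#'   prepended.
#' @export
as_functional_network <- function(g) {
  stopifnot(igraph::is_igraph(g))
  if (igraph::is_directed(g)) g <- igraph::as_undirected(g, mode = "collapse")
  if (igraph::any_loop(g)) stop("functional network must have no self-loops")
  if (igraph::any_multiple(g)) stop("functional network must have no ",
                                    "parallel edges")
  w <- igraph::E(g)$weight
  if (igraph::ecount(g) > 0) {
    if (is.null(w)) stop("edges must carry a weight attribute")
    if (any(w <= 0 | w > 1)) stop("edge weights must lie in (0, 1]")
  }
  class(g) <- unique(c("functional_network", class(g)))
  g
}

#' Read a weighted edge-list TSV into a functional network
#'
#' @param path TSV with header columns `from`/`gene_a`, `to`/`gene_b`,
#'   `weight`.
#' @return A `functional_network` igraph graph.
#' @export
read_network <- function(path) {
  el <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(el)[1:2] <- c("from", "to")
  as_functional_network(
    igraph::graph_from_data_frame(el[, c("from", "to", "weight")],
                                  directed = FALSE))
}

#' Edge list of a functional network
#'
#' @param net A `functional_network`.
#' @return Data frame `gene_a`, `gene_b`, `weight`.
#' @export
network_edges <- function(net) {
  el <- igraph::as_data_frame(net, what = "edges")
  data.frame(gene_a = el$from, gene_b = el$to, weight = el$weight,
             stringsAsFactors = FALSE)
}

#' Annotation DAG container
#'
#' A rooted, acyclic term hierarchy: directed child-to-parent edges with
#' relation `is_a` or `part_of`, split by namespace (`BP`, `MF`). Acyclicity
#' is asserted at construction.
#'
#' @param edges Data frame with columns `child`, `parent`, `relation`.
#' @param terms Data frame with columns `term`, `namespace` (optional
#'   `layer`); if omitted, terms and namespaces are inferred from the ids'
#'   `NS:` prefixes.
#' @return A list of class `ontology_dag` with elements `edges`, `terms`,
#'   `parents` (named list term -> data.frame(parent, relation)) and `roots`
#'   (named character vector per namespace).
#' @export
ontology_dag <- function(edges, terms = NULL) {
  stopifnot(all(c("child", "parent", "relation") %in% names(edges)))
  bad <- setdiff(unique(edges$relation), c("is_a", "part_of"))
  if (length(bad)) stop("unknown relations: ", paste(bad, collapse = ", "))
  if (is.null(terms)) {
    ids <- unique(c(edges$child, edges$parent))
    terms <- data.frame(term = ids, namespace = sub(":.*$", "", ids),
                        stringsAsFactors = FALSE)
  }
  # acyclicity: topological sort must consume every term
  if (nrow(edges) > 0) {
    g <- igraph::graph_from_data_frame(edges[, c("child", "parent")],
                                       directed = TRUE,
                                       vertices = terms$term)
    if (!igraph::is_dag(g)) stop("internal error: ontology edges contain ",
                                 "a cycle")
  }
  parents <- split(edges[, c("parent", "relation")], edges$child)
  roots <- vapply(split(terms$term, terms$namespace), function(tt) {
    r <- setdiff(tt, edges$child)
    if (length(r) != 1) stop("each namespace must have exactly one root")
    r
  }, character(1))
  non_root <- setdiff(terms$term, roots)
  orphan <- setdiff(non_root, edges$child)
  if (length(orphan)) stop("non-root terms without a parent: ",
                           paste(utils::head(orphan, 5), collapse = ", "))
  structure(list(edges = edges, terms = terms, parents = parents,
                 roots = roots),
            class = "ontology_dag")
}

#' Gene-to-term annotation container
#'
#' @param table Data frame with columns `gene_id`, `term_id`, `namespace`.
#' @param dag The `ontology_dag` the terms must belong to (optional check).
#' @return A list of class `annotation_map` with the deduplicated table and a
#'   per-namespace named list `gene2terms`.
#' @export
annotation_map <- function(table, dag = NULL) {
  stopifnot(all(c("gene_id", "term_id", "namespace") %in% names(table)))
  table <- unique(table[, c("gene_id", "term_id", "namespace")])
  if (!is.null(dag)) {
    bad <- setdiff(table$term_id, dag$terms$term)
    if (length(bad)) stop("annotated terms missing from the DAG: ",
                          paste(utils::head(bad, 5), collapse = ", "))
  }
  gene2terms <- lapply(split(table, table$namespace), function(tb) {
    split(tb$term_id, tb$gene_id)
  })
  structure(list(table = table, gene2terms = gene2terms),
            class = "annotation_map")
}

#' Functional classes (term -> gene set) of an annotation map
#'
#' The direct annotation sets used as the functional classes `B` of the
#' biological homogeneity index and as GMT gene sets.
#'
#' @param ann An `annotation_map`.
#' @param namespace `"BP"` or `"MF"`.
#' @return Named list of character vectors (term -> genes).
#' @export
annotation_gene_sets <- function(ann, namespace = "BP") {
  tb <- ann$table[ann$table$namespace == namespace, ]
  split(tb$gene_id, tb$term_id)
}

#' Read / write gene-set collections in GMT format
#'
#' Standard GMT: one set per line — name, description, then tab-separated
#' gene ids.
#'
#' @param path File path.
#' @return `read_gmt`: named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(x) x[-(1:2)])
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, "", 1)
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a probe matrix and its annotation from TSV files
#'
#' @param matrix_path TSV with `probe_id` column then one column per sample.
#' @param annotation_path TSV with `probe_id`, `gene_id` (`NA` allowed).
#' @return A `probe_matrix`.
#' @export
read_probe_matrix <- function(matrix_path, annotation_path) {
  pm <- utils::read.delim(matrix_path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  values <- as.matrix(pm[, -1, drop = FALSE])
  rownames(values) <- pm$probe_id
  ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  probe_matrix(values, ann)
}

#' Read sample metadata from TSV
#'
#' @param path TSV with columns `sample_id`, `phenotype`, `batch`.
#' @return Data frame.
#' @export
read_metadata <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = "character")
}

#' Read an ontology DAG and annotations from TSV
#'
#' @param ontology_path TSV with columns `child`, `parent`, `relation`.
#' @param annotation_path TSV with columns `gene_id`, `term_id`, `namespace`.
#' @return A list with `dag` and `annotations`.
#' @export
read_ontology <- function(ontology_path, annotation_path) {
  dag <- ontology_dag(utils::read.delim(ontology_path,
                                        stringsAsFactors = FALSE))
  ann <- annotation_map(utils::read.delim(annotation_path,
                                          stringsAsFactors = FALSE), dag)
  list(dag = dag, annotations = ann)
}

#' Write / read a gene-level expression matrix with metadata
#'
#' Two TSV files: the matrix (`gene_id` column then one column per sample,
#' full double precision) and the metadata (`sample_id`, `phenotype`,
#' `batch`).
#'
#' @param em An `expression_matrix`.
#' @param matrix_path,metadata_path Output / input file paths.
#' @return `write_expression_matrix`: invisibly, the matrix path.
#' @export
write_expression_matrix <- function(em, matrix_path, metadata_path) {
  vals <- em$values
  df <- data.frame(gene_id = rownames(vals),
                   matrix(sprintf("%.17g", vals), nrow(vals),
                          dimnames = dimnames(vals)),
                   check.names = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(em$metadata, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(matrix_path)
}

#' @rdname write_expression_matrix
#' @export
read_expression_matrix <- function(matrix_path, metadata_path) {
  df <- utils::read.delim(matrix_path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df$gene_id
  expression_matrix(vals, read_metadata(metadata_path))
}
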