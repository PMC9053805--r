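#' Newman modularity of a partition
#'
#' `Q = (1 / 2m) * sum_ij (A_ij - k_i k_j / 2m) * delta(c_i, c_j)`, summed
#' over all ordered node pairs including `i = j` (with `A_ii = 0`). The
#' adjacency is binary by default for scoring parity with the classic
#' definition; set `weighted = TRUE` to use edge weights (then `m` is the
#' total weight and `k` the strength).
#'
#' @param net A `functional_network` with at least one edge.
#' @param part A `partition` covering the nodes.
#' @param weighted Use edge weights (default `FALSE`).
#' @return Modularity `Q` in `[-0.5, 1]`.
#' @export
modularity_q <- function(net, part, weighted = FALSE) {
  check_partition_covers(net, part)
  if (igraph::ecount(net) == 0) stop("modularity undefined for m = 0")
  attr_name <- if (weighted) "weight" else NULL
  a <- igraph::as_adjacency_matrix(net, attr = attr_name, sparse = FALSE)
  diag(a) <- 0
  memb <- unclass(part)[rownames(a)]
  k <- rowSums(a)
  two_m <- sum(k)
  q <- 0
  for (cl in unique(memb)) {
    in_cl <- memb == cl
    q <- q + sum(a[in_cl, in_cl]) / two_m - (sum(k[in_cl]) / two_m)^2
  }
  q
}

#' Connectivity-based silhouette index of a partition
#'
#' Node dissimilarity is the unweighted shortest-path length, with
#' disconnected pairs set to `n` (the node count). For each node,
#' `a(i)` is the mean distance to the other members of its cluster, `b(i)`
#' the smallest mean distance to another cluster, and
#' `S(i) = (b - a) / max(a, b)`; members of singleton clusters score 0. The
#' index `S(u)` is the mean of `S(i)`.
#'
#' @param net A `functional_network`.
#' @param part A `partition` with at least two clusters.
#' @return A list: `s_u` (mean silhouette), `s_i` (named per-node values).
#' @export
silhouette_index <- function(net, part) {
  check_partition_covers(net, part)
  if (n_clusters(part) < 2) stop("silhouette requires >= 2 clusters")
  nodes <- igraph::V(net)$name
  n <- length(nodes)
  d <- igraph::distances(net, weights = NA)
  d[!is.finite(d)] <- n
  d <- d[nodes, nodes]
  memb <- unclass(part)[nodes]
  cl_ids <- unique(memb)
  # mean distance of every node to every cluster (excluding self for own)
  sums <- vapply(cl_ids, function(cl) rowSums(d[, memb == cl, drop = FALSE]),
                 numeric(n))
  sizes <- vapply(cl_ids, function(cl) sum(memb == cl), numeric(1))
  s_i <- stats::setNames(numeric(n), nodes)
  for (i in seq_len(n)) {
    own <- match(memb[i], cl_ids)
    if (sizes[own] == 1) { s_i[i] <- 0; next }
    a_i <- sums[i, own] / (sizes[own] - 1)
    b_i <- min((sums[i, -own] / sizes[-own]))
    s_i[i] <- (b_i - a_i) / max(a_i, b_i)
  }
  list(s_u = mean(s_i), s_i = s_i)
}

#' Biological homogeneity index (BHI)
#'
#' The probability that two annotated genes placed in the same cluster share
#' at least one functional class. Genes without any class are excluded;
#' clusters with fewer than two annotated genes are skipped; per qualifying
#' cluster the score is the fraction of ordered pairs sharing a class, and
#' BHI is the mean over qualifying clusters.
#'
#' @param part A `partition` (gene -> cluster).
#' @param classes Named list: functional class -> character vector of genes
#'   (e.g. [annotation_gene_sets()]).
#' @return BHI in `[0, 1]`.
#' @export
bhi <- function(part, classes) {
  gene_classes <- invert_sets(classes)
  memb <- unclass(part)
  annotated <- intersect(names(memb), names(gene_classes))
  per_cluster <- c()
  for (cl in unique(memb)) {
    genes <- intersect(names(memb)[memb == cl], annotated)
    nk <- length(genes)
    if (nk < 2) next
    share <- 0
    for (i in seq_len(nk - 1)) {
      for (j in (i + 1):nk) {
        if (length(intersect(gene_classes[[genes[i]]],
                             gene_classes[[genes[j]]]))) {
          share <- share + 2  # ordered pairs
        }
      }
    }
    per_cluster <- c(per_cluster, share / (nk * (nk - 1)))
  }
  if (!length(per_cluster)) {
    stop("no cluster has >= 2 annotated genes")
  }
  mean(per_cluster)
}

invert_sets <- function(sets) {
  df <- data.frame(gene = unlist(sets, use.names = FALSE),
                   class = rep(names(sets), lengths(sets)),
                   stringsAsFactors = FALSE)
  split(df$class, df$gene)
}

#' Wang semantic similarity between two terms
#'
#' Each term's ancestor closure receives S-values: `S_T(T) = 1` and
#' `S_T(t) = max over children c of t within the closure of w_rel * S_T(c)`,
#' with contribution factors 0.8 for `is_a` and 0.6 for `part_of`. With
#' `SV(T) = sum of S-values`, the similarity of terms A and B is the summed
#' S-values of their shared ancestors under both terms, divided by
#' `SV(A) + SV(B)`.
#'
#' @param dag An `ontology_dag`.
#' @param term_a,term_b Term ids in the DAG.
#' @return Similarity in `[0, 1]`.
#' @export
wang_term_similarity <- function(dag, term_a, term_b) {
  sa <- wang_svalues(dag, term_a)
  sb <- wang_svalues(dag, term_b)
  shared <- intersect(names(sa), names(sb))
  sum(sa[shared] + sb[shared]) / (sum(sa) + sum(sb))
}

# S-values of a term over its ancestor closure (named numeric vector).
wang_svalues <- function(dag, term,
                         w_rel = c(is_a = 0.8, part_of = 0.6)) {
  if (!term %in% dag$terms$term) stop("term not in DAG: ", term)
  s <- stats::setNames(1, term)
  frontier <- term
  while (length(frontier)) {
    nxt <- character()
    for (t in frontier) {
      pp <- dag$parents[[t]]
      if (is.null(pp)) next
      for (r in seq_len(nrow(pp))) {
        cand <- w_rel[[pp$relation[r]]] * s[[t]]
        p <- pp$parent[r]
        if (is.na(s[p]) || cand > s[[p]]) {
          s[p] <- cand
          nxt <- c(nxt, p)
        }
      }
    }
    frontier <- unique(nxt)
  }
  s
}

#' Wang semantic similarity between two genes
#'
#' Best-match average over the two genes' term sets in a namespace: for every
#' term of gene A the best similarity against gene B's terms (and vice
#' versa), averaged over all terms of both genes.
#'
#' @param dag An `ontology_dag`.
#' @param ann An `annotation_map`.
#' @param gene_a,gene_b Gene ids annotated in the namespace.
#' @param namespace `"BP"` or `"MF"`.
#' @return Similarity in `[0, 1]`.
#' @export
wang_gene_similarity <- function(dag, ann, gene_a, gene_b,
                                 namespace = "BP") {
  g2t <- ann$gene2terms[[namespace]]
  ta <- g2t[[gene_a]]; tb <- g2t[[gene_b]]
  if (is.null(ta)) stop("gene not annotated in ", namespace, ": ", gene_a)
  if (is.null(tb)) stop("gene not annotated in ", namespace, ": ", gene_b)
  sim <- wang_term_matrix(dag, ta, tb)
  (sum(apply(sim, 1, max)) + sum(apply(sim, 2, max))) /
    (length(ta) + length(tb))
}

wang_term_matrix <- function(dag, terms_a, terms_b) {
  sva <- lapply(terms_a, wang_svalues, dag = dag)
  svb <- lapply(terms_b, wang_svalues, dag = dag)
  out <- matrix(0, length(terms_a), length(terms_b))
  for (i in seq_along(sva)) {
    for (j in seq_along(svb)) {
      shared <- intersect(names(sva[[i]]), names(svb[[j]]))
      out[i, j] <- sum(sva[[i]][shared] + svb[[j]][shared]) /
        (sum(sva[[i]]) + sum(svb[[j]]))
    }
  }
  out
}

# Mean pairwise Wang gene similarity of a gene set (unordered pairs);
# genes lacking annotation in the namespace are skipped. S-values of every
# involved term are computed once and reused across pairs.
wang_cluster_score <- function(dag, ann, genes, namespace = "BP") {
  g2t <- ann$gene2terms[[namespace]]
  genes <- genes[genes %in% names(g2t)]
  if (length(genes) < 2) return(NA_real_)
  terms <- unique(unlist(g2t[genes]))
  sv <- lapply(terms, wang_svalues, dag = dag)
  names(sv) <- terms
  tsim <- matrix(0, length(terms), length(terms),
                 dimnames = list(terms, terms))
  for (i in seq_along(terms)) {
    for (j in i:length(terms)) {
      shared <- intersect(names(sv[[i]]), names(sv[[j]]))
      tsim[i, j] <- tsim[j, i] <-
        sum(sv[[i]][shared] + sv[[j]][shared]) / (sum(sv[[i]]) + sum(sv[[j]]))
    }
  }
  sims <- c()
  for (i in seq_len(length(genes) - 1)) {
    for (j in (i + 1):length(genes)) {
      ta <- g2t[[genes[i]]]; tb <- g2t[[genes[j]]]
      block <- tsim[ta, tb, drop = FALSE]
      sims <- c(sims, (sum(apply(block, 1, max)) +
                         sum(apply(block, 2, max))) /
                  (length(ta) + length(tb)))
    }
  }
  mean(sims)
}

#' Score a partition with internal and biological metrics
#'
#' Computes the partition-level modularity and silhouette index plus, for
#' every cluster (submodule), its size, annotated size, single-cluster BHI,
#' mean pairwise Wang BP and MF similarity, and the counts of down- and
#' up-regulated differentially expressed member genes.
#'
#' @param net A `functional_network`.
#' @param part A `partition` of the network.
#' @param ann An `annotation_map`.
#' @param dag An `ontology_dag`.
#' @param degs A DEG table from [differential_expression()] (may be `NULL`;
#'   DEG counts are then 0).
#' @return A list of class `metric_report`: `algorithm`, `q`, `s_u`,
#'   `submodules` (data frame `cluster`, `size`, `annotated_size`, `bhi`,
#'   `wang_bp`, `wang_mf`, `n_down`, `n_up`).
#' @export
evaluate_partition <- function(net, part, ann, dag, degs = NULL) {
  check_partition_covers(net, part)
  q <- modularity_q(net, part)
  s_u <- if (n_clusters(part) >= 2) silhouette_index(net, part)$s_u
  else NA_real_
  classes <- annotation_gene_sets(ann, "BP")
  gene_classes <- invert_sets(classes)
  memb <- unclass(part)
  down_genes <- up_genes <- character()
  if (!is.null(degs)) {
    down_genes <- degs$gene_id[degs$direction == "down"]
    up_genes <- degs$gene_id[degs$direction == "up"]
  }
  rows <- lapply(sort(unique(memb)), function(cl) {
    genes <- names(memb)[memb == cl]
    annotated <- intersect(genes, names(gene_classes))
    cluster_bhi <- if (length(annotated) >= 2) {
      sub <- partition(stats::setNames(rep(1L, length(genes)), genes))
      bhi(sub, classes)
    } else NA_real_
    data.frame(cluster = cl, size = length(genes),
               annotated_size = length(annotated),
               bhi = cluster_bhi,
               wang_bp = wang_cluster_score(dag, ann, genes, "BP"),
               wang_mf = wang_cluster_score(dag, ann, genes, "MF"),
               n_down = length(intersect(genes, down_genes)),
               n_up = length(intersect(genes, up_genes)))
  })
  structure(list(algorithm = attr(part, "algorithm"), q = q, s_u = s_u,
                 submodules = do.call(rbind, rows)),
            class = "metric_report")
}
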