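# Independent brute-force oracles and small fixtures used across the suite.
# Every oracle is written from the defining formula, not from the package's
# implementation path.

ari <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) a <- a[names(b)]
  mclust::adjustedRandIndex(a, b)
}

# Eq-style modularity: explicit double loop over all ordered node pairs
# (including i = j, with A_ii = 0).
oracle_modularity <- function(net, memb, weighted = FALSE) {
  attr_name <- if (weighted) "weight" else NULL
  a <- igraph::as_adjacency_matrix(net, attr = attr_name, sparse = FALSE)
  diag(a) <- 0
  memb <- memb[rownames(a)]
  k <- rowSums(a)
  two_m <- sum(k)
  q <- 0
  n <- nrow(a)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (memb[i] == memb[j]) {
        q <- q + a[i, j] - k[i] * k[j] / two_m
      }
    }
  }
  as.numeric(q / two_m)
}

# Silhouette with hop distances and d = n for disconnected pairs, looped
# directly from the definition.
oracle_silhouette <- function(net, memb) {
  nodes <- igraph::V(net)$name
  n <- length(nodes)
  d <- igraph::distances(net, weights = NA)
  d[!is.finite(d)] <- n
  d <- d[nodes, nodes]
  memb <- memb[nodes]
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- names(memb)[memb == memb[i] & names(memb) != nodes[i]]
    if (!length(own)) { s[i] <- 0; next }
    a_i <- mean(d[nodes[i], own])
    b_i <- Inf
    for (cl in setdiff(unique(memb), memb[i])) {
      others <- names(memb)[memb == cl]
      b_i <- min(b_i, mean(d[nodes[i], others]))
    }
    s[i] <- (b_i - a_i) / max(a_i, b_i)
  }
  mean(s)
}

# BHI: enumerate ordered pairs of annotated genes per cluster.
oracle_bhi <- function(memb, gene_classes) {
  annotated <- intersect(names(memb), names(gene_classes))
  vals <- c()
  for (cl in unique(memb)) {
    genes <- intersect(names(memb)[memb == cl], annotated)
    nk <- length(genes)
    if (nk < 2) next
    hits <- 0
    for (i in seq_len(nk)) {
      for (j in seq_len(nk)) {
        if (i != j && length(intersect(gene_classes[[genes[i]]],
                                       gene_classes[[genes[j]]])) > 0) {
          hits <- hits + 1
        }
      }
    }
    vals <- c(vals, hits / (nk * (nk - 1)))
  }
  mean(vals)
}

# Wang S-values by explicit path enumeration: S_T(t) is the maximum over all
# directed child-to-parent paths from T to t of the product of relation
# weights along the path.
oracle_wang_svalues <- function(dag, term) {
  w <- c(is_a = 0.8, part_of = 0.6)
  best <- new.env()
  rec <- function(t, val) {
    cur <- get0(t, envir = best, ifnotfound = -Inf)
    if (val > cur) assign(t, val, envir = best)
    pp <- dag$parents[[t]]
    if (!is.null(pp)) {
      for (r in seq_len(nrow(pp))) {
        rec(pp$parent[r], val * w[[pp$relation[r]]])
      }
    }
  }
  rec(term, 1)
  unlist(as.list(best))
}

oracle_wang_term_sim <- function(dag, a, b) {
  sa <- oracle_wang_svalues(dag, a)
  sb <- oracle_wang_svalues(dag, b)
  shared <- intersect(names(sa), names(sb))
  sum(sa[shared] + sb[shared]) / (sum(sa) + sum(sb))
}

oracle_wang_gene_sim <- function(dag, ann, ga, gb, ns = "BP") {
  ta <- ann$gene2terms[[ns]][[ga]]
  tb <- ann$gene2terms[[ns]][[gb]]
  m <- outer(ta, tb, Vectorize(function(x, y) oracle_wang_term_sim(dag, x, y)))
  m <- matrix(m, length(ta), length(tb))
  (sum(apply(m, 1, max)) + sum(apply(m, 2, max))) / (length(ta) + length(tb))
}

# Benjamini-Hochberg step-up from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Hypergeometric upper tail P(X >= k) by direct summation of the pmf.
oracle_hyper_tail <- function(overlap, set_size, universe_size, query_size) {
  ks <- overlap:min(set_size, query_size)
  sum(choose(set_size, ks) * choose(universe_size - set_size,
                                    query_size - ks)) /
    choose(universe_size, query_size)
}

# --- fixtures -------------------------------------------------------------

# Two disjoint triangles {a,b,c} and {d,e,f}, unit weights.
two_triangles <- function() {
  el <- data.frame(from = c("a", "a", "b", "d", "d", "e"),
                   to = c("b", "c", "c", "e", "f", "f"),
                   weight = 1)
  as_functional_network(igraph::graph_from_data_frame(el, directed = FALSE))
}

triangle_partition <- function() {
  partition(c(a = 1, b = 1, c = 1, d = 2, e = 2, f = 2))
}

# Random weighted graph with guaranteed >= 1 edge.
rand_net <- function(n = 10, p = 0.35, seed = 1) {
  set.seed(seed)
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::ecount(g) > 0 && min(igraph::degree(g)) > 0) break
  }
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  igraph::E(g)$weight <- stats::runif(igraph::ecount(g), 0.1, 1)
  as_functional_network(g)
}

rand_partition <- function(nodes, k = 3, seed = 1) {
  set.seed(seed)
  partition(stats::setNames(sample.int(k, length(nodes), replace = TRUE),
                            nodes))
}

# Small random layered DAG (one namespace) plus diversified annotations.
rand_dag_ann <- function(seed = 1, n_terms = 12, n_genes = 15,
                         p_home = 0.3) {
  cfg <- sim_config(n_genes = n_genes,
                    modules = list(planted_module(
                      default_gene_ids_test(n_genes)[1:2])),
                    n_samples_per_batch = c(4L, 4L),
                    ontology = list(n_terms = n_terms, depth = 3L,
                                    p_home = p_home, p_second = 0.5),
                    seed = seed)
  simulate_ontology(cfg)
}

default_gene_ids_test <- function(n) sprintf("g%05d", seq_len(n))

# Tiny expression matrix built by hand.
toy_expression <- function(values, phenotype = NULL, batch = NULL) {
  n <- ncol(values)
  if (is.null(colnames(values))) colnames(values) <- sprintf("s%02d",
                                                             seq_len(n))
  if (is.null(rownames(values))) rownames(values) <- sprintf("g%03d",
                                                             seq_len(nrow(values)))
  if (is.null(phenotype)) phenotype <- rep(c("normal", "polyp"), length.out = n)
  if (is.null(batch)) batch <- rep("b1", n)
  expression_matrix(values, data.frame(sample_id = colnames(values),
                                       phenotype = phenotype, batch = batch,
                                       stringsAsFactors = FALSE))
}

# Reference synthetic configuration of the study conditions.
reference_config <- function(seed = 7L) sim_config(seed = seed)

# Validation cohorts emulating the two independent validation sets
# (67 = 38 normal + 29 polyp; 106 = 55 normal + 51 polyp), one batch each.
validation_configs <- function(seed = 7L) {
  list(
    cohortA = sim_config(n_samples_per_batch = 67L,
                         phenotype_balance = 29 / 67,
                         seed = seed + 1000L),
    cohortB = sim_config(n_samples_per_batch = 106L,
                         phenotype_balance = 51 / 106,
                         seed = seed + 2000L)
  )
}
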