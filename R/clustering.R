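#' Build a partition object
#'
#' A partition maps every node of a graph to exactly one cluster, with
#' cluster ids renumbered densely 1..K (by decreasing cluster size, ties by
#' smallest member id).
#'
#' @param membership Named integer/character vector node -> cluster.
#' @param algorithm Character tag of the producing algorithm.
#' @param params List of parameters used.
#' @return Named integer vector of class `partition` with attributes
#'   `algorithm` and `params`.
#' @export
partition <- function(membership, algorithm = "manual", params = list()) {
  stopifnot(!is.null(names(membership)), !anyDuplicated(names(membership)))
  raw <- as.character(membership)
  names(raw) <- names(membership)
  dense <- relabel_by_size(stats::setNames(raw, names(membership)),
                           min_size = 1L)
  structure(dense, algorithm = algorithm, params = params,
            class = "partition")
}

#' Number of clusters in a partition
#' @param part A `partition`.
#' @return Integer count of clusters.
#' @export
n_clusters <- function(part) length(unique(unclass(part)))

check_partition_covers <- function(net, part) {
  if (!setequal(names(part), igraph::V(net)$name)) {
    stop("partition must cover exactly the nodes of the graph")
  }
}

# Relabel vertex ids so vertices are ordered by name: clustering output then
# depends only on the graph, not on the construction order of its edge list.
canonical_network <- function(net) {
  nm <- igraph::V(net)$name
  if (is.unsorted(nm)) {
    net <- igraph::permute(net, match(nm, sort(nm)))
  }
  net
}

#' Markov clustering (MCL)
#'
#' Flow simulation on the column-stochastic transition matrix of the weighted
#' graph with self-loops (loop weight = the node's maximum incident edge
#' weight, 1 for isolated nodes). Each iteration expands (matrix power),
#' inflates (elementwise power with column renormalization) and prunes small
#' entries, until the matrix change falls below `tol` or `max_iter` is
#' reached. Clusters are read off the attractor structure of the limit
#' matrix: each attractor row spans one cluster, overlapping attractor
#' systems are merged, and a node reachable from several attractor systems is
#' assigned to the lowest cluster id.
#'
#' @param net A `functional_network`.
#' @param inflation Inflation exponent (> 1; pipeline default 1.2).
#' @param expansion Expansion power (integer >= 2, default 2).
#' @param prune_threshold Entries below this are zeroed each iteration.
#' @param max_iter Maximum iterations.
#' @param tol Convergence tolerance on the maximum absolute matrix change.
#' @return A `partition`; attribute `converged` reports convergence (a
#'   warning is raised when the iteration limit is hit).
#' @export
mcl <- function(net, inflation = 1.2, expansion = 2L, prune_threshold = 1e-5,
                max_iter = 200L, tol = 1e-6) {
  if (inflation <= 1) stop("inflation must be > 1")
  if (expansion < 2) stop("expansion must be an integer >= 2")
  net <- canonical_network(net)
  nodes <- igraph::V(net)$name
  n <- length(nodes)
  w <- igraph::as_adjacency_matrix(net, attr = "weight", sparse = FALSE)
  loop <- apply(w, 1, max)
  loop[loop == 0] <- 1
  diag(w) <- loop
  m <- sweep(w, 2, colSums(w), "/")
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    prev <- m
    for (e in seq_len(expansion - 1L)) m <- m %*% prev  # m = prev^expansion
    m <- m^inflation
    m <- sweep(m, 2, colSums(m), "/")
    m[m < prune_threshold] <- 0
    cs <- colSums(m)
    cs[cs == 0] <- 1
    m <- sweep(m, 2, cs, "/")
    if (max(abs(m - prev)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("MCL did not converge within ", max_iter,
            " iterations; interpreting the current matrix")
  }
  memb <- interpret_mcl(m, nodes)
  part <- partition(memb, "mcl",
                    list(inflation = inflation, expansion = expansion,
                         prune_threshold = prune_threshold, tol = tol))
  attr(part, "converged") <- converged
  part
}

# Clusters from an MCL limit matrix: attractor rows (positive diagonal) span
# clusters; overlapping attractor supports are unioned; remaining nodes go to
# the lowest cluster that claims them.
interpret_mcl <- function(m, nodes) {
  n <- length(nodes)
  eps <- 1e-9
  attractors <- which(diag(m) > eps)
  if (!length(attractors)) attractors <- which(rowSums(m) > eps)
  supports <- lapply(attractors, function(i) which(m[i, ] > eps))
  # union-find over attractors with overlapping supports
  comp <- seq_along(supports)
  find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
  if (length(supports) > 1) {
    claimed <- integer(n)
    for (s in seq_along(supports)) {
      for (v in supports[[s]]) {
        if (claimed[v] == 0) claimed[v] <- s
        else comp[find(s)] <- find(claimed[v])
      }
    }
  }
  roots <- vapply(seq_along(supports), find, integer(1))
  memb <- rep(NA_integer_, n)
  for (s in order(roots)) {
    take <- supports[[s]]
    memb[take[is.na(memb[take])]] <- roots[s]
  }
  memb[is.na(memb)] <- max(roots, 0L) + seq_len(sum(is.na(memb)))
  stats::setNames(memb, nodes)
}

#' Select the MCL inflation by maximum modularity
#'
#' Runs [mcl()] over a grid of inflation values and keeps the partition with
#' the highest (binary) modularity — the selection procedure used to fix the
#' inflation operator on real data.
#'
#' @param net A `functional_network`.
#' @param inflations Numeric grid of inflation values to test.
#' @param ... Further arguments passed to [mcl()].
#' @return The best `partition`; attributes `inflation` and `modularity`
#'   record the winning value and score.
#' @export
mcl_select_inflation <- function(net, inflations = c(1.2, 1.4, 1.6, 2, 2.5, 3),
                                 ...) {
  best <- NULL
  best_q <- -Inf
  best_i <- NA_real_
  for (infl in inflations) {
    p <- suppressWarnings(mcl(net, inflation = infl, ...))
    q <- if (n_clusters(p) >= 1 && igraph::ecount(net) > 0) {
      modularity_q(net, p)
    } else -Inf
    if (q > best_q) {
      best_q <- q
      best <- p
      best_i <- infl
    }
  }
  attr(best, "inflation") <- best_i
  attr(best, "modularity") <- best_q
  best
}

#' Greedy modularity community detection
#'
#' Newman-style agglomerative modularity maximization on the weighted graph:
#' communities are merged greedily while modularity improves, and the
#' partition at maximum modularity is returned (via
#' [igraph::cluster_fast_greedy()]). An edgeless graph yields the singleton
#' partition with a warning.
#'
#' @param net A `functional_network`.
#' @return A `partition` with attribute `modularity` (the weighted modularity
#'   of the returned partition).
#' @export
fn_cluster <- function(net) {
  net <- canonical_network(net)
  nodes <- igraph::V(net)$name
  if (igraph::ecount(net) == 0) {
    warning("edgeless graph: every node is its own cluster (Q = 0)")
    part <- partition(stats::setNames(seq_along(nodes), nodes), "fn")
    attr(part, "modularity") <- 0
    return(part)
  }
  cm <- igraph::cluster_fast_greedy(net, weights = igraph::E(net)$weight)
  # cut the merge tree at the modularity-maximizing number of communities
  n_comm <- length(nodes) - which.max(cm$modularity) + 1L
  memb <- igraph::cut_at(cm, no = n_comm)
  part <- partition(stats::setNames(memb, nodes), "fn")
  attr(part, "modularity") <- max(cm$modularity)
  part
}

#' Spectral clustering with precomputed affinity
#'
#' The weighted adjacency matrix is used as the affinity; the bottom `k`
#' eigenvectors of the symmetric normalized Laplacian are discretized into
#' labels with the deterministic rotation-based procedure (seeded, default
#' seed 0). A disconnected graph is clustered per component, with `k`
#' apportioned by component size.
#'
#' @param net A `functional_network`.
#' @param k Number of clusters (>= 2, <= node count).
#' @param seed Integer seed for the discretization initialization.
#' @return A `partition`.
#' @export
spectral_cluster <- function(net, k, seed = 0L) {
  n <- igraph::vcount(net)
  if (k > n) stop("k must not exceed the node count")
  if (k < 2) stop("k must be >= 2")
  net <- canonical_network(net)
  nodes <- igraph::V(net)$name
  if (k == n) {
    return(partition(stats::setNames(seq_len(n), nodes), "spectral",
                     list(k = k, seed = seed)))
  }
  cmp <- igraph::components(net)
  if (cmp$no > 1) {
    sizes <- cmp$csize
    if (k <= cmp$no) {
      # fewer clusters than components: the k-1 largest components keep their
      # own cluster, the rest share the last one
      ord <- order(-sizes)
      cl_of_comp <- integer(cmp$no)
      cl_of_comp[ord] <- pmin(seq_len(cmp$no), k)
      return(partition(stats::setNames(cl_of_comp[cmp$membership], nodes),
                       "spectral", list(k = k, seed = seed)))
    }
    # apportion k by component size (each component gets >= 1)
    alloc <- pmax(1L, round(k * sizes / sum(sizes)))
    while (sum(alloc) > k) {
      i <- order(-alloc)[1]
      alloc[i] <- alloc[i] - 1L
    }
    while (sum(alloc) < k) {
      i <- which.max(sizes / alloc)
      alloc[i] <- alloc[i] + 1L
    }
    memb <- stats::setNames(rep(NA_character_, n), nodes)
    for (i in seq_len(cmp$no)) {
      sub_nodes <- nodes[cmp$membership == i]
      sub <- igraph::induced_subgraph(net, sub_nodes)
      if (alloc[i] == 1 || length(sub_nodes) <= alloc[i]) {
        lab <- stats::setNames(
          if (alloc[i] == 1) rep(1L, length(sub_nodes))
          else seq_along(sub_nodes), sub_nodes)
      } else {
        lab <- spectral_cluster(as_functional_network(sub), alloc[i], seed)
      }
      memb[sub_nodes] <- paste0("c", i, "_", unclass(lab))
    }
    return(partition(memb, "spectral", list(k = k, seed = seed)))
  }
  w <- igraph::as_adjacency_matrix(net, attr = "weight", sparse = FALSE)
  d <- rowSums(w)
  d[d == 0] <- 1
  dm <- 1 / sqrt(d)
  sym <- dm * sweep(w, 2, dm, "*")  # D^-1/2 W D^-1/2
  es <- eigen((sym + t(sym)) / 2, symmetric = TRUE)
  x <- es$vectors[, seq_len(k), drop = FALSE]
  labels <- with_seed(seed, discretize_eigenvectors(x))
  partition(stats::setNames(labels, nodes), "spectral",
            list(k = k, seed = seed))
}

# Rotation-based discretization of spectral embeddings (Yu & Shi): find the
# rotation R that makes X R closest to a cluster indicator matrix, assigning
# each row to its argmax column.
discretize_eigenvectors <- function(x, max_iter = 30L, tol = 1e-8) {
  n <- nrow(x); k <- ncol(x)
  norms <- sqrt(rowSums(x^2))
  norms[norms == 0] <- 1
  xn <- x / norms
  # initialize R from rows spread as far apart as possible
  r <- matrix(0, k, k)
  first <- sample.int(n, 1)
  r[, 1] <- xn[first, ]
  c_acc <- rep(0, n)
  for (j in seq_len(k - 1)) {
    c_acc <- c_acc + abs(xn %*% r[, j])
    r[, j + 1] <- xn[which.min(c_acc), ]
  }
  last_obj <- -Inf
  labels <- NULL
  for (it in seq_len(max_iter)) {
    y <- xn %*% r
    labels <- max.col(y, ties.method = "first")
    ind <- matrix(0, n, k)
    ind[cbind(seq_len(n), labels)] <- 1
    sv <- svd(t(xn) %*% ind)
    obj <- sum(sv$d)
    if (abs(obj - last_obj) < tol) break
    last_obj <- obj
    r <- sv$u %*% t(sv$v)
  }
  labels
}
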