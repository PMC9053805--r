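test_that("modularity closed forms hold", {
  g <- two_triangles()
  # single community: Q = 0
  one <- partition(stats::setNames(rep(1L, 6), igraph::V(g)$name))
  expect_equal(modularity_q(g, one), 0)
  g2 <- rand_net(12, 0.3, seed = 2)
  one2 <- partition(stats::setNames(rep(1L, 12), igraph::V(g2)$name))
  expect_equal(modularity_q(g2, one2), 0)
  # two disjoint triangles under the true split: (12 - 6) / 12
  expect_equal(modularity_q(g, triangle_partition()), 0.5)
  empty <- as_functional_network(
    igraph::make_empty_graph(2, directed = FALSE) |>
      igraph::set_vertex_attr("name", value = c("a", "b")))
  expect_error(modularity_q(empty, partition(c(a = 1, b = 1))), "m = 0")
})

test_that("modularity matches the double-loop oracle on random instances", {
  for (s in 1:40) {
    g <- rand_net(n = sample(5:14, 1), p = 0.4, seed = s)
    p <- rand_partition(igraph::V(g)$name, k = sample(2:4, 1), seed = s + 100)
    expect_equal(modularity_q(g, p),
                 oracle_modularity(g, unclass(p)), tolerance = 1e-12)
    expect_equal(modularity_q(g, p, weighted = TRUE),
                 oracle_modularity(g, unclass(p), weighted = TRUE),
                 tolerance = 1e-12)
  }
})

test_that("singleton-partition modularity equals -sum(k_i^2)/(2m)^2", {
  for (s in 1:5) {
    g <- rand_net(10, 0.4, seed = s)
    singles <- partition(stats::setNames(1:10, igraph::V(g)$name))
    k <- igraph::degree(g)
    expect_equal(modularity_q(g, singles),
                 -sum(k^2) / sum(k)^2, tolerance = 1e-12)
  }
})

test_that("silhouette closed form: two disjoint triangles score 5/6", {
  g <- two_triangles()
  s <- silhouette_index(g, triangle_partition())
  # a = 1, b = 6 (disconnected pairs at d = n = 6): (6 - 1)/6
  expect_equal(unname(s$s_i), rep(5 / 6, 6), tolerance = 1e-12)
  expect_equal(s$s_u, 5 / 6, tolerance = 1e-12)
})

test_that("silhouette conventions: singletons zero, K >= 2 required, range", {
  g <- two_triangles()
  singles <- partition(stats::setNames(1:6, igraph::V(g)$name))
  s <- silhouette_index(g, singles)
  expect_equal(s$s_u, 0)
  one <- partition(stats::setNames(rep(1L, 6), igraph::V(g)$name))
  expect_error(silhouette_index(g, one), ">= 2")
  for (s_ in 1:10) {
    g2 <- rand_net(n = sample(6:12, 1), p = 0.3, seed = s_)
    p2 <- rand_partition(igraph::V(g2)$name, k = 3, seed = s_)
    if (n_clusters(p2) < 2) next
    si <- silhouette_index(g2, p2)
    expect_true(all(si$s_i >= -1 & si$s_i <= 1))
    expect_equal(si$s_u, oracle_silhouette(g2, unclass(p2)),
                 tolerance = 1e-12)
  }
})

test_that("BHI closed forms and oracle agreement", {
  # all genes share one class: BHI = 1 for any partition
  classes1 <- list(root = sprintf("g%02d", 1:9))
  p <- rand_partition(sprintf("g%02d", 1:9), k = 3, seed = 1)
  expect_equal(bhi(p, classes1), 1)
  # one cluster with classes {X, X, Y}: 2 of 6 ordered pairs match
  classes2 <- list(X = c("a", "b"), Y = "c")
  p2 <- partition(c(a = 1, b = 1, c = 1))
  expect_equal(bhi(p2, classes2), 1 / 3, tolerance = 1e-12)
  # unannotated genes are excluded; underfilled clusters skipped
  p3 <- partition(c(a = 1, b = 1, c = 1, d = 2, e = 3))
  expect_equal(bhi(p3, classes2), 1 / 3, tolerance = 1e-12)
  expect_error(bhi(partition(c(a = 1, d = 2)), classes2), "annotated")
  # random instances against the ordered-pair oracle
  for (s in 1:30) {
    set.seed(s)
    genes <- sprintf("g%02d", 1:12)
    classes <- lapply(1:4, function(i) sample(genes, sample(2:6, 1)))
    names(classes) <- paste0("C", 1:4)
    memb <- stats::setNames(sample.int(3, 12, replace = TRUE), genes)
    gene_classes <- split(rep(names(classes), lengths(classes)),
                          unlist(classes))
    expect_equal(bhi(partition(memb), classes),
                 oracle_bhi(memb, gene_classes), tolerance = 1e-12)
  }
})

test_that("Wang term similarity: identity, siblings, symmetry", {
  dag <- ontology_dag(data.frame(
    child = c("BP:0001", "BP:0002"),
    parent = c("BP:0000", "BP:0000"),
    relation = "is_a", stringsAsFactors = FALSE))
  expect_equal(wang_term_similarity(dag, "BP:0001", "BP:0001"), 1)
  # siblings: S = {self: 1, root: 0.8}, SV = 1.8; shared root only
  expect_equal(wang_term_similarity(dag, "BP:0001", "BP:0002"),
               (0.8 + 0.8) / (1.8 + 1.8), tolerance = 1e-12)
  expect_equal(wang_term_similarity(dag, "BP:0001", "BP:0002"), 0.4444,
               tolerance = 1e-3)
})

test_that("Wang similarity matches the path-enumeration oracle", {
  for (s in 1:12) {
    on <- rand_dag_ann(seed = s, n_terms = 14, n_genes = 10)
    terms <- sample(on$dag$terms$term[on$dag$terms$namespace == "BP"], 4)
    for (i in 1:3) {
      expect_equal(wang_term_similarity(on$dag, terms[i], terms[i + 1]),
                   oracle_wang_term_sim(on$dag, terms[i], terms[i + 1]),
                   tolerance = 1e-12)
      # symmetry
      expect_equal(wang_term_similarity(on$dag, terms[i], terms[i + 1]),
                   wang_term_similarity(on$dag, terms[i + 1], terms[i]),
                   tolerance = 1e-12)
    }
    genes <- names(on$annotations$gene2terms$BP)[1:4]
    expect_equal(wang_gene_similarity(on$dag, on$annotations, genes[1],
                                      genes[2]),
                 oracle_wang_gene_sim(on$dag, on$annotations, genes[1],
                                      genes[2]), tolerance = 1e-12)
    # self-similarity of a gene is 1
    expect_equal(wang_gene_similarity(on$dag, on$annotations, genes[3],
                                      genes[3]), 1, tolerance = 1e-12)
  }
  on <- rand_dag_ann(seed = 99)
  expect_error(wang_gene_similarity(on$dag, on$annotations, "nope",
                                    "nope2"), "not annotated")
})

test_that("partition reports carry consistent per-submodule metrics", {
  gid <- default_gene_ids_test(60)
  cfg <- sim_config(n_genes = 60,
                    modules = list(planted_module(gid[1:30]),
                                   planted_module(gid[31:60])),
                    n_samples_per_batch = c(10L, 10L),
                    network = list(p_within = 0.4, p_between = 0.02),
                    seed = 8L)
  sim <- simulate_all(cfg)
  em <- drop_unannotated_and_aggregate(sim$probes, sim$metadata)
  degs <- suppressWarnings(differential_expression(em))
  part <- fn_cluster(sim$network)
  rep_ <- evaluate_partition(sim$network, part, sim$annotations, sim$dag,
                             degs)
  expect_s3_class(rep_$submodules, "data.frame")
  expect_equal(sum(rep_$submodules$size), igraph::vcount(sim$network))
  expect_true(all(rep_$submodules$bhi >= 0 & rep_$submodules$bhi <= 1,
                  na.rm = TRUE))
  expect_true(all(rep_$submodules$wang_bp >= 0 &
                    rep_$submodules$wang_bp <= 1, na.rm = TRUE))
  expect_gte(rep_$q, -0.5)
  expect_lte(rep_$q, 1)
  # per-submodule BHI equals the standalone single-cluster restriction
  memb <- unclass(part)
  classes <- annotation_gene_sets(sim$annotations, "BP")
  cl <- rep_$submodules$cluster[which.max(rep_$submodules$annotated_size)]
  genes <- names(memb)[memb == cl]
  solo <- partition(stats::setNames(rep(1L, length(genes)), genes))
  expect_equal(rep_$submodules$bhi[rep_$submodules$cluster == cl],
               bhi(solo, classes), tolerance = 1e-12)
  # DEG counts equal a set-intersection oracle
  up <- degs$gene_id[degs$direction == "up"]
  down <- degs$gene_id[degs$direction == "down"]
  for (i in seq_len(nrow(rep_$submodules))) {
    genes_i <- names(memb)[memb == rep_$submodules$cluster[i]]
    expect_equal(rep_$submodules$n_up[i], length(intersect(genes_i, up)))
    expect_equal(rep_$submodules$n_down[i],
                 length(intersect(genes_i, down)))
  }
})
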