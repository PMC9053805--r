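small_config <- function(seed = 3L, ...) {
  gid <- default_gene_ids_test(120)
  sim_config(n_genes = 120,
             modules = list(
               planted_module(gid[1:20], de_genes = gid[1:10]),
               planted_module(gid[21:40], de_genes = gid[21:30])),
             n_samples_per_batch = c(12L, 12L),
             network = list(bg_community_size = 40),
             seed = seed, ...)
}

test_that("identical config and seed give byte-identical artifacts", {
  a <- simulate_all(small_config())
  b <- simulate_all(small_config())
  expect_identical(a$probes, b$probes)
  expect_identical(a$metadata, b$metadata)
  expect_identical(network_edges(a$network), network_edges(b$network))
  expect_identical(a$dag$edges, b$dag$edges)
  expect_identical(a$annotations$table, b$annotations$table)
  c <- simulate_all(small_config(seed = 4L))
  expect_false(identical(a$probes$values, c$probes$values))
})

test_that("written simulation files are deterministic and complete", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_simulation(simulate_all(small_config()), d1)
  p2 <- write_simulation(simulate_all(small_config()), d2)
  expect_true(all(file.exists(p1)))
  for (k in names(p1)) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]), label = k)
  }
})

test_that("planted modules show higher within- than between-module correlation", {
  gid <- default_gene_ids_test(300)
  cfg <- sim_config(n_genes = 300,
                    modules = list(planted_module(gid[1:50]),
                                   planted_module(gid[51:100])),
                    n_samples_per_batch = c(30L, 30L),
                    batch_shift_sd = 0, batch_scale_sd = 0,
                    seed = 11L)
  co <- simulate_cohort(cfg)
  x <- co$truth$gene_values
  cc <- cor(t(x))
  m1 <- gid[1:50]; m2 <- gid[51:100]; bg <- gid[101:300]
  within1 <- mean(abs(cc[m1, m1][upper.tri(cc[m1, m1])]))
  within2 <- mean(abs(cc[m2, m2][upper.tri(cc[m2, m2])]))
  between <- mean(abs(cc[m1, m2]))
  background <- mean(abs(cc[m1, bg]))
  expect_gt(within1, between)
  expect_gt(within2, between)
  expect_gt(between, background)  # shared phenotype factor couples modules
})

test_that("marginals resemble log2 intensities and samples match metadata", {
  co <- simulate_cohort(small_config())
  expect_true(all(is.finite(co$probes$values)))
  expect_identical(colnames(co$probes$values), co$metadata$sample_id)
  med <- median(co$probes$values)
  expect_gt(med, 2)
  expect_lt(med, 14)
  # ~5% of probes are unannotated
  frac_na <- mean(is.na(co$probes$annotation$gene_id))
  expect_gt(frac_na, 0.02)
  expect_lt(frac_na, 0.08)
})

test_that("without batch effects, per-batch gene means differ only by noise", {
  gid <- default_gene_ids_test(500)
  cfg <- sim_config(n_genes = 500, modules = list(),
                    n_samples_per_batch = c(50L, 50L),
                    batch_shift_sd = 0, batch_scale_sd = 0, seed = 5L)
  co <- simulate_cohort(cfg)
  x <- co$truth$gene_values
  b <- co$metadata$batch
  p <- apply(x, 1, function(row) {
    t.test(row[b == "batch1"], row[b == "batch2"], var.equal = TRUE)$p.value
  })
  expect_lt(mean(p < 0.05), 0.10)
})

test_that("module members outside the gene universe are a configuration error", {
  expect_error(
    sim_config(n_genes = 10,
               modules = list(planted_module(c("g00001", "zzz"))),
               n_samples_per_batch = c(4L, 4L)),
    "outside the gene universe")
})

test_that("planted-partition network has the promised structure", {
  gid <- default_gene_ids_test(60)
  cfg <- sim_config(n_genes = 60,
                    modules = list(planted_module(gid[1:30]),
                                   planted_module(gid[31:60])),
                    n_samples_per_batch = c(6L, 6L),
                    network = list(p_within = 0.5, p_between = 0.01),
                    seed = 2L)
  nt <- simulate_network(cfg)
  g <- nt$network
  w <- igraph::E(g)$weight
  expect_true(all(w > 0 & w <= 1))
  expect_false(igraph::any_loop(g))
  expect_false(igraph::any_multiple(g))
  truth <- nt$truth$communities[igraph::V(g)$name]
  expect_gt(oracle_modularity(g, truth), 0.3)
})

test_that("degenerate edge probabilities are rejected", {
  expect_error(
    sim_config(network = list(p_within = 0.1, p_between = 0.1)),
    "must exceed")
})

test_that("emitted DAG is acyclic, rooted, with valid relations", {
  on <- rand_dag_ann(seed = 9, n_terms = 20, n_genes = 25)
  dag <- on$dag
  g <- igraph::graph_from_data_frame(dag$edges[, c("child", "parent")],
                                     directed = TRUE)
  expect_true(igraph::is_dag(g))
  expect_true(all(dag$edges$relation %in% c("is_a", "part_of")))
  for (ns in c("BP", "MF")) {
    terms_ns <- dag$terms$term[dag$terms$namespace == ns]
    non_root <- setdiff(terms_ns, dag$roots[[ns]])
    expect_true(all(non_root %in% dag$edges$child))
  }
  # every annotated gene maps to >= 1 existing term
  expect_true(all(on$annotations$table$term_id %in% dag$terms$term))
})

test_that("community genes are functionally closer than cross-community genes", {
  gid <- default_gene_ids_test(40)
  cfg <- sim_config(n_genes = 40,
                    modules = list(planted_module(gid[1:20]),
                                   planted_module(gid[21:40])),
                    n_samples_per_batch = c(4L, 4L),
                    ontology = list(n_terms = 25L, depth = 3L),
                    seed = 13L)
  nt <- simulate_network(cfg)
  on <- simulate_ontology(cfg, nt$truth)
  comm <- nt$truth$communities
  c1 <- sample(names(comm)[comm == 1], 6)
  c2 <- sample(names(comm)[comm == 2], 6)
  sim_within <- mean(vapply(1:5, function(i)
    oracle_wang_gene_sim(on$dag, on$annotations, c1[i], c1[i + 1]),
    numeric(1)))
  sim_between <- mean(vapply(1:5, function(i)
    oracle_wang_gene_sim(on$dag, on$annotations, c1[i], c2[i]), numeric(1)))
  expect_gt(sim_within, sim_between)
})

test_that("a single-term ontology annotates everything to the root, BHI 1", {
  gid <- default_gene_ids_test(12)
  cfg <- sim_config(n_genes = 12, modules = list(planted_module(gid[1:6])),
                    n_samples_per_batch = c(4L, 4L),
                    ontology = list(n_terms = 1L), seed = 1L)
  on <- simulate_ontology(cfg)
  expect_true(all(on$annotations$table$term_id %in% on$dag$roots))
  part <- rand_partition(gid, k = 3, seed = 2)
  expect_equal(bhi(part, annotation_gene_sets(on$annotations, "BP")), 1)
})
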