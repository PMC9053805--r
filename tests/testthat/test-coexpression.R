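# Two well-separated planted modules: independent latent factors, no
# phenotype coupling, low noise.
separable_cohort <- function(seed = 17L, n_genes = 200) {
  gid <- default_gene_ids_test(n_genes)
  size <- max(10, round(n_genes / 5))
  cfg <- sim_config(n_genes = n_genes,
                    modules = list(
                      planted_module(gid[seq_len(size)], eigen_effect = 0,
                                     loading_range = c(0.8, 1)),
                      planted_module(gid[(size + 1):(2 * size)],
                                     eigen_effect = 0,
                                     loading_range = c(0.8, 1))),
                    n_samples_per_batch = c(30L, 30L),
                    batch_shift_sd = 0, batch_scale_sd = 0,
                    noise_sd = 0.6, seed = seed)
  co <- simulate_cohort(cfg)
  list(em = expression_matrix(co$truth$gene_values, co$metadata),
       truth = co$truth$gene_module)
}

test_that("soft-threshold selection follows the scale-free criterion", {
  sc <- separable_cohort()
  ps <- suppressWarnings(
    pick_soft_threshold(sc$em, candidates = 1:8, r2_cut = 0.8))
  expect_s3_class(ps, "power_selection")
  expect_true(ps$power %in% 1:8)
  # mean connectivity decreases monotonically in the power
  expect_true(all(diff(ps$table$mean_k) < 0))
  # forced choice when the cut is unreachable by construction
  forced <- suppressWarnings(
    pick_soft_threshold(sc$em, candidates = 1, r2_cut = -1))
  expect_equal(forced$power, 1)
})

test_that("constant gene rows are rejected", {
  sc <- separable_cohort()
  sc$em$values[3, ] <- 7
  expect_error(pick_soft_threshold(sc$em, candidates = 2),
               "constant gene rows")
  expect_error(tom_from_expression(sc$em, 2), "constant gene rows")
})

test_that("TOM matches hand-evaluated cases", {
  # adjacency power: cor 0.5 at beta 8
  expect_equal(0.5^8, 0.00390625)
  # three genes, all pairwise adjacency 1: TOM = (1*1 + 1)/(2 + 1 - 1) = 1
  a <- matrix(1, 3, 3) - diag(3)
  dimnames(a) <- list(letters[1:3], letters[1:3])
  tom <- tom_from_adjacency(a)
  expect_equal(unname(tom["a", "b"]), 1)
  expect_equal(diag(tom), c(a = 1, b = 1, c = 1))
  # no direct link, no shared neighbours -> overlap 0
  b <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  b["a", "b"] <- b["b", "a"] <- 1
  b["c", "d"] <- b["d", "c"] <- 1
  tom2 <- tom_from_adjacency(b)
  expect_equal(unname(tom2["a", "c"]), 0)
})

test_that("TOM is symmetric, bounded, and invariant to gene scaling", {
  sc <- separable_cohort(seed = 19L, n_genes = 60)
  tom <- tom_from_expression(sc$em, 4)
  expect_true(isSymmetric(unname(tom)))
  expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  scaled <- sc$em
  scaled$values <- scaled$values * 3.7
  expect_equal(tom_from_expression(scaled, 4), tom, tolerance = 1e-12)
})

test_that("well-separated planted modules are recovered by the tree cut", {
  sc <- separable_cohort()
  tom <- tom_from_expression(sc$em, 6)
  labels <- detect_modules(tom, min_module_size = 20, cut_height = 0.99)
  expect_setequal(names(labels), rownames(tom))
  expect_gte(ari(labels, sc$truth[names(labels)]), 0.8)
  expect_equal(length(unique(labels[labels > 0])), 2)
})

test_that("degenerate cuts behave as documented", {
  sc <- separable_cohort(seed = 23L, n_genes = 40)
  tom <- tom_from_expression(sc$em, 4)
  all_in_one <- detect_modules(tom, min_module_size = 2, cut_height = 1.5)
  expect_equal(unique(unname(all_in_one)), 1L)
  expect_error(detect_modules(tom, min_module_size = 1), "min_module_size")
  # equal dissimilarities: permutation changes nothing up to relabelling
  flat <- matrix(0.5, 10, 10,
                 dimnames = list(sprintf("g%02d", 1:10),
                                 sprintf("g%02d", 1:10)))
  diag(flat) <- 1
  l1 <- detect_modules(flat, min_module_size = 2, cut_height = 0.4)
  perm <- sample(10)
  l2 <- detect_modules(flat[perm, perm], min_module_size = 2,
                       cut_height = 0.4)
  expect_equal(ari(l1, l2[names(l1)]), 1)
})

test_that("eigengenes are first principal components with positive orientation", {
  # rank-1 module: identical rows
  profile <- c(1, 4, 2, 8, 5, 7)
  vals <- rbind(g1 = profile, g2 = profile, g3 = profile,
                g4 = rnorm(6), g5 = rnorm(6))
  em <- toy_expression(vals)
  labels <- c(g1 = 1L, g2 = 1L, g3 = 1L, g4 = 0L, g5 = 0L)
  me <- module_eigengenes(em, labels)
  expect_equal(nrow(me), 1)
  expect_equal(sum(me[1, ]^2), 1)
  expect_equal(abs(cor(me[1, ], profile)), 1, tolerance = 1e-10)
  expect_true(all(cor(me[1, ], t(em$values[1:3, ])) > 0.999))
  # sign-flipping all member genes does not flip the oriented eigengene sign
  # convention (orientation is re-derived from the members)
  flipped <- em
  flipped$values[1:3, ] <- -flipped$values[1:3, ]
  me2 <- module_eigengenes(flipped, labels)
  expect_true(mean(cor(me2[1, ], t(flipped$values[1:3, ]))) > 0)
  expect_error(module_eigengenes(em, c(g1 = 1L, g2 = 0L, g3 = 0L,
                                       g4 = 0L, g5 = 0L)),
               "fewer than 2")
})

test_that("the first component explains at least as much variance as the second", {
  sc <- separable_cohort(seed = 29L, n_genes = 60)
  labels <- stats::setNames(rep(c(1L, 2L, 0L), c(12, 12, 36)),
                            rownames(sc$em$values))
  me <- module_eigengenes(sc$em, labels)
  ve <- attr(me, "var_explained")
  for (m in c(1, 2)) {
    genes <- names(labels)[labels == m]
    x <- t(scale(t(sc$em$values[genes, ])))
    sv <- svd(x)
    expect_gte(sv$d[1], sv$d[2])
    expect_equal(unname(ve[paste0("ME", m)]),
                 sv$d[1]^2 / sum(sv$d^2), tolerance = 1e-10)
  }
})

test_that("module merging honours the eigengene-correlation threshold", {
  set.seed(7)
  n <- 40
  f1 <- rnorm(n)
  f2 <- 0.95 * f1 + sqrt(1 - 0.95^2) * rnorm(n)  # cor ~ 0.95 -> merge
  f3 <- rnorm(n)                                  # cor ~ 0   -> keep
  mk <- function(f, k) t(vapply(seq_len(k), function(i)
    f + rnorm(n, 0, 0.3), numeric(n)))
  vals <- rbind(mk(f1, 10), mk(f2, 10), mk(f3, 10))
  rownames(vals) <- sprintf("g%03d", 1:30)
  em <- toy_expression(vals)
  labels <- stats::setNames(rep(1:3, each = 10), rownames(vals))
  merged <- merge_close_modules(em, labels, merge_height = 0.25)
  expect_equal(merged$cor_threshold, 0.75)
  expect_equal(length(unique(merged$labels[merged$labels > 0])), 2)
  # the two correlated blocks ended up together, the third alone
  expect_equal(length(unique(merged$labels[1:20])), 1)
  expect_false(merged$labels[1] == merged$labels[25])
  # merge_height 0 is the identity
  same <- merge_close_modules(em, labels, merge_height = 0)
  expect_equal(length(unique(same$labels)), 3)
})

test_that("module-trait correlation matches the closed-form t-test", {
  set.seed(11)
  n <- 6
  me <- matrix(rnorm(2 * n), 2, n,
               dimnames = list(c("ME1", "ME2"), sprintf("s%d", 1:n)))
  md <- data.frame(sample_id = colnames(me),
                   phenotype = c("normal", "normal", "normal",
                                 "polyp", "polyp", "polyp"),
                   batch = "b1", stringsAsFactors = FALSE)
  res <- module_trait_select(me, md, r_threshold = 0.3)
  z <- c(0, 0, 0, 1, 1, 1)
  for (i in 1:2) {
    r_direct <- sum((me[i, ] - mean(me[i, ])) * (z - mean(z))) /
      sqrt(sum((me[i, ] - mean(me[i, ]))^2) * sum((z - mean(z))^2))
    t_direct <- r_direct * sqrt((n - 2) / (1 - r_direct^2))
    p_direct <- 2 * pt(-abs(t_direct), n - 2)
    expect_equal(res$table$r[i], r_direct, tolerance = 1e-12)
    expect_equal(res$table$p[i], p_direct, tolerance = 1e-12)
  }
  # an eigengene equal to the phenotype indicator is selected with r = 1
  me2 <- rbind(ME1 = z + 0)
  colnames(me2) <- colnames(me)
  res2 <- module_trait_select(me2, md)
  expect_equal(res2$table$r, 1)
  expect_true(res2$table$selected)
  # |r| at the threshold is not selected (strict inequality)
  res3 <- module_trait_select(me, md, r_threshold = abs(res$table$r[1]))
  expect_false(res3$table$selected[1])
})

test_that("labels always partition the genes", {
  sc <- separable_cohort(seed = 31L, n_genes = 80)
  tom <- tom_from_expression(sc$em, 5)
  labels <- detect_modules(tom, min_module_size = 10)
  expect_equal(sort(names(labels)), sort(rownames(tom)))
  expect_false(any(is.na(labels)))
})
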