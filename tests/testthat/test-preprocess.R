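toy_probes <- function() {
  vals <- matrix(c(1, 10,
                   3, 12,
                   5, 14,
                   2, 20,
                   4, 22,
                   9, 90,
                   8, 80), ncol = 2, byrow = TRUE,
                 dimnames = list(sprintf("p%d", 1:7), c("s1", "s2")))
  ann <- data.frame(probe_id = sprintf("p%d", 1:7),
                    gene_id = c("gA", "gA", "gA", "gB", "gB", NA, "gC"),
                    stringsAsFactors = FALSE)
  probe_matrix(vals, ann)
}

toy_meta <- data.frame(sample_id = c("s1", "s2"),
                       phenotype = c("normal", "polyp"),
                       batch = "b1", stringsAsFactors = FALSE)

test_that("probe aggregation takes medians and drops NA probes", {
  em <- drop_unannotated_and_aggregate(toy_probes(), toy_meta)
  expect_identical(rownames(em$values), c("gA", "gB", "gC"))
  expect_equal(em$values["gA", "s1"], 3)    # odd count: middle of {1,3,5}
  expect_equal(em$values["gB", "s1"], 3)    # even count: mean of {2,4}
  expect_equal(em$values["gA", "s2"], 12)
  # single-probe gene passes through unchanged (idempotence)
  expect_equal(em$values["gC", ], c(s1 = 8, s2 = 80))
})

test_that("a fully unannotated probe matrix is an error", {
  pm <- toy_probes()
  pm$annotation$gene_id <- NA_character_
  expect_error(drop_unannotated_and_aggregate(pm, toy_meta),
               "unannotated")
})

test_that("output gene count equals distinct annotated genes", {
  set.seed(1)
  vals <- matrix(rnorm(10 * 3, 8), 10, 3,
                 dimnames = list(sprintf("p%02d", 1:10),
                                 sprintf("s%d", 1:3)))
  ann <- data.frame(probe_id = rownames(vals),
                    gene_id = c("g1", "g2", NA, "g2", NA, "g3", NA, "g4",
                                NA, "g1"), stringsAsFactors = FALSE)
  md <- data.frame(sample_id = colnames(vals),
                   phenotype = c("normal", "normal", "polyp"), batch = "b1",
                   stringsAsFactors = FALSE)
  em <- drop_unannotated_and_aggregate(probe_matrix(vals, ann), md)
  expect_equal(nrow(em$values), 4)
})

make_em <- function(genes, samples, prefix, batch, seed = 1) {
  set.seed(seed)
  vals <- matrix(rnorm(length(genes) * samples, 8), length(genes), samples,
                 dimnames = list(genes, paste0(prefix, seq_len(samples))))
  expression_matrix(vals, data.frame(
    sample_id = colnames(vals),
    phenotype = rep(c("normal", "polyp"), length.out = samples),
    batch = batch, stringsAsFactors = FALSE))
}

test_that("cohort assembly intersects genes and concatenates samples", {
  a <- make_em(c("a", "b", "c"), 4, "A", "dsA", seed = 1)
  b <- make_em(c("b", "c", "d"), 6, "B", "dsB", seed = 2)
  merged <- assemble_cohort(list(dsA = a, dsB = b))
  expect_identical(rownames(merged$values), c("b", "c"))
  expect_equal(ncol(merged$values), 10)
  expect_identical(unique(merged$metadata$batch), c("dsA", "dsB"))
  # single input is the identity
  solo <- assemble_cohort(list(a))
  expect_identical(solo$values, a$values)
})

test_that("assembly rejects duplicate sample ids and empty intersections", {
  a <- make_em(c("a", "b"), 4, "S", "dsA")
  b <- make_em(c("a", "b"), 4, "S", "dsB")
  expect_error(assemble_cohort(list(dsA = a, dsB = b)), "duplicate sample")
  c2 <- make_em(c("x", "y"), 4, "C", "dsC")
  expect_error(assemble_cohort(list(dsA = a, dsC = c2)), "intersection")
})

test_that("batch correction preconditions: single batch, singleton batch, zero variance", {
  a <- make_em(sprintf("g%02d", 1:20), 6, "A", "b1")
  expect_error(combat_adjust(a), ">= 2 batches")
  b <- make_em(sprintf("g%02d", 1:20), 1, "B", "b2")
  b$metadata$phenotype <- "normal"
  ab <- assemble_cohort(list(b1 = a, b2 = b))
  expect_error(combat_adjust(ab), "single sample.*b2")
  d <- make_em(sprintf("g%02d", 1:20), 6, "D", "b2")
  abd <- assemble_cohort(list(b1 = a, b2 = d))
  abd$values["g01", ] <- 5
  expect_error(combat_adjust(abd), "zero-variance.*g01")
})

test_that("heterogeneous batch shifts are removed to near the location oracle", {
  set.seed(21)
  ng <- 300; n <- 20
  base <- matrix(rnorm(ng * 2 * n, 8, 1), ng, 2 * n,
                 dimnames = list(sprintf("g%03d", 1:ng),
                                 sprintf("s%02d", 1:(2 * n))))
  shift <- rnorm(ng, 0, 0.8)
  vals <- base
  vals[, (n + 1):(2 * n)] <- vals[, (n + 1):(2 * n)] + shift
  md <- data.frame(sample_id = colnames(vals),
                   phenotype = rep(rep(c("normal", "polyp"), each = n / 2), 2),
                   batch = rep(c("A", "B"), each = n),
                   stringsAsFactors = FALSE)
  em <- expression_matrix(vals, md)
  emc <- combat_adjust(em)
  expect_identical(dim(emc$values), dim(vals))
  expect_identical(colnames(emc$values), colnames(vals))
  gap_pre <- rowMeans(vals[, 1:n]) - rowMeans(vals[, (n + 1):(2 * n)])
  gap_post <- rowMeans(emc$values[, 1:n]) -
    rowMeans(emc$values[, (n + 1):(2 * n)])
  # empirical-Bayes shrinkage removes most but not all of the shift: the
  # residual is about (1 - w) of the per-gene deviation plus estimation
  # noise, so require at least 70% removal
  expect_lt(mean(abs(gap_post)), 0.3 * mean(abs(gap_pre)))
  # location-only oracle: remove per-batch gene means, restore grand mean
  oracle <- vals
  for (b in c("A", "B")) {
    cols <- md$batch == b
    oracle[, cols] <- vals[, cols] - rowMeans(vals[, cols]) + rowMeans(vals)
  }
  expect_lt(mean(abs(emc$values - oracle)), 0.15)
})

test_that("batch-only null: post-correction batch means are indistinguishable", {
  gid <- default_gene_ids_test(400)
  cfg <- sim_config(n_genes = 400, modules = list(),
                    n_samples_per_batch = c(25L, 25L, 25L),
                    batch_shift_sd = 0.8, batch_scale_sd = 0.2, seed = 31L)
  co <- simulate_cohort(cfg)
  em <- expression_matrix(co$truth$gene_values, co$metadata)
  emc <- combat_adjust(em)
  b <- factor(emc$metadata$batch)
  p <- apply(emc$values, 1, function(row) {
    anova(lm(row ~ b))[["Pr(>F)"]][1]
  })
  expect_lte(mean(p < 0.05), 0.05)
})

test_that("correction with no batch effect leaves the matrix nearly unchanged", {
  gid <- default_gene_ids_test(200)
  cfg <- sim_config(n_genes = 200, modules = list(),
                    n_samples_per_batch = c(20L, 20L),
                    batch_shift_sd = 0, batch_scale_sd = 0,
                    noise_sd = 1, seed = 41L)
  co <- simulate_cohort(cfg)
  em <- expression_matrix(co$truth$gene_values, co$metadata)
  emc <- combat_adjust(em)
  rms_change <- sqrt(rowMeans((emc$values - em$values)^2))
  expect_true(all(rms_change < 1))  # below the per-gene noise SD
})

test_that("balanced designs preserve the planted phenotype effect within 10%", {
  gid <- default_gene_ids_test(300)
  cfg <- sim_config(n_genes = 300,
                    modules = list(planted_module(
                      gid[1:40], eigen_effect = 0.5,
                      de_genes = gid[1:40], de_lfc = -1.5)),
                    n_samples_per_batch = c(30L, 30L),
                    batch_shift_sd = 0.8, batch_scale_sd = 0.2, seed = 51L)
  co <- simulate_cohort(cfg)
  em <- expression_matrix(co$truth$gene_values, co$metadata)
  emc <- combat_adjust(em)
  z <- em$metadata$phenotype == "polyp"
  lfc <- function(m) rowMeans(m[, z]) - rowMeans(m[, !z])
  de <- gid[1:40]
  eff_pre <- mean(lfc(em$values)[de])
  eff_post <- mean(lfc(emc$values)[de])
  expect_lt(abs(eff_post - eff_pre) / abs(eff_pre), 0.1)
})
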